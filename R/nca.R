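#' @title Non-compartmental analysis of breath washout curves
#' @description Helpers operating on a single subject's washout curve: a data
#'   frame with columns `timepoint_min` and `limonene_ng` (optionally
#'   `censored`), timepoints strictly increasing, amounts positive. `t = 0` is
#'   the pre-dose baseline and never enters peak finding or the terminal fit.
#' @name nca-curve
NULL

check_curve <- function(curve) {
  if (!is.data.frame(curve) ||
      !all(c("timepoint_min", "limonene_ng") %in% names(curve))) {
    stop_invalid("a washout curve needs columns `timepoint_min` and `limonene_ng`")
  }
  curve <- arrange(as_tibble(curve), .data$timepoint_min)
  if (any(duplicated(curve$timepoint_min))) {
    stop_invalid("duplicate timepoints in washout curve")
  }
  if (any(!is.finite(curve$limonene_ng)) || any(curve$limonene_ng <= 0)) {
    stop_invalid("amounts must be positive and finite")
  }
  curve
}

#' Peak breath amount and its time
#'
#' Maximum observed post-dose amount (`Cmax`) and the sampling time at which
#' it occurs (`Tmax`). The baseline sample is excluded; ties go to the
#' earliest time.
#'
#' @param curve A washout curve (see [nca-curve]).
#' @return One-row tibble with `cmax_ng` and `tmax_min`.
#' @examples
#' compute_cmax_tmax(tibble::tibble(timepoint_min = c(0, 20, 40, 60),
#'                                  limonene_ng = c(2, 600, 500, 300)))
#' @export
compute_cmax_tmax <- function(curve) {
  curve <- check_curve(curve)
  post <- filter(curve, .data$timepoint_min > 0)
  if (nrow(post) == 0) stop_insufficient("no post-dose observations")
  i <- which.max(post$limonene_ng)  # which.max takes the first maximum: earliest tie
  tibble(cmax_ng = post$limonene_ng[i], tmax_min = post$timepoint_min[i])
}

#' Terminal log-linear washout fit
#'
#' Ordinary least squares of `log(amount)` on time using every post-dose
#' observation from `Tmax` (inclusive) onward. Under first-order elimination
#' this line has slope `-ke`; its intercept extrapolated to `t = 0` is the
#' terminal-phase intercept `C0` on the log scale. The coefficient of
#' determination screens subjects whose washout is not single-phase
#' log-linear (`r_squared <= 0.8` by convention in downstream summaries).
#'
#' @param curve A washout curve (see [nca-curve]).
#' @param log_base Base of the logarithm for the fit and the reported
#'   intercept. Natural log by default; the slope in base `b` is the natural
#'   slope divided by `log(b)`.
#' @return One-row tibble with `slope_per_min` (negative under washout),
#'   `c0_log` (intercept at `t = 0`, log scale), `r_squared` and
#'   `n_fit_points`.
#' @examples
#' tt <- c(0, 20, 40, 60, 90, 120)
#' fit_terminal_slope(tibble::tibble(timepoint_min = tt,
#'                                   limonene_ng = c(2, 1000 * exp(-0.025 * tt[-1]))))
#' @export
fit_terminal_slope <- function(curve, log_base = exp(1)) {
  curve <- check_curve(curve)
  peak <- compute_cmax_tmax(curve)
  fitpts <- filter(curve, .data$timepoint_min >= peak$tmax_min,
                   .data$timepoint_min > 0)
  if (nrow(fitpts) < 3) {
    stop_insufficient(sprintf(
      "terminal fit needs >= 3 points from Tmax onward, have %d", nrow(fitpts)))
  }
  x <- fitpts$timepoint_min
  y <- log(fitpts$limonene_ng, base = log_base)
  fit <- lm(y ~ x)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss <= .Machine$double.eps) as.numeric(rss <= 1e-12) else 1 - rss / tss
  tibble(slope_per_min = unname(coef(fit)[2]),
         c0_log = unname(coef(fit)[1]),
         r_squared = min(max(r2, 0), 1),
         n_fit_points = nrow(fitpts))
}

#' Linear trapezoidal area under the washout curve
#'
#' Integrates the observed amounts over `[t_start, t_end]` by the linear
#' trapezoid rule. If a window endpoint falls between two observations its
#' value is linearly interpolated from the flanking observations before
#' integration, so the result is additive over sub-intervals split at
#' observed timepoints. LOQ-imputed baselines participate at their imputed
#' value.
#'
#' @param curve A washout curve (see [nca-curve]).
#' @param t_start,t_end Integration window in minutes (default 0–90).
#' @return AUC in ng·min per 400 mL sample.
#' @examples
#' trapezoid_auc(tibble::tibble(timepoint_min = c(0, 20, 40, 60, 90),
#'                              limonene_ng = c(1e-9, 100, 80, 60, 30) + 1e-12))
#' @export
trapezoid_auc <- function(curve, t_start = 0, t_end = 90) {
  curve <- check_curve(curve)
  if (t_end <= t_start) stop_invalid_param("`t_end` must exceed `t_start`")
  tt <- curve$timepoint_min
  if (min(tt) > t_start || max(tt) < t_end) {
    stop_invalid(sprintf(
      "observations do not span [%g, %g]; AUC incomplete", t_start, t_end),
      class = "breathkin_incomplete_window")
  }
  ends <- approx(tt, curve$limonene_ng, xout = c(t_start, t_end))$y
  inside <- tt > t_start & tt < t_end
  x <- c(t_start, tt[inside], t_end)
  y <- c(ends[1], curve$limonene_ng[inside], ends[2])
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Per-subject kinetic parameters for a washout table
#'
#' Runs the non-compartmental analysis ([compute_cmax_tmax()],
#' [fit_terminal_slope()], [trapezoid_auc()]) on every subject of a
#' long-format washout table. Subjects whose curve cannot support a given
#' parameter (too few terminal points, or samples not spanning the AUC
#' window) get `NA` for that parameter and are reported, not dropped.
#'
#' @param washout Long table with columns `subject_id`, `group`,
#'   `timepoint_min`, `limonene_ng` (as produced by [simulate_cohort()] or
#'   [read_washout_csv()]).
#' @param t_end End of the AUC window in minutes (default 90).
#' @param log_base Base for the terminal fit (see [fit_terminal_slope()]).
#' @return A tibble with one row per subject: `subject_id`, `group`,
#'   `cmax_ng`, `tmax_min`, `slope_per_min`, `c0_log`, `r_squared`,
#'   `n_fit_points`, `half_life_min` (`log(2)/-slope`), `auc_0_90`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_control = 3, n_cirrhosis = 3, seed = 2))
#' nca(cohort$washout)
#' @export
nca <- function(washout, t_end = 90, log_base = exp(1)) {
  need <- c("subject_id", "group", "timepoint_min", "limonene_ng")
  if (!all(need %in% names(washout))) {
    stop_invalid(sprintf("washout table needs columns %s",
                         paste(need, collapse = ", ")))
  }
  washout %>%
    group_by(.data$subject_id, .data$group) %>%
    dplyr::group_modify(function(curve, key) {
      peak <- tryCatch(compute_cmax_tmax(curve), breathkin_error = function(e) NULL)
      term <- tryCatch(fit_terminal_slope(curve, log_base = log_base),
                       breathkin_error = function(e) NULL)
      auc <- tryCatch(trapezoid_auc(curve, 0, t_end),
                      breathkin_error = function(e) NA_real_)
      tibble(
        cmax_ng = if (is.null(peak)) NA_real_ else peak$cmax_ng,
        tmax_min = if (is.null(peak)) NA_real_ else peak$tmax_min,
        slope_per_min = if (is.null(term)) NA_real_ else term$slope_per_min,
        c0_log = if (is.null(term)) NA_real_ else term$c0_log,
        r_squared = if (is.null(term)) NA_real_ else term$r_squared,
        n_fit_points = if (is.null(term)) NA_integer_ else term$n_fit_points,
        half_life_min = if (is.null(term)) NA_real_ else log(2) / -term$slope_per_min,
        auc_0_90 = auc)
    }) %>%
    ungroup()
}

#' Group summary of kinetic parameters
#'
#' Median and interquartile range per group for `Cmax`, the terminal
#' intercept, AUC and slope, with two-sided Mann–Whitney group comparisons,
#' plus a `Tmax` frequency table. Slope and intercept summaries are restricted
#' to subjects whose terminal fit passed the log-linearity screen
#' (`r_squared > r2_threshold`); level parameters (Cmax, AUC) keep everyone.
#'
#' @param kinetics Output of [nca()] with a `group` column (2 levels).
#' @param r2_threshold Log-linearity screen for slope/intercept summaries
#'   (default 0.8).
#' @return A `kinetics_summary`: list of tibbles `stats` (parameter, group, n,
#'   median, q25, q75), `tests` (parameter, U statistic, p_value, method) and
#'   `tmax_counts` (group, tmax_min, n, pct), plus `n_low_r2`.
#' @export
summarize_kinetics <- function(kinetics, r2_threshold = 0.8) {
  if (!all(c("group") %in% names(kinetics))) stop_invalid("`kinetics` needs a `group` column")
  counts <- table(kinetics$group)
  if (length(counts) != 2) stop_invalid("exactly two groups are required")
  if (any(counts < 2)) {
    stop_invalid(sprintf("each group needs >= 2 subjects (have %s)",
                         paste(counts, collapse = "/")))
  }
  params <- c("cmax_ng", "c0_log", "auc_0_90", "slope_per_min")
  restricted <- c("c0_log", "slope_per_min")
  ok_fit <- !is.na(kinetics$r_squared) & kinetics$r_squared > r2_threshold

  one_param <- function(p) {
    d <- if (p %in% restricted) kinetics[ok_fit, ] else kinetics
    d <- d[!is.na(d[[p]]), ]
    d %>% group_by(.data$group) %>%
      summarise(n = n(), median = median(.data[[p]]),
                q25 = unname(quantile(.data[[p]], 0.25)),
                q75 = unname(quantile(.data[[p]], 0.75)), .groups = "drop") %>%
      mutate(parameter = p, .before = 1)
  }
  stats_tbl <- bind_rows(lapply(params, one_param))

  gl <- names(counts)
  one_test <- function(p) {
    d <- if (p %in% restricted) kinetics[ok_fit, ] else kinetics
    a <- d[[p]][d$group == gl[1] & !is.na(d[[p]])]
    b <- d[[p]][d$group == gl[2] & !is.na(d[[p]])]
    res <- mann_whitney_u(a, b)
    tibble(parameter = p, statistic = res$statistic,
           p_value = res$p_value, method = res$method)
  }
  tests_tbl <- bind_rows(lapply(params, one_test))

  tmax_tbl <- kinetics %>%
    filter(!is.na(.data$tmax_min)) %>%
    dplyr::count(.data$group, .data$tmax_min) %>%
    group_by(.data$group) %>%
    mutate(pct = 100 * n / sum(n)) %>%
    ungroup()

  structure(list(stats = stats_tbl, tests = tests_tbl,
                 tmax_counts = tmax_tbl,
                 n_low_r2 = sum(!ok_fit & !is.na(kinetics$r_squared)),
                 r2_threshold = r2_threshold),
            class = "kinetics_summary")
}

#' @export
print.kinetics_summary <- function(x, ...) {
  cat("Washout kinetic parameters by group (median [IQR])\n")
  wide <- x$stats %>%
    mutate(cell = sprintf("%.4g [%.4g-%.4g]", .data$median, .data$q25, .data$q75)) %>%
    select("parameter", "group", "cell") %>%
    tidyr::pivot_wider(names_from = "group", values_from = "cell") %>%
    left_join(select(x$tests, "parameter", "p_value"), by = "parameter")
  print.data.frame(as.data.frame(wide), row.names = FALSE)
  cat(sprintf("slope/intercept rows restricted to terminal-fit R^2 > %.2g (%d excluded)\n",
              x$r2_threshold, x$n_low_r2))
  cat("Tmax distribution:\n")
  print.data.frame(as.data.frame(x$tmax_counts), row.names = FALSE)
  invisible(x)
}
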