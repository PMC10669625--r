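#' Mann–Whitney U test (two-sided)
#'
#' Rank-sum comparison of two samples. The U statistic is computed from
#' mid-ranks. The two-sided p-value is exact (full null enumeration of rank
#' allocations) when the pooled sample is small (`n1 + n2 <= exact_cutoff`)
#' and tie-free; otherwise the normal approximation with tie and continuity
#' corrections is used.
#'
#' @param a,b Numeric samples (non-empty).
#' @param exact_cutoff Largest pooled size for the exact route (default 16).
#' @return One-row tibble: `statistic` (U for sample `a`), `p_value`,
#'   `method` (`"exact"` or `"normal-approx"`), `n1`, `n2`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(a, b, exact_cutoff = 16) {
  if (length(a) == 0 || length(b) == 0) stop_invalid("both samples must be non-empty")
  if (!is.numeric(a) || !is.numeric(b) || any(!is.finite(c(a, b)))) {
    stop_invalid("samples must be finite numeric")
  }
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0
  if (length(unique(c(a, b))) == 1L) {            # degenerate: everything tied
    return(tibble(statistic = u, p_value = 1, method = "normal-approx",
                  n1 = n1, n2 = n2))
  }
  if (!ties && n1 + n2 <= exact_cutoff) {
    p <- wilcox.test(a, b, exact = TRUE)$p.value
    method <- "exact"
  } else {
    p <- wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    method <- "normal-approx"
  }
  tibble(statistic = u, p_value = min(p, 1), method = method, n1 = n1, n2 = n2)
}

#' Random-intercept linear mixed model
#'
#' Fits `response ~ fixed terms + (1 | subject)` by maximum likelihood
#' (ML by default rather than REML, so Wald tests and likelihood comparisons
#' are coherent). This is the confounder-check machinery for longitudinal
#' washout data: repeated breath samples per subject are correlated, and a
#' subject-level random intercept absorbs that correlation.
#'
#' @param data A data frame containing all model variables.
#' @param formula Fixed-effects formula, e.g.
#'   `log(limonene_ng) ~ group + age + factor(timepoint_min)`.
#' @param subject Name of the subject-id column (default `"subject_id"`).
#' @param reml Use REML instead of ML.
#' @return A `breath_lmm`: list with `fixed_effects` (term, estimate,
#'   std_error, z, p_value), `var_random_intercept`, `var_residual`,
#'   `loglik`, `n_obs`, `n_subjects`, and the underlying `lme4` fit.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_control = 6, n_cirrhosis = 6, seed = 3))
#' d <- dplyr::left_join(cohort$washout, cohort$subjects,
#'                       by = c("subject_id", "group"))
#' fit <- random_intercept_lmm(d, log(limonene_ng) ~ group + age)
#' tidy(fit)
#' @export
random_intercept_lmm <- function(data, formula, subject = "subject_id",
                                 reml = FALSE) {
  if (!subject %in% names(data)) {
    stop_invalid(sprintf("column `%s` not found", subject))
  }
  ids <- data[[subject]]
  if (length(unique(ids)) < 2) stop_insufficient("need >= 2 subjects")
  mf <- stats::model.frame(formula, data = data)
  X <- stats::model.matrix(formula, mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_invalid(sprintf("singular fixed-effects design; offending column(s): %s",
                         paste(bad, collapse = ", ")),
                 class = "breathkin_singular_design")
  }
  full <- stats::update(formula,
                        paste(". ~ . +", sprintf("(1 | %s)", subject)))
  fit <- suppressMessages(lme4::lmer(full, data = data, REML = reml))
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  z <- est / se
  fe <- tibble(term = names(est), estimate = unname(est),
               std_error = unname(se), z = unname(z),
               p_value = 2 * pnorm(-abs(unname(z))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    fixed_effects = fe,
    var_random_intercept = vc$vcov[vc$grp == subject][1],
    var_residual = vc$vcov[vc$grp == "Residual"][1],
    loglik = as.numeric(logLik(fit)),
    n_obs = nrow(mf), n_subjects = length(unique(ids)),
    reml = reml, model = fit), class = "breath_lmm")
}

#' @export
print.breath_lmm <- function(x, ...) {
  cat(sprintf("Random-intercept LMM (%s), %d obs / %d subjects\n",
              if (x$reml) "REML" else "ML", x$n_obs, x$n_subjects))
  print.data.frame(as.data.frame(x$fixed_effects), row.names = FALSE)
  cat(sprintf("var(intercept) = %.4g, var(residual) = %.4g, logLik = %.2f\n",
              x$var_random_intercept, x$var_residual, x$loglik))
  invisible(x)
}

#' @method tidy breath_lmm
#' @export
tidy.breath_lmm <- function(x, ...) x$fixed_effects

#' @method glance breath_lmm
#' @export
glance.breath_lmm <- function(x, ...) {
  tibble(var_random_intercept = x$var_random_intercept,
         var_residual = x$var_residual, loglik = x$loglik,
         n_obs = x$n_obs, n_subjects = x$n_subjects)
}

#' Age-confounding check for washout levels
#'
#' Fits the random-intercept model
#' `log(limonene_ng) ~ group + age + factor(timepoint_min)` on post-dose
#' samples, one random intercept per subject. A non-significant age
#' coefficient indicates that the group difference in breath levels is not
#' explained by the age imbalance between groups.
#'
#' @param washout,subjects Tables as produced by [simulate_cohort()].
#' @param reml Use REML instead of ML.
#' @return A `breath_lmm` (see [random_intercept_lmm()]); the age row of
#'   `tidy()` carries the confounder p-value.
#' @export
age_confounder_check <- function(washout, subjects, reml = FALSE) {
  d <- washout %>%
    filter(.data$timepoint_min > 0) %>%
    left_join(select(subjects, "subject_id", "age"), by = "subject_id")
  random_intercept_lmm(d, log(limonene_ng) ~ group + age + factor(timepoint_min),
                       reml = reml)
}

#' Compare bioavailability by a clinical flag within the cirrhosis group
#'
#' Mann–Whitney comparison of AUC between flag-positive and flag-negative
#' cirrhosis subjects, for flags that proxy portal hypertension
#' (`portal_htn`, `thrombocytopenia` i.e. platelets < 150e9/L, `splenomegaly`
#' i.e. spleen > 12 cm).
#'
#' @param kinetics Output of [nca()].
#' @param subjects Subject metadata table containing the flag column.
#' @param flag One of `"portal_htn"`, `"thrombocytopenia"`, `"splenomegaly"`.
#' @param group Group within which to compare (default `"cirrhosis"`).
#' @return One-row tibble: flag, per-level n / median / IQR of `auc_0_90`,
#'   U statistic and two-sided p-value.
#' @export
compare_auc_by_flag <- function(kinetics, subjects,
                                flag = c("portal_htn", "thrombocytopenia",
                                         "splenomegaly"),
                                group = "cirrhosis") {
  flag <- match.arg(flag)
  d <- kinetics %>%
    left_join(select(subjects, "subject_id", all_of(flag)), by = "subject_id") %>%
    filter(.data$group == !!group, !is.na(.data$auc_0_90), !is.na(.data[[flag]]))
  pos <- d$auc_0_90[d[[flag]]]
  neg <- d$auc_0_90[!d[[flag]]]
  if (length(pos) == 0 || length(neg) == 0) {
    stop_invalid(sprintf("flag `%s` has a single level within group `%s`",
                         flag, group))
  }
  res <- mann_whitney_u(pos, neg)
  tibble(flag = flag,
         n_present = length(pos), n_absent = length(neg),
         median_present = median(pos),
         q25_present = unname(quantile(pos, 0.25)),
         q75_present = unname(quantile(pos, 0.75)),
         median_absent = median(neg),
         q25_absent = unname(quantile(neg, 0.25)),
         q75_absent = unname(quantile(neg, 0.75)),
         statistic = res$statistic, p_value = res$p_value,
         method = res$method)
}
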