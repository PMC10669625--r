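#' One-compartment oral-dose breath amount (Bateman function)
#'
#' Amount of probe recovered in a standardized breath sample at time `t` after
#' an oral dose, under first-order absorption and elimination:
#' `scale * f_sys * dose * ka/(ka-ke) * (exp(-ke*t) - exp(-ka*t))`.
#' After absorption is complete this decays mono-exponentially at rate `ke`,
#' i.e. the washout is log-linear. When `ka` and `ke` coincide to within a
#' relative tolerance of 1e-8 the degenerate limit
#' `scale * f_sys * dose * ka * t * exp(-ka*t)` is used.
#'
#' @param t Time since dosing, minutes (vectorized, >= 0).
#' @param dose Oral dose, ng.
#' @param f_sys Systemic availability, fraction in \[0, 1\]
#'   (see [systemic_availability()]).
#' @param ka,ke First-order absorption / elimination rates, 1/min (> 0).
#' @param scale Dimensionless blood-to-breath scaling of the sampled amount.
#' @return Amounts in ng (>= 0), same length as `t`.
#' @examples
#' bateman_amount(c(0, 20, 90), dose = 1e8, f_sys = 0.1, ka = 0.1, ke = 0.027,
#'                scale = 1e-4)
#' @export
bateman_amount <- function(t, dose, f_sys, ka, ke, scale = 1) {
  for (nm in c("dose", "f_sys", "ka", "ke", "scale")) assert_scalar_num(get(nm), nm)
  if (!is.numeric(t) || any(!is.finite(t))) stop_invalid_param("`t` must be finite numeric")
  if (any(t < 0)) stop_invalid_param("`t` must be >= 0")
  if (ka <= 0 || ke <= 0) stop_invalid_param("rates `ka` and `ke` must be > 0")
  if (f_sys < 0 || f_sys > 1) stop_invalid_param("`f_sys` must lie in [0, 1]")
  if (abs(ka - ke) <= 1e-8 * max(ka, ke)) {
    out <- scale * f_sys * dose * ka * t * exp(-ka * t)
  } else {
    out <- scale * f_sys * dose * ka / (ka - ke) * (exp(-ke * t) - exp(-ka * t))
  }
  pmax(out, 0)
}

# closed-form integral of bateman_amount over [t1, t2] (same limit branch)
bateman_auc_exact <- function(t1, t2, dose, f_sys, ka, ke, scale = 1) {
  k <- scale * f_sys * dose
  if (abs(ka - ke) <= 1e-8 * max(ka, ke)) {
    prim <- function(t) -k * exp(-ka * t) * (ka * t + 1) / ka
  } else {
    prim <- function(t) k * ka / (ka - ke) * (-exp(-ke * t) / ke + exp(-ka * t) / ka)
  }
  prim(t2) - prim(t1)
}

#' Systemic availability under the well-stirred hepatic first-pass model
#'
#' For a high-extraction (flow-limited) probe the fraction reaching the
#' systemic circulation is set by hepatic extraction and portosystemic
#' shunting: extraction is `E = cl/(1+cl)` where `cl` is the
#' intrinsic-clearance-to-flow ratio, and the shunted fraction bypasses the
#' liver entirely, giving `f_abs * (shunt + (1-shunt) * (1-E))`. Availability
#' therefore rises with shunt and falls with intrinsic clearance — the
#' mechanism by which cirrhosis raises breath levels of the probe without
#' changing its elimination slope.
#'
#' @param f_abs Fraction absorbed from the gut, in \[0, 1\].
#' @param cl_int_rel Intrinsic-clearance-to-flow ratio (>= 0); vectorized.
#' @param shunt Portosystemic shunt fraction in \[0, 1\]; vectorized.
#' @return Systemic availability, fraction in \[0, 1\].
#' @examples
#' systemic_availability(1, cl_int_rel = 9, shunt = 0)    # healthy: 0.1
#' systemic_availability(1, cl_int_rel = 3, shunt = 0.25) # cirrhosis-like
#' @export
systemic_availability <- function(f_abs, cl_int_rel, shunt) {
  if (any(!is.finite(f_abs)) || any(f_abs < 0) || any(f_abs > 1)) {
    stop_invalid_param("`f_abs` must lie in [0, 1]")
  }
  if (any(!is.finite(shunt)) || any(shunt < 0) || any(shunt > 1)) {
    stop_invalid_param("`shunt` must lie in [0, 1]")
  }
  if (any(!is.finite(cl_int_rel)) || any(cl_int_rel < 0)) {
    stop_invalid_param("`cl_int_rel` must be >= 0")
  }
  extraction <- cl_int_rel / (1 + cl_int_rel)
  f_abs * (shunt + (1 - shunt) * (1 - extraction))
}

#' Impute values below the limit of quantification
#'
#' Bioanalytical convention for this assay: a measurable but non-quantifiable
#' signal is approximated to the limit of quantification rather than dropped
#' or zeroed, and flagged as censored.
#'
#' @param value Measured amounts, ng (vectorized, >= 0).
#' @param loq Limit of quantification, ng (> 0).
#' @return A tibble with columns `value` (imputed amounts) and `censored`.
#' @examples
#' apply_loq(c(0.5, 1.18, 2.0), loq = 1.18)
#' @export
apply_loq <- function(value, loq) {
  assert_scalar_num(loq, "loq")
  if (loq <= 0) stop_invalid_param("`loq` must be > 0")
  if (!is.numeric(value) || any(!is.finite(value)) || any(value < 0)) {
    stop_invalid("`value` must be non-negative finite numeric")
  }
  censored <- value < loq
  tibble(value = ifelse(censored, loq, value), censored = censored)
}

#' Simulate a breath-washout cohort
#'
#' Generates a two-group cohort (healthy controls and cirrhosis) of timed
#' breath measurements plus clinical metadata, with the mechanistic structure
#' of a dynamic volatile-probe breath test:
#'
#' * each subject's washout follows [bateman_amount()] with a subject-level
#'   absorption rate, an elimination rate drawn from the same distribution in
#'   both groups, and a systemic availability from
#'   [systemic_availability()] — cirrhosis subjects draw a latent disease
#'   severity that raises shunt and lowers intrinsic clearance, so their
#'   availability (and hence intercept, Cmax and AUC) is stochastically
#'   larger while the washout slope distribution is unchanged;
#' * the pre-dose baseline is log-normal (higher in cirrhosis, reflecting
#'   impaired clearance of dietary exposure) and LOQ-censored via
#'   [apply_loq()];
#' * post-dose samples are signal plus baseline carryover times multiplicative
#'   log-normal noise, then LOQ-censored;
#' * MELD/FIB4/APRI track `ln AUC` in the cirrhosis group through
#'   `score_coupling` (strongest for MELD) and are independent of AUC in
#'   controls; platelets, spleen length and the portal-hypertension flag are
#'   driven by the same latent severity, so thrombocytopenia
#'   (platelets < 150) and splenomegaly (spleen > 12 cm) co-segregate with
#'   bioavailability;
#' * scheduled samples go missing completely at random at `missing_rate`.
#'
#' The generator is fully deterministic for a fixed `config$seed` (the global
#' RNG state is left untouched).
#'
#' @param config A [sim_config()].
#' @return An object of class `breath_cohort`: a list with tibbles
#'   `subjects` (one row per subject: demographics, labs, scores, flags),
#'   `washout` (one row per retained subject-timepoint: `subject_id`, `group`,
#'   `timepoint_min`, `limonene_ng`, `censored`), and `truth` (the latent
#'   per-subject parameters: `ka`, `ke`, `cl_int_rel`, `shunt`, `f_sys`,
#'   `baseline_true_ng`, `auc_true_0_90`, `severity`), plus the `config`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_control = 4, n_cirrhosis = 4, seed = 7))
#' cohort$washout
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) config <- validate_sim_config(config)
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  groups <- c(control = cfg$n_control, cirrhosis = cfg$n_cirrhosis)
  subj <- purrr::imap(names(groups), function(g, i) {
    simulate_group_subjects(g, groups[[g]], cfg)
  }) %>% bind_rows()

  # washout rows: baseline is the drawn pre-dose level; post-dose adds the
  # Bateman signal to the baseline carryover under multiplicative noise
  sdlog_noise <- sqrt(log(1 + cfg$noise_cv^2))
  washout <- tidyr::crossing(subject_id = subj$subject_id,
                             timepoint_min = cfg$timepoints_min) %>%
    left_join(subj %>% select("subject_id", "group", ".ka", ".ke", ".f_sys", ".baseline"),
              by = "subject_id") %>%
    arrange(.data$subject_id, .data$timepoint_min)
  signal <- purrr::pmap_dbl(
    list(washout$timepoint_min, washout$.f_sys, washout$.ka, washout$.ke),
    function(t, f, ka, ke) bateman_amount(t, cfg$dose_ng, f, ka, ke, cfg$breath_scale))
  noise <- exp(rnorm(nrow(washout), 0, sdlog_noise))
  raw <- ifelse(washout$timepoint_min == 0,
                washout$.baseline,
                (signal + washout$.baseline) * noise)
  cens <- apply_loq(raw, cfg$loq_ng)
  washout <- washout %>%
    mutate(limonene_ng = cens$value, censored = cens$censored) %>%
    select("subject_id", "group", "timepoint_min", "limonene_ng", "censored")
  if (cfg$missing_rate > 0) {
    keep <- runif(nrow(washout)) >= cfg$missing_rate
    washout <- washout[keep, , drop = FALSE]
  }

  truth <- subj %>%
    select("subject_id", "group",
           ka = ".ka", ke = ".ke", cl_int_rel = ".cl", shunt = ".shunt",
           f_sys = ".f_sys", baseline_true_ng = ".baseline",
           auc_true_0_90 = ".auc_true", severity = ".z")
  subjects <- subj %>% select(-dplyr::starts_with("."))

  structure(list(subjects = subjects, washout = washout,
                 truth = truth, config = cfg),
            class = "breath_cohort")
}

simulate_group_subjects <- function(group, n, cfg) {
  prefix <- if (group == "control") "ctrl" else "cirr"
  z <- rnorm(n)                                   # latent disease severity
  ka <- exp(log(cfg$ka_per_min[["median"]]) + cfg$ka_per_min[["sdlog"]] * rnorm(n))
  ke <- exp(log(cfg$ke_per_min[["median"]]) + cfg$ke_per_min[["sdlog"]] * rnorm(n))
  sh <- cfg$shunt_fraction[[group]]
  shunt <- if (sh[["median"]] <= 0) rep(0, n) else
    plogis(qlogis(sh[["median"]]) + sh[["sd"]] * z)
  clp <- cfg$cl_int_rel[[group]]
  # clearance falls with severity; the residual spread is severity-independent
  cl <- exp(log(clp[["median"]]) + clp[["sdlog"]] * (-0.6 * z + 0.8 * rnorm(n)))
  f_sys <- systemic_availability(1, cl, shunt)
  # the dietary baseline rides through the same first pass as the dose, so it
  # scales with the subject's availability relative to the group's typical one
  f_design <- systemic_availability(1, clp[["median"]], sh[["median"]])
  bl <- cfg$baseline_ng[[group]]
  baseline <- exp(log(bl[["median"]]) + bl[["sdlog"]] * rnorm(n)) *
    (f_sys / f_design)
  t_end <- min(90, max(cfg$timepoints_min))
  auc_true <- purrr::pmap_dbl(list(f_sys, ka, ke, baseline), function(f, a, e, b) {
    bateman_auc_exact(0, t_end, cfg$dose_ng, f, a, e, cfg$breath_scale) + b * t_end
  })

  if (group == "cirrhosis") {
    sc <- cfg$score_coupling
    lnauc <- log(auc_true)
    mk_score <- function(p, floor) {
      pmax(floor, p[["base"]] + p[["slope"]] * (lnauc - sc$center_lnauc) +
             rnorm(n, 0, p[["sd"]]))
    }
    meld <- round(mk_score(sc$meld, 6), 1)
    fib4 <- round(mk_score(sc$fib4, 0.2), 2)
    apri <- round(mk_score(sc$apri, 0.05), 2)
    age <- pmin(85, pmax(30, round(rnorm(n, 59, 9))))
    sex <- ifelse(runif(n) < 0.31, "m", "f")
    alt <- round(exp(log(28.5) + 0.40 * rnorm(n)))
    ast <- round(exp(log(35) + 0.35 * rnorm(n)))
    platelets <- round(exp(log(150) - 0.35 * z + 0.25 * rnorm(n)))
    spleen <- round(pmax(6, 12.5 + 1.8 * z + 1.2 * rnorm(n)), 1)
    portal <- (z + rnorm(n, 0, 0.5)) > 0
    cp <- sample(c("A", "B", "unknown"), n, replace = TRUE,
                 prob = c(0.78, 0.16, 0.06))
  } else {
    meld <- pmax(6, round(rnorm(n, 7, 1.2), 1))
    fib4 <- round(exp(log(1.4) + 0.55 * rnorm(n)), 2)
    apri <- round(exp(log(0.22) + 0.45 * rnorm(n)), 2)
    age <- pmin(85, pmax(18, round(rnorm(n, 47, 12))))
    sex <- ifelse(runif(n) < 0.38, "m", "f")
    alt <- round(exp(log(18) + 0.30 * rnorm(n)))
    ast <- round(exp(log(21) + 0.20 * rnorm(n)))
    platelets <- round(exp(log(245) + 0.17 * rnorm(n)))
    spleen <- round(pmax(6, 10 + 1.3 * rnorm(n)), 1)
    portal <- rep(FALSE, n)
    cp <- rep(NA_character_, n)
  }
  # a random single score goes missing for a fraction of subjects
  if (cfg$score_missing_rate > 0) {
    for (i in which(runif(n) < cfg$score_missing_rate)) {
      j <- sample(3, 1)
      if (j == 1) meld[i] <- NA else if (j == 2) fib4[i] <- NA else apri[i] <- NA
    }
  }

  tibble(
    subject_id = sprintf("%s_%02d", prefix, seq_len(n)),
    group = group, age = age, sex = sex, ast = ast, alt = alt,
    platelets = platelets, meld = meld, fib4 = fib4, apri = apri,
    spleen_cm = spleen,
    portal_htn = portal,
    thrombocytopenia = platelets < 150,
    splenomegaly = spleen > 12,
    child_pugh = cp,
    .z = z, .ka = ka, .ke = ke, .cl = cl, .shunt = shunt,
    .f_sys = f_sys, .baseline = baseline, .auc_true = auc_true)
}

#' @export
print.breath_cohort <- function(x, ...) {
  n <- table(x$subjects$group)
  cat("<breath_cohort>\n")
  cat(sprintf("  %d subjects (%s), %d washout rows, %d censored\n",
              nrow(x$subjects),
              paste(sprintf("%s: %d", names(n), n), collapse = ", "),
              nrow(x$washout), sum(x$washout$censored)))
  cat(sprintf("  seed %d; timepoints (min): %s\n", x$config$seed,
              paste(x$config$timepoints_min, collapse = ", ")))
  invisible(x)
}
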