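#' Configuration for the synthetic breath-washout cohort generator
#'
#' Builds and validates the full parameterization of [simulate_cohort()].
#' Defaults are calibrated so that the generated cohorts show the structure of
#' a dynamic limonene breath test in cirrhosis versus healthy controls: a
#' 100 mg oral dose, sampling at 0/20/40/60/90/120 min, a >100-fold post-dose
#' spike over baseline, single-phase first-order washout with group-equal
#' elimination rates, and an elevated bioavailability (intercept, Cmax, AUC)
#' in the cirrhosis group driven by reduced intrinsic clearance and
#' portosystemic shunting.
#'
#' Distribution parameters are given as named vectors. Log-normal quantities
#' (`ka_per_min`, `ke_per_min`, `cl_int_rel`, `baseline_ng`) use
#' `c(median, sdlog)`; the shunt fraction uses a logit-normal
#' `c(median, sd)` where `sd` is the spread on the logit scale (a median of 0
#' pins the whole distribution at 0, as for healthy controls).
#'
#' @param n_control,n_cirrhosis Subjects per group (>= 2).
#' @param dose_ng Oral dose in ng; default 1e8 (100 mg).
#' @param timepoints_min Sampling schedule in minutes; strictly increasing and
#'   including 0 (the pre-dose baseline).
#' @param ka_per_min,ke_per_min Absorption and elimination rate distributions
#'   (1/min). The elimination distribution is shared by both groups: for a
#'   flow-limited probe, liver disease raises availability, not the slope.
#' @param cl_int_rel Per-group intrinsic-clearance-to-flow ratio distribution;
#'   hepatic extraction is `E = cl/(1+cl)` (well-stirred model).
#' @param shunt_fraction Per-group portosystemic shunt fraction distribution.
#' @param breath_scale Dimensionless constant mapping systemic amount to ng
#'   recovered in a 400 mL breath sample.
#' @param baseline_ng Per-group log-normal distribution of the pre-dose
#'   (dietary) breath level at the group's typical availability; each
#'   subject's baseline is additionally scaled by their systemic availability
#'   relative to that typical value, since dietary exposure undergoes the
#'   same hepatic first pass as the dose.
#' @param loq_ng Limit of quantification in ng; values below are imputed at
#'   the limit and flagged censored.
#' @param noise_cv Coefficient of variation of the multiplicative log-normal
#'   measurement noise on post-dose samples.
#' @param score_coupling Coupling of the clinical scores (MELD, FIB4, APRI) to
#'   `ln AUC` in the cirrhosis group: a list with `center_lnauc` and, per
#'   score, `c(slope, sd, base)` so that
#'   `score = base + slope * (lnAUC - center) + N(0, sd)`. Controls draw
#'   scores independently of AUC.
#' @param missing_rate Probability that any scheduled sample is absent
#'   (missing completely at random).
#' @param score_missing_rate Probability that a subject has one clinical score
#'   missing (emulates incomplete metadata; such subjects drop out of
#'   complete-case analyses).
#' @param seed Integer seed; a fixed seed makes [simulate_cohort()] fully
#'   reproducible.
#'
#' @return A validated list of class `sim_config`.
#' @seealso [simulate_cohort()], [sim_config_from_yaml()]
#' @examples
#' cfg <- sim_config(n_control = 5, n_cirrhosis = 5, seed = 1)
#' cfg$loq_ng
#' @export
sim_config <- function(n_control = 29,
                       n_cirrhosis = 29,
                       dose_ng = 1e8,
                       timepoints_min = c(0, 20, 40, 60, 90, 120),
                       ka_per_min = c(median = 0.18, sdlog = 0.25),
                       ke_per_min = c(median = 0.026, sdlog = 0.12),
                       cl_int_rel = list(control   = c(median = 9, sdlog = 0.55),
                                         cirrhosis = c(median = 3, sdlog = 0.85)),
                       shunt_fraction = list(control   = c(median = 0,    sd = 0),
                                             cirrhosis = c(median = 0.25, sd = 1.6)),
                       breath_scale = 1e-4,
                       baseline_ng = list(control   = c(median = 2, sdlog = 0.35),
                                          cirrhosis = c(median = 5, sdlog = 0.55)),
                       loq_ng = 1.18,
                       noise_cv = 0.15,
                       score_coupling = list(
                         center_lnauc = log(121437),
                         meld = c(slope = 3.8,  sd = 2.2,  base = 10),
                         fib4 = c(slope = 0.85, sd = 1.3,  base = 2.6),
                         apri = c(slope = 0.12, sd = 0.35, base = 0.65)),
                       missing_rate = 0.02,
                       score_missing_rate = 0.1,
                       seed = 20231118L) {
  cfg <- list(
    n_control = n_control, n_cirrhosis = n_cirrhosis, dose_ng = dose_ng,
    timepoints_min = timepoints_min, ka_per_min = ka_per_min,
    ke_per_min = ke_per_min, cl_int_rel = cl_int_rel,
    shunt_fraction = shunt_fraction, breath_scale = breath_scale,
    baseline_ng = baseline_ng, loq_ng = loq_ng, noise_cv = noise_cv,
    score_coupling = score_coupling, missing_rate = missing_rate,
    score_missing_rate = score_missing_rate, seed = as.integer(seed))
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (cfg$n_control < 2 || cfg$n_cirrhosis < 2) {
    stop_invalid_param("group sizes must be >= 2")
  }
  tp <- cfg$timepoints_min
  if (length(tp) < 2 || any(diff(tp) <= 0) || !0 %in% tp) {
    stop_invalid_param("timepoints must be strictly increasing and include 0")
  }
  if (cfg$loq_ng <= 0) stop_invalid_param("loq_ng must be > 0")
  if (cfg$dose_ng <= 0) stop_invalid_param("dose_ng must be > 0")
  if (cfg$breath_scale <= 0) stop_invalid_param("breath_scale must be > 0")
  if (cfg$noise_cv < 0) stop_invalid_param("noise_cv must be >= 0")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1 ||
      cfg$score_missing_rate < 0 || cfg$score_missing_rate >= 1) {
    stop_invalid_param("missingness rates must be in [0, 1)")
  }
  for (nm in c("ka_per_min", "ke_per_min")) {
    d <- cfg[[nm]]
    if (d[["median"]] <= 0 || d[["sdlog"]] < 0) {
      stop_invalid_param(sprintf("`%s` requires median > 0 and sdlog >= 0", nm))
    }
  }
  for (g in c("control", "cirrhosis")) {
    if (cfg$cl_int_rel[[g]][["median"]] < 0) {
      stop_invalid_param("cl_int_rel medians must be >= 0")
    }
    s <- cfg$shunt_fraction[[g]]
    if (s[["median"]] < 0 || s[["median"]] > 1 || s[["sd"]] < 0) {
      stop_invalid_param("shunt_fraction median must lie in [0, 1], sd >= 0")
    }
    if (cfg$baseline_ng[[g]][["median"]] <= 0) {
      stop_invalid_param("baseline_ng medians must be > 0")
    }
  }
  structure(cfg, class = "sim_config")
}

#' Read a simulation configuration from YAML
#'
#' Reads a YAML file whose keys mirror the arguments of [sim_config()];
#' missing keys fall back to the defaults. Per-group distribution blocks are
#' nested maps (`control:` / `cirrhosis:`) of named scalars.
#'
#' @param path Path to a YAML file.
#' @param seed Optional seed overriding the file's value.
#' @return A validated `sim_config`.
#' @export
sim_config_from_yaml <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop_invalid(sprintf("unknown config keys: %s", paste(bad, collapse = ", ")))
  }
  raw <- lapply(raw, function(x) if (is.list(x) && !is.list(x[[1]])) lapply(x, unlist) else x)
  # flat numeric maps (e.g. ka_per_min) arrive as lists; flatten to named vectors
  raw <- lapply(raw, function(x) {
    if (is.list(x) && all(vapply(x, is.numeric, logical(1))) &&
        !is.null(names(x)) && all(lengths(x) == 1L)) unlist(x) else x
  })
  if (!is.null(seed)) raw$seed <- seed
  do.call(sim_config, raw)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  groups: %d control / %d cirrhosis, seed %d\n",
              x$n_control, x$n_cirrhosis, x$seed))
  cat(sprintf("  dose: %.3g ng; timepoints (min): %s\n",
              x$dose_ng, paste(x$timepoints_min, collapse = ", ")))
  cat(sprintf("  LOQ: %.3g ng; noise CV: %.2f; missing rate: %.2f\n",
              x$loq_ng, x$noise_cv, x$missing_rate))
  invisible(x)
}
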