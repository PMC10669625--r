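#' Read and validate a washout CSV
#'
#' Expects the columns `subject_id`, `group`, `timepoint_min`, `limonene_ng`,
#' `censored` (extra columns are preserved but ignored by the analyses).
#' Amounts must be strictly positive and each (subject, timepoint) pair
#' unique; violations raise a parse error naming the offending row. Rows are
#' returned ordered by subject then time.
#'
#' @param path CSV file path.
#' @return A validated washout tibble.
#' @export
read_washout_csv <- function(path) {
  # base strtod parsing is correctly rounded, so write -> read -> write is
  # byte-stable with readr's shortest-round-trip writer
  d <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("subject_id", "group", "timepoint_min", "limonene_ng", "censored")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols)) {
    stop_invalid(sprintf("washout file lacks column(s): %s",
                         paste(missing_cols, collapse = ", ")),
                 class = "breathkin_parse_error")
  }
  if (!is.numeric(d$limonene_ng) || !is.numeric(d$timepoint_min)) {
    stop_invalid("`timepoint_min` and `limonene_ng` must be numeric",
                 class = "breathkin_parse_error")
  }
  bad <- which(!is.finite(d$limonene_ng) | d$limonene_ng <= 0)
  if (length(bad)) {
    stop_invalid(sprintf("non-positive or non-numeric amount at row %d", bad[1]),
                 class = "breathkin_parse_error")
  }
  dup <- which(duplicated(d[, c("subject_id", "timepoint_min")]))
  if (length(dup)) {
    stop_invalid(sprintf("duplicate (subject, timepoint) at row %d (%s, %g min)",
                         dup[1], d$subject_id[dup[1]], d$timepoint_min[dup[1]]),
                 class = "breathkin_parse_error")
  }
  d$censored <- as.logical(d$censored)
  arrange(d, .data$subject_id, .data$timepoint_min)
}

#' Write a washout table as CSV
#' @param washout Washout tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_washout_csv <- function(washout, path) {
  readr::write_csv(washout, path, progress = FALSE)
  invisible(path)
}

#' Read a subject metadata CSV
#' @param path CSV file path.
#' @return A subjects tibble (requires unique `subject_id` and a `group`
#'   column).
#' @export
read_subjects_csv <- function(path) {
  d <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if (!all(c("subject_id", "group") %in% names(d))) {
    stop_invalid("subjects file needs `subject_id` and `group`",
                 class = "breathkin_parse_error")
  }
  if (anyDuplicated(d$subject_id)) {
    stop_invalid("duplicate subject_id in subjects file",
                 class = "breathkin_parse_error")
  }
  d
}

#' Run the full breath-test analysis pipeline
#'
#' Orchestrates simulate -> NCA -> per-timepoint classification -> CCA ->
#' flag comparisons -> age-confounder check, writing all tables and a run
#' manifest to `out_dir`. Outputs: `subjects.csv`, `washout.csv`,
#' `kinetics.csv`, `table2.tsv` (kinetic group summary), `table3.tsv`
#' (per-timepoint diagnostic performance), `cca.tsv` (canonical loadings),
#' `flags.tsv` (AUC by portal-hypertension proxies), `report.json`
#' (all stage results, with split-averaged and whole-cohort classification
#' metrics explicitly labelled) and `manifest.json` (config snapshot, seed,
#' file digests). The run is fully deterministic for a fixed seed.
#'
#' @param config A [sim_config()], a list of its arguments, or a YAML path
#'   (see [sim_config_from_yaml()]); `NULL` uses the defaults.
#' @param seed Master seed; overrides the config's seed and drives the
#'   classification splits.
#' @param out_dir Output directory (created if absent).
#' @param reps,test_frac Passed to [evaluate_timepoints()].
#' @param quiet Suppress progress messages.
#' @return The manifest, invisibly (class `run_manifest`).
#' @export
run_pipeline <- function(config = NULL, seed = 1L, out_dir, reps = 5,
                         test_frac = 0.2, quiet = FALSE) {
  cfg <- resolve_config(config, seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)),
            class = c("breathkin_stage_failure", "breathkin_error"),
            stage = name, parent = e)
    })
  }
  fp <- function(f) file.path(out_dir, f)

  cohort <- stage("simulate", simulate_cohort(cfg))
  readr::write_csv(cohort$subjects, fp("subjects.csv"), progress = FALSE)
  write_washout_csv(cohort$washout, fp("washout.csv"))
  n_loq <- sum(cohort$washout$censored)
  say("simulate: %d subjects, %d washout rows, %d LOQ-imputed values",
      nrow(cohort$subjects), nrow(cohort$washout), n_loq)

  kin <- stage("nca", nca(cohort$washout))
  readr::write_csv(kin, fp("kinetics.csv"), progress = FALSE)
  summ <- stage("nca", summarize_kinetics(kin))
  table2 <- summ$stats %>%
    tidyr::pivot_wider(names_from = "group",
                       values_from = c("n", "median", "q25", "q75")) %>%
    left_join(select(summ$tests, "parameter", "p_value"), by = "parameter")
  readr::write_tsv(table2, fp("table2.tsv"), progress = FALSE)
  say("nca: %d subjects analysed, %d with terminal-fit R^2 <= %.2g",
      nrow(kin), summ$n_low_r2, summ$r2_threshold)

  report <- stage("classify",
                  evaluate_timepoints(cohort$washout, kin, cohort$subjects,
                                      reps = reps, test_frac = test_frac,
                                      seed = cfg$seed))
  readr::write_tsv(as_tibble(report), fp("table3.tsv"), progress = FALSE)
  say("classify: %d features evaluated (%s, %d repeats)",
      nrow(report), attr(report, "scheme"), attr(report, "reps"))

  cca <- stage("cca", cca_auc_vs_scores(kin, cohort$subjects))
  readr::write_tsv(tidy(cca), fp("cca.tsv"), progress = FALSE)
  say("cca: r1 = %.3f, first-dimension p = %.3g (%d complete, %d dropped)",
      cca$canonical_correlations[1], cca$p_value, cca$n_complete, cca$n_dropped)

  flags <- stage("compare", bind_rows(lapply(
    c("portal_htn", "thrombocytopenia", "splenomegaly"),
    function(f) compare_auc_by_flag(kin, cohort$subjects, f))))
  readr::write_tsv(flags, fp("flags.tsv"), progress = FALSE)

  lmm <- stage("lmm", age_confounder_check(cohort$washout, cohort$subjects))
  age_p <- lmm$fixed_effects$p_value[lmm$fixed_effects$term == "age"]
  say("lmm: age coefficient p = %.3g", age_p)

  report_json <- list(
    seed = cfg$seed,
    counts = list(
      n_control = sum(cohort$subjects$group == "control"),
      n_cirrhosis = sum(cohort$subjects$group == "cirrhosis"),
      washout_rows = nrow(cohort$washout),
      loq_imputed = n_loq,
      low_r2 = summ$n_low_r2),
    kinetics = list(summary = summ$stats, tests = summ$tests,
                    tmax_counts = summ$tmax_counts),
    classification = list(
      scheme = attr(report, "scheme"), reps = attr(report, "reps"),
      split_averaged = as_tibble(report)[, c("feature", "auroc_mean", "auroc_sd",
                                             "sens_mean", "sens_sd",
                                             "spec_mean", "spec_sd")],
      whole_cohort = as_tibble(report)[, c("feature", "auroc_full", "sens_full",
                                           "spec_full", "ppv_pct", "npv_pct",
                                           "lr_pos", "lr_neg", "threshold_prob",
                                           "threshold_ng")]),
    cca = c(as.list(glance(cca)), list(loadings = tidy(cca))),
    flags = flags,
    age_check = list(fixed_effects = lmm$fixed_effects,
                     age_p_value = age_p))
  jsonlite::write_json(report_json, fp("report.json"), auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)

  outputs <- c("subjects.csv", "washout.csv", "kinetics.csv", "table2.tsv",
               "table3.tsv", "cca.tsv", "flags.tsv", "report.json")
  digests <- tools::md5sum(vapply(outputs, fp, character(1)))
  names(digests) <- outputs
  manifest <- list(
    package_version = as.character(utils::packageVersion("breathkin")),
    seed = cfg$seed,
    config = unclass(cfg),
    reps = reps, test_frac = test_frac,
    timestamp = format(Sys.time(), tz = "UTC"),
    digests = as.list(digests))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(structure(manifest, class = "run_manifest"))
}

resolve_config <- function(config, seed = NULL) {
  cfg <- if (is.null(config)) {
    sim_config()
  } else if (inherits(config, "sim_config")) {
    config
  } else if (is.character(config) && length(config) == 1) {
    sim_config_from_yaml(config)
  } else if (is.list(config)) {
    do.call(sim_config, config)
  } else {
    stop_invalid("`config` must be a sim_config, argument list, or YAML path")
  }
  if (!is.null(seed)) {
    cfg$seed <- as.integer(seed)
    cfg <- validate_sim_config(unclass(cfg))
  }
  cfg
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> breathkin %s, seed %d, %d outputs\n",
              x$package_version, x$seed, length(x$digests)))
  invisible(x)
}
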