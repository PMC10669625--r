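#' Univariable logistic scoring model
#'
#' Maximum-likelihood logistic regression of a binary outcome on a single
#' feature (here, log breath amounts), fitted by iteratively reweighted least
#' squares. Complete or quasi-complete separation makes the unpenalized MLE
#' diverge; when detected, the fit is redone with a small ridge penalty
#' (1e-4 on the slope only) by damped Newton iterations and flagged.
#'
#' @param x Numeric feature vector (finite).
#' @param y Binary labels: logical, 0/1, or a two-level factor (second level
#'   is the positive class).
#' @return A `breath_logit`: list with `intercept`, `coefficient`,
#'   `separation` (flag), `n`; `predict()` gives the linear predictor
#'   (`type = "link"`) or probability (`type = "response"`).
#' @examples
#' set.seed(1)
#' x <- c(rnorm(20), rnorm(20, 2))
#' fit <- fit_logistic(x, rep(c(0, 1), each = 20))
#' predict(fit, c(-1, 0, 1, 2))
#' @export
fit_logistic <- function(x, y) {
  y <- as_binary_labels(y)
  if (!is.numeric(x) || any(!is.finite(x))) stop_invalid("`x` must be finite numeric")
  if (length(x) != length(y)) stop_invalid("`x` and `y` lengths differ")
  if (length(unique(y)) < 2) stop_invalid("both classes must be present")

  separation <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ x, family = binomial(), control = list(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  est <- unname(coef(fit))
  if (separation || any(abs(est) > 1e3)) {
    separation <- TRUE
    est <- ridge_logit_newton(x, y, lambda = 1e-4)
  }
  structure(list(intercept = est[1], coefficient = est[2],
                 separation = separation, n = length(y)),
            class = "breath_logit")
}

# damped Newton for the ridge-penalized (slope-only) logistic likelihood;
# stops at gradient norm < 1e-8
ridge_logit_newton <- function(x, y, lambda, maxit = 200) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  pen <- diag(c(0, lambda))
  negll <- function(b) {
    eta <- drop(X %*% b)
    sum(log1p(exp(eta)) - y * eta) + 0.5 * lambda * b[2]^2
  }
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    g <- drop(crossprod(X, p - y)) + c(0, lambda * beta[2])
    if (sqrt(sum(g^2)) < 1e-8) break
    H <- crossprod(X * (p * (1 - p)), X) + pen
    step <- solve(H, g)
    f0 <- negll(beta); damp <- 1
    while (negll(beta - damp * step) > f0 && damp > 1e-8) damp <- damp / 2
    beta <- beta - damp * step
  }
  beta
}

#' @export
predict.breath_logit <- function(object, newdata, type = c("link", "response"), ...) {
  type <- match.arg(type)
  eta <- object$intercept + object$coefficient * newdata
  if (type == "link") eta else plogis(eta)
}

#' @export
print.breath_logit <- function(x, ...) {
  cat(sprintf("Logistic score: intercept %.4g, coefficient %.4g (n = %d)%s\n",
              x$intercept, x$coefficient, x$n,
              if (x$separation) " [separation: ridge-penalized]" else ""))
  invisible(x)
}

#' @method tidy breath_logit
#' @export
tidy.breath_logit <- function(x, ...) {
  tibble(term = c("(Intercept)", "x"),
         estimate = c(x$intercept, x$coefficient),
         separation = x$separation)
}

as_binary_labels <- function(y) {
  if (is.logical(y)) return(as.integer(y))
  if (is.factor(y)) {
    if (nlevels(y) != 2) stop_invalid("factor labels must have exactly 2 levels")
    return(as.integer(y == levels(y)[2]))
  }
  if (is.numeric(y) && all(y %in% c(0, 1))) return(as.integer(y))
  stop_invalid("labels must be logical, 0/1, or a two-level factor")
}

#' ROC curve and area under it
#'
#' Sweeps the finite thresholds defined by the unique score values (rule:
#' `score >= threshold` is called positive) and integrates the resulting
#' curve by the trapezoid rule. Tied scores move sensitivity and
#' 1-specificity together, so ties earn half credit and the area equals the
#' mid-rank Mann–Whitney `U / (n1 * n2)` — the probability a random positive
#' outscores a random negative.
#'
#' @param scores Numeric scores; higher means more disease-like.
#' @param labels Binary labels (see [fit_logistic()]).
#' @return A `breath_roc`: list with `points` (threshold, tpr, fpr), `auroc`,
#'   `n_pos`, `n_neg` and the sorted unique scores.
#' @examples
#' roc_auroc(c(1, 2, 2, 3), c(0, 1, 0, 1))$auroc  # 0.875
#' @export
roc_auroc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (!is.numeric(scores) || any(!is.finite(scores))) {
    stop_invalid("`scores` must be finite numeric")
  }
  if (length(scores) != length(y)) stop_invalid("`scores` and `labels` lengths differ")
  if (length(unique(y)) < 2) stop_invalid("both classes must be present")
  pos <- scores[y == 1]; neg <- scores[y == 0]
  u <- sort(unique(scores))
  ths <- c(Inf, sort(u, decreasing = TRUE))
  tpr <- vapply(ths, function(th) mean(pos >= th), numeric(1))
  fpr <- vapply(ths, function(th) mean(neg >= th), numeric(1))
  auroc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(list(points = tibble(threshold = ths, tpr = tpr, fpr = fpr),
                 auroc = auroc, n_pos = length(pos), n_neg = length(neg),
                 unique_scores = u),
            class = "breath_roc")
}

#' @export
print.breath_roc <- function(x, ...) {
  cat(sprintf("ROC: AUROC = %.4f (%d positive / %d negative)\n",
              x$auroc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @method tidy breath_roc
#' @export
tidy.breath_roc <- function(x, ...) x$points

#' @method glance breath_roc
#' @export
glance.breath_roc <- function(x, ...) {
  tibble(auroc = x$auroc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Youden operating point of a ROC curve
#'
#' Finds the threshold maximizing Youden's `J = sensitivity + specificity - 1`
#' by exhaustive sweep over the ROC's operating points. Ties in `J` are
#' broken toward higher specificity. The reported threshold is placed in the
#' middle of the score gap it sits in (midpoint between adjacent unique
#' scores), so for perfectly separated groups it is the midpoint of the
#' between-class gap.
#'
#' @param roc A `breath_roc` from [roc_auroc()].
#' @return One-row tibble: `threshold`, `sens`, `spec`, `j`.
#' @examples
#' youden_threshold(roc_auroc(c(1, 2, 3, 10, 11, 12), rep(c(0, 1), each = 3)))
#' @export
youden_threshold <- function(roc) {
  if (!inherits(roc, "breath_roc")) stop_invalid("`roc` must be a breath_roc")
  pts <- roc$points
  j <- pts$tpr - pts$fpr
  best <- which(j == max(j))
  best <- best[pts$fpr[best] == min(pts$fpr[best])]
  best <- best[1]
  u <- roc$unique_scores
  th <- pts$threshold[best]
  th_mid <- if (!is.finite(th)) {
    max(u) + 1            # classify nothing positive
  } else {
    i <- match(th, u)
    if (i == 1) u[1] - 1 else (u[i - 1] + u[i]) / 2
  }
  tibble(threshold = th_mid, sens = pts$tpr[best],
         spec = 1 - pts$fpr[best], j = j[best])
}

#' Confusion-matrix counts at a threshold
#'
#' @param scores Numeric scores; `score >= threshold` is called positive.
#' @param labels Binary labels.
#' @param threshold Decision threshold.
#' @return Named numeric vector `c(tp, fp, fn, tn)`.
#' @export
confusion_counts <- function(scores, labels, threshold) {
  y <- as_binary_labels(labels)
  call_pos <- scores >= threshold
  c(tp = sum(call_pos & y == 1), fp = sum(call_pos & y == 0),
    fn = sum(!call_pos & y == 1), tn = sum(!call_pos & y == 0))
}

#' Diagnostic metrics from a confusion matrix
#'
#' Sensitivity, specificity, predictive values (in percent, i.e. the
#' post-test probabilities at the cohort's prevalence) and likelihood ratios.
#' Zero denominators yield a signalled `Inf`/`NaN` with a classed warning,
#' never a silent `NaN`.
#'
#' @param cm Named counts `c(tp, fp, fn, tn)` (or a list/one-row data frame
#'   with those names); both true-condition rows must be non-empty.
#' @return One-row tibble: `sens`, `spec`, `ppv_pct`, `npv_pct`, `lr_pos`,
#'   `lr_neg`.
#' @examples
#' confusion_metrics(c(tp = 24, fp = 3, fn = 5, tn = 26))
#' @export
confusion_metrics <- function(cm) {
  cm <- unlist(cm[c("tp", "fp", "fn", "tn")])
  if (any(is.na(cm)) || any(cm < 0)) stop_invalid("counts must be non-negative")
  if (sum(cm) == 0) stop_invalid("empty confusion matrix")
  if (cm[["tp"]] + cm[["fn"]] == 0 || cm[["tn"]] + cm[["fp"]] == 0) {
    stop_invalid("both condition-positive and condition-negative rows must be non-empty")
  }
  ratio <- function(num, den, what) {
    if (den > 0) return(num / den)
    out <- if (num > 0) Inf else NaN
    warn(sprintf("%s undefined (zero denominator); returning %s", what, out),
         class = "breathkin_degenerate_metric")
    out
  }
  sens <- cm[["tp"]] / (cm[["tp"]] + cm[["fn"]])
  spec <- cm[["tn"]] / (cm[["tn"]] + cm[["fp"]])
  tibble(sens = sens, spec = spec,
         ppv_pct = 100 * ratio(cm[["tp"]], cm[["tp"]] + cm[["fp"]], "PPV"),
         npv_pct = 100 * ratio(cm[["tn"]], cm[["tn"]] + cm[["fn"]], "NPV"),
         lr_pos = ratio(sens, 1 - spec, "LR+"),
         lr_neg = ratio(1 - sens, spec, "LR-"))
}

#' Per-timepoint diagnostic evaluation of breath features
#'
#' Evaluates each sampling timepoint (and `Cmax`) as a univariable classifier
#' for group membership. Each feature is log-transformed and scored by
#' logistic regression. Out-of-sample performance (AUROC, sensitivity and
#' specificity at the train-derived Youden threshold) is estimated by
#' repeated stratified 80/20 train/test splits and reported as mean and sd
#' across repeats; 5-fold stratified cross-validation is available as an
#' alternative scheme. Predictive values and likelihood ratios are instead
#' computed from the whole-cohort confusion matrix at the full-fit Youden
#' threshold — the operating point a reader would apply to the cohort as a
#' whole — and the threshold is also reported back on the ng scale (logistic
#' scoring of one feature is monotone, so the operating point is a breath
#' amount).
#'
#' @param washout Long washout table (see [nca()]).
#' @param kinetics Output of [nca()] (supplies the `Cmax` feature).
#' @param subjects Subject table with `subject_id` and `group`.
#' @param positive_group Group treated as condition-positive
#'   (default `"cirrhosis"`).
#' @param scheme `"repeated-split"` (default) or `"kfold"`.
#' @param reps Number of repeated splits (or folds), default 5.
#' @param test_frac Test fraction for repeated splits, default 0.2.
#' @param seed Master seed; all splits derive from it and the report is
#'   reproducible.
#' @return A `classifier_report` tibble, one row per feature
#'   (`"0"`, `"20"`, ..., `"cmax"`): split-averaged `auroc_mean/sd`,
#'   `sens_mean/sd`, `spec_mean/sd`; whole-cohort `auroc_full`, `sens_full`,
#'   `spec_full`, `ppv_pct`, `npv_pct`, `lr_pos`, `lr_neg`,
#'   `threshold_prob`, `threshold_ng`, `separation`, class sizes. Split
#'   membership is attached as attribute `"splits"`.
#' @export
evaluate_timepoints <- function(washout, kinetics, subjects,
                                positive_group = "cirrhosis",
                                scheme = c("repeated-split", "kfold"),
                                reps = 5, test_frac = 0.2, seed = 1L) {
  scheme <- match.arg(scheme)
  labels_tbl <- subjects %>%
    mutate(label = as.integer(.data$group == positive_group)) %>%
    select("subject_id", "label")
  wide <- washout %>%
    select("subject_id", "timepoint_min", "limonene_ng") %>%
    tidyr::pivot_wider(names_from = "timepoint_min", values_from = "limonene_ng")
  feat_tbl <- wide %>%
    left_join(select(kinetics, "subject_id", cmax = "cmax_ng"), by = "subject_id") %>%
    left_join(labels_tbl, by = "subject_id")
  tp_names <- as.character(sort(unique(washout$timepoint_min)))
  features <- c(tp_names, "cmax")

  withr::with_seed(seed, {
    splits_log <- list()
    rows <- purrr::map(features, function(f) {
      d <- feat_tbl %>%
        filter(!is.na(.data[[f]]), !is.na(.data$label))
      x <- log(d[[f]]); y <- d$label
      n_pos <- sum(y == 1); n_neg <- sum(y == 0)
      if (n_pos < 5 || n_neg < 5) {
        stop_invalid(sprintf(
          "feature `%s`: need >= 5 subjects per class for stratified splits (have %d/%d)",
          f, n_pos, n_neg), class = "breathkin_class_too_small")
      }
      split_sets <- if (scheme == "repeated-split") {
        purrr::map(seq_len(reps), function(r) {
          test <- c(sample(which(y == 1), max(1, round(n_pos * test_frac))),
                    sample(which(y == 0), max(1, round(n_neg * test_frac))))
          list(rep = r, test = test)
        })
      } else {
        fold_of <- integer(length(y))
        fold_of[y == 1] <- sample(rep_len(seq_len(reps), n_pos))
        fold_of[y == 0] <- sample(rep_len(seq_len(reps), n_neg))
        purrr::map(seq_len(reps), function(r) list(rep = r, test = which(fold_of == r)))
      }
      per_split <- purrr::map(split_sets, function(s) {
        test <- s$test; train <- setdiff(seq_along(y), test)
        fit <- fit_logistic(x[train], y[train])
        tr_scores <- predict(fit, x[train], type = "response")
        te_scores <- predict(fit, x[test], type = "response")
        op <- youden_threshold(roc_auroc(tr_scores, y[train]))
        cm <- confusion_counts(te_scores, y[test], op$threshold)
        tibble(auroc = roc_auroc(te_scores, y[test])$auroc,
               sens = cm[["tp"]] / (cm[["tp"]] + cm[["fn"]]),
               spec = cm[["tn"]] / (cm[["tn"]] + cm[["fp"]]),
               separation = fit$separation)
      }) %>% bind_rows()
      splits_log[[f]] <<- tibble(
        feature = f,
        rep = rep(vapply(split_sets, function(s) s$rep, integer(1)),
                  vapply(split_sets, function(s) length(s$test), integer(1))),
        subject_id = d$subject_id[unlist(lapply(split_sets, `[[`, "test"))],
        role = "test")

      full_fit <- fit_logistic(x, y)
      full_scores <- predict(full_fit, x, type = "response")
      full_roc <- roc_auroc(full_scores, y)
      op_full <- youden_threshold(full_roc)
      cm_full <- confusion_counts(full_scores, y, op_full$threshold)
      mets <- confusion_metrics(cm_full)
      op_raw <- youden_threshold(roc_auroc(x, y))  # same operating point, ng scale

      tibble(feature = f, n_pos = n_pos, n_neg = n_neg,
             auroc_mean = mean(per_split$auroc), auroc_sd = sd(per_split$auroc),
             sens_mean = mean(per_split$sens), sens_sd = sd(per_split$sens),
             spec_mean = mean(per_split$spec), spec_sd = sd(per_split$spec),
             auroc_full = full_roc$auroc,
             sens_full = mets$sens, spec_full = mets$spec,
             ppv_pct = mets$ppv_pct, npv_pct = mets$npv_pct,
             lr_pos = mets$lr_pos, lr_neg = mets$lr_neg,
             threshold_prob = op_full$threshold,
             threshold_ng = exp(op_raw$threshold),
             separation = any(per_split$separation) || full_fit$separation)
    })
    out <- bind_rows(rows)
    attr(out, "splits") <- bind_rows(splits_log)
    attr(out, "scheme") <- scheme
    attr(out, "reps") <- reps
    attr(out, "test_frac") <- test_frac
    attr(out, "seed") <- seed
    class(out) <- c("classifier_report", class(out))
    out
  })
}
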