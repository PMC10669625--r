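test_that("fit_logistic recovers the closed form when the feature is uninformative", {
  x <- rep(c(1, 2, 3), 4)
  y <- rep(c(0, 1), each = 6)   # same x multiset in both classes, 2:1 imbalance below
  fit <- fit_logistic(x, y)
  expect_equal(fit$coefficient, 0, tolerance = 1e-6)
  expect_equal(fit$intercept, log(6 / 6), tolerance = 1e-6)

  y2 <- c(rep(0, 3), rep(1, 9))
  fit2 <- fit_logistic(rep(c(1, 2, 3), 4), y2[c(1:3, 4:6, 7:9, 10:12)])
  expect_equal(fit2$coefficient, 0, tolerance = 1e-6)
  expect_equal(fit2$intercept, log(9 / 3), tolerance = 1e-6)
})

test_that("fit_logistic matches a two-stage likelihood grid oracle on a small dataset", {
  x <- c(-1.2, -0.4, 0.1, 0.6, 1.1, 1.9)
  y <- c(0, 0, 1, 0, 1, 1)
  fit <- fit_logistic(x, y)
  loglik <- function(a, b) {
    eta <- a + b * x
    sum(y * eta - log1p(exp(eta)))
  }
  coarse <- expand.grid(a = seq(-4, 4, by = 0.05), b = seq(-1, 8, by = 0.05))
  ll <- mapply(loglik, coarse$a, coarse$b)
  top <- coarse[which.max(ll), ]
  fine <- expand.grid(a = seq(top$a - 0.06, top$a + 0.06, by = 1e-3),
                      b = seq(top$b - 0.06, top$b + 0.06, by = 1e-3))
  llf <- mapply(loglik, fine$a, fine$b)
  best <- fine[which.max(llf), ]
  expect_equal(fit$intercept, best$a, tolerance = 1e-2)
  expect_equal(fit$coefficient, best$b, tolerance = 1e-2)
  expect_false(fit$separation)
})

test_that("fit_logistic flags complete separation and returns a finite penalized fit", {
  x <- c(1, 2, 3, 10, 11, 12)
  y <- c(0, 0, 0, 1, 1, 1)
  fit <- fit_logistic(x, y)
  expect_true(fit$separation)
  expect_true(is.finite(fit$coefficient))
  expect_gt(fit$coefficient, 0)
  expect_error(fit_logistic(x, rep(1, 6)), class = "breathkin_invalid_input")
})

test_that("roc_auroc handles separation, coincident score sets, and ties", {
  expect_equal(roc_auroc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))$auroc, 1)
  expect_equal(roc_auroc(c(1, 2, 3, 1, 2, 3), c(0, 0, 0, 1, 1, 1))$auroc, 0.5)
  expect_equal(roc_auroc(c(1, 2, 2, 3), c(0, 1, 0, 1))$auroc, 0.875)
  expect_error(roc_auroc(c(1, 2), c(1, 1)), class = "breathkin_invalid_input")
})

test_that("AUROC is antisymmetric in score sign and invariant to monotone transforms", {
  withr::with_seed(7, {
    for (i in 1:30) {
      n <- sample(8:30, 1)
      scores <- round(rnorm(n), sample(c(0, 1, 6), 1))  # sometimes heavy ties
      labels <- rbinom(n, 1, 0.5)
      if (length(unique(labels)) < 2) next
      a <- roc_auroc(scores, labels)$auroc
      expect_equal(a + roc_auroc(-scores, labels)$auroc, 1, tolerance = 1e-12)
      expect_equal(roc_auroc(plogis(0.3 + 2 * scores), labels)$auroc, a,
                   tolerance = 1e-12)
      expect_equal(roc_auroc(exp(scores), labels)$auroc, a, tolerance = 1e-12)
    }
  })
})

test_that("youden_threshold matches brute-force maximization and reports gap midpoints", {
  sep <- roc_auroc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  op <- youden_threshold(sep)
  expect_equal(op$j, 1)
  expect_equal(op$threshold, 6.5)   # midpoint of the class gap

  flat <- roc_auroc(c(5, 5, 5, 5), c(0, 1, 0, 1))
  expect_equal(youden_threshold(flat)$j, 0)

  withr::with_seed(19, {
    for (i in 1:25) {
      n <- sample(8:20, 1)
      scores <- round(rnorm(n), 1)
      labels <- rbinom(n, 1, 0.5)
      if (length(unique(labels)) < 2) next
      op <- youden_threshold(roc_auroc(scores, labels))
      ref <- brute_youden(scores, labels)
      expect_equal(op$j, ref$j, tolerance = 1e-12)
      expect_equal(op$sens, ref$sens)
      expect_equal(op$spec, ref$spec)
    }
  })
})

test_that("confusion_metrics satisfies the Bayes prevalence identity and signals degeneracy", {
  withr::with_seed(23, {
    for (i in 1:40) {
      cm <- c(tp = sample(1:30, 1), fp = sample(0:30, 1),
              fn = sample(1:30, 1), tn = sample(1:30, 1))
      m <- suppressWarnings(confusion_metrics(cm))  # fp = 0 draws legitimately warn
      total <- sum(cm)
      prev <- (cm[["tp"]] + cm[["fn"]]) / total
      expect_equal(m$ppv_pct / 100,
                   m$sens * prev / (m$sens * prev + (1 - m$spec) * (1 - prev)),
                   tolerance = 1e-12)
    }
  })
  perfect <- suppressWarnings(confusion_metrics(c(tp = 29, fp = 0, fn = 0, tn = 29)))
  expect_equal(perfect$sens, 1); expect_equal(perfect$spec, 1)
  expect_equal(perfect$ppv_pct, 100); expect_equal(perfect$npv_pct, 100)
  expect_identical(perfect$lr_pos, Inf)
  expect_equal(perfect$lr_neg, 0)
  expect_warning(confusion_metrics(c(tp = 5, fp = 0, fn = 2, tn = 7)),
                 class = "breathkin_degenerate_metric")
  expect_error(confusion_metrics(c(tp = 0, fp = 0, fn = 0, tn = 0)),
               class = "breathkin_invalid_input")
  expect_error(confusion_metrics(c(tp = 0, fp = 3, fn = 0, tn = 4)),
               class = "breathkin_invalid_input")
})

test_that("evaluate_timepoints is deterministic and perfect on separated cohorts", {
  co <- simulate_cohort(small_config(n = 12, seed = 55, missing_rate = 0))
  k <- nca(co$washout)
  r1 <- suppressWarnings(evaluate_timepoints(co$washout, k, co$subjects, seed = 9))
  r2 <- suppressWarnings(evaluate_timepoints(co$washout, k, co$subjects, seed = 9))
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  r3 <- suppressWarnings(evaluate_timepoints(co$washout, k, co$subjects, seed = 10))
  expect_false(identical(r1$auroc_mean, r3$auroc_mean))
  expect_setequal(r1$feature, c("0", "20", "40", "60", "90", "120", "cmax"))

  # push the groups far apart: every split must be perfect
  w <- co$washout
  w$limonene_ng <- w$limonene_ng * ifelse(w$group == "cirrhosis", 1e4, 1)
  ksep <- nca(w)
  rsep <- suppressWarnings(evaluate_timepoints(w, ksep, co$subjects, seed = 3))
  post <- rsep[rsep$feature != "0", ]
  expect_true(all(post$auroc_mean == 1))
  expect_true(all(post$auroc_sd == 0))
  expect_true(all(post$sens_mean == 1) && all(post$spec_mean == 1))
})

test_that("evaluate_timepoints is centred at chance under label permutation", {
  co <- simulate_cohort(small_config(n = 14, seed = 77, missing_rate = 0))
  k <- nca(co$washout)
  # average over 20 independent reshuffles of the labels
  aurocs <- withr::with_seed(5, vapply(1:20, function(i) {
    subj <- co$subjects
    subj$group <- sample(subj$group)
    r <- suppressWarnings(evaluate_timepoints(co$washout, k, subj,
                                              reps = 2, seed = i))
    mean(r$auroc_mean)
  }, numeric(1)))
  expect_lt(abs(mean(aurocs) - 0.5), 0.15)
})

test_that("evaluate_timepoints rejects classes too small for stratified splitting", {
  co <- simulate_cohort(small_config(n = 4, seed = 2))
  k <- nca(co$washout)
  expect_error(evaluate_timepoints(co$washout, k, co$subjects, seed = 1),
               class = "breathkin_class_too_small")
})

test_that("the k-fold scheme runs and reports the same columns", {
  co <- simulate_cohort(small_config(n = 10, seed = 31, missing_rate = 0))
  k <- nca(co$washout)
  r <- suppressWarnings(evaluate_timepoints(co$washout, k, co$subjects,
                                            scheme = "kfold", seed = 2))
  expect_equal(nrow(r), 7)
  expect_true(all(c("auroc_mean", "ppv_pct", "threshold_ng") %in% names(r)))
})
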