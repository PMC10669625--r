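test_that("bateman_amount matches the closed form, its peak, and the ka=ke limit", {
  # nothing on board at the dosing instant
  expect_equal(bateman_amount(0, dose = 1e8, f_sys = 0.5, ka = 0.1, ke = 0.027), 0)

  # analytic peak time ln(ka/ke)/(ka-ke); confirm by dense grid search
  ka <- 0.1; ke <- 0.027
  tpk <- log(ka / ke) / (ka - ke)
  expect_equal(tpk, 17.93, tolerance = 1e-3)
  grid <- seq(0, 120, by = 0.001)
  vals <- bateman_amount(grid, 1e8, 0.1, ka, ke, 1e-4)
  expect_equal(grid[which.max(vals)], tpk, tolerance = 1e-2)

  # near-degenerate rates agree with the explicit limit branch
  t <- c(5, 20, 60)
  near <- bateman_amount(t, 1e8, 0.2, ka = 0.05 + 1e-9, ke = 0.05, scale = 1e-4)
  lim <- bateman_amount(t, 1e8, 0.2, ka = 0.05, ke = 0.05, scale = 1e-4)
  expect_equal(near, lim, tolerance = 1e-6)

  expect_error(bateman_amount(-1, 1e8, 0.5, 0.1, 0.03),
               class = "breathkin_invalid_parameter")
  expect_error(bateman_amount(10, 1e8, 0.5, 0, 0.03),
               class = "breathkin_invalid_parameter")
  expect_error(bateman_amount(10, 1e8, 1.5, 0.1, 0.03),
               class = "breathkin_invalid_parameter")
})

test_that("systemic_availability follows the well-stirred shunt model and is monotone", {
  expect_equal(systemic_availability(0.8, 0, 0.3), 0.8)   # no extraction
  expect_equal(systemic_availability(0.7, 50, 1), 0.7)    # full bypass
  expect_equal(systemic_availability(1, 9, 0), 0.1)       # E = 9/10

  withr::with_seed(11, {
    for (i in 1:50) {
      cl <- runif(1, 0, 20); sh <- runif(1); f <- runif(1)
      d_sh <- min(1 - sh, 0.1); d_cl <- 0.5
      expect_gte(systemic_availability(f, cl, sh + d_sh),
                 systemic_availability(f, cl, sh))
      expect_lte(systemic_availability(f, cl + d_cl, sh),
                 systemic_availability(f, cl, sh))
    }
  })
  expect_error(systemic_availability(1.2, 1, 0), class = "breathkin_invalid_parameter")
  expect_error(systemic_availability(1, -1, 0), class = "breathkin_invalid_parameter")
})

test_that("apply_loq imputes below-limit values and flags them", {
  out <- apply_loq(c(0.5, 1.18, 2.0), loq = 1.18)
  expect_equal(out$value, c(1.18, 1.18, 2.0))
  expect_equal(out$censored, c(TRUE, FALSE, FALSE))
  expect_error(apply_loq(-0.1, 1.18), class = "breathkin_invalid_input")
  expect_error(apply_loq(1, 0), class = "breathkin_invalid_parameter")
})

test_that("sim_config validates its invariants", {
  expect_error(sim_config(n_control = 1), class = "breathkin_invalid_parameter")
  expect_error(sim_config(timepoints_min = c(20, 40)), class = "breathkin_invalid_parameter")
  expect_error(sim_config(timepoints_min = c(0, 40, 20)), class = "breathkin_invalid_parameter")
  expect_error(sim_config(loq_ng = 0), class = "breathkin_invalid_parameter")
  expect_error(sim_config(ke_per_min = c(median = -1, sdlog = 0.1)),
               class = "breathkin_invalid_parameter")
  expect_error(sim_config(shunt_fraction = list(control = c(median = 0, sd = 0),
                                                cirrhosis = c(median = 1.4, sd = 0.2))),
               class = "breathkin_invalid_parameter")
})

test_that("simulate_cohort is deterministic and leaves the global RNG alone", {
  cfg <- small_config(seed = 77)
  set.seed(123); before <- runif(1)
  set.seed(123)
  a <- simulate_cohort(cfg)
  after <- runif(1)
  b <- simulate_cohort(cfg)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$washout, b$washout)
  expect_identical(a$truth, b$truth)
  expect_identical(before, after)

  c2 <- simulate_cohort(small_config(seed = 78))
  expect_false(identical(a$washout, c2$washout))
})

test_that("simulated metadata flags are internally consistent", {
  co <- simulate_cohort(small_config(n = 40, seed = 5))
  s <- co$subjects
  expect_identical(s$thrombocytopenia, s$platelets < 150)
  expect_identical(s$splenomegaly, s$spleen_cm > 12)
  expect_true(all(s$group[s$portal_htn] == "cirrhosis"))
  expect_true(all(co$truth$shunt[co$truth$group == "control"] == 0))
  expect_true(all(co$truth$f_sys >= 0 & co$truth$f_sys <= 1))
  # washout contract
  w <- co$washout
  expect_named(w, c("subject_id", "group", "timepoint_min", "limonene_ng", "censored"))
  expect_true(all(w$limonene_ng >= co$config$loq_ng))
  expect_false(any(duplicated(w[, c("subject_id", "timepoint_min")])))
})

test_that("noiseless washouts are log-linear beyond twice the peak time", {
  co <- simulate_cohort(small_config(n = 15, seed = 9, noise_cv = 0,
                                     missing_rate = 0))
  split_curves <- split(co$washout, co$washout$subject_id)
  for (cur in split_curves) {
    peak <- compute_cmax_tmax(cur)
    late <- cur[cur$timepoint_min >= 2 * peak$tmax_min, ]
    if (nrow(late) < 3) next
    fit <- lm(log(limonene_ng) ~ timepoint_min, data = late)
    expect_gt(summary(fit)$r.squared, 0.999)
  }
})

test_that("the default calibration yields a >100-fold post-dose spike in >=95% of subjects", {
  co <- simulate_cohort(sim_config(n_control = 100, n_cirrhosis = 100,
                                   missing_rate = 0, seed = 31))
  base <- co$washout[co$washout$timepoint_min == 0, c("subject_id", "limonene_ng")]
  names(base)[2] <- "baseline"
  k <- nca(co$washout)
  d <- merge(k, base, by = "subject_id")
  expect_gte(mean(d$cmax_ng / d$baseline > 100), 0.95)
})

test_that("cirrhosis-vs-control Cmax ratio sits in the flow-limited range under defaults", {
  co <- simulate_cohort(sim_config(n_control = 200, n_cirrhosis = 200, seed = 13))
  k <- nca(co$washout)
  med <- tapply(k$cmax_ng, k$group, median, na.rm = TRUE)
  ratio <- med[["cirrhosis"]] / med[["control"]]
  expect_gte(ratio, 2); expect_lte(ratio, 6)
})

test_that("a null generator (no shunt, equal clearance) gives nominal AUC rejection rates", {
  null_cfg <- function(seed) {
    sim_config(n_control = 12, n_cirrhosis = 12, seed = seed,
               shunt_fraction = list(control = c(median = 0, sd = 0),
                                     cirrhosis = c(median = 0, sd = 0)),
               cl_int_rel = list(control = c(median = 5, sdlog = 0.4),
                                 cirrhosis = c(median = 5, sdlog = 0.4)),
               baseline_ng = list(control = c(median = 2, sdlog = 0.4),
                                  cirrhosis = c(median = 2, sdlog = 0.4)),
               missing_rate = 0)
  }
  reps <- 200
  p <- vapply(seq_len(reps), function(s) {
    co <- simulate_cohort(null_cfg(s))
    w90 <- co$washout[co$washout$timepoint_min %in% c(0, 20, 40, 60, 90), ]
    auc <- tapply(seq_len(nrow(w90)), w90$subject_id, function(idx) {
      trapezoid_auc(w90[idx, ])
    })
    grp <- co$subjects$group[match(names(auc), co$subjects$subject_id)]
    mann_whitney_u(auc[grp == "cirrhosis"], auc[grp == "control"])$p_value
  }, numeric(1))
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.01); expect_lte(rate, 0.11)
})
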