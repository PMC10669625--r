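#' Canonical correlation of two variable blocks
#'
#' Finds the linear combinations of an `x` block and a `y` block with maximal
#' correlation — the natural tool for asking whether breath bioavailability
#' (ln AUC) collectively tracks a panel of clinical liver scores. Columns are
#' standardized and rows with any missing value in either block are dropped
#' (complete-case analysis); the canonical directions are obtained through
#' R's QR-based routine, which agrees with the eigen decomposition of
#' `Sxx^-1 Sxy Syy^-1 Syx` to high accuracy while avoiding explicit inverses.
#'
#' Significance of the leading dimension uses Bartlett's sequential
#' chi-squared approximation: with `Lambda = prod(1 - r_i^2)`,
#' `chi2 = -(n - 1 - (p + q + 1)/2) * log(Lambda)` on `p*q` degrees of
#' freedom. Rao's F approximation is also computed. Canonical loadings are
#' the correlations between each original variable and its block's canonical
#' variate; signs are fixed so the `y` variable with the largest absolute
#' loading has a positive loading (both variates flipped together, so the
#' canonical correlation is untouched).
#'
#' @param x_block,y_block Numeric matrices or data frames (n rows each);
#'   requires `n_complete > p + q + 1`.
#' @return A `breath_cca`: canonical correlations (descending, in `[0, 1]`),
#'   `x_loadings` / `y_loadings` for the first dimension, `wilks_lambda`,
#'   `bartlett_chi2`, `df` (= `p*q`), `p_value`, `rao_f` / `rao_p`,
#'   `n_complete`, `n_dropped`, a per-dimension sequential-test table
#'   `dimensions`, and the standardization/coefficients needed by
#'   [cca_scores()].
#' @examples
#' set.seed(1)
#' y <- matrix(rnorm(150), 50, 3)
#' x <- y %*% c(1, 0.5, 0) + rnorm(50)
#' fit <- canonical_correlation(x, y)
#' glance(fit)
#' @export
canonical_correlation <- function(x_block, y_block) {
  x <- as.matrix(as.data.frame(x_block))
  y <- as.matrix(as.data.frame(y_block))
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (is.null(colnames(y))) colnames(y) <- paste0("y", seq_len(ncol(y)))
  if (nrow(x) != nrow(y)) stop_invalid("blocks must have the same number of rows")
  ok <- complete.cases(x) & complete.cases(y)
  n_dropped <- sum(!ok)
  x <- x[ok, , drop = FALSE]; y <- y[ok, , drop = FALSE]
  n <- nrow(x); p <- ncol(x); q <- ncol(y)
  if (n <= p + q + 1) {
    stop_invalid(sprintf("need n > p + q + 1 complete cases (n=%d, p=%d, q=%d)",
                         n, p, q))
  }
  check_rank <- function(m, what) {
    sds <- apply(m, 2, sd)
    if (any(sds == 0)) {
      stop_invalid(sprintf("block %s is rank-deficient; constant column: %s",
                           what, colnames(m)[which(sds == 0)[1]]),
                   class = "breathkin_rank_deficient")
    }
    ms <- scale(m)
    qrm <- qr(ms)
    if (qrm$rank < ncol(m)) {
      bad <- colnames(m)[qrm$pivot[(qrm$rank + 1):ncol(m)]]
      stop_invalid(sprintf("block %s is rank-deficient; offending column(s): %s",
                           what, paste(bad, collapse = ", ")),
                   class = "breathkin_rank_deficient")
    }
    ms
  }
  xs <- check_rank(x, "x"); ys <- check_rank(y, "y")

  cc <- cancor(xs, ys, xcenter = FALSE, ycenter = FALSE)
  d <- min(p, q)
  r <- pmin(pmax(cc$cor[seq_len(d)], 0), 1)

  scores_x <- xs %*% cc$xcoef[, seq_len(d), drop = FALSE]
  scores_y <- ys %*% cc$ycoef[, seq_len(d), drop = FALSE]
  scores_x <- scale(scores_x)
  scores_y <- scale(scores_y)
  # sign convention: dominant |loading| y variable loads positively
  y_load1 <- drop(cor(y, scores_y[, 1]))
  flip <- sign(y_load1[which.max(abs(y_load1))])
  if (flip < 0) {
    scores_x[, 1] <- -scores_x[, 1]
    scores_y[, 1] <- -scores_y[, 1]
  }
  x_loadings <- drop(cor(x, scores_x[, 1])); names(x_loadings) <- colnames(x)
  y_loadings <- drop(cor(y, scores_y[, 1])); names(y_loadings) <- colnames(y)

  # sequential (Bartlett) tests: dimension k uses Lambda_k = prod_{i>=k}(1-r_i^2)
  seq_tbl <- purrr::map(seq_len(d), function(k) {
    lam <- prod(1 - r[k:d]^2)
    chi2 <- -(n - 1 - (p + q + 1) / 2) * log(lam)
    dfk <- (p - k + 1) * (q - k + 1)
    tibble(dimension = k, canonical_correlation = r[k], wilks_lambda = lam,
           bartlett_chi2 = chi2, df = dfk,
           p_value = pchisq(chi2, dfk, lower.tail = FALSE))
  }) %>% bind_rows()

  rao <- rao_f_test(r, n, p, q)

  structure(list(
    canonical_correlations = r,
    x_loadings = x_loadings, y_loadings = y_loadings,
    wilks_lambda = seq_tbl$wilks_lambda[1],
    bartlett_chi2 = seq_tbl$bartlett_chi2[1],
    df = p * q, p_value = seq_tbl$p_value[1],
    rao_f = rao$f, rao_df1 = rao$df1, rao_df2 = rao$df2, rao_p = rao$p,
    dimensions = seq_tbl,
    n_complete = n, n_dropped = n_dropped, p = p, q = q,
    xcoef = cc$xcoef[, seq_len(d), drop = FALSE],
    ycoef = cc$ycoef[, seq_len(d), drop = FALSE],
    flip1 = flip,
    x_center = attr(scale(x), "scaled:center"), x_scale = attr(scale(x), "scaled:scale"),
    y_center = attr(scale(y), "scaled:center"), y_scale = attr(scale(y), "scaled:scale"),
    sx_center = attr(scores_x, "scaled:center"), sx_scale = attr(scores_x, "scaled:scale"),
    sy_center = attr(scores_y, "scaled:center"), sy_scale = attr(scores_y, "scaled:scale")),
    class = "breath_cca")
}

# Rao's F approximation to Wilks' Lambda for the full first test
rao_f_test <- function(r, n, p, q) {
  lam <- prod(1 - r^2)
  s <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  m <- n - 1 - (p + q + 1) / 2
  df1 <- p * q
  df2 <- m * s - p * q / 2 + 1
  lam_s <- lam^(1 / s)
  f <- (1 - lam_s) / lam_s * df2 / df1
  list(f = f, df1 = df1, df2 = df2,
       p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' @export
print.breath_cca <- function(x, ...) {
  cat(sprintf("Canonical correlation (p = %d, q = %d, n = %d complete, %d dropped)\n",
              x$p, x$q, x$n_complete, x$n_dropped))
  cat("  r:", paste(sprintf("%.3f", x$canonical_correlations), collapse = ", "), "\n")
  cat(sprintf("  first dimension: Wilks' Lambda = %.4f, Bartlett chi2(%d) = %.2f, p = %.4g\n",
              x$wilks_lambda, x$df, x$bartlett_chi2, x$p_value))
  cat("  y loadings:", paste(sprintf("%s %.2f", names(x$y_loadings), x$y_loadings),
                             collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy breath_cca
#' @export
tidy.breath_cca <- function(x, ...) {
  bind_rows(
    tibble(block = "x", variable = names(x$x_loadings),
           loading = unname(x$x_loadings)),
    tibble(block = "y", variable = names(x$y_loadings),
           loading = unname(x$y_loadings)))
}

#' @method glance breath_cca
#' @export
glance.breath_cca <- function(x, ...) {
  tibble(r1 = x$canonical_correlations[1], wilks_lambda = x$wilks_lambda,
         bartlett_chi2 = x$bartlett_chi2, df = x$df, p_value = x$p_value,
         rao_f = x$rao_f, rao_p = x$rao_p,
         n_complete = x$n_complete, n_dropped = x$n_dropped)
}

#' First canonical variate scores
#'
#' Projects (new) data onto the fitted first canonical directions, using the
#' standardization learned at fit time; projections are standardized to unit
#' variance on the training scale. On the training data the correlation of
#' the two score columns equals the first canonical correlation.
#'
#' @param result A `breath_cca`.
#' @param x_block,y_block Data with the same columns as at fit time.
#' @return Tibble with `score_x` and `score_y` (rows with missing values in
#'   either block are dropped, matching the fit's complete-case rule).
#' @export
cca_scores <- function(result, x_block, y_block) {
  if (!inherits(result, "breath_cca")) stop_invalid("`result` must be a breath_cca")
  x <- as.matrix(as.data.frame(x_block))
  y <- as.matrix(as.data.frame(y_block))
  if (ncol(x) != result$p || ncol(y) != result$q) {
    stop_invalid("block dimensions do not match the fitted result")
  }
  if (nrow(x) != nrow(y)) stop_invalid("blocks must have the same number of rows")
  ok <- complete.cases(x) & complete.cases(y)
  x <- x[ok, , drop = FALSE]; y <- y[ok, , drop = FALSE]
  xs <- scale(x, center = result$x_center, scale = result$x_scale)
  ys <- scale(y, center = result$y_center, scale = result$y_scale)
  sx <- drop(xs %*% result$xcoef[, 1])
  sy <- drop(ys %*% result$ycoef[, 1])
  sx <- (sx - result$sx_center[1]) / result$sx_scale[1]
  sy <- (sy - result$sy_center[1]) / result$sy_scale[1]
  tibble(score_x = result$flip1 * sx, score_y = result$flip1 * sy)
}

#' Canonical correlation of bioavailability against clinical scores
#'
#' Convenience wrapper running [canonical_correlation()] of `ln AUC` (from
#' [nca()]) against the MELD/FIB4/APRI block within one group, dropping
#' subjects with incomplete metadata or missing AUC.
#'
#' @param kinetics Output of [nca()].
#' @param subjects Subject table with `meld`, `fib4`, `apri`.
#' @param group Group to analyse (default `"cirrhosis"`).
#' @return A `breath_cca`.
#' @export
cca_auc_vs_scores <- function(kinetics, subjects, group = "cirrhosis") {
  d <- kinetics %>%
    filter(.data$group == !!group, !is.na(.data$auc_0_90)) %>%
    left_join(select(subjects, "subject_id", "meld", "fib4", "apri"),
              by = "subject_id")
  canonical_correlation(
    x_block = data.frame(ln_auc = log(d$auc_0_90)),
    y_block = d[, c("meld", "fib4", "apri")])
}
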