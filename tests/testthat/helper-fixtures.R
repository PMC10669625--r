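# shared fixtures and independent oracles used across test files

small_config <- function(n = 10, seed = 101, ...) {
  sim_config(n_control = n, n_cirrhosis = n, seed = seed, ...)
}

curve_tbl <- function(t, amt) {
  tibble::tibble(timepoint_min = t, limonene_ng = amt)
}

# exact Mann-Whitney two-sided p by full enumeration of the C(n1+n2, n1)
# group allocations of the pooled ranks (tie-free inputs only)
enumerate_mw_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# rank-based AUROC: P(pos > neg) with half credit for ties
rank_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  n1 <- length(pos); n2 <- length(neg)
  r <- rank(c(pos, neg))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u / (n1 * n2)
}

# brute-force Youden sweep over a dense candidate grid
brute_youden <- function(scores, labels) {
  cand <- sort(unique(c(scores - 1e-9, scores + 1e-9,
                        min(scores) - 1, max(scores) + 1)))
  best <- -Inf; out <- NULL
  for (th in cand) {
    sens <- mean(scores[labels == 1] >= th)
    spec <- mean(scores[labels == 0] < th)
    j <- sens + spec - 1
    if (j > best + 1e-12 || (abs(j - best) <= 1e-12 && !is.null(out) && spec > out$spec)) {
      best <- j; out <- list(j = j, sens = sens, spec = spec)
    }
  }
  out
}
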