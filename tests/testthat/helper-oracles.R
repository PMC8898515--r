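# Shared fixtures and independent oracles, built in code.

# Tiny balanced frame: `n_cell` subjects per (block, cell).
tiny_frame <- function(n_cell = 1L, blocks = c("men", "women")) {
  n <- 12L * n_cell * length(blocks)
  data.frame(subject_id = sprintf("T%04d", seq_len(n)),
             block = rep(blocks, each = 12L * n_cell),
             stringsAsFactors = FALSE)
}

# Brute-force maximizer of the weighted Bernoulli log-likelihood over a
# 2-coefficient model, by iteratively refined dense grid search. Independent
# of the IRLS code path.
grid_logistic_oracle <- function(X, y, w, lo = c(-4, -4), hi = c(4, 4),
                                 stages = 6L, pts = 61L) {
  ll <- function(b1, b2) {
    eta <- X[, 1] * b1 + X[, 2] * b2
    sum(w * (y * eta - log1p(exp(eta))))
  }
  for (s in seq_len(stages)) {
    g1 <- seq(lo[1], hi[1], length.out = pts)
    g2 <- seq(lo[2], hi[2], length.out = pts)
    vals <- outer(g1, g2, Vectorize(ll))
    ij <- arrayInd(which.max(vals), dim(vals))
    best <- c(g1[ij[1]], g2[ij[2]])
    span <- c(g1[2] - g1[1], g2[2] - g2[1]) * 2
    lo <- best - span
    hi <- best + span
  }
  best
}

# Direct Pearson chi-square statistic, sum (O - E)^2 / E.
pearson_oracle <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}
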