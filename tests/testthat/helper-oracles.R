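# Independent oracles used against the closed-form implementations.

# truncated Neumann series q + q^2 + ... for total trophic impacts
mti_by_path_sum <- function(q, order = 50000, tol = 1e-15) {
  M <- q
  qk <- q
  for (k in 2:order) {
    qk <- qk %*% q
    M <- M + qk
    if (max(abs(qk)) < tol) break
  }
  M
}

# cycling via the power series of the inflow-fraction matrix
finn_by_power_series <- function(Tm, imports, order = 200) {
  thr <- colSums(Tm) + imports
  n <- nrow(Tm)
  G <- matrix(0, n, n)
  pos <- thr > 0
  G[, pos] <- sweep(Tm[, pos, drop = FALSE], 2, thr[pos], "/")
  L <- diag(n)
  Gk <- diag(n)
  for (k in 1:order) {
    Gk <- Gk %*% G
    L <- L + Gk
    if (max(abs(Gk)) < 1e-14) break
  }
  dg <- diag(L)
  cycled <- ifelse(dg > 0, thr * (dg - 1) / dg, 0)
  list(cycled = cycled, throughput = thr)
}
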