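# Independent oracles: exhaustive hidden-path enumeration for genotype
# probabilities, direct least-squares LOD computation, and a grid-search
# restricted likelihood. These deliberately share no code with the package
# internals they check.

or_haldane <- function(d) 0.5 * (1 - exp(-d / 50))

or_trans <- function(r, cross_type) {
  if (cross_type == "backcross") {
    matrix(c(1 - r, r, r, 1 - r), 2, 2, byrow = TRUE)
  } else if (cross_type == "riself") {
    R <- 2 * r / (1 + 2 * r)
    matrix(c(1 - R, R, R, 1 - R), 2, 2, byrow = TRUE)
  } else {
    rbind(
      c((1 - r)^2, 2 * r * (1 - r), r^2),
      c(r * (1 - r), (1 - r)^2 + r^2, r * (1 - r)),
      c(r^2, 2 * r * (1 - r), (1 - r)^2)
    )
  }
}

# posterior state probabilities for ONE individual by summing over every
# hidden path; `pos` are grid positions (cM), `obs` observed genotype state
# index per position (NA = missing/pseudomarker), states indexed within the
# cross's own state set
oracle_genoprob1 <- function(pos, obs, cross_type, error_prob) {
  states <- switch(cross_type, f2 = 1:3, backcross = 1:2, riself = c(1, 3))
  K <- length(states)
  init <- if (cross_type == "f2") c(0.25, 0.5, 0.25) else c(0.5, 0.5)
  Tn <- length(pos)
  r <- or_haldane(diff(pos))
  emis <- function(t, k) {
    if (is.na(obs[t])) return(1)
    if (obs[t] == states[k]) 1 - error_prob else
      if (K == 2) error_prob else error_prob / 2
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  post <- matrix(0, Tn, K)
  total <- 0
  for (p in seq_len(nrow(paths))) {
    path <- paths[p, ]
    w <- init[path[1]] * emis(1, path[1])
    if (Tn > 1) {
      for (t in seq_len(Tn - 1)) {
        Tm <- or_trans(r[t], cross_type)
        w <- w * Tm[path[t], path[t + 1]] * emis(t + 1, path[t + 1])
      }
    }
    total <- total + w
    for (t in seq_len(Tn)) post[t, path[t]] <- post[t, path[t]] + w
  }
  post / total
}

# gaussian LOD from direct residual sums of squares via lm()
oracle_lod_gauss <- function(y, X0, X1) {
  rss0 <- sum(stats::lm(y ~ X0 - 1)$residuals^2)
  rss1 <- sum(stats::lm(y ~ X1 - 1)$residuals^2)
  length(y) / 2 * log10(rss0 / rss1)
}

# restricted log-likelihood of V = tau * (h1 K1 + h2 K2 + (1-h1-h2) I),
# profiled over the overall scale tau
oracle_remll_profiled <- function(y, X, K1, K2, h1, h2) {
  n <- length(y)
  p <- ncol(X)
  V0 <- h1 * K1 + h2 * K2 + (1 - h1 - h2) * diag(n)
  ch <- chol(V0 + diag(1e-10, n))
  Vi <- chol2inv(ch)
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  P0y <- drop(Vi %*% y - ViX %*% solve(XtViX, crossprod(ViX, y)))
  quad <- sum(y * P0y)
  tau <- quad / (n - p)
  -0.5 * ((n - p) * log(tau) + 2 * sum(log(diag(ch))) +
            determinant(XtViX)$modulus[1] + quad / tau)
}

# grid search over variance proportions; returns the best restricted LL
oracle_reml_grid <- function(y, X, K1, K2, step = 0.02) {
  best <- -Inf
  hs <- seq(0, 1, by = step)
  for (h1 in hs) for (h2 in hs) {
    if (h1 + h2 > 1 - 1e-9) next
    ll <- oracle_remll_profiled(y, X, K1, K2, h1, h2)
    if (is.finite(ll) && ll > best) best <- ll
  }
  best
}
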