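## Independent oracles used by the tests. These deliberately avoid the
## package's own implementation paths.

## Monte-Carlo random walk of water molecules inside an impermeable sphere:
## phase accumulation under a rectangular PGSE pair with gradient along z.
## Returns the normalised signal per Delta. Not part of the library API.
mcSphereSignal <- function(R_um, delta, Deltas, G, d = 1e-9,
                           nWalkers = 1e4, seed = 1) {
  set.seed(seed)
  R <- R_um * 1e-6
  gam <- gyromagneticRatio()
  total <- max(Deltas) + delta
  ## step small vs both the pulse duration and the sphere size
  dt <- min(delta / 20, R^2 / (600 * d))
  nst <- ceiling(total / dt)
  dt <- total / nst
  n <- nWalkers
  x <- matrix(stats::rnorm(3 * n), ncol = 3)
  x <- x / sqrt(rowSums(x^2)) * stats::runif(n)^(1 / 3) * R
  s1 <- numeric(n)
  s2 <- matrix(0, n, length(Deltas))
  step <- sqrt(2 * d * dt)
  t <- 0
  for (k in seq_len(nst)) {
    x <- x + matrix(stats::rnorm(3 * n, 0, step), ncol = 3)
    r <- sqrt(rowSums(x^2))
    out <- r > R
    if (any(out)) x[out, ] <- x[out, , drop = FALSE] * (2 * R - r[out]) / r[out]
    tm <- t + dt / 2
    if (tm < delta) s1 <- s1 + x[, 3] * dt
    for (j in seq_along(Deltas))
      if (tm >= Deltas[j] && tm < Deltas[j] + delta)
        s2[, j] <- s2[, j] + x[, 3] * dt
    t <- t + dt
  }
  vapply(seq_along(Deltas),
         function(j) mean(cos(gam * G * (s1 - s2[, j]))), numeric(1))
}

## literal step-down Sidak evaluation with explicit loops
bruteHolmSidak <- function(p, m = length(p)) {
  ord <- order(p)
  adj <- numeric(length(p))
  for (i in seq_along(ord)) {
    cand <- -Inf
    for (j in seq_len(i)) {
      pj <- p[ord[j]]
      cand <- max(cand, 1 - (1 - pj)^(m - j + 1))
    }
    adj[ord[i]] <- min(cand, 1)
  }
  adj
}

## Spearman rho from first principles: Pearson correlation of mid-ranks
bruteSpearman <- function(x, y) {
  rk <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- mean(which(sort(v) == v[i]))
    ## mid-rank: average position of tied values
    sapply(v, function(vi) mean(which(sort(v) == vi)))
  }
  rx <- rk(x); ry <- rk(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

## exact Wilcoxon signed-rank p (two-sided) by enumerating all sign patterns
bruteWilcoxonP <- function(x, y) {
  d <- y - x
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wall <- signs %*% r
  pGe <- mean(Wall >= W)
  pLe <- mean(Wall <= W)
  min(1, 2 * min(pGe, pLe))
}

## Gaussian log-likelihood (high-SNR limit of the Rician one)
gaussianLogLik <- function(observed, predicted, sigma) {
  sum(stats::dnorm(observed, predicted, sigma, log = TRUE))
}
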