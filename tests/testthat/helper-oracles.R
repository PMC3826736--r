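# Independent oracles used across the suite. These deliberately avoid the
# package's coordinate-descent code path.

# proximal-gradient (ISTA) minimizer of the elastic-net logistic objective:
#   (1/n) sum [log(1+e^eta) - y*eta] + lam*(alpha*|b|_1 + (1-alpha)/2*|b|^2)
# on the raw (unstandardized) design, intercept unpenalized
ista_enet_logit <- function(x, y, alpha, lambda, iters = 50000) {
  n <- nrow(x); p <- ncol(x)
  xa <- cbind(1, x)
  L <- 0.25 * max(eigen(crossprod(xa) / n, symmetric = TRUE,
                        only.values = TRUE)$values) + lambda * (1 - alpha)
  s <- 1 / L
  b0 <- 0; b <- rep(0, p)
  for (it in seq_len(iters)) {
    eta <- b0 + drop(x %*% b)
    r <- plogis(eta) - y
    g0 <- mean(r)
    g <- drop(crossprod(x, r)) / n + lambda * (1 - alpha) * b
    b0n <- b0 - s * g0
    bn <- b - s * g
    bn <- sign(bn) * pmax(abs(bn) - s * lambda * alpha, 0)
    if (max(abs(c(b0n - b0, bn - b))) < 1e-11 && it > 10) {
      b0 <- b0n; b <- bn; break
    }
    b0 <- b0n; b <- bn
  }
  list(intercept = b0, beta = b)
}

# brute-force two-sample ECDF sup-difference
ks_brute <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  fa <- vapply(pts, function(t) mean(a <= t), 0)
  fb <- vapply(pts, function(t) mean(b <= t), 0)
  max(abs(fa - fb))
}

# Breslow log partial likelihood for a single covariate
cox_logpl <- function(beta, z, time, event) {
  s <- 0
  for (i in which(event == 1)) {
    at_risk <- time >= time[i]
    s <- s + beta * z[i] - log(sum(exp(beta * z[at_risk])))
  }
  s
}

# balanced two-cloud Gaussian design with the given between-class distance
# (in per-feature SD units spread over the first n_signal features)
two_clouds <- function(n = 60, p = 50, distance = 10, n_signal = 5, seed = 1) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  x <- matrix(rnorm(n * p), n, p)
  shift <- distance / sqrt(n_signal)
  x[y == 1, seq_len(n_signal)] <- x[y == 1, seq_len(n_signal)] + shift
  colnames(x) <- paste0("v", seq_len(p))
  list(x = x, y = y)
}

# small non-separable logistic dataset
small_logit_data <- function(n = 20, p = 3, seed = 7) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  colnames(x) <- paste0("v", seq_len(p))
  y <- rbinom(n, 1, plogis(0.6 * x[, 1] - 0.4 * x[, 2]))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  list(x = x, y = y)
}

# compact synthetic cohort spec for fast pipeline tests: 10x10x10 grids,
# one planted block per tissue
tiny_cohort_spec <- function(n_per_group = 12, noise_sd = 0.12) {
  cohort_spec(
    group_sizes = c(CNsim = n_per_group, ncMCIsim = n_per_group,
                    cMCIsim = n_per_group, ADsim = n_per_group),
    grid_shape = c(10, 10, 10),
    noise_sd = noise_sd,
    effect_regions = list(
      GM = list(block(c(2, 5), c(2, 5), c(2, 5))),
      WM = list(block(c(5, 8), c(5, 8), c(5, 8))),
      CSF = list(block(c(2, 4), c(6, 9), c(2, 4)))))
}
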