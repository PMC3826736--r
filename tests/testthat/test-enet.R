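test_that("unpenalized fit matches the maximum-likelihood oracle", {
  d <- small_logit_data(n = 20, p = 3)
  fit <- enet_logit(d$x, d$y, alpha = 0.5, lambda = 0)
  ml <- glm(d$y ~ d$x, family = binomial)
  expect_lt(max(abs(coef(fit) - coef(ml))), 1e-4)
  expect_true(fit$converged)
  # label-flip symmetry: probabilities complement under the flipped refit
  flip <- enet_logit(d$x, 1 - d$y, alpha = 0.5, lambda = 0)
  expect_equal(predict(fit, d$x), 1 - predict(flip, d$x), tolerance = 1e-6)
})

test_that("penalized solutions satisfy the KKT conditions and match an ISTA oracle", {
  d <- small_logit_data(n = 40, p = 8, seed = 3)
  for (alpha in c(1, 0.5, 0.2)) {
    lam <- 0.4 * lambda_max(d$x, d$y, alpha, standardize = FALSE)
    fit <- enet_logit(d$x, d$y, alpha = alpha, lambda = lam,
                      standardize = FALSE)
    kk <- kkt_residuals(fit, d$x, d$y)
    expect_lt(max(kk$coordinate), 1e-6)
    expect_lt(kk$intercept, 1e-6)
    oracle <- ista_enet_logit(d$x, d$y, alpha, lam)
    expect_lt(max(abs(fit$coefficients - oracle$beta)), 1e-5)
    expect_lt(abs(fit$intercept - oracle$intercept), 1e-5)
  }
})

test_that("heavy penalty gives the empty model with the log-odds intercept", {
  d <- small_logit_data(n = 30, p = 5, seed = 11)
  for (alpha in c(1, 0.5)) {
    lmax <- lambda_max(d$x, d$y, alpha)
    fit <- enet_logit(d$x, d$y, alpha = alpha, lambda = 1.01 * lmax)
    expect_identical(fit$n_nonzero, 0L)
    expect_equal(fit$intercept, qlogis(mean(d$y)), tolerance = 1e-6)
    # objective at the solution never exceeds the all-zeros start: log(2)
    expect_lte(fit$objective, log(2) + 1e-12)
  }
})

test_that("lambda_max scales as 1/alpha and matches the direct KKT bound", {
  d <- small_logit_data(n = 24, p = 4, seed = 5)
  expect_equal(lambda_max(d$x, d$y, 0.5), 2 * lambda_max(d$x, d$y, 1))
  # balanced y, one raw column equal to y - mean(y): bound is the max
  # absolute column score / (n * alpha)
  y <- rep(0:1, each = 10)
  x <- cbind(a = y - mean(y), b = rnorm(20, sd = 0.01))
  got <- lambda_max(x, y, alpha = 1, standardize = FALSE)
  expect_equal(got, max(abs(crossprod(x, y - mean(y)))) / (20 * 1))
  expect_error(lambda_max(d$x, d$y, alpha = 0), "positive")
})

test_that("the inner weighted least squares step decouples on orthonormal designs", {
  # orthonormal zero-mean columns (orthogonal polynomials) decouple the
  # penalized WLS subproblem: each coordinate has an exact closed-form
  # soft-threshold solution and the intercept is the plain mean
  set.seed(9)
  n <- 32; p <- 4
  q <- poly(seq_len(n), degree = p)      # q'q = I, colSums(q) = 0
  class(q) <- NULL; attributes(q) <- list(dim = dim(q))
  z <- rnorm(n); w <- rep(1, n)
  for (alpha in c(1, 0.6)) {
    lam <- 0.002
    res <- adps:::.cpp_wls_enet(q, z, w, alpha, lam, 1e-12, 10000L)
    expect_equal(res$intercept, mean(z), tolerance = 1e-10)
    num <- drop(crossprod(q, z - mean(z))) / n
    closed <- sign(num) * pmax(abs(num) - lam * alpha, 0) /
      (1 / n + lam * (1 - alpha))
    expect_equal(res$beta, closed, tolerance = 1e-9)
  }
})

test_that("the lasso path is sparser at larger penalties and warm starts are exact", {
  d <- small_logit_data(n = 120, p = 10, seed = 13)
  path <- enet_logit_path(d$x, d$y, alpha = 1, nlambda = 10)
  expect_true(all(diff(path$n_nonzero) >= 0))   # lambda decreasing
  expect_identical(path$n_nonzero[1], 0L)        # starts at lambda_max
  # cold start at each lambda reproduces the warm-started solution
  for (k in c(3, 6, 10)) {
    cold <- enet_logit(d$x, d$y, alpha = 1, lambda = path$lambda[k])
    expect_lt(max(abs(cold$coefficients - path$beta[, k])), 1e-6)
  }
})

test_that("objective decreases along the path and is finite at convergence", {
  d <- small_logit_data(n = 40, p = 10, seed = 21)
  path <- enet_logit_path(d$x, d$y, alpha = 0.5, nlambda = 12)
  expect_true(all(is.finite(path$objective[path$converged])))
  expect_true(all(diff(path$objective) <= 1e-10))  # relaxing the penalty
})

test_that("single-class labels and malformed inputs are rejected", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(enet_logit(x, rep(1, 10), alpha = 0.5, lambda = 0.1),
               "both classes")
  expect_error(enet_logit(x, rep(c(0, 1), 5), alpha = 0.5, lambda = 0.1,
                          tol = -1))
  xna <- x; xna[1] <- NA
  expect_error(enet_logit(xna, rep(c(0, 1), 5), alpha = 0.5, lambda = 0.1),
               "missing")
  xd <- x; colnames(xd) <- c("a", "a")
  expect_error(enet_logit(xd, rep(c(0, 1), 5), alpha = 0.5, lambda = 0.1),
               "unique")
})

test_that("predictions are proper probabilities with the documented tie rule", {
  d <- small_logit_data()
  fit <- enet_logit(d$x, d$y, alpha = 0.5, lambda = 0.05)
  p <- predict(fit, d$x)
  expect_true(all(p > 0 & p < 1))
  # zero model predicts 0.5 everywhere
  null_fit <- enet_logit(d$x, rep(c(0, 1), 10), alpha = 1,
                         lambda = 10 * lambda_max(d$x, rep(c(0, 1), 10), 1))
  expect_equal(unname(predict(null_fit, d$x)),
               rep(0.5, nrow(d$x)), tolerance = 1e-9)
  expect_identical(classify(c(0.2, 0.8)), c(0L, 1L))
  expect_identical(classify(0.5), 0L)                 # tie goes to class 0
  expect_identical(classify(c(0, 0.3, 1), threshold = 0), c(0L, 1L, 1L))
  # column mismatch is rejected
  xw <- d$x; colnames(xw) <- paste0("w", seq_len(ncol(xw)))
  expect_error(predict(fit, xw), "column names")
  expect_error(predict(fit, d$x[, 1:2]), "columns")
})

test_that("model serialization round-trips through the JSON container", {
  d <- small_logit_data(n = 30, p = 6, seed = 2)
  fit <- enet_logit(d$x, d$y, alpha = 0.5, lambda = 0.03)
  path <- tempfile(fileext = ".json")
  write_enet_model(fit, path)
  back <- read_enet_model(path)
  expect_equal(back$coefficients, fit$coefficients)
  expect_equal(back$intercept, fit$intercept)
  expect_equal(predict(back, d$x), predict(fit, d$x))
  unlink(path)
})

test_that("independent penalized cross-check against the reference library", {
  skip_if_not_installed("glmnet")
  d <- small_logit_data(n = 40, p = 12, seed = 17)
  lam <- 0.03
  fit <- enet_logit(d$x, d$y, alpha = 0.5, lambda = lam)
  ref <- glmnet::glmnet(d$x, d$y, family = "binomial", alpha = 0.5,
                        lambda = lam, standardize = TRUE, thresh = 1e-12)
  expect_lt(max(abs(fit$coefficients - as.numeric(ref$beta))), 1e-5)
  expect_lt(abs(fit$intercept - as.numeric(ref$a0)), 1e-5)
})
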