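#' Elastic-net penalized logistic regression
#'
#' Fits a binomial model with the elastic-net penalty by an iteratively
#' reweighted least squares outer loop and coordinate-wise soft-threshold
#' updates on the quadratic approximation. The solver operates directly on
#' high-dimensional feature matrices (subjects x voxels, or subjects x
#' cognitive scores) and is the engine behind the AD-PS scores: the fitted
#' class-conditional probability P(class 1 | x) is the score.
#'
#' The objective minimized is
#' \deqn{\frac{1}{n}\sum_i \left[\log(1+e^{\eta_i}) - y_i \eta_i\right] +
#'   \lambda\left(\alpha\|\beta\|_1 + \frac{1-\alpha}{2}\|\beta\|_2^2\right)}
#' with \eqn{\eta_i = \beta_0 + x_i^\top\beta}; the intercept is never
#' penalized. With `standardize = TRUE` (default) columns are centered and
#' scaled to unit variance (population SD) internally and coefficients are
#' returned on the original scale, so \eqn{\lambda} grids are comparable
#' across modalities.
#'
#' @param x numeric matrix, subjects in rows, variables (voxels or cognitive
#'   scores) in columns. No missing values.
#' @param y binary response coded 0/1 (0 = cognitively normal anchor class,
#'   1 = disease anchor class). Both classes must be present.
#' @param alpha elastic-net mixing parameter in \[0, 1\]: 1 is the lasso,
#'   0 the ridge penalty.
#' @param lambda non-negative penalty strength (a single value; see
#'   [enet_logit_path()] for a warm-started path).
#' @param standardize center and unit-scale columns internally (default TRUE).
#' @param tol convergence tolerance on the maximum coefficient change per
#'   sweep, on the standardized scale.
#' @param max_iter total coordinate-descent sweep budget.
#' @return an object of class `"enet_logit"` with components `intercept`,
#'   `coefficients` (original scale, named), `regularization` (`alpha`,
#'   `lambda`), `n_nonzero`, `converged`, `objective` (penalized objective on
#'   the standardized scale), `sweeps`, and standardization metadata.
#' @seealso [enet_logit_path()], [lambda_max()], [predict.enet_logit()]
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40 * 10), 40, 10)
#' y <- rbinom(40, 1, plogis(x[, 1] - x[, 2]))
#' fit <- enet_logit(x, y, alpha = 0.5, lambda = 0.05)
#' fit$n_nonzero
#' head(predict(fit, x))
#' @export
enet_logit <- function(x, y, alpha = 0.5, lambda, standardize = TRUE,
                       tol = 1e-7, max_iter = 1e4) {
  xv <- validate_feature_matrix(x)
  y <- validate_labels(y, n = nrow(xv), require_both = TRUE)
  stopifnot(length(alpha) == 1, alpha >= 0, alpha <= 1,
            length(lambda) == 1, lambda >= 0, tol > 0)
  fit <- enet_logit_path(xv, y, alpha = alpha, lambda = lambda,
                         standardize = standardize, tol = tol,
                         max_iter = max_iter)
  extract_path_model(fit, 1L)
}

#' Warm-started elastic-net path for logistic regression
#'
#' Fits a decreasing sequence of penalty strengths with warm starts. When
#' `lambda` is omitted the path is log-spaced over
#' `[lambda_max * lambda_min_ratio, lambda_max]`.
#'
#' @inheritParams enet_logit
#' @param lambda optional decreasing vector of penalty strengths.
#' @param nlambda number of grid points when `lambda` is omitted.
#' @param lambda_min_ratio smallest lambda as a fraction of [lambda_max()].
#' @param warn emit a warning when any path point fails to converge. Internal
#'   search loops set this to `FALSE` and read the `converged` flags instead.
#' @return an object of class `"enet_logit_path"`: a list with `lambda`,
#'   `intercept`, `beta` (p x nlambda, original scale), `n_nonzero`,
#'   `converged`, `objective`, `sweeps`, `alpha` and standardization
#'   metadata. Use `[[`-style extraction via [extract_path_model()].
#' @export
enet_logit_path <- function(x, y, alpha = 0.5, lambda = NULL, nlambda = 20,
                            lambda_min_ratio = 1e-4, standardize = TRUE,
                            tol = 1e-7, max_iter = 1e4, warn = TRUE) {
  xv <- validate_feature_matrix(x)
  y <- validate_labels(y, n = nrow(xv), require_both = TRUE)
  std <- standardize_columns(xv, standardize)
  if (is.null(lambda)) {
    lmax <- lambda_max_std(std$x, y, max(alpha, 0.001))
    lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                      length.out = nlambda))
  }
  if (is.unsorted(rev(lambda)) && length(lambda) > 1)
    lambda <- sort(lambda, decreasing = TRUE)
  res <- .cpp_enet_logistic_path(std$x, as.numeric(y), alpha,
                                 as.numeric(lambda), tol,
                                 as.integer(max_iter), 100L)
  # back-transform to the original scale
  beta_std <- res$beta
  beta <- beta_std / std$scale
  b0 <- res$intercept - colSums(beta_std * (std$center / std$scale))
  rownames(beta) <- colnames(xv)
  if (warn && any(!res$converged))
    warning(sprintf(
      "coordinate descent did not converge within %d sweeps at %d of %d lambda value(s); results are partial diagnostics",
      as.integer(max_iter), sum(!res$converged), length(lambda)),
      call. = FALSE)
  structure(list(lambda = as.numeric(lambda), alpha = alpha,
                 intercept = as.numeric(b0), beta = beta,
                 intercept_std = as.numeric(res$intercept),
                 beta_std = beta_std,
                 n_nonzero = as.integer(res$n_nonzero),
                 converged = as.logical(res$converged),
                 objective = as.numeric(res$objective),
                 sweeps = as.integer(res$sweeps),
                 standardize = standardize,
                 center = std$center, scale = std$scale,
                 column_ids = colnames(xv)),
            class = "enet_logit_path")
}

#' Extract one fitted model from a lambda path
#'
#' @param path an `"enet_logit_path"` object.
#' @param index position along the path.
#' @return an `"enet_logit"` object for that penalty strength.
#' @export
extract_path_model <- function(path, index) {
  stopifnot(inherits(path, "enet_logit_path"),
            index >= 1, index <= length(path$lambda))
  co <- path$beta[, index]
  names(co) <- path$column_ids
  structure(list(intercept = path$intercept[index],
                 coefficients = co,
                 coefficients_std = path$beta_std[, index],
                 intercept_std = path$intercept_std[index],
                 regularization = list(alpha = path$alpha,
                                       lambda = path$lambda[index]),
                 n_nonzero = path$n_nonzero[index],
                 converged = path$converged[index],
                 objective = path$objective[index],
                 sweeps = path$sweeps[index],
                 standardize = path$standardize,
                 center = path$center, scale = path$scale,
                 column_ids = path$column_ids),
            class = "enet_logit")
}

#' Smallest penalty at which all coefficients are zero
#'
#' Returns the smallest \eqn{\lambda} for which the all-zero coefficient
#' vector (with intercept at the log-odds of the sample mean of `y`)
#' satisfies the subgradient optimality conditions:
#' \eqn{\max_j |x_j^\top (y - \bar y)| / (n\alpha)} on the (optionally
#' standardized) design. Fitting at any larger penalty returns an empty
#' model; this anchors the search grid.
#'
#' @inheritParams enet_logit
#' @export
lambda_max <- function(x, y, alpha = 0.5, standardize = TRUE) {
  if (alpha <= 0)
    stop("alpha must be positive: the ridge penalty (alpha = 0) never zeroes coefficients")
  xv <- validate_feature_matrix(x)
  y <- validate_labels(y, n = nrow(xv), require_both = TRUE)
  std <- standardize_columns(xv, standardize)
  lambda_max_std(std$x, y, alpha)
}

lambda_max_std <- function(x_std, y, alpha) {
  n <- nrow(x_std)
  r <- y - mean(y)
  max(abs(crossprod(x_std, r))) / (n * alpha)
}

#' Predicted probabilities, linear predictor or class labels
#'
#' @param object an `"enet_logit"` fit.
#' @param newx matrix whose columns match the training columns (checked by
#'   name when both are named).
#' @param type `"response"` (probability P(class 1 | x), strictly inside
#'   (0,1)), `"link"` (linear predictor) or `"class"` (thresholded label).
#' @param threshold classification cut point for `type = "class"`; a
#'   probability exactly at the threshold is assigned class 0.
#' @param ... unused.
#' @export
predict.enet_logit <- function(object, newx, type = c("response", "link", "class"),
                               threshold = 0.5, ...) {
  type <- match.arg(type)
  newx <- as.matrix(newx)
  if (ncol(newx) != length(object$coefficients))
    stop(sprintf("newx has %d columns; model was trained on %d",
                 ncol(newx), length(object$coefficients)))
  if (!is.null(colnames(newx)) && !is.null(object$column_ids) &&
      !identical(colnames(newx), object$column_ids))
    stop("column names of newx do not match the model's training columns")
  eta <- drop(object$intercept + newx %*% object$coefficients)
  switch(type,
         link = eta,
         response = clip_probability(stats::plogis(eta)),
         class = classify(clip_probability(stats::plogis(eta)), threshold))
}

#' Threshold probabilities into class labels
#'
#' Label 1 iff probability strictly exceeds the threshold; a tie at the
#' threshold goes to class 0.
#'
#' @param probabilities numeric vector in \[0, 1\].
#' @param threshold cut point, default 0.5.
#' @export
classify <- function(probabilities, threshold = 0.5) {
  stopifnot(all(probabilities >= 0 & probabilities <= 1))
  as.integer(probabilities > threshold)
}

# keep probabilities strictly inside (0, 1)
clip_probability <- function(p, eps = 1e-10) pmin(pmax(p, eps), 1 - eps)

#' Subgradient (KKT) optimality residuals of a fitted model
#'
#' For each penalized coordinate the residual is how far the coordinate is
#' from satisfying the soft-threshold stationarity condition on the
#' standardized scale; for the intercept it is the mean raw residual. A
#' converged solution has all residuals below the solver tolerance.
#'
#' @param object an `"enet_logit"` fit.
#' @param x,y the training data.
#' @return list with `coordinate` (length-p residual vector) and
#'   `intercept` residuals.
#' @export
kkt_residuals <- function(object, x, y) {
  xv <- validate_feature_matrix(x)
  y <- validate_labels(y, n = nrow(xv), require_both = FALSE)
  xs <- sweep(sweep(xv, 2, object$center, "-"), 2, object$scale, "/")
  n <- nrow(xs)
  eta <- drop(object$intercept_std + xs %*% object$coefficients_std)
  p <- clip_probability(stats::plogis(eta))
  g <- -drop(crossprod(xs, y - p)) / n   # gradient of the mean neg log-lik
  lam <- object$regularization$lambda
  al <- object$regularization$alpha
  b <- object$coefficients_std
  res <- numeric(length(b))
  nz <- b != 0
  res[nz] <- abs(g[nz] + lam * (1 - al) * b[nz] + lam * al * sign(b[nz]))
  res[!nz] <- pmax(abs(g[!nz]) - lam * al, 0)
  list(coordinate = res, intercept = abs(mean(y - p)))
}

#' @export
print.enet_logit <- function(x, ...) {
  cat("Elastic-net logistic regression\n")
  cat(sprintf("  alpha = %.3g, lambda = %.4g\n",
              x$regularization$alpha, x$regularization$lambda))
  cat(sprintf("  %d of %d coefficients nonzero; %s (objective %.6g)\n",
              x$n_nonzero, length(x$coefficients),
              if (x$converged) "converged" else "NOT converged",
              x$objective))
  invisible(x)
}

#' @export
coef.enet_logit <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
summary.enet_logit <- function(object, ...) {
  nz <- object$coefficients[object$coefficients != 0]
  structure(list(fit = object, nonzero = nz[order(-abs(nz))]),
            class = "summary.enet_logit")
}

#' @export
print.summary.enet_logit <- function(x, ...) {
  print(x$fit)
  cat("Largest-magnitude nonzero coefficients (original scale):\n")
  print(utils::head(x$nonzero, 10))
  invisible(x)
}

#' @export
print.enet_logit_path <- function(x, ...) {
  cat(sprintf("Elastic-net logistic path: alpha = %.3g, %d lambda values\n",
              x$alpha, length(x$lambda)))
  print(data.frame(lambda = signif(x$lambda, 4), n_nonzero = x$n_nonzero,
                   converged = x$converged))
  invisible(x)
}

#' Serialize a fitted model to a plain-text (JSON) container
#'
#' Stores the intercept, the nonzero coefficient triplets
#' (column id, index, value), the regularization pair and training metadata.
#'
#' @param object an `"enet_logit"` fit.
#' @param path file to write.
#' @export
write_enet_model <- function(object, path) {
  nz <- which(object$coefficients != 0)
  obj <- list(intercept = object$intercept,
              coefficients = list(index = nz,
                                  column_id = object$column_ids[nz],
                                  value = unname(object$coefficients[nz])),
              p = length(object$coefficients),
              column_ids = object$column_ids,
              regularization = object$regularization,
              standardize = object$standardize,
              center = object$center, scale = object$scale,
              intercept_std = object$intercept_std,
              coefficients_std = unname(object$coefficients_std),
              n_nonzero = object$n_nonzero,
              converged = object$converged,
              objective = object$objective, sweeps = object$sweeps)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model serialized by [write_enet_model()]
#' @param path file written by [write_enet_model()].
#' @export
read_enet_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  co <- numeric(obj$p)
  if (length(obj$coefficients$index))
    co[obj$coefficients$index] <- obj$coefficients$value
  names(co) <- obj$column_ids
  structure(list(intercept = obj$intercept, coefficients = co,
                 coefficients_std = obj$coefficients_std,
                 intercept_std = obj$intercept_std,
                 regularization = obj$regularization,
                 n_nonzero = obj$n_nonzero, converged = obj$converged,
                 objective = obj$objective, sweeps = obj$sweeps,
                 standardize = obj$standardize,
                 center = obj$center, scale = obj$scale,
                 column_ids = obj$column_ids),
            class = "enet_logit")
}

# ---- input validation and standardization ------------------------------

validate_feature_matrix <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("feature matrix must be numeric")
  if (anyNA(x)) stop("feature matrix contains missing values")
  if (nrow(x) < 2) stop("need at least 2 subjects")
  if (ncol(x) < 1) stop("need at least 1 variable")
  if (!is.null(colnames(x)) && anyDuplicated(colnames(x)))
    stop("column ids must be unique")
  x
}

validate_labels <- function(y, n, require_both = TRUE) {
  y <- as.numeric(y)
  if (length(y) != n) stop("labels and feature matrix are not conformable")
  if (anyNA(y) || !all(y %in% c(0, 1))) stop("labels must be coded 0/1")
  if (require_both && length(unique(y)) < 2)
    stop("both classes must be present to fit a classifier")
  y
}

# center/unit-scale columns (population SD, the solver library convention);
# constant columns get scale 1 so they pass through with a zero coefficient
standardize_columns <- function(x, standardize) {
  if (!standardize)
    return(list(x = x, center = rep(0, ncol(x)), scale = rep(1, ncol(x))))
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr, "-")
  sc <- sqrt(colMeans(xc^2))
  sc[sc == 0] <- 1
  list(x = sweep(xc, 2, sc, "/"), center = ctr, scale = sc)
}
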