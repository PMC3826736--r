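#' Class-stratified nested cross-validation fold plan
#'
#' Builds the three-way-split partition used throughout: an external K1-fold
#' split for testing, and, for each external fold, an internal K2-fold split
#' of the retained subjects for training/validation grid search. Folds are
#' class-stratified (each fold's class count within one subject of
#' proportional) so no validation fold degenerates to a single class at
#' small n.
#'
#' @param labels 0/1 label vector.
#' @param K1 external fold count.
#' @param K2 internal fold count.
#' @param seed integer seed; the same seed reproduces the plan exactly.
#' @return an object of class `"fold_plan"` with `external` (fold id per
#'   subject, 1..K1) and `internal` (list over external folds; fold id per
#'   subject in 1..K2, `NA` for the held-out external fold's subjects).
#' @export
make_fold_plan <- function(labels, K1 = 10, K2 = 10, seed = 1) {
  y <- as.numeric(labels)
  stopifnot(all(y %in% c(0, 1)), K1 >= 2, K2 >= 2)
  n <- length(y)
  if (min(table(y)) < K1)
    stop(sprintf("smallest class has %d subjects; stratified K1 = %d folds need at least K1 per class",
                 min(table(y)), K1))
  seeds <- derive_seeds(seed, K1 + 1L)
  external <- stratified_assignment(y, K1, seeds[1L])
  internal <- lapply(seq_len(K1), function(k) {
    keep <- external != k
    inner <- rep(NA_integer_, n)
    inner[keep] <- stratified_assignment(y[keep], K2, seeds[k + 1L])
    inner
  })
  structure(list(n_subjects = n, K1 = K1, K2 = K2, seed = seed,
                 external = external, internal = internal, labels = y),
            class = "fold_plan")
}

# per class, shuffle then deal round-robin into K folds (balanced within
# one subject); fold order itself is shuffled so fold 1 is not always largest
stratified_assignment <- function(y, K, seed) {
  n <- length(y)
  fold <- integer(n)
  with_local_seed(seed, {
    for (cl in sort(unique(y))) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(sample.int(K), length(idx))
    }
  })
  fold
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("Stratified nested CV plan: n = %d, K1 = %d, K2 = %d, seed = %d\n",
              x$n_subjects, x$K1, x$K2, x$seed))
  print(table(external_fold = x$external, class = x$labels))
  invisible(x)
}

#' Regularization search grid
#'
#' For imaging data the mixing parameter is fixed in advance (one `alpha`)
#' and only the penalty strength is searched; for cognitive data both are
#' searched on a two-dimensional grid. The lambda grid is anchored at
#' [lambda_max()] of each external fold's retained subjects and log-spaced
#' downward, so the path adapts to fold composition; a fixed
#' `lambda_values` vector overrides this.
#'
#' @param alpha_values mixing parameters to search (length 1 fixes alpha).
#' @param nlambda points on the log-spaced lambda grid.
#' @param lambda_min_ratio smallest lambda as a fraction of lambda_max.
#' @param lambda_values optional fixed, strictly decreasing lambda grid.
#' @return an object of class `"search_grid"`.
#' @export
search_grid <- function(alpha_values = 0.5, nlambda = 20,
                        lambda_min_ratio = 1e-4, lambda_values = NULL) {
  stopifnot(length(alpha_values) >= 1, all(alpha_values >= 0 & alpha_values <= 1))
  if (!is.null(lambda_values)) {
    stopifnot(length(lambda_values) >= 1, all(lambda_values > 0))
    if (length(lambda_values) > 1 && any(diff(lambda_values) >= 0))
      stop("lambda_values must be strictly decreasing")
  }
  structure(list(alpha_values = sort(alpha_values), nlambda = nlambda,
                 lambda_min_ratio = lambda_min_ratio,
                 lambda_values = lambda_values),
            class = "search_grid")
}

# concrete lambda grid for one training set (shared across inner folds)
resolve_lambda_grid <- function(grid, x, y) {
  if (!is.null(grid$lambda_values)) return(grid$lambda_values)
  lmax <- lambda_max(x, y, alpha = max(min(grid$alpha_values), 0.001))
  exp(seq(log(lmax), log(lmax * grid$lambda_min_ratio),
          length.out = grid$nlambda))
}

#' Classification accuracy, sensitivity and specificity (percent)
#'
#' Sensitivity is the true-positive rate on class 1, specificity the
#' true-negative rate on class 0, accuracy the overall correct fraction.
#' An absent class yields `NA` for its rate (flagged missing, never zero).
#'
#' @param truth,predicted 0/1 vectors of equal length.
#' @return named numeric vector `accuracy`, `sensitivity`, `specificity`,
#'   each on the 0-100 percent scale.
#' @export
performance_metrics <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  truth <- as.numeric(truth); predicted <- as.numeric(predicted)
  acc <- 100 * mean(predicted == truth)
  sens <- if (any(truth == 1)) 100 * mean(predicted[truth == 1] == 1) else NA_real_
  spec <- if (any(truth == 0)) 100 * mean(predicted[truth == 0] == 0) else NA_real_
  c(accuracy = acc, sensitivity = sens, specificity = spec)
}

#' Inner-loop grid selection of the regularization pair
#'
#' Runs the internal K2-fold training/validation loop on one external fold's
#' retained subjects and returns the regularization pair with maximum mean
#' validation accuracy. Ties are broken toward the larger lambda, then the
#' larger alpha (the sparser model). `select = "average"` instead records
#' each internal fold's maximizing pair and returns their arithmetic means.
#'
#' @param x,y retained subjects' data (the K1-1 training/validation folds).
#' @param inner_fold internal fold id per retained subject (1..K2).
#' @param grid a [search_grid()].
#' @param lambda_grid concrete lambda values (from [resolve_lambda_grid()]);
#'   computed from `x`, `y` when omitted.
#' @param select `"max"` (mean-accuracy maximizer, default) or `"average"`.
#' @param tol,max_iter passed to the solver.
#' @return list with `alpha`, `lambda`, and the mean validation `accuracy`
#'   surface (alpha x lambda, percent).
#' @export
inner_select <- function(x, y, inner_fold, grid, lambda_grid = NULL,
                         select = c("max", "average"),
                         tol = 1e-7, max_iter = 1e4) {
  select <- match.arg(select)
  if (is.null(lambda_grid)) lambda_grid <- resolve_lambda_grid(grid, x, y)
  K2 <- max(inner_fold)
  alphas <- grid$alpha_values
  L <- length(lambda_grid)
  # acc[a, l, k]: validation accuracy at grid point for inner fold k
  acc <- array(NA_real_, dim = c(length(alphas), L, K2))
  for (k in seq_len(K2)) {
    tr <- inner_fold != k
    va <- !tr
    for (a in seq_along(alphas)) {
      path <- enet_logit_path(x[tr, , drop = FALSE], y[tr],
                              alpha = alphas[a], lambda = lambda_grid,
                              tol = tol, max_iter = max_iter, warn = FALSE)
      eta <- sweep(x[va, , drop = FALSE] %*% path$beta, 2, path$intercept, "+")
      pred <- (stats::plogis(eta) > 0.5) + 0L
      acc[a, , k] <- 100 * colMeans(pred == y[va])
    }
  }
  mean_acc <- apply(acc, c(1, 2), mean)
  if (select == "max") {
    best <- which(mean_acc == max(mean_acc), arr.ind = TRUE)
    # largest lambda (smallest column index on the decreasing grid),
    # then largest alpha
    best <- best[order(best[, 2], -best[, 1]), , drop = FALSE][1, ]
    list(alpha = alphas[best[1]], lambda = lambda_grid[best[2]],
         accuracy_surface = mean_acc, lambda_grid = lambda_grid)
  } else {
    sel <- t(vapply(seq_len(K2), function(k) {
      m <- acc[, , k, drop = FALSE][, , 1, drop = FALSE]
      dim(m) <- dim(acc)[1:2]
      b <- which(m == max(m), arr.ind = TRUE)
      b <- b[order(b[, 2], -b[, 1]), , drop = FALSE][1, ]
      c(alphas[b[1]], lambda_grid[b[2]])
    }, numeric(2)))
    list(alpha = mean(sel[, 1]), lambda = mean(sel[, 2]),
         accuracy_surface = mean_acc, lambda_grid = lambda_grid)
  }
}

#' Nested cross-validation evaluation with out-of-fold scoring
#'
#' The full three-way-split protocol: for each repetition a fresh stratified
#' partition is drawn; for each external fold the regularization pair is
#' chosen by [inner_select()] using only that fold's retained subjects, the
#' model is refitted on those subjects at the chosen pair, and evaluated on
#' the held-out fold. Accuracy, sensitivity and specificity are averaged
#' over external folds within a repetition; medians across repetitions are
#' reported. Each subject's out-of-fold probability (from the one external
#' model that never saw it) is recorded once per repetition — these are the
#' raw material of the AD-PS scores.
#'
#' @param x feature matrix (subjects x variables).
#' @param y 0/1 labels.
#' @param grid a [search_grid()].
#' @param K1,K2 external/internal fold counts.
#' @param repetitions number of fresh random partitions.
#' @param seed base seed; repetition r uses the r-th derived sub-seed, so
#'   results for repetition r never depend on how many repetitions follow.
#' @param select inner selection rule, see [inner_select()].
#' @param tol,max_iter solver controls.
#' @return an object of class `"adps_cv"`: `per_repetition` (metrics per
#'   repetition, percent), `fold_detail` (per repetition x fold: selected
#'   pair + metrics), `oof` (n x repetitions out-of-fold probabilities),
#'   `oof_fold` (which external fold scored each subject), `plans`
#'   (external assignments per repetition, for leakage audits), and
#'   `median_accuracy` / `median_sensitivity` / `median_specificity`.
#' @export
nested_cv <- function(x, y, grid = search_grid(), K1 = 10, K2 = 10,
                      repetitions = 100, seed = 1,
                      select = c("max", "average"),
                      tol = 1e-7, max_iter = 1e4) {
  select <- match.arg(select)
  xv <- validate_feature_matrix(x)
  y <- validate_labels(y, n = nrow(xv), require_both = TRUE)
  stopifnot(repetitions >= 1)
  n <- nrow(xv)
  rep_seeds <- derive_seeds(seed, repetitions)

  oof <- matrix(NA_real_, n, repetitions)
  oof_fold <- matrix(NA_integer_, n, repetitions)
  plans <- matrix(NA_integer_, n, repetitions)
  fold_rows <- vector("list", repetitions)
  per_rep <- matrix(NA_real_, repetitions, 3,
                    dimnames = list(NULL, c("accuracy", "sensitivity", "specificity")))

  for (r in seq_len(repetitions)) {
    plan <- make_fold_plan(y, K1 = K1, K2 = K2, seed = rep_seeds[r])
    plans[, r] <- plan$external
    fm <- matrix(NA_real_, K1, 3)
    rows <- vector("list", K1)
    for (k in seq_len(K1)) {
      keep <- plan$external != k
      sel <- inner_select(xv[keep, , drop = FALSE], y[keep],
                          inner_fold = plan$internal[[k]][keep],
                          grid = grid, select = select,
                          tol = tol, max_iter = max_iter)
      fit <- enet_logit(xv[keep, , drop = FALSE], y[keep],
                        alpha = sel$alpha, lambda = sel$lambda,
                        tol = tol, max_iter = max_iter)
      test <- which(!keep)
      prob <- predict(fit, xv[test, , drop = FALSE], type = "response")
      oof[test, r] <- prob
      oof_fold[test, r] <- k
      m <- performance_metrics(y[test], classify(prob))
      fm[k, ] <- m
      rows[[k]] <- data.frame(repetition = r, fold = k,
                              alpha = sel$alpha, lambda = sel$lambda,
                              accuracy = m[1], sensitivity = m[2],
                              specificity = m[3])
    }
    per_rep[r, ] <- colMeans(fm, na.rm = TRUE)
    fold_rows[[r]] <- do.call(rbind, rows)
  }

  per_repetition <- data.frame(repetition = seq_len(repetitions), per_rep)
  structure(list(per_repetition = per_repetition,
                 fold_detail = do.call(rbind, fold_rows),
                 oof = oof, oof_fold = oof_fold, plans = plans,
                 labels = y, K1 = K1, K2 = K2, seed = seed,
                 repetitions = repetitions, grid = grid,
                 median_accuracy = median(per_rep[, 1]),
                 median_sensitivity = median(per_rep[, 2]),
                 median_specificity = median(per_rep[, 3])),
            class = "adps_cv")
}

#' @export
print.adps_cv <- function(x, ...) {
  cat(sprintf("Nested CV (K1 = %d, K2 = %d, %d repetition(s))\n",
              x$K1, x$K2, x$repetitions))
  cat(sprintf("  median accuracy    %5.1f%%\n", x$median_accuracy))
  cat(sprintf("  median sensitivity %5.1f%%\n", x$median_sensitivity))
  cat(sprintf("  median specificity %5.1f%%\n", x$median_specificity))
  invisible(x)
}

#' @export
summary.adps_cv <- function(object, ...) {
  s <- apply(object$per_repetition[, -1], 2, quantile,
             probs = c(0.25, 0.5, 0.75), na.rm = TRUE)
  structure(list(cv = object, quartiles = s), class = "summary.adps_cv")
}

#' @export
print.summary.adps_cv <- function(x, ...) {
  print(x$cv)
  cat("Quartiles across repetitions (percent):\n")
  print(round(x$quartiles, 1))
  invisible(x)
}

#' Audit an `adps_cv` object for train/test leakage
#'
#' Verifies from the recorded fold provenance that every subject's
#' out-of-fold probability came from a model whose training subjects
#' exclude it (the subject's external fold differs from every training
#' subject's fold in that repetition, by construction of the plan).
#'
#' @param cv an `"adps_cv"` object.
#' @return TRUE invisibly; stops with a message on any violation.
#' @export
audit_no_leakage <- function(cv) {
  stopifnot(inherits(cv, "adps_cv"))
  for (r in seq_len(cv$repetitions)) {
    scored_by <- cv$oof_fold[, r]
    own_fold <- cv$plans[, r]
    if (any(is.na(scored_by)))
      stop(sprintf("repetition %d: some subjects were never scored", r))
    if (!all(scored_by == own_fold))
      stop(sprintf("repetition %d: a subject was scored by a model trained on its own fold", r))
    if (anyDuplicated(cbind(seq_along(scored_by), r)) > 0)
      stop("duplicate scoring records")
  }
  invisible(TRUE)
}
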