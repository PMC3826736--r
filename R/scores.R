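#' AD-PS scores for the anchor classes (out-of-fold)
#'
#' Scores the two anchor classes (cognitively normal = 0, disease = 1) with
#' the nested-CV out-of-fold protocol: each subject's score is the median,
#' across repetitions, of the probability produced by the external-fold
#' model that held that subject out. This avoids the optimism of scoring a
#' subject with a model that saw it.
#'
#' @inheritParams nested_cv
#' @param modality label recorded with the scores, e.g. `"GM"`, `"WM"`,
#'   `"CSF"`, `"cognitive"`.
#' @param subject_ids optional ids (defaults to rownames of `x` or 1..n).
#' @return an object of class `"adps_scores"`: `table` (data frame with
#'   subject_id, score, provenance), `modality`, `repetitions_used`, and the
#'   underlying `"adps_cv"` object in `$cv`.
#' @export
adps_scores <- function(x, y, grid = search_grid(), K1 = 10, K2 = 10,
                        repetitions = 100, seed = 1, modality = "GM",
                        subject_ids = NULL, ...) {
  cv <- nested_cv(x, y, grid = grid, K1 = K1, K2 = K2,
                  repetitions = repetitions, seed = seed, ...)
  score <- apply(cv$oof, 1, median)
  ids <- subject_ids %||% rownames(x) %||% as.character(seq_len(nrow(x)))
  structure(list(table = data.frame(subject_id = ids, score = score,
                                    provenance = "out_of_fold",
                                    label = y,
                                    stringsAsFactors = FALSE),
                 modality = modality, repetitions_used = repetitions,
                 cv = cv),
            class = "adps_scores")
}

#' AD-PS scores for a held-out (intermediate) group
#'
#' Intermediate groups (e.g. MCI) are scored by models trained on all
#' available anchor-class subjects: per repetition, the regularization pair
#' is selected by an internal K2-fold grid search on the full anchor set,
#' the model is refitted on all anchors at that pair, and the held-out
#' subjects' probabilities are computed. The score is the median across
#' repetitions; provenance is `full_model`.
#'
#' @param x_anchor,y_anchor anchor-class data.
#' @param x_holdout held-out subjects' data (columns must match the anchors).
#' @inheritParams adps_scores
#' @param K2 internal fold count for the per-repetition grid search.
#' @return an `"adps_scores"` object (provenance `full_model`); the
#'   per-repetition fitted models' metadata are in `$ensemble`.
#' @export
adps_score_holdout <- function(x_anchor, y_anchor, x_holdout,
                               grid = search_grid(), K2 = 10,
                               repetitions = 100, seed = 1,
                               modality = "GM", subject_ids = NULL, ...) {
  x_anchor <- validate_feature_matrix(x_anchor)
  x_holdout <- as.matrix(x_holdout)
  if (ncol(x_holdout) != ncol(x_anchor))
    stop("holdout columns do not match anchor columns")
  if (!is.null(colnames(x_holdout)) && !is.null(colnames(x_anchor)) &&
      !identical(colnames(x_holdout), colnames(x_anchor)))
    stop("holdout column ids do not match anchor column ids")
  ens <- full_model_ensemble(x_anchor, y_anchor, grid = grid, K2 = K2,
                             repetitions = repetitions, seed = seed, ...)
  probs <- vapply(ens$models,
                  function(m) predict(m, x_holdout, type = "response"),
                  numeric(nrow(x_holdout)))
  probs <- matrix(probs, nrow = nrow(x_holdout))
  score <- apply(probs, 1, median)
  ids <- subject_ids %||% rownames(x_holdout) %||%
    as.character(seq_len(nrow(x_holdout)))
  structure(list(table = data.frame(subject_id = ids, score = score,
                                    provenance = "full_model",
                                    label = NA_real_,
                                    stringsAsFactors = FALSE),
                 modality = modality, repetitions_used = repetitions,
                 ensemble = ens, per_repetition_probability = probs),
            class = "adps_scores")
}

#' Per-repetition full-anchor model ensemble
#'
#' One fit on all anchor subjects per repetition, at the regularization pair
#' selected by that repetition's internal K2-fold grid search. This is the
#' shared machinery behind holdout scoring and the discriminative-map weight
#' ensembles.
#'
#' @inheritParams adps_score_holdout
#' @param x,y anchor-class data.
#' @return list with `models` (list of `"enet_logit"` fits), `selected`
#'   (data frame of per-repetition alpha/lambda) and the call parameters.
#' @export
full_model_ensemble <- function(x, y, grid = search_grid(), K2 = 10,
                                repetitions = 100, seed = 1,
                                select = c("max", "average"),
                                tol = 1e-7, max_iter = 1e4) {
  select <- match.arg(select)
  xv <- validate_feature_matrix(x)
  y <- validate_labels(y, n = nrow(xv), require_both = TRUE)
  rep_seeds <- derive_seeds(seed, repetitions)
  models <- vector("list", repetitions)
  sel_tab <- matrix(NA_real_, repetitions, 2,
                    dimnames = list(NULL, c("alpha", "lambda")))
  for (r in seq_len(repetitions)) {
    inner_fold <- stratified_assignment(y, K2, rep_seeds[r])
    sel <- inner_select(xv, y, inner_fold = inner_fold, grid = grid,
                        select = select, tol = tol, max_iter = max_iter)
    models[[r]] <- enet_logit(xv, y, alpha = sel$alpha, lambda = sel$lambda,
                              tol = tol, max_iter = max_iter)
    sel_tab[r, ] <- c(sel$alpha, sel$lambda)
  }
  list(models = models,
       selected = data.frame(repetition = seq_len(repetitions), sel_tab),
       K2 = K2, seed = seed, repetitions = repetitions)
}

#' @export
print.adps_scores <- function(x, ...) {
  cat(sprintf("AD-PS scores [%s], %d subjects, %d repetition(s), provenance: %s\n",
              x$modality, nrow(x$table), x$repetitions_used,
              paste(unique(x$table$provenance), collapse = "/")))
  print(summary(x$table$score))
  invisible(x)
}

#' Combine AD-PS score sets across modalities and groups
#'
#' Row-binds anchor and holdout score sets of the same modality into one
#' table, preserving provenance.
#'
#' @param ... `"adps_scores"` objects of the same modality.
#' @return a combined `"adps_scores"` object (without CV internals).
#' @export
combine_scores <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) >= 1, all(vapply(sets, inherits, TRUE, "adps_scores")))
  mods <- unique(vapply(sets, `[[`, "", "modality"))
  if (length(mods) != 1) stop("cannot combine scores of different modalities")
  tab <- do.call(rbind, lapply(sets, `[[`, "table"))
  if (anyDuplicated(tab$subject_id)) stop("duplicate subject ids across sets")
  structure(list(table = tab, modality = mods,
                 repetitions_used = max(vapply(sets, `[[`, 0, "repetitions_used"))),
            class = "adps_scores")
}

#' Composite anatomical and cognitive-anatomical risk scores
#'
#' The anatomical composite is the exact sum of the GM, WM and CSF
#' probabilities (range \[0, 3\]); the cognitive-anatomical composite adds
#' the cognitive score (range \[0, 4\]). No renormalization is applied: the
#' composite equals the sum of its parts.
#'
#' @param scores named list of `"adps_scores"` objects; names must include
#'   `GM`, `WM`, `CSF` (and `cognitive` for the cognitive-anatomical kind).
#'   All sets must cover the same subjects.
#' @param kind `"anatomical"` or `"cognitive_anatomical"`.
#' @return data frame with subject_id and `composite`.
#' @export
adps_composite <- function(scores, kind = c("anatomical", "cognitive_anatomical")) {
  kind <- match.arg(kind)
  need <- if (kind == "anatomical") c("GM", "WM", "CSF")
          else c("GM", "WM", "CSF", "cognitive")
  missing_mod <- setdiff(need, names(scores))
  if (length(missing_mod))
    stop("missing modality for composite: ", paste(missing_mod, collapse = ", "))
  ids <- scores[[need[1]]]$table$subject_id
  vals <- matrix(0, length(ids), length(need))
  for (i in seq_along(need)) {
    tab <- scores[[need[i]]]$table
    if (!identical(sort(tab$subject_id), sort(ids)))
      stop("modalities cover different subject sets")
    vals[, i] <- tab$score[match(ids, tab$subject_id)]
  }
  data.frame(subject_id = ids, composite = rowSums(vals),
             stringsAsFactors = FALSE)
}

#' Positions in the probability hypercube
#'
#' Stacks per-modality scores into an n x D matrix of coordinates inside the
#' unit hypercube, in the fixed recorded order (GM, WM, CSF, cognitive by
#' default). Each subject's score vector is a point; the all-ones vertex is
#' the "AD corner".
#'
#' @param scores named list of `"adps_scores"` objects.
#' @param order modality order of the axes.
#' @return numeric matrix with one row per subject (rownames = subject ids),
#'   columns named by modality, attribute `modality_order` recorded.
#' @export
hypercube_points <- function(scores,
                             order = c("GM", "WM", "CSF", "cognitive")) {
  order <- intersect(order, names(scores))
  if (!length(order)) stop("no requested modality present")
  ids <- scores[[order[1]]]$table$subject_id
  pts <- vapply(order, function(m) {
    tab <- scores[[m]]$table
    tab$score[match(ids, tab$subject_id)]
  }, numeric(length(ids)))
  pts <- matrix(pts, nrow = length(ids), dimnames = list(ids, order))
  structure(pts, modality_order = order)
}

#' Risk-zone classification inside the probability hypercube
#'
#' A point is in the low-risk zone iff every coordinate is strictly below
#' the threshold, the high-risk zone iff every coordinate is strictly above
#' it, and indeterminate otherwise (including any coordinate exactly at the
#' threshold). The three zones partition the hypercube.
#'
#' @param points numeric vector (one point) or n x D matrix.
#' @param threshold per-coordinate cut, default 0.5.
#' @return factor with levels `low`, `indeterminate`, `high`.
#' @export
risk_zone <- function(points, threshold = 0.5) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  lo <- apply(points < threshold, 1, all)
  hi <- apply(points > threshold, 1, all)
  factor(ifelse(lo, "low", ifelse(hi, "high", "indeterminate")),
         levels = c("low", "indeterminate", "high"))
}

#' Euclidean distance to a hypercube corner
#'
#' Proximity to the origin corner (0, 0, ..., 0) signals lower risk;
#' proximity to the AD corner (1, 1, ..., 1) signals AD-like patterns
#' across all modalities. Distances lie in \[0, sqrt(D)\].
#'
#' @param points numeric vector or n x D matrix of hypercube positions.
#' @param corner binary vector of length D.
#' @export
corner_distance <- function(points, corner) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  if (ncol(points) != length(corner))
    stop("corner dimension does not match point dimension")
  stopifnot(all(corner %in% c(0, 1)))
  sqrt(rowSums(sweep(points, 2, corner, "-")^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
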