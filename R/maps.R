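#' Full-data weight ensemble across CV repetitions
#'
#' Fits one model per repetition on the full anchor dataset, at the
#' regularization pair re-selected by that repetition's internal CV
#' partition, and collects the coefficient vectors (original feature scale).
#' The row-wise variability of this ensemble reflects sensitivity to CV
#' partitioning; its summary is the discriminative map.
#'
#' @inheritParams adps_scores
#' @return an object of class `"weight_ensemble"`: `weights`
#'   (repetitions x p matrix), `intercepts`, `selected` (per-repetition
#'   alpha/lambda), `column_ids`.
#' @export
weight_ensemble <- function(x, y, grid = search_grid(), K2 = 10,
                            repetitions = 100, seed = 1, ...) {
  ens <- full_model_ensemble(x, y, grid = grid, K2 = K2,
                             repetitions = repetitions, seed = seed, ...)
  w <- t(vapply(ens$models, function(m) unname(m$coefficients),
                numeric(length(ens$models[[1]]$coefficients))))
  colnames(w) <- ens$models[[1]]$column_ids
  structure(list(weights = w,
                 intercepts = vapply(ens$models, `[[`, 0, "intercept"),
                 selected = ens$selected,
                 column_ids = ens$models[[1]]$column_ids,
                 repetitions = repetitions, seed = seed),
            class = "weight_ensemble")
}

#' @export
print.weight_ensemble <- function(x, ...) {
  cat(sprintf("Weight ensemble: %d repetitions x %d variables; mean support %0.1f voxels\n",
              nrow(x$weights), ncol(x$weights),
              mean(rowSums(x$weights != 0))))
  invisible(x)
}

#' Stability-ratio discriminative map
#'
#' Per voxel, the mean of the ensemble weights divided by their standard
#' deviation (n-1 denominator) across repetitions: a signed, unitless
#' stability measure. Voxels never selected (SD 0, mean 0) map to 0;
#' degenerate voxels with identical nonzero weights (SD 0, mean != 0) are
#' capped at a signed sentinel and flagged. The sign convention follows the
#' label coding (0 = CN, 1 = AD): with atrophy coded as lower intensity, a
#' voxel whose atrophy predicts AD carries a negative weight. Signs are
#' recorded, interpretation is left to the caller.
#'
#' @param ensemble a `"weight_ensemble"` (>= 2 repetitions for a meaningful
#'   SD; 1 is allowed and treated as degenerate).
#' @param cap sentinel magnitude for SD = 0, mean != 0 voxels.
#' @return an object of class `"discriminative_map"`: `ratio` (per masked
#'   voxel), `mean`, `sd`, `capped` (logical), `n_repetitions`,
#'   `column_ids`.
#' @export
stability_ratio <- function(ensemble, cap = 1e6) {
  stopifnot(inherits(ensemble, "weight_ensemble"))
  w <- ensemble$weights
  if (nrow(w) == 0) stop("empty ensemble")
  m <- colMeans(w)
  s <- if (nrow(w) >= 2) apply(w, 2, sd) else rep(0, ncol(w))
  ratio <- numeric(length(m))
  ok <- s > 0
  ratio[ok] <- m[ok] / s[ok]
  degen <- !ok & m != 0
  ratio[degen] <- sign(m[degen]) * cap
  structure(list(ratio = ratio, mean = m, sd = s, capped = degen,
                 n_repetitions = nrow(w), cap = cap,
                 column_ids = ensemble$column_ids),
            class = "discriminative_map")
}

#' @export
print.discriminative_map <- function(x, ...) {
  cat(sprintf("Discriminative map over %d voxels (%d repetitions): %d nonzero, %d capped\n",
              length(x$ratio), x$n_repetitions, sum(x$ratio != 0),
              sum(x$capped)))
  invisible(x)
}

#' Top-magnitude voxels of a discriminative map
#'
#' @param map a `"discriminative_map"`.
#' @param k how many voxels.
#' @return integer vector of voxel linear indices (from `column_ids`) of the
#'   k largest |ratio| values.
#' @export
top_map_voxels <- function(map, k) {
  ord <- order(-abs(map$ratio))
  head_idx <- ord[seq_len(min(k, length(ord)))]
  as.integer(map$column_ids[head_idx])
}
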