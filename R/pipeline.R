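#' Pipeline run configuration
#'
#' Collects every analysis constant in one place: fold counts, repetition
#' count, the fixed imaging mixing parameter, the two-dimensional cognitive
#' grid, and the thresholds (mask 0.5, risk zone 0.5, age 75, FAQ 2). All
#' are defaults, never hard-coded downstream.
#'
#' @param modalities which modalities to analyse.
#' @param K1,K2 external/internal fold counts (>= 2).
#' @param repetitions CV repetitions per modality.
#' @param seed base seed for the whole run.
#' @param alpha_imaging fixed mixing parameter for voxel data.
#' @param alpha_cognitive grid of mixing parameters for cognitive data.
#' @param nlambda,lambda_min_ratio lambda grid geometry.
#' @param mask_threshold,risk_threshold,age_cut,faq_cut analysis thresholds.
#' @param tol,max_iter solver controls.
#' @return an object of class `"run_config"`.
#' @export
run_config <- function(modalities = c("GM", "WM", "CSF", "cognitive"),
                       K1 = 10, K2 = 10, repetitions = 100, seed = 1,
                       alpha_imaging = 0.5,
                       alpha_cognitive = seq(0.1, 1, by = 0.1),
                       nlambda = 20, lambda_min_ratio = 1e-4,
                       mask_threshold = 0.5, risk_threshold = 0.5,
                       age_cut = 75, faq_cut = 2,
                       tol = 1e-7, max_iter = 1e4) {
  stopifnot(K1 >= 2, K2 >= 2, repetitions >= 1,
            is.finite(c(mask_threshold, risk_threshold, age_cut, faq_cut)))
  # canonical storage types and 15-significant-digit numeric values (the
  # precision JSON text carries), so a config that round-trips through
  # write_run_config / config_from_manifest hashes identically
  num <- function(x) signif(as.numeric(x), 15)
  structure(list(modalities = as.character(modalities),
                 K1 = as.integer(K1), K2 = as.integer(K2),
                 repetitions = as.integer(repetitions),
                 seed = as.integer(seed),
                 alpha_imaging = num(alpha_imaging),
                 alpha_cognitive = num(alpha_cognitive),
                 nlambda = as.integer(nlambda),
                 lambda_min_ratio = num(lambda_min_ratio),
                 mask_threshold = num(mask_threshold),
                 risk_threshold = num(risk_threshold),
                 age_cut = num(age_cut), faq_cut = num(faq_cut),
                 tol = num(tol), max_iter = num(max_iter)),
            class = "run_config")
}

modality_grid <- function(config, modality) {
  if (modality == "cognitive")
    search_grid(alpha_values = config$alpha_cognitive,
                nlambda = config$nlambda,
                lambda_min_ratio = config$lambda_min_ratio)
  else
    search_grid(alpha_values = config$alpha_imaging,
                nlambda = config$nlambda,
                lambda_min_ratio = config$lambda_min_ratio)
}

# stable short hash of an arbitrary R object (polynomial rolling hash over
# its serialization, kept inside 2^31 so integer arithmetic never overflows)
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full AD-PS analysis on a cohort
#'
#' Executes, per modality: nested-CV performance estimation, out-of-fold
#' anchor scoring (CN-like vs AD-like groups), full-model scoring of the
#' intermediate (MCI-like) groups, then across modalities: composites,
#' hypercube risk zones, stratified median/KS tables (cognitive status,
#' age, FAQ), discriminative maps for the tissue modalities, and the
#' proportional-hazards association of each metric with conversion time.
#' Every stage is seeded from the config seed, so a rerun with the same
#' cohort and config reproduces all outputs exactly.
#'
#' @param cohort a `"synthetic_cohort"` (or a list of the same shape built
#'   from real data).
#' @param config a [run_config()].
#' @param anchor_groups length-2 character: the class-0 and class-1 anchor
#'   group labels.
#' @param outdir optional directory; when given, score tables, result
#'   tables and a JSON manifest are written there. If a stage fails, the
#'   score tables of the stages already completed are still written there
#'   before the error propagates.
#' @param maps fit weight ensembles and stability-ratio maps for tissue
#'   modalities (skipped when FALSE to save time).
#' @param verbose log per-stage wall time and solver convergence counts
#'   (informational only).
#' @return an object of class `"adps_run"`.
#' @export
run_pipeline <- function(cohort, config = run_config(),
                         anchor_groups = c("CNsim", "ADsim"),
                         outdir = NULL, maps = TRUE, verbose = FALSE) {
  grp <- cohort$subjects$group
  ids <- cohort$subjects$subject_id
  anchor <- grp %in% anchor_groups
  y_anchor <- as.numeric(grp[anchor] == anchor_groups[2])
  if (!any(anchor)) stop("stage anchors: no anchor-group subjects found")
  seeds <- derive_seeds(config$seed, length(config$modalities) * 2L + 2L)
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))

  get_x <- function(modality) {
    if (modality == "cognitive") cohort$cognitive
    else cohort$images[[modality]]$x
  }

  scores <- list(); performance <- list(); ensembles <- list()
  persist_partial <- function(e) {
    if (!is.null(outdir) && length(scores)) {
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      partial <- do.call(rbind, lapply(names(scores), function(m)
        cbind(modality = m, scores[[m]]$table)))
      write.csv(partial, file.path(outdir, "scores_partial.csv"),
                row.names = FALSE)
    }
    stop(e)
  }
  si <- 1L
  for (m in config$modalities) {
    t_stage <- Sys.time()
    x <- get_x(m)
    if (is.null(x))
      persist_partial(simpleError(
        paste0("stage scoring: cohort is missing modality ", m)))
    g <- modality_grid(config, m)
    anc <- adps_scores(x[anchor, , drop = FALSE], y_anchor, grid = g,
                       K1 = config$K1, K2 = config$K2,
                       repetitions = config$repetitions,
                       seed = seeds[si], modality = m,
                       subject_ids = ids[anchor],
                       tol = config$tol, max_iter = config$max_iter)
    hold <- adps_score_holdout(x[anchor, , drop = FALSE], y_anchor,
                               x[!anchor, , drop = FALSE], grid = g,
                               K2 = config$K2,
                               repetitions = config$repetitions,
                               seed = seeds[si + 1L], modality = m,
                               subject_ids = ids[!anchor],
                               tol = config$tol, max_iter = config$max_iter)
    performance[[m]] <- anc$cv
    scores[[m]] <- combine_scores(anc, hold)
    if (maps && m != "cognitive")
      ensembles[[m]] <- structure(list(
        weights = t(vapply(hold$ensemble$models,
                           function(mm) unname(mm$coefficients),
                           numeric(ncol(x)))),
        intercepts = vapply(hold$ensemble$models, `[[`, 0, "intercept"),
        selected = hold$ensemble$selected,
        column_ids = colnames(x),
        repetitions = config$repetitions, seed = seeds[si + 1L]),
        class = "weight_ensemble")
    say("stage scoring [%s]: %.1f s, %d/%d holdout refits converged", m,
        as.numeric(difftime(Sys.time(), t_stage, units = "secs")),
        sum(vapply(hold$ensemble$models, `[[`, TRUE, "converged")),
        length(hold$ensemble$models))
    si <- si + 2L
  }

  # reorder every score table to cohort subject order
  score_vec <- lapply(scores, function(s)
    s$table$score[match(ids, s$table$subject_id)])
  names(score_vec) <- names(scores)

  metrics <- score_vec
  tissue_mods <- intersect(c("GM", "WM", "CSF"), names(scores))
  if (length(tissue_mods) == 3) {
    metrics$Anatomical <- Reduce(`+`, score_vec[tissue_mods])
    if ("cognitive" %in% names(scores))
      metrics$Composite <- metrics$Anatomical + score_vec$cognitive
  }

  pts <- hypercube_points(scores,
                          order = intersect(c("GM", "WM", "CSF", "cognitive"),
                                            names(scores)))
  pts <- pts[match(ids, rownames(pts)), , drop = FALSE]
  zones <- risk_zone(pts, threshold = config$risk_threshold)

  strata_tables <- list(
    status = stratified_table(metrics, grp),
    age = stratified_table(metrics,
                           ifelse(cohort$subjects$age < config$age_cut,
                                  "young", "old")),
    faq = stratified_table(metrics,
                           ifelse(cohort$subjects$faq <= config$faq_cut,
                                  "low_faq", "high_faq")))

  survival_results <- NULL
  if (!is.null(cohort$survival)) {
    sid <- cohort$survival$subject_id
    survival_results <- do.call(rbind, lapply(names(metrics), function(mn) {
      v <- metrics[[mn]][match(sid, ids)]
      cx <- cox_fit_safe(v, cohort$survival$time_months, cohort$survival$event)
      data.frame(metric = mn, hazard_ratio_per_sd = cx$hazard_ratio,
                 ci95_low = cx$ci95_low, ci95_high = cx$ci95_high,
                 z = cx$z_statistic, p_value = cx$p_value)
    }))
  }

  disc_maps <- lapply(ensembles, stability_ratio)

  run <- structure(list(scores = scores, performance = performance,
                        metrics = metrics, hypercube = pts,
                        risk_zone = zones,
                        strata_tables = strata_tables,
                        survival = survival_results,
                        ensembles = ensembles, maps = disc_maps,
                        subjects = cohort$subjects,
                        config = config,
                        config_hash = config_hash(config),
                        anchor_groups = anchor_groups),
                   class = "adps_run")
  if (!is.null(outdir)) write_run(run, outdir)
  run
}

cox_fit_safe <- function(v, time, event) {
  tryCatch(cox_per_sd(v, time, event),
           error = function(e) list(hazard_ratio = NA_real_,
                                    ci95_low = NA_real_, ci95_high = NA_real_,
                                    z_statistic = NA_real_, p_value = NA_real_))
}

#' @export
print.adps_run <- function(x, ...) {
  cat("AD-PS pipeline run (config hash ", x$config_hash, ")\n", sep = "")
  for (m in names(x$performance))
    cat(sprintf("  %-9s median accuracy %5.1f%%\n", m,
                x$performance[[m]]$median_accuracy))
  cat("Risk zones: ")
  print(table(x$risk_zone))
  invisible(x)
}

#' Write all pipeline outputs and a manifest
#'
#' Writes the per-modality score table, per-repetition CV metric tables,
#' stratified median/p-value tables, survival results and a JSON manifest
#' recording the seed, config hash and files produced.
#'
#' @param run an `"adps_run"`.
#' @param outdir output directory (created if needed).
#' @export
write_run <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(df, name) {
    # every table carries the seed and config hash that produced it
    df$seed <- run$config$seed
    df$config_hash <- run$config_hash
    path <- file.path(outdir, name)
    write.csv(df, path, row.names = FALSE)
    files <<- c(files, name)
  }
  score_tab <- do.call(rbind, lapply(names(run$scores), function(m) {
    tab <- run$scores[[m]]$table
    data.frame(subject_id = tab$subject_id,
               group = run$subjects$group[match(tab$subject_id,
                                                run$subjects$subject_id)],
               modality = m, score = tab$score,
               provenance = tab$provenance,
               repetitions_used = run$scores[[m]]$repetitions_used)
  }))
  emit(score_tab, "scores.csv")
  emit(do.call(rbind, lapply(names(run$performance), function(m)
    cbind(modality = m, run$performance[[m]]$fold_detail))),
    "cv_fold_detail.csv")
  emit(do.call(rbind, lapply(names(run$performance), function(m)
    cbind(modality = m, run$performance[[m]]$per_repetition))),
    "cv_per_repetition.csv")
  comp <- data.frame(subject_id = run$subjects$subject_id,
                     risk_zone = run$risk_zone)
  for (mn in names(run$metrics)) comp[[mn]] <- run$metrics[[mn]]
  emit(comp, "composites.csv")
  for (nm in names(run$strata_tables))
    emit(run$strata_tables[[nm]], paste0("strata_", nm, ".csv"))
  if (!is.null(run$survival)) emit(run$survival, "survival.csv")
  manifest <- list(seed = run$config$seed, config = unclass(run$config),
                   config_hash = run$config_hash,
                   anchor_groups = run$anchor_groups,
                   files = files,
                   package_version = as.character(utils::packageVersion("adps")))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Rebuild a run configuration from a written manifest
#'
#' Reads the `manifest.json` emitted by [write_run()] and reconstructs the
#' [run_config()] it records, so a rerun on the same cohort reproduces all
#' deterministic outputs exactly.
#'
#' @param path path to a `manifest.json` (or the directory containing it).
#' @return a `"run_config"`.
#' @export
config_from_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.json")
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  cf <- man$config
  config <- run_config(modalities = cf$modalities, K1 = cf$K1, K2 = cf$K2,
                       repetitions = cf$repetitions, seed = cf$seed,
                       alpha_imaging = cf$alpha_imaging,
                       alpha_cognitive = cf$alpha_cognitive,
                       nlambda = cf$nlambda,
                       lambda_min_ratio = cf$lambda_min_ratio,
                       mask_threshold = cf$mask_threshold,
                       risk_threshold = cf$risk_threshold,
                       age_cut = cf$age_cut, faq_cut = cf$faq_cut,
                       tol = cf$tol, max_iter = cf$max_iter)
  if (config_hash(config) != man$config_hash)
    stop("manifest config hash mismatch: expected ", man$config_hash,
         ", reconstructed ", config_hash(config))
  config
}

#' Read and write run configurations as plain-text JSON
#'
#' A [run_config()] round-trips through a single structured text file, so
#' analyses can be configured without touching code.
#'
#' @param config a `"run_config"`.
#' @param path file path.
#' @return `read_run_config` returns a `"run_config"`;
#'   `write_run_config` returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cf <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, cf)
}
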