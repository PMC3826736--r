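#' Specification of a synthetic multi-group cohort
#'
#' Parameterizes a desk-scale cohort with the statistical structure the
#' AD-PS analyses assume: per-tissue 3D volumes with group-graded atrophy
#' planted in localized voxel blocks plus Gaussian noise, a 25-score
#' cognitive battery with group-graded mean shifts, age and functional
#' (FAQ) values correlated with latent severity, and censored conversion
#' times whose hazard increases with severity.
#'
#' Four groups are simulated in severity order: `CNsim` (no effect),
#' `ncMCIsim`, `cMCIsim`, `ADsim` (full effect); intermediate groups get
#' graded fractions of the full decrement, so group medians of any
#' signal-carrying score are ordered by construction. Defaults keep the
#' p >> n regime (8000 voxels per tissue vs ~160 subjects) at minutes-scale
#' runtime. The default per-voxel effect sizes step down GM > WM > CSF,
#' mirroring the relative informativeness of the tissue classes.
#'
#' @param group_sizes named counts for CNsim, ncMCIsim, cMCIsim, ADsim.
#' @param grid_shape 3D grid per tissue.
#' @param noise_sd per-voxel Gaussian noise SD.
#' @param decrements named per-tissue maximum intensity decrement (the ADsim
#'   level; atrophy = lower intensity).
#' @param grades per-group fraction of the full decrement (monotone, CN 0).
#' @param cognitive_shift mean shift (in noise-SD units) applied to the
#'   designated cognitive scores at full severity.
#' @param n_cognitive_effects how many of the 25 scores carry signal.
#' @param severity_jitter SD of the subject-level latent-severity noise
#'   around the group grade (drives survival, age and FAQ).
#' @param baseline_hazard exponential event rate per month at mean severity.
#'   The default keeps administrative censoring at the 36-month horizon
#'   below the censoring target, so the target stays attainable by top-up.
#' @param log_hazard_per_sd log hazard ratio per 1 SD of latent severity.
#' @param censoring_fraction target overall censoring fraction among the
#'   MCI-sim subjects (administrative + random), hit within 5 points.
#' @param horizon_months administrative censoring horizon.
#' @param age_slope,faq_slope strength of the severity-age / severity-FAQ
#'   association (years and FAQ points per unit severity).
#' @param effect_regions optional named per-tissue list of planted voxel
#'   blocks (each built with [block()]); when omitted, two blocks per
#'   tissue at fixed locations inside the default 20x20x20 grid.
#' @return an object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(group_sizes = c(CNsim = 40, ncMCIsim = 40,
                                        cMCIsim = 40, ADsim = 40),
                        grid_shape = c(20, 20, 20),
                        noise_sd = 0.15,
                        decrements = c(GM = 0.35, WM = 0.25, CSF = 0.18),
                        grades = c(CNsim = 0, ncMCIsim = 1/3,
                                   cMCIsim = 2/3, ADsim = 1),
                        cognitive_shift = 2.0,
                        n_cognitive_effects = 10,
                        severity_jitter = 0.08,
                        baseline_hazard = 0.05,
                        log_hazard_per_sd = 0.69,
                        censoring_fraction = 0.30,
                        horizon_months = 36,
                        age_slope = 4, faq_slope = 8,
                        effect_regions = NULL) {
  stopifnot(all(group_sizes >= 0), length(grid_shape) == 3,
            noise_sd >= 0, all(decrements >= 0),
            all(diff(grades) > 0), grades[1] == 0,
            censoring_fraction >= 0, censoring_fraction < 1,
            baseline_hazard > 0, horizon_months > 0)
  # two planted blocks per tissue, 27-125 voxels each, at tissue-specific
  # locations inside the grid
  regions <- effect_regions %||% list(
    GM  = list(block(c(3, 6),   c(3, 6),   c(3, 6)),     # 4x4x4 = 64
               block(c(12, 14), c(12, 14), c(12, 14))),  # 3x3x3 = 27
    WM  = list(block(c(8, 11),  c(4, 7),   c(8, 11)),
               block(c(15, 17), c(10, 12), c(4, 6))),
    CSF = list(block(c(5, 8),   c(12, 15), c(5, 8)),
               block(c(13, 15), c(5, 7),   c(13, 15))))
  structure(list(group_sizes = group_sizes, grid_shape = grid_shape,
                 noise_sd = noise_sd, decrements = decrements,
                 grades = grades, effect_regions = regions,
                 cognitive_dim = 25L,
                 cognitive_shift = cognitive_shift,
                 n_cognitive_effects = n_cognitive_effects,
                 severity_jitter = severity_jitter,
                 baseline_hazard = baseline_hazard,
                 log_hazard_per_sd = log_hazard_per_sd,
                 censoring_fraction = censoring_fraction,
                 horizon_months = horizon_months,
                 age_slope = age_slope, faq_slope = faq_slope),
            class = "cohort_spec")
}

#' Axis-aligned voxel block (inclusive index ranges)
#' @param xr,yr,zr length-2 integer ranges along each axis.
#' @export
block <- function(xr, yr, zr) list(x = xr, y = yr, z = zr)

block_indices <- function(b, shape) {
  if (b$x[2] > shape[1] || b$y[2] > shape[2] || b$z[2] > shape[3] ||
      any(c(b$x[1], b$y[1], b$z[1]) < 1))
    stop("effect region lies outside the grid")
  g <- expand.grid(x = b$x[1]:b$x[2], y = b$y[1]:b$y[2], z = b$z[1]:b$z[2])
  as.integer((g$z - 1) * shape[1] * shape[2] + (g$y - 1) * shape[1] + g$x)
}

group_vector <- function(spec) {
  rep(names(spec$group_sizes), times = spec$group_sizes)
}

#' The 25-score cognitive battery column names
#'
#' Thirteen AD Assessment Scale-Cognitive items, nine Rey Auditory Verbal
#' Learning Test scores, two Logical Memory scores and the MMSE total.
#' @export
cognitive_battery <- function() {
  c(paste0("ADAS_Q", c(1:12, 14)),
    paste0("RAVLT_", c("Trial1", "Trial2", "Trial3", "Trial4", "Trial5",
                       "Interference", "Immediate", "Delay30", "Recognition")),
    "LM_Immediate", "LM_Delay", "MMSE_Total")
}

#' Generate one tissue's synthetic image matrix
#'
#' Baseline intensity 1.0 at every masked voxel, minus the subject's group
#' decrement inside that tissue's planted blocks, plus Gaussian noise.
#' Rows are ordered CNsim, ncMCIsim, cMCIsim, ADsim. Deterministic under
#' the seed.
#'
#' @param spec a [cohort_spec()].
#' @param tissue `"GM"`, `"WM"` or `"CSF"`.
#' @param seed integer seed.
#' @return list with `x` (subjects x voxels feature matrix, columns named by
#'   voxel linear index), `mask` (a `"tissue_mask"` covering the grid),
#'   `planted` (linear indices of the planted voxels), `group` (per
#'   subject).
#' @export
generate_images <- function(spec, tissue = c("GM", "WM", "CSF"), seed = 1) {
  tissue <- match.arg(tissue)
  grp <- group_vector(spec)
  n <- length(grp)
  p <- prod(spec$grid_shape)
  planted <- sort(unique(unlist(lapply(spec$effect_regions[[tissue]],
                                       block_indices, shape = spec$grid_shape))))
  dec <- spec$decrements[[tissue]] * spec$grades[grp]
  x <- with_local_seed(seed, {
    m <- matrix(1.0, n, p)
    m[, planted] <- m[, planted] - dec
    if (spec$noise_sd > 0) m <- m + matrix(rnorm(n * p, sd = spec$noise_sd), n, p)
    m
  })
  colnames(x) <- as.character(seq_len(p))
  rownames(x) <- sprintf("S%03d", seq_len(n))
  template <- array(0.9, dim = spec$grid_shape)
  list(x = x, mask = build_mask(template, 0.5), planted = planted,
       group = grp)
}

#' Generate the synthetic cognitive battery
#'
#' Standard-normal scores for all 25 battery columns, with the group-graded
#' mean shift added to the designated signal-carrying subset.
#'
#' @inheritParams generate_images
#' @return n x 25 matrix with battery column names; attribute
#'   `signal_columns` records which columns carry signal.
#' @export
generate_cognitive <- function(spec, seed = 1) {
  grp <- group_vector(spec)
  n <- length(grp)
  cols <- cognitive_battery()
  k <- spec$n_cognitive_effects
  shift <- spec$cognitive_shift * spec$grades[grp]
  x <- with_local_seed(seed, {
    m <- matrix(rnorm(n * spec$cognitive_dim), n, spec$cognitive_dim)
    if (k > 0) m[, seq_len(k)] <- m[, seq_len(k)] + shift
    m
  })
  colnames(x) <- cols
  rownames(x) <- sprintf("S%03d", seq_len(n))
  attr(x, "signal_columns") <- cols[seq_len(min(k, length(cols)))]
  x
}

#' Generate censored conversion-time records
#'
#' Exponential event times with log hazard linear in (standardized) latent
#' severity; administrative censoring at the follow-up horizon plus random
#' censoring of additional subjects until the configured overall censoring
#' fraction is reached (within 5 points when attainable).
#'
#' @param spec a [cohort_spec()] (supplies hazard, slope, horizon, target
#'   censoring).
#' @param severity latent severity per subject.
#' @param seed integer seed.
#' @return data frame (class `"survival_records"`): `subject_id`,
#'   `time_months`, `event`; attribute `truth` records the generating
#'   parameters.
#' @export
generate_survival <- function(spec, severity, seed = 1) {
  n <- length(severity)
  s <- sd(severity)
  z <- if (is.finite(s) && s > 0) (severity - mean(severity)) / s
       else rep(0, n)
  out <- with_local_seed(seed, {
    rate <- spec$baseline_hazard * exp(spec$log_hazard_per_sd * z)
    t_event <- rexp(n, rate = rate)
    time <- pmin(t_event, spec$horizon_months)
    event <- as.integer(t_event <= spec$horizon_months)
    # top up with random censoring to reach the target fraction
    target <- round(spec$censoring_fraction * n)
    deficit <- target - sum(event == 0)
    if (deficit > 0) {
      cand <- which(event == 1)
      pick <- cand[sample.int(length(cand), min(deficit, length(cand)))]
      time[pick] <- runif(length(pick), 0, time[pick])
      event[pick] <- 0L
    }
    list(time = time, event = event)
  })
  if (all(out$event == 0))
    warning("degenerate draw: all records censored", call. = FALSE)
  rec <- data.frame(subject_id = names(severity) %||% sprintf("S%03d", seq_len(n)),
                    time_months = out$time, event = out$event,
                    stringsAsFactors = FALSE)
  attr(rec, "truth") <- list(baseline_hazard = spec$baseline_hazard,
                             log_hazard_per_sd = spec$log_hazard_per_sd,
                             censoring_fraction = spec$censoring_fraction,
                             horizon_months = spec$horizon_months)
  class(rec) <- c("survival_records", "data.frame")
  rec
}

#' Generate a complete synthetic cohort
#'
#' Draws the per-tissue image matrices, the cognitive battery, subject
#' covariates (age, FAQ) correlated with latent severity, and conversion
#' records for the MCI-sim subjects, all deterministically from one seed.
#' Ground truth (planted voxel sets, latent severity, survival parameters)
#' is retained for recovery tests.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed.
#' @return an object of class `"synthetic_cohort"`: `images` (per tissue:
#'   `x`, `mask`, `planted`), `cognitive`, `subjects` (subject_id, group,
#'   age, faq), `survival` (MCI-sim subjects only), `ground_truth`, `spec`,
#'   `seed`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = 1) {
  seeds <- derive_seeds(seed, 6L)
  grp <- group_vector(spec)
  n <- length(grp)
  ids <- sprintf("S%03d", seq_len(n))

  images <- list(GM = generate_images(spec, "GM", seeds[1]),
                 WM = generate_images(spec, "WM", seeds[2]),
                 CSF = generate_images(spec, "CSF", seeds[3]))
  cognitive <- generate_cognitive(spec, seeds[4])

  covs <- with_local_seed(seeds[5], {
    sev <- spec$grades[grp] + rnorm(n, sd = spec$severity_jitter)
    sev <- pmax(sev, 0)
    age <- round(72 + spec$age_slope * sev + rnorm(n, sd = 5))
    faq <- round(pmax(0, spec$faq_slope * sev + rnorm(n, sd = 1.5)))
    list(sev = sev, age = age, faq = faq)
  })
  severity <- stats::setNames(covs$sev, ids)

  mci <- grp %in% c("ncMCIsim", "cMCIsim")
  surv <- if (any(mci)) generate_survival(spec, severity[mci], seeds[6]) else NULL

  structure(list(images = images, cognitive = cognitive,
                 subjects = data.frame(subject_id = ids, group = grp,
                                       age = covs$age, faq = covs$faq,
                                       stringsAsFactors = FALSE),
                 survival = surv,
                 ground_truth = list(
                   planted = lapply(images, `[[`, "planted"),
                   severity = severity,
                   survival = if (!is.null(surv)) attr(surv, "truth")),
                 spec = spec, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort (seed ", x$seed, ")\n", sep = "")
  print(table(x$subjects$group))
  cat(sprintf("  %d voxels/tissue, %d planted (GM), noise SD %.3g\n",
              ncol(x$images$GM$x), length(x$images$GM$planted),
              x$spec$noise_sd))
  invisible(x)
}
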