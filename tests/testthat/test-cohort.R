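test_that("noise-free image generation is exact inside and outside planted blocks", {
  spec <- tiny_cohort_spec(noise_sd = 0)
  spec$decrements <- c(GM = 0.3, WM = 0.3, CSF = 0.3)
  img <- generate_images(spec, "GM", seed = 1)
  ad <- img$group == "ADsim"
  expect_true(all(img$x[ad, img$planted] == 0.7))
  outside <- setdiff(seq_len(ncol(img$x)), img$planted)
  expect_true(all(img$x[, outside] == 1.0))
  cn <- img$group == "CNsim"
  expect_true(all(img$x[cn, ] == 1.0))
  # graded: intermediate groups between CN and AD
  nc <- img$group == "ncMCIsim"; cm <- img$group == "cMCIsim"
  expect_equal(unique(as.numeric(img$x[nc, img$planted])), 1 - 0.3 / 3)
  expect_equal(unique(as.numeric(img$x[cm, img$planted])), 1 - 0.3 * 2 / 3)
})

test_that("generators are pure functions of spec and seed", {
  spec <- tiny_cohort_spec()
  expect_identical(generate_images(spec, "WM", seed = 5)$x,
                   generate_images(spec, "WM", seed = 5)$x)
  expect_false(identical(generate_images(spec, "WM", seed = 5)$x,
                         generate_images(spec, "WM", seed = 6)$x))
  expect_identical(generate_cognitive(spec, seed = 3),
                   generate_cognitive(spec, seed = 3))
  co1 <- simulate_cohort(spec, seed = 2)
  co2 <- simulate_cohort(spec, seed = 2)
  expect_identical(co1$images$GM$x, co2$images$GM$x)
  expect_identical(co1$survival, co2$survival)
})

test_that("the cognitive battery has 25 named columns with graded group shifts", {
  spec <- tiny_cohort_spec()
  x <- generate_cognitive(spec, seed = 4)
  expect_equal(ncol(x), 25)
  expect_identical(colnames(x), cognitive_battery())
  grp <- rep(names(spec$group_sizes), spec$group_sizes)
  sig <- attr(x, "signal_columns")
  med <- tapply(rowMeans(x[, sig]), grp, median)
  expect_true(med["CNsim"] < med["ncMCIsim"] &&
              med["ncMCIsim"] < med["cMCIsim"] &&
              med["cMCIsim"] < med["ADsim"])
  # zero shift: exchangeable groups
  spec0 <- tiny_cohort_spec(); spec0$cognitive_shift <- 0
  x0 <- generate_cognitive(spec0, seed = 4)
  med0 <- tapply(rowMeans(x0[, sig]), grp, median)
  expect_lt(max(med0) - min(med0), 0.5)
})

test_that("a 3 SD shift on 10 scores makes the cognitive classifier near-perfect", {
  spec <- tiny_cohort_spec(n_per_group = 20)
  spec$cognitive_shift <- 3
  x <- generate_cognitive(spec, seed = 9)
  grp <- rep(names(spec$group_sizes), spec$group_sizes)
  anchor <- grp %in% c("CNsim", "ADsim")
  y <- as.numeric(grp[anchor] == "ADsim")
  cv <- nested_cv(x[anchor, ], y,
                  grid = search_grid(alpha_values = c(0.5, 1), nlambda = 8),
                  K1 = 4, K2 = 3, repetitions = 3, seed = 2)
  expect_gte(cv$median_accuracy, 95)
})

test_that("survival generation honors horizon, censoring target and hazard slope", {
  spec <- tiny_cohort_spec()
  sev <- setNames(runif(200), paste0("S", 1:200))
  rec <- generate_survival(spec, sev, seed = 11)
  expect_true(all(rec$time_months <= spec$horizon_months))
  expect_true(all(rec$event %in% c(0, 1)))
  cens <- mean(rec$event == 0)
  expect_lt(abs(cens - spec$censoring_fraction), 0.05 + 1e-9)
  # no censoring, infinite horizon: every event observed
  spec_all <- tiny_cohort_spec()
  spec_all$censoring_fraction <- 0
  spec_all$horizon_months <- Inf
  rec_all <- generate_survival(spec_all, sev, seed = 12)
  expect_true(all(rec_all$event == 1))
  # zero slope: hazard unrelated to severity, Cox recovers HR ~ 1
  spec0 <- tiny_cohort_spec()
  spec0$log_hazard_per_sd <- 0
  rec0 <- generate_survival(spec0, setNames(rnorm(300), NULL), seed = 13)
  fit0 <- cox_per_sd(rnorm(300), rec0$time_months, rec0$event)
  expect_true(fit0$ci95_low < 1 && 1 < fit0$ci95_high)
})

test_that("an effect region outside the grid is rejected", {
  spec <- tiny_cohort_spec()
  spec$effect_regions$GM <- list(block(c(8, 12), c(1, 3), c(1, 3)))
  expect_error(generate_images(spec, "GM", seed = 1), "outside the grid")
})

test_that("a null cohort gives chance-level classification", {
  spec <- tiny_cohort_spec(n_per_group = 15)
  spec$decrements <- c(GM = 0, WM = 0, CSF = 0)
  img <- generate_images(spec, "GM", seed = 30)
  anchor <- img$group %in% c("CNsim", "ADsim")
  y <- as.numeric(img$group[anchor] == "ADsim")
  # non-convergence warnings are expected: tiny near-separable noise folds
  cv <- suppressWarnings(
    nested_cv(img$x[anchor, ], y,
              grid = search_grid(alpha_values = 0.5, nlambda = 6),
              K1 = 5, K2 = 3, repetitions = 5, seed = 3))
  expect_gt(cv$median_accuracy, 20)
  expect_lt(cv$median_accuracy, 80)
})
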