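test_that("fold plans are stratified, exhaustive and deterministic", {
  y <- rep(c(0, 1), each = 10)
  plan <- make_fold_plan(y, K1 = 10, K2 = 3, seed = 4)
  # 10/10 subjects in 10 folds: exactly one of each class per fold
  tab <- table(plan$external, y)
  expect_true(all(tab == 1))
  # every subject in exactly one external fold
  expect_identical(sort(unique(plan$external)), 1:10)
  expect_length(plan$external, 20)
  # internal folds never include the held-out external fold
  for (k in 1:10) {
    expect_true(all(is.na(plan$internal[[k]][plan$external == k])))
    expect_false(anyNA(plan$internal[[k]][plan$external != k]))
  }
  # class ratio within one subject of proportional at larger n
  y2 <- rep(c(0, 1), c(30, 70))
  p2 <- make_fold_plan(y2, K1 = 5, K2 = 5, seed = 1)
  tab2 <- table(p2$external, y2)
  expect_true(all(abs(tab2[, "0"] - 6) <= 1) && all(abs(tab2[, "1"] - 14) <= 1))
  # determinism and seed sensitivity
  expect_identical(make_fold_plan(y2, 5, 5, seed = 9),
                   make_fold_plan(y2, 5, 5, seed = 9))
  expect_false(identical(make_fold_plan(y2, 5, 5, seed = 1)$external,
                         make_fold_plan(y2, 5, 5, seed = 2)$external))
  expect_error(make_fold_plan(rep(c(0, 1), c(3, 17)), K1 = 5), "stratified")
})

test_that("performance metrics count hits per class in percent", {
  m <- performance_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
  expect_equal(unname(m), c(75, 50, 100))
  expect_equal(unname(performance_metrics(c(1, 0), c(1, 0))), c(100, 100, 100))
  expect_equal(unname(performance_metrics(c(1, 0), c(0, 1))), c(0, 0, 0))
  # absent class flagged missing, not zero
  m2 <- performance_metrics(c(1, 1), c(1, 0))
  expect_true(is.na(m2["specificity"]))
})

test_that("inner selection maximizes mean validation accuracy with sparse tie-breaks", {
  d <- two_clouds(n = 40, p = 10, distance = 8, seed = 2)
  fold <- stats::ave(d$y, d$y, FUN = function(v) rep_len(1:4, length(v)))
  # single grid point: returned verbatim, no search
  g1 <- search_grid(alpha_values = 0.5, lambda_values = 0.07)
  sel <- inner_select(d$x, d$y, fold, g1)
  expect_equal(sel$alpha, 0.5)
  expect_equal(sel$lambda, 0.07)
  # exact ties (duplicated alphas on a flat surface) resolve to the largest
  # lambda, then the largest alpha
  xnull <- matrix(rnorm(40 * 3), 40, 3)  # no signal: heavy penalty ties
  g2 <- search_grid(alpha_values = c(0.4, 0.8),
                    lambda_values = c(50, 20, 10))
  sel2 <- inner_select(xnull, d$y, fold, g2)
  expect_equal(sel2$lambda, 50)
  expect_equal(sel2$alpha, 0.8)
})

test_that("a strongly superior penalty is selected reliably", {
  # signal recoverable at moderate penalty, destroyed at a huge one;
  # the moderate lambda must win in every seeded run
  wins <- 0L
  for (s in 1:10) {
    d <- two_clouds(n = 40, p = 20, distance = 8, seed = 100 + s)
    plan <- make_fold_plan(d$y, K1 = 4, K2 = 4, seed = s)
    keep <- plan$external != 1
    g <- search_grid(alpha_values = 0.5, lambda_values = c(1000, 0.05))
    sel <- inner_select(d$x[keep, ], d$y[keep], plan$internal[[1]][keep], g)
    wins <- wins + (sel$lambda == 0.05)
  }
  expect_identical(wins, 10L)
})

test_that("nested CV separates well-separated clouds and respects seeding", {
  d <- two_clouds(n = 60, p = 50, distance = 10, seed = 3)
  cv <- nested_cv(d$x, d$y, grid = search_grid(alpha_values = 0.5, nlambda = 8),
                  K1 = 5, K2 = 3, repetitions = 3, seed = 5)
  expect_equal(cv$median_accuracy, 100)
  expect_true(all(!is.na(cv$oof)))
  audit_no_leakage(cv)
  # repetition 1 identical whether 1 or 2 repetitions are run
  cv1 <- nested_cv(d$x, d$y, grid = search_grid(alpha_values = 0.5, nlambda = 8),
                   K1 = 5, K2 = 3, repetitions = 1, seed = 5)
  expect_equal(cv1$oof[, 1], cv$oof[, 1])
  expect_equal(cv1$per_repetition[1, ], cv$per_repetition[1, ])
})

test_that("medians across repetitions are the empirical 50th percentile", {
  d <- two_clouds(n = 40, p = 10, distance = 3, seed = 8)
  cv <- nested_cv(d$x, d$y, grid = search_grid(alpha_values = 0.5, nlambda = 6),
                  K1 = 4, K2 = 3, repetitions = 5, seed = 2)
  expect_equal(cv$median_accuracy, median(cv$per_repetition$accuracy))
  expect_equal(cv$median_sensitivity, median(cv$per_repetition$sensitivity))
  expect_true(all(cv$per_repetition$accuracy >= 0 &
                  cv$per_repetition$accuracy <= 100))
})

test_that("the averaging variant of inner selection is available", {
  d <- two_clouds(n = 40, p = 10, distance = 6, seed = 12)
  fold <- stats::ave(d$y, d$y, FUN = function(v) rep_len(1:4, length(v)))
  g <- search_grid(alpha_values = 0.5, nlambda = 6)
  sel <- inner_select(d$x, d$y, fold, g, select = "average")
  expect_true(sel$lambda > 0)
  expect_equal(sel$alpha, 0.5)
})
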