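test_that("anchor scores are out-of-fold medians inside [0,1] and ranked by class", {
  d <- two_clouds(n = 40, p = 20, distance = 6, seed = 4)
  sc <- adps_scores(d$x, d$y, grid = search_grid(alpha_values = 0.5, nlambda = 8),
                    K1 = 4, K2 = 3, repetitions = 3, seed = 6, modality = "GM")
  expect_true(all(sc$table$score >= 0 & sc$table$score <= 1))
  expect_true(all(sc$table$provenance == "out_of_fold"))
  expect_gt(median(sc$table$score[d$y == 1]), median(sc$table$score[d$y == 0]))
  # median across repetitions, by definition
  expect_equal(sc$table$score, apply(sc$cv$oof, 1, median))
  # a single repetition's score is that repetition's out-of-fold probability
  sc1 <- adps_scores(d$x, d$y, grid = search_grid(alpha_values = 0.5, nlambda = 8),
                     K1 = 4, K2 = 3, repetitions = 1, seed = 6)
  expect_equal(sc1$table$score, sc1$cv$oof[, 1])
})

test_that("holdout scoring uses full-anchor models and respects symmetry", {
  d <- two_clouds(n = 40, p = 10, distance = 6, seed = 9)
  # holdout: a duplicated strong-signal anchor, the exact midpoint of the
  # two clouds, and the overall feature mean
  mid <- (colMeans(d$x[d$y == 0, ]) + colMeans(d$x[d$y == 1, ])) / 2
  hold <- rbind(dup_ad = d$x[which(d$y == 1)[1], ],
                midpoint = mid,
                grand_mean = colMeans(d$x))
  sc <- adps_score_holdout(d$x, d$y, hold,
                           grid = search_grid(alpha_values = 0.5, nlambda = 8),
                           K2 = 4, repetitions = 20, seed = 3)
  expect_true(all(sc$table$provenance == "full_model"))
  expect_true(all(sc$table$score >= 0 & sc$table$score <= 1))
  expect_gt(sc$table$score[1], 0.5)           # duplicated AD anchor
  expect_lt(abs(sc$table$score[2] - 0.5), 0.1) # symmetric midpoint
  expect_lt(abs(sc$table$score[3] - 0.5), 0.15) # grand mean, balanced classes
  # duplicated anchors track their own full-model fitted probabilities
  dup_all <- adps_score_holdout(d$x, d$y, d$x,
                                grid = search_grid(alpha_values = 0.5, nlambda = 8),
                                K2 = 4, repetitions = 5, seed = 3)
  fitted_med <- apply(vapply(dup_all$ensemble$models,
                             function(m) predict(m, d$x), numeric(40)),
                      1, median)
  expect_gt(cor(dup_all$table$score, fitted_med), 0.99)
  expect_error(adps_score_holdout(d$x, d$y, hold[, 1:5]), "columns")
})

test_that("composites are exact unrenormalized sums with the documented bounds", {
  mk <- function(mod, v) structure(list(
    table = data.frame(subject_id = paste0("s", seq_along(v)), score = v,
                       provenance = "full_model", label = NA),
    modality = mod, repetitions_used = 1), class = "adps_scores")
  s <- list(GM = mk("GM", c(0, 1, 0.2)), WM = mk("WM", c(0, 1, 0.3)),
            CSF = mk("CSF", c(0, 1, 0.4)), cognitive = mk("cognitive", c(0, 1, 0.5)))
  anat <- adps_composite(s, "anatomical")
  comp <- adps_composite(s, "cognitive_anatomical")
  expect_equal(anat$composite, c(0, 3, 0.9))
  expect_equal(comp$composite, c(0, 4, 1.4))
  expect_error(adps_composite(s[c("GM", "WM")], "anatomical"), "missing modality")
  # composite conservation on random scores
  set.seed(2)
  r <- lapply(c("GM", "WM", "CSF", "cognitive"),
              function(m) mk(m, runif(10)))
  names(r) <- c("GM", "WM", "CSF", "cognitive")
  got <- adps_composite(r, "cognitive_anatomical")$composite
  want <- Reduce(`+`, lapply(r, function(z) z$table$score))
  expect_equal(got, want)
})

test_that("risk zones partition the hypercube with strict thresholds", {
  expect_equal(as.character(risk_zone(c(0.1, 0.2, 0.3, 0.4))), "low")
  expect_equal(as.character(risk_zone(c(0.6, 0.9, 0.7, 0.51))), "high")
  expect_equal(as.character(risk_zone(c(0.4, 0.6, 0.2, 0.9))), "indeterminate")
  expect_equal(as.character(risk_zone(c(0.5, 0.6))), "indeterminate")
  # exhaustive and exclusive on random points
  set.seed(5)
  pts <- matrix(runif(400), 100, 4)
  z <- risk_zone(pts)
  expect_false(anyNA(z))
  lo <- apply(pts, 1, function(r) all(r < 0.5))
  hi <- apply(pts, 1, function(r) all(r > 0.5))
  expect_equal(z == "low", lo)
  expect_equal(z == "high", hi)
  expect_equal(z == "indeterminate", !(lo | hi))
})

test_that("corner distances match hand-computed hypercube geometry", {
  expect_equal(corner_distance(c(0, 0), c(0, 0)), 0)
  expect_equal(corner_distance(c(1, 1), c(0, 0)), sqrt(2))
  expect_equal(corner_distance(rep(0.5, 4), rep(1, 4)), 1)
  expect_error(corner_distance(c(0.1, 0.2), c(0, 0, 0)), "dimension")
  # all distances within [0, sqrt(D)]
  set.seed(1)
  pts <- matrix(runif(300), 100, 3)
  dd <- corner_distance(pts, c(1, 1, 1))
  expect_true(all(dd >= 0 & dd <= sqrt(3)))
})

test_that("hypercube points preserve subject order and modality order", {
  mk <- function(mod, v, ids) structure(list(
    table = data.frame(subject_id = ids, score = v,
                       provenance = "full_model", label = NA),
    modality = mod, repetitions_used = 1), class = "adps_scores")
  ids <- c("a", "b")
  s <- list(GM = mk("GM", c(0.1, 0.9), ids), WM = mk("WM", c(0.2, 0.8), ids),
            CSF = mk("CSF", c(0.3, 0.7), ids),
            cognitive = mk("cognitive", c(0.4, 0.6), ids))
  pts <- hypercube_points(s)
  expect_identical(colnames(pts), c("GM", "WM", "CSF", "cognitive"))
  expect_equal(pts["a", ], c(GM = 0.1, WM = 0.2, CSF = 0.3, cognitive = 0.4))
})
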