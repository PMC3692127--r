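sep_data <- function() {
  # linearly separable toy data: 2 features, 40 points
  set.seed(1)
  X <- cbind(f1 = c(rnorm(20, -2), rnorm(20, 2)),
             f2 = rnorm(40))
  list(X = X, y = rep(c(0L, 1L), each = 20))
}

test_that("train_forest separates separable data and is seed-deterministic", {
  d <- sep_data()
  f <- train_forest(d$X, d$y, n_trees = 50, seed = 3)
  expect_equal(score_windows(f, d$X) >= 0.5, d$y == 1)

  probe <- cbind(f1 = seq(-3, 3, length.out = 25), f2 = rnorm(25))
  f2 <- train_forest(d$X, d$y, n_trees = 50, seed = 3)
  expect_identical(score_windows(f, probe), score_windows(f2, probe))

  expect_error(train_forest(d$X, rep(1L, 40), seed = 1), "both classes")
  Xna <- d$X; Xna[3, 1] <- NA
  expect_error(train_forest(Xna, d$y, seed = 1), "NaN/NA")
})

test_that("scores are vote fractions on the exact tree-count grid", {
  d <- sep_data()
  f <- train_forest(d$X, d$y, n_trees = 40, seed = 5)
  set.seed(9)
  probe <- cbind(f1 = rnorm(20, 0, 2), f2 = rnorm(20))
  s <- score_windows(f, probe)
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(s * 40, round(s * 40))  # multiples of 1/n_trees

  # per-tree vote oracle
  all_votes <- stats::predict(f$forest, newdata = probe, predict.all = TRUE)
  manual <- rowMeans(all_votes$individual == "1")
  expect_equal(s, unname(manual))

  # invariant to row order
  perm <- sample(20)
  expect_equal(score_windows(f, probe[perm, ]), s[perm])

  bad <- probe
  colnames(bad) <- c("f1", "wrong")
  expect_error(score_windows(f, bad), "wrong")
})

test_that("forest OOB error does not exceed a single tree's held-out error", {
  # one labelled motif dataset, split in half: forest and single tree are
  # trained on the same training half; the forest's OOB estimate should be
  # no worse than the single tree's error on the held-out half
  cfg <- fixture_config(n_pos = 200, mutation_rate = 0.2, seed = 101)
  ds <- make_dataset(cfg)
  spec <- feature_spec(nchar(cfg$motif_consensus), flank = cfg$flank,
                       scales = c("bendability", "propeller_twist"))
  Xp <- build_feature_matrix(ds$positives$seq, spec)
  set.seed(55)
  negw <- motifforest:::sample_bg_windows(ds$background$seq, nrow(Xp),
                                          motifforest:::window_width(spec))
  Xn <- build_feature_matrix(negw, spec)
  X <- rbind(Xp, Xn)
  y <- rep(c(1, 0), c(nrow(Xp), nrow(Xn)))
  set.seed(7)
  tr <- sample(nrow(X), nrow(X) / 2)

  forest <- train_forest(X[tr, ], y[tr], n_trees = 100, seed = 2)
  single <- train_forest(X[tr, ], y[tr], n_trees = 1, seed = 2)
  s_single <- score_windows(single, X[-tr, ])
  err_single <- mean((s_single >= 0.5) != (y[-tr] == 1))
  expect_lte(forest$oob_error, err_single + 1e-9)
})

test_that("build_null is sorted, seeded, and concentrated at low scores", {
  m <- test_model()
  ds <- test_dataset()
  null1 <- build_null(m$forest, ds$background, m$spec, n_samples = 300, seed = 4)
  null2 <- build_null(m$forest, ds$background, m$spec, n_samples = 300, seed = 4)
  expect_identical(null1, null2)
  expect_false(is.unsorted(null1$scores))
  expect_equal(null1$n, 300L)
  expect_lt(stats::median(null1$scores), 0.5)

  short_bg <- tibble::tibble(id = "x", seq = "ACGT")
  expect_error(build_null(m$forest, short_bg, m$spec, 10, seed = 1),
               "shorter than")
})

test_that("empirical_pvalue implements the add-one estimator", {
  null <- list(scores = sort(stats::runif(999)), n = 999L)
  class(null) <- "null_distribution"
  expect_equal(empirical_pvalue(1, null), 1 / 1000)
  expect_equal(empirical_pvalue(0, null), 1)

  # brute-force count oracle on a 50-point null
  set.seed(12)
  null50 <- list(scores = sort(round(stats::runif(50), 2)), n = 50L)
  class(null50) <- "null_distribution"
  for (s in c(0, 0.21, 0.5, null50$scores[7], 0.999, 1)) {
    expect_equal(empirical_pvalue(s, null50),
                 (1 + sum(null50$scores >= s)) / 51)
  }

  # non-increasing in s, bounded in (0, 1]
  s_grid <- seq(0, 1, by = 0.05)
  p <- empirical_pvalue(s_grid, null50)
  expect_true(all(diff(p) <= 0))
  expect_true(all(p > 0 & p <= 1))

  expect_error(empirical_pvalue(1.5, null50), "\\[0, 1\\]")
  expect_error(empirical_pvalue(0.5, list(scores = numeric(0))), "empty")
})

test_that("rank-based AUC agrees with the pROC oracle", {
  skip_if_not_installed("pROC")
  set.seed(8)
  sp <- stats::runif(40, 0.3, 1)
  sn <- stats::runif(60, 0, 0.7)
  got <- score_auc(sp, sn)
  want <- as.numeric(pROC::auc(pROC::roc(
    response = rep(c(1, 0), c(40, 60)), predictor = c(sp, sn),
    quiet = TRUE, direction = "<")))
  expect_equal(got, want)
  expect_equal(score_auc(c(0.9, 0.8), c(0.1, 0.2)), 1)
  expect_equal(score_auc(c(0.5), c(0.5)), 0.5)
})
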