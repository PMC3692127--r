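test_that("encode_direct produces fixed-order one-hot indicators", {
  expect_equal(unname(encode_direct("AC")), c(1, 0, 0, 0, 0, 1, 0, 0))
  # every position block sums to 1
  for (w in random_dna(5, 9, seed = 2)) {
    v <- encode_direct(w)
    expect_equal(unname(colSums(matrix(v, nrow = 4))), rep(1, 9))
  }
  # enumeration: any two distinct 2-mers differ in exactly 4 coordinates
  # when both bases differ, 2 when one differs
  two <- do.call(paste0, expand.grid(c("A","C","G","T"), c("A","C","G","T")))
  for (a in two) for (b in two) {
    d <- sum(encode_direct(a) != encode_direct(b))
    nd <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    expect_equal(d, 2 * nd)
  }
  expect_equal(sum(encode_direct("GT") != encode_direct("TG")), 4)
  expect_error(encode_direct("ANT"), "N or illegal")
})

test_that("encode_dependencies produces per-pair 16-blocks that sum to 1", {
  pairs <- tibble::tibble(i = 0L, j = 1L)
  v <- encode_dependencies("AG", pairs)
  expect_length(v, 16)
  expect_equal(sum(v), 1)
  expect_equal(names(v)[v == 1], "dep0_1_AG")

  # brute-force oracle over random windows and pairs
  set.seed(7)
  combos <- as.vector(t(outer(c("A","C","G","T"), c("A","C","G","T"), paste0)))
  for (w in random_dna(20, 8, seed = 31)) {
    prs <- tibble::tibble(i = c(0L, 2L, 4L), j = c(3L, 5L, 7L))
    got <- encode_dependencies(w, prs)
    ch <- strsplit(w, "")[[1]]
    want <- unlist(lapply(seq_len(3), function(r) {
      as.numeric(combos == paste0(ch[prs$i[r] + 1], ch[prs$j[r] + 1]))
    }))
    expect_equal(unname(got), want)
    expect_equal(as.numeric(tapply(got, rep(1:3, each = 16), sum)), rep(1, 3))
  }
  expect_error(encode_dependencies("ACGT", tibble::tibble(i = 0L, j = 4L)),
               "out of range")
})

test_that("select_dependency_pairs ranks perfectly correlated positions first", {
  # positions 0 and 1 perfectly correlated ({AC, GT} balanced), rest uniform
  set.seed(5)
  tails <- random_dna(40, 4, seed = 13)
  pos <- paste0(rep(c("AC", "GT"), each = 20), tails)
  ranked <- select_dependency_pairs(pos, k = 3)
  expect_equal(c(ranked$i[1], ranked$j[1]), c(0L, 1L))
  # hand-computed MI of a balanced two-state joint: ln 2
  expect_equal(ranked$mi[1], log(2), tolerance = 1e-12)

  expect_equal(nrow(select_dependency_pairs(pos, k = 0)), 0L)

  # degenerate: identical positives, all MI 0, lexicographic fallback
  same <- rep("ACGTAC", 30)
  r <- select_dependency_pairs(same, k = 4)
  expect_equal(r$mi, rep(0, 4))
  expect_equal(r[, c("i", "j")],
               tibble::tibble(i = c(0L, 0L, 0L, 0L), j = c(1L, 2L, 3L, 4L)))

  expect_warning(select_dependency_pairs(same, k = 100), "possible pairs")
})

test_that("MI estimates are bounded and vanish for independent columns", {
  pos <- random_dna(3000, 6, seed = 99)
  r <- select_dependency_pairs(pos, k = 15)
  expect_true(all(r$mi >= 0))
  expect_true(all(r$mi <= log(4)))
  # plug-in MI bias is O(df / 2n): 9/6000 in nats, allow slack
  expect_true(all(r$mi < 0.01))
})

test_that("build_feature_matrix reduces to encode_direct without scales/pairs", {
  spec <- feature_spec(6, flank = 0)
  w <- "GATTCA"
  X <- build_feature_matrix(w, spec)
  expect_equal(X[1, ], encode_direct(w))
})

test_that("feature matrix column count follows the layout arithmetic", {
  pairs <- tibble::tibble(i = c(0L, 1L), j = c(2L, 3L))
  spec <- feature_spec(8, flank = 10,
                       scales = c("bendability", "propeller_twist"),
                       dependency_pairs = pairs)
  expect_length(spec$feature_names, 4 * 8 + 16 * 2 + 2 * 3 * 3)
  X <- build_feature_matrix(random_dna(3, 28, seed = 17), spec)
  expect_equal(dim(X), c(3L, length(spec$feature_names)))
  expect_true(all(is.finite(X)))
})

test_that("feature matrix equals row-by-row independent recomputation", {
  pairs <- tibble::tibble(i = c(1L, 3L), j = c(4L, 6L))
  spec <- feature_spec(7, flank = 5, scales = c("bendability", "stacking_energy"),
                       dependency_pairs = pairs)
  wins <- random_dna(10, 17, seed = 23)
  X <- build_feature_matrix(wins, spec)
  oracle_row <- function(w) {
    core <- substr(w, 6, 12)
    left <- substr(w, 1, 5)
    right <- substr(w, 13, 17)
    props <- unlist(lapply(spec$scales, function(sc) {
      unlist(lapply(list(core, left, right), function(region) {
        prof <- property_profile(region, sc)
        c(mean(prof), min(prof), max(prof))
      }))
    }))
    unname(c(encode_direct(core), encode_dependencies(core, pairs), props))
  }
  for (r in seq_along(wins)) {
    expect_equal(unname(X[r, ]), oracle_row(wins[r]))
  }
})

test_that("build_feature_matrix is deterministic and row-equivariant", {
  spec <- feature_spec(6, flank = 4, scales = "bendability")
  wins <- random_dna(8, 14, seed = 41)
  X1 <- build_feature_matrix(wins, spec)
  X2 <- build_feature_matrix(wins, spec)
  expect_identical(X1, X2)
  perm <- c(3, 1, 8, 2, 6, 4, 7, 5)
  expect_equal(build_feature_matrix(wins[perm], spec), X1[perm, ])
})

test_that("window problems are reported by name", {
  spec <- feature_spec(6, flank = 0)
  expect_error(build_feature_matrix(c("ACGTAC", "ACGT"), spec), "'ACGT'")
  expect_error(build_feature_matrix("ACGNAC", spec), "N or illegal")
})
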