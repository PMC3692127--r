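#' Train the random-forest site classifier
#'
#' An ensemble of `n_trees` decision trees, each grown on a bootstrap sample
#' of the labelled feature vectors with per-split feature subsampling
#' (default `floor(sqrt(p))` candidate features per split). The classifier
#' score of a window is the fraction of trees voting positive, so scores lie
#' exactly on the grid `{0, 1/n_trees, ..., 1}`. Training is reproducible
#' for a fixed seed and the out-of-bag (OOB) error estimate is retained.
#'
#' @param X Numeric feature matrix (rows = windows, columns named by the
#'   feature spec).
#' @param y Binary labels (0/1, logical, or 2-level factor); both classes
#'   must be present.
#' @param n_trees Number of trees (default 100).
#' @param mtry Features tried per split; default `floor(sqrt(ncol(X)))`.
#' @param seed Integer seed (mandatory for reproducibility).
#' @return A `site_forest` object wrapping the fitted ensemble, with fields
#'   `forest`, `feature_names`, `n_trees`, `oob_error`, `seed`.
#' @export
train_forest <- function(X, y, n_trees = 100, mtry = NULL, seed = 1) {
  if (anyNA(X)) stop("NaN/NA in feature matrix")
  y <- if (is.logical(y)) as.integer(y) else as.integer(as.character(y))
  if (anyNA(y) || !all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (length(unique(y)) < 2) stop("both classes must be present in y")
  if (nrow(X) != length(y)) stop("X rows must match length of y")
  if (is.null(mtry)) mtry <- max(1, floor(sqrt(ncol(X))))
  yf <- factor(y, levels = c(0, 1))
  set.seed(seed)
  rf <- randomForest::randomForest(x = X, y = yf, ntree = n_trees,
                                   mtry = mtry, importance = TRUE)
  structure(list(forest = rf, feature_names = colnames(X),
                 n_trees = as.integer(n_trees),
                 oob_error = unname(rf$err.rate[n_trees, "OOB"]),
                 seed = as.integer(seed)),
            class = "site_forest")
}

#' @export
print.site_forest <- function(x, ...) {
  cat(sprintf("<site_forest> %d trees, %d features, OOB error %.3f\n",
              x$n_trees, length(x$feature_names), x$oob_error))
  invisible(x)
}

#' Score candidate windows with a trained forest
#'
#' @param forest A `site_forest`.
#' @param X Feature matrix whose column layout matches the training spec.
#' @return Numeric vector in `[0, 1]`: per row, the fraction of trees voting
#'   positive.
#' @export
score_windows <- function(forest, X) {
  stopifnot(inherits(forest, "site_forest"))
  mism <- which(colnames(X) != forest$feature_names)
  if (ncol(X) != length(forest$feature_names) || length(mism) > 0) {
    bad <- if (ncol(X) != length(forest$feature_names)) {
      sprintf("%d columns, expected %d", ncol(X), length(forest$feature_names))
    } else {
      sprintf("first mismatched feature: '%s' (expected '%s')",
              colnames(X)[mism[1]], forest$feature_names[mism[1]])
    }
    stop("feature layout mismatch: ", bad)
  }
  votes <- stats::predict(forest$forest, newdata = X, type = "vote",
                          norm.votes = TRUE)
  unname(votes[, "1"])
}

#' Build the null score distribution from background sequence
#'
#' Draws `n_samples` windows uniformly at random (position and strand) from
#' the background records, featurises and scores them, and stores the sorted
#' scores. This empirical null is what the scanner's P-values are computed
#' against: it answers "how often does random background score at least
#' this high".
#'
#' @param forest A `site_forest`.
#' @param background Tibble of background records (`id`, `seq`).
#' @param spec The model's [feature_spec()].
#' @param n_samples Number of null windows (default 10000).
#' @param seed Integer seed.
#' @return A `null_distribution` object: list with sorted `scores` and `n`.
#' @export
build_null <- function(forest, background, spec, n_samples = 10000, seed = 1) {
  ww <- window_width(spec)
  ok <- background$seq[nchar(background$seq) >= ww]
  if (length(ok) == 0) stop("background sequences shorter than the window width")
  set.seed(seed)
  wins <- character(0)
  guard <- 0
  while (length(wins) < n_samples) {
    need <- n_samples - length(wins)
    si <- sample.int(length(ok), need, replace = TRUE)
    maxstart <- nchar(ok[si]) - ww
    pos <- floor(stats::runif(need) * (maxstart + 1))  # 0-based window starts
    w <- substring(ok[si], pos + 1, pos + ww)
    flip <- stats::runif(need) < 0.5
    w[flip] <- reverse_complement(w[flip])
    w <- w[!grepl("N", w, fixed = TRUE)]
    wins <- c(wins, w)
    guard <- guard + 1
    if (guard > 1000) stop("unable to draw enough N-free background windows")
  }
  X <- build_feature_matrix(wins[seq_len(n_samples)], spec)
  structure(list(scores = sort(score_windows(forest, X)),
                 n = as.integer(n_samples)),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> n = %d, median score %.3f\n",
              x$n, stats::median(x$scores)))
  invisible(x)
}

#' Empirical P-value of a classifier score
#'
#' Add-one estimator `p = (1 + #\{null >= s\}) / (1 + n)`, so P-values lie in
#' `(0, 1]` and are never exactly zero; the smallest attainable value with an
#' `n`-point null is `1 / (n + 1)`. Vectorised over `s` and non-increasing
#' in it.
#'
#' @param s Score(s) in `[0, 1]`.
#' @param null A `null_distribution`.
#' @return Numeric vector of P-values in `(0, 1]`.
#' @export
empirical_pvalue <- function(s, null) {
  if (is.null(null) || length(null$scores) == 0) stop("empty null distribution")
  if (any(s < 0 | s > 1)) stop("score must lie in [0, 1]")
  n <- length(null$scores)
  # null$scores sorted ascending: #{>= s} via binary search
  below <- findInterval(s, null$scores, left.open = TRUE)
  (1 + (n - below)) / (1 + n)
}

#' Rank-based ROC AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney U statistic
#' (ties counted half), used for the structure-signal benchmark comparing
#' the full model against a PWM-only scorer.
#'
#' @param scores_pos Scores of true positives.
#' @param scores_neg Scores of negatives.
#' @return AUC in `[0, 1]`.
#' @export
score_auc <- function(scores_pos, scores_neg) {
  if (length(scores_pos) == 0 || length(scores_neg) == 0) {
    stop("both score vectors must be nonempty")
  }
  r <- rank(c(scores_pos, scores_neg))
  n1 <- length(scores_pos)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * length(scores_neg))
}
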