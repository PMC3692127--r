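#' Precision / recall / F-measure over a threshold grid
#'
#' At each threshold `t`, a window counts as predicted positive when its
#' classifier score is `>= t`: `TP = #\{pos >= t\}`, `FP = #\{neg >= t\}`,
#' `FN = #\{pos < t\}`; precision = TP/(TP+FP), recall = TP/(TP+FN) and
#' F-measure = 2PR/(P+R). Precision at thresholds where TP + FP = 0 is
#' defined as 0 (and such thresholds are excluded from the maxima in
#' [derive_thresholds()]), preventing the vacuous "perfect precision above
#' every score" artifact; F is 0 where P + R = 0.
#'
#' @param scores_pos Classifier scores of validation positives.
#' @param scores_neg Classifier scores of validation negatives.
#' @param grid Sorted threshold grid in `[0, 1]`; default is all distinct
#'   observed scores plus the endpoints 0 and 1, which guarantees the true
#'   maxima lie on the grid.
#' @return A `calibration_table`: tibble with columns `threshold, tp, fp,
#'   fn, precision, recall, fmeasure` and attributes `n_pos`, `n_neg`.
#' @export
calibration_curve <- function(scores_pos, scores_neg, grid = NULL) {
  if (length(scores_pos) == 0 || length(scores_neg) == 0) {
    stop("both positive and negative score sets must be nonempty")
  }
  if (is.null(grid)) grid <- sort(unique(c(0, scores_pos, scores_neg, 1)))
  if (is.unsorted(grid) || any(grid < 0 | grid > 1)) {
    stop("grid must be sorted ascending within [0, 1]")
  }
  tab <- purrr::map_dfr(grid, function(t) {
    tp <- sum(scores_pos >= t)
    fp <- sum(scores_neg >= t)
    fn <- sum(scores_pos < t)
    precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
    recall <- tp / (tp + fn)
    fmeasure <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
    tibble::tibble(threshold = t, tp = tp, fp = fp, fn = fn,
                   precision = precision, recall = recall, fmeasure = fmeasure)
  })
  attr(tab, "n_pos") <- length(scores_pos)
  attr(tab, "n_neg") <- length(scores_neg)
  class(tab) <- c("calibration_table", class(tab))
  tab
}

#' Derive the three named decision thresholds
#'
#' * `max_precision` — the smallest threshold achieving the maximal
#'   precision among thresholds with at least one true positive;
#' * `max_fmeasure` — the smallest threshold achieving the maximal
#'   F-measure (same TP >= 1 restriction);
#' * `average` — the arithmetic mean of the two threshold values.
#'
#' "Smallest on the plateau" makes ties deterministic and favours recall at
#' equal precision/F.
#'
#' @param table A `calibration_table` from [calibration_curve()].
#' @return A `threshold_set`: list with `max_precision`, `max_fmeasure`,
#'   `average`.
#' @export
derive_thresholds <- function(table) {
  ok <- table$tp >= 1
  if (!any(ok)) stop("model degenerate: no threshold yields a true positive")
  tt <- table[ok, ]
  max_precision <- tt$threshold[which.max(tt$precision)]
  max_fmeasure <- tt$threshold[which.max(tt$fmeasure)]
  structure(list(max_precision = max_precision,
                 max_fmeasure = max_fmeasure,
                 average = (max_precision + max_fmeasure) / 2),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf(paste0("<threshold_set> max_precision = %.4f, ",
                     "max_fmeasure = %.4f, average = %.4f\n"),
              x$max_precision, x$max_fmeasure, x$average))
  invisible(x)
}

#' Export a calibration table as TSV
#'
#' @param table A `calibration_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration_tsv <- function(table, path) {
  utils::write.table(
    table[, c("threshold", "precision", "recall", "fmeasure")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot a calibration curve
#'
#' Precision, recall and F-measure against the score threshold, with the
#' three calibrated thresholds marked when supplied.
#'
#' @param object A `calibration_table`.
#' @param thresholds Optional `threshold_set` to mark as vertical lines.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot calibration_table
#' @export
autoplot.calibration_table <- function(object, thresholds = NULL, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("threshold", "precision", "recall", "fmeasure")],
    -"threshold", names_to = "metric", values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$threshold, .data$value,
                                          colour = .data$metric)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "score threshold", y = "metric value") +
    ggplot2::ylim(0, 1)
  if (!is.null(thresholds)) {
    v <- tibble::tibble(
      name = c("max_precision", "max_fmeasure", "average"),
      threshold = c(thresholds$max_precision, thresholds$max_fmeasure,
                    thresholds$average))
    p <- p + ggplot2::geom_vline(data = v,
                                 ggplot2::aes(xintercept = .data$threshold),
                                 linetype = "dashed", colour = "grey40")
  }
  p
}
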