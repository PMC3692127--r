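#' Build a positional weight matrix from aligned positives
#'
#' Column frequencies use a background-weighted pseudocount,
#' `f(b, i) = (count(b, i) + pseudocount * background[b]) / (n + pseudocount)`,
#' and the matrix entries are natural-log odds `ln(f / background)`.
#'
#' @param positives Character vector of equal-length aligned sequences over
#'   `A,C,G,T`.
#' @param pseudocount Positive pseudocount mass (default 1, Laplace-style,
#'   spread over the bases in background proportion).
#' @param background Length-4 base frequency vector (A,C,G,T order, summing
#'   to 1); default uniform.
#' @return A `pwm` object: list with `width`, `counts` (4 x width),
#'   `freq`, `logodds` (rows A,C,G,T), `background`, and the filter fields
#'   `filter_columns` / `filter_threshold` (unset until calibrated).
#' @export
build_pwm <- function(positives, pseudocount = 1, background = NULL) {
  if (length(positives) == 0) stop("empty set of positives")
  W <- nchar(positives[1])
  if (any(nchar(positives) != W)) stop("positives must be equal length")
  if (any(grepl("[^ACGT]", positives))) stop("positives must be over A,C,G,T")
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  if (is.null(background)) background <- rep(0.25, 4)
  if (length(background) != 4 || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-8) {
    stop("background must be 4 positive frequencies summing to 1")
  }
  names(background) <- BASES
  M <- do.call(rbind, strsplit(positives, ""))
  n <- length(positives)
  counts <- vapply(seq_len(W), function(i) {
    as.numeric(table(factor(M[, i], BASES)))
  }, numeric(4))
  counts <- matrix(counts, nrow = 4, dimnames = list(BASES, NULL))
  freq <- (counts + pseudocount * background) / (n + pseudocount)
  logodds <- log(freq / background)
  structure(list(width = W, counts = counts, freq = freq, logodds = logodds,
                 background = background,
                 filter_columns = NULL, filter_threshold = NULL),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> width %d, consensus %s", x$width, pwm_consensus(x)))
  if (!is.null(x$filter_columns)) {
    cat(sprintf("; filter columns %d-%d", min(x$filter_columns),
                max(x$filter_columns)))
  }
  if (!is.null(x$filter_threshold)) {
    cat(sprintf(", threshold %.3f", x$filter_threshold))
  }
  cat("\n")
  invisible(x)
}

#' Consensus sequence of a PWM (highest-frequency base per column)
#' @param pwm A `pwm` object.
#' @return A single string.
#' @export
pwm_consensus <- function(pwm) {
  paste(BASES[apply(pwm$freq, 2, which.max)], collapse = "")
}

#' Score windows with a PWM
#'
#' Log-odds score: the sum over positions of `logodds[base, i]`. Vectorised
#' over windows.
#'
#' @param pwm A `pwm` object.
#' @param window Character vector of sequences, each exactly `pwm$width`
#'   long, over `A,C,G,T`.
#' @return Numeric vector of scores (natural-log-odds units).
#' @export
pwm_score <- function(pwm, window) {
  if (any(nchar(window) != pwm$width)) {
    stop("window length must equal PWM width (", pwm$width, ")")
  }
  if (any(grepl("[^ACGT]", window))) stop("window contains N or illegal character")
  M <- matrix(match(do.call(rbind, strsplit(window, "")), BASES),
              nrow = length(window))
  S <- vapply(seq_len(pwm$width), function(i) pwm$logodds[M[, i], i],
              numeric(length(window)))
  if (is.null(dim(S))) S <- matrix(S, nrow = 1)  # single window
  unname(rowSums(S))
}

# Per-column information content in nats: relative entropy of the column
# frequencies against the background.
column_ic <- function(pwm) {
  colSums(pwm$freq * log(pwm$freq / pwm$background))
}

#' Extract the short, most informative filter PWM
#'
#' Selects the contiguous run of `filter_width` columns maximising total
#' information content (relative entropy vs background, in nats; ties broken
#' leftmost) and returns a PWM restricted to those columns, with
#' `filter_columns` recording their 0-based positions within the full core.
#'
#' @param pwm Full-width `pwm`.
#' @param filter_width Number of columns to keep (default
#'   `min(8, pwm$width)`).
#' @return A `pwm` of width `filter_width`.
#' @export
shorten_for_filter <- function(pwm, filter_width = min(8, pwm$width)) {
  stopifnot(filter_width >= 1, filter_width <= pwm$width)
  ic <- column_ic(pwm)
  starts <- seq_len(pwm$width - filter_width + 1)
  totals <- vapply(starts, function(s) sum(ic[s:(s + filter_width - 1)]), 0)
  s <- starts[which.max(totals)]  # which.max: leftmost on ties
  cols <- s:(s + filter_width - 1)
  out <- pwm
  out$width <- as.integer(filter_width)
  out$counts <- pwm$counts[, cols, drop = FALSE]
  out$freq <- pwm$freq[, cols, drop = FALSE]
  out$logodds <- pwm$logodds[, cols, drop = FALSE]
  out$filter_columns <- cols - 1L
  out
}

#' Maximum-recall filter threshold
#'
#' The pre-filter threshold is set a fixed margin below the minimum filter
#' score over the training positives, so by construction every training
#' positive passes the filter (recall 1.0 on training data) and the margin
#' buys headroom for unseen variants.
#'
#' @param filter_pwm A filter `pwm` from [shorten_for_filter()] (or any pwm
#'   whose `filter_columns` are set; a full pwm scores all columns).
#' @param positives Training core sequences (full core width).
#' @param margin Non-negative log-odds margin subtracted from the minimum
#'   (default 0.5).
#' @return The threshold (log-odds units).
#' @export
max_recall_threshold <- function(filter_pwm, positives, margin = 0.5) {
  if (length(positives) == 0) stop("empty set of positives")
  stopifnot(margin >= 0)
  cols <- filter_pwm$filter_columns
  if (is.null(cols)) cols <- seq_len(filter_pwm$width) - 1L
  parts <- substring(positives, min(cols) + 1, max(cols) + 1)
  min(pwm_score(filter_pwm, parts)) - margin
}

# Sliding log-odds scores of all length-`width` windows of `seq` (plus
# strand); positions whose window contains N score NA.
slide_scores <- function(seq, logodds) {
  w <- ncol(logodds)
  idx <- match(strsplit(seq, "")[[1]], BASES)  # N -> NA
  L <- length(idx)
  if (L < w) return(numeric(0))
  npos <- L - w + 1
  s <- numeric(npos)
  for (c in seq_len(w)) {
    s <- s + logodds[cbind(idx[c:(c + npos - 1)], c)]
  }
  s
}

#' Pre-filter a sequence for candidate sites
#'
#' Scans both strands with the short filter PWM at its low, maximum-recall
#' threshold and returns every candidate core placement whose filter-column
#' score reaches the threshold. Candidates whose full window (core plus
#' flanks) would overrun the sequence are dropped, as are windows containing
#' `N`.
#'
#' @param seq A single sequence over `A,C,G,T,N`.
#' @param filter_pwm Filter `pwm` with `filter_columns` set.
#' @param core_width Full core width of the model.
#' @param flank Flank length of the model.
#' @param threshold Filter threshold; defaults to
#'   `filter_pwm$filter_threshold`. Use `-Inf` to keep every valid position.
#' @return Tibble with 0-based column `start` (core start on the forward
#'   sequence) and `strand` (`+`/`-`), sorted by (start, strand).
#' @export
prefilter <- function(seq, filter_pwm, core_width, flank = 0,
                      threshold = filter_pwm$filter_threshold) {
  if (is.null(threshold)) stop("filter threshold not set")
  cols <- filter_pwm$filter_columns
  if (is.null(cols)) cols <- seq_len(filter_pwm$width) - 1L
  o <- min(cols)
  L <- nchar(seq)
  one_strand <- function(s) {
    sc <- slide_scores(s, filter_pwm$logodds)
    p <- which(!is.na(sc) & sc >= threshold) - 1L  # 0-based filter starts
    p - o                                          # 0-based core starts
  }
  k_plus <- one_strand(seq)
  k_rc <- one_strand(reverse_complement(seq))
  k_minus <- L - k_rc - core_width
  cand <- tibble::tibble(
    start = c(k_plus, k_minus),
    strand = rep(c("+", "-"), c(length(k_plus), length(k_minus))))
  cand <- dplyr::filter(cand, .data$start - flank >= 0,
                        .data$start + core_width + flank <= L)
  # drop windows containing N anywhere in core + flanks
  if (nrow(cand) > 0) {
    win <- substring(seq, cand$start - flank + 1, cand$start + core_width + flank)
    cand <- cand[!grepl("N", win, fixed = TRUE), ]
  }
  dplyr::arrange(cand, .data$start, .data$strand)
}

#' Render a PWM as a plain-text block
#'
#' @param pwm A `pwm` object.
#' @param what `"logodds"`, `"freq"` or `"counts"`.
#' @return Character vector of lines (4 rows, A,C,G,T).
#' @export
format_pwm <- function(pwm, what = c("logodds", "freq", "counts")) {
  what <- match.arg(what)
  M <- pwm[[what]]
  unname(vapply(BASES, function(b) {
    paste(b, paste(formatC(M[b, ], format = "g", digits = 6), collapse = "\t"),
          sep = "\t")
  }, ""))
}

#' Export a PWM in JASPAR-style count format
#'
#' Four rows `A [ ... ]` etc., for interoperability with motif tools.
#'
#' @param pwm A `pwm` object.
#' @param name Motif name for the header line.
#' @param path Optional file to write to.
#' @return Character vector of lines (invisibly if `path` is given).
#' @export
export_pwm_jaspar <- function(pwm, name = "motif", path = NULL) {
  lines <- c(paste0(">", name),
             unname(vapply(BASES, function(b) {
               sprintf("%s  [ %s ]", b,
                       paste(formatC(pwm$counts[b, ], format = "g"),
                             collapse = " "))
             }, "")))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
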