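BASES <- c("A", "C", "G", "T")

#' Define the feature layout of a binding-site model
#'
#' A candidate site is a window of `core_width + 2 * flank` bases: the core
#' motif (the aligned, protein-contacted part) plus symmetric flanks. The
#' feature vector concatenates, in this fixed order:
#'
#' 1. direct readout: `4 * core_width` one-hot base indicators (A,C,G,T per
#'    core position);
#' 2. position dependencies: for each selected core position pair (i, j),
#'    16 indicators, one per ordered base pair — these capture within-motif
#'    correlations linked to local DNA structure;
#' 3. indirect readout: for each property scale, each region (core, left
#'    flank, right flank) and each aggregator, one summary of the property
#'    profile over that region.
#'
#' @param core_width Width of the aligned core motif in bp.
#' @param flank Flank length in bp on each side (default 10). Must be 0 (no
#'   flank regions) or at least the largest scale order.
#' @param scales Character vector of property scale names (see
#'   [list_scales()]), or a list of `property_scale` objects.
#' @param aggregators Subset of `c("mean", "min", "max")`.
#' @param dependency_pairs Tibble/data frame with integer columns `i`, `j`
#'   (0-based core positions, `i < j`), e.g. from
#'   [select_dependency_pairs()].
#' @return A `feature_spec` object with the implied `feature_names`.
#' @export
feature_spec <- function(core_width, flank = 10,
                         scales = character(),
                         aggregators = c("mean", "min", "max"),
                         dependency_pairs = NULL) {
  stopifnot(core_width >= 1, flank >= 0)
  if (is.character(scales)) scales <- lapply(scales, get_scale)
  stopifnot(all(vapply(scales, inherits, TRUE, "property_scale")))
  aggregators <- match.arg(aggregators, several.ok = TRUE)
  if (is.null(dependency_pairs)) {
    dependency_pairs <- tibble::tibble(i = integer(), j = integer())
  }
  dependency_pairs <- tibble::as_tibble(dependency_pairs)[c("i", "j")]
  if (nrow(dependency_pairs) > 0) {
    ok <- dependency_pairs$i >= 0 & dependency_pairs$i < dependency_pairs$j &
      dependency_pairs$j < core_width
    if (!all(ok)) stop("dependency pairs must satisfy 0 <= i < j < core_width")
  }
  orders <- vapply(scales, `[[`, 0L, "order")
  if (length(scales) > 0) {
    if (flank > 0 && flank < max(orders)) {
      stop("flank must be 0 or >= the largest scale order (", max(orders), ")")
    }
    if (core_width < max(orders)) {
      stop("core_width must be >= the largest scale order (", max(orders), ")")
    }
  }
  regions <- if (flank > 0) c("core", "flank_left", "flank_right") else "core"
  direct_names <- as.vector(t(outer(seq_len(core_width) - 1, BASES,
                                    function(i, b) sprintf("core%02d_%s", i, b))))
  dep_names <- character(0)
  if (nrow(dependency_pairs) > 0) {
    combos <- as.vector(t(outer(BASES, BASES, paste0)))
    dep_names <- unlist(purrr::pmap(dependency_pairs, function(i, j) {
      sprintf("dep%d_%d_%s", i, j, combos)
    }))
  }
  prop_names <- unlist(lapply(scales, function(sc) {
    as.vector(vapply(regions, function(r) paste(sc$name, r, aggregators, sep = "_"),
                     character(length(aggregators))))
  }))
  feature_names <- c(direct_names, dep_names, prop_names)
  if (anyDuplicated(feature_names)) stop("duplicate feature names")
  structure(list(core_width = as.integer(core_width), flank = as.integer(flank),
                 scales = scales, aggregators = aggregators,
                 dependency_pairs = dependency_pairs, regions = regions,
                 feature_names = feature_names),
            class = "feature_spec")
}

#' @export
print.feature_spec <- function(x, ...) {
  cat(sprintf(paste0("<feature_spec> core %d bp + %d bp flanks; %d pairs; ",
                     "%d scales x %d regions x %d aggregators; %d features\n"),
              x$core_width, x$flank, nrow(x$dependency_pairs),
              length(x$scales), length(x$regions), length(x$aggregators),
              length(x$feature_names)))
  invisible(x)
}

window_width <- function(spec) spec$core_width + 2L * spec$flank

#' One-hot encode the core of a window
#'
#' @param window Core sequence (length must equal the core width), no `N`.
#' @return Numeric vector of `4 * nchar(window)` indicators in fixed
#'   A,C,G,T order per position.
#' @examples
#' encode_direct("AC")
#' @export
encode_direct <- function(window) {
  if (grepl("[^ACGT]", window)) stop("N or illegal character in core window")
  ch <- strsplit(window, "")[[1]]
  v <- as.numeric(as.vector(t(outer(ch, BASES, `==`))))
  names(v) <- as.vector(t(outer(seq_along(ch) - 1, BASES,
                                function(i, b) sprintf("core%02d_%s", i, b))))
  v
}

#' Indicator features for nucleotide position dependencies
#'
#' For each position pair (i, j) the 16 ordered-dinucleotide indicators of
#' `(window[i], window[j])`, concatenated in pair order.
#'
#' @param window Core sequence, no `N`.
#' @param pairs Tibble/data frame with 0-based columns `i`, `j`.
#' @return Numeric vector of `16 * nrow(pairs)` indicators.
#' @export
encode_dependencies <- function(window, pairs) {
  if (grepl("[^ACGT]", window)) stop("N or illegal character in core window")
  pairs <- tibble::as_tibble(pairs)
  if (nrow(pairs) == 0) return(numeric(0))
  W <- nchar(window)
  if (any(pairs$i < 0 | pairs$j >= W | pairs$i >= pairs$j)) {
    stop("dependency pair out of range for window of width ", W)
  }
  ch <- strsplit(window, "")[[1]]
  combos <- as.vector(t(outer(BASES, BASES, paste0)))
  unlist(purrr::pmap(pairs, function(i, j) {
    v <- as.numeric(combos == paste0(ch[i + 1], ch[j + 1]))
    names(v) <- sprintf("dep%d_%d_%s", i, j, combos)
    v
  }))
}

#' Select core position pairs by mutual information
#'
#' Ranks all within-core position pairs by the mutual information (natural
#' log, maximum-likelihood plug-in estimate, no pseudocounts) between the
#' two positions' base distributions in the aligned positives, and returns
#' the top `k`. Ties are broken by (i, j) lexicographic order, so the
#' selection is deterministic for a fixed input.
#'
#' @param positives Character vector of equal-length aligned core sequences.
#' @param k Number of pairs to keep; if it exceeds the number of possible
#'   pairs, all pairs are returned with a warning.
#' @return Tibble with 0-based columns `i`, `j` and the MI value `mi`
#'   (nats), sorted by decreasing `mi` then (i, j).
#' @export
select_dependency_pairs <- function(positives, k) {
  stopifnot(length(positives) > 0, k >= 0)
  W <- nchar(positives[1])
  if (any(nchar(positives) != W)) stop("positives must be equal length")
  if (k == 0) return(tibble::tibble(i = integer(), j = integer(), mi = double()))
  M <- do.call(rbind, strsplit(positives, ""))
  n <- nrow(M)
  pairs <- which(upper.tri(matrix(0, W, W)), arr.ind = TRUE)  # col > row
  res <- purrr::map_dfr(seq_len(nrow(pairs)), function(r) {
    i <- unname(pairs[r, "row"]); j <- unname(pairs[r, "col"])
    joint <- table(factor(M[, i], BASES), factor(M[, j], BASES)) / n
    pi <- rowSums(joint); pj <- colSums(joint)
    nz <- joint > 0
    mi <- sum(joint[nz] * log(joint[nz] / outer(pi, pj)[nz]))
    tibble::tibble(i = i - 1L, j = j - 1L, mi = mi)
  })
  res <- dplyr::arrange(res, dplyr::desc(.data$mi), .data$i, .data$j)
  if (k > nrow(res)) {
    warning("k = ", k, " exceeds the ", nrow(res), " possible pairs; using all")
    k <- nrow(res)
  }
  res[seq_len(k), ]
}

# Profile matrix (n windows x n steps) for one scale over a set of
# equal-length region strings; vectorised k-mer table lookup.
profile_matrix <- function(regions, scale) {
  L <- nchar(regions[1])
  steps <- L - scale$order + 1
  out <- matrix(0, length(regions), steps)
  for (t in seq_len(steps)) {
    out[, t] <- scale$table[substring(regions, t, t + scale$order - 1)]
  }
  out
}

agg_rows <- function(P, aggregator) {
  switch(aggregator,
         mean = rowMeans(P),
         min = do.call(pmin, lapply(seq_len(ncol(P)), function(j) P[, j])),
         max = do.call(pmax, lapply(seq_len(ncol(P)), function(j) P[, j])))
}

#' Build the feature matrix for a set of candidate windows
#'
#' @param windows Character vector of windows, each of length
#'   `core_width + 2 * flank`, over `A,C,G,T` (windows containing `N` must
#'   be screened out by the caller).
#' @param spec A [feature_spec()].
#' @return Numeric matrix, one row per window, with `spec$feature_names` as
#'   column names.
#' @export
build_feature_matrix <- function(windows, spec) {
  stopifnot(inherits(spec, "feature_spec"))
  ww <- window_width(spec)
  bad <- which(nchar(windows) != ww)
  if (length(bad) > 0) {
    stop("window '", windows[bad[1]], "' has length ", nchar(windows[bad[1]]),
         ", expected ", ww)
  }
  if (any(grepl("[^ACGT]", windows))) stop("window contains N or illegal character")
  n <- length(windows)
  W <- spec$core_width; F <- spec$flank
  cores <- substring(windows, F + 1, F + W)
  M <- do.call(rbind, strsplit(cores, ""))
  direct <- matrix(0, n, 4 * W)
  for (p in seq_len(W)) {
    for (b in seq_along(BASES)) {
      direct[, (p - 1) * 4 + b] <- as.numeric(M[, p] == BASES[b])
    }
  }
  blocks <- list(direct)
  if (nrow(spec$dependency_pairs) > 0) {
    combos <- as.vector(t(outer(BASES, BASES, paste0)))
    dep <- matrix(0, n, 16 * nrow(spec$dependency_pairs))
    for (r in seq_len(nrow(spec$dependency_pairs))) {
      i <- spec$dependency_pairs$i[r]; j <- spec$dependency_pairs$j[r]
      obs <- paste0(M[, i + 1], M[, j + 1])
      for (c in seq_along(combos)) {
        dep[, (r - 1) * 16 + c] <- as.numeric(obs == combos[c])
      }
    }
    blocks <- c(blocks, list(dep))
  }
  if (length(spec$scales) > 0) {
    region_str <- list(core = cores)
    if (F > 0) {
      region_str$flank_left <- substring(windows, 1, F)
      region_str$flank_right <- substring(windows, F + W + 1, ww)
    }
    prop <- lapply(spec$scales, function(sc) {
      cols <- lapply(spec$regions, function(r) {
        P <- profile_matrix(region_str[[r]], sc)
        m <- vapply(spec$aggregators, function(a) agg_rows(P, a), numeric(n))
        matrix(m, nrow = n)  # vapply drops to a vector when n == 1
      })
      do.call(cbind, cols)
    })
    blocks <- c(blocks, prop)
  }
  X <- do.call(cbind, blocks)
  colnames(X) <- spec$feature_names
  X
}
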