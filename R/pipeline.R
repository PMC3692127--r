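#' Train a binding-site model end to end
#'
#' Takes aligned positive windows (core motif plus flanks, all in the same
#' orientation) and background sequence, and produces the full trained
#' bundle: a PWM with its short maximum-recall pre-filter, a feature
#' specification (direct readout, position dependencies, biophysical
#' property aggregates), the random-forest classifier, calibrated decision
#' thresholds and the empirical null score distribution.
#'
#' Positives are split into a training and a validation set with a seeded
#' random split. By default at most 100 positives are used for training and
#' the remainder for validation (with fewer than ~140 supplied positives,
#' 70% train / 30% validation, so threshold calibration always has held-out
#' data). The PWM, dependency pairs and forest are fitted on the training
#' split only; precision/recall calibration uses the validation positives
#' against freshly sampled background windows.
#'
#' @param positives Tibble with `id`, `seq` (from [read_fasta()]) or a
#'   character vector: aligned, equal-length windows of
#'   `core + 2 * flank` bases. At least 20 required.
#' @param background Tibble with `id`, `seq`: background/negative sequence
#'   (total length at least 100 x the core width).
#' @param name Model name (goes into BED output and reports).
#' @param evidence `"direct_evidence"` if the motif matches the factor's
#'   literature consensus, `"PAF"` (putative associated factor) otherwise;
#'   user-supplied metadata, stored verbatim.
#' @param flank Flank width in bp on each side of the core (default 10).
#' @param scales Property scale names (default: every scale in the shipped
#'   registry).
#' @param aggregators Profile summaries per region (default mean, min, max).
#' @param n_pairs Number of position-dependency pairs selected by mutual
#'   information (default 5).
#' @param n_trees Random-forest size (default 100).
#' @param n_train Training-split size override; `NULL` for the default rule.
#' @param pseudocount PWM pseudocount (default 1).
#' @param filter_width Width of the short filter PWM (default
#'   `min(8, core width)`).
#' @param filter_margin Log-odds margin below the minimum training-positive
#'   filter score (default 0.5).
#' @param null_samples Size of the empirical null (default 10000).
#' @param seed Integer seed governing the split, negative sampling, forest
#'   and null (mandatory; recorded in the model).
#' @return A `tfbs_model` object.
#' @export
train_model <- function(positives, background, name = "model",
                        evidence = c("direct_evidence", "PAF"),
                        flank = 10, scales = list_scales()$name,
                        aggregators = c("mean", "min", "max"),
                        n_pairs = 5, n_trees = 100, n_train = NULL,
                        pseudocount = 1, filter_width = NULL,
                        filter_margin = 0.5, null_samples = 10000,
                        seed = 1) {
  evidence <- match.arg(evidence)
  pos <- if (is.data.frame(positives)) positives$seq else positives
  bg <- if (is.data.frame(background)) background else
    tibble::tibble(id = paste0("bg", seq_along(background)), seq = background)
  if (length(pos) < 20) stop("need at least 20 aligned positives")
  len <- nchar(pos[1])
  if (any(nchar(pos) != len)) stop("positives must be aligned to equal length")
  if (any(grepl("[^ACGT]", pos))) stop("positives must be over A,C,G,T")
  core_width <- len - 2L * flank
  if (core_width < 4) stop("window too short for flank = ", flank)
  if (sum(nchar(bg$seq)) < 100 * core_width) {
    stop("background total length must be at least 100 x core width")
  }

  n <- length(pos)
  if (is.null(n_train)) n_train <- min(100L, floor(0.7 * n))
  n_train <- as.integer(n_train)
  if (n_train < 10 || n_train >= n) stop("n_train must be in [10, n_positives)")
  set.seed(seed)
  train_idx <- sort(sample.int(n, n_train))
  val_idx <- setdiff(seq_len(n), train_idx)

  train_win <- pos[train_idx]
  val_win <- pos[val_idx]
  train_cores <- substring(train_win, flank + 1, flank + core_width)

  bg_comp <- background_composition(bg$seq)
  pwm <- build_pwm(train_cores, pseudocount = pseudocount, background = bg_comp)
  if (is.null(filter_width)) filter_width <- min(8L, core_width)
  filter_pwm <- shorten_for_filter(pwm, filter_width)
  filter_pwm$filter_threshold <-
    max_recall_threshold(filter_pwm, train_cores, margin = filter_margin)

  pairs <- select_dependency_pairs(train_cores, n_pairs)
  spec <- feature_spec(core_width, flank = flank, scales = scales,
                       aggregators = aggregators, dependency_pairs = pairs)

  # Negatives are drawn to match the distribution the classifier sees in
  # deployment: in filter mode it only ever scores windows that pass the
  # low PWM pre-filter, so half the training negatives (and all calibration
  # negatives) are filter-passing background windows ("hard" negatives),
  # the rest uniform background windows.
  set.seed(seed + 1L)
  n_hard <- floor(n_train / 2)
  hard <- sample_candidate_windows(bg$seq, n_hard, filter_pwm,
                                   core_width, flank)
  neg_train <- c(sample_bg_windows(bg$seq, n_train - length(hard),
                                   window_width(spec)), hard)
  X <- build_feature_matrix(c(train_win, neg_train), spec)
  y <- rep(c(1L, 0L), c(length(train_win), length(neg_train)))
  forest <- train_forest(X, y, n_trees = n_trees, seed = seed + 2L)

  # calibration negatives: enough filter-passing windows that precision is
  # resolved finely — with too few negatives the named thresholds are
  # noisy and the scan false-positive rate swings between seeds
  set.seed(seed + 3L)
  n_negval <- max(4L * length(val_win), 200L)
  neg_val <- sample_candidate_windows(bg$seq, n_negval, filter_pwm,
                                      core_width, flank)
  if (length(neg_val) < n_negval) {
    neg_val <- c(neg_val, sample_bg_windows(bg$seq, n_negval - length(neg_val),
                                            window_width(spec)))
  }
  s_pos <- score_windows(forest, build_feature_matrix(val_win, spec))
  s_neg <- score_windows(forest, build_feature_matrix(neg_val, spec))
  calibration <- calibration_curve(s_pos, s_neg)
  thresholds <- derive_thresholds(calibration)

  null <- build_null(forest, bg, spec, n_samples = null_samples,
                     seed = seed + 4L)

  structure(list(
    name = name, evidence = evidence, spec = spec,
    pwm = pwm, filter_pwm = filter_pwm, forest = forest,
    thresholds = thresholds, null = null, calibration = calibration,
    training_meta = list(n_train = n_train, n_validation = length(val_idx),
                         seed = as.integer(seed), n_trees = as.integer(n_trees),
                         flank = as.integer(flank),
                         scales = vapply(spec$scales, `[[`, "", "name"))),
    class = "tfbs_model")
}

# Base composition (A,C,G,T frequencies) of a set of sequences; N ignored.
background_composition <- function(seqs) {
  ch <- strsplit(paste(seqs, collapse = ""), "")[[1]]
  counts <- table(factor(ch[ch %in% BASES], BASES))
  if (sum(counts) == 0) return(stats::setNames(rep(0.25, 4), BASES))
  p <- as.numeric(counts) / sum(counts)
  if (any(p == 0)) p <- (as.numeric(counts) + 1) / (sum(counts) + 4)
  stats::setNames(p, BASES)
}

# Draw n random N-free windows (uniform position and strand) from seqs.
# Caller seeds the RNG.
sample_bg_windows <- function(seqs, n, width) {
  ok <- seqs[nchar(seqs) >= width]
  if (length(ok) == 0) stop("background sequences shorter than the window width")
  wins <- character(0)
  guard <- 0
  while (length(wins) < n) {
    need <- n - length(wins)
    si <- sample.int(length(ok), need, replace = TRUE)
    pos <- floor(stats::runif(need) * (nchar(ok[si]) - width + 1))
    w <- substring(ok[si], pos + 1, pos + width)
    flip <- stats::runif(need) < 0.5
    if (any(flip)) w[flip] <- reverse_complement(w[flip])
    w <- w[!grepl("N", w, fixed = TRUE)]
    wins <- c(wins, w)
    guard <- guard + 1
    if (guard > 1000) stop("unable to draw enough N-free background windows")
  }
  wins[seq_len(n)]
}

# Draw up to n filter-passing ("hard negative") windows from background
# sequences, oriented to the strand on which they pass the filter. Returns
# fewer than n when the background yields fewer candidates. Caller seeds
# the RNG (used only for subsampling).
sample_candidate_windows <- function(seqs, n, filter_pwm, core_width, flank) {
  cand <- purrr::map_dfr(seq_along(seqs), function(r) {
    k <- prefilter(seqs[r], filter_pwm, core_width, flank = flank)
    if (nrow(k) == 0) return(NULL)
    k$rec <- r
    k
  })
  if (nrow(cand) == 0) return(character(0))
  if (nrow(cand) > n) cand <- cand[sample.int(nrow(cand), n), ]
  win <- substring(seqs[cand$rec], cand$start - flank + 1,
                   cand$start + core_width + flank)
  minus <- cand$strand == "-"
  if (any(minus)) win[minus] <- reverse_complement(win[minus])
  win
}

#' @export
print.tfbs_model <- function(x, ...) {
  cat(sprintf("<tfbs_model> '%s' (%s)\n", x$name, x$evidence))
  cat(sprintf("  core %d bp + %d bp flanks, consensus %s\n",
              x$spec$core_width, x$spec$flank, pwm_consensus(x$pwm)))
  cat(sprintf("  %d features, %d trees, OOB error %.3f\n",
              length(x$spec$feature_names), x$forest$n_trees,
              x$forest$oob_error))
  cat(sprintf("  thresholds: max_precision %.3f | average %.3f | max_fmeasure %.3f\n",
              x$thresholds$max_precision, x$thresholds$average,
              x$thresholds$max_fmeasure))
  cat(sprintf("  null: %d background windows; trained on %d (+%d validation)\n",
              x$null$n, x$training_meta$n_train, x$training_meta$n_validation))
  invisible(x)
}

# Map a threshold choice to a numeric score cutoff.
resolve_threshold <- function(model, threshold) {
  if (is.numeric(threshold)) {
    if (threshold < 0 || threshold > 1) stop("custom threshold must lie in [0, 1]")
    return(threshold)
  }
  choice <- match.arg(threshold, c("average", "max_precision", "max_fmeasure"))
  model$thresholds[[choice]]
}

#' Scan sequences for binding sites
#'
#' Strand-aware scan of arbitrary sequences with a trained model. In filter
#' mode (the default) candidate windows are pre-screened with the short
#' maximum-recall PWM, which prunes most of the sequence without losing
#' true sites; with `filter_mode = FALSE` every valid window on both strands
#' is classified. Candidate windows are always featurised in the site's own
#' 5'->3' orientation, so hits on the two strands of the same site get
#' identical scores. Windows containing `N` are skipped.
#'
#' Overlapping same-strand hits (overlap > 50% of the core width) are
#' resolved by keeping the highest-scoring hit (ties: leftmost).
#'
#' @param model A `tfbs_model`.
#' @param records Tibble with `id`, `seq` (e.g. from [read_fasta()]).
#' @param threshold `"average"` (default), `"max_precision"`,
#'   `"max_fmeasure"`, or a custom numeric cutoff in `[0, 1]`.
#' @param filter_mode Use the PWM pre-filter (default `TRUE`).
#' @return Tibble of hits, sorted by (`seq_id`, `start`): columns `seq_id`,
#'   `start`, `end` (0-based half-open core coordinates), `strand`, `score`
#'   (fraction of trees voting positive), `pvalue` (empirical, add-one),
#'   `passes` (comma-joined names of the calibrated thresholds the score
#'   reaches).
#' @export
scan_sequences <- function(model, records,
                           threshold = "average", filter_mode = TRUE) {
  stopifnot(inherits(model, "tfbs_model"))
  if (!is.data.frame(records)) {
    records <- tibble::tibble(id = paste0("seq", seq_along(records)),
                              seq = records)
  }
  cutoff <- resolve_threshold(model, threshold)
  W <- model$spec$core_width
  F <- model$spec$flank
  thr <- if (filter_mode) model$filter_pwm$filter_threshold else -Inf
  hits <- purrr::map_dfr(seq_len(nrow(records)), function(r) {
    seq <- records$seq[r]
    if (nchar(seq) < window_width(model$spec)) return(NULL)
    cand <- prefilter(seq, model$filter_pwm, W, flank = F, threshold = thr)
    cand <- dplyr::distinct(cand, .data$start, .data$strand)
    if (nrow(cand) == 0) return(NULL)
    win <- substring(seq, cand$start - F + 1, cand$start + W + F)
    minus <- cand$strand == "-"
    if (any(minus)) win[minus] <- reverse_complement(win[minus])
    s <- score_windows(model$forest, build_feature_matrix(win, model$spec))
    tibble::tibble(seq_id = records$id[r], start = cand$start,
                   end = cand$start + W, strand = cand$strand, score = s)
  })
  if (nrow(hits) == 0) return(empty_hits())
  hits <- dplyr::filter(hits, .data$score >= cutoff)
  if (nrow(hits) == 0) return(empty_hits())
  hits$pvalue <- empirical_pvalue(hits$score, model$null)
  th <- model$thresholds
  hits$passes <- vapply(hits$score, function(s) {
    paste(c("max_precision", "max_fmeasure", "average")[
      s >= c(th$max_precision, th$max_fmeasure, th$average)], collapse = ",")
  }, "")
  hits <- resolve_overlaps(hits, W)
  hits <- dplyr::select(hits, "seq_id", "start", "end", "strand",
                        "score", "pvalue", "passes")
  dplyr::arrange(hits, .data$seq_id, .data$start, .data$strand)
}

empty_hits <- function() {
  tibble::tibble(seq_id = character(), start = integer(), end = integer(),
                 strand = character(), score = double(), pvalue = double(),
                 passes = character())
}

# Greedy non-maximum suppression: among same-sequence, same-strand hits
# whose cores overlap by more than half the core width, keep the highest
# score (ties: leftmost).
resolve_overlaps <- function(hits, core_width) {
  if (nrow(hits) <= 1) return(hits)
  keep <- dplyr::group_modify(
    dplyr::group_by(hits, .data$seq_id, .data$strand),
    function(g, key) {
      g <- g[order(-g$score, g$start), ]
      kept <- integer(0)
      for (i in seq_len(nrow(g))) {
        ov <- pmin(g$end[i], g$end[kept]) - pmax(g$start[i], g$start[kept])
        if (length(kept) == 0 || all(ov <= core_width / 2)) kept <- c(kept, i)
      }
      g[sort(kept), ]
    })
  dplyr::ungroup(keep)
}

MODEL_FORMAT_VERSION <- 1L

#' Save / load a trained model
#'
#' The bundle is written as a versioned, self-describing RDS file carrying
#' the feature spec (including the full property-scale tables), PWM, filter,
#' forest, thresholds, null distribution and training metadata (seeds,
#' split sizes). Loading checks the format version and verifies every
#' property scale used by the model still exists in the installed registry,
#' failing with the scale's name otherwise. Saving the same model twice
#' produces byte-identical files.
#'
#' @param model A `tfbs_model`.
#' @param path File path (conventionally `.rds`).
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   the `tfbs_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "tfbs_model"))
  obj <- list(format = "motifforest_model",
              format_version = MODEL_FORMAT_VERSION,
              model = model)
  # compress = FALSE keeps the file free of compression-header timestamps,
  # so identical models serialize to byte-identical files
  saveRDS(obj, path, compress = FALSE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("corrupt or truncated model file: ",
                                           conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, "motifforest_model")) {
    stop("not a motifforest model file")
  }
  if (!identical(obj$format_version, MODEL_FORMAT_VERSION)) {
    stop("model format version ", obj$format_version,
         " not supported (expected ", MODEL_FORMAT_VERSION, ")")
  }
  registry <- list_scales()$name
  for (nm in obj$model$training_meta$scales) {
    if (!nm %in% registry) {
      stop("model requires property scale '", nm,
           "' which is missing from the registry")
    }
  }
  obj$model
}

#' Write hits as a TSV report
#'
#' Columns: `seq_id, start, end, strand, score, pvalue, passes`.
#'
#' @param hits Hit tibble from [scan_sequences()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trained model into per-feature importances
#'
#' @param x A `tfbs_model`.
#' @param ... Ignored.
#' @return Tibble with `feature`, `importance` (mean decrease in Gini
#'   impurity) and `block` (`direct`, `dependency` or `property`), sorted by
#'   decreasing importance.
#' @method tidy tfbs_model
#' @export
tidy.tfbs_model <- function(x, ...) {
  imp <- randomForest::importance(x$forest$forest, type = 2)
  out <- tibble::tibble(
    feature = rownames(imp),
    importance = as.numeric(imp[, 1]),
    block = dplyr::case_when(
      startsWith(rownames(imp), "core") ~ "direct",
      startsWith(rownames(imp), "dep") ~ "dependency",
      TRUE ~ "property"))
  dplyr::arrange(out, dplyr::desc(.data$importance))
}

#' One-row summary of a trained model
#'
#' @param x A `tfbs_model`.
#' @param ... Ignored.
#' @return One-row tibble: name, evidence, geometry, split sizes, OOB error,
#'   the three calibrated thresholds and the null size.
#' @method glance tfbs_model
#' @export
glance.tfbs_model <- function(x, ...) {
  tibble::tibble(
    name = x$name, evidence = x$evidence,
    core_width = x$spec$core_width, flank = x$spec$flank,
    n_features = length(x$spec$feature_names),
    n_train = x$training_meta$n_train,
    n_validation = x$training_meta$n_validation,
    n_trees = x$forest$n_trees, oob_error = x$forest$oob_error,
    max_precision = x$thresholds$max_precision,
    max_fmeasure = x$thresholds$max_fmeasure,
    average = x$thresholds$average,
    null_n = x$null$n)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a model's calibration curve with its thresholds
#'
#' @param object A `tfbs_model`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot tfbs_model
#' @export
autoplot.tfbs_model <- function(object, ...) {
  autoplot.calibration_table(object$calibration, thresholds = object$thresholds)
}
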