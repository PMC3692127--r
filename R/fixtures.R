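#' Sample random background sequences
#'
#' I.i.d. bases with `P(G) = P(C) = gc/2` and `P(A) = P(T) = (1 - gc)/2`;
#' reproducible for a fixed seed.
#'
#' @param n Number of sequences.
#' @param length Length of each sequence in bp.
#' @param gc GC content in (0, 1) (0 and 1 allowed for degenerate alphabets).
#' @param seed Integer seed (mandatory).
#' @param prefix Record ID prefix.
#' @return Tibble with `id`, `seq`.
#' @export
sample_background <- function(n, length, gc = 0.5, seed, prefix = "bg") {
  stopifnot(n > 0, length > 0, gc >= 0, gc <= 1)
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(BASES, length, replace = TRUE, prob = p), collapse = "")
  }, "")
  tibble::tibble(id = paste0(prefix, seq_len(n)), seq = seqs)
}

# Gradient of the i.i.d. mean property value with respect to the base
# composition, evaluated at composition p0:
#   d/dp_b E[v(k-mer)] = sum_k v(k) sum_i [k_i == b] prod_{j != i} p0[k_j].
# A plain per-base marginal average is not enough here: for tables like
# bendability the same base can dominate both the most rigid (AAA) and the
# most flexible (TCA, ATA) k-mers, so only the local gradient gives a
# reliable direction for shifting the mean.
property_mean_gradient <- function(scale, p0) {
  kmers <- strsplit(names(scale$table), "")
  g <- stats::setNames(numeric(4), BASES)
  for (k in seq_along(kmers)) {
    km <- kmers[[k]]
    v <- scale$table[[k]]
    probs <- p0[km]
    for (i in seq_along(km)) {
      g[km[i]] <- g[km[i]] + v * prod(probs[-i])
    }
  }
  g
}

# Flank base probabilities tilted so the property's i.i.d. mean moves by
# `shift` standard deviations of the k-mer table (sign = direction). The
# composition follows the property-mean gradient in small exponential-tilt
# steps until the target displacement is reached; if the reachable extreme
# of the mean surface is hit first (e.g. bendability's i.i.d. mean has an
# interior maximum close to typical genomic compositions, so large upward
# shifts are unattainable), the flow stops there.
tilted_composition <- function(gc, scale, shift) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  if (shift == 0) return(p)
  iid_mean <- function(q) {
    kmers <- strsplit(names(scale$table), "")
    sum(vapply(seq_along(kmers),
               function(k) scale$table[[k]] * prod(q[kmers[[k]]]), 0))
  }
  target <- abs(shift) * stats::sd(scale$table)
  m0 <- iid_mean(p)
  eta <- sign(shift) * 0.02
  for (s in seq_len(500L)) {
    if (abs(iid_mean(p) - m0) >= target) break
    g <- property_mean_gradient(scale, p)
    z <- g - sum(p * g)
    nz <- sqrt(sum(p * z^2))
    if (nz < 1e-9 * stats::sd(scale$table)) break  # reachable extreme
    p <- p * exp(eta * z / nz)
    p <- p / sum(p)
  }
  p
}

#' Implant one motif instance per record
#'
#' Each record receives one site at a uniform random position (leaving room
#' for the model flanks) and uniform random strand. The implanted core is
#' the consensus with independent per-position substitution probability
#' `mutation_rate` (substituted bases drawn uniformly from the other
#' three); on the minus strand its reverse complement is written. With
#' `structural_bias`, the `flank` bases on both sides of every true site are
#' rewritten from a tilted composition chosen so the named property's mean
#' over the flanks moves by `shift` standard deviations of the property
#' table (sign gives the direction; displacement is capped at the extreme
#' reachable by composition alone). The structural signal is injected
#' through composition, so the output stays valid DNA and the property
#' tables transduce it into property-value shifts.
#'
#' @param records Tibble with `id`, `seq`.
#' @param consensus Motif consensus to implant (the core).
#' @param mutation_rate Per-position substitution probability in `[0, 1]`.
#' @param structural_bias `NULL`, or `list(scale = <name>, shift = <real>)`.
#' @param flank Flank width the downstream model will use (default 10);
#'   sites are placed so core + flanks fit, and this is the width of the
#'   biased flank region.
#' @param seed Integer seed.
#' @param gc GC content used for biased-flank tilting (default 0.5).
#' @return List with `records` (modified tibble) and `truth` (tibble
#'   `seq_id, start, end, strand`, 0-based half-open core coordinates).
#' @export
implant_sites <- function(records, consensus, mutation_rate = 0,
                          structural_bias = NULL, flank = 10, seed,
                          gc = 0.5) {
  stopifnot(mutation_rate >= 0, mutation_rate <= 1)
  W <- nchar(consensus)
  L <- nchar(records$seq)
  if (any(L < W + 2 * flank)) {
    stop("consensus + flanks longer than at least one record")
  }
  set.seed(seed)
  cons <- strsplit(consensus, "")[[1]]
  tilt <- NULL
  if (!is.null(structural_bias)) {
    tilt <- tilted_composition(gc, get_scale(structural_bias$scale),
                               structural_bias$shift)
  }
  n <- nrow(records)
  starts <- flank + floor(stats::runif(n) * (L - W - 2 * flank + 1))
  strands <- ifelse(stats::runif(n) < 0.5, "+", "-")
  seqs <- records$seq
  for (r in seq_len(n)) {
    site <- cons
    mut <- stats::runif(W) < mutation_rate
    if (any(mut)) {
      site[mut] <- vapply(site[mut],
                          function(b) sample(setdiff(BASES, b), 1), "")
    }
    site <- paste(site, collapse = "")
    oriented <- if (strands[r] == "-") reverse_complement(site) else site
    s <- seqs[r]
    k <- starts[r]  # 0-based core start
    left <- substr(s, 1, k)
    right <- substr(s, k + W + 1, nchar(s))
    if (!is.null(tilt)) {
      lf <- paste(sample(BASES, flank, replace = TRUE, prob = tilt), collapse = "")
      rf <- paste(sample(BASES, flank, replace = TRUE, prob = tilt), collapse = "")
      left <- paste0(substr(left, 1, k - flank), lf)
      right <- paste0(rf, substr(right, flank + 1, nchar(right)))
    }
    seqs[r] <- paste0(left, oriented, right)
  }
  list(records = tibble::tibble(id = records$id, seq = seqs),
       truth = tibble::tibble(seq_id = records$id, start = as.integer(starts),
                              end = as.integer(starts + W), strand = strands))
}

#' Fixture configuration for synthetic benchmark data
#'
#' Bundles the generator settings. Defaults emulate a typical ChIP-derived
#' training scenario: a well-defined 12-bp aligned core (a composite
#' CRE/E-box-like consensus) with 10% per-position degeneracy, 150 positive
#' regions (so the default training split is 100 train / 50 validation),
#' 500-bp regions at 50% GC, and no structural signal unless requested.
#'
#' @param motif_consensus Planted core motif (default `"TGACGTCACGTG"`).
#' @param mutation_rate Per-position substitution probability (default 0.1).
#' @param structural_bias `NULL` or `list(scale = , shift = )`; see
#'   [implant_sites()].
#' @param n_pos Number of positive (site-bearing) regions (default 150).
#' @param n_neg Number of background regions (default 50).
#' @param n_scan Number of site-bearing regions in the scan set (default 20).
#' @param seq_len Region length in bp (default 500).
#' @param gc_content Background GC fraction (default 0.5).
#' @param flank Flank width used when extracting aligned positives
#'   (default 10).
#' @param seed Integer seed (mandatory).
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(motif_consensus = "TGACGTCACGTG", mutation_rate = 0.1,
                           structural_bias = NULL, n_pos = 150, n_neg = 50,
                           n_scan = 20, seq_len = 500, gc_content = 0.5,
                           flank = 10, seed) {
  stopifnot(mutation_rate >= 0, mutation_rate <= 1,
            gc_content > 0, gc_content < 1)
  if (missing(seed)) stop("seed is mandatory")
  structure(list(motif_consensus = motif_consensus,
                 mutation_rate = mutation_rate,
                 structural_bias = structural_bias,
                 n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 n_scan = as.integer(n_scan), seq_len = as.integer(seq_len),
                 gc_content = gc_content, flank = as.integer(flank),
                 seed = as.integer(seed)),
            class = "fixture_config")
}

#' Generate a complete synthetic dataset with ground truth
#'
#' Produces everything a training-plus-scanning experiment needs:
#' * `positives` — aligned core+flank windows extracted from site-bearing
#'   regions, all re-oriented to the motif's strand (ready for
#'   [train_model()]);
#' * `background` — plain background regions;
#' * `scan` — a fresh set of site-bearing regions to scan;
#' * `truth` — the implanted-site coordinates of the scan set (BED-style).
#'
#' @param config A [fixture_config()].
#' @return List of tibbles `positives`, `background`, `scan`, `truth`, plus
#'   the `config`.
#' @export
make_dataset <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  cfg <- config
  bg_pos <- sample_background(cfg$n_pos, cfg$seq_len, cfg$gc_content,
                              seed = cfg$seed, prefix = "pos")
  imp <- implant_sites(bg_pos, cfg$motif_consensus, cfg$mutation_rate,
                       cfg$structural_bias, flank = cfg$flank,
                       seed = cfg$seed + 1L, gc = cfg$gc_content)
  W <- nchar(cfg$motif_consensus)
  win <- substring(imp$records$seq, imp$truth$start - cfg$flank + 1,
                   imp$truth$start + W + cfg$flank)
  minus <- imp$truth$strand == "-"
  if (any(minus)) win[minus] <- reverse_complement(win[minus])
  positives <- tibble::tibble(id = imp$records$id, seq = win)

  background <- sample_background(cfg$n_neg, cfg$seq_len, cfg$gc_content,
                                  seed = cfg$seed + 2L, prefix = "bg")

  scan_bg <- sample_background(cfg$n_scan, cfg$seq_len, cfg$gc_content,
                               seed = cfg$seed + 3L, prefix = "scan")
  scan_imp <- implant_sites(scan_bg, cfg$motif_consensus, cfg$mutation_rate,
                            cfg$structural_bias, flank = cfg$flank,
                            seed = cfg$seed + 4L, gc = cfg$gc_content)
  list(positives = positives, background = background,
       scan = scan_imp$records, truth = scan_imp$truth, config = cfg)
}

#' Write a synthetic dataset to disk
#'
#' Emits `positives.fa`, `background.fa`, `scan.fa` and `truth.bed`
#' (BED6, score 0) under `outdir`.
#'
#' @param dataset Output of [make_dataset()].
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_dataset <- function(dataset, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(dataset$positives, file.path(outdir, "positives.fa"))
  write_fasta(dataset$background, file.path(outdir, "background.fa"))
  write_fasta(dataset$scan, file.path(outdir, "scan.fa"))
  truth <- dplyr::mutate(dataset$truth, score = 0)
  write_bed(truth, file.path(outdir, "truth.bed"), name = "true_site")
  invisible(outdir)
}
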