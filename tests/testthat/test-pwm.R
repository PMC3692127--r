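test_that("build_pwm frequencies and log-odds follow the pseudocount formula", {
  # vanishing pseudocount: pure columns approach ln(1/0.25)
  p <- build_pwm(c("AA", "AA"), pseudocount = 1e-9)
  expect_equal(unname(p$logodds["A", 1]), log(4), tolerance = 1e-6)
  expect_lt(p$logodds["C", 1], -15)
  # pseudocount 1 keeps everything finite
  p1 <- build_pwm(c("AA", "AA"), pseudocount = 1)
  expect_true(all(is.finite(p1$logodds)))

  # uniform counts under uniform background give log-odds 0
  pu <- build_pwm(c("A", "C", "G", "T"), pseudocount = 1)
  expect_equal(unname(pu$logodds[, 1]), rep(0, 4))

  # hand-computed oracle on 5 toy 6-mers
  pos <- c("TGACGT", "TGACGT", "TGACTT", "AGACGT", "TGGCGT")
  bg <- rep(0.25, 4)
  pwm <- build_pwm(pos, pseudocount = 1, background = bg)
  counts <- sapply(1:6, function(i) {
    tab <- table(factor(substring(pos, i, i), c("A", "C", "G", "T")))
    as.numeric(tab)
  })
  f <- (counts + 1 * 0.25) / (5 + 1)
  expect_equal(unname(pwm$freq), f)
  expect_equal(unname(pwm$logodds), log(f / 0.25))
  # column frequencies sum to 1
  expect_equal(unname(colSums(pwm$freq)), rep(1, 6))

  expect_error(build_pwm(c("AA", "AAA")), "equal length")
  expect_error(build_pwm(character(0)), "empty")
})

test_that("pwm_score sums per-position log-odds", {
  pos <- c("TGACGT", "TGACGT", "TGACTT", "AGACGT", "TGGCGT")
  pwm <- build_pwm(pos, pseudocount = 1)
  # consensus window attains the column-wise maximum sum
  expect_equal(pwm_score(pwm, pwm_consensus(pwm)),
               sum(apply(pwm$logodds, 2, max)))
  # uniform PWM scores 0 for any window
  pu <- build_pwm(c("ACGT", "CGTA", "GTAC", "TACG"), pseudocount = 1e-9)
  expect_equal(pwm_score(pu, "GGGG"), 0, tolerance = 1e-6)

  # brute-force per-position summation oracle
  for (w in random_dna(10, 6, seed = 3)) {
    ch <- strsplit(w, "")[[1]]
    manual <- sum(vapply(1:6, function(i) pwm$logodds[ch[i], i], 0))
    expect_equal(pwm_score(pwm, w), manual)
  }
  expect_error(pwm_score(pwm, "ACGT"), "width")
})

test_that("shorten_for_filter picks the max-IC contiguous window", {
  pos <- c("TGACGTCA", "TGACGTCA", "AGACGTCT", "TGACGACA", "TGTCGTCA")
  pwm <- build_pwm(pos, pseudocount = 1)

  # full width is the identity selection
  full <- shorten_for_filter(pwm, 8)
  expect_equal(full$filter_columns, 0:7)
  expect_equal(full$logodds, pwm$logodds)

  # exhaustive window-search oracle at every width
  ic <- motifforest:::column_ic(pwm)
  for (fw in c(3, 4, 6)) {
    short <- shorten_for_filter(pwm, fw)
    totals <- vapply(seq_len(8 - fw + 1), function(s) sum(ic[s:(s + fw - 1)]), 0)
    best <- which.max(totals)
    expect_equal(short$filter_columns, (best - 1):(best + fw - 2))
    expect_equal(short$logodds, pwm$logodds[, best:(best + fw - 1)])
  }

  # uninformative matrix: leftmost window chosen
  pu <- build_pwm(c("ACGT", "CGTA", "GTAC", "TACG"), pseudocount = 1)
  expect_equal(shorten_for_filter(pu, 2)$filter_columns, 0:1)
})

test_that("max_recall_threshold passes every training positive by construction", {
  pos <- c("TGACGTCA", "TGACGTCA", "AGACGTCT", "TGACGACA", "TGTCGTCA")
  pwm <- build_pwm(pos, pseudocount = 1)
  filt <- shorten_for_filter(pwm, 5)
  thr <- max_recall_threshold(filt, pos, margin = 0.5)

  cols <- filt$filter_columns
  parts <- substring(pos, min(cols) + 1, max(cols) + 1)
  scores <- pwm_score(filt, parts)
  expect_equal(thr, min(scores) - 0.5)       # brute-force min oracle
  expect_true(all(scores >= thr))            # recall 1.0 on training set

  # all-consensus training set: threshold = max score - margin
  cons <- rep("TGACGTCA", 10)
  pc <- build_pwm(cons, pseudocount = 1)
  fc <- shorten_for_filter(pc, 8)
  expect_equal(max_recall_threshold(fc, cons, margin = 0.25),
               max(pwm_score(fc, cons)) - 0.25)
})

test_that("prefilter matches a brute-force scan oracle on a random 200-mer", {
  pos <- random_dna(30, 8, seed = 8)
  pwm <- build_pwm(pos, pseudocount = 1)
  filt <- shorten_for_filter(pwm, 6)
  filt$filter_threshold <- stats::quantile(
    pwm_score(filt, substring(pos, min(filt$filter_columns) + 1,
                              max(filt$filter_columns) + 1)), 0.25)

  seq <- random_dna(1, 200, seed = 77)
  got <- prefilter(seq, filt, core_width = 8, flank = 5)

  # oracle: score every candidate core start on both strands directly
  oracle <- list()
  o <- min(filt$filter_columns)
  for (k in 5:(200 - 8 - 5)) {
    fwd <- substr(seq, k + o + 1, k + o + 6)
    if (pwm_score(filt, fwd) >= filt$filter_threshold) {
      oracle[[length(oracle) + 1]] <- c(k, "+")
    }
    core_rc <- reverse_complement(substr(seq, k + 1, k + 8))
    rcpart <- substr(core_rc, o + 1, o + 6)
    if (pwm_score(filt, rcpart) >= filt$filter_threshold) {
      oracle[[length(oracle) + 1]] <- c(k, "-")
    }
  }
  want <- tibble::tibble(start = as.integer(vapply(oracle, `[`, "", 1)),
                         strand = vapply(oracle, `[`, "", 2))
  want <- dplyr::arrange(want, start, strand)
  expect_equal(got, want)
})

test_that("prefilter finds a planted consensus and honors the -Inf limit", {
  pos <- c("TGACGGCA", "TGACGGCA", "TGACGGCT", "AGACGGCA")
  pwm <- build_pwm(pos, pseudocount = 1)
  filt <- shorten_for_filter(pwm, 8)
  filt$filter_threshold <- max_recall_threshold(filt, pos, margin = 0.5)

  seq <- paste0(strrep("A", 40), "TGACGGCA", strrep("A", 40))
  cand <- prefilter(seq, filt, core_width = 8, flank = 10)
  expect_true(any(cand$start == 40 & cand$strand == "+"))

  all_pos <- prefilter(seq, filt, core_width = 8, flank = 10, threshold = -Inf)
  expect_equal(nrow(all_pos), 2 * (88 - 8 - 2 * 10 + 1))
})

test_that("prefilter is strand-mirror symmetric and monotone in the threshold", {
  pos <- random_dna(30, 8, seed = 15)
  pwm <- build_pwm(pos, pseudocount = 1)
  filt <- shorten_for_filter(pwm, 6)
  filt$filter_threshold <- -1

  seq <- random_dna(1, 150, seed = 60)
  fwd <- prefilter(seq, filt, core_width = 8, flank = 4)
  rev <- prefilter(reverse_complement(seq), filt, core_width = 8, flank = 4)
  mirrored <- dplyr::arrange(
    tibble::tibble(start = 150L - rev$start - 8L,
                   strand = ifelse(rev$strand == "+", "-", "+")),
    start, strand)
  expect_equal(fwd, mirrored)

  looser <- prefilter(seq, filt, core_width = 8, flank = 4, threshold = -3)
  expect_true(nrow(looser) >= nrow(fwd))
  expect_true(all(paste(fwd$start, fwd$strand) %in%
                    paste(looser$start, looser$strand)))

  # windows containing N are skipped
  seqN <- paste0(substr(seq, 1, 70), "N", substr(seq, 72, 150))
  candN <- prefilter(seqN, filt, core_width = 8, flank = 4, threshold = -Inf)
  win_has_n <- grepl("N", substring(seqN, candN$start - 4 + 1,
                                    candN$start + 8 + 4))
  expect_false(any(win_has_n))
})

test_that("PWM text exports render all four base rows", {
  pwm <- build_pwm(c("ACGT", "ACGT", "ACCT"), pseudocount = 1)
  lo <- format_pwm(pwm)
  expect_length(lo, 4)
  expect_match(lo[1], "^A\t")
  jas <- export_pwm_jaspar(pwm, name = "toy")
  expect_equal(jas[1], ">toy")
  expect_match(jas[2], "^A  \\[")
})
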