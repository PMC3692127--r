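# Shared fixtures: one small trained model reused across test files
# (training is seeded, so every test sees the same object).

.cache <- new.env(parent = emptyenv())

test_dataset <- function() {
  if (is.null(.cache$ds)) {
    .cache$ds <- make_dataset(fixture_config(seed = 42))
  }
  .cache$ds
}

test_model <- function() {
  if (is.null(.cache$model)) {
    ds <- test_dataset()
    .cache$model <- train_model(ds$positives, ds$background, name = "toy",
                                null_samples = 500, seed = 7)
  }
  .cache$model
}

random_dna <- function(n, len, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, "")
}

# independent reverse complement (Biostrings), used as an oracle
rc_oracle <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# fraction of truth sites overlapped (> half the core) by some hit, and
# count of hits overlapping no truth site
scan_vs_truth <- function(hits, truth) {
  W <- truth$end[1] - truth$start[1]
  ov <- function(h_start, h_end, t) {
    pmin(h_end, t$end) - pmax(h_start, t$start) > W / 2
  }
  found <- vapply(seq_len(nrow(truth)), function(j) {
    t <- truth[j, ]
    h <- hits[hits$seq_id == t$seq_id, ]
    nrow(h) > 0 && any(ov(h$start, h$end, t))
  }, TRUE)
  fp <- vapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    t <- truth[truth$seq_id == h$seq_id, ]
    nrow(t) == 0 || !any(pmin(h$end, t$end) - pmax(h$start, t$start) > W / 2)
  }, TRUE)
  list(recall = mean(found), n_fp = sum(fp))
}
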