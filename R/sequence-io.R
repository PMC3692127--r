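#' Read FASTA sequences into a tibble
#'
#' Parses FASTA text into one row per record. Sequences are uppercased and
#' `U` is mapped to `T` so RNA input is tolerated; any other character
#' outside `A,C,G,T,N` is a hard error (masked or corrupted input must not
#' silently enter feature vectors). Lowercase (soft-masked) input is
#' accepted but the masking information is discarded.
#'
#' @param source Path to a FASTA file, or a character vector of FASTA text
#'   lines (handy for tests and pipes).
#' @return A tibble with columns `id` (character) and `seq` (character,
#'   uppercase over `A,C,G,T,N`).
#' @examples
#' read_fasta(c(">s1", "acgt", "ACGT"))
#' @export
read_fasta <- function(source) {
  if (length(source) == 1 && !startsWith(trimws(source[1]), ">")) {
    if (!file.exists(source)) stop("FASTA file not found: ", source)
    set <- Biostrings::readBStringSet(source)
  } else {
    tf <- tempfile(fileext = ".fa")
    on.exit(unlink(tf), add = TRUE)
    writeLines(source, tf)
    set <- Biostrings::readBStringSet(tf)
  }
  if (length(set) == 0) stop("no records in FASTA input")
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, "", 1)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) stop("duplicate FASTA ID: ", dup[1])
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf("illegal character '%s' in record '%s' at position %d",
                 substr(seqs[i], bad[i], bad[i]), ids[i], bad[i]))
  }
  tibble::tibble(id = unname(ids), seq = unname(seqs))
}

#' Write sequence records to a FASTA file
#'
#' @param records Tibble or data frame with columns `id` and `seq`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  lines <- as.vector(rbind(paste0(">", records$id), records$seq))
  writeLines(lines, path)
  invisible(path)
}

#' Reverse-complement a DNA sequence
#'
#' Standard Watson-Crick complement, reversed; `N` maps to `N`. Vectorised
#' over its input and an involution: `reverse_complement(reverse_complement(x))`
#' is `x`.
#'
#' @param seq Character vector of sequences over `A,C,G,T,N`.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("AAAC")  # "GTTT"
#' @export
reverse_complement <- function(seq) {
  if (any(grepl("[^ACGTN]", seq))) stop("illegal character in sequence")
  comp <- chartr("ACGTN", "TGCAN", seq)
  vapply(strsplit(comp, ""), function(s) paste(rev(s), collapse = ""), "")
}

#' Write predicted hits as BED6
#'
#' Emits one BED6 line per hit: `chrom, start, end, name, score, strand`
#' with 0-based half-open coordinates. The BED score column is the
#' classifier score scaled to 0-1000 (`round(1000 * score)`, clamped).
#' Hits are sorted by (chrom, start) before writing.
#'
#' @param hits Tibble of hits as returned by [scan_sequences()]; must carry
#'   `seq_id`, `start`, `end`, `strand`, `score`.
#' @param path Output file path.
#' @param name Feature name for column 4 (typically the model name).
#' @return `path`, invisibly.
#' @export
write_bed <- function(hits, path, name = "model") {
  need <- c("seq_id", "start", "end", "strand", "score")
  if (!all(need %in% names(hits))) {
    stop("hits must have columns: ", paste(need, collapse = ", "))
  }
  hits <- dplyr::arrange(hits, .data$seq_id, .data$start)
  if ("name" %in% names(hits)) name <- hits$name
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   hits$seq_id, hits$start, hits$end, name,
                   pmin(pmax(round(1000 * hits$score), 0), 1000),
                   hits$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED6 file into a tibble
#'
#' Used mainly to round-trip the synthetic truth tables; scores are
#' rescaled back from the 0-1000 BED convention to `[0, 1]`.
#'
#' @param path BED file path.
#' @return Tibble with columns `seq_id, start, end, name, score, strand`.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0) {
    return(tibble::tibble(seq_id = character(), start = integer(),
                          end = integer(), name = character(),
                          score = double(), strand = character()))
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("seq_id", "start", "end",
                                        "name", "score", "strand"),
                          colClasses = c("character", "integer", "integer",
                                         "character", "double", "character"))
  df$score <- df$score / 1000
  tibble::as_tibble(df)
}
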