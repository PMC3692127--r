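#' @importFrom rlang .data
#' @importFrom stats setNames
NULL

the <- new.env(parent = emptyenv())

#' DNA biophysical property scales
#'
#' The package ships a registry of k-mer -> value conversion tables, one per
#' biophysical DNA property (indirect-readout features). Each scale maps
#' every dinucleotide or trinucleotide to a real value; sliding the table
#' along a sequence yields a structural profile that is then summarised
#' (mean/min/max) over the core and flank regions of a candidate site.
#'
#' Shipped scales: trinucleotide DNase I bendability, dinucleotide propeller
#' twist, base-stacking energy and duplex free energy, trinucleotide
#' nucleosome positioning preference, and a synthetic stand-in for the
#' solvent-excluded surface of the DNA (constructed, not published — see the
#' manifest's citation column). All shipped tables are strand-symmetric:
#' a k-mer and its reverse complement share the same value.
#'
#' @param name Scale name as listed by `list_scales()`.
#' @return `list_scales()` returns a tibble describing the registry;
#'   `get_scale()` returns a `property_scale` object: a list with fields
#'   `name`, `order`, `table` (named numeric of length `4^order`),
#'   `strand_symmetric`, `units`, `citation`.
#' @examples
#' list_scales()
#' sc <- get_scale("bendability")
#' sc$table[["AAA"]]
#' @name property_scales
NULL

scale_dir <- function() system.file("extdata", "scales", package = "motifforest")

load_registry <- function() {
  if (!is.null(the$registry)) return(the$registry)
  man <- utils::read.delim(file.path(scale_dir(), "manifest.tsv"),
                           stringsAsFactors = FALSE)
  reg <- lapply(seq_len(nrow(man)), function(i) {
    tab <- utils::read.delim(file.path(scale_dir(), man$file[i]),
                             stringsAsFactors = FALSE)
    new_property_scale(
      name = man$name[i], order = man$order[i],
      table = setNames(tab$value, tab$kmer),
      strand_symmetric = man$strand_symmetric[i],
      units = man$units[i], citation = man$citation[i])
  })
  names(reg) <- man$name
  the$registry <- reg
  reg
}

#' Construct a property scale
#'
#' Validates and wraps a k-mer -> value table. Exported so users can
#' register their own scales alongside the shipped ones.
#'
#' @param name Scale name.
#' @param order k-mer length (2 for dinucleotide, 3 for trinucleotide).
#' @param table Named numeric vector with exactly `4^order` entries, one per
#'   k-mer over `A,C,G,T`.
#' @param strand_symmetric Logical; if `TRUE`, `table[kmer]` must equal
#'   `table[revcomp(kmer)]` for every k-mer (checked).
#' @param units Free-text units of the values.
#' @param citation Literature source (or a statement that the scale is
#'   synthetic).
#' @return A `property_scale` object.
#' @export
new_property_scale <- function(name, order, table, strand_symmetric,
                               units = "", citation = "") {
  kmers <- all_kmers(order)
  if (length(table) != 4^order || !all(kmers %in% names(table))) {
    stop("table must have exactly 4^order entries covering all k-mers")
  }
  table <- table[kmers]
  if (strand_symmetric &&
      !isTRUE(all.equal(unname(table), unname(table[reverse_complement(kmers)])))) {
    stop("scale '", name, "' declared strand_symmetric but table is not")
  }
  structure(list(name = name, order = as.integer(order), table = table,
                 strand_symmetric = strand_symmetric,
                 units = units, citation = citation),
            class = "property_scale")
}

all_kmers <- function(k) {
  g <- expand.grid(rep(list(c("A", "C", "G", "T")), k),
                   stringsAsFactors = FALSE)[, k:1, drop = FALSE]
  sort(do.call(paste0, g))
}

#' @rdname property_scales
#' @export
list_scales <- function() {
  reg <- load_registry()
  tibble::tibble(
    name = names(reg),
    order = vapply(reg, `[[`, 0L, "order"),
    strand_symmetric = vapply(reg, `[[`, TRUE, "strand_symmetric"),
    units = vapply(reg, `[[`, "", "units"),
    citation = vapply(reg, `[[`, "", "citation"))
}

#' @rdname property_scales
#' @export
get_scale <- function(name) {
  reg <- load_registry()
  if (!name %in% names(reg)) {
    stop("unknown property scale '", name, "'; see list_scales()")
  }
  reg[[name]]
}

#' @export
print.property_scale <- function(x, ...) {
  cat(sprintf("<property_scale> %s (order %d, %s)\n  units: %s\n  source: %s\n",
              x$name, x$order,
              if (x$strand_symmetric) "strand-symmetric" else "strand-specific",
              x$units, x$citation))
  invisible(x)
}

#' Profile a sequence with a property scale
#'
#' Slides the scale's k-mer table along the sequence: element `t` of the
#' result is the table value of `substr(seq, t, t + order - 1)`. The profile
#' has length `nchar(seq) - order + 1`.
#'
#' @param seq A single sequence over `A,C,G,T` (no `N`: property values are
#'   undefined on ambiguous bases, callers must pre-screen).
#' @param scale A `property_scale` object (see [get_scale()]).
#' @return Numeric vector of per-step property values.
#' @examples
#' property_profile("AAAA", get_scale("bendability"))
#' @export
property_profile <- function(seq, scale) {
  stopifnot(inherits(scale, "property_scale"), length(seq) == 1)
  if (grepl("[^ACGT]", seq)) stop("sequence contains a non-ACGT character")
  L <- nchar(seq)
  if (L < scale$order) stop("sequence shorter than scale order")
  starts <- seq_len(L - scale$order + 1)
  unname(scale$table[substring(seq, starts, starts + scale$order - 1)])
}

#' Summarise a property profile
#'
#' @param profile Nonempty numeric vector from [property_profile()].
#' @param aggregator One of `"mean"`, `"min"`, `"max"`.
#' @return A single number.
#' @export
aggregate_property <- function(profile, aggregator = c("mean", "min", "max")) {
  aggregator <- match.arg(aggregator)
  if (length(profile) == 0) stop("empty profile")
  switch(aggregator, mean = mean(profile), min = min(profile), max = max(profile))
}
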