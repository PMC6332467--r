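# Top-level haplogroup assignment by best match against a flat marker table.
#
# This is an explicit simplification of phylogeny-walking classifiers
# (Mitomaster/HaploGrep traverse the full Phylotree): the analysis only uses
# top-level labels, so samples are matched against flat per-label marker
# sets. Back-mutations and private variants are ignored; only the presence
# of defining alternate alleles counts.

#' Read a haplogroup marker table
#'
#' TSV with columns \code{haplogroup}, \code{position}, \code{alt}. The
#' packaged table is a simplified synthetic stand-in covering fifteen
#' top-level labels, each separable by unique markers, with the thirteen
#' published high-scoring common variants attached to plausible labels.
#'
#' @param path Path to the TSV.
#' @param genome_length Coordinate upper bound.
#' @return A data frame of markers.
#' @export
read_marker_table <- function(path, genome_length = MT_RCRS_LENGTH) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_marker_table(m, genome_length)
  m
}

validate_marker_table <- function(markers, genome_length = MT_RCRS_LENGTH) {
  need <- c("haplogroup", "position", "alt")
  miss <- setdiff(need, names(markers))
  if (length(miss) > 0L)
    stop("marker table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(markers) == 0L)
    stop("marker table is empty", call. = FALSE)
  if (any(markers$position < 1L | markers$position > genome_length))
    stop("marker positions must lie in [1, ", genome_length, "]",
         call. = FALSE)
  if (anyDuplicated(markers[, c("haplogroup", "position", "alt")]))
    stop("duplicate (haplogroup, position, alt) marker rows", call. = FALSE)
  invisible(markers)
}

#' Assign a haplogroup to one sample
#'
#' Ranks labels by the fraction of their defining markers carried by the
#' sample (fraction, not raw count, so labels with many markers are not
#' favoured). Ties break deterministically by larger matched count, then
#' lexicographic label order. A sample matching no marker of any label is
#' returned as \code{"unclassified"} with fraction 0.
#'
#' @param variants Data frame with columns \code{position} and \code{alt}
#'   (one sample's variants; row order is irrelevant).
#' @param markers Marker table (see \code{\link{read_marker_table}}).
#' @return A list with \code{haplogroup}, \code{matched}, \code{total} and
#'   \code{fraction}.
#' @export
assign_haplogroup <- function(variants, markers) {
  validate_marker_table(markers)
  have <- unique(variant_key(variants$position, variants$alt))
  mkey <- variant_key(markers$position, markers$alt)
  hit <- mkey %in% have
  total <- tapply(rep.int(1L, nrow(markers)), markers$haplogroup, sum)
  matched <- tapply(as.integer(hit), markers$haplogroup, sum)
  labels <- sort(names(total))
  total <- total[labels]
  matched <- matched[labels]
  frac <- matched / total
  if (all(matched == 0L))
    return(list(haplogroup = "unclassified", matched = 0L, total = 0L,
                fraction = 0))
  # order: fraction desc, matched desc, label asc (labels pre-sorted)
  best <- order(-frac, -matched)[1L]
  list(haplogroup = labels[best],
       matched = as.integer(matched[best]),
       total = as.integer(total[best]),
       fraction = unname(frac[best]))
}

#' Assign haplogroups to every sample of a variant table
#'
#' @param variants Variant data frame with a \code{sample} column.
#' @param markers Marker table.
#' @return Data frame with one row per sample: \code{sample},
#'   \code{haplogroup}, \code{matched}, \code{total}, \code{fraction}.
#' @export
assign_haplogroups <- function(variants, markers) {
  samples <- unique(variants$sample)
  by_sample <- split(variants[, c("position", "alt")], variants$sample)
  calls <- lapply(samples, function(s) {
    v <- by_sample[[as.character(s)]]
    if (is.null(v)) v <- data.frame(position = integer(), alt = character())
    assign_haplogroup(v, markers)
  })
  data.frame(sample = samples,
             haplogroup = vapply(calls, `[[`, "", "haplogroup"),
             matched = vapply(calls, `[[`, 0L, "matched"),
             total = vapply(calls, `[[`, 0L, "total"),
             fraction = vapply(calls, `[[`, 0, "fraction"),
             stringsAsFactors = FALSE)
}
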