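# Mitochondrial genome model: rCRS-coordinate sequence, gene features and
# consequence classification under the vertebrate mitochondrial genetic code.

MT_BASES <- c("A", "C", "G", "T")
MT_RCRS_LENGTH <- 16569L

.pkg_env <- new.env(parent = emptyenv())

# Vertebrate mitochondrial genetic code (TGA=Trp, ATA=Met, AGA/AGG=Stop),
# keyed by DNA codon. NCBI translation table 2.
mito_code <- function() {
  if (is.null(.pkg_env$mito_code)) {
    gc2 <- Biostrings::getGeneticCode("2")
    .pkg_env$mito_code <- stats::setNames(as.character(gc2), names(gc2))
  }
  .pkg_env$mito_code
}

comp_base <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A", N = "N")[b]
}

revcomp <- function(s) {
  paste(rev(unname(comp_base(strsplit(s, "", fixed = TRUE)[[1]]))),
        collapse = "")
}

#' Construct a mitochondrial genome object
#'
#' @param name Sequence identifier.
#' @param bases Single string over \code{A,C,G,T,N}; coordinates used
#'   throughout the package are 1-based positions into this string, matching
#'   rCRS "m." notation.
#' @return An object of class \code{mt_genome}.
#' @export
mt_genome <- function(name, bases) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(bases), length(bases) == 1L)
  bases <- toupper(bases)
  bad <- gsub("[ACGTN]", "", bases)
  if (nchar(bad) > 0L)
    stop("genome contains characters outside {A,C,G,T,N}: ",
         substr(bad, 1L, 10L), call. = FALSE)
  structure(list(name = name, bases = bases), class = "mt_genome")
}

is_mt_genome <- function(x) inherits(x, "mt_genome")

#' @export
print.mt_genome <- function(x, ...) {
  cat("mt_genome:", x$name, "(", nchar(x$bases), "bp )\n")
  invisible(x)
}

#' Length of a mitochondrial genome
#' @param x An \code{mt_genome}.
#' @export
length.mt_genome <- function(x) nchar(x$bases)

genome_base <- function(genome, position) {
  substr(genome$bases, position, position)
}

#' Read a single-record FASTA genome
#'
#' Reads one sequence (wrap-agnostic) and returns an \code{mt_genome}.
#'
#' @param path Path to a FASTA file containing exactly one record.
#' @return An \code{mt_genome}.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1L)
    stop("expected a single-record FASTA, found ", length(ss), " records",
         call. = FALSE)
  mt_genome(name = sub("\\s.*$", "", names(ss)[1L]),
            bases = as.character(ss[[1L]]))
}

#' Read a gene feature map
#'
#' The map is a TSV with columns \code{gene}, \code{start}, \code{end},
#' \code{strand} (\code{heavy}/\code{light}) and \code{class}
#' (\code{protein}/\code{tRNA}/\code{rRNA}). Coordinates are 1-based
#' inclusive; the packaged map carries the 13 protein, 22 tRNA and 2 rRNA
#' genes at their rCRS coordinates, with no origin-spanning features.
#'
#' @param path Path to the TSV.
#' @param genome_length Upper bound for coordinates (default rCRS length).
#' @return A data frame of gene features.
#' @export
read_gene_map <- function(path, genome_length = MT_RCRS_LENGTH) {
  gm <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_gene_map(gm, genome_length)
  gm
}

validate_gene_map <- function(gene_map, genome_length = MT_RCRS_LENGTH) {
  need <- c("gene", "start", "end", "strand", "class")
  miss <- setdiff(need, names(gene_map))
  if (length(miss) > 0L)
    stop("gene map is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(gene_map$strand %in% c("heavy", "light")))
    stop("gene map strand must be 'heavy' or 'light'", call. = FALSE)
  if (!all(gene_map$class %in% c("protein", "tRNA", "rRNA", "non-coding")))
    stop("gene map class must be protein/tRNA/rRNA/non-coding", call. = FALSE)
  with(gene_map, {
    if (any(start < 1L | end > genome_length | start > end))
      stop("gene map coordinates must satisfy 1 <= start <= end <= ",
           genome_length, call. = FALSE)
  })
  len <- gene_map$end - gene_map$start + 1L
  if (any(gene_map$class == "protein" & len < 3L))
    stop("protein features must span at least one codon", call. = FALSE)
  invisible(gene_map)
}

#' Features overlapping a position
#'
#' Returns every feature whose \code{[start, end]} interval contains the
#' position. Mitochondrial genes overlap (ATP8/ATP6, ND4L/ND4), so more than
#' one feature can be returned; control-region positions return zero rows.
#'
#' @param position 1-based rCRS coordinate.
#' @param gene_map Gene feature data frame (see \code{\link{read_gene_map}}).
#' @param genome_length Coordinate upper bound used for validation.
#' @return The subset of \code{gene_map} rows containing \code{position}.
#' @export
locate_features <- function(position, gene_map,
                            genome_length = MT_RCRS_LENGTH) {
  if (length(position) != 1L || is.na(position) ||
      position < 1L || position > genome_length)
    stop("position must be a single coordinate in [1, ", genome_length, "]",
         call. = FALSE)
  gene_map[gene_map$start <= position & gene_map$end >= position, ,
           drop = FALSE]
}

#' Export a gene map as BED-like intervals
#'
#' Conversion to 0-based half-open coordinates happens on export only; all
#' package interfaces are 1-based inclusive.
#'
#' @param gene_map Gene feature data frame.
#' @param chrom Chromosome name to use in the first column.
#' @return A data frame with columns chrom, chromStart, chromEnd, name,
#'   score, strand (\code{+} for heavy, \code{-} for light).
#' @export
gene_map_as_bed <- function(gene_map, chrom = "chrM") {
  validate_gene_map(gene_map)
  data.frame(chrom = chrom,
             chromStart = gene_map$start - 1L,
             chromEnd = gene_map$end,
             name = gene_map$gene,
             score = 0L,
             strand = ifelse(gene_map$strand == "heavy", "+", "-"),
             stringsAsFactors = FALSE)
}

consequence_row <- function(gene = NA_character_, codon_index = NA_integer_,
                            ref_aa = NA_character_, alt_aa = NA_character_,
                            consequence) {
  data.frame(gene = gene, codon_index = codon_index, ref_aa = ref_aa,
             alt_aa = alt_aa, consequence = consequence,
             stringsAsFactors = FALSE)
}

protein_consequence <- function(position, ref, alt, genome, feat) {
  code <- mito_code()
  if (feat$strand == "heavy") {
    off <- position - feat$start
    ci <- off %/% 3L
    cp <- off %% 3L
    cstart <- feat$start + 3L * ci
    if (cstart + 2L > feat$end)  # incomplete 3' stop codon (polyadenylated)
      return(consequence_row(feat$gene, ci + 1L,
                             consequence = "untranslatable"))
    codon <- substr(genome$bases, cstart, cstart + 2L)
    calt <- alt
  } else {
    # Light-strand genes (MT-ND6) are read as the reverse complement of the
    # heavy strand; coding offset of heavy position p is end - p.
    off <- feat$end - position
    ci <- off %/% 3L
    cp <- off %% 3L
    cfirst <- feat$end - 3L * ci      # heavy coord of codon's first base
    if (cfirst - 2L < feat$start)
      return(consequence_row(feat$gene, ci + 1L,
                             consequence = "untranslatable"))
    codon <- revcomp(substr(genome$bases, cfirst - 2L, cfirst))
    calt <- unname(comp_base(alt))
  }
  if (grepl("N", codon, fixed = TRUE))
    return(consequence_row(feat$gene, ci + 1L,
                           consequence = "untranslatable"))
  alt_codon <- codon
  substr(alt_codon, cp + 1L, cp + 1L) <- calt
  ref_aa <- unname(code[codon])
  alt_aa <- unname(code[alt_codon])
  cons <- if (ref_aa == alt_aa) "synonymous"
          else if (alt_aa == "*") "stop-gain"
          else if (ref_aa == "*") "stop-loss"
          else "non-synonymous"
  consequence_row(feat$gene, ci + 1L, ref_aa, alt_aa, cons)
}

#' Classify a single-nucleotide substitution
#'
#' Reconstructs the containing codon for every overlapping protein feature
#' (reverse-complementing light-strand genes first), translates reference
#' and alternate codons with the vertebrate mitochondrial genetic code and
#' compares them. Non-protein features yield \code{tRNA}/\code{rRNA} calls;
#' a position outside all features yields a single \code{non-coding} call.
#' Codons truncated by an incomplete 3' stop codon, and codons containing
#' \code{N}, are reported as \code{untranslatable}.
#'
#' Only single-base substitutions are accepted; indels and multi-nucleotide
#' variants are rejected.
#'
#' @param position 1-based rCRS coordinate.
#' @param ref Reference base; must match the genome at \code{position}.
#' @param alt Alternate base, different from \code{ref}.
#' @param genome An \code{mt_genome}.
#' @param gene_map Gene feature data frame.
#' @return A data frame with one row per call and columns \code{gene},
#'   \code{codon_index}, \code{ref_aa}, \code{alt_aa}, \code{consequence}.
#' @examples
#' gm <- read_gene_map(mitoload_fixture("gene_map.tsv"))
#' g <- read_genome_fasta(mitoload_fixture("mt_genome_synthetic.fasta"))
#' classify_snv(4216, "T", "C", g, gm)
#' @export
classify_snv <- function(position, ref, alt, genome, gene_map) {
  stopifnot(is_mt_genome(genome))
  n <- nchar(genome$bases)
  if (length(position) != 1L || is.na(position) ||
      position < 1L || position > n)
    stop("position must be a single coordinate in [1, ", n, "]",
         call. = FALSE)
  if (!is.character(ref) || !is.character(alt) ||
      nchar(ref) != 1L || nchar(alt) != 1L)
    stop("only single-nucleotide substitutions are supported; ",
         "indels and MNVs are rejected", call. = FALSE)
  if (!(ref %in% MT_BASES) || !(alt %in% MT_BASES))
    stop("ref and alt must be one of A, C, G, T", call. = FALSE)
  if (ref == alt)
    stop("ref and alt must differ", call. = FALSE)
  gbase <- genome_base(genome, position)
  if (gbase != ref)
    stop(sprintf(
      "reference mismatch at position %d: genome has %s, variant ref is %s",
      as.integer(position), gbase, ref), call. = FALSE)
  feats <- locate_features(position, gene_map, genome_length = n)
  if (nrow(feats) == 0L)
    return(consequence_row(consequence = "non-coding"))
  calls <- lapply(seq_len(nrow(feats)), function(i) {
    f <- feats[i, ]
    if (f$class == "tRNA")
      consequence_row(f$gene, consequence = "tRNA")
    else if (f$class == "rRNA")
      consequence_row(f$gene, consequence = "rRNA")
    else if (f$class == "protein")
      protein_consequence(position, ref, alt, genome, f)
    else
      consequence_row(f$gene, consequence = "non-coding")
  })
  do.call(rbind, calls)
}

#' Path to a packaged fixture file
#'
#' @param name File name under the package's \code{extdata} directory.
#' @return Absolute path to the file.
#' @export
mitoload_fixture <- function(name) {
  p <- system.file("extdata", name, package = "mitoload", mustWork = FALSE)
  if (identical(p, ""))
    stop("no packaged fixture named ", name, call. = FALSE)
  p
}
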