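# Variant input (TSV and minimal VCF), consequence annotation and
# score/frequency attachment.

variant_key <- function(position, alt) paste(position, alt, sep = ":")

#' Validate a variant table
#'
#' A variant table is a data frame with columns \code{sample},
#' \code{position}, \code{ref}, \code{alt} and \code{fraction} (alternate
#' allele fraction, 1.0 when unstated); an optional \code{cohort} column
#' carries the case/control label.
#'
#' @param variants Data frame to validate.
#' @param genome_length Coordinate upper bound.
#' @return The validated (and type-normalised) data frame, invisibly usable.
#' @export
validate_variants <- function(variants, genome_length = MT_RCRS_LENGTH) {
  need <- c("sample", "position", "ref", "alt")
  miss <- setdiff(need, names(variants))
  if (length(miss) > 0L)
    stop("variant table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(variants$fraction))
    variants$fraction <- 1.0
  variants$position <- as.integer(variants$position)
  if (any(is.na(variants$position)) ||
      any(variants$position < 1L | variants$position > genome_length))
    stop("variant positions must be integers in [1, ", genome_length, "]",
         call. = FALSE)
  if (any(nchar(variants$ref) != 1L | nchar(variants$alt) != 1L))
    stop("only single-nucleotide substitutions are supported; ",
         "indels and MNVs are rejected", call. = FALSE)
  if (!all(variants$ref %in% MT_BASES) || !all(variants$alt %in% MT_BASES))
    stop("ref and alt must be one of A, C, G, T", call. = FALSE)
  if (any(variants$ref == variants$alt))
    stop("ref and alt must differ", call. = FALSE)
  if (any(variants$fraction < 0 | variants$fraction > 1))
    stop("allele fractions must lie in [0, 1]", call. = FALSE)
  variants
}

#' Read a variant table from TSV
#'
#' Expected columns: \code{sample}, \code{position}, \code{ref}, \code{alt},
#' optional \code{fraction} and \code{cohort}.
#'
#' @param path Path to the TSV file.
#' @return A validated variant data frame.
#' @export
read_variants <- function(path) {
  v <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_variants(v)
}

#' Write a variant table to TSV
#' @param variants Variant data frame.
#' @param path Output path.
#' @export
write_variants <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read variants from a minimal VCF
#'
#' Reads POS/REF/ALT and, when present, the AF INFO field of a
#' single-sample VCF; CHROM is ignored. Multi-allelic records are split.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF file.
#' @param sample Sample identifier to assign; defaults to the VCF sample
#'   column name when present, else the file name.
#' @return A validated variant data frame.
#' @export
read_variants_vcf <- function(path, sample = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  af <- suppressWarnings(as.numeric(vcfR::extract.info(v, "AF")))
  if (is.null(sample)) {
    sn <- colnames(v@gt)
    sample <- if (!is.null(sn) && length(sn) > 1L) sn[2L]
              else sub("\\.vcf(\\.gz)?$", "", basename(path))
  }
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  nalt <- lengths(alts)
  out <- data.frame(sample = sample,
                    position = rep(as.integer(fix$POS), nalt),
                    ref = rep(fix$REF, nalt),
                    alt = unlist(alts),
                    fraction = rep(ifelse(is.na(af), 1.0, af), nalt),
                    stringsAsFactors = FALSE)
  validate_variants(out)
}

summarise_calls <- function(calls) {
  # Variant-level summary across overlapping features: protein consequences
  # take precedence, in severity order; nonsyn means at least one protein
  # feature sees an amino-acid substitution.
  prio <- c("non-synonymous", "stop-gain", "stop-loss", "synonymous",
            "untranslatable", "tRNA", "rRNA", "non-coding")
  cons <- prio[min(match(calls$consequence, prio))]
  list(genes = paste(stats::na.omit(unique(calls$gene)), collapse = ";"),
       consequence = cons,
       nonsyn = any(calls$consequence == "non-synonymous"))
}

#' Annotate a variant table with consequence calls
#'
#' Classifies every distinct substitution once (see
#' \code{\link{classify_snv}}) and joins the variant-level summary back onto
#' the table. For substitutions inside overlapping genes the most severe
#' protein consequence is reported and the variant still counts once
#' downstream (scores are keyed by position and alternate allele, not by
#' gene).
#'
#' @param variants Variant data frame.
#' @param genome An \code{mt_genome}.
#' @param gene_map Gene feature data frame.
#' @return The variant table with added columns \code{genes},
#'   \code{consequence}, \code{nonsyn}.
#' @export
annotate_variants <- function(variants, genome, gene_map) {
  variants <- validate_variants(variants,
                                genome_length = nchar(genome$bases))
  key <- paste(variants$position, variants$ref, variants$alt)
  uk <- !duplicated(key)
  # memoise per-substitution calls for the packaged reference, where the
  # same substitutions recur across simulated cohorts
  cache <- NULL
  if (!is.null(.pkg_env$packaged) &&
      identical(genome, .pkg_env$packaged$genome) &&
      identical(gene_map, .pkg_env$packaged$gene_map)) {
    if (is.null(.pkg_env$class_cache))
      .pkg_env$class_cache <- new.env(parent = emptyenv())
    cache <- .pkg_env$class_cache
  }
  ucalls <- lapply(which(uk), function(i) {
    k <- key[i]
    if (!is.null(cache) && !is.null(cache[[k]])) return(cache[[k]])
    res <- summarise_calls(classify_snv(variants$position[i],
                                        variants$ref[i],
                                        variants$alt[i], genome, gene_map))
    if (!is.null(cache)) cache[[k]] <- res
    res
  })
  idx <- match(key, key[uk])
  variants$genes <- vapply(ucalls, `[[`, "", "genes")[idx]
  variants$consequence <- vapply(ucalls, `[[`, "", "consequence")[idx]
  variants$nonsyn <- vapply(ucalls, `[[`, TRUE, "nonsyn")[idx]
  variants
}

#' Read a pathogenicity score table
#'
#' TSV with columns \code{position}, \code{ref}, \code{alt}, \code{score};
#' scores are probabilities of a deleterious amino-acid substitution in
#' \code{[0, 1]}, keyed by (position, alt). The packaged fixture carries the
#' published scores of the thirteen high-scoring common haplogroup-associated
#' variants; it stands in for MutPred output, which this package never
#' computes.
#'
#' @param path Path to the TSV.
#' @return A data frame.
#' @export
read_score_table <- function(path) {
  s <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_score_table(s)
}

validate_score_table <- function(scores) {
  need <- c("position", "alt", "score")
  miss <- setdiff(need, names(scores))
  if (length(miss) > 0L)
    stop("score table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(scores$score < 0 | scores$score > 1))
    stop("pathogenicity scores must lie in [0, 1]", call. = FALSE)
  if (anyDuplicated(variant_key(scores$position, scores$alt)))
    stop("score table keys (position, alt) must be unique", call. = FALSE)
  scores
}

#' Read a population frequency table
#'
#' TSV with columns \code{position}, \code{ref}, \code{alt},
#' \code{frequency} (proportion of database sequences carrying the
#' alternate allele, in \code{[0, 1]}).
#'
#' @param path Path to the TSV.
#' @return A data frame.
#' @export
read_frequency_table <- function(path) {
  f <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("position", "alt", "frequency")
  miss <- setdiff(need, names(f))
  if (length(miss) > 0L)
    stop("frequency table is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(f$frequency < 0 | f$frequency > 1))
    stop("population frequencies must lie in [0, 1]", call. = FALSE)
  f
}

#' Rarity class from population frequency
#'
#' \code{rare} below 0.1\%, \code{common} above 1\%, \code{intermediate}
#' in between, \code{unknown} when no frequency is available.
#'
#' @param frequency Numeric vector of frequencies (NA allowed).
#' @param rare_cutoff Strict upper bound for rare (default 0.001).
#' @param common_cutoff Strict lower bound for common (default 0.01).
#' @return Character vector of rarity classes.
#' @export
rarity_class <- function(frequency, rare_cutoff = 0.001,
                         common_cutoff = 0.01) {
  ifelse(is.na(frequency), "unknown",
         ifelse(frequency < rare_cutoff, "rare",
                ifelse(frequency > common_cutoff, "common", "intermediate")))
}

#' Attach pathogenicity scores and population frequencies
#'
#' Scores are attached only to non-synonymous variants present in the score
#' table (they describe amino-acid substitutions); frequency and rarity are
#' attached independently of consequence. Variants absent from the tables
#' get \code{NA} score / \code{unknown} rarity.
#'
#' @param variants Annotated variant data frame
#'   (see \code{\link{annotate_variants}}).
#' @param scores Score table.
#' @param freqs Frequency table.
#' @param rare_cutoff,common_cutoff Rarity band bounds.
#' @return The variant table with added columns \code{score},
#'   \code{frequency}, \code{rarity}.
#' @export
attach_scores <- function(variants, scores, freqs,
                          rare_cutoff = 0.001, common_cutoff = 0.01) {
  if (is.null(variants$nonsyn))
    stop("variants must be annotated before scores are attached; ",
         "run annotate_variants() first", call. = FALSE)
  validate_score_table(scores)
  k <- variant_key(variants$position, variants$alt)
  sc <- scores$score[match(k, variant_key(scores$position, scores$alt))]
  variants$score <- ifelse(variants$nonsyn, sc, NA_real_)
  fr <- freqs$frequency[match(k, variant_key(freqs$position, freqs$alt))]
  variants$frequency <- fr
  variants$rarity <- rarity_class(fr, rare_cutoff, common_cutoff)
  variants
}

qualifying_mask <- function(variants, threshold, homoplasmy_cutoff) {
  if (threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]", call. = FALSE)
  !is.na(variants$score) & variants$nonsyn &
    variants$score > threshold & variants$fraction >= homoplasmy_cutoff
}

#' Per-sample variant load
#'
#' Sum of pathogenicity scores over non-synonymous, operationally
#' homoplasmic variants whose score is strictly above the threshold. The
#' strict inequality mirrors the "above 0.5" rule; the allele-fraction
#' cutoff operationalises homoplasmy and defaults to 0.95.
#'
#' @param variants Scored variant data frame for one sample.
#' @param threshold Score threshold (default 0.5).
#' @param homoplasmy_cutoff Minimum allele fraction (default 0.95).
#' @return Non-negative numeric load; 0 when nothing qualifies.
#' @export
variant_load <- function(variants, threshold = 0.5,
                         homoplasmy_cutoff = 0.95) {
  q <- qualifying_mask(variants, threshold, homoplasmy_cutoff)
  sum(variants$score[q])
}

#' Carrier category (0 / 1 / 2+)
#'
#' Bins the count of qualifying variants (same filter as
#' \code{\link{variant_load}}).
#'
#' @inheritParams variant_load
#' @return One of \code{"0"}, \code{"1"}, \code{"2+"}.
#' @export
carrier_category <- function(variants, threshold = 0.5,
                             homoplasmy_cutoff = 0.95) {
  n <- sum(qualifying_mask(variants, threshold, homoplasmy_cutoff))
  if (n == 0L) "0" else if (n == 1L) "1" else "2+"
}

combination_from_counts <- function(n_qual, n_rare, n_common, n_unknown) {
  # intermediate-rarity qualifying variants are grouped with common here;
  # unknown-rarity variants are flagged upstream and classified by the rest
  ifelse(n_qual == 0L, "none",
  ifelse(n_qual == 1L, "single",
  ifelse(n_rare > 0L & n_common > 0L, "common+rare",
  ifelse(n_rare == 0L & n_common > 0L, "common-only",
  ifelse(n_rare > 0L & n_common == 0L, "rare-only", "none")))))
}

#' Combination class of a sample's qualifying variants
#'
#' Among qualifying variants: none; a single variant; two or more, all
#' common; a mixture of common and rare; or all rare. Intermediate-frequency
#' qualifying variants are grouped with common for this classification;
#' qualifying variants of unknown rarity are flagged (attribute
#' \code{rarity_unknown}) and the class is computed from the known ones.
#'
#' @inheritParams variant_load
#' @return One of \code{"none"}, \code{"single"}, \code{"common-only"},
#'   \code{"common+rare"}, \code{"rare-only"}, with attribute
#'   \code{rarity_unknown}.
#' @export
combination_class <- function(variants, threshold = 0.5,
                              homoplasmy_cutoff = 0.95) {
  q <- qualifying_mask(variants, threshold, homoplasmy_cutoff)
  r <- variants$rarity[q]
  cls <- combination_from_counts(sum(q),
                                 sum(r == "rare"),
                                 sum(r %in% c("common", "intermediate")),
                                 sum(r == "unknown"))
  attr(cls, "rarity_unknown") <- any(r == "unknown")
  cls
}

#' Read the known pathogenic variant list
#'
#' TSV with columns \code{position}, \code{ref}, \code{alt}, \code{label}.
#' The packaged list carries m.3243A>G (MELAS/MIDD) and m.1555A>G
#' (aminoglycoside-induced and non-syndromic deafness).
#'
#' @param path Path to the TSV; defaults to the packaged list.
#' @return A data frame.
#' @export
read_pathogenic_table <- function(path = mitoload_fixture("pathogenic_variants.tsv")) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Screen for proven pathogenic variants
#'
#' Flags every sample variant matching the known list regardless of allele
#' fraction: heteroplasmic carriers are reported (the homoplasmy cutoff used
#' for load computation deliberately does not apply here).
#'
#' @param variants Variant data frame (any number of samples).
#' @param known Known pathogenic variants
#'   (see \code{\link{read_pathogenic_table}}).
#' @param heteroplasmy_below Fraction below which a flag is annotated as
#'   heteroplasmic (default 0.95).
#' @return Data frame of flags: sample, position, ref, alt, fraction,
#'   label, heteroplasmic.
#' @export
screen_pathogenic <- function(variants, known = read_pathogenic_table(),
                              heteroplasmy_below = 0.95) {
  variants <- validate_variants(variants)
  k <- variant_key(variants$position, variants$alt)
  hit <- match(k, variant_key(known$position, known$alt))
  f <- variants[!is.na(hit), c("sample", "position", "ref", "alt",
                               "fraction"), drop = FALSE]
  f$label <- known$label[hit[!is.na(hit)]]
  f$heteroplasmic <- f$fraction < heteroplasmy_below
  rownames(f) <- NULL
  f
}
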