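# Per-sample profiles: annotation, scoring, haplogroup call, variant load,
# carrier category and combination class, computed cohort-wide.

#' Profile every sample of a cohort
#'
#' Runs the full per-sample pipeline: consequence annotation, score and
#' frequency attachment, haplogroup call, variant load, carrier category
#' and combination class. Accepts either a variant data frame (with
#' \code{cohort} column) plus explicit reference inputs, or an
#' \code{mt_cohorts} object from \code{\link{generate_cohorts}} (whose own
#' score/frequency tables are then used).
#'
#' @param variants Variant data frame or \code{mt_cohorts}.
#' @param genome,gene_map,scores,freqs,markers Reference inputs; packaged
#'   fixtures by default. \code{markers = NULL} skips haplogroup calls.
#' @param score_threshold Qualifying-score threshold (default 0.5).
#' @param homoplasmy_cutoff Minimum allele fraction (default 0.95).
#' @param haplogroups Set \code{FALSE} to skip haplogroup assignment.
#' @return Object of class \code{mt_profiles}: \code{samples} (one row per
#'   sample) and \code{variants} (the annotated, scored variant table).
#' @export
profile_cohorts <- function(variants, genome = NULL, gene_map = NULL,
                            scores = NULL, freqs = NULL, markers = NULL,
                            score_threshold = 0.5, homoplasmy_cutoff = 0.95,
                            haplogroups = TRUE) {
  if (inherits(variants, "mt_cohorts")) {
    if (is.null(scores)) scores <- variants$scores
    if (is.null(freqs)) freqs <- variants$freqs
    variants <- variants$variants
  }
  pk <- NULL
  if (is.null(genome) || is.null(gene_map) || is.null(scores) ||
      is.null(freqs) || (haplogroups && is.null(markers)))
    pk <- packaged_inputs()
  if (is.null(genome)) genome <- pk$genome
  if (is.null(gene_map)) gene_map <- pk$gene_map
  if (is.null(scores)) scores <- pk$scores
  if (is.null(freqs)) freqs <- pk$freqs
  if (haplogroups && is.null(markers)) markers <- pk$markers

  ann <- annotate_variants(variants, genome, gene_map)
  ann <- attach_scores(ann, scores, freqs)

  sample_ids <- unique(ann$sample)
  sf <- factor(ann$sample, levels = sample_ids)
  q <- qualifying_mask(ann, score_threshold, homoplasmy_cutoff)
  # rowsum over integer codes keeps rows in factor-level (= sample) order
  agg <- function(x) as.vector(rowsum(x, as.integer(sf), na.rm = TRUE))
  load <- agg(ifelse(q, ann$score, 0))
  nq <- agg(as.integer(q))
  n_rare <- agg(as.integer(q & ann$rarity == "rare"))
  n_common <- agg(as.integer(q & ann$rarity %in% c("common", "intermediate")))
  n_unknown <- agg(as.integer(q & ann$rarity == "unknown"))
  out <- data.frame(
    sample = sample_ids,
    n_variants = as.vector(table(sf)),
    variant_load = load,
    n_qualifying = nq,
    carrier_category = ifelse(nq == 0L, "0", ifelse(nq == 1L, "1", "2+")),
    combination_class = combination_from_counts(nq, n_rare, n_common,
                                                n_unknown),
    rarity_unknown = n_unknown > 0L,
    stringsAsFactors = FALSE)
  if (!is.null(ann$cohort))
    out$cohort <- ann$cohort[match(sample_ids, ann$sample)]
  if (haplogroups && !is.null(markers)) {
    hap <- assign_haplogroups(ann, markers)
    out$haplogroup <- hap$haplogroup[match(out$sample, hap$sample)]
    out$hap_fraction <- hap$fraction[match(out$sample, hap$sample)]
  }
  structure(list(samples = out, variants = ann,
                 score_threshold = score_threshold,
                 homoplasmy_cutoff = homoplasmy_cutoff),
            class = "mt_profiles")
}

#' @export
print.mt_profiles <- function(x, ...) {
  cat("mt_profiles:", nrow(x$samples), "samples,",
      nrow(x$variants), "variant records\n")
  cat("  mean variant load:",
      format(mean(x$samples$variant_load), digits = 3), "\n")
  invisible(x)
}
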