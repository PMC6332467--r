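# Synthetic case-control cohort generator: haplogroup-structured common
# variants, Poisson rare private variants, and an injectable case effect.

# Haplogroup composition of the packaged control cohort (counts over the
# fifteen top-level labels); the default generator frequency vector.
CONTROL_HAP_COUNTS <- c(C = 1, D = 2, G = 0, H = 43, HV = 2, I = 1, J = 7,
                        K = 6, N = 0, R = 2, T = 8, U = 30, V = 8, W = 3,
                        X = 2)

sub_seed <- function(seed, i) {
  as.integer(((as.numeric(seed) %% 2147483563) * 48271 + i * 30269) %%
               2147483563)
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study conditions the analysis assumes: three case
#' cohorts of 100 and one control cohort of 115; haplogroups drawn from the
#' control-cohort frequency vector over the fifteen top-level labels;
#' haplogroup-associated common variants (the packaged scored fixture)
#' inherited through the marker table; rare private non-synonymous variants
#' per individual Poisson with mean 0.5, scores Beta(2, 2) rescaled to
#' [0.3, 0.9] and population frequencies below 0.1\%; and a case effect
#' probability of 0 (null).
#'
#' @param sizes Named integer vector of cohort sizes.
#' @param control Name of the control cohort within \code{sizes}.
#' @param hap_freq Named haplogroup frequency vector summing to 1; default
#'   the packaged control-cohort proportions.
#' @param lambda Mean number of rare private variants per individual.
#' @param rare_score Function drawing n rare-variant scores in [0, 1].
#' @param rare_freq_max Strict upper bound for rare-variant population
#'   frequencies (default 0.001).
#' @param effect_pi Probability that a treated case sample gains one extra
#'   qualifying rare variant (0 = null).
#' @param effect_score Score of injected variants (a number > 0.5, or a
#'   function drawing n such scores).
#' @param effect_cohorts Cohorts receiving the effect; default all
#'   non-control cohorts.
#' @param seed Master seed; all draws derive from it.
#' @return Object of class \code{mt_sim_config}.
#' @export
synthetic_config <- function(sizes = c(t2dm = 100L, obesity = 100L,
                                       atherosclerosis = 100L,
                                       control = 115L),
                             control = "control",
                             hap_freq = NULL,
                             lambda = 0.5,
                             rare_score = function(n)
                               0.3 + 0.6 * stats::rbeta(n, 2, 2),
                             rare_freq_max = 0.001,
                             effect_pi = 0,
                             effect_score = 0.6,
                             effect_cohorts = NULL,
                             seed = 1L) {
  if (is.null(names(sizes)) || !(control %in% names(sizes)))
    stop("sizes must be named and include the control cohort", call. = FALSE)
  if (is.null(hap_freq))
    hap_freq <- CONTROL_HAP_COUNTS / sum(CONTROL_HAP_COUNTS)
  if (abs(sum(hap_freq) - 1) > 1e-9)
    stop("haplogroup frequencies must sum to 1", call. = FALSE)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  if (effect_pi < 0 || effect_pi > 1)
    stop("effect_pi must lie in [0, 1]", call. = FALSE)
  if (is.null(effect_cohorts))
    effect_cohorts <- setdiff(names(sizes), control)
  structure(list(sizes = sizes, control = control, hap_freq = hap_freq,
                 lambda = lambda, rare_score = rare_score,
                 rare_freq_max = rare_freq_max, effect_pi = effect_pi,
                 effect_score = effect_score,
                 effect_cohorts = effect_cohorts, seed = seed),
            class = "mt_sim_config")
}

packaged_inputs <- function() {
  if (is.null(.pkg_env$packaged)) {
    .pkg_env$packaged <- list(
      genome = read_genome_fasta(mitoload_fixture("mt_genome_synthetic.fasta")),
      gene_map = read_gene_map(mitoload_fixture("gene_map.tsv")),
      markers = read_marker_table(mitoload_fixture("haplogroup_markers_synthetic.tsv")),
      scores = read_score_table(mitoload_fixture("mutpred_scores.tsv")),
      freqs = read_frequency_table(mitoload_fixture("genbank_frequencies.tsv")),
      pathogenic = read_pathogenic_table())
  }
  .pkg_env$packaged
}

#' Enumerate non-synonymous single-nucleotide substitutions
#'
#' Builds the pool of all protein-coding SNVs whose consequence is a pure
#' amino-acid substitution (stop gains/losses and synonymous changes
#' excluded), with light-strand genes handled through their reverse
#' complement. The generator draws rare private variants from this pool.
#'
#' @param genome An \code{mt_genome}.
#' @param gene_map Gene feature data frame.
#' @param exclude_positions Positions to leave out (e.g. fixture variants).
#' @return Data frame with columns \code{position}, \code{ref}, \code{alt},
#'   \code{gene}, unique by (position, ref, alt).
#' @export
nonsyn_pool <- function(genome, gene_map, exclude_positions = integer()) {
  code <- mito_code()
  prot <- gene_map[gene_map$class == "protein", , drop = FALSE]
  out <- vector("list", 0L)
  for (i in seq_len(nrow(prot))) {
    f <- prot[i, ]
    s <- substr(genome$bases, f$start, f$end)
    if (f$strand == "light") s <- revcomp(s)
    ncod <- nchar(s) %/% 3L
    if (ncod == 0L) next
    chars <- strsplit(substr(s, 1L, 3L * ncod), "", fixed = TRUE)[[1L]]
    dim(chars) <- c(3L, ncod)
    codons <- paste0(chars[1L, ], chars[2L, ], chars[3L, ])
    ref_aa <- unname(code[codons])
    for (cp in 1:3) {
      refb <- chars[cp, ]
      for (alt in MT_BASES) {
        altcodons <- codons
        substr(altcodons, cp, cp) <- alt
        alt_aa <- unname(code[altcodons])
        ns <- refb != alt & refb != "N" & !is.na(ref_aa) & !is.na(alt_aa) &
          ref_aa != "*" & alt_aa != "*" & ref_aa != alt_aa
        idx <- which(ns)
        if (length(idx) == 0L) next
        coff <- (idx - 1L) * 3L + (cp - 1L)   # 0-based coding offset
        if (f$strand == "heavy") {
          pos <- f$start + coff
          rh <- refb[idx]; ah <- alt
        } else {
          pos <- f$end - coff
          rh <- unname(comp_base(refb[idx])); ah <- unname(comp_base(alt))
        }
        out[[length(out) + 1L]] <-
          data.frame(position = pos, ref = rh, alt = ah, gene = f$gene,
                     stringsAsFactors = FALSE)
      }
    }
  }
  pool <- do.call(rbind, out)
  pool <- pool[!duplicated(paste(pool$position, pool$ref, pool$alt)), ,
               drop = FALSE]
  pool <- pool[!(pool$position %in% exclude_positions), , drop = FALSE]
  rownames(pool) <- NULL
  pool[order(pool$position, pool$alt), ]
}

default_pool <- function(genome, gene_map, markers, scores, pathogenic) {
  excl <- unique(c(markers$position, scores$position, pathogenic$position))
  nonsyn_pool(genome, gene_map, exclude_positions = excl)
}

#' Generate synthetic case-control cohorts
#'
#' Each sample draws a haplogroup from the configured frequency vector and
#' inherits every marker variant of that label (including its scored common
#' variants), then gains Poisson-distributed rare private non-synonymous
#' variants at positions drawn from the non-synonymous pool (unused fixture
#' positions are excluded; every rare variant is private to one sample).
#' Case cohorts additionally receive the configured effect (see
#' \code{\link{inject_effect}}). All draws derive from the master seed via
#' fixed substreams, so a cohort's content does not depend on the order in
#' which other cohorts are generated.
#'
#' @param config An \code{mt_sim_config}.
#' @param genome,gene_map,markers,scores,freqs Inputs; default the packaged
#'   fixtures.
#' @param pool Optional precomputed non-synonymous pool
#'   (see \code{\link{nonsyn_pool}}).
#' @return Object of class \code{mt_cohorts}: \code{variants} (variant
#'   table with cohort labels), \code{scores} and \code{freqs} (fixture
#'   tables extended with the generated rare variants), \code{truth}
#'   (per-sample generating haplogroup) and the config.
#' @export
generate_cohorts <- function(config, genome = NULL, gene_map = NULL,
                             markers = NULL, scores = NULL, freqs = NULL,
                             pool = NULL) {
  stopifnot(inherits(config, "mt_sim_config"))
  use_default <- is.null(genome) && is.null(gene_map) && is.null(markers) &&
    is.null(scores) && is.null(freqs)
  if (use_default) {
    pk <- packaged_inputs()
    genome <- pk$genome; gene_map <- pk$gene_map; markers <- pk$markers
    scores <- pk$scores; freqs <- pk$freqs
    if (is.null(pool)) {
      if (is.null(.pkg_env$default_pool))
        .pkg_env$default_pool <- default_pool(genome, gene_map, markers,
                                              scores, pk$pathogenic)
      pool <- .pkg_env$default_pool
    }
  } else if (is.null(pool)) {
    pool <- nonsyn_pool(genome, gene_map,
                        exclude_positions = unique(c(markers$position,
                                                     scores$position)))
  }
  labels <- names(config$hap_freq)
  if (!all(labels %in% markers$haplogroup) &&
      any(config$hap_freq[!(labels %in% markers$haplogroup)] > 0))
    stop("haplogroup frequency vector names labels absent from the marker ",
         "table", call. = FALSE)
  mref <- substring(genome$bases, markers$position, markers$position)
  mk_idx <- split(seq_len(nrow(markers)), markers$haplogroup)

  cohorts <- names(config$sizes)
  all_samples <- character(0); all_cohort <- character(0)
  hap <- character(0)
  for (i in seq_along(cohorts)) {
    n <- config$sizes[[i]]
    ids <- sprintf("%s_%03d", cohorts[i], seq_len(n))
    h <- with_local_seed(sub_seed(config$seed, i),
                         sample(labels, n, replace = TRUE,
                                prob = config$hap_freq))
    all_samples <- c(all_samples, ids)
    all_cohort <- c(all_cohort, rep(cohorts[i], n))
    hap <- c(hap, h)
  }
  # marker (haplogroup) variants
  midx <- mk_idx[hap]
  nmk <- vapply(midx, length, 0L)
  mv <- data.frame(sample = rep(all_samples, nmk),
                   cohort = rep(all_cohort, nmk),
                   position = markers$position[unlist(midx)],
                   ref = mref[unlist(midx)],
                   alt = markers$alt[unlist(midx)],
                   fraction = rep(1.0, sum(nmk)),
                   stringsAsFactors = FALSE)
  # rare private variants, globally unique positions
  rv <- with_local_seed(sub_seed(config$seed, 101L), {
    counts <- stats::rpois(length(all_samples), config$lambda)
    M <- sum(counts)
    if (M > nrow(pool))
      stop("requested rare variants exceed available genome positions",
           call. = FALSE)
    take <- sample.int(nrow(pool), M, replace = FALSE)
    list(variants = data.frame(sample = rep(all_samples, counts),
                               cohort = rep(all_cohort, counts),
                               position = pool$position[take],
                               ref = pool$ref[take],
                               alt = pool$alt[take],
                               fraction = rep(1.0, M),
                               stringsAsFactors = FALSE),
         scores = data.frame(position = pool$position[take],
                             ref = pool$ref[take],
                             alt = pool$alt[take],
                             score = config$rare_score(M),
                             stringsAsFactors = FALSE),
         freqs = data.frame(position = pool$position[take],
                            ref = pool$ref[take],
                            alt = pool$alt[take],
                            frequency = stats::runif(M, 0,
                                                     config$rare_freq_max),
                            stringsAsFactors = FALSE),
         used = take)
  })
  obj <- structure(list(
    variants = rbind(mv, rv$variants),
    scores = rbind(scores[, c("position", "ref", "alt", "score")],
                   rv$scores),
    freqs = rbind(freqs[, c("position", "ref", "alt", "frequency")],
                  rv$freqs),
    truth = data.frame(sample = all_samples, cohort = all_cohort,
                       haplogroup = hap, stringsAsFactors = FALSE),
    pool = pool,
    pool_used = rv$used,
    config = config), class = "mt_cohorts")
  if (config$effect_pi > 0)
    obj <- inject_effect(obj, pi = config$effect_pi,
                         score = config$effect_score,
                         seed = sub_seed(config$seed, 202L),
                         cohorts = config$effect_cohorts)
  obj
}

#' @export
print.mt_cohorts <- function(x, ...) {
  cat("Synthetic cohorts:",
      paste(sprintf("%s (n=%d)", names(x$config$sizes), x$config$sizes),
            collapse = ", "), "\n")
  cat(" ", nrow(x$variants), "variant records,",
      nrow(x$scores), "scored substitutions\n")
  invisible(x)
}

#' Inject a case-effect variant into samples
#'
#' Each treated sample independently gains, with probability \code{pi}, one
#' extra non-synonymous rare variant with score above 0.5, so the expected
#' load increase per treated sample is \code{pi} times the mean injected
#' score.
#'
#' @param samples An \code{mt_cohorts} object.
#' @param pi Per-sample injection probability in [0, 1].
#' @param score A number > 0.5, or a function drawing n scores > 0.5.
#' @param seed Seed for the injection draws.
#' @param cohorts Cohort labels to treat; default all cohorts present.
#' @return The modified \code{mt_cohorts}.
#' @export
inject_effect <- function(samples, pi, score = 0.6, seed = 1L,
                          cohorts = NULL) {
  stopifnot(inherits(samples, "mt_cohorts"))
  if (pi < 0 || pi > 1) stop("pi must lie in [0, 1]", call. = FALSE)
  if (pi == 0) return(samples)
  tr <- samples$truth
  if (!is.null(cohorts)) tr <- tr[tr$cohort %in% cohorts, , drop = FALSE]
  res <- with_local_seed(seed, {
    gains <- stats::runif(nrow(tr)) < pi
    M <- sum(gains)
    if (M == 0L) NULL else {
      avail <- setdiff(seq_len(nrow(samples$pool)), samples$pool_used)
      if (M > length(avail))
        stop("requested effect variants exceed available genome positions",
             call. = FALSE)
      take <- avail[sample.int(length(avail), M, replace = FALSE)]
      sc <- if (is.function(score)) score(M) else rep(score, M)
      if (any(sc <= 0.5))
        stop("injected scores must be above 0.5 (qualifying variants)",
             call. = FALSE)
      list(gains = gains, take = take, sc = sc,
           fr = stats::runif(M, 0, samples$config$rare_freq_max))
    }
  })
  if (is.null(res)) return(samples)
  pool <- samples$pool
  take <- res$take
  nv <- data.frame(sample = tr$sample[res$gains],
                   cohort = tr$cohort[res$gains],
                   position = pool$position[take], ref = pool$ref[take],
                   alt = pool$alt[take], fraction = 1.0,
                   stringsAsFactors = FALSE)
  samples$variants <- rbind(samples$variants, nv)
  samples$scores <- rbind(samples$scores,
                          data.frame(position = pool$position[take],
                                     ref = pool$ref[take],
                                     alt = pool$alt[take], score = res$sc,
                                     stringsAsFactors = FALSE))
  samples$freqs <- rbind(samples$freqs,
                         data.frame(position = pool$position[take],
                                    ref = pool$ref[take],
                                    alt = pool$alt[take],
                                    frequency = res$fr,
                                    stringsAsFactors = FALSE))
  samples$pool_used <- c(samples$pool_used, take)
  samples
}
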