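# End-to-end association analysis: haplogroup distribution, unique-variant
# rarity tables, carrier tables, variant loads with ANOVA + Dunnett, the
# combination-class summary and the proven-pathogenic screen.

#' Cross-tabulate unique variants by rarity
#'
#' A variant is unique when, considering all cohorts, it occurs in exactly
#' one of them. For each disease-control pair, unique non-synonymous
#' operationally homoplasmic variants of the two compared cohorts are
#' cross-tabulated rare (frequency below 0.1\%) versus common (above 1\%);
#' intermediate-band and unknown-frequency variants are dropped from the
#' table. Counts are counts of distinct substitutions, not of carriers.
#'
#' @param profiles An \code{mt_profiles} with cohort labels.
#' @param control Control cohort label.
#' @param homoplasmy_cutoff Minimum allele fraction.
#' @return Named list of 2x2 matrices (rows rare/common, columns
#'   disease/control), one per disease cohort.
#' @export
build_unique_variant_tables <- function(profiles, control = "control",
                                        homoplasmy_cutoff = 0.95) {
  v <- profiles$variants
  if (is.null(v$cohort))
    stop("profiles carry no cohort labels", call. = FALSE)
  v <- v[v$nonsyn & v$fraction >= homoplasmy_cutoff, , drop = FALSE]
  key <- paste(v$position, v$ref, v$alt)
  pres <- table(key, v$cohort) > 0
  uniq <- rownames(pres)[rowSums(pres) == 1L]
  v <- v[!duplicated(key), , drop = FALSE]
  v <- v[paste(v$position, v$ref, v$alt) %in% uniq, , drop = FALSE]
  ukey <- paste(v$position, v$ref, v$alt)
  ucohort <- colnames(pres)[apply(pres[ukey, , drop = FALSE], 1L,
                                  which.max)]
  diseases <- setdiff(unique(profiles$samples$cohort), control)
  out <- lapply(diseases, function(d) {
    tab <- matrix(0L, 2L, 2L,
                  dimnames = list(c("rare", "common"), c(d, control)))
    for (grp in c(d, control)) {
      sel <- ucohort == grp
      tab["rare", grp] <- sum(sel & v$rarity == "rare")
      tab["common", grp] <- sum(sel & v$rarity == "common")
    }
    tab
  })
  names(out) <- diseases
  out
}

count_table <- function(values, cohorts, levels, cols) {
  f <- table(factor(values, levels = levels),
             factor(cohorts, levels = cols))
  contingency_table(unclass(f), row_labels = levels, col_labels = cols)
}

#' Run the full case-control association analysis
#'
#' Profiles every sample, then runs the statistical battery against the
#' shared control cohort: the r x c haplogroup-distribution exact test with
#' adjusted-standardized-residual post-hoc (Bonferroni-corrected over the
#' haplogroup rows), unique-variant rare/common 2x2 exact tests, carrier
#' 2x2 tests at the main and high score thresholds, the 0/1/2+ carrier-count
#' exact test, one-way ANOVA on variant loads with Dunnett many-to-one
#' comparisons, the combination-class summary, and the proven-pathogenic
#' screen. Deterministic given the seed.
#'
#' @param variants Variant data frame with \code{cohort} column, an
#'   \code{mt_cohorts} object, or a path to a variant TSV.
#' @param genome,gene_map,scores,freqs,markers Reference inputs; packaged
#'   fixtures by default.
#' @param control Control cohort label.
#' @param score_threshold Main qualifying-score threshold (default 0.5).
#' @param high_threshold Secondary, stricter threshold (default 0.7).
#' @param homoplasmy_cutoff Minimum allele fraction (default 0.95).
#' @param mc_replicates Monte Carlo replicates for exact tests and Dunnett.
#' @param seed Seed for all randomized procedures.
#' @param pathogenic Known pathogenic variant list.
#' @return Object of class \code{mt_report}.
#' @export
run_analysis <- function(variants, genome = NULL, gene_map = NULL,
                         scores = NULL, freqs = NULL, markers = NULL,
                         control = "control", score_threshold = 0.5,
                         high_threshold = 0.7, homoplasmy_cutoff = 0.95,
                         mc_replicates = 1e5, seed = 1L,
                         pathogenic = NULL) {
  if (is.character(variants) && length(variants) == 1L)
    variants <- read_variants(variants)
  prof <- profile_cohorts(variants, genome = genome, gene_map = gene_map,
                          scores = scores, freqs = freqs, markers = markers,
                          score_threshold = score_threshold,
                          homoplasmy_cutoff = homoplasmy_cutoff)
  s <- prof$samples
  if (is.null(s$cohort))
    stop("variant input carries no cohort labels", call. = FALSE)
  cohorts <- unique(s$cohort)
  if (!(control %in% cohorts))
    stop("control cohort '", control, "' not present", call. = FALSE)
  diseases <- setdiff(cohorts, control)
  if (is.null(pathogenic)) pathogenic <- packaged_inputs()$pathogenic

  # haplogroup distribution -------------------------------------------------
  hap_levels <- sort(unique(s$haplogroup))
  hap_table <- count_table(s$haplogroup, s$cohort, hap_levels,
                           c(diseases, control))
  hap_tests <- lapply(seq_along(diseases), function(i) {
    d <- diseases[i]
    tab <- hap_table[, c(d, control), drop = FALSE]
    tab <- tab[rowSums(tab) > 0L, , drop = FALSE]
    fh <- freeman_halton_exact(tab, mc_replicates = mc_replicates,
                               seed = sub_seed(seed, 300L + i))
    res <- adjusted_residuals(tab)
    list(cohort = d, table = tab, exact = fh, residuals = res,
         p.bonferroni = bonferroni_adjust(res$p.value[, d],
                                          m = nrow(tab)))
  })
  names(hap_tests) <- diseases

  # unique-variant rare/common tables ---------------------------------------
  uv_tables <- build_unique_variant_tables(prof, control = control,
                                           homoplasmy_cutoff =
                                             homoplasmy_cutoff)
  uv_tests <- lapply(uv_tables, fisher_exact_2x2)

  # carrier tables -----------------------------------------------------------
  sf <- factor(prof$variants$sample, levels = s$sample)
  thresholds <- c(score_threshold, high_threshold)
  carrier_tests <- lapply(stats::setNames(thresholds, format(thresholds)),
                          function(thr) {
    q <- qualifying_mask(prof$variants, thr, homoplasmy_cutoff)
    nq <- as.vector(rowsum(as.integer(q), as.integer(sf)))
    lapply(stats::setNames(diseases, diseases), function(d) {
      sel <- s$cohort %in% c(d, control)
      tab <- count_table(ifelse(nq[sel] > 0L, "carrier", "non-carrier"),
                         s$cohort[sel], c("carrier", "non-carrier"),
                         c(d, control))
      list(table = tab, test = fisher_exact_2x2(tab))
    })
  })

  count_tests <- lapply(stats::setNames(diseases, diseases), function(d) {
    sel <- s$cohort %in% c(d, control)
    tab <- count_table(s$carrier_category[sel], s$cohort[sel],
                       c("0", "1", "2+"), c(d, control))
    list(table = tab,
         test = freeman_halton_exact(tab, mc_replicates = mc_replicates,
                                     seed = sub_seed(seed, 400L +
                                                       match(d, diseases))))
  })

  # variant loads -------------------------------------------------------------
  load_groups <- split(s$variant_load, s$cohort)[c(diseases, control)]
  load_summary <- data.frame(
    cohort = names(load_groups),
    n = vapply(load_groups, length, 0L),
    mean = vapply(load_groups, mean, 0),
    sd = vapply(load_groups, stats::sd, 0),
    stringsAsFactors = FALSE)
  anova <- anova_oneway_raw(load_groups)
  dunnett <- dunnett_two_tailed(load_groups,
                                control_index = length(load_groups),
                                mc_replicates = max(mc_replicates, 1e5),
                                seed = sub_seed(seed, 500L))

  combo_table <- count_table(s$combination_class, s$cohort,
                             c("none", "single", "common-only",
                               "common+rare", "rare-only"),
                             c(diseases, control))

  flags <- screen_pathogenic(prof$variants, known = pathogenic,
                             heteroplasmy_below = homoplasmy_cutoff)

  filter_log <- c(
    variants_in = nrow(prof$variants),
    non_synonymous = sum(prof$variants$nonsyn),
    homoplasmic = sum(prof$variants$fraction >= homoplasmy_cutoff),
    scored = sum(!is.na(prof$variants$score)),
    qualifying = sum(qualifying_mask(prof$variants, score_threshold,
                                     homoplasmy_cutoff)))

  structure(list(profiles = prof,
                 haplogroup_table = hap_table,
                 haplogroup_tests = hap_tests,
                 unique_variant_tables = uv_tables,
                 unique_variant_tests = uv_tests,
                 carrier_tests = carrier_tests,
                 count_tests = count_tests,
                 load_summary = load_summary,
                 anova = anova,
                 dunnett = dunnett,
                 combination_table = combo_table,
                 pathogenic_flags = flags,
                 filter_log = filter_log,
                 settings = list(control = control,
                                 score_threshold = score_threshold,
                                 high_threshold = high_threshold,
                                 homoplasmy_cutoff = homoplasmy_cutoff,
                                 mc_replicates = mc_replicates,
                                 seed = seed)),
            class = "mt_report")
}

scores_from <- function(prof) {
  v <- prof$variants
  keep <- !is.na(v$score)
  unique(data.frame(position = v$position[keep], ref = v$ref[keep],
                    alt = v$alt[keep], score = v$score[keep],
                    stringsAsFactors = FALSE))
}

freqs_from <- function(prof) {
  v <- prof$variants
  keep <- !is.na(v$frequency)
  unique(data.frame(position = v$position[keep], ref = v$ref[keep],
                    alt = v$alt[keep], frequency = v$frequency[keep],
                    stringsAsFactors = FALSE))
}

#' @export
print.mt_report <- function(x, ...) {
  cat("mtDNA variant-load association report\n")
  cat("  cohorts:", paste(x$load_summary$cohort, collapse = ", "), "\n")
  cat("  load means:",
      paste(sprintf("%s %.2f", x$load_summary$cohort, x$load_summary$mean),
            collapse = ", "), "\n")
  cat("  ANOVA p =", format(x$anova$p.value, digits = 3), "\n")
  cat("  Dunnett adjusted p:",
      paste(sprintf("%s %.3f", x$dunnett$comparisons$group,
                    x$dunnett$comparisons$p.adjust), collapse = ", "), "\n")
  invisible(x)
}

report_json <- function(report) {
  tests_list <- function(tt) lapply(tt, function(h) {
    if (inherits(h, "mt_exact_test")) return(exact_json(h))
    out <- list()
    if (!is.null(h$table)) out$table <- as.data.frame(as.table(h$table))
    if (!is.null(h$exact)) out$exact <- exact_json(h$exact)
    if (!is.null(h$test)) out$exact <- exact_json(h$test)
    if (!is.null(h$residuals)) {
      out$residuals <- round(h$residuals$residuals, 6)
      out$phi <- round(h$residuals$phi, 6)
      out$residual_p <- signif(h$residuals$p.value, 6)
    }
    if (!is.null(h$p.bonferroni)) out$p.bonferroni <- h$p.bonferroni
    out
  })
  exact_json <- function(t) list(p = t$p.value, method = t$method,
                                 replicates = t$replicates, seed = t$seed,
                                 std_error = t$std.error,
                                 degenerate = t$degenerate)
  list(settings = report$settings,
       filter_log = as.list(report$filter_log),
       haplogroup_table = as.data.frame(as.table(report$haplogroup_table)),
       haplogroup_tests = tests_list(report$haplogroup_tests),
       unique_variant_tables = lapply(report$unique_variant_tables,
                                      function(m)
                                        as.data.frame(as.table(m))),
       unique_variant_tests = lapply(report$unique_variant_tests,
                                     exact_json),
       carrier_tests = lapply(report$carrier_tests, tests_list),
       count_tests = tests_list(report$count_tests),
       load_summary = report$load_summary,
       anova = list(F = report$anova$statistic, df = report$anova$df,
                    p = report$anova$p.value),
       dunnett = list(comparisons = report$dunnett$comparisons,
                      df = report$dunnett$df, mse = report$dunnett$mse,
                      replicates = report$dunnett$replicates,
                      seed = report$dunnett$seed),
       combination_table = as.data.frame(as.table(report$combination_table)),
       pathogenic_flags = report$pathogenic_flags)
}

#' Write a machine-readable report
#'
#' Serializes the association report as JSON plus a set of TSV tables
#' (per-sample profiles, contingency tables, load summary). Re-running the
#' analysis with the same inputs and seed reproduces the files
#' byte-identically.
#'
#' @param report An \code{mt_report}.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report_json(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  utils::write.table(report$profiles$samples,
                     file.path(dir, "sample_profiles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$profiles$variants,
                     file.path(dir, "annotated_variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ht <- cbind(haplogroup = rownames(report$haplogroup_table),
              as.data.frame(report$haplogroup_table))
  utils::write.table(ht, file.path(dir, "haplogroup_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$load_summary,
                     file.path(dir, "load_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
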