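# Variant IO, score/frequency attachment, loads, carrier and combination
# classes, pathogenic screen.

scored_profile <- function(variants, pk = packaged()) {
  ann <- annotate_variants(variants, pk$genome, pk$gene_map)
  attach_scores(ann, pk$scores, pk$freqs)
}

one_sample <- function(position, ref, alt, fraction = 1.0) {
  data.frame(sample = "s1", position = position, ref = ref, alt = alt,
             fraction = fraction, stringsAsFactors = FALSE)
}

test_that("variant tables round-trip through TSV and validate", {
  v <- data.frame(sample = c("a", "b"), position = c(4216L, 1555L),
                  ref = c("T", "A"), alt = c("C", "G"),
                  fraction = c(1, 0.12))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variants(v, path)
  expect_equal(read_variants(path), v)
  expect_error(validate_variants(transform(v, alt = ref)), "differ")
  expect_error(validate_variants(transform(v, position = 99999L)),
               "positions")
  expect_error(validate_variants(transform(v, ref = "AT")),
               "single-nucleotide")
})

test_that("minimal VCF input is read with AF and multi-allelic splitting", {
  skip_if_not_installed("vcfR")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chrM\t4216\t.\tT\tC\t.\tPASS\tAF=1.0",
    "chrM\t1555\t.\tA\tG\t.\tPASS\tAF=0.1181",
    "chrM\t5460\t.\tG\tA,T\t.\tPASS\t."), path)
  v <- read_variants_vcf(path, sample = "x")
  expect_equal(nrow(v), 4L)
  expect_equal(v$fraction[v$position == 1555], 0.1181)
  expect_equal(v$fraction[v$position == 4216], 1.0)
  expect_setequal(v$alt[v$position == 5460], c("A", "T"))
})

test_that("scores attach to non-synonymous calls only, with rarity bands", {
  pk <- packaged()
  v <- scored_profile(one_sample(c(4216L, 3394L), c("T", "T"),
                                 c("C", "C")), pk)
  expect_equal(v$score[v$position == 4216], 0.611)
  expect_equal(v$frequency[v$position == 4216], 0.1001)
  expect_equal(v$rarity[v$position == 4216], "common")
  expect_equal(v$score[v$position == 3394], 0.783)
  # a synonymous variant at a scored position must get no score
  syn_pos <- NA
  for (p in 3307:4262) {
    ref <- substr(pk$genome$bases, p, p)
    for (a in setdiff(c("A", "C", "G", "T"), ref)) {
      calls <- classify_snv(p, ref, a, pk$genome, pk$gene_map)
      if (all(calls$consequence == "synonymous")) { syn_pos <- c(p, ref, a) }
      if (!anyNA(syn_pos)) break
    }
    if (!anyNA(syn_pos)) break
  }
  sc2 <- rbind(pk$scores,
               data.frame(position = as.integer(syn_pos[1]),
                          ref = syn_pos[2], alt = syn_pos[3], score = 0.9))
  ann <- annotate_variants(one_sample(as.integer(syn_pos[1]), syn_pos[2],
                                      syn_pos[3]), pk$genome, pk$gene_map)
  got <- attach_scores(ann, sc2, pk$freqs)
  expect_true(is.na(got$score))
  expect_error(validate_score_table <- attach_scores(
    ann, transform(sc2, score = score * 2), pk$freqs), "0, 1")
})

test_that("variant load sums qualifying scores with strict threshold", {
  v <- scored_profile(one_sample(c(4216L, 4917L), c("T", "A"), c("C", "G")))
  expect_equal(variant_load(v), 1.239)
  expect_equal(carrier_category(v), "2+")
  expect_equal(combination_class(v), "common-only", ignore_attr = TRUE)
  # empty sample
  empty <- scored_profile(data.frame(sample = character(),
                                     position = integer(),
                                     ref = character(), alt = character(),
                                     fraction = numeric()))
  expect_equal(variant_load(empty), 0)
  expect_equal(carrier_category(empty), "0")
  expect_equal(combination_class(empty), "none", ignore_attr = TRUE)
  # score exactly at the threshold does not qualify
  pk <- packaged()
  v505 <- scored_profile(one_sample(5460L, "G", "A"), pk)
  expect_equal(variant_load(v505, threshold = 0.505), 0)
  expect_equal(variant_load(v505, threshold = 0.5), 0.505)
  # heteroplasmic variants are excluded from the load
  vhet <- scored_profile(one_sample(4216L, "T", "C", fraction = 0.5))
  expect_equal(variant_load(vhet), 0)
  expect_error(variant_load(v, threshold = 1.5), "0, 1")
})

test_that("load is monotone in the threshold and in added variants", {
  cfg <- synthetic_config(sizes = c(a = 40L, control = 2L), seed = 99)
  prof <- profile_cohorts(generate_cohorts(cfg))
  v <- prof$variants
  for (s in unique(v$sample)) {
    sv <- v[v$sample == s, ]
    expect_lte(variant_load(sv, 0.7), variant_load(sv, 0.5))
  }
  # adding a qualifying variant strictly increases the load
  sv <- v[v$sample == unique(v$sample)[1], ]
  extra <- sv[1, ]
  extra$position <- 1L; extra$score <- 0.9; extra$nonsyn <- TRUE
  extra$fraction <- 1.0
  expect_gt(variant_load(rbind(sv, extra)), variant_load(sv))
})

test_that("carrier category and load agree across a cohort", {
  cfg <- synthetic_config(sizes = c(a = 60L, control = 2L), seed = 7)
  prof <- profile_cohorts(generate_cohorts(cfg))
  s <- prof$samples
  expect_equal(s$variant_load > 0, s$carrier_category != "0")
  # combination classes partition the cohort
  expect_equal(sum(table(s$combination_class)), nrow(s))
  # vectorised profile equals the per-sample recount
  for (id in sample(s$sample, 10)) {
    sv <- prof$variants[prof$variants$sample == id, ]
    expect_equal(s$variant_load[s$sample == id], variant_load(sv))
    expect_equal(s$carrier_category[s$sample == id], carrier_category(sv))
    expect_equal(s$combination_class[s$sample == id],
                 combination_class(sv), ignore_attr = TRUE)
  }
})

test_that("combination classes follow the rare/common composition", {
  pk <- packaged()
  pool <- mitoload:::default_pool(pk$genome, pk$gene_map, pk$markers,
                                  pk$scores, read_pathogenic_table())
  rare <- pool[1, ]
  sc <- rbind(pk$scores, data.frame(position = rare$position,
                                    ref = rare$ref, alt = rare$alt,
                                    score = 0.6))
  fq <- rbind(pk$freqs, data.frame(position = rare$position,
                                   ref = rare$ref, alt = rare$alt,
                                   frequency = 0.0005))
  v <- data.frame(sample = "s1",
                  position = c(4216L, rare$position),
                  ref = c("T", rare$ref), alt = c("C", rare$alt),
                  fraction = 1)
  ann <- attach_scores(annotate_variants(v, pk$genome, pk$gene_map), sc, fq)
  expect_equal(combination_class(ann), "common+rare", ignore_attr = TRUE)
  single <- ann[1, ]
  expect_equal(combination_class(single), "single", ignore_attr = TRUE)
  rare_only <- ann[2, ]
  rare2 <- rare_only; rare2$position <- pool$position[2]
  rare2$ref <- pool$ref[2]; rare2$alt <- pool$alt[2]
  rare2$score <- 0.55; rare2$rarity <- "rare"
  expect_equal(combination_class(rbind(rare_only, rare2)), "rare-only",
               ignore_attr = TRUE)
})

test_that("rarity bands use strict cutoffs and unknowns are flagged", {
  expect_equal(rarity_class(c(0.0009, 0.001, 0.01, 0.011, NA)),
               c("rare", "intermediate", "intermediate", "common",
                 "unknown"))
})

test_that("pathogenic screen flags known variants at any allele fraction", {
  cfg <- synthetic_config(seed = 3)
  ch <- generate_cohorts(cfg)
  v <- ch$variants
  planted <- data.frame(
    sample = c(v$sample[1], v$sample[nrow(v)]),
    cohort = c(v$cohort[1], v$cohort[nrow(v)]),
    position = 1555L, ref = "A", alt = "G",
    fraction = c(0.1181, 1.0), stringsAsFactors = FALSE)
  flags <- screen_pathogenic(rbind(v, planted))
  expect_equal(nrow(flags), 2L)
  expect_equal(sort(flags$fraction), c(0.1181, 1.0))
  expect_equal(flags$heteroplasmic, flags$fraction < 0.95)
  expect_false(any(grepl("3243", flags$label)))
  expect_equal(nrow(screen_pathogenic(v)), 0L)
})

test_that("variant loads match an independent recount from raw tables", {
  cfg <- synthetic_config(seed = 55)
  ch <- generate_cohorts(cfg)
  prof <- profile_cohorts(ch)
  pk <- packaged()
  skey <- paste(ch$scores$position, ch$scores$alt)
  set.seed(1)
  for (id in sample(prof$samples$sample, 25)) {
    sv <- ch$variants[ch$variants$sample == id, ]
    total <- 0
    for (j in seq_len(nrow(sv))) {
      calls <- classify_snv(sv$position[j], sv$ref[j], sv$alt[j],
                            pk$genome, pk$gene_map)
      if (!any(calls$consequence == "non-synonymous")) next
      if (sv$fraction[j] < 0.95) next
      sc <- ch$scores$score[match(paste(sv$position[j], sv$alt[j]), skey)]
      if (!is.na(sc) && sc > 0.5) total <- total + sc
    }
    expect_equal(prof$samples$variant_load[prof$samples$sample == id],
                 total, tolerance = 1e-12)
  }
})
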