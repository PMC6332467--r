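# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: a literal 64-entry vertebrate mitochondrial
# codon table and a brute-force per-gene classifier.

MITO_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "M", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "W", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "*", AGG = "*",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# Brute-force consequence classifier: extracts the whole gene, splits it
# into codons, translates with the literal table.
oracle_classify <- function(position, ref, alt, bases, gm) {
  feats <- gm[gm$start <= position & gm$end >= position, , drop = FALSE]
  if (nrow(feats) == 0L)
    return(data.frame(gene = NA_character_, consequence = "non-coding",
                      stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(feats)), function(i) {
    f <- feats[i, ]
    if (f$class != "protein")
      return(data.frame(gene = f$gene, consequence = f$class,
                        stringsAsFactors = FALSE))
    gene_seq <- substr(bases, f$start, f$end)
    if (f$strand == "light") {
      cs <- oracle_revcomp(gene_seq)
      idx <- f$end - position + 1L
      sub_ref <- chartr("ACGT", "TGCA", ref)
      sub_alt <- chartr("ACGT", "TGCA", alt)
    } else {
      cs <- gene_seq
      idx <- position - f$start + 1L
      sub_ref <- ref
      sub_alt <- alt
    }
    ci <- ceiling(idx / 3)
    cstart <- (ci - 1L) * 3L + 1L
    if (cstart + 2L > nchar(cs))
      return(data.frame(gene = f$gene, consequence = "untranslatable",
                        stringsAsFactors = FALSE))
    codon <- substr(cs, cstart, cstart + 2L)
    k <- idx - cstart + 1L
    stopifnot(substr(codon, k, k) == sub_ref)
    if (grepl("N", codon, fixed = TRUE))
      return(data.frame(gene = f$gene, consequence = "untranslatable",
                        stringsAsFactors = FALSE))
    altcodon <- codon
    substr(altcodon, k, k) <- sub_alt
    a1 <- unname(MITO_TABLE[codon])
    a2 <- unname(MITO_TABLE[altcodon])
    cons <- if (a1 == a2) "synonymous"
            else if (a2 == "*") "stop-gain"
            else if (a1 == "*") "stop-loss"
            else "non-synonymous"
    data.frame(gene = f$gene, consequence = cons, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Small fully-specified test genomes ---------------------------------------

# heavy-strand gene 4..12 (3 codons: ATG AAA TAA), light-strand gene 16..27
# whose coding sequence (revcomp of heavy 16..27) is ATG CTA TTC TAA
toy_genome <- function() {
  heavy_gene <- "ATGAAATAA"
  light_coding <- "ATGCTATTCTAA"
  light_heavy <- oracle_revcomp(light_coding)
  bases <- paste0("CCC", heavy_gene, "GGG", light_heavy, "TT")
  stopifnot(nchar(bases) == 29L)
  list(genome = mitoload::mt_genome("toy", bases),
       gene_map = data.frame(
         gene = c("toyH", "toyL"),
         start = c(4L, 16L), end = c(12L, 27L),
         strand = c("heavy", "light"),
         class = c("protein", "protein"),
         stringsAsFactors = FALSE))
}

random_toy_genome <- function(len, seed) {
  set.seed(seed)
  bases <- paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
  # one heavy gene with an incomplete tail, one light gene, one tRNA
  gm <- data.frame(
    gene = c("gH", "gL", "tX"),
    start = c(5L, 35L, 60L),
    end = c(24L + 2L, 35L + 11L, min(len, 70L)),   # gH has a 2-base tail
    strand = c("heavy", "light", "heavy"),
    class = c("protein", "protein", "tRNA"),
    stringsAsFactors = FALSE)
  gm <- gm[gm$end <= len, , drop = FALSE]
  list(genome = mitoload::mt_genome("rand", bases), gene_map = gm)
}

packaged <- function() {
  list(genome = read_genome_fasta(mitoload_fixture("mt_genome_synthetic.fasta")),
       gene_map = read_gene_map(mitoload_fixture("gene_map.tsv")),
       markers = read_marker_table(mitoload_fixture("haplogroup_markers_synthetic.tsv")),
       scores = read_score_table(mitoload_fixture("mutpred_scores.tsv")),
       freqs = read_frequency_table(mitoload_fixture("genbank_frequencies.tsv")))
}

# published haplogroup distribution (packaged printed-counts fixture)
study_hap_table <- function() {
  read_contingency_table(mitoload_fixture("study_haplogroup_counts.tsv"))
}
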