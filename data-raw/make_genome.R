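# Deterministic builder for inst/extdata/mt_genome_synthetic.fasta.
#
# The genome is a synthetic stand-in on real rCRS gene coordinates
# (16,569 bp). Protein genes carry random non-stop codons in their own
# reading frame (a terminal stop where the gene length allows a complete
# codon, a bare 1-2 base tail where the real gene's stop codon is completed
# by polyadenylation). The codons containing the thirteen packaged scored
# variants are set to the amino-acid contexts in which those substitutions
# are non-synonymous; marker and pathogenic-list positions get the
# reference alleles the fixtures assume.
#
# Run from the package root: Rscript data-raw/make_genome.R

set.seed(20260928)

gm <- read.delim("inst/extdata/gene_map.tsv", stringsAsFactors = FALSE)

STOPS <- c("TAA", "TAG", "AGA", "AGG")
codon_pool <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                c("A","C","G","T")), 1, paste, collapse = "")
codon_pool <- setdiff(codon_pool, STOPS)
comp <- c(A = "T", C = "G", G = "C", T = "A")

bases <- sample(c("A", "C", "G", "T"), 16569, replace = TRUE)

write_gene <- function(bases, start, end, strand) {
  len <- end - start + 1L
  nfull <- len %/% 3L
  tail_len <- len %% 3L
  codons <- sample(codon_pool, nfull, replace = TRUE)
  if (tail_len == 0L) codons[nfull] <- "TAA"
  coding <- unlist(strsplit(codons, ""))
  if (tail_len > 0L) coding <- c(coding, c("T", "A")[seq_len(tail_len)])
  if (strand == "heavy") {
    bases[start:end] <- coding
  } else {
    bases[start:end] <- rev(unname(comp[coding]))
  }
  bases
}

prot <- gm[gm$class == "protein", ]
for (i in seq_len(nrow(prot)))
  bases <- write_gene(bases, prot$start[i], prot$end[i], prot$strand[i])

# codon contexts of the scored variants (codon start position -> codon)
overrides <- list(
  c(3394,  "TAC"),   # ND1  Y>H  via 3394 T>C
  c(4216,  "TAC"),   # ND1  Y>H  via 4216 T>C
  c(4917,  "AAC"),   # ND2  N>D  via 4917 A>G
  c(5460,  "GCC"),   # ND2  A>T  via 5460 G>A
  c(8414,  "CTC"),   # ATP8 L>F  via 8414 C>T
  c(8584,  "GCC"),   # ATP6 A>T  via 8584 G>A
  c(11969, "GCC"),   # ND4  A>T  via 11969 G>A
  c(12811, "TAC"),   # ND5  Y>H  via 12811 T>C
  c(13780, "ATC"),   # ND5  I>V  via 13780 A>G
  c(14798, "TTC"),   # CYB  F>L  via 14798 T>C
  c(15203, "ATC"),   # CYB  I>T  via 15204 T>C (codon position 2)
  c(15257, "GAC"),   # CYB  D>N  via 15257 G>A
  c(15812, "GTA"))   # CYB  V>M  via 15812 G>A
for (ov in overrides) {
  p <- as.integer(ov[1])
  bases[p:(p + 2L)] <- strsplit(ov[2], "")[[1]]
}

# reference alleles assumed by the marker and pathogenic fixtures
markers <- read.delim("inst/extdata/haplogroup_markers_synthetic.tsv",
                      stringsAsFactors = FALSE)
ctrl_region <- markers$position[markers$position >= 16024]
bases[ctrl_region] <- "T"            # markers there are T>C
bases[3243] <- "A"                   # m.3243A>G
bases[1555] <- "A"                   # m.1555A>G

seqstr <- paste(bases, collapse = "")
lines <- c(">MT_SYNTH synthetic mitochondrial genome stand-in (rCRS coordinates)",
           substring(seqstr, seq(1, nchar(seqstr), 70),
                     pmin(seq(1, nchar(seqstr), 70) + 69, nchar(seqstr))))
writeLines(lines, "inst/extdata/mt_genome_synthetic.fasta")

# sanity: every scored variant must be non-synonymous under the package
pkgload::load_all(".", quiet = TRUE)
g <- read_genome_fasta("inst/extdata/mt_genome_synthetic.fasta")
sc <- read_score_table("inst/extdata/mutpred_scores.tsv")
for (i in seq_len(nrow(sc))) {
  calls <- classify_snv(sc$position[i], sc$ref[i], sc$alt[i], g, gm)
  stopifnot(any(calls$consequence == "non-synonymous"))
}
known <- read.delim("inst/extdata/pathogenic_variants.tsv",
                    stringsAsFactors = FALSE)
stopifnot(substring(g$bases, known$position, known$position) == known$ref)
stopifnot(substring(g$bases, markers$position, markers$position) !=
            markers$alt)
cat("mt_genome_synthetic.fasta written and verified\n")
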