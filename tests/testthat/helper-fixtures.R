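# Hand-built two-gene toy genome with known codon layout, plus a
# whole-protein-diff oracle used to cross-check the codon-level annotator.

# Plus-strand gene on chrA:
#   1-10 intergenic, 11-15 5'UTR, CDS = ATG GCT TGG TAC TAA split 16-22 /
#   31-38 around the intron 23-30 (GT..AG), 39-42 3'UTR, pad to 60 bp.
toy_plus_fixture <- function() {
  seq <- paste0("AAAAACCCCC", "TTTTT", "ATGGCTT", "GTCCCCAG", "GGTACTAA",
                "GGGG", paste(rep("ACTG", 5), collapse = ""))
  total <- nchar(seq)
  stopifnot(total == 62)
  model <- gene_model("gA", "gA.t1", "chrA", "+",
                      exons = rbind(c(11, 22), c(31, 42)),
                      cds = rbind(c(16, 22), c(31, 38)),
                      utr5 = rbind(c(11, 15)), utr3 = rbind(c(39, 42)))
  list(genome = c(chrA = seq), model = model)
}

# Minus-strand gene on chrB with the same transcript layout (5bp UTR5,
# CDS ATGGCTT|GGTACTAA around an 8bp GT..AG intron, 4bp UTR3), placed at
# genomic offset 11 and reverse-complemented.
toy_minus_fixture <- function() {
  local_seq <- paste0("TTTTT", "ATGGCTT", "GTCCCCAG", "GGTACTAA", "GGGG")
  stopifnot(nchar(local_seq) == 32)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(local_seq)))
  seq <- paste0("AAAAACCCCC", rc, paste(rep("GTCA", 5), collapse = ""))
  model <- gene_model("gB", "gB.t1", "chrB", "-",
                      exons = rbind(c(11, 22), c(31, 42)),
                      cds = rbind(c(15, 22), c(31, 37)),
                      utr5 = rbind(c(38, 42)), utr3 = rbind(c(11, 14)))
  list(genome = c(chrB = seq), model = model)
}

# Independent oracle: apply the SNP to the chromosome, re-extract and
# translate the full CDS, and classify from the protein diff.
oracle_classify_cds_snp <- function(pos, alt, model, genome) {
  chrom <- model$chrom
  mut <- genome
  substring(mut[[chrom]], pos, pos) <- alt
  prot_ref <- translate_cds(cds_sequence(model, genome))
  prot_alt <- translate_cds(cds_sequence(model, mut))
  n <- nchar(prot_ref)
  if (substr(prot_alt, 1, 1) != "M") return("start_loss")
  if (substr(prot_ref, n, n) == "*" && substr(prot_alt, n, n) != "*")
    return("stop_loss")
  if (grepl("[*]", substr(prot_alt, 1, n - 1))) return("stop_gain")
  if (prot_alt == prot_ref) return("synonymous")
  "nonsynonymous"
}

# Map from the truth set's intended_class labels to annotator output.
intended_to_consequence <- c(
  synonymous = "synonymous", nonsynonymous = "nonsynonymous",
  stop_gain = "stop_gain", start_loss = "start_loss",
  stop_loss = "stop_loss", splice_disrupt = "splice_disrupt")

small_config <- function(seed = 1, ...) {
  simulation_config(seed = seed, n_chroms = 2, chrom_length = 60000,
                    n_genes = 12, n_intergenic_snp = 30, n_intron_snp = 8,
                    n_utr_snp = 6, ...)
}
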