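test_that("genome generation is byte-identical under a fixed seed", {
  cfg <- small_config(seed = 5)
  a <- generate_genome(cfg)
  b <- generate_genome(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$genes, b$genes)
  sp_a <- spike_variants(a$genome, a$genes, cfg)
  sp_b <- spike_variants(b$genome, b$genes, cfg)
  expect_identical(sp_a$truth, sp_b$truth)
  expect_identical(as.character(sp_a$genome), as.character(sp_b$genome))
})

test_that("generated CDS translate cleanly and introns are GT..AG", {
  gen <- generate_genome(small_config(seed = 2))
  for (m in Filter(is_coding, gen$genes)) {
    prot <- translate_cds(cds_sequence(m, gen$genome))
    expect_identical(substr(prot, 1, 1), "M")
    expect_identical(substr(prot, nchar(prot), nchar(prot)), "*")
    expect_false(grepl("[*]", substr(prot, 1, nchar(prot) - 1)))
    ir <- introns(m)
    seq <- as.character(gen$genome[[m$chrom]])
    for (i in seq_len(nrow(ir))) {
      intron <- substring(seq, ir[i, 1], ir[i, 2])
      # transcription-order donor/acceptor: genomic GT..AG on plus strand,
      # CT..AC on minus
      if (m$strand == "+") {
        expect_identical(substr(intron, 1, 2), "GT")
        expect_identical(substring(intron, nchar(intron) - 1), "AG")
      } else {
        expect_identical(substr(intron, 1, 2), "CT")
        expect_identical(substring(intron, nchar(intron) - 1), "AC")
      }
    }
  }
})

test_that("chromosomes too small for the requested genes error", {
  cfg <- simulation_config(seed = 1, n_chroms = 1, chrom_length = 5000,
                           n_genes = 10)
  expect_error(generate_genome(cfg), "too small")
})

test_that("spiked variants are recovered with their intended class", {
  cfg <- small_config(seed = 9)
  gen <- generate_genome(cfg)
  sp <- spike_variants(gen$genome, gen$genes, cfg)
  truth <- sp$truth
  # class counts match the request
  expect_identical(sum(truth$intended_class == "synonymous"),
                   as.integer(cfg$n_synonymous))
  expect_identical(sum(truth$intended_class == "stop_gain"),
                   as.integer(cfg$n_stop_gain))
  expect_identical(sum(truth$var_class == "INV"), as.integer(cfg$n_inv))
  # annotation against the ORIGINAL genome recovers every intended class
  snps <- truth[truth$var_class == "SNP", ]
  ann <- annotate_variants(snps, gen$genes, gen$genome)
  coding <- ann[ann$intended_class %in% names(intended_to_consequence), ]
  expect_identical(coding$consequence,
                   unname(intended_to_consequence[coding$intended_class]))
  regional <- ann[ann$intended_class %in% c("intron", "UTR", "intergenic"), ]
  expect_identical(regional$region, regional$intended_class)
  expect_true(all(regional$consequence == "none"))
  # splice spikes land on the first/last 2 nt of an intron
  spl <- truth[truth$intended_class == "splice_disrupt", ]
  gidx <- stats::setNames(gen$genes, vapply(gen$genes, `[[`, "", "gene_id"))
  for (i in seq_len(nrow(spl))) {
    ir <- introns(gidx[[spl$gene_id[i]]])
    edges <- c(ir[, 1], ir[, 1] + 1L, ir[, 2] - 1L, ir[, 2])
    expect_true(spl$pos[i] %in% edges)
  }
  # spiked ref alleles match the reference sequence
  snp_ref <- substring(as.character(gen$genome)[snps$chrom], snps$pos, snps$pos)
  expect_identical(unname(snp_ref), snps$ref)
  # mutated genome carries the alt allele at SNPs whose coordinates are not
  # shifted by a lower-position indel/SV on the same chromosome
  mut <- as.character(sp$genome)
  for (ch in names(mut)) {
    shifts <- truth$pos[truth$chrom == ch & truth$var_class != "SNP"]
    first_shift <- if (length(shifts)) min(shifts) else Inf
    stable <- snps[snps$chrom == ch & snps$pos < first_shift, ]
    if (nrow(stable))
      expect_identical(unname(substring(mut[[ch]], stable$pos, stable$pos)),
                       stable$alt)
  }
})

test_that("CDS indel spikes carry the correct frame class", {
  cfg <- small_config(seed = 4, cds_indel_sizes = c(3L, 4L, 6L, 5L))
  gen <- generate_genome(cfg)
  sp <- spike_variants(gen$genome, gen$genes, cfg)
  cds_indels <- sp$truth[sp$truth$intended_class %in% c("inframe", "frameshift"), ]
  expect_identical(nrow(cds_indels), 4L)
  expect_identical(cds_indels$intended_class,
                   ifelse(cds_indels$length %% 3 == 0, "inframe", "frameshift"))
  loc <- locate_variant(cds_indels, gen$genes)
  expect_true(all(loc$region == "CDS"))
})

test_that("F2 simulation honors Mendelian limits", {
  # recombination fraction 0: marker on top of the locus tracks it exactly
  pop <- simulate_f2(200, c(M0 = 5000L), 5000L, seed = 1)
  expect_identical(pop$M0, pop$locus)
  expect_identical(unname(c(AA = "waxy", AB = "heterozygous",
                            BB = "non_waxy")[pop$locus]),
                   pop$phenotype)
  expect_error(simulate_f2(0, c(M0 = 1L), 1L), "positive")
})

test_that("waxy fraction is ~1/4 and locus genotypes ~1:2:1 at n=460", {
  frac <- vapply(1:40, function(s) {
    pop <- simulate_f2(460, locus_position = 10000L, seed = s)
    mean(pop$phenotype == "waxy")
  }, 0)
  expect_equal(mean(frac), 0.25, tolerance = 0.02)
  pop <- do.call(rbind, lapply(1:10, function(s)
    simulate_f2(460, locus_position = 10000L, seed = 100 + s)))
  counts <- table(pop$locus)[c("AA", "AB", "BB")]
  expect_equal(unname(counts["AB"] / sum(counts)), 0.5, tolerance = 0.03)
})

test_that("inversion contigs match both strands; decoys plus-only", {
  cfg <- small_config(seed = 3)
  gen <- generate_genome(cfg)
  chrom <- names(gen$genome)[1]
  len <- genome_lengths(gen$genome)[[chrom]]
  inv <- data.frame(chrom = chrom, start = len - 3000L, end = len - 2001L)
  contigs <- generate_inversion_contigs(gen$genome, inv, cfg)
  seq <- as.character(gen$genome[[chrom]])
  seg <- substring(seq, inv$start, inv$end)
  seg_rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seg)))
  inv_ctgs <- contigs[grepl("^inv", names(contigs))]
  decoys <- contigs[grepl("^decoy", names(contigs))]
  expect_true(length(inv_ctgs) >= 1)
  # oracle: exact substring search on both strands
  expect_true(any(vapply(inv_ctgs, function(ctg)
    grepl(substr(seg_rc, 1, 200), ctg, fixed = TRUE), TRUE)))
  for (d in decoys) {
    expect_true(grepl(d, seq, fixed = TRUE) ||
                  grepl(d, as.character(gen$genome[[2]]), fixed = TRUE))
    expect_false(grepl(substr(seg_rc, 1, 200), d, fixed = TRUE))
  }
  # empty inversion list: only decoys
  none <- generate_inversion_contigs(gen$genome,
                                     inv[0, , drop = FALSE], cfg)
  expect_true(all(grepl("^decoy", names(none))))
  # out-of-bounds interval errors
  expect_error(generate_inversion_contigs(
    gen$genome, data.frame(chrom = chrom, start = len - 100L, end = len + 500L),
    cfg), "bounds")
})
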