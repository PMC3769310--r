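test_that("substitutions fall into six unordered classes", {
  expect_identical(classify_substitution("C", "T")$class, "C/T")
  expect_identical(classify_substitution("T", "C")$class, "C/T")  # unordered
  expect_identical(classify_substitution("C", "T")$kind, "transition")
  expect_identical(classify_substitution("A", "G")$class, "G/A")
  expect_identical(classify_substitution("T", "A")$class, "T/A")
  expect_identical(classify_substitution("T", "A")$kind, "transversion")
  expect_identical(classify_substitution("G", "T")$class, "G/T")
  expect_error(classify_substitution("A", "A"), "differ")
  expect_error(classify_substitution("A", "N"), "A/C/G/T")
  # swapping ref/alt never changes the class
  bases <- c("A", "C", "G", "T")
  for (r in bases) for (a in setdiff(bases, r))
    expect_identical(classify_substitution(r, a)$class,
                     classify_substitution(a, r)$class)
})

test_that("Ts/Tv reproduces the published substitution tables", {
  yugu <- c("C/T" = 274004, "G/A" = 275427, "C/G" = 53493,
            "T/A" = 45776, "A/C" = 56996, "G/T" = 56386)
  zhanggu <- c("C/T" = 326850, "G/A" = 328049, "C/G" = 64454,
               "T/A" = 56686, "A/C" = 69612, "G/T" = 69783)
  expect_equal(round(compute_ts_tv(yugu), 1), 2.6)
  expect_equal(round(compute_ts_tv(zhanggu), 1), 2.5)
  equal <- c("C/T" = 50, "G/A" = 50, "C/G" = 25, "T/A" = 25,
             "A/C" = 25, "G/T" = 25)
  expect_equal(compute_ts_tv(equal), 1.0)
  none <- c("C/T" = 10, "G/A" = 10, "C/G" = 0, "T/A" = 0, "A/C" = 0, "G/T" = 0)
  expect_error(compute_ts_tv(none), "transversions")
})

test_that("spectrum counts partition a SNP set (Ts + Tv = total)", {
  set.seed(12)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, 500, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  spec <- substitution_spectrum(data.frame(ref = ref, alt = alt))
  expect_identical(sum(spec), 500L)
})

test_that("region assignment distinguishes CDS/UTR/intron/intergenic", {
  fx <- toy_plus_fixture()
  v <- data.frame(chrom = "chrA", pos = c(5L, 12L, 20L, 26L, 40L, 55L))
  loc <- locate_variant(v, list(fx$model))
  expect_identical(loc$region, c("intergenic", "UTR", "CDS", "intron",
                                 "UTR", "intergenic"))
  expect_identical(loc$gene_id[3], "gA")
  expect_warning(locate_variant(data.frame(chrom = "chrZ", pos = 1L),
                                list(fx$model)), "chrZ")
})

test_that("plus-strand codon annotation matches the standard code", {
  fx <- toy_plus_fixture()
  genes <- list(fx$model)
  ann <- function(pos, alt) {
    v <- data.frame(chrom = "chrA", pos = pos, ref = "N", alt = alt)
    annotate_variants(v, genes, fx$genome)
  }
  a <- ann(21L, "C")  # GCT -> GCC, Ala -> Ala
  expect_identical(a$consequence, "synonymous")
  expect_identical(a$ref_aa, "A"); expect_identical(a$codon_index, 2L)
  a <- ann(19L, "A")  # GCT -> ACT, Ala -> Thr
  expect_identical(a$consequence, "nonsynonymous")
  expect_identical(a$alt_aa, "T")
  a <- ann(32L, "A")  # TGG -> TGA across the intron: premature stop
  expect_identical(a$consequence, "stop_gain")
  a <- ann(17L, "C")  # ATG -> ACG: initiation codon lost
  expect_identical(a$consequence, "start_loss")
  a <- ann(36L, "C")  # TAA -> CAA: annotated stop removed
  expect_identical(a$consequence, "stop_loss")
  a <- ann(23L, "A")  # first intron base, GT -> AT donor
  expect_identical(a$consequence, "splice_disrupt")
  a <- ann(30L, "C")  # last intron base, AG -> AC acceptor
  expect_identical(a$consequence, "splice_disrupt")
  a <- ann(26L, "A")  # intron interior
  expect_identical(a$consequence, "none")
  expect_identical(a$region, "intron")
})

test_that("minus-strand SNPs are classified via the transcript codon", {
  fx <- toy_minus_fixture()
  genes <- list(fx$model)
  # transcript codon 2 is GCT at transcript CDS offsets 4-6; genomic positions
  # descend from 34; a genomic A->G at 32 reads T->C on the transcript (GCC)
  v <- data.frame(chrom = "chrB", pos = 32L, ref = "A", alt = "G")
  a <- annotate_variants(v, genes, fx$genome)
  expect_identical(a$consequence, "synonymous")
  # oracle agreement across every single-base CDS substitution of the gene
  cpos <- cds_positions(fx$model)
  for (p in cpos) {
    ref <- substring(fx$genome[["chrB"]], p, p)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      got <- annotate_variants(
        data.frame(chrom = "chrB", pos = p, ref = ref, alt = alt),
        genes, fx$genome)$consequence
      expect_identical(got, oracle_classify_cds_snp(p, alt, fx$model, fx$genome),
                       info = sprintf("pos %d %s>%s", p, ref, alt))
    }
  }
})

test_that("IDP analysis counts sizes, CDS membership, and frame class", {
  cfg <- small_config(seed = 21, cds_indel_sizes = c(3L, 6L, 9L),
                      noncoding_indel_sizes = c(1L, 2L, 4L, 7L, 10L))
  gen <- generate_genome(cfg)
  sp <- spike_variants(gen$genome, gen$genes, cfg)
  indels <- sp$truth[sp$truth$var_class %in% c("INS", "DEL") &
                       sp$truth$length <= 10, ]
  idp <- analyze_idps(indels, gen$genes)
  expect_identical(idp$size, 1:10)
  expect_identical(idp$frameshift, (1:10) %% 3 != 0)
  expect_identical(sum(idp$n_genome), nrow(indels))
  # only multiples of 3 were spiked into CDS: frameshift CDS count is 0
  expect_identical(sum(idp$n_cds[idp$frameshift]), 0L)
  expect_identical(sum(idp$n_cds), 3L)
  expect_true(all(idp$n_genes[c(3, 6, 9)] >= 1))
})

test_that("annotation summary partitions counts and reports ns/s", {
  fx <- toy_plus_fixture()
  ann <- annotate_variants(
    data.frame(chrom = "chrA", pos = c(21L, 19L, 5L, 26L, 12L),
               ref = "N", alt = c("C", "A", "G", "A", "A")),
    list(fx$model), fx$genome)
  s <- summarize_annotation(ann)
  expect_identical(s$n_total, 5L)
  expect_identical(s$n_genic + s$n_intergenic, s$n_total)
  expect_identical(unname(sum(s$by_region)), s$n_genic)
  expect_equal(s$ns_s_ratio, 1)
  # no CDS SNPs: ratio undefined
  s0 <- summarize_annotation(ann[ann$region == "intergenic", ])
  expect_true(is.na(s0$ns_s_ratio))
  # published genome-wide counts give the published ratio
  expect_equal(round(ns_s_ratio(23550, 38199 - 23550), 1), 1.6)
})

test_that("severity ordering resolves variants overlapping two genes", {
  fx <- toy_plus_fixture()
  # a second, overlapping single-exon gene whose CDS covers position 21
  other <- gene_model("gX", "gX.t1", "chrA", "+",
                      exons = rbind(c(16, 42)), cds = rbind(c(16, 42)))
  # in gA pos 21 is synonymous (GCT->GCC); classification must not downgrade
  # a more severe call from the overlapping model
  ann <- annotate_variants(
    data.frame(chrom = "chrA", pos = 21L, ref = "T", alt = "C"),
    list(fx$model, other), fx$genome)
  sev <- c(none = 0, synonymous = 1, nonsynonymous = 2, splice_disrupt = 3,
           start_loss = 4, stop_loss = 5, stop_gain = 6)
  per_gene <- c(
    annotate_variants(data.frame(chrom = "chrA", pos = 21L, ref = "T", alt = "C"),
                      list(fx$model), fx$genome)$consequence,
    annotate_variants(data.frame(chrom = "chrA", pos = 21L, ref = "T", alt = "C"),
                      list(other), fx$genome)$consequence)
  expect_identical(unname(sev[ann$consequence]), max(sev[per_gene]))
})
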