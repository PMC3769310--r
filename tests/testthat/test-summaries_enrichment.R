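test_that("window densities scale counts to per-Mb and conserve totals", {
  v <- data.frame(chrom = "c1", pos = as.integer(seq(1000, 91000, by = 10000)))
  w <- compute_window_densities(v, c(c1 = 300000L), window = 1e5)
  expect_identical(nrow(w), 3L)
  expect_identical(w$count, c(10L, 0L, 0L))
  expect_equal(w$rate_per_mb[1], 100)
  expect_identical(sum(w$count), nrow(v))
  # empty chromosome: all-zero windows
  w2 <- compute_window_densities(v[0, ], c(c2 = 250000L), window = 1e5)
  expect_identical(w2$count, c(0L, 0L, 0L))
  expect_identical(w2$end[3], 250000L)  # last window truncated
  expect_error(compute_window_densities(
    data.frame(chrom = "c1", pos = 400001L), c(c1 = 300000L)), "beyond")
})

test_that("window binning matches direct per-window counting", {
  set.seed(5)
  v <- data.frame(chrom = "c1", pos = sample.int(1e6, 2000))
  w <- compute_window_densities(v, c(c1 = 1000000L), window = 1e5)
  oracle <- vapply(seq_len(10), function(i)
    sum(v$pos >= (i - 1) * 1e5 + 1 & v$pos <= i * 1e5), 0L)
  expect_identical(w$count, oracle)
})

test_that("density regions merge maximal runs above/below thresholds", {
  mk <- function(rates) data.frame(
    chrom = "c1", start = as.integer((seq_along(rates) - 1) * 1e5 + 1),
    end = as.integer(seq_along(rates) * 1e5), count = 0L, rate_per_mb = rates)
  r <- call_density_regions(mk(c(600, 700, 650, 100, 800)))
  high <- r[r$class == "high", ]
  expect_identical(nrow(high), 2L)
  expect_identical(high$start[1], 1L)
  expect_identical(high$end[1], 300000L)  # 3 windows merged into 300 kb
  expect_identical(high$n_windows, c(3L, 1L))
  # alternating high/normal: each high window is its own region
  r2 <- call_density_regions(mk(c(600, 100, 600, 100, 600)))
  expect_identical(nrow(r2[r2$class == "high", ]), 3L)
  # uniform mid-range rates: no regions of either class
  r3 <- call_density_regions(mk(rep(100, 5)))
  expect_identical(nrow(r3), 0L)
  # low-density windows are called below the floor
  r4 <- call_density_regions(mk(c(100, 5, 100)))
  expect_identical(r4$class, "low")
})

test_that("size-class histogram reproduces the published fractions", {
  # per-class INS/DEL counts as printed: 1 bp 9,032+8,616; 2-5 bp 4,702+4,452;
  # 6-10 bp 1,312+1,331; 11-100 bp 899+2,052; >100 bp 8+3,610
  counts <- data.frame(
    n_ins = c(9032L, 4702L, 1312L, 899L, 8L),
    n_del = c(8616L, 4452L, 1331L, 2052L, 3610L),
    len = c(1L, 3L, 8L, 50L, 150L))
  calls <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) rbind(
    data.frame(var_class = "INS", length = rep(counts$len[i], counts$n_ins[i])),
    data.frame(var_class = "DEL", length = rep(counts$len[i], counts$n_del[i])))))
  h <- histogram_sv_sizes(calls)
  expect_identical(h$n_total, c(17648L, 9154L, 2643L, 2951L, 3618L))
  expect_equal(round(100 * h$fraction, 1), c(49.0, 25.4, 7.3, 8.2, 10.0))
  expect_identical(sum(h$n_total), nrow(calls))
})

test_that("size-class histogram boundaries and errors", {
  h <- histogram_sv_sizes(data.frame(var_class = "INS", length = 1L))
  expect_equal(h$fraction[1], 1)
  h2 <- histogram_sv_sizes(data.frame(var_class = c("DEL", "DEL"),
                                      length = c(5L, 6L)))
  expect_identical(h2$n_total[2:3], c(1L, 1L))
  expect_error(histogram_sv_sizes(data.frame(var_class = "DEL", length = 0L)),
               ">= 1")
})

test_that("SV-type summary reproduces the published INS+DEL percentages", {
  # per-type counts reconstructed from the published percentages and totals
  mk <- function(n) {
    types <- rep(SV <- c("INS", "DEL", "CTX", "IDE", "ITX", "INV"), n)
    data.frame(var_class = types)
  }
  yugu <- mk(c(16166L, 20165L, 417L, 287L, 149L, 48L))
  expect_identical(nrow(yugu), 37232L)
  s <- summarize_sv_types(yugu)
  expect_equal(round(attr(s, "ins_del_pct"), 1), 97.6)
  zhanggu <- mk(c(17066L, 22949L, 893L, 353L, 158L, 95L))
  expect_identical(nrow(zhanggu), 41514L)
  s2 <- summarize_sv_types(zhanggu)
  expect_equal(round(attr(s2, "ins_del_pct"), 1), 96.4)
  expect_equal(sum(s2$pct), 100)
})

test_that("Pfam enrichment chi-square matches the closed form and the floor", {
  ann <- data.frame(
    gene_id = rep(c("g1", "g2"), c(200, 29)),
    consequence = c(rep(c("nonsynonymous", "synonymous"), c(150, 50)),
                    rep(c("nonsynonymous", "synonymous"), c(20, 9))),
    region = "CDS")
  pfam <- data.frame(gene_id = c("g1", "g2"),
                     pfam_accession = c("PF00001", "PF00002"))
  res <- pfam_ns_s_enrichment(ann, pfam, background = c(23550, 14649),
                              min_count = 30)
  expect_identical(res$analyzed$pfam_accession, "PF00001")
  expect_identical(res$excluded$pfam_accession, "PF00002")  # 29 < floor
  # hand-computed: exp = 200 * (23550, 14649)/38199
  exp_counts <- 200 * c(23550, 14649) / 38199
  chi_hand <- sum((c(150, 50) - exp_counts)^2 / exp_counts)
  expect_equal(res$analyzed$chi_square, chi_hand, tolerance = 1e-12)
  expect_equal(chi_hand, 15.07, tolerance = 0.01)
  expect_true(res$analyzed$flagged)
  # independent cross-check against stats::chisq.test
  ct <- stats::chisq.test(c(150, 50), p = c(23550, 14649) / 38199,
                          correct = FALSE)
  expect_equal(res$analyzed$chi_square, unname(ct$statistic), tolerance = 1e-9)
  expect_equal(res$analyzed$p_value, ct$p.value, tolerance = 1e-9)
})

test_that("family at the background proportion has chi-square 0", {
  ann <- data.frame(gene_id = "g1",
                    consequence = rep(c("nonsynonymous", "synonymous"),
                                      c(60, 40)),
                    region = "CDS")
  pfam <- data.frame(gene_id = "g1", pfam_accession = "PF1")
  res <- pfam_ns_s_enrichment(ann, pfam, background = c(600, 400),
                              min_count = 30)
  expect_equal(res$analyzed$chi_square, 0)
  expect_false(res$analyzed$flagged)
})

test_that("enrichment ranking is invariant to scaling family counts", {
  set.seed(8)
  mk_ann <- function(scale) do.call(rbind, lapply(1:5, function(i) data.frame(
    gene_id = paste0("g", i),
    consequence = rep(c("nonsynonymous", "synonymous"),
                      scale * c(10 + 5 * i, 40 - 4 * i)),
    region = "CDS")))
  pfam <- data.frame(gene_id = paste0("g", 1:5),
                     pfam_accession = paste0("PF", 1:5))
  r1 <- pfam_ns_s_enrichment(mk_ann(1), pfam, background = c(100, 100),
                             min_count = 1)
  r2 <- pfam_ns_s_enrichment(mk_ann(3), pfam, background = c(100, 100),
                             min_count = 1)
  expect_identical(r1$analyzed$pfam_accession, r2$analyzed$pfam_accession)
})

test_that("closed-form chi-square matches chisq.test on random 2-cell tables", {
  set.seed(77)
  for (i in 1:50) {
    obs <- sample(1:500, 2)
    p <- stats::runif(1, 0.1, 0.9)
    res <- segregation_test(obs, expected = c(p, 1 - p))
    ct <- stats::chisq.test(obs, p = c(p, 1 - p), correct = FALSE)
    expect_equal(res$chi_square, unname(ct$statistic), tolerance = 1e-9)
  }
})
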