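# End-to-end orchestration on a synthetic run: simulate -> filter -> annotate
# -> summarize -> markers -> inversions -> f2 map, with a consolidated report.

#' Per-chromosome variant summary table
#'
#' Counts and per-Mb densities of SNPs, small indels and SVs per chromosome,
#' plus a totals row (densities on the totals row use the summed chromosome
#' length).
#'
#' @param snps,indels,svs Call data frames with `chrom`.
#' @param chrom_lengths Named integer vector of chromosome lengths in bp.
#' @return Data frame `chrom, length_bp, n_snp, snp_per_mb, n_indel,
#'   indel_per_mb, n_sv, sv_per_mb`.
#' @export
summarize_per_chromosome <- function(snps, indels, svs, chrom_lengths) {
  chroms <- names(chrom_lengths)
  count <- function(calls, ch) sum(calls$chrom == ch)
  rows <- lapply(chroms, function(ch) {
    len <- chrom_lengths[[ch]]
    data.frame(chrom = ch, length_bp = len,
               n_snp = count(snps, ch), snp_per_mb = count(snps, ch) / len * 1e6,
               n_indel = count(indels, ch),
               indel_per_mb = count(indels, ch) / len * 1e6,
               n_sv = count(svs, ch), sv_per_mb = count(svs, ch) / len * 1e6,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  total_len <- sum(chrom_lengths)
  tab <- rbind(tab, data.frame(
    chrom = "Total", length_bp = total_len,
    n_snp = sum(tab$n_snp), snp_per_mb = sum(tab$n_snp) / total_len * 1e6,
    n_indel = sum(tab$n_indel),
    indel_per_mb = sum(tab$n_indel) / total_len * 1e6,
    n_sv = sum(tab$n_sv), sv_per_mb = sum(tab$n_sv) / total_len * 1e6))
  rownames(tab) <- NULL
  tab
}

# Toy Pfam assignment: genes cycle through a small pool of accessions so the
# enrichment stage has multi-gene families to work with.
assign_toy_pfam <- function(genes) {
  pool <- c("PF00931", "PF00069", "PF13855", "PF00999", "PF05725")
  ids <- vapply(genes, `[[`, "", "gene_id")
  data.frame(gene_id = ids,
             pfam_accession = pool[(seq_along(ids) - 1L) %% length(pool) + 1L],
             domain_name = "synthetic_domain", stringsAsFactors = FALSE)
}

#' Run the full synthetic-data pipeline
#'
#' Generates a genome, spikes variants, filters the candidate calls, annotates
#' effects, computes the summary statistics and density scans, designs
#' SV markers, validates inversions against simulated contigs, simulates and
#' maps the F2 population, and returns a consolidated report. When `outdir`
#' is given, stage outputs (FASTA, GFF3, VCF, SV table, report TSVs) are
#' written with stable names.
#'
#' @param config A [simulation_config()].
#' @param outdir Optional output directory.
#' @param enrichment_min_count Pfam count floor used on the toy genome
#'   (default 5; the genome-scale default of 30 in
#'   [pfam_ns_s_enrichment()] would exclude every toy family).
#' @return List of report sections: `per_chromosome`, `substitution_spectrum`,
#'   `ts_tv`, `annotation_summary`, `idp_table`, `window_density`,
#'   `density_regions`, `sv_size_histogram`, `sv_type_summary`, `enrichment`,
#'   `markers`, `inversions`, `mapping_interval`, `candidate_genes`,
#'   `segregation`, `filter_reports`, `truth`.
#' @export
run_pipeline <- function(config = simulation_config(), outdir = NULL,
                         enrichment_min_count = 5) {
  gen <- generate_genome(config)
  spiked <- spike_variants(gen$genome, gen$genes, config)
  truth <- spiked$truth
  chrom_len <- genome_lengths(gen$genome)

  snp_calls <- truth[truth$var_class == "SNP", , drop = FALSE]
  sv_calls <- truth[truth$var_class != "SNP", , drop = FALSE]
  snp_f <- filter_snps(snp_calls, repeat_mask = NULL,
                       avg_depth = config$avg_depth)
  sv_f <- filter_svs(sv_calls)
  parts <- split_indels_from_svs(sv_f$passed)

  ann <- annotate_variants(snp_f$passed, gen$genes, gen$genome)
  ann_summary <- summarize_annotation(ann)
  spectrum <- substitution_spectrum(snp_f$passed)
  idp <- analyze_idps(sv_f$passed, gen$genes)
  windows <- compute_window_densities(snp_f$passed, chrom_len, window = 1e4)
  regions <- call_density_regions(windows, high = 500, low = 10)
  sv_hist <- histogram_sv_sizes(sv_f$passed)
  sv_types <- summarize_sv_types(sv_f$passed)
  pfam_map <- assign_toy_pfam(gen$genes)
  enrich <- pfam_ns_s_enrichment(ann, pfam_map,
                                 min_count = enrichment_min_count)
  markers <- select_marker_candidates(parts$svs, gen$genome)

  inv_truth <- truth[truth$var_class == "INV", , drop = FALSE]
  inv_calls <- data.frame(chrom = inv_truth$chrom,
                          start = inv_truth$pos - config$inversion_call_pad,
                          end = inv_truth$end + config$inversion_call_pad)
  contigs <- generate_inversion_contigs(
    gen$genome, inv_truth[, c("chrom", "pos", "end")] |>
      stats::setNames(c("chrom", "start", "end")), config)
  inversions <- validate_inversions(inv_calls, gen$genome, contigs)

  # the recessive locus sits inside the middle chr1 gene; the SV marker grid
  # is centred on it so the mapped interval overlaps annotated genes
  genes1 <- Filter(function(m) m$chrom == "chr1", gen$genes)
  mid_gene <- genes1[[ceiling(length(genes1) / 2)]]
  locus_pos <- as.integer(floor(mean(gene_span(mid_gene))))
  offsets <- (seq_len(config$n_markers) - (config$n_markers %/% 2L)) *
    config$marker_spacing_bp - config$marker_spacing_bp %/% 4L
  marker_pos <- stats::setNames(pmax(locus_pos + offsets, 500L),
                                paste0("SV", seq_len(config$n_markers)))
  pop <- simulate_f2(config$f2_size, marker_pos, locus_pos,
                     cm_per_bp = config$cm_per_bp, seed = config$seed + 3L)
  seg <- segregation_test(c(sum(pop$phenotype != "waxy"),
                            sum(pop$phenotype == "waxy")))
  interval <- map_recessive_locus(pop, marker_pos, chrom = "chr1")
  cand_genes <- if (!is.na(interval$left_pos) && !is.na(interval$right_pos))
    report_candidate_window(interval, gen$genes)
  else data.frame()

  report <- list(per_chromosome = summarize_per_chromosome(
                   snp_f$passed, parts$indels, parts$svs, chrom_len),
                 substitution_spectrum = spectrum,
                 ts_tv = compute_ts_tv(spectrum),
                 annotation_summary = ann_summary,
                 idp_table = idp,
                 window_density = windows,
                 density_regions = regions,
                 sv_size_histogram = sv_hist,
                 sv_type_summary = sv_types,
                 enrichment = enrich$analyzed,
                 markers = markers,
                 inversions = inversions,
                 mapping_interval = interval,
                 candidate_genes = cand_genes,
                 segregation = seg,
                 filter_reports = list(snps = snp_f$report, svs = sv_f$report),
                 truth = truth)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_genome_fasta(gen$genome, file.path(outdir, "genome.fa"))
    write_gene_models_gff3(gen$genes, file.path(outdir, "genes.gff3"))
    small <- truth[truth$var_class == "SNP" |
                     (!is.na(truth$ref) & !is.na(truth$alt)), , drop = FALSE]
    write_variants_vcf(small, file.path(outdir, "variants.vcf"))
    write_sv_table(sv_calls, file.path(outdir, "svs.tsv"))
    write_f2_table(pop, file.path(outdir, "f2_population.csv"))
    for (nm in c("per_chromosome", "idp_table", "window_density",
                 "density_regions", "sv_size_histogram", "sv_type_summary",
                 "enrichment", "markers", "inversions")) {
      utils::write.table(report[[nm]], file.path(outdir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  report
}
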