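# F2 fine mapping of a single recessive locus: seed-pool phenotype
# classification, 3:1 segregation testing, in-silico marker genotyping, and
# recombinant-class interval mapping.

#' Classify an F2 individual from its stained seed pool
#'
#' Endosperm starch staining: pink seeds are waxy (amylose-free), dark blue
#' seeds are non-waxy. All pink = waxy individual; all dark blue = non-waxy;
#' a segregating pool = heterozygous; no seeds = missing.
#'
#' @param stain_results Character vector of per-seed colors
#'   (`"pink"`/`"dark_blue"`).
#' @return One of `"waxy"`, `"non_waxy"`, `"heterozygous"`, `"missing"`.
#' @export
classify_seed_pool <- function(stain_results) {
  if (!length(stain_results)) return("missing")
  bad <- setdiff(stain_results, c("pink", "dark_blue"))
  if (length(bad)) stop("unknown stain color: ", bad[1])
  if (all(stain_results == "pink")) return("waxy")
  if (all(stain_results == "dark_blue")) return("non_waxy")
  "heterozygous"
}

#' Chi-square test of phenotype segregation against an expected ratio
#'
#' 1-df goodness-of-fit of observed (dominant, recessive) counts against the
#' expected ratio (default 3:1 for a single recessive gene).
#'
#' @param phenotype_counts Length-2 numeric: dominant-class then
#'   recessive-class count.
#' @param expected Expected ratio as a length-2 numeric (default `c(3, 1)`).
#' @param alpha Consistency threshold on the p-value (default 0.05).
#' @return List: `chi_square`, `p_value`, `consistent`.
#' @export
segregation_test <- function(phenotype_counts, expected = c(3, 1),
                             alpha = 0.05) {
  if (sum(phenotype_counts) <= 0) stop("no phenotyped individuals")
  chi <- chi_square_2cell(phenotype_counts, expected / sum(expected))
  list(chi_square = chi$statistic, p_value = chi$p_value,
       consistent = chi$p_value >= alpha)
}

#' Genotype an individual from PCR band sizes
#'
#' A length-polymorphic marker distinguishes the two parental alleles by band
#' size; a homozygote shows one band, a heterozygote both. Uninformative
#' markers (equal allele bands) yield `missing`.
#'
#' @param bands Numeric vector of observed band sizes for the individual.
#' @param a_band Band size of the A (recessive-parent) allele.
#' @param b_band Band size of the B allele.
#' @return One of `"AA"`, `"AB"`, `"BB"`, `"missing"`.
#' @export
genotype_marker_in_silico <- function(bands, a_band, b_band) {
  if (a_band == b_band) return("missing")
  bands <- unique(bands)
  has_a <- a_band %in% bands
  has_b <- b_band %in% bands
  if (has_a && has_b) return("AB")
  if (has_a) return("AA")
  if (has_b) return("BB")
  "missing"
}

#' Map a recessive locus by the recombinant-class method
#'
#' Uses only phenotypically recessive (waxy) individuals, which are homozygous
#' AA at the locus: for each marker the recombinants are the waxy individuals
#' whose marker genotype is not AA. The locus interval is bounded by the
#' nearest markers flanking the zero-recombinant marker(s) that show at least
#' one recombinant. When no marker co-segregates perfectly, the
#' minimum-recombinant marker is used as the inner anchor with a warning.
#'
#' @param population Data frame with `phenotype` and one genotype column per
#'   marker (as from [simulate_f2()] or [read_f2_table()]).
#' @param marker_positions Named integer vector of marker positions (bp),
#'   names matching the genotype columns.
#' @param chrom Chromosome name for the report.
#' @return A `mapping_interval` list: `chrom, left_marker, right_marker,
#'   left_pos, right_pos, span_bp, cosegregating, recombinants` (per-marker
#'   counts among waxy individuals).
#' @export
map_recessive_locus <- function(population, marker_positions, chrom = NA) {
  waxy <- population[population$phenotype == "waxy", , drop = FALSE]
  if (!nrow(waxy)) stop("no phenotypically recessive (waxy) individuals")
  ord <- order(marker_positions)
  markers <- names(marker_positions)[ord]
  pos <- marker_positions[ord]
  rec <- vapply(markers, function(m) {
    g <- waxy[[m]]
    sum(g != "AA" & g != "missing", na.rm = TRUE)
  }, 0L)
  zero <- which(rec == min(rec))
  if (min(rec) > 0)
    warning("no marker co-segregates perfectly; using minimum-recombinant marker")
  inner_lo <- min(zero)
  inner_hi <- max(zero)
  left_idx <- if (inner_lo > 1) max(which(rec[seq_len(inner_lo - 1)] >= 1)) else NA
  right_idx <- if (inner_hi < length(rec))
    inner_hi + min(which(rec[(inner_hi + 1):length(rec)] >= 1)) else NA
  left_pos <- if (is.na(left_idx)) NA_integer_ else unname(pos[left_idx])
  right_pos <- if (is.na(right_idx)) NA_integer_ else unname(pos[right_idx])
  structure(list(
    chrom = chrom,
    left_marker = if (is.na(left_idx)) NA_character_ else markers[left_idx],
    right_marker = if (is.na(right_idx)) NA_character_ else markers[right_idx],
    left_pos = left_pos, right_pos = right_pos,
    span_bp = if (is.na(left_pos) || is.na(right_pos)) NA_integer_
              else right_pos - left_pos,
    cosegregating = markers[zero][rec[zero] == 0],
    recombinants = rec), class = "mapping_interval")
}

#' @exportS3Method base::print
print.mapping_interval <- function(x, ...) {
  cat(sprintf("<mapping_interval> %s: %s (%s) -- %s (%s), span %s bp\n",
              x$chrom, x$left_marker, x$left_pos, x$right_marker, x$right_pos,
              x$span_bp))
  cat("  co-segregating:", paste(x$cosegregating, collapse = ", "), "\n")
  invisible(x)
}

#' Genes overlapping a mapping interval
#'
#' @param interval A `mapping_interval` from [map_recessive_locus()], or a
#'   list with `chrom`, `left_pos`, `right_pos`.
#' @param gene_models List of [gene_model()]s.
#' @return Data frame `gene_id, chrom, start, end`, ordered by position; a
#'   gene bisected by an interval boundary is included (overlap rule).
#' @export
report_candidate_window <- function(interval, gene_models) {
  rows <- lapply(gene_models, function(m) {
    if (!is.na(interval$chrom) && m$chrom != interval$chrom) return(NULL)
    sp <- gene_span(m)
    if (sp[2] < interval$left_pos || sp[1] > interval$right_pos) return(NULL)
    data.frame(gene_id = m$gene_id, chrom = m$chrom, start = sp[1],
               end = sp[2], stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows))
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$start), ]
  rownames(out) <- NULL
  out
}
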