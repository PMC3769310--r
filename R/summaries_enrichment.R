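# Window-based density scans, SV size-class histograms, SV-type summaries,
# and per-Pfam ns/s chi-square enrichment.

#' Tile variants into fixed windows and compute densities
#'
#' Windows tile each chromosome without overlap (the last window may be
#' shorter); rates are scaled to per-Mb (`count * 1e6 / window`).
#'
#' @param variants Data frame with `chrom` and `pos` (pre-filter by type if a
#'   per-type scan is wanted).
#' @param chrom_lengths Named integer vector of chromosome lengths in bp.
#' @param window Window width in bp (default 100 kb).
#' @return Data frame `chrom, start, end, count, rate_per_mb`.
#' @export
compute_window_densities <- function(variants, chrom_lengths, window = 1e5) {
  out <- list()
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    pos <- variants$pos[variants$chrom == ch]
    if (length(pos) && any(pos < 1 | pos > len))
      stop("variant position beyond chromosome end on ", ch)
    window <- as.integer(window)
    n_win <- as.integer(ceiling(len / window))
    counts <- tabulate(floor((pos - 1) / window) + 1L, nbins = n_win)
    start <- (seq_len(n_win) - 1L) * window + 1L
    out[[ch]] <- data.frame(chrom = ch, start = start,
                            end = pmin(start + window - 1L, len),
                            count = counts,
                            rate_per_mb = counts * 1e6 / window,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call high- and low-density regions from a window scan
#'
#' Maximal runs of consecutive windows with rate above `high` (below `low`)
#' are merged into regions.
#'
#' @param windows Data frame from [compute_window_densities()].
#' @param high Per-Mb rate above which a window is high-density (default 500,
#'   strict `>`).
#' @param low Per-Mb rate below which a window is low-density (default 10,
#'   strict `<`).
#' @return Data frame `chrom, start, end, class, n_windows, mean_rate`.
#' @export
call_density_regions <- function(windows, high = 500, low = 10) {
  regions <- list()
  for (cls in c("high", "low")) {
    flag <- if (cls == "high") windows$rate_per_mb > high
            else windows$rate_per_mb < low
    for (ch in unique(windows$chrom)) {
      sel <- windows$chrom == ch
      f <- flag[sel]
      w <- windows[sel, , drop = FALSE]
      r <- rle(f)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        i <- starts[k]:ends[k]
        regions[[length(regions) + 1L]] <-
          data.frame(chrom = ch, start = w$start[starts[k]],
                     end = w$end[ends[k]], class = cls,
                     n_windows = length(i), mean_rate = mean(w$rate_per_mb[i]),
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(regions))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), class = character(0),
                      n_windows = integer(0), mean_rate = numeric(0)))
  res <- do.call(rbind, regions)
  res[order(res$class, res$chrom, res$start), ]
}

SV_SIZE_CLASSES <- c("1", "2-5", "6-10", "11-100", ">100")

#' Size-class histogram of INS/DEL variants
#'
#' Lengths are partitioned into the five classes 1, 2-5, 6-10, 11-100 and
#' >100 bp; class counts sum to the input size.
#'
#' @param ins_dels Data frame of INS/DEL calls with `var_class` and `length`.
#' @return Data frame `size_class, n_ins, n_del, n_total, fraction` (fraction
#'   of the grand total, full precision).
#' @export
histogram_sv_sizes <- function(ins_dels) {
  calls <- ins_dels[ins_dels$var_class %in% c("INS", "DEL"), , drop = FALSE]
  if (any(calls$length < 1)) stop("INS/DEL length must be >= 1")
  cls <- cut(calls$length, breaks = c(0, 1, 5, 10, 100, Inf),
             labels = SV_SIZE_CLASSES)
  n_ins <- as.integer(table(cls[calls$var_class == "INS"]))
  n_del <- as.integer(table(cls[calls$var_class == "DEL"]))
  n_total <- n_ins + n_del
  data.frame(size_class = SV_SIZE_CLASSES, n_ins = n_ins, n_del = n_del,
             n_total = n_total, fraction = n_total / sum(n_total),
             stringsAsFactors = FALSE)
}

#' Per-type summary of an SV set
#'
#' @param calls Data frame of SV calls with `var_class` in the six-type
#'   enumeration (INS, DEL, CTX, IDE, ITX, INV).
#' @return Data frame `type, n, pct` over all six types, plus an
#'   `ins_del_pct` attribute (INS% + DEL%).
#' @export
summarize_sv_types <- function(calls) {
  counts <- table(factor(calls$var_class, levels = SV_TYPES))
  n <- as.integer(counts)
  pct <- 100 * n / sum(n)
  out <- data.frame(type = SV_TYPES, n = n, pct = pct, stringsAsFactors = FALSE)
  attr(out, "ins_del_pct") <- sum(pct[SV_TYPES %in% c("INS", "DEL")])
  out
}

# 1-df goodness-of-fit chi-square of observed (ns, s) against background
# proportions; optional Yates continuity correction.
chi_square_2cell <- function(obs, expected_prop, correct = FALSE) {
  exp <- sum(obs) * expected_prop
  dev <- abs(obs - exp)
  if (correct) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / exp)
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Per-Pfam ns/s enrichment
#'
#' For every Pfam family with at least `min_count` nonsynonymous plus
#' synonymous CDS SNPs, the observed (ns, s) split is tested against the
#' genome-wide background proportions with a 1-df goodness-of-fit chi-square
#' (no continuity correction by default). A gene carrying several domains
#' contributes its SNPs to each family. Families are ranked by ns/s ratio.
#'
#' @param annotations Data frame from [annotate_variants()].
#' @param pfam_map Data frame `gene_id, pfam_accession` (and optionally
#'   `domain_name`).
#' @param background Length-2 numeric `(ns, s)` genome-wide totals; defaults to
#'   the totals of `annotations`.
#' @param min_count Count floor for analysis (default 30).
#' @param correct Apply the Yates continuity correction.
#' @param flag_p Significance threshold for the `flagged` column
#'   (default 0.001).
#' @return List with `analyzed` (data frame sorted by descending ns/s ratio:
#'   `pfam_accession, n_nonsyn, n_syn, ns_s_ratio, chi_square, p_value,
#'   flagged`) and `excluded` (families below the floor).
#' @export
pfam_ns_s_enrichment <- function(annotations, pfam_map, background = NULL,
                                 min_count = 30, correct = FALSE,
                                 flag_p = 0.001) {
  cds <- annotations[annotations$consequence %in%
                       c("synonymous", "nonsynonymous"), , drop = FALSE]
  if (is.null(background))
    background <- c(sum(cds$consequence == "nonsynonymous"),
                    sum(cds$consequence == "synonymous"))
  bg_prop <- background / sum(background)
  joined <- merge(cds, pfam_map[, c("gene_id", "pfam_accession")],
                  by = "gene_id")
  fams <- unique(joined$pfam_accession)
  rows <- lapply(fams, function(f) {
    sub <- joined[joined$pfam_accession == f, ]
    ns <- sum(sub$consequence == "nonsynonymous")
    s <- sum(sub$consequence == "synonymous")
    chi <- chi_square_2cell(c(ns, s), bg_prop, correct = correct)
    data.frame(pfam_accession = f, n_nonsyn = ns, n_syn = s,
               ns_s_ratio = if (s > 0) ns / s else NA_real_,
               chi_square = chi$statistic, p_value = chi$p_value,
               flagged = chi$p_value < flag_p, stringsAsFactors = FALSE)
  })
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pfam_accession = character(0), n_nonsyn = integer(0),
               n_syn = integer(0), ns_s_ratio = numeric(0),
               chi_square = numeric(0), p_value = numeric(0),
               flagged = logical(0))
  total <- res$n_nonsyn + res$n_syn
  analyzed <- res[total >= min_count, , drop = FALSE]
  analyzed <- analyzed[order(-analyzed$ns_s_ratio), ]
  rownames(analyzed) <- NULL
  excluded <- res[total < min_count, , drop = FALSE]
  rownames(excluded) <- NULL
  list(analyzed = analyzed, excluded = excluded)
}
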