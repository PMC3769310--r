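# Acceptance filtering of candidate SNP and SV calls.
#
# Thresholds follow the re-sequencing study's screening criteria: SNPs need
# depth >= 2 (>= 3 at heterozygous loci), depth <= 3x the genome-wide average,
# and must fall outside the repeat mask; SVs need depth in [2, 100] and
# quality strictly above 20. "No less than"/"no more than" are read as
# inclusive, "more than 20" as strict.

#' Filter candidate SNP calls
#'
#' @param calls Data frame of SNP calls (`chrom, pos, depth, zygosity`, ...).
#' @param repeat_mask Optional data frame `chrom, start, end` (1-based closed)
#'   of repeat intervals; SNPs inside are discarded.
#' @param avg_depth Genome-wide average sequencing depth (the study's value is
#'   ~11x); must be positive.
#' @param min_depth,min_het_depth,max_depth_multiple Threshold overrides.
#' @return List with `passed` (data frame) and `report` (a `filter_report`:
#'   `n_input`, `n_passed`, and rejection counts by rule). Rejection reasons,
#'   in order of precedence: `missing_depth`, `min_depth`, `max_depth`,
#'   `repeat_region`.
#' @export
filter_snps <- function(calls, repeat_mask = NULL, avg_depth,
                        min_depth = 2, min_het_depth = 3,
                        max_depth_multiple = 3) {
  if (avg_depth <= 0) stop("avg_depth must be positive")
  if (nrow(calls) && any(calls$var_class != "SNP"))
    stop("filter_snps expects SNP calls only")
  n <- nrow(calls)
  reason <- rep(NA_character_, n)
  need <- ifelse(calls$zygosity == "het", min_het_depth, min_depth)
  reason[is.na(calls$depth)] <- "missing_depth"
  sel <- is.na(reason) & calls$depth < need
  reason[sel] <- "min_depth"
  sel <- is.na(reason) & calls$depth > max_depth_multiple * avg_depth
  reason[sel] <- "max_depth"
  if (!is.null(repeat_mask) && nrow(repeat_mask)) {
    in_rep <- vapply(seq_len(n), function(i) {
      rm <- repeat_mask[repeat_mask$chrom == calls$chrom[i], , drop = FALSE]
      nrow(rm) > 0 && any(calls$pos[i] >= rm$start & calls$pos[i] <= rm$end)
    }, TRUE)
    reason[is.na(reason) & in_rep] <- "repeat_region"
  }
  build_filter_result(calls, reason)
}

#' Filter candidate SV calls
#'
#' @param calls Data frame of SV-class calls (`depth`, `quality`, ...).
#' @param depth_range Inclusive depth bounds (default 2 to 100).
#' @param min_quality Quality must be strictly greater than this (default 20).
#' @return List with `passed` and `report`, as in [filter_snps()]. Reasons:
#'   `missing_field`, `depth_range`, `quality`.
#' @export
filter_svs <- function(calls, depth_range = c(2, 100), min_quality = 20) {
  if (nrow(calls) && any(calls$var_class == "SNP"))
    stop("filter_svs expects SV-class calls only")
  n <- nrow(calls)
  reason <- rep(NA_character_, n)
  reason[is.na(calls$depth) | is.na(calls$quality)] <- "missing_field"
  sel <- is.na(reason) &
    (calls$depth < depth_range[1] | calls$depth > depth_range[2])
  reason[sel] <- "depth_range"
  sel <- is.na(reason) & calls$quality <= min_quality
  reason[sel] <- "quality"
  build_filter_result(calls, reason)
}

build_filter_result <- function(calls, reason) {
  passed <- calls[is.na(reason), , drop = FALSE]
  rejected <- calls[!is.na(reason), , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reason[!is.na(reason)]
  counts <- table(factor(reason[!is.na(reason)]))
  report <- structure(
    list(n_input = nrow(calls), n_passed = nrow(passed),
         rejections = stats::setNames(as.integer(counts), names(counts))),
    class = "filter_report")
  list(passed = passed, rejected = rejected, report = report)
}

#' @exportS3Method base::print
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %d input, %d passed, %d rejected\n",
              x$n_input, x$n_passed, x$n_input - x$n_passed))
  for (r in names(x$rejections))
    cat(sprintf("  %-15s %d\n", r, x$rejections[[r]]))
  invisible(x)
}

#' Split small indels from structural variants by length
#'
#' Insertions and deletions of 1-5 bp are indel polymorphisms (InDels); longer
#' INS/DEL and every other SV type stay in the SV set. The partition is exact.
#'
#' @param calls Data frame of filtered calls.
#' @param indel_max_len Upper length bound for the indel set (default 5 bp).
#' @return List with `indels` and `svs`.
#' @export
split_indels_from_svs <- function(calls, indel_max_len = 5) {
  is_indel <- calls$var_class %in% c("INS", "DEL") &
    calls$length >= 1 & calls$length <= indel_max_len
  list(indels = calls[is_indel, , drop = FALSE],
       svs = calls[!is_indel, , drop = FALSE])
}

#' Merge SV candidate lists from two callers
#'
#' Union with duplicates removed: two records are duplicates when chromosome
#' and type match and both start coordinates agree within `tolerance` bp. The
#' merged record keeps the coordinates of the higher-quality member.
#'
#' @param list_a,list_b Call data frames (same columns).
#' @param tolerance Coordinate agreement window in bp (default 10).
#' @param mode `"union"` (default) or `"intersection"` (keep only calls seen by
#'   both callers).
#' @return Merged data frame.
#' @export
merge_caller_candidates <- function(list_a, list_b, tolerance = 10,
                                    mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  if (!nrow(list_a)) return(if (mode == "union") list_b else list_a)
  if (!nrow(list_b)) return(if (mode == "union") list_a else list_b)
  matched_b <- rep(NA_integer_, nrow(list_b))
  out <- list_a
  for (j in seq_len(nrow(list_b))) {
    cand <- which(out$chrom == list_b$chrom[j] &
                    out$var_class == list_b$var_class[j] &
                    abs(out$pos - list_b$pos[j]) <= tolerance)
    if (length(cand)) {
      i <- cand[which.min(abs(out$pos[cand] - list_b$pos[j]))]
      matched_b[j] <- i
      if (!is.na(list_b$quality[j]) &&
          (is.na(out$quality[i]) || list_b$quality[j] > out$quality[i]))
        out[i, ] <- list_b[j, ]
    }
  }
  if (mode == "union") {
    rbind(out, list_b[is.na(matched_b), , drop = FALSE])
  } else {
    out[unique(matched_b[!is.na(matched_b)]), , drop = FALSE]
  }
}
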