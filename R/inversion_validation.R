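# Inversion confirmation from contig alignments: HSP filtering and
# plus/reverse strand coverage ratios. The naive exact-match aligner is for
# synthetic tests; production input is an external HSP table
# (read_hsp_table()).

#' Filter HSPs by the alignment acceptance cut-offs
#'
#' Keeps HSPs with e-value at most `max_evalue`, identity at least
#' `min_identity` percent, and alignment length at least `min_length` bp
#' (defaults: 1e-20, 98, 200).
#'
#' @param hsps Data frame as from [read_hsp_table()] or
#'   [align_contigs_naive()].
#' @param max_evalue,min_identity,min_length Cut-offs.
#' @return The passing subset.
#' @export
filter_hsps <- function(hsps, max_evalue = 1e-20, min_identity = 98,
                        min_length = 200) {
  keep <- hsps$e_value <= max_evalue &
    hsps$percent_identity >= min_identity &
    hsps$alignment_length >= min_length
  hsps[keep, , drop = FALSE]
}

#' Plus/reverse strand coverage of an inversion segment
#'
#' Per strand, the union of HSP query intervals (clipped to the segment)
#' divided by the segment length. An inversion is confirmed when both the
#' plus and the reverse ratio exceed their floors (default: strictly
#' positive, i.e. matches on both strands).
#'
#' @param inversion_length Length of the query segment in bp (> 0).
#' @param hsps Data frame with `q_start`, `q_end`, `strand`.
#' @param plus_floor,reverse_floor Ratio floors (strict `>`).
#' @return List: `plus_ratio`, `reverse_ratio`, `confirmed`.
#' @export
strand_coverage <- function(inversion_length, hsps, plus_floor = 0,
                            reverse_floor = 0) {
  if (inversion_length <= 0) stop("inversion length must be positive")
  ratio <- function(strand) {
    sub <- hsps[hsps$strand == strand, , drop = FALSE]
    if (!nrow(sub)) return(0)
    lo <- pmax(pmin(sub$q_start, sub$q_end), 1)
    hi <- pmin(pmax(sub$q_start, sub$q_end), inversion_length)
    ok <- hi >= lo
    if (!any(ok)) return(0)
    ir <- IRanges::reduce(IRanges::IRanges(lo[ok], hi[ok]))
    sum(IRanges::width(ir)) / inversion_length
  }
  plus <- ratio("plus")
  rev <- ratio("reverse")
  list(plus_ratio = plus, reverse_ratio = rev,
       confirmed = plus > plus_floor && rev > reverse_floor)
}

#' Naive exact-match contig aligner
#'
#' Seed-and-extend on shared k-mers, both strands: maximal exact matches of at
#' least `min_match` bp between the query segment and each contig are emitted
#' as HSP records in the same schema as [read_hsp_table()] (identity 100,
#' e-value 0). Intended for synthetic-data tests in place of an external
#' similarity search.
#'
#' @param query_seq Query (inversion segment) sequence.
#' @param contigs Named character vector of contig sequences.
#' @param k Seed k-mer size (default 31).
#' @param min_match Minimum match length to report (default `k`).
#' @param query_id Query identifier for the HSP records.
#' @return HSP data frame with a `strand` column (`plus`/`reverse`).
#' @export
align_contigs_naive <- function(query_seq, contigs, k = 31, min_match = k,
                                query_id = "query") {
  k <- as.integer(k)
  qn <- nchar(query_seq)
  if (qn < k) return(empty_hsps())
  qstarts <- seq_len(qn - k + 1L)
  qk <- substring(query_seq, qstarts, qstarts + k - 1L)
  qmap <- split(qstarts, qk)
  rows <- list()
  for (cn in names(contigs)) {
    for (strand in c("plus", "reverse")) {
      s <- if (strand == "plus") contigs[[cn]] else revcomp(contigs[[cn]])
      sn <- nchar(s)
      if (sn < k) next
      sstarts <- seq_len(sn - k + 1L)
      sk <- substring(s, sstarts, sstarts + k - 1L)
      hit <- sk %in% names(qmap)
      if (!any(hit)) next
      anchors <- do.call(rbind, lapply(which(hit), function(j) {
        cbind(q = qmap[[sk[j]]], s = j)
      }))
      diag <- anchors[, "q"] - anchors[, "s"]
      for (d in unique(diag)) {
        qpos <- sort(anchors[diag == d, "q"])
        runs <- split(qpos, cumsum(c(1L, diff(qpos) != 1L)))
        for (run in runs) {
          q1 <- run[1]; q2 <- run[length(run)] + k - 1L
          len <- q2 - q1 + 1L
          if (len < min_match) next
          s1 <- q1 - d; s2 <- q2 - d
          if (strand == "reverse") {  # map back to original contig coords
            tmp <- sn - s1 + 1L
            s1 <- sn - s2 + 1L
            s2 <- tmp
          }
          rows[[length(rows) + 1L]] <- data.frame(
            query_id = query_id, subject_id = cn, percent_identity = 100,
            alignment_length = as.integer(len), mismatches = 0L,
            gap_opens = 0L, q_start = as.integer(q1), q_end = as.integer(q2),
            s_start = as.integer(if (strand == "plus") s1 else s2),
            s_end = as.integer(if (strand == "plus") s2 else s1),
            e_value = 0, bit_score = 2 * len, strand = strand,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) return(empty_hsps())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_hsps <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             percent_identity = numeric(0), alignment_length = integer(0),
             mismatches = integer(0), gap_opens = integer(0),
             q_start = integer(0), q_end = integer(0), s_start = integer(0),
             s_end = integer(0), e_value = numeric(0), bit_score = numeric(0),
             strand = character(0), stringsAsFactors = FALSE)
}

#' Validate candidate inversions against contigs
#'
#' For each candidate call the query segment is extracted from the reference,
#' aligned to the contigs with [align_contigs_naive()], filtered with
#' [filter_hsps()], and scored with [strand_coverage()]. Candidate calls
#' typically carry some breakpoint imprecision, so the query includes
#' non-inverted margin that contributes the plus-strand matches.
#'
#' @param inversion_calls Data frame `chrom, start, end` of candidate calls
#'   (reference coordinates, padding included).
#' @param genome Named [Biostrings::DNAStringSet] or character vector.
#' @param contigs Named character vector of contig sequences.
#' @param k Seed size for the naive aligner.
#' @param min_length HSP length cut-off (default 200).
#' @param plus_floor,reverse_floor Confirmation floors for [strand_coverage()].
#' @return Data frame: `id, chrom, start, end, length, plus_ratio,
#'   reverse_ratio, confirmed`.
#' @export
validate_inversions <- function(inversion_calls, genome, contigs, k = 31,
                                min_length = 200, plus_floor = 0,
                                reverse_floor = 0) {
  if (methods::is(genome, "DNAStringSet"))
    genome <- stats::setNames(as.character(genome), names(genome))
  rows <- lapply(seq_len(nrow(inversion_calls)), function(i) {
    r <- inversion_calls[i, ]
    query <- substring(genome[[r$chrom]], r$start, r$end)
    hsps <- align_contigs_naive(query, contigs, k = k,
                                query_id = sprintf("inv_%d", i))
    passed <- filter_hsps(hsps, min_length = min_length)
    cov <- strand_coverage(nchar(query), passed, plus_floor, reverse_floor)
    data.frame(id = sprintf("inv_%d", i), chrom = r$chrom, start = r$start,
               end = r$end, length = nchar(query),
               plus_ratio = cov$plus_ratio, reverse_ratio = cov$reverse_ratio,
               confirmed = cov$confirmed, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
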