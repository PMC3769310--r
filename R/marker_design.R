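# SV-derived PCR length-marker design: select INS/DEL by length class, check
# flank uniqueness by exact k-mer counting, and predict allele band sizes.

#' Select SV-derived marker candidates
#'
#' Keeps INS/DEL calls with `min_len <= length <= max_len` (other SV types are
#' excluded), extracts flanking sequence, checks flank uniqueness and predicts
#' allele band sizes with primer anchors at the outer flank edges. The band
#' size difference always equals the SV length.
#'
#' @param svs Filtered SV data frame (`chrom, pos, end, var_class, length`).
#' @param genome Named [Biostrings::DNAStringSet] or character vector.
#' @param min_len,max_len Length-class bounds in bp (default 100-400, the
#'   range convenient for agarose-resolvable PCR markers).
#' @param flank Flank width per side in bp (default 300).
#' @param k K-mer size for the uniqueness check (default 31).
#' @return Data frame: `id, chrom, pos, type, sv_length, length_class,
#'   unique_flanks, flank_truncated, ref_band, alt_band`.
#' @export
select_marker_candidates <- function(svs, genome, min_len = 100, max_len = 400,
                                     flank = 300, k = 31) {
  if (methods::is(genome, "DNAStringSet"))
    genome_chr <- stats::setNames(as.character(genome), names(genome))
  else genome_chr <- genome
  sel <- svs$var_class %in% c("INS", "DEL") &
    svs$length >= min_len & svs$length <= max_len
  cand <- svs[sel, , drop = FALSE]
  if (!nrow(cand))
    return(data.frame(id = character(0), chrom = character(0), pos = integer(0),
                      type = character(0), sv_length = integer(0),
                      length_class = character(0), unique_flanks = logical(0),
                      flank_truncated = logical(0), ref_band = integer(0),
                      alt_band = integer(0)))
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    r <- cand[i, ]
    span_end <- if (r$var_class == "DEL") r$end else r$pos
    fl <- extract_flanks(genome_chr, r$chrom, r$pos, span_end, flank)
    uq <- check_flank_uniqueness(genome_chr, fl$left, fl$right, k = k)
    anchors <- c(max(r$pos - flank, 1L), span_end + nchar(fl$right))
    bands <- predict_band_sizes(r$var_class, r$length, anchors[1], anchors[2],
                                r$pos, span_end)
    data.frame(id = sprintf("%s_SV_%d", r$chrom, r$pos), chrom = r$chrom,
               pos = r$pos, type = r$var_class, sv_length = r$length,
               length_class = if (r$length <= 200) "100-200" else "100-400",
               unique_flanks = uq$unique, flank_truncated = fl$truncated,
               ref_band = bands[1], alt_band = bands[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

extract_flanks <- function(genome_chr, chrom, pos, span_end, flank) {
  seq <- genome_chr[[chrom]]
  left_start <- max(pos - flank, 1L)
  right_end <- min(span_end + flank, nchar(seq))
  list(left = substring(seq, left_start, pos - 1L),
       right = substring(seq, span_end + 1L, right_end),
       truncated = left_start > pos - flank || right_end < span_end + flank)
}

#' Check marker flank uniqueness by exact k-mer counting
#'
#' True iff every k-mer of both flanks occurs exactly once in the genome
#' across both strands. Flanks shorter than `flank` (chromosome-end
#' truncation) are evaluated on the available sequence.
#'
#' @param genome Named [Biostrings::DNAStringSet] or character vector.
#' @param left_flank,right_flank Flank sequences.
#' @param k K-mer size; must not exceed either flank length (default 31, odd
#'   so no k-mer is its own reverse complement).
#' @return List with `unique` (logical) and `max_count` (the largest k-mer
#'   occurrence count seen).
#' @export
check_flank_uniqueness <- function(genome, left_flank, right_flank, k = 31) {
  if (!methods::is(genome, "DNAStringSet")) {
    nms <- names(genome)
    genome <- Biostrings::DNAStringSet(unlist(genome))
    names(genome) <- nms
  }
  flanks <- c(left_flank, right_flank)
  flanks <- flanks[nchar(flanks) > 0]
  if (any(nchar(flanks) < k))
    stop("k (", k, ") larger than flank length")
  kmers <- unlist(lapply(flanks, function(f) {
    starts <- seq_len(nchar(f) - k + 1L)
    substring(f, starts, starts + k - 1L)
  }))
  kmers <- unique(kmers)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers))
  fwd <- Biostrings::vcountPDict(pd, genome)
  rev <- Biostrings::vcountPDict(pd, Biostrings::reverseComplement(genome))
  totals <- rowSums(fwd) + rowSums(rev)
  list(unique = all(totals == 1L), max_count = max(totals))
}

#' Predict PCR band sizes for a marker candidate
#'
#' The reference band is the distance between the primer anchors on the
#' reference allele; the variant band differs by the SV length (+ for INS,
#' - for DEL).
#'
#' @param type `"INS"` or `"DEL"`.
#' @param sv_length SV length in bp.
#' @param anchor_left,anchor_right Primer anchor positions (1-based,
#'   reference coordinates); they must flank the SV.
#' @param sv_start,sv_end SV span on the reference (for INS both equal the
#'   insertion anchor base).
#' @return Integer vector `c(ref_size, alt_size)`.
#' @export
predict_band_sizes <- function(type, sv_length, anchor_left, anchor_right,
                               sv_start, sv_end = sv_start) {
  if (!type %in% c("INS", "DEL")) stop("band prediction is for INS/DEL only")
  if (anchor_left > sv_start || anchor_right < sv_end)
    stop("primer anchors do not flank the SV")
  ref_size <- anchor_right - anchor_left + 1L
  alt_size <- if (type == "INS") ref_size + sv_length else ref_size - sv_length
  c(ref_size = as.integer(ref_size), alt_size = as.integer(alt_size))
}
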