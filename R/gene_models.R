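# Gene model container: one transcript with genomic-coordinate exons/CDS.
# All coordinates are 1-based closed; minus-strand models keep genomic
# coordinates and reverse-complementation happens only inside codon extraction.

#' Construct a gene model
#'
#' A gene model is one transcript on a named chromosome: sorted, non-overlapping
#' exons, the CDS segments they contain, and the UTR remainders. Coordinates are
#' genomic, 1-based and closed on both ends regardless of strand; accessors that
#' need transcription order ([cds_positions()], [cds_sequence()]) handle the
#' strand flip internally.
#'
#' @param gene_id,transcript_id Identifiers.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons,cds,utr5,utr3 Two-column integer matrices (`start`, `end`),
#'   possibly zero-row. `cds` must lie within `exons`.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, transcript_id, chrom, strand, exons,
                       cds = empty_intervals(), utr5 = empty_intervals(),
                       utr3 = empty_intervals()) {
  stopifnot(strand %in% c("+", "-"))
  exons <- as_interval_matrix(exons)
  cds <- as_interval_matrix(cds)
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (nrow(cds)) cds <- cds[order(cds[, 1]), , drop = FALSE]
  if (any(exons[, 2] < exons[, 1])) stop("exon end before start in ", transcript_id)
  if (nrow(exons) > 1 && any(exons[-1, 1] <= exons[-nrow(exons), 2]))
    stop("overlapping exons in ", transcript_id)
  for (i in seq_len(nrow(cds))) {
    inside <- any(cds[i, 1] >= exons[, 1] & cds[i, 2] <= exons[, 2])
    if (!inside)
      stop("CDS segment outside exon bounds in transcript ", transcript_id)
  }
  structure(
    list(gene_id = gene_id, transcript_id = transcript_id, chrom = chrom,
         strand = strand, exons = exons, cds = cds,
         utr5 = as_interval_matrix(utr5), utr3 = as_interval_matrix(utr3)),
    class = "gene_model")
}

empty_intervals <- function() {
  matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
}

as_interval_matrix <- function(x) {
  if (is.null(x) || (is.matrix(x) && nrow(x) == 0) || length(x) == 0)
    return(empty_intervals())
  x <- matrix(as.integer(x), ncol = 2)
  colnames(x) <- c("start", "end")
  x
}

#' @exportS3Method base::print
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %s:%d-%d strand %s, %d exon(s), CDS %d bp\n",
              x$transcript_id, x$gene_id, x$chrom,
              gene_span(x)[1], gene_span(x)[2], x$strand,
              nrow(x$exons), cds_length(x)))
  invisible(x)
}

#' Genomic span of a gene model
#' @param model A `gene_model`.
#' @return Integer vector `c(start, end)`.
#' @export
gene_span <- function(model) c(min(model$exons[, 1]), max(model$exons[, 2]))

#' Is a gene model protein coding?
#' @param model A `gene_model`.
#' @export
is_coding <- function(model) nrow(model$cds) > 0

#' Total CDS length in bp
#' @param model A `gene_model`.
#' @export
cds_length <- function(model) {
  if (!is_coding(model)) return(0L)
  sum(model$cds[, 2] - model$cds[, 1] + 1L)
}

#' Introns of a gene model
#'
#' Gaps between consecutive exons, in genomic order.
#'
#' @param model A `gene_model`.
#' @return Two-column matrix of 1-based closed intervals (zero rows for
#'   single-exon models).
#' @export
introns <- function(model) {
  n <- nrow(model$exons)
  if (n < 2) return(empty_intervals())
  cbind(start = model$exons[-n, 2] + 1L, end = model$exons[-1, 1] - 1L)
}

#' Genomic positions of the CDS in transcription order
#'
#' For plus-strand models positions ascend; for minus-strand models they
#' descend, so element `i` is the genomic position of coding base `i` of the
#' transcript.
#'
#' @param model A coding `gene_model`.
#' @return Integer vector of genomic positions.
#' @export
cds_positions <- function(model) {
  if (!is_coding(model)) stop("non-coding model has no CDS positions")
  segs <- model$cds
  pos <- unlist(lapply(seq_len(nrow(segs)),
                       function(i) seq.int(segs[i, 1], segs[i, 2])))
  if (model$strand == "-") rev(pos) else pos
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Spliced CDS sequence of a gene model
#'
#' @param model A coding `gene_model`.
#' @param genome A named [Biostrings::DNAStringSet] (or named character vector)
#'   containing `model$chrom`.
#' @return Character scalar: the coding sequence 5'→3' on the transcript.
#' @export
cds_sequence <- function(model, genome) {
  seq <- genome_chrom_string(genome, model$chrom)
  pos <- cds_positions(model)
  bases <- substring(seq, pos, pos)
  if (model$strand == "-") bases <- COMPLEMENT[bases]
  paste(bases, collapse = "")
}

genome_chrom_string <- function(genome, chrom) {
  if (methods::is(genome, "DNAStringSet")) {
    if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
    return(as.character(genome[[chrom]]))
  }
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  genome[[chrom]]
}

#' Pick the canonical transcript per gene
#'
#' When a gene has several transcripts, the one with the longest CDS is used
#' for effect annotation (ties broken by transcript id).
#'
#' @param models List of `gene_model`s.
#' @return List of `gene_model`s, one per `gene_id`.
#' @export
canonical_transcripts <- function(models) {
  if (!length(models)) return(models)
  ids <- vapply(models, `[[`, "", "gene_id")
  keep <- tapply(seq_along(models), ids, function(idx) {
    lens <- vapply(models[idx], cds_length, 0)
    tid <- vapply(models[idx], `[[`, "", "transcript_id")
    idx[order(-lens, tid)][1]
  })
  models[sort(unname(keep))]
}

#' Translate a nucleotide string under the standard genetic code
#'
#' @param seq Character scalar over ACGT; length a multiple of 3 (trailing
#'   partial codons are dropped with a warning).
#' @return Character scalar amino-acid string (`*` for stop).
#' @export
translate_cds <- function(seq) {
  n <- nchar(seq)
  if (n %% 3 != 0) {
    warning("CDS length not divisible by 3; translating complete codons only")
    n <- n - n %% 3
  }
  if (n == 0) return("")
  starts <- seq.int(1, n, by = 3)
  codons <- substring(seq, starts, starts + 2)
  paste(Biostrings::GENETIC_CODE[codons], collapse = "")
}

#' Interval-position membership test
#' @param pos Integer vector of positions.
#' @param intervals Two-column matrix of 1-based closed intervals.
#' @return Logical vector: is each position inside any interval?
#' @keywords internal
in_intervals <- function(pos, intervals) {
  if (!nrow(intervals)) return(rep(FALSE, length(pos)))
  vapply(pos, function(p) any(p >= intervals[, 1] & p <= intervals[, 2]), TRUE)
}
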