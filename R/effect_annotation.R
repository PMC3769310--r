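# Variant effect annotation: substitution spectrum (Ts/Tv), region assignment
# (intergenic / CDS / UTR / intron), synonymous vs nonsynonymous calls, the
# four large-effect classes, and indel frame analysis.

SUBSTITUTION_CLASSES <- c("C/T", "G/A", "C/G", "T/A", "A/C", "G/T")
TRANSITION_CLASSES <- c("C/T", "G/A")

# Most severe first; used when a variant overlaps several genes.
CONSEQUENCE_SEVERITY <- c(stop_gain = 6, stop_loss = 5, start_loss = 4,
                          splice_disrupt = 3, nonsynonymous = 2,
                          synonymous = 1, none = 0)

#' Classify a nucleotide substitution
#'
#' Substitutions are unordered base pairs in six classes: transitions C/T and
#' G/A; transversions C/G, T/A, A/C and G/T. Strand complements are kept
#' distinct (C/T is not collapsed with G/A).
#'
#' @param ref,alt Character vectors of single bases (A/C/G/T), `ref != alt`.
#' @return Data frame with `class` (one of the six labels) and `kind`
#'   (`transition`/`transversion`).
#' @export
classify_substitution <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (any(!ok)) stop("substitution bases must be A/C/G/T")
  if (any(ref == alt)) stop("ref and alt must differ")
  key <- paste(pmin(ref, alt), pmax(ref, alt))  # alphabetical unordered pair
  map <- c("C T" = "C/T", "A G" = "G/A", "C G" = "C/G",
           "A T" = "T/A", "A C" = "A/C", "G T" = "G/T")
  cls <- unname(map[key])
  data.frame(class = cls,
             kind = ifelse(cls %in% TRANSITION_CLASSES,
                           "transition", "transversion"),
             stringsAsFactors = FALSE)
}

#' Substitution spectrum of a SNP set
#'
#' @param snps Data frame with `ref` and `alt` columns.
#' @return Named integer vector of counts over the six substitution classes,
#'   in the order C/T, G/A, C/G, T/A, A/C, G/T.
#' @export
substitution_spectrum <- function(snps) {
  cls <- classify_substitution(snps$ref, snps$alt)$class
  counts <- table(factor(cls, levels = SUBSTITUTION_CLASSES))
  stats::setNames(as.integer(counts), SUBSTITUTION_CLASSES)
}

#' Transition/transversion ratio
#'
#' `(C/T + G/A) / (C/G + T/A + A/C + G/T)`.
#'
#' @param class_counts Named numeric vector over the six substitution classes
#'   (as from [substitution_spectrum()]).
#' @return The Ts/Tv ratio at full precision.
#' @export
compute_ts_tv <- function(class_counts) {
  miss <- setdiff(SUBSTITUTION_CLASSES, names(class_counts))
  if (length(miss)) stop("missing substitution classes: ", paste(miss, collapse = ", "))
  ts <- sum(class_counts[TRANSITION_CLASSES])
  tv <- sum(class_counts[setdiff(SUBSTITUTION_CLASSES, TRANSITION_CLASSES)])
  if (tv == 0) stop("Ts/Tv undefined: zero transversions")
  ts / tv
}

# Index gene models by chromosome for repeated lookups.
index_genes <- function(models) {
  models <- canonical_transcripts(models)
  chroms <- vapply(models, `[[`, "", "chrom")
  split(models, chroms)
}

#' Assign a genomic region to each variant
#'
#' Positions inside any gene span are genic, refined to CDS / UTR / intron on
#' the canonical transcript; everything else is intergenic. Chromosomes absent
#' from the annotation yield intergenic with a warning.
#'
#' @param variants Data frame with `chrom` and `pos`.
#' @param gene_models List of [gene_model()]s.
#' @return Data frame with `region` (`CDS`/`UTR`/`intron`/`intergenic`) and
#'   `gene_id` (NA when intergenic).
#' @export
locate_variant <- function(variants, gene_models) {
  idx <- index_genes(gene_models)
  n <- nrow(variants)
  region <- rep("intergenic", n)
  gene_id <- rep(NA_character_, n)
  warned <- character(0)
  for (i in seq_len(n)) {
    ch <- variants$chrom[i]
    if (!ch %in% names(idx)) {
      if (!ch %in% warned) {
        warning("chromosome absent from annotation: ", ch)
        warned <- c(warned, ch)
      }
      next
    }
    for (m in idx[[ch]]) {
      sp <- gene_span(m)
      p <- variants$pos[i]
      if (p < sp[1] || p > sp[2]) next
      gene_id[i] <- m$gene_id
      if (in_intervals(p, m$cds)) region[i] <- "CDS"
      else if (in_intervals(p, m$exons)) region[i] <- "UTR"
      else region[i] <- "intron"
      break
    }
  }
  keep <- setdiff(names(variants), c("region", "gene_id"))
  cbind(variants[, keep, drop = FALSE],
        data.frame(region = region, gene_id = gene_id, stringsAsFactors = FALSE))
}

# Codon-level annotation of one SNP inside the CDS of one gene.
annotate_cds_position <- function(pos, alt, model, chrom_seq) {
  cpos <- cds_positions(model)
  idx <- match(pos, cpos)
  codon_index <- (idx - 1L) %/% 3L + 1L
  within <- (idx - 1L) %% 3L + 1L
  n_codons <- length(cpos) %/% 3L
  if (codon_index > n_codons)  # trailing partial codon of an incomplete model
    return(list(consequence = "none", ref_aa = NA, alt_aa = NA,
                codon_index = codon_index))
  cod_pos <- cpos[(3L * codon_index - 2L):(3L * codon_index)]
  bases <- substring(chrom_seq, cod_pos, cod_pos)
  if (model$strand == "-") bases <- COMPLEMENT[bases]
  ref_codon <- paste(bases, collapse = "")
  alt_t <- if (model$strand == "-") COMPLEMENT[[alt]] else alt
  alt_codon <- ref_codon
  substring(alt_codon, within, within) <- alt_t
  ref_aa <- Biostrings::GENETIC_CODE[[ref_codon]]
  alt_aa <- Biostrings::GENETIC_CODE[[alt_codon]]
  consequence <-
    if (codon_index == 1L && ref_codon == "ATG" && alt_codon != "ATG") "start_loss"
    else if (ref_aa == "*" && alt_aa != "*") "stop_loss"
    else if (ref_aa != "*" && alt_aa == "*" && codon_index < n_codons) "stop_gain"
    else if (alt_aa == ref_aa) "synonymous"
    else "nonsynonymous"
  list(consequence = consequence, ref_aa = ref_aa, alt_aa = alt_aa,
       codon_index = codon_index)
}

# Splice check: does pos hit the first 2 or last 2 nt of any intron?
is_splice_site <- function(pos, model) {
  ir <- introns(model)
  nrow(ir) > 0 && any(pos %in% c(ir[, 1], ir[, 1] + 1L, ir[, 2] - 1L, ir[, 2]))
}

#' Annotate SNPs with region and functional consequence
#'
#' Each SNP is located against the canonical transcript of every overlapping
#' gene; CDS SNPs get codon-level annotation (codons extracted in transcription
#' order, reverse-complemented on minus-strand models), intronic SNPs within
#' 2 nt of an intron end are splice-disrupting, and large-effect classes take
#' precedence over plain synonymous/nonsynonymous. When a SNP overlaps several
#' genes the most severe consequence is reported (stop_gain > stop_loss >
#' start_loss > splice_disrupt > nonsynonymous > synonymous).
#'
#' @param variants SNP data frame (`chrom, pos, ref, alt`).
#' @param gene_models List of [gene_model()]s.
#' @param genome Named [Biostrings::DNAStringSet] or character vector.
#' @return The input with `region`, `gene_id`, `consequence`, `ref_aa`,
#'   `alt_aa`, `codon_index` columns appended.
#' @export
annotate_variants <- function(variants, gene_models, genome) {
  if (methods::is(genome, "DNAStringSet"))
    genome <- stats::setNames(as.character(genome), names(genome))
  idx <- index_genes(gene_models)
  n <- nrow(variants)
  out <- data.frame(region = rep("intergenic", n), gene_id = NA_character_,
                    consequence = rep("none", n), ref_aa = NA_character_,
                    alt_aa = NA_character_, codon_index = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    ch <- variants$chrom[i]
    p <- variants$pos[i]
    if (!ch %in% names(idx)) next
    best <- NULL
    for (m in idx[[ch]]) {
      sp <- gene_span(m)
      if (p < sp[1] || p > sp[2]) next
      ann <- list(region = "intron", gene_id = m$gene_id, consequence = "none",
                  ref_aa = NA, alt_aa = NA, codon_index = NA)
      if (is_coding(m) && in_intervals(p, m$cds)) {
        ann$region <- "CDS"
        cd <- annotate_cds_position(p, variants$alt[i], m, genome[[ch]])
        ann[c("consequence", "ref_aa", "alt_aa", "codon_index")] <-
          cd[c("consequence", "ref_aa", "alt_aa", "codon_index")]
      } else if (in_intervals(p, m$exons)) {
        ann$region <- "UTR"
      } else if (is_splice_site(p, m)) {
        ann$consequence <- "splice_disrupt"
      }
      if (is.null(best) ||
          CONSEQUENCE_SEVERITY[[ann$consequence]] >
            CONSEQUENCE_SEVERITY[[best$consequence]])
        best <- ann
    }
    if (!is.null(best)) {
      out$region[i] <- best$region
      out$gene_id[i] <- best$gene_id
      out$consequence[i] <- best$consequence
      out$ref_aa[i] <- if (is.na(best$ref_aa[1])) NA else best$ref_aa
      out$alt_aa[i] <- if (is.na(best$alt_aa[1])) NA else best$alt_aa
      out$codon_index[i] <- if (is.na(best$codon_index[1])) NA
                            else as.integer(best$codon_index)
    }
  }
  keep <- setdiff(names(variants), names(out))
  cbind(variants[, keep, drop = FALSE], out)
}

#' Indel polymorphism (IDP) frame analysis
#'
#' IDPs are insertions/deletions of 1-10 bp. For each size the genome-wide
#' count, the count inside CDS, the frameshift flag (size not a multiple of
#' 3), and the number of distinct genes containing IDPs of that size are
#' reported.
#'
#' @param indel_calls Data frame of INS/DEL calls with `length`.
#' @param gene_models List of [gene_model()]s.
#' @return Data frame with one row per size 1-10.
#' @export
analyze_idps <- function(indel_calls, gene_models) {
  idps <- indel_calls[indel_calls$var_class %in% c("INS", "DEL") &
                        indel_calls$length >= 1 & indel_calls$length <= 10, ,
                      drop = FALSE]
  loc <- locate_variant(idps, gene_models)
  sizes <- 1:10
  data.frame(
    size = sizes,
    n_genome = vapply(sizes, function(s) sum(idps$length == s), 0L),
    n_cds = vapply(sizes, function(s)
      sum(idps$length == s & loc$region == "CDS"), 0L),
    frameshift = sizes %% 3 != 0,
    n_genes = vapply(sizes, function(s)
      length(unique(stats::na.omit(loc$gene_id[idps$length == s]))), 0L))
}

#' Summarize an annotated variant set
#'
#' Counts partition the input exactly: genic + intergenic = total and
#' CDS + UTR + intron = genic. The ns/s ratio is nonsynonymous / synonymous
#' over CDS SNPs; large-effect SNPs are tallied separately and are not part of
#' either ns/s term.
#'
#' @param annotations Data frame from [annotate_variants()].
#' @return List of counts: `n_total`, `n_genic`, `n_intergenic`, `by_region`,
#'   `by_consequence`, `n_synonymous`, `n_nonsynonymous`, `ns_s_ratio` (NA when
#'   there are no synonymous CDS SNPs), `n_large_effect`.
#' @export
summarize_annotation <- function(annotations) {
  n <- nrow(annotations)
  genic <- annotations$region != "intergenic"
  by_region <- table(factor(annotations$region[genic],
                            levels = c("CDS", "UTR", "intron")))
  by_consequence <- table(annotations$consequence)
  n_syn <- sum(annotations$consequence == "synonymous")
  n_ns <- sum(annotations$consequence == "nonsynonymous")
  large <- c("stop_gain", "start_loss", "splice_disrupt", "stop_loss")
  list(n_total = n,
       n_genic = sum(genic),
       n_intergenic = sum(!genic),
       by_region = stats::setNames(as.integer(by_region), names(by_region)),
       by_consequence = stats::setNames(as.integer(by_consequence),
                                        names(by_consequence)),
       n_synonymous = n_syn,
       n_nonsynonymous = n_ns,
       ns_s_ratio = if (n_syn > 0) n_ns / n_syn else NA_real_,
       n_large_effect = stats::setNames(
         vapply(large, function(k) sum(annotations$consequence == k), 0L),
         large))
}

#' Nonsynonymous/synonymous ratio from counts
#'
#' @param n_nonsyn,n_syn Counts of nonsynonymous and synonymous CDS SNPs.
#' @return `n_nonsyn / n_syn`, or NA when `n_syn` is zero.
#' @export
ns_s_ratio <- function(n_nonsyn, n_syn) {
  if (n_syn == 0) return(NA_real_)
  n_nonsyn / n_syn
}
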