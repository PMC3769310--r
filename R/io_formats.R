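# Readers/writers for the external formats the pipeline touches.
# Internal convention is 1-based closed coordinates (as in GFF3/VCF); BED I/O
# converts at the boundary.

#' Read a reference genome from FASTA
#'
#' Sequence is uppercased; record names are truncated at the first whitespace.
#'
#' @param path FASTA file (plain or gzip).
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (!length(seqs)) stop("empty FASTA: ", path)
  nms <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nms))
    stop("duplicate chromosome name in FASTA: ", nms[duplicated(nms)][1])
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  names(seqs) <- nms
  seqs
}

#' Write a genome to FASTA
#'
#' @param genome Named [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(unlist(genome))
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Chromosome lengths of a genome
#' @param genome Named [Biostrings::DNAStringSet] or named character vector.
#' @return Named integer vector of lengths in bp.
#' @export
genome_lengths <- function(genome) {
  if (methods::is(genome, "DNAStringSet"))
    return(stats::setNames(Biostrings::width(genome), names(genome)))
  stats::setNames(nchar(unlist(genome)), names(genome))
}

#' Read gene models from GFF3
#'
#' Builds one [gene_model()] per mRNA/transcript feature, resolving exon and
#' CDS children through their `Parent` attributes. UTRs are derived as the
#' exon portions outside the CDS, split into 5' and 3' by strand. mRNAs
#' without CDS children are flagged non-coding.
#'
#' @param path GFF3 file.
#' @return List of `gene_model`s.
#' @export
read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parents <- gr$Parent  # CharacterList
  parent1 <- vapply(parents, function(p) if (length(p)) p[[1]] else NA_character_,
                    "")
  mrna_idx <- which(type %in% c("mRNA", "transcript"))
  models <- vector("list", length(mrna_idx))
  for (k in seq_along(mrna_idx)) {
    i <- mrna_idx[k]
    tid <- ids[i]
    gid <- if (!is.na(parent1[i])) parent1[i] else tid
    child <- which(vapply(parents, function(p) tid %in% p, TRUE))
    ex <- child[type[child] == "exon"]
    cd <- child[type[child] == "CDS"]
    exons <- cbind(GenomicRanges::start(gr)[ex], GenomicRanges::end(gr)[ex])
    cds <- if (length(cd))
      cbind(GenomicRanges::start(gr)[cd], GenomicRanges::end(gr)[cd])
    else empty_intervals()
    strand <- as.character(GenomicRanges::strand(gr))[i]
    if (!strand %in% c("+", "-")) strand <- "+"
    m <- gene_model(gid, tid, as.character(GenomicRanges::seqnames(gr))[i],
                    strand, exons, cds)
    utrs <- derive_utrs(m)
    m$utr5 <- utrs$utr5
    m$utr3 <- utrs$utr3
    models[[k]] <- m
  }
  models
}

# Exon minus CDS, split into 5'/3' sides relative to the CDS by strand.
derive_utrs <- function(model) {
  if (!is_coding(model))
    return(list(utr5 = empty_intervals(), utr3 = empty_intervals()))
  ex <- IRanges::IRanges(model$exons[, 1], model$exons[, 2])
  cd <- IRanges::IRanges(model$cds[, 1], model$cds[, 2])
  rest <- IRanges::setdiff(ex, cd)
  if (!length(rest)) return(list(utr5 = empty_intervals(), utr3 = empty_intervals()))
  cds_lo <- min(model$cds[, 1]); cds_hi <- max(model$cds[, 2])
  left <- rest[IRanges::end(rest) < cds_lo]
  right <- rest[IRanges::start(rest) > cds_hi]
  left_m <- cbind(IRanges::start(left), IRanges::end(left))
  right_m <- cbind(IRanges::start(right), IRanges::end(right))
  if (model$strand == "+")
    list(utr5 = as_interval_matrix(left_m), utr3 = as_interval_matrix(right_m))
  else
    list(utr5 = as_interval_matrix(right_m), utr3 = as_interval_matrix(left_m))
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA, exon and CDS features with `ID`/`Parent` attributes and
#' correct CDS phase, so the file round-trips through [read_gene_models_gff3()].
#'
#' @param models List of `gene_model`s.
#' @param path Output path.
#' @export
write_gene_models_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (m in models) {
    span <- gene_span(m)
    lines <- c(lines,
      gff_line(m$chrom, "gene", span[1], span[2], m$strand,
               paste0("ID=", m$gene_id)),
      gff_line(m$chrom, "mRNA", span[1], span[2], m$strand,
               paste0("ID=", m$transcript_id, ";Parent=", m$gene_id)))
    for (i in seq_len(nrow(m$exons)))
      lines <- c(lines, gff_line(m$chrom, "exon", m$exons[i, 1], m$exons[i, 2],
                                 m$strand, paste0("Parent=", m$transcript_id)))
    if (is_coding(m)) {
      segs <- m$cds
      ord <- if (m$strand == "+") seq_len(nrow(segs)) else rev(seq_len(nrow(segs)))
      done <- 0L
      for (i in ord) {
        phase <- (3L - done %% 3L) %% 3L
        lines <- c(lines, gff_line(m$chrom, "CDS", segs[i, 1], segs[i, 2],
                                   m$strand,
                                   paste0("Parent=", m$transcript_id),
                                   phase = phase))
        done <- done + segs[i, 2] - segs[i, 1] + 1L
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

gff_line <- function(chrom, type, start, end, strand, attrs, phase = NA) {
  paste(chrom, "varikit", type, start, end, ".", strand,
        if (is.na(phase)) "." else phase, attrs, sep = "\t")
}

#' Read SNP/indel candidate calls from a VCF
#'
#' Positions stay 1-based; alleles are uppercased. Variant class and length are
#' derived from the allele strings (equal length 1 = SNP; longer ALT =
#' insertion; longer REF = deletion). Depth is taken from `INFO/DP`, zygosity
#' from the first sample's `GT` when present. Records without `DP` are kept
#' with `depth = NA` so depth-dependent filters can report them instead of
#' silently dropping them.
#'
#' @param path VCF 4.x file.
#' @return A data frame of calls: `chrom, pos, ref, alt, var_class, length,
#'   depth, quality, zygosity`.
#' @export
read_variants_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ref <- toupper(fix$REF)
  alt <- toupper(fix$ALT)
  dp <- suppressWarnings(as.numeric(vcfR::extract.info(v, "DP")))
  qual <- suppressWarnings(as.numeric(fix$QUAL))
  zyg <- rep("unknown", nrow(fix))
  if (!is.null(v@gt) && ncol(v@gt) >= 2) {
    gt <- vcfR::extract.gt(v, "GT")
    g <- gt[, 1]
    zyg <- ifelse(is.na(g), "unknown",
                  ifelse(g %in% c("0/1", "0|1", "1/0", "1|0"), "het",
                         ifelse(g %in% c("1/1", "1|1"), "hom", "unknown")))
  }
  len <- abs(nchar(ref) - nchar(alt))
  var_class <- ifelse(len == 0 & nchar(ref) == 1, "SNP",
                      ifelse(nchar(alt) > nchar(ref), "INS", "DEL"))
  data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS), ref = ref, alt = alt,
             var_class = var_class, length = as.integer(len), depth = dp,
             quality = qual, zygosity = zyg, stringsAsFactors = FALSE)
}

#' Write SNP/indel calls as a minimal VCF
#'
#' Emits `INFO/DP` and a single-sample `GT` column carrying zygosity
#' (`1/1` hom, `0/1` het, `./.` unknown); round-trips through
#' [read_variants_vcf()].
#'
#' @param variants Call data frame as returned by [read_variants_vcf()].
#' @param path Output path.
#' @param sample Sample column name.
#' @export
write_variants_vcf <- function(variants, path, sample = "SAMPLE") {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                 "FORMAT", sample, sep = "\t"))
  gt <- c(hom = "1/1", het = "0/1", unknown = "./.")[variants$zygosity]
  gt[is.na(gt)] <- "./."
  info <- ifelse(is.na(variants$depth), ".", paste0("DP=", variants$depth))
  qual <- ifelse(is.na(variants$quality), ".", variants$quality)
  body <- paste(variants$chrom, variants$pos, ".", variants$ref, variants$alt,
                qual, "PASS", info, "GT", gt, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

SV_TYPES <- c("INS", "DEL", "CTX", "IDE", "ITX", "INV")

#' Read a structural-variant call table
#'
#' Tab-separated with header columns `chrom, start, end, type, length, depth,
#' quality`; `type` must be one of INS, DEL, CTX (interchromosomal
#' translocation), IDE (insertion in deletion), ITX (intrachromosomal
#' translocation), INV (inversion).
#'
#' @param path TSV file.
#' @return Data frame of calls with `pos = start` and `var_class = type`.
#' @export
read_sv_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "type", "length", "depth", "quality")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("SV table missing columns: ", paste(miss, collapse = ", "))
  bad <- which(!tab$type %in% SV_TYPES)
  if (length(bad))
    stop("unknown SV type '", tab$type[bad[1]], "' at line ", bad[1] + 1L,
         " of ", path)
  data.frame(chrom = tab$chrom, pos = as.integer(tab$start),
             end = as.integer(tab$end), var_class = tab$type,
             length = as.integer(tab$length), depth = as.numeric(tab$depth),
             quality = as.numeric(tab$quality),
             zygosity = if ("zygosity" %in% names(tab)) tab$zygosity else "unknown",
             stringsAsFactors = FALSE)
}

#' Write a structural-variant call table
#' @param svs SV data frame (as from [read_sv_table()]).
#' @param path Output path.
#' @export
write_sv_table <- function(svs, path) {
  out <- data.frame(chrom = svs$chrom, start = svs$pos, end = svs$end,
                    type = svs$var_class, length = svs$length,
                    depth = svs$depth, quality = svs$quality)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a repeat mask from BED
#'
#' BED half-open 0-based intervals are converted to the internal 1-based closed
#' convention, then sorted and merged per chromosome.
#'
#' @param path BED file.
#' @return Data frame `chrom, start, end` (1-based closed, merged).
#' @export
read_repeat_mask_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  gr <- GenomicRanges::reduce(gr)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Write a repeat mask to BED
#' @param mask Data frame `chrom, start, end`, 1-based closed.
#' @param path Output path.
#' @export
write_repeat_mask_bed <- function(mask, path) {
  gr <- GenomicRanges::GRanges(mask$chrom,
                               IRanges::IRanges(mask$start, mask$end))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Convert BED (0-based half-open) to 1-based closed coordinates
#' @param start,end Integer vectors.
#' @return Data frame `start, end` in 1-based closed convention.
#' @export
bed0_to_closed1 <- function(start, end) data.frame(start = start + 1L, end = end)

#' Convert 1-based closed to BED (0-based half-open) coordinates
#' @param start,end Integer vectors.
#' @return Data frame `start, end` in BED convention.
#' @export
closed1_to_bed0 <- function(start, end) data.frame(start = start - 1L, end = end)

#' Read gene-to-Pfam assignments
#'
#' @param path TSV with columns `gene_id, pfam_accession, domain_name`.
#' @return Data frame.
#' @export
read_pfam_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "pfam_accession")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("Pfam map missing columns: ", paste(miss, collapse = ", "))
  tab
}

HSP_COLS <- c("query_id", "subject_id", "percent_identity", "alignment_length",
              "mismatches", "gap_opens", "q_start", "q_end", "s_start", "s_end",
              "e_value", "bit_score")

#' Read an HSP table (BLAST outfmt-6 column order)
#'
#' Twelve unnamed tab-separated columns. Subject strand is inferred from
#' subject coordinate orientation (start > end means the match is on the
#' reverse strand).
#'
#' @param path TSV file without header.
#' @return Data frame with named columns and a `strand` factor
#'   (`plus`/`reverse`).
#' @export
read_hsp_table <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) != 12)
    stop("HSP table must have 12 columns (outfmt 6), got ", ncol(tab))
  names(tab) <- HSP_COLS
  num <- c("percent_identity", "alignment_length", "mismatches", "gap_opens",
           "q_start", "q_end", "s_start", "s_end", "e_value", "bit_score")
  for (cn in num) {
    val <- suppressWarnings(as.numeric(tab[[cn]]))
    if (anyNA(val))
      stop("malformed HSP row at line ", which(is.na(val))[1], " (column ", cn, ")")
    tab[[cn]] <- val
  }
  tab$strand <- ifelse(tab$s_start > tab$s_end, "reverse", "plus")
  tab
}

#' Write an HSP table in outfmt-6 column order
#' @param hsps Data frame as from [read_hsp_table()].
#' @param path Output path.
#' @export
write_hsp_table <- function(hsps, path) {
  utils::write.table(hsps[, HSP_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an F2 genotype/phenotype table
#'
#' CSV with one row per individual: `id`, `phenotype`, then one column per
#' marker with genotypes in `{AA, AB, BB, missing}`.
#'
#' @param path CSV file.
#' @return Data frame.
#' @export
read_f2_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write an F2 genotype/phenotype table
#' @param population Data frame as from [simulate_f2()].
#' @param path Output path.
#' @export
write_f2_table <- function(population, path) {
  utils::write.csv(population, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
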