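# Synthetic miniature genome: annotated genes, spiked variants of every class,
# inversion-bearing contigs, and a Mendelian F2 population. Everything is
# deterministic under the config seed: generate_genome() seeds with `seed`,
# spike_variants() with `seed + 1`, generate_inversion_contigs() with
# `seed + 2`, so each generator is reproducible standalone as well as in a
# pipeline run.

SENSE_CODONS <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
STOP_CODONS <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == "*"]

#' Simulation configuration
#'
#' Defaults describe a two-chromosome miniature genome (120 kb each, 24 genes)
#' with enough spiked variants of every class to exercise each analysis stage,
#' and an F2 design of 460 individuals segregating one recessive locus --
#' the population size of the mapping cross the package models.
#'
#' @param seed Integer seed; fully determines all generator output.
#' @param n_chroms,chrom_length,n_genes,exons_per_gene Genome architecture.
#' @param gc GC content of background and intron/UTR sequence.
#' @param n_synonymous,n_nonsynonymous,n_stop_gain,n_start_loss,n_splice,n_stop_loss
#'   SNP counts per coding effect class.
#' @param n_intron_snp,n_utr_snp,n_intergenic_snp SNP counts per region class.
#' @param cds_indel_sizes,noncoding_indel_sizes Small-indel lengths to spike
#'   (alternating insertion/deletion).
#' @param sv_ins_lengths,sv_del_lengths Structural INS/DEL lengths.
#' @param n_inv,inv_length,n_ctx,n_ide,n_itx Other SV classes.
#' @param het_fraction Fraction of SNP/indel spikes called heterozygous.
#' @param avg_depth Mean sequencing depth the depth fields are drawn around.
#' @param f2_size F2 population size.
#' @param n_markers,marker_spacing_bp Marker grid around the locus for the F2
#'   simulation (positions on chromosome 1).
#' @param cm_per_bp Genetic map scale (default 1 cM per 4 kb).
#' @param inversion_call_pad Breakpoint imprecision added to candidate
#'   inversion calls relative to the true inverted segment (bp each side).
#' @param n_decoy_contigs Plain (non-inverted) contigs added per genome.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_chroms = 2L, chrom_length = 120000L,
                              n_genes = 24L, exons_per_gene = 3L, gc = 0.46,
                              n_synonymous = 12L, n_nonsynonymous = 12L,
                              n_stop_gain = 4L, n_start_loss = 3L,
                              n_splice = 4L, n_stop_loss = 3L,
                              n_intron_snp = 15L, n_utr_snp = 10L,
                              n_intergenic_snp = 80L,
                              cds_indel_sizes = c(3L, 3L, 6L),
                              noncoding_indel_sizes = c(1L, 1L, 1L, 2L, 2L, 3L, 4L, 5L, 7L, 10L),
                              sv_ins_lengths = c(120L, 180L, 350L),
                              sv_del_lengths = c(150L, 250L, 380L, 1200L),
                              n_inv = 2L, inv_length = 1000L,
                              n_ctx = 1L, n_ide = 1L, n_itx = 1L,
                              het_fraction = 0.2, avg_depth = 11,
                              f2_size = 460L, n_markers = 8L,
                              marker_spacing_bp = 2000L,
                              cm_per_bp = 1 / 4000,
                              inversion_call_pad = 250L,
                              n_decoy_contigs = 3L) {
  cfg <- as.list(environment())
  counts <- unlist(cfg[grep("^n_", names(cfg))])
  if (any(counts < 0)) stop("variant/structure counts must be >= 0")
  if (f2_size <= 0) stop("f2_size must be positive")
  structure(cfg, class = "simulation_config")
}

random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p), collapse = "")
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Build one gene in transcript orientation with local (1-based) coordinates;
# placement onto a chromosome and strand flip happen in place_gene().
build_gene_local <- function(config) {
  n_codons <- sample(30:60, 1)
  n_exons <- config$exons_per_gene
  cds_len <- 3L * n_codons
  coding <- paste0("ATG",
                   paste(sample(SENSE_CODONS, n_codons - 2L, replace = TRUE),
                         collapse = ""),
                   sample(STOP_CODONS, 1))
  # split the CDS into n_exons chunks of >= 9 nt each
  repeat {
    cuts <- sort(sample(seq.int(2L, cds_len - 1L), n_exons - 1L))
    sizes <- diff(c(0L, cuts, cds_len))
    if (all(sizes >= 9L)) break
  }
  chunk_at <- c(0L, cumsum(sizes))
  utr5_len <- sample(20:40, 1)
  utr3_len <- sample(20:40, 1)
  intron_lens <- sample(60:150, max(n_exons - 1L, 0L), replace = TRUE)

  parts <- character(0)
  exon_loc <- NULL; cds_loc <- NULL
  cursor <- 0L
  for (j in seq_len(n_exons)) {
    chunk <- substring(coding, chunk_at[j] + 1L, chunk_at[j + 1L])
    lead <- if (j == 1L) random_dna(utr5_len, config$gc) else ""
    trail <- if (j == n_exons) random_dna(utr3_len, config$gc) else ""
    exon_seq <- paste0(lead, chunk, trail)
    exon_loc <- rbind(exon_loc, c(cursor + 1L, cursor + nchar(exon_seq)))
    cds_loc <- rbind(cds_loc, c(cursor + nchar(lead) + 1L,
                                cursor + nchar(lead) + nchar(chunk)))
    parts <- c(parts, exon_seq)
    cursor <- cursor + nchar(exon_seq)
    if (j < n_exons) {
      il <- intron_lens[j]
      intron_seq <- paste0("GT", random_dna(il - 4L, config$gc), "AG")
      parts <- c(parts, intron_seq)
      cursor <- cursor + il
    }
  }
  utr5_loc <- if (utr5_len > 0) rbind(c(1L, utr5_len)) else NULL
  utr3_loc <- if (utr3_len > 0) rbind(c(cursor - utr3_len + 1L, cursor)) else NULL
  list(seq = paste(parts, collapse = ""), len = cursor,
       exons = exon_loc, cds = cds_loc, utr5 = utr5_loc, utr3 = utr3_loc)
}

place_gene <- function(local, gene_id, transcript_id, chrom, offset, strand) {
  L <- local$len
  flip <- function(m) {
    if (is.null(m)) return(empty_intervals())
    if (strand == "+") {
      out <- cbind(offset + m[, 1] - 1L, offset + m[, 2] - 1L)
    } else {
      out <- cbind(offset + L - m[, 2], offset + L - m[, 1])
    }
    out[order(out[, 1]), , drop = FALSE]
  }
  seq <- if (strand == "+") local$seq else revcomp(local$seq)
  model <- gene_model(gene_id, transcript_id, chrom, strand,
                      flip(local$exons), flip(local$cds),
                      flip(local$utr5), flip(local$utr3))
  list(model = model, seq = seq)
}

#' Generate a miniature annotated genome
#'
#' Genes have an ATG start codon, a single in-frame stop at the end, GT/AG
#' intron boundaries and no internal in-frame stops; strands are drawn at
#' random and minus-strand models store genomic coordinates.
#'
#' @param config A [simulation_config()].
#' @return List with `genome` (named [Biostrings::DNAStringSet]) and `genes`
#'   (list of [gene_model()]s).
#' @export
generate_genome <- function(config) {
  set.seed(config$seed)
  gene_chrom <- rep(seq_len(config$n_chroms), length.out = config$n_genes)
  min_gap <- 500L
  seqs <- character(config$n_chroms)
  genes <- list()
  gi <- 0L
  for (ci in seq_len(config$n_chroms)) {
    chrom <- paste0("chr", ci)
    parts <- character(0)
    cursor <- 0L
    for (k in seq_len(sum(gene_chrom == ci))) {
      gi <- gi + 1L
      gap <- sample(min_gap:(min_gap + 800L), 1)
      parts <- c(parts, random_dna(gap, config$gc))
      cursor <- cursor + gap
      local <- build_gene_local(config)
      strand <- sample(c("+", "-"), 1)
      placed <- place_gene(local, sprintf("g%03d", gi),
                           sprintf("g%03d.t1", gi), chrom, cursor + 1L, strand)
      parts <- c(parts, placed$seq)
      cursor <- cursor + local$len
      genes[[length(genes) + 1L]] <- placed$model
    }
    if (cursor > config$chrom_length - min_gap)
      stop("chrom_length too small for the requested genes on ", chrom)
    parts <- c(parts, random_dna(config$chrom_length - cursor, config$gc))
    seqs[ci] <- paste(parts, collapse = "")
  }
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- paste0("chr", seq_len(config$n_chroms))
  list(genome = genome, genes = genes)
}

# Enumerate single-base substitutions of a codon matching a requested effect.
codon_substitutions <- function(codon, want) {
  ref_aa <- Biostrings::GENETIC_CODE[[codon]]
  out <- NULL
  for (p in 1:3) {
    ref_base <- substring(codon, p, p)
    for (b in setdiff(c("A", "C", "G", "T"), ref_base)) {
      alt <- codon
      substring(alt, p, p) <- b
      alt_aa <- Biostrings::GENETIC_CODE[[alt]]
      ok <- switch(want,
        syn = ref_aa != "*" && alt_aa == ref_aa,
        nonsyn = ref_aa != "*" && alt_aa != ref_aa && alt_aa != "*",
        stop_gain = ref_aa != "*" && alt_aa == "*",
        stop_loss = ref_aa == "*" && alt_aa != "*",
        any = TRUE)
      if (ok) out <- rbind(out, data.frame(pos = p, alt_base = b,
                                           alt_codon = alt,
                                           stringsAsFactors = FALSE))
    }
  }
  out
}

new_truth_row <- function(chrom, pos, end = pos, ref = NA, alt = NA,
                          var_class, length = 0L, depth, quality, zygosity,
                          intended_class, gene_id = NA, seq = NA) {
  data.frame(chrom = chrom, pos = as.integer(pos), end = as.integer(end),
             ref = ref, alt = alt, var_class = var_class,
             length = as.integer(length), depth = depth, quality = quality,
             zygosity = zygosity, intended_class = intended_class,
             gene_id = gene_id, seq = seq, stringsAsFactors = FALSE)
}

#' Spike variants of every class into a synthetic genome
#'
#' Places SNPs of each coding-effect and region class, small indels in and out
#' of CDS, and structural variants (INS, DEL, INV plus placeholder CTX/IDE/ITX
#' records), each tagged with its intended class. Every spiked variant, when
#' annotated against the *original* genome, yields its intended class; the
#' mutated genome carries the applied changes.
#'
#' @param genome Named [Biostrings::DNAStringSet] from [generate_genome()].
#' @param genes List of [gene_model()]s.
#' @param config The [simulation_config()] used to generate them.
#' @return List with `genome` (mutated sequences) and `truth` (data frame of
#'   spiked calls with an `intended_class` column).
#' @export
spike_variants <- function(genome, genes, config) {
  set.seed(config$seed + 1L)
  chrom_seq <- stats::setNames(as.character(genome), names(genome))
  chrom_len <- genome_lengths(genome)
  used <- lapply(chrom_len, function(n) logical(n))

  reserve <- function(chrom, start, end) {
    if (start < 1L || end > chrom_len[[chrom]]) return(FALSE)
    if (any(used[[chrom]][start:end])) return(FALSE)
    used[[chrom]][start:end] <<- TRUE
    TRUE
  }

  base_at <- function(chrom, pos) substring(chrom_seq[[chrom]], pos, pos)

  draw_depth <- function(zyg) {
    d <- max(stats::rpois(1, config$avg_depth), if (zyg == "het") 3L else 2L)
    min(d, 3L * config$avg_depth)
  }
  draw_zyg <- function() {
    if (stats::runif(1) < config$het_fraction) "het" else "hom"
  }
  snp_row <- function(chrom, pos, ref, alt, class, gene_id = NA) {
    zyg <- draw_zyg()
    new_truth_row(chrom, pos, ref = ref, alt = alt, var_class = "SNP",
                  depth = draw_depth(zyg), quality = sample(30:60, 1),
                  zygosity = zyg, intended_class = class, gene_id = gene_id)
  }

  coding <- Filter(is_coding, canonical_transcripts(genes))
  gene_info <- lapply(coding, function(m) {
    pos <- cds_positions(m)
    seq <- cds_sequence(m, chrom_seq)
    list(model = m, pos = pos, seq = seq, n_codons = nchar(seq) %/% 3L)
  })

  rows <- list()
  add <- function(row) rows[[length(rows) + 1L]] <<- row

  # --- coding-effect SNPs ------------------------------------------------
  spike_cds_class <- function(n, want, codon_pick) {
    placed <- 0L; tries <- 0L
    while (placed < n) {
      tries <- tries + 1L
      if (tries > 5000L) stop("unable to place requested class: ", want)
      gi <- gene_info[[sample(length(gene_info), 1)]]
      ci <- codon_pick(gi$n_codons)
      codon <- substring(gi$seq, 3L * ci - 2L, 3L * ci)
      subs <- codon_substitutions(codon, want)
      if (is.null(subs)) next
      s <- subs[sample(nrow(subs), 1), ]
      gpos <- gi$pos[3L * (ci - 1L) + s$pos]
      m <- gi$model
      if (!reserve(m$chrom, gpos, gpos)) next
      ref_g <- base_at(m$chrom, gpos)
      alt_g <- if (m$strand == "-") COMPLEMENT[[s$alt_base]] else s$alt_base
      cls <- switch(want, syn = "synonymous", nonsyn = "nonsynonymous",
                    stop_gain = "stop_gain", stop_loss = "stop_loss")
      add(snp_row(m$chrom, gpos, ref_g, alt_g, cls, m$gene_id))
      placed <- placed + 1L
    }
  }
  interior <- function(n) sample(2:(n - 1L), 1)
  spike_cds_class(config$n_synonymous, "syn", interior)
  spike_cds_class(config$n_nonsynonymous, "nonsyn", interior)
  spike_cds_class(config$n_stop_gain, "stop_gain", interior)
  spike_cds_class(config$n_stop_loss, "stop_loss", function(n) n)

  # start loss: any substitution in codon 1 (ATG)
  placed <- 0L
  while (placed < config$n_start_loss) {
    gi <- gene_info[[sample(length(gene_info), 1)]]
    s <- codon_substitutions("ATG", "any")
    s <- s[sample(nrow(s), 1), ]
    gpos <- gi$pos[s$pos]
    m <- gi$model
    if (!reserve(m$chrom, gpos, gpos)) next
    alt_g <- if (m$strand == "-") COMPLEMENT[[s$alt_base]] else s$alt_base
    add(snp_row(m$chrom, gpos, base_at(m$chrom, gpos), alt_g, "start_loss",
                m$gene_id))
    placed <- placed + 1L
  }

  # splice-site SNPs: first 2 / last 2 nt of an intron
  multi <- Filter(function(gi) nrow(introns(gi$model)) > 0, gene_info)
  placed <- 0L
  while (placed < config$n_splice) {
    gi <- multi[[sample(length(multi), 1)]]
    m <- gi$model
    ir <- introns(m)
    row <- ir[sample(nrow(ir), 1), ]
    gpos <- sample(c(row[1], row[1] + 1L, row[2] - 1L, row[2]), 1)
    if (!reserve(m$chrom, gpos, gpos)) next
    ref <- base_at(m$chrom, gpos)
    add(snp_row(m$chrom, gpos, ref, sample(setdiff(c("A", "C", "G", "T"), ref), 1),
                "splice_disrupt", m$gene_id))
    placed <- placed + 1L
  }

  # intron-interior and UTR SNPs
  placed <- 0L
  while (placed < config$n_intron_snp) {
    gi <- multi[[sample(length(multi), 1)]]
    m <- gi$model
    ir <- introns(m)
    row <- ir[sample(nrow(ir), 1), ]
    if (row[2] - row[1] < 6L) next
    gpos <- sample((row[1] + 2L):(row[2] - 2L), 1)
    if (!reserve(m$chrom, gpos, gpos)) next
    ref <- base_at(m$chrom, gpos)
    add(snp_row(m$chrom, gpos, ref, sample(setdiff(c("A", "C", "G", "T"), ref), 1),
                "intron", m$gene_id))
    placed <- placed + 1L
  }
  placed <- 0L
  while (placed < config$n_utr_snp) {
    gi <- gene_info[[sample(length(gene_info), 1)]]
    m <- gi$model
    utr <- rbind(m$utr5, m$utr3)
    if (!nrow(utr)) next
    row <- utr[sample(nrow(utr), 1), ]
    gpos <- sample(row[1]:row[2], 1)
    if (!reserve(m$chrom, gpos, gpos)) next
    ref <- base_at(m$chrom, gpos)
    add(snp_row(m$chrom, gpos, ref, sample(setdiff(c("A", "C", "G", "T"), ref), 1),
                "UTR", m$gene_id))
    placed <- placed + 1L
  }

  # intergenic placement helper (margin keeps spikes clear of gene spans)
  spans <- lapply(names(chrom_len), function(ch) {
    g <- Filter(function(m) m$chrom == ch, genes)
    if (!length(g)) return(empty_intervals())
    do.call(rbind, lapply(g, function(m) rbind(gene_span(m))))
  })
  names(spans) <- names(chrom_len)
  intergenic_ok <- function(chrom, start, end, margin = 10L) {
    sp <- spans[[chrom]]
    if (!nrow(sp)) return(TRUE)
    !any(start - margin <= sp[, 2] & end + margin >= sp[, 1])
  }
  pick_intergenic <- function(width, margin = 10L) {
    for (i in 1:2000) {
      chrom <- sample(names(chrom_len), 1)
      start <- sample(seq.int(400L, chrom_len[[chrom]] - width - 400L), 1)
      end <- start + width - 1L
      if (!intergenic_ok(chrom, start, end, margin)) next
      if (!reserve(chrom, start, end)) next
      return(list(chrom = chrom, start = start, end = end))
    }
    stop("unable to place intergenic feature of width ", width)
  }

  for (i in seq_len(config$n_intergenic_snp)) {
    loc <- pick_intergenic(1L)
    ref <- base_at(loc$chrom, loc$start)
    add(snp_row(loc$chrom, loc$start, ref,
                sample(setdiff(c("A", "C", "G", "T"), ref), 1), "intergenic"))
  }

  # --- small indels ------------------------------------------------------
  indel_row <- function(chrom, anchor, ref, alt, class, size, gene_id = NA) {
    zyg <- draw_zyg()
    new_truth_row(chrom, anchor, ref = ref, alt = alt,
                  var_class = if (nchar(alt) > nchar(ref)) "INS" else "DEL",
                  length = size, depth = draw_depth(zyg),
                  quality = sample(30:60, 1), zygosity = zyg,
                  intended_class = class, gene_id = gene_id)
  }
  # CDS indels: anchored within one CDS segment, clear of start/stop codons
  for (k in seq_along(config$cds_indel_sizes)) {
    size <- config$cds_indel_sizes[k]
    is_del <- k %% 2L == 0L
    placed <- FALSE
    for (i in 1:2000) {
      gi <- gene_info[[sample(length(gene_info), 1)]]
      m <- gi$model
      segs <- m$cds
      si <- sample(nrow(segs), 1)
      lo <- segs[si, 1] + 4L
      hi <- segs[si, 2] - 4L - (if (is_del) size else 0L)
      if (hi <= lo) next
      anchor <- sample(lo:hi, 1)
      span_end <- anchor + (if (is_del) size else 0L)
      cdsp <- sort(gi$pos)
      if (!all((anchor:span_end) %in% cdsp)) next
      # keep clear of the first and last codon in transcript order
      edge <- c(gi$pos[1:3], gi$pos[(length(gi$pos) - 2L):length(gi$pos)])
      if (any((anchor:span_end) %in% edge)) next
      if (!reserve(m$chrom, anchor, span_end)) next
      if (is_del) {
        ref <- substring(chrom_seq[[m$chrom]], anchor, anchor + size)
        alt <- substring(ref, 1, 1)
      } else {
        ref <- base_at(m$chrom, anchor)
        alt <- paste0(ref, random_dna(size, 0.5))
      }
      add(indel_row(m$chrom, anchor, ref, alt,
                    if (size %% 3L == 0L) "inframe" else "frameshift",
                    size, m$gene_id))
      placed <- TRUE
      break
    }
    if (!placed) stop("unable to place CDS indel of size ", size)
  }
  # noncoding indels (intergenic)
  for (k in seq_along(config$noncoding_indel_sizes)) {
    size <- config$noncoding_indel_sizes[k]
    is_del <- k %% 2L == 0L
    loc <- pick_intergenic(size + 2L)
    anchor <- loc$start
    if (is_del) {
      ref <- substring(chrom_seq[[loc$chrom]], anchor, anchor + size)
      alt <- substring(ref, 1, 1)
    } else {
      ref <- base_at(loc$chrom, anchor)
      alt <- paste0(ref, random_dna(size, 0.5))
    }
    add(indel_row(loc$chrom, anchor, ref, alt, "noncoding_indel", size))
  }

  # --- structural variants ----------------------------------------------
  sv_row <- function(chrom, start, end, type, len, class, seq = NA) {
    new_truth_row(chrom, start, end = end, var_class = type, length = len,
                  depth = sample(10:60, 1), quality = sample(30:60, 1),
                  zygosity = "hom", intended_class = class, seq = seq)
  }
  for (len in config$sv_del_lengths) {
    loc <- pick_intergenic(len, margin = 50L)
    add(sv_row(loc$chrom, loc$start, loc$end, "DEL", len, "sv_del"))
  }
  for (len in config$sv_ins_lengths) {
    loc <- pick_intergenic(2L, margin = 50L)
    add(sv_row(loc$chrom, loc$start, loc$start, "INS", len, "sv_ins",
               seq = random_dna(len, 0.5)))
  }
  for (i in seq_len(config$n_inv)) {
    loc <- pick_intergenic(config$inv_length, margin = 400L)
    add(sv_row(loc$chrom, loc$start, loc$end, "INV", config$inv_length, "sv_inv"))
  }
  other <- c(CTX = config$n_ctx, IDE = config$n_ide, ITX = config$n_itx)
  for (type in names(other)) {
    for (i in seq_len(other[[type]])) {
      loc <- pick_intergenic(500L, margin = 50L)
      add(sv_row(loc$chrom, loc$start, loc$end, type, 500L,
                 paste0("sv_", tolower(type))))
    }
  }

  truth <- do.call(rbind, rows)
  truth <- truth[order(truth$chrom, truth$pos), ]
  rownames(truth) <- NULL
  mutated <- apply_variants_to_genome(chrom_seq, truth)
  list(genome = mutated, truth = truth)
}

#' Apply spiked variants to a genome
#'
#' SNPs, anchored small indels, and INS/DEL/INV structural variants are applied
#' right-to-left per chromosome so reference coordinates stay valid during
#' application; CTX/IDE/ITX records describe rearrangements the sequence-level
#' simulator does not apply.
#'
#' @param genome Named character vector or [Biostrings::DNAStringSet].
#' @param truth Truth-set data frame from [spike_variants()].
#' @return Mutated genome as a named [Biostrings::DNAStringSet].
#' @export
apply_variants_to_genome <- function(genome, truth) {
  if (methods::is(genome, "DNAStringSet"))
    genome <- stats::setNames(as.character(genome), names(genome))
  for (chrom in names(genome)) {
    rows <- truth[truth$chrom == chrom & !truth$var_class %in% c("CTX", "IDE", "ITX"), ]
    if (!nrow(rows)) next
    rows <- rows[order(-rows$pos), ]
    s <- genome[[chrom]]
    for (i in seq_len(nrow(rows))) {
      r <- rows[i, ]
      if (r$var_class == "SNP") {
        substring(s, r$pos, r$pos) <- r$alt
      } else if (!is.na(r$ref) && !is.na(r$alt)) {  # anchored small indel
        s <- paste0(substring(s, 1, r$pos - 1L), r$alt,
                    substring(s, r$pos + nchar(r$ref), nchar(s)))
      } else if (r$var_class == "DEL") {
        s <- paste0(substring(s, 1, r$pos - 1L),
                    substring(s, r$end + 1L, nchar(s)))
      } else if (r$var_class == "INS") {
        s <- paste0(substring(s, 1, r$pos), r$seq,
                    substring(s, r$pos + 1L, nchar(s)))
      } else if (r$var_class == "INV") {
        s <- paste0(substring(s, 1, r$pos - 1L),
                    revcomp(substring(s, r$pos, r$end)),
                    substring(s, r$end + 1L, nchar(s)))
      }
    }
    genome[[chrom]] <- s
  }
  out <- Biostrings::DNAStringSet(genome)
  names(out) <- names(genome)
  out
}

#' Simulate an F2 population segregating a single recessive locus
#'
#' Gametes are generated under Mendelian segregation with per-interval
#' crossover probabilities from physical distance (Haldane map function, no
#' interference). Allele A is the recessive parent's; phenotype is `waxy` for
#' locus genotype AA, `heterozygous` for AB (a selfed seed pool segregates),
#' and `non_waxy` for BB.
#'
#' @param n Population size (> 0).
#' @param marker_positions Named integer vector of marker positions (bp) on one
#'   chromosome.
#' @param locus_position Position (bp) of the recessive locus.
#' @param cm_per_bp Genetic map scale in cM per bp (default 1 cM / 4 kb).
#' @param seed Optional seed.
#' @param phenotype_error Per-individual misclassification probability
#'   (default 0: the staining assay is treated as error-free).
#' @return Data frame: `id`, `phenotype`, `locus` genotype, then one genotype
#'   column per marker (`AA`/`AB`/`BB`).
#' @export
simulate_f2 <- function(n, marker_positions = integer(0), locus_position,
                        cm_per_bp = 1 / 4000, seed = NULL,
                        phenotype_error = 0) {
  if (n <= 0) stop("f2 population size must be positive")
  if (!is.null(seed)) set.seed(seed)
  if (length(marker_positions) && is.null(names(marker_positions)))
    names(marker_positions) <- paste0("M", seq_along(marker_positions))
  pos <- c(marker_positions, .locus = locus_position)
  ord <- order(pos)
  pos_sorted <- pos[ord]
  k <- length(pos_sorted)
  d_morgan <- diff(pos_sorted) * cm_per_bp / 100
  r <- 0.5 * (1 - exp(-2 * d_morgan))
  gamete <- function() {
    g <- matrix(0L, nrow = 2L * n, ncol = k)
    g[, 1] <- stats::rbinom(2L * n, 1L, 0.5)
    for (j in seq_len(k - 1L)) {
      sw <- stats::rbinom(2L * n, 1L, r[j])
      g[, j + 1L] <- ifelse(sw == 1L, 1L - g[, j], g[, j])
    }
    g
  }
  g <- gamete()
  geno_num <- g[seq_len(n), , drop = FALSE] + g[n + seq_len(n), , drop = FALSE]
  lab <- c("BB", "AB", "AA")
  geno <- matrix(lab[geno_num + 1L], nrow = n)
  colnames(geno) <- names(pos_sorted)
  locus_geno <- geno[, ".locus"]
  phenotype <- c(BB = "non_waxy", AB = "heterozygous", AA = "waxy")[locus_geno]
  if (phenotype_error > 0) {
    flip <- stats::runif(n) < phenotype_error
    classes <- c("waxy", "non_waxy", "heterozygous")
    phenotype[flip] <- vapply(phenotype[flip], function(p)
      sample(setdiff(classes, p), 1), "")
  }
  out <- data.frame(id = paste0("F2_", seq_len(n)), phenotype = phenotype,
                    locus = locus_geno, stringsAsFactors = FALSE)
  for (mname in names(marker_positions)) out[[mname]] <- geno[, mname]
  rownames(out) <- NULL
  out
}

#' Generate contigs harboring inversions, plus plain decoys
#'
#' For each true inversion the inverted haplotype (flanks forward, interior
#' reverse-complemented) is reconstructed and cut into contigs spanning each
#' breakpoint, so a similarity search of the (padded) reference segment
#' against them yields matches on both strands. Decoy contigs are plain
#' substrings of the reference and align plus-strand only.
#'
#' @param genome Named [Biostrings::DNAStringSet] (the reference).
#' @param inversions Data frame `chrom, start, end` of true inverted segments.
#' @param config A [simulation_config()].
#' @param ext Flank length carried on each side of a breakpoint (bp).
#' @return Named character vector of contig sequences.
#' @export
generate_inversion_contigs <- function(genome, inversions, config, ext = 600L) {
  set.seed(config$seed + 2L)
  chrom_seq <- stats::setNames(as.character(genome), names(genome))
  chrom_len <- genome_lengths(genome)
  contigs <- character(0)
  for (i in seq_len(nrow(inversions))) {
    inv <- inversions[i, ]
    if (inv$start < ext + 1L || inv$end + ext > chrom_len[[inv$chrom]])
      stop("inversion interval out of chromosome bounds: row ", i)
    seg <- substring(chrom_seq[[inv$chrom]], inv$start, inv$end)
    left <- substring(chrom_seq[[inv$chrom]], inv$start - ext, inv$start - 1L)
    right <- substring(chrom_seq[[inv$chrom]], inv$end + 1L, inv$end + ext)
    hap <- paste0(left, revcomp(seg), right)
    if (nchar(seg) <= 2L * ext) {
      contigs[paste0("inv", i, "_ctg")] <- hap
    } else {
      contigs[paste0("inv", i, "_ctgL")] <- substring(hap, 1, 2L * ext)
      contigs[paste0("inv", i, "_ctgR")] <- substring(hap, nchar(hap) - 2L * ext + 1L,
                                                      nchar(hap))
    }
  }
  for (d in seq_len(config$n_decoy_contigs)) {
    for (try in 1:200) {
      chrom <- sample(names(chrom_len), 1)
      start <- sample(seq.int(1L, chrom_len[[chrom]] - 1200L), 1)
      end <- start + 1199L
      clash <- nrow(inversions) > 0 &&
        any(inversions$chrom == chrom &
              start - 2000L <= inversions$end & end + 2000L >= inversions$start)
      if (!clash) break
    }
    contigs[paste0("decoy", d)] <- substring(chrom_seq[[chrom]], start, end)
  }
  contigs
}
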