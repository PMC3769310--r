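---
title: "Methods and design of varikit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of varikit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varikit)
```

varikit implements the downstream half of a whole-genome re-sequencing
comparison between two crop genotypes — the analyses that start from candidate
variant calls and end at biological conclusions: which calls to trust, what
each variant does to a gene, how variation is distributed and organized, which
variants make good PCR markers, and how those markers localize a recessive
trait locus in an F2 cross. The motivating setting is a foxtail millet
(*Setaria italica*) landrace re-sequenced against two reference cultivars, but
every function works on generic FASTA/GFF3/VCF/TSV inputs.

This vignette records the models, the tunable parameters and their defaults,
the numerical and design choices made where the method left room, and what the
synthetic-data tests do and do not demonstrate.

## Coordinate conventions

All internal coordinates are 1-based and closed on both ends, matching GFF3
and VCF, the two dominant input formats. BED input/output converts at the
boundary (`bed0_to_closed1()`, `closed1_to_bed0()`), and the conversion pair
is property-tested as an inverse bijection. Minus-strand gene models keep
genomic coordinates; reverse-complementation happens in exactly one place,
codon extraction, which minimizes strand-logic bugs.

## Variant acceptance filtering

`filter_snps()` keeps a SNP call when its depth is at least 2× (3× at
heterozygous loci), at most three times the genome-wide average depth
(supplied as a parameter, ~11× in the motivating data set; read alignment is
out of scope so the average is never recomputed from reads), and its position
is outside the repeat mask. `filter_svs()` keeps an SV call when depth lies in
[2, 100] and quality exceeds 20. Wording such as "no less than" / "no more
than" is read inclusively (≥, ≤) and "more than 20" strictly (>); the depth
window is inclusive on both ends. Every call lands in exactly one of
passed/rejected (with a reason), the report conserves counts
(`n_input = n_passed + Σ rejections`), and tightening any threshold can only
shrink the passed set — all three properties are tested.

Small insertions/deletions of 1–5 bp are split out of the SV set as indel
polymorphisms (`split_indels_from_svs()`, boundary inclusive at 5 bp).
Candidate lists from two SV callers are reconciled by
`merge_caller_candidates()`: records merge when chromosome and type match and
start coordinates agree within a tolerance window (default 10 bp — the callers
report breakpoints with a few bases of jitter; the exact reconciliation used
in the original analysis is unstated, so both union and intersection modes
are provided and the merged record keeps the higher-quality coordinates).

## Effect annotation

Substitutions are classified into six unordered base-pair classes exactly as
substitution tables in this literature lay them out — transitions C/T and G/A,
transversions C/G, T/A, A/C, G/T — without collapsing strand complements, and
`compute_ts_tv()` is their transition:transversion ratio.

Region assignment (`locate_variant()`) refines genic positions to CDS, UTR or
intron on the canonical transcript. Where a gene has several transcripts the
longest CDS is canonical (annotation sources rarely flag one; longest-CDS is
the common convention and is deterministic). Codon-level annotation
(`annotate_variants()`) extracts the codon in transcription order and
translates under the standard genetic code. Large-effect classes take
precedence over plain synonymous/nonsynonymous calls:

* **stop_gain** — the alternate codon is a stop before the annotated stop;
* **start_loss** — codon 1 is no longer ATG;
* **splice_disrupt** — the SNP hits the first or last 2 intronic nucleotides
  of any intron (the canonical GT/AG dinucleotides; no motif content check,
  since "donor or acceptor site" is not defined more finely than that);
* **stop_loss** — the annotated stop codon becomes a sense codon.

A variant overlapping two genes is annotated against each and reported once
with the most severe consequence (stop_gain > stop_loss > start_loss >
splice_disrupt > nonsynonymous > synonymous). Indels in CDS get a frame class
only (in-frame when the length is a multiple of 3), because the size/frame
level is where the downstream analyses operate. `summarize_annotation()`
reports the ns/s ratio over plain synonymous/nonsynonymous CDS SNPs and
tallies large-effect SNPs separately, so both conventions (large-effect SNPs
in or out of the nonsynonymous total) are recoverable.

The annotator is validated two ways: against a hand-built two-gene fixture
with a known codon layout on both strands, and against an independent
whole-protein-diff oracle — apply the SNP to the chromosome, re-translate the
entire CDS, and classify from the protein difference — across every possible
substitution of the fixture gene and one random CDS SNP in each of 1,000
random synthetic genes.

## Summaries and enrichment

`compute_window_densities()` tiles each chromosome into fixed windows
(default 100 kb) and scales counts to per-Mb rates; counts conserve totals
per chromosome. `call_density_regions()` merges maximal runs of consecutive
windows above a high threshold (default >500/Mb) or below a low one
(default <10/Mb) into regions. The windowing/merge scheme behind the original
region counts is unstated; this definition is deterministic and documented,
which is what matters for reuse.

`histogram_sv_sizes()` partitions INS/DEL lengths into the five classes
1, 2–5, 6–10, 11–100 and >100 bp. `pfam_ns_s_enrichment()` tests each Pfam
family's observed (ns, s) split against the genome-wide background proportion
with a 1-df goodness-of-fit chi-square — the simplest reading of a two-cell
significance test; no continuity correction by default, with a Yates flag for
users who want it — and analyzes only families with at least 30 ns+s SNPs
(the count floor the genome-scale analysis used; families below the floor are
listed separately, never silently dropped). A gene carrying several domains
contributes its SNPs to each family, matching the domain-centric framing of
the analysis. Raw p-values are flagged at p < 0.001; no multiple-testing
correction is applied by default because the reference analysis reports raw
thresholds.

## Marker design

`select_marker_candidates()` keeps INS/DEL variants of 100–400 bp — large
enough to resolve as a length polymorphism on agarose, small enough to
amplify reliably — and checks that the flanking sequence (default 300 bp per
side) is unique in the genome by exact k-mer counting (default k = 31, odd so
no k-mer is its own reverse complement; both strands counted). Uniqueness by
exact k-mers rather than primer thermodynamics is deliberate: the method only
requires unique flanking sequence, and primer design proper is out of scope.
Predicted band sizes for the two alleles differ by exactly the SV length,
which is asserted for every candidate.

## Inversion validation

External alignments arrive as 12-column tabular HSP tables (BLAST outfmt-6
order), with subject strand inferred from subject coordinate orientation.
`filter_hsps()` keeps HSPs with e-value ≤ 1e-20, identity ≥ 98% and length
≥ 200 bp. `strand_coverage()` unions the query intervals per strand (verified
against brute-force per-base counting) and confirms an inversion when both
plus- and reverse-strand coverage are strictly positive — the
"matches on both strands" criterion; no numeric ratio threshold is imposed
because none is established, but the floors are configurable.

For self-contained tests, `align_contigs_naive()` is a small exact-match
seed-and-extend aligner (shared 31-mers, extended to maximal exact matches on
both strands) that emits the same HSP schema. It exists only so the synthetic
path needs no external search tool and is kept separate from the table-driven
production path. The synthetic design mirrors why real inversions show both
strands: candidate calls carry breakpoint imprecision (default 250 bp padding
around the true inverted segment), so the extracted query includes
non-inverted margin that matches contigs on the plus strand while the inverted
interior matches in reverse. Decoy contigs from non-inverted sequence match
plus-only and are never confirmed.

## F2 mapping

Phenotypes come from stained seed pools: all pink = waxy (homozygous
recessive), all dark blue = non-waxy, segregating = heterozygous, empty =
missing. `segregation_test()` checks the dominant:recessive counts against
3:1 with a 1-df goodness-of-fit chi-square (cross-checked against
`stats::chisq.test`).

`map_recessive_locus()` implements the classical recessive-class strategy:
only phenotypically waxy individuals (genotype AA at the locus) are scored,
a recombinant at a marker is a waxy individual whose marker genotype is not
AA, and the locus interval is bounded by the nearest flanking markers with at
least one recombinant, containing the zero-recombinant marker(s). Heterozygous
phenotype calls are not used for interval bounding — that is the
recessive-class method — and mapping is purely ordinal over marker positions;
physical-to-genetic conversion lives only in the simulator.

## The synthetic-data generator

The generator is first-class, tested code, not a fixture. Its defaults are
the study conditions the package models where those are stated (an F2 of 460
individuals segregating one recessive locus; average depth ~11×; indel and SV
class definitions), and field-realistic choices elsewhere, fixed once:

* **Genome**: 2 chromosomes × 120 kb, 24 genes of 3 exons (30–60 codons,
  20–40 bp UTRs, 60–150 bp introns), uniform background at 46% GC. Background
  composition is irrelevant to method behavior; the sizes keep the full test
  suite fast while leaving room for every variant class.
* **Genes** are built in transcript orientation — ATG, sense codons, one
  terminal stop, GT/AG introns — then placed on a random strand, so the
  generated annotation is correct by construction and independently asserted
  by translation.
* **Spiked variants**: each requested class (synonymous, nonsynonymous,
  stop gain/loss, start loss, splice, intron/UTR/intergenic SNPs, in-frame and
  frameshift CDS indels, INS/DEL/INV/CTX/IDE/ITX SVs) is placed by enumerating
  codon substitutions with the required effect, and tagged with its intended
  class. The round-trip invariant — annotating the truth set against the
  original genome recovers the intended class for 100% of spikes — is the
  package's strongest correctness check.
* **F2 populations**: gametes recombine between adjacent positions with
  Haldane probabilities from physical distance at 1 cM per 4 kb (a typical
  plant genome-wide average, compressed into the toy genome's scale), no
  interference, no phenotype noise by default (the staining assay is treated
  as error-free; a misclassification rate parameter exists).
* **Determinism**: `generate_genome()` seeds the RNG with the config seed,
  `spike_variants()` with seed+1 and `generate_inversion_contigs()` with
  seed+2, so each generator is reproducible standalone and in pipeline order.

What the generator does *not* emulate — sequencing error, alignment artifacts,
repeat-driven false calls, segmental duplications, annotation errors,
segregation distortion — bounds what passing tests show: they demonstrate that
the implementations compute their definitions correctly and recover known
truth under clean conditions, not that the thresholds are optimal for any
particular real data set.

## Problem sizes and numerical notes

The test suite exercises the annotator-vs-oracle comparison on 1,000 random
genes, segregation on 1,000 simulated F2 populations of 460, and interval
containment on 200 populations with markers every 0.5 cM — sizes chosen so the
full suite runs in well under a minute while the stochastic checks have
negligible Monte-Carlo noise. The two-cell chi-square is computed in closed
form and matches `stats::chisq.test` to 1e-9 on random tables. Degenerate
inputs have defined behavior: zero transversions, zero synonymous SNPs, empty
seed pools, zero-length inversions, and markers with equal allele bands all
yield errors or NA/missing rather than silent nonsense.

## Orchestration

`run_pipeline()` chains the stages on a synthetic configuration and returns a
consolidated report (per-chromosome counts and densities, substitution
spectrum and Ts/Tv, annotation partitions, IDP table, density scan, size and
type histograms, enrichment, markers, inversion confirmations, mapping
interval and candidate genes), optionally writing each stage's output under
stable file names. On the toy genome the enrichment count floor defaults to 5
(the function default stays at the genome-scale 30, which no toy family can
reach). The recessive locus is placed inside the middle chromosome-1 gene so
the mapped interval demonstrably recovers an annotated candidate gene, the
way a starch-synthase gene is recovered in the motivating study. The package
is function-first: the pipeline entry point, the per-stage functions and this
vignette are the interface, and every report quantity is traceable to a stage
output.
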