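---
title: "Methods: cohort-level VCF summarization and mutational signatures"
author: "vcfcohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort-level VCF summarization and mutational signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, which
choices were genuinely open, and what its synthetic tests do and do not
demonstrate about real data.

## Data model

A variant record is one *normalized allele observation*: chromosome,
1-based position, reference and alternate allele, class, sample label.
Multi-allelic VCF sites are split into one record per ALT allele before
anything else happens, so "a variant" always means a single allele change.

Normalization trims bases shared by REF and ALT — suffix first, then
prefix, always retaining one anchor base when an allele would otherwise
become empty, and advancing the position by the trimmed prefix length.
This makes representation-dependent encodings of the same change compare
equal (the identity used by all overlap analyses is the key
`chrom:pos:ref:alt` *after* normalization), it is idempotent, and it never
alters the genomic edit the record encodes — the test suite verifies this
by applying raw and normalized alleles to toy sequences and comparing the
results. Classification is pure length arithmetic on normalized alleles:
both length 1 is an SNV, unequal lengths an insertion/deletion with
`indel_len = |len(ref) − len(alt)|`, equal multi-base lengths an MNV.
Symbolic ALTs (`<DEL>`, breakends, `*`) are skipped and counted; this
package does not analyze structural variants.

A cohort is an ordered set of samples partitioned into named groups
(replicates), defined by an explicit manifest (`path`, `group`, `sample`)
rather than filename conventions — grouping is an experimental-design
fact, not something to guess from names. FILTER defaults to keeping only
`PASS`/`.` records (`pass_only = FALSE` keeps everything); genotypes are
used only to attribute records of multi-sample VCFs to the samples that
carry a non-reference call.

## Feature annotation

Variants are annotated directly from a GTF or GFF3 file; both dialects of
the same models must and do produce identical calls (tested on shared
probes). Each variant receives exactly one category by fixed precedence:

```
exonic > splicing > UTR5 > UTR3 > intronic > upstream > downstream > intergenic
```

The choices behind that vocabulary, with defaults and units:

* **exonic** — the position lies in a coding exon segment of any
  transcript of any gene, or in any exon of a non-coding transcript. If
  any transcript makes a variant exonic, it is exonic.
* **UTR5/UTR3** — exon segments outside the CDS extent, sided by the
  transcript strand. UTRs are derived from CDS versus exon extents when a
  file does not annotate them explicitly.
* **splicing** — intronic position within `splice_window_bp` (default
  2 bp) of an exon/intron boundary. Two base pairs covers the canonical
  donor/acceptor dinucleotides.
* **upstream/downstream** — within `upstream_downstream_bp` (default
  1000 bp) of a transcript end, measured on the transcript strand, outside
  any transcript span.
* **intergenic** — everything else; the nearest flanking gene(s) and the
  distance in bp to the nearest gene are reported.

Indels are annotated by their anchor (leftmost) position rather than by
span overlap: deterministic, cheap, and unambiguous for the multi-category
spans long deletions could touch. Overlapping genes that tie at the
winning category are all reported, sorted lexicographically. The indexed
implementation (interval overlap queries) is tested for exact agreement
with a brute-force linear scan over all transcripts on random probes, and
an exhaustive 1-bp scan checks that every position receives exactly one
category.

VCFs that already carry Annovar-style annotation (`Func.refGene`,
`Gene.refGene`) can skip re-annotation: a fixed mapping folds the Annovar
vocabulary onto the eight categories (`ncRNA_exonic → exonic`, compound
calls take the first term, etc.).

## Cohort summaries

All summaries are long-format tables (`sample`, `group`, `category`,
`count`, `frequency`) with frequencies computed within sample — per-sample
rates are comparable across unequal library depths, pooling across groups
is left to the caller. Deterministic ordering and LF-only atomic TSV
writing make reruns byte-identical.

* **Spectrum**: 6-class (pyrimidine reference, complement-collapsed) is
  the default view; the 12-class directed table is always available, and
  the 6-class counts equal the 12-class counts with complementary pairs
  summed (tested).
* **Indel bins** default to {1, 2, 3, 4–5, 6–10, >10} bp — fine resolution
  where polymerase-slippage indels concentrate, one open tail —
  overridable as any strictly increasing set of lower bounds starting at 1.
* **Genome windows** tile each chromosome as `[1, w], [w+1, 2w], …` with
  the last window truncated; default 1 Mb for real genomes (the fixture
  manifests use 25 kb, matched to 150 kb toy chromosomes). MNVs appear in
  neither the SNV nor the indel column; per-sample window sums therefore
  reproduce the SNV and indel totals exactly.
* **Replicate overlap** reports every exclusive subset region of a group's
  replicates by normalized key. Counting is uncapped; only the plot is
  limited (regions are drawn as a bar chart — with more than three sets a
  circle Venn is unreadable anyway).
* **Gene screens**: the high-frequency ranking defaults to
  {exonic, splicing, UTR5, UTR3} — "mutated gene" is read as "variant in
  the mature transcript or its immediate splice context" — configurable to
  any category subset; ties break lexicographically so output is stable.
  Driver tallies count variants whose call is a gene-body category
  (exonic…intronic) in a listed gene, matched exactly and
  case-sensitively.

## Mutational signatures

SBS96 channels are `X[R>A]Y` with pyrimidine reference R, ordered
substitution-major then 5'/3' context lexicographically — the order is
fixed across every matrix and file; catalogs are reordered (or rejected)
on load. Purine-reference SNVs are reverse-complemented into the
pyrimidine frame. SNVs whose context runs off the chromosome, contains N,
or whose REF disagrees with the genome are dropped and *counted*, so
`colSums(counts) + dropped` always equals the SNV totals — conservation is
asserted on every fixture.

De novo extraction factorizes the count matrix V (96 × n) into
column-stochastic signatures W (96 × k) and exposures H (k × n) by
multiplicative updates minimizing generalized Kullback–Leibler divergence.
Numerical choices: 10 random restarts (best final objective wins; uniform
random initialization per restart from a seed-derived RNG stream, so runs
are bit-reproducible), at most 2000 iterations, relative objective
tolerance 1e-8 checked every 10 iterations, machine-epsilon floors against
division by zero. The scale ambiguity of NMF is resolved by normalizing
signature columns to sum 1 and absorbing the scale into exposures, which
then read as attributed mutation counts; signatures are ordered by total
exposure. k is user-chosen; a scan mode reports reconstruction error and
restart stability per candidate rank without auto-selecting, because rank
selection is a judgment call the analyst should see, not a heuristic to
hide. NMF rather than a topic model was chosen as the field-standard
formulation for count matrices of this shape; refitting against a known
catalog is per-sample non-negative least squares, and catalog matching is
plain cosine similarity with the full similarity matrix emitted.

## What the synthetic generator emulates — and what it does not

The generator builds uniform-random ACGT genomes (default 2 × 150 kb), 30
non-overlapping genes with 1–3 transcripts and 2–6 exons each, and
replicated cohorts in which each group is a shared core (1400 variants)
plus per-replicate private sets (600 each) — i.e. the overlap structure,
class mix (84% SNV, 7% + 7% indel, 2% MNV), C>T-dominant spectrum,
1-bp-dominant indel lengths and feature-category mix are *planted by exact
largest-remainder allocation*, not sampled. The manifest that records the
planted truth therefore predicts every count-level summary exactly, and
those tests run at zero tolerance. Only signature analysis involves
sampling: channel counts are drawn multinomially/Poisson from planted
signature mixtures, and recovery is asserted at cosine ≥ 0.95 (4 planted
signatures with pairwise cosine ≤ 0.3, 30 samples, 5000 mutations per
sample) with exposure fractions within 0.05.

These conditions demonstrate correctness of the *computations*, not
realism of the *data*: real genomes are not uniform-random (trinucleotide
availability differs), real spectra are flatter, replicate concordance is
graded rather than core-plus-private, real gene models overlap and nest,
and real cohorts carry caller artifacts this generator never produces.
Passing tests show the pipeline reports exactly what is in a VCF cohort —
not that any particular biological inference is warranted.

## Degenerate inputs and edge policy

Empty samples yield zero counts (frequencies 0, flagged); SNV-free samples
are listed in a spectrum attribute rather than silently emitting NaN.
Variants on chromosomes missing from the gene model index become
intergenic with no gene and a warning; missing from `chrom_sizes`, they
fall into an explicit `unplaced` window row. An all-zero count matrix,
k outside [1, min(96, n)], empty driver lists, non-monotone bins and
unknown groups/subcommands are errors, not coerced defaults. The command
wrapper distinguishes configuration errors (exit 2) from data errors
(exit 1) and writes every table atomically (temp file + rename), so a
failed run leaves no partial outputs.

## Problem sizes used by the test suite

The suite exercises: 1000-pair normalization properties; 500-probe
annotation oracle comparisons plus a 12 kb exhaustive scan; a 2 × 3 × 2000
variant study cohort checked against its manifest at zero tolerance; 3 ×
200-key overlap oracles; SBS96 conservation on three cohorts; and the
30-sample signature recovery above. These sizes were chosen as the
smallest that exercise every code path with planted structure left over to
detect miscounting; the full suite and the acceptance script each complete
in a few minutes on one CPU.

## Known limitations

No BCF, phased-genotype or structural-variant support; no amino-acid
consequence calling or HGVS; no indel/doublet signature classes or
strand-bias channels; no statistical testing between groups; annotation
precedence is Annovar-compatible but not configurable beyond its two
window parameters; and the bundled signature machinery ships only a
synthetic 4-signature catalog — analyses against real catalogs require the
user to supply the catalog TSV.
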