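---
title: "SSR mining and cross-sample classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SSR mining and cross-sample classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrscape)
```

This vignette is the package's account of what it computes and why the
open design choices were made the way they were. The pipeline targets
per-locus multiple sequence alignments from target-enrichment sequencing
of low-copy nuclear loci — the setting in which microsatellite markers
are catalogued across related species of a plant family — but every
stage is generic.

## The detection model

A perfect SSR is a maximal run of a *primitive* motif of length
1–6 bp (a motif is primitive when it is not a whole-number repetition of
a shorter one; a run of `AGAG` *is* a run of `AG`). A run qualifies when
it reaches the class's minimum number of complete repetitions:

| class | motif length | min repeats (default) | min length |
|-------|--------------|----------------------:|-----------:|
| I     | 1 (mono)     | 12                    | 12 bp      |
| II    | 2 (di)       | 6                     | 12 bp      |
| III   | 3 (tri)      | 4                     | 12 bp      |
| IV    | 4 (tetra)    | 3                     | 12 bp      |
| V     | 5 (penta)    | 3                     | 15 bp      |
| VI    | 6 (hexa)     | 3                     | 18 bp      |

These are MISA-compatible settings. Runs are broken by `N` and by
fragment ends; a partial trailing unit extends the periodic region but
never the repeat count. Gaps are removed before mining — a repeat
interrupted only by alignment gaps is one repeat — and every degapped
position keeps its alignment column through an invertible coordinate map
(`degap()` / `regap()`), so detections can be compared across samples in
column space. All coordinates are 1-based inclusive.

The motif is reported in the phase in which the run starts; rotations
(`AAG`/`AGA`/`GAA`) are *not* folded, and neither are reverse
complements (`AG` and `CT` are tallied separately; a complement-merged
view exists in `motif_frequency()` as a report option only). This
mirrors how such catalogues are conventionally tabulated and keeps the
raw output faithful to the sequence; rotation equivalence is applied
later, where it belongs, in cross-sample grouping and in the phase
consensus.

## Compound SSRs and normalization

Two or more perfect SSRs form a compound SSR only when they are strictly
adjacent — zero interspersed nucleotides. This is deliberately stricter
than MISA's default interruption distance of 100: the package treats the
zero-interruption definition as part of the detection model, and a
one-nucleotide gap keeps two repeats simple.

Where maximal runs of different motifs *overlap* (the last unit of one
doubles as the first unit of the next), a naive per-period scan emits
overlap notation such as (GTAT)2(GTA&lt;T&gt;G)(TG)12. The package
instead clusters overlapping candidate runs and re-segments the spanned
region into adjacent perfect runs under two ordered criteria:

1. fewest components, each meeting its class threshold;
2. among equal counts, the longest earliest component (then the lower
   motif class on remaining ties).

This is the package's formalization of "the simpler reading": for
`GTAT`×3 + `GT`×12 it yields (GTAT)3(GT)12, the form a human curator
writes down. The re-segmentation is lossless — concatenating the
components reproduces the region exactly — and is validated in the test
suite against an exhaustive enumerator of all segmentations. When a
cluster admits no full segmentation, the package falls back to a greedy
longest-run-first selection and drops conflicting shorter runs; ties
between equal-length runs go to the lower motif class, then the leftmost
start. These tie-breaks are normative choices (the exact behavior of
MISA's scanner in such corners is not documented); they are deterministic
and tested against the brute-force oracle rather than against MISA
binaries.

When fragments start inside a repeat, different samples can exhibit
different rotations of one motif. `consensus_phase()` resolves the label
by majority vote among samples whose repeat does *not* touch a fragment
edge — edge-truncated members are the suspected cause of the phase
shift, so they do not vote (unless every member is truncated) — with
lexicographic tie-breaking, and relabels only the edge-truncated members.
Repeat counts are never altered. A related judgment call: when one
sample shows a tetranucleotide (e.g. (AAGA)n) and another a
trinucleotide ((AAG)n) at the same site, the package treats them as
different motif classes (separate groups), not as a phase error; no
cross-class normalization is attempted.

## Exon subtraction

For exon+flank datasets the whole alignment is mined and detections that
also occur in the exon-only dataset are removed, leaving the
flanking-region set. The two datasets are different alignments with no
shared coordinate system, so the subtraction is a multiset difference on
(sample, locus, motif, repeat count): each exon detection consumes at
most one identical full-dataset detection. When the caller can supply
per-(sample, locus) offsets of the exon inside the full fragment,
positions are compared as well. The key-based rule can in principle
remove a flanking SSR that happens to match an exon SSR of the same
locus exactly; with positional offsets supplied the match is exact.

## Classification

SSRs from different samples belong to one *locus group* when their
alignment intervals overlap by at least one column and their motifs are
cyclic rotations of one another (transitive closure). One overlapping
column is the weakest testable reading of "the same locus position"; the
per-member overlap fraction is emitted so users can re-filter with a
stricter criterion. Groups are then classified:

* **unique** — one sample carries the repeat;
* **shared** — ≥2 samples, identical repeat counts;
* **polymorphic** — ≥2 samples, ≥2 distinct repeat counts;

with a taxonomic tier: for shared groups the narrowest rank containing
all members, for polymorphic groups the narrowest rank containing two
members with *differing* counts (a within-species difference is reported
as within-species even if the group spans genera). Samples identified
only to genus ("Sceptridium sp.") are treated as distinct species for
tier computation. Compound SSRs are classified component-wise; the
compound table carries the whole-compound view.

A polymorphic group whose repeat-count variation disappears once
edge-truncated members are set aside is flagged `edge_artifact`: the
"polymorphism" is probably an incomplete repeat at a fragment edge, not
real length variation. The package classifies strictly by observed
counts and exposes the flag rather than reassigning the category.

## Summaries and rounding

SSR density is (count / sequence length) × 1000, per kb, with the
per-sample non-gap residue total as denominator. Densities are rounded
half-up to 4 decimals, percentages half-up to 2 (`round_half_up()`;
base R's round-half-to-even would disagree with conventionally printed
table values in the last digit). Missing data per sample is
(1 − sample bp / concatenated alignment bp) × 100 over all loci of the
dataset. All distribution views (class, length, motif) count compound
components individually and conserve the total SSR count.

## The synthetic-data generator

`simulate_dataset()` exists so that every stage — including
classification tiers and edge-artifact flagging — can be tested against
a known truth without any external data. Its defaults emulate the study
conditions the pipeline targets: 29 samples spanning six genera with the
genus/species structure of `default_taxonomy()` (including duplicated
species and genus-only samples, so every tier is realizable), locus
alignment lengths drawn uniformly from 159–2228 bp, per-sample
missing-data fractions drawn from 0.12–0.95, and a planted plan of 10
unique, 20 shared and 30 polymorphic SSRs cycling the three tiers, six
of them extended into two-component compounds and five edge-truncated.

Design decisions worth knowing:

* **Backgrounds are rejection-sampled against the miner itself**: i.i.d.
  bases (default composition 30/20/20/30) are redrawn until the fragment
  contains no SSR under the configured thresholds, and the residues
  bordering a planted repeat are constrained so they cannot extend it.
  Every assembled fragment is then re-mined and must reproduce its
  planted SSR set *exactly* before it is accepted. This makes the truth
  ledger exact rather than probabilistic, which is what lets recovery
  tests demand set equality.
* **Repeat-count polymorphism is realized as gap columns**: all carriers
  of a planted SSR share the same alignment columns; shorter alleles are
  right-padded with gaps, exercising the degap/colmap path the way a
  real MSA would.
* **Missing data is whole-locus dropout** per sample (plus deliberate
  edge trims for truncation cases). Real target-capture missingness is
  mostly failed loci, and an absent sample contributes 0 bp by
  definition; modelling partial fragments beyond the truncation cases
  would complicate the ledger without changing what is being tested.
* **Truncation cuts at motif boundaries**, so the observed motif phase
  is preserved and the expected repeat count is planted minus cut
  copies. Phase-shifting cuts are exercised separately in the
  `consensus_phase()` unit tests.

What the generator does **not** emulate — and hence what passing
recovery tests do not show about real data: no evolutionary model of SSR
mutation (no stepwise mutation, no homoplasy), no homology between
background regions of different samples (alignments are only
column-consistent where repeats are planted), no sequencing error, no
imperfect/interrupted repeats, and no heptanucleotide-or-longer motifs
(outside the 1–6 bp definition by construction). Recovery on synthetic
data demonstrates the correctness of the bookkeeping — coordinates,
grouping, categories, tiers, flags — not the biological completeness of
the detection model.

## Problem sizes and runtime choices

The test suite validates the miner against a brute-force oracle (every
position × motif length by direct string comparison, with exhaustive
segmentation enumeration for overlap clusters) on over a thousand random
sequences up to 2 kb, and runs the full recovery end-to-end on the
default 29-sample × 100-locus simulation; these sizes keep the suite
comfortably within a coffee break while covering every code path. The
bundled `fixture_small()` (5 samples × 10 loci, one planted case of each
kind) has its expected mining and classification tables stored under
`inst/extdata/` for byte-level regression checks; outputs are ordered
with locale-independent sorts precisely so that such comparisons are
stable across machines.

## Degenerate inputs and numerical corners

Empty sequences and all-gap rows mine to empty tables; a sample absent
from a locus contributes 0 bp to its totals; density is an error for
zero-length sequence but 0 for zero SSRs; zero-row tables write valid
TSV headers. `N` is a residue for coordinates and statistics but breaks
repeat runs. Identical runs reportable at two motif lengths keep the
shorter class. The phase-consensus vote falls back to all members when
every member is edge-truncated.

## Limitations

* Only perfect repeats are modelled; interrupted or imperfect SSRs are
  out of scope, as is primer thermodynamics (the package emits
  Boulder-IO for an external Primer3 and stops there). The default
  minimum flank of 50 bp per side for primer eligibility is a
  configurable convention, not a derived value.
* The "same locus" criterion (≥1 overlapping column) is deliberately
  the weakest defensible choice; use the emitted overlap fractions to
  tighten it.
* Exon subtraction without offsets is key-based and can over-subtract a
  coincidentally identical flanking repeat of the same locus.
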