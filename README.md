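# ssrscape

Microsatellite (SSR) mining and cross-sample classification for per-locus
multiple sequence alignments from target-enrichment data — nuclear exons
and their flanking regions — with a synthetic-alignment generator so the
whole pipeline is testable without any sequencing data.

## The problem

Simple sequence repeats (SSRs, tandem repeats of 1–6 bp motifs) in
low-copy nuclear loci are a prime source of markers for population and
evolutionary genetics in groups without reference genomes, such as
eusporangiate ferns. Target-enrichment datasets deliver hundreds of
per-locus alignments across dozens of samples, but turning them into an
SSR catalogue requires a chain of fiddly steps: gaps must be stripped
before mining (a repeat interrupted by alignment gaps is still one
repeat), detections must be lifted back into alignment columns to compare
samples, MISA-style compound output must be normalized, and apparent
repeat-count polymorphism must be disentangled from fragments that simply
end inside a repeat. `ssrscape` implements that chain as composable,
tested functions.

## What it computes

* **Perfect SSRs**: maximal runs of a primitive motif *m* of class
  *k* = |*m*| ∈ {1..6} with at least the class minimum of complete
  repetitions — defaults (*n*₁,…,*n*₆) = (12, 6, 4, 3, 3, 3), so the
  shortest reportable repeat is 12 bp (15 bp for penta-, 18 bp for
  hexanucleotides). Runs are broken by `N` and by fragment ends; partial
  trailing units do not count.
* **Compound SSRs**: two or more perfect SSRs strictly adjacent with
  zero interspersed nucleotides. Where maximal runs of different motifs
  overlap (MISA's "shared nucleotide" notation), the region is
  re-segmented into the fewest adjacent perfect runs:
  `GTATGTATGTAT` + `GT`×12 is reported as (GTAT)3(GT)12, never
  (GTAT)2(GTA&lt;T&gt;G)(TG)12.
* **Classification**: SSRs from different samples whose alignment
  intervals overlap and whose motifs are cyclic rotations of one another
  form one locus group; a group is *unique* (one sample), *shared*
  (≥2 samples, identical repeat counts) or *polymorphic* (≥2 samples,
  differing counts), at the narrowest taxonomic tier (within species <
  within genus < across genera). Polymorphism explainable by an
  edge-truncated fragment is flagged as an artifact.
* **Summaries**: SSR density = (count / sequence length) × 1000 per kb,
  per-class and per-length distributions, motif frequencies (optionally
  merging reverse-complement pairs), per-sample tables.
* **Primer templates**: SSR ± flank, clipped to the fragment, with
  eligibility by minimum flank length, emitted as Primer3 Boulder-IO.

## Worked example

```r
library(ssrscape)

# the normalized compound reading of a 36-nt repetitive region
s <- paste0(strrep("GTAT", 3), strrep("GT", 12))
merge_compound(find_perfect_ssrs(s))$compounds$notation
#> [1] "(GTAT)3(GT)12"

# a deterministic 5-sample, 10-locus synthetic dataset with known truth
fx  <- fixture_small()
res <- analyze_dataset(fx$alignments, fx$taxonomy)
res$sample_table
#>   sample_id I II III IV V VI total n_compound sequence_bp density
#> 1 P015_WE12 1  1   1  0 0  0     3          0        2654  1.1304
#> 2 P015_WH11 0  1   2  1 0  0     4          0        3589  1.1145
#> 3 P028_WD08 0  1   1  0 0  0     2          0        3337  0.5993
#> 4  P03_WA06 0  1   0  2 0  0     3          1        3371  0.8899
#> 5 P072_WC08 1  1   0  2 0  0     4          1        4126  0.9695
#> 6     Total 2  5   4  5 0  0    16          2          NA      NA
res$report$by_category
#>      category n_ssrs n_groups n_loci n_samples
#> 1      unique      1        1      1         1
#> 2      shared      9        4      3         4
#> 3 polymorphic      6        3      3         4
```

Each row counts component-level SSRs per motif class (I = mono- …
VI = hexanucleotide); `density` is SSRs per kb of that sample's non-gap
sequence. The 16 detected SSRs are exactly the 16 planted ones, including
the (GTAT)3(GT)12 compound in two samples and an edge-truncated (AAG)
repeat that is classified polymorphic but flagged as an edge artifact.

A shell entry point wrapping the same stages is installed at
`inst/scripts/ssrscape`:

```sh
ssrscape mine|classify|summarize|primers|simulate --config cfg.yaml
```

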