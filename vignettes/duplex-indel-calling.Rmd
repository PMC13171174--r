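---
title: "Strand-aware somatic indel calling from Tn5 duplex sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strand-aware somatic indel calling from Tn5 duplex sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duplexcall)
library(dplyr)
```

## The problem and the model

Somatic small insertions and deletions (indels) in non-clonal cell
populations occur at allele fractions far below what bulk sequencing can
separate from noise. Tn5-based duplex sequencing addresses this at the
single-molecule level: the transposase cuts double-stranded DNA and tags both
fragment ends with barcodes, and the adapter orientation distinguishes the
two strands of each original molecule. Because a true mutation existed on
both strands of the template, a credible somatic call must be supported by
reads from *both* strand families; most polymerase and library artifacts are
single-stranded and fail that complementarity check.

`duplexcall` implements this calling model end to end:

1. **Preprocessing** (`extract_barcodes()`, `trim_adapter()`,
   `merge_overlap()`): terminal barcodes are identified within a Hamming
   tolerance against a reference barcode list and removed; 3' adapter
   read-through is trimmed; mates are merged across their overlap, keeping
   the higher-quality base at disagreements so merged bases are at least as
   reliable as either mate.
2. **Molecule grouping** (`group_molecules()`): aligned reads sharing a
   barcode pair (in either orientation) and the same Tn5 cut sites form one
   molecule; read orientation recovers the strand. A barcode pair observed
   with more than one fragment interval is a *barcode collision* and every
   molecule involved is flagged.
3. **Candidate generation** (`indel_observations()`, `call_candidates()`):
   indels are read off the alignment operations (no local realignment),
   left-normalized, and aggregated per molecule and strand. Under the
   threshold `aXsY` (`call_threshold(a, s)`), a candidate needs `a` total
   supporting reads; it is `DOUBLE` (duplex consensus) if each strand
   contributes at least `s` reads and `SINGLE` otherwise. The default is
   `a4s2`. Sex chromosomes are excluded, and an optional high-confidence
   genome mask labels candidates outside it.
4. **Filtering** (`filter_*()`, `finalize_calls()`): germline,
   adjacent-germline, merge-confound, cut-site and population-frequency
   filters annotate candidates; a call is `PASS` only if it is `DOUBLE` and
   carries no filter label. Single-strand calls are emitted on a separate
   track and never `PASS` — with Tn5 chemistry, single-stranded events
   cannot be distinguished from DNA damage or library artifacts, but they
   remain informative for comparative analyses.

## Tunable parameters

| Parameter | Default | Where | Rationale |
|---|---|---|---|
| `a`, `s` | 4, 2 | `call_threshold()` | four total alternative reads with two per strand — the standard duplex consensus stringency; constructor enforces `a >= 2s >= 2` |
| `max_mismatch` | 1 | `barcode_ref()` | barcodes are short and Tn5 tagging introduces no gaps; the reference list must keep pairs > 2 mismatches apart so assignment is unambiguous |
| `min_match` | 5 bp | `trim_adapter()` | exact suffix match; the shortest adapter prefix worth trimming |
| `min_overlap` | 10 bp | `merge_overlap()` | shorter overlaps are indistinguishable from chance matches |
| `max_mismatch_rate` | 0.1 | `merge_overlap()` | an overlap must be near-perfect to merge |
| `min_mapq` | 30 | `group_molecules()` | drops ambiguous alignments before molecule grouping |
| `min_bq` | 20 | `indel_observations()` | the anchor base and the first base after the event must both reach Q20 for an observation to count |
| `cutsite_tolerance` | 0 bp | `group_molecules()` | Tn5 cut sites are exact; 2 bp accommodates noisy ends |
| `germline_min_bulk_depth` | 10 | `filter_config()` | below this bulk depth germline status cannot be excluded, so candidates are conservatively removed |
| `adjacency_window` | 10 bp | `filter_config()` | mapping errors concentrate within a few bases of germline indels |
| `af_cutoff` | 0.01 | `filter_config()` | indels at >= 1% population frequency are likely contamination or unremoved germline |

## Numerical and design choices

**Left-normalization.** Indels from different reads, the bulk table and the
population-AF table are only comparable in a canonical representation.
`normalize_indel()` right-trims shared suffix bases (pulling in the preceding
reference base when an allele would empty), then left-trims shared prefix
bases — the standard leftmost, minimal VCF form. The test suite checks this
against an exhaustive enumeration of equivalent representations.

**Merge ambiguity.** When both read ends terminate inside a tandem repeat or
share microhomology, several overlap offsets explain the data and merging may
fabricate or erase repeat units. `merge_overlap()` records `ambiguous = TRUE`
when a second *qualifying* offset (mismatch fraction within bound) reaches at
least 90% of the best offset's match count. Only qualifying offsets are
compared: long chance overlaps of unrelated sequence match ~25% of bases and
would otherwise trigger spurious ambiguity. The merge-confound filter then
labels a candidate when all of its support lies inside merged overlaps and
any supporting read's merge was ambiguous, or when the indel's repeat tract
(unit <= 6 bp, tract >= 12 bp) spans a merge boundary.

**Germline evidence.** A single bulk alternative read suffices to label a
candidate `germline` (maximally conservative), while the *adjacency* set —
germline indels that define "difficult regions" — requires at least 2 bulk
reads or VAF >= 0.2 so that isolated bulk noise does not blacklist windows.

**Per-molecule candidates.** Calling operates at single-molecule resolution,
so one candidate is emitted per (molecule, allele); several molecules carrying
the same allele yield several candidates, collapsed only at VCF emission
(molecule key in the `MOL` INFO field). Filters therefore act on exactly the
evidence of one original DNA fragment.

**Strand convention.** After merging, mate 1 starts with the barcode its
strand encountered first, so a plus-strand molecule's merged read aligns
forward and a minus-strand one reverse; `assign_strand()` reads the strand
off the alignment orientation, and molecule keys use the lexicographically
ordered barcode pair so both strands collapse to one molecule.

**Filter algebra.** Filters only append labels and never drop rows, so they
commute and the final label set is independent of application order;
`finalize_calls()` sorts labels into a fixed order. Disabling a filter can
only grow the PASS set. Both properties are tested.

## The 83-channel spectrum and benchmarking

Variant-level comparison is a poor benchmark for single-molecule callers,
which routinely see private mutations absent from any bulk truth set.
Spectrum-level comparison is robust to that: `classify_indels()` maps each
call into the community-standard 83-channel indel classification — 1-bp
insertions/deletions by pyrimidine base and homopolymer length, longer events
by adjacent repeat-unit count, and deletions additionally by flanking
microhomology length — and `cosine_similarity()` compares spectra on shape
alone (scale-invariant).

`bootstrap_similarity()` resamples calls with replacement and reports
percentile 95% intervals of the similarity to a reference spectrum and to
user-supplied unrelated ("negative control") spectra; a genuine match sits
above the upper bound of every control interval. `downsample_molecules()`
thins datasets at the molecule level — never at the read level, which would
break duplex families — for depth-robustness experiments.

## What the simulator emulates — and what it does not

`simulate_duplex()` generates the entire study from first principles:
a reference with planted homopolymers (>= 8 bp) and tandem repeats
(unit 2-6 bp, >= 12 bp) plus a sex contig; molecules with barcode pairs,
fragments and strand-split merged reads (both raw FASTQ and aligned records,
so no external aligner is needed); germline indels at VAF 0.5/1 mirrored in
a bulk evidence table; somatic indels planted on both strands of one
molecule each; and independently switchable artifact classes — single-strand
indels, barcode collisions, mis-merges at tandem repeats — each recorded in
a ground-truth table. A `mixture_fraction` parameter thins realized somatic
molecules, emulating spiking a mutant sample into a wild-type background.

Default conditions are fixed once and used throughout the tests: 1000
molecules, 200 somatic and 60 germline indels on a 200 kb autosome (10% of
molecules on chrX), fragments 230 ± 25 bp (truncated to [170, 270] so 150 bp
mates always overlap), duplex families of 4 + Poisson(1) reads per strand,
substitution errors at 10^-3^/bp, bulk depth ~30x with every germline allele
guaranteed at least one bulk read (the truth contract "germline means
detectable in bulk"). Family size was chosen to represent deeply sequenced
duplex libraries, where either strand alone can reach the default total
threshold; artifacts are planted on autosomes, where calling is in scope.

The simulator does **not** model: alignment and mapping error (reads are
emitted pre-aligned at their true locus; the merge-confound and
adjacent-germline filters are exercised through planted artifacts instead),
Tn5 insertion-site sequence bias, PCR family-size distributions beyond the
configurable reads-per-strand law, indel sequencing errors (substitutions
only, so truth remains unambiguous), or chimeric molecules. Passing tests
therefore demonstrate the correctness of the calling and filtering logic
under the stated generative model, not performance on real data with real
alignment artifacts.

## Problem sizes

The test suite runs the full caller at the default study size (1000
molecules) in the acceptance properties and at 25-500 molecules in unit
tests; the brute-force pileup recount is checked on ~1000 reads; spectrum
recovery uses 500 sampled calls; bootstraps use 300-500 resamples. These
sizes give stable properties while keeping the whole suite to a few minutes
on one CPU.

## Known limitations

* Simple indels only: multi-nucleotide and complex variants are out of
  scope, as is SNV calling.
* Calling is threshold-based; there is no probabilistic genotype or artifact
  model (no panel of normals, no Mutect2-style filtering).
* Unmerged read pairs are not split into two records; the expected input is
  merged single-end duplex reads with the documented `XB/XC/XM/XO/XA/XP`
  tags (the `XP` overlap-offset tag extends the minimal contract because the
  merge-confound filter needs the overlap interval, not just its length).
* The germline filter is only as good as the bulk: sites the bulk does not
  cover at `germline_min_bulk_depth` are discarded rather than risked.

## A minimal worked run

```{r example, eval = FALSE}
sim <- simulate_duplex(sim_config(seed = 7, n_molecules = 300,
                                  n_somatic = 60, n_germline = 20,
                                  artifact_rate = 0.05))
run <- run_pipeline(sim$reads, sim$reference, bulk = sim$bulk)
glance(run)
calls <- tidy(run)
spectrum <- indel_spectrum(
  classify_indels(filter(calls, pass), sim$reference)$channel)
autoplot(spectrum)
```
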