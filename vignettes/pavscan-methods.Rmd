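---
title: "Methods: sliding-window PAV detection and molecular-clock analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sliding-window PAV detection and molecular-clock analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pavscan)
```

This vignette documents the models and procedures the package implements,
the parameters that matter and their defaults, the design choices made
where the procedure was genuinely open, what the synthetic-data generator
does and does not emulate, and the known limitations. All empirical
behaviour referred to here is computed by the test suite
(`tests/testthat/`) or by `scripts/acceptance.R`; the vignette itself
states no number the code does not produce.

## 1. Sliding-window presence/absence variation

Two assemblies are compared symmetrically. Each genome is tiled into
overlapping windows of `window = 500` bp stepped by `step = 100` bp;
windows exist while `start + window <= chromosome length`, so there are
no trailing partial windows and up to `window - 1` bases at each
chromosome end are unclassifiable (documented, deliberate: a partial
window would have a different coverage denominator).

A window is called **genome-specific** when both of the following hold:

* its *primary alignment coverage* on the counterpart genome is strictly
  below `min_other_cov = 0.25`, or it produces no alignment at all; and
* it aligns *properly* back to its own assembly, meaning self-coverage at
  least `min_self_cov = 0.90`.

Primary alignment coverage is the fraction of the window's bases spanned
by its single best alignment; supplementary or secondary alignments are
ignored. Both thresholds are strict inequalities, mirroring the "< 25%"
convention; the self-alignment condition is applied to *both* branches
(including fully unaligned windows) because a window that cannot even
align to its own assembly is an assembly artifact, not evidence of
absence in the counterpart. This uniform application is configurable
(`min_self_cov = 0` disables it).

Windows whose N fraction reaches `max_n_frac = 0.5` are masked and never
called specific: assembly gaps look "unalignable" for the wrong reason.

Specific windows merge into maximal unions (a window extends a segment
when its start does not exceed the running union end); merging is
implemented on `IRanges::reduce()` and is property-tested against a
brute-force boolean-mask union. Reported segments must be strictly longer
than `min_segment = 500` bp, with a large class strictly above
`large_segment = 5000` bp.

### The internal window mapper

The package ships a deterministic seed mapper rather than shelling out to
an external aligner: exact 15-mer seeds are looked up in a sorted,
prefix-bucketed index of the target; hits are clustered by target
locality (cluster gap = query length + 200 bp) on both strands; the best
cluster is the primary alignment and its seed-covered query fraction is
the coverage. Repetitive seeds occurring more than `max_occ = 64` times
are skipped. Under the study divergence (24 SNPs + 6 indels per kb) a
shared 500-bp window retains expected exact-15-mer coverage near 0.65 —
comfortably above the 0.25 specificity threshold — while a truly specific
window has essentially zero (the chance collision probability of a seeded
15-mer chain is far below 1e-9). Windows mapped with an external aligner
can be substituted by supplying PAF records (`read_paf()`) and computing
coverage from them; the classification logic is agnostic to the mapper.

The known cost of seed coverage is at segment boundaries: windows
overhanging a planted segment by less than ~(1 - 0.25/0.65) of their
length are still called specific, so merged segments overrun true
boundaries by up to `window - step` bp less one seed on each side. At the
5 Mb study scale this keeps base-level precision near 0.96; on very small
genomes with short segments the same fixed overhang weighs more, which is
why the small-scale unit test bounds precision at 0.85 while the
study-scale bound is 0.90.

## 2. Gene-level PAV

CDS intervals of a gene's transcripts are merged by interval union
(tested against a base-set oracle). A gene is a **candidate** when
strictly more than 75% of the merged CDS is covered by same-genome PAV
segments. Candidates are validated against reads of the counterpart
genome mapped onto this genome: strictly more than 50% CDS coverage by
such reads evidences the sequence is in fact present in the counterpart,
so the candidate is *rejected*; the remainder are final PAV genes. "Reads
covering" means covered at depth ≥ 1 by primary alignments of reads
passing an identity floor of 95%. Because the internal mapper measures
exact-seed coverage rather than alignment identity, the floor is
translated: one mismatch can erase up to k seed-covered bases, so 95%
identity maps to a seed-coverage floor of `1 - 0.05 * 15 = 0.25`.

The same mechanism scores presence across additional taxa
(`taxon_presence_matrix()`); the presence threshold is unstated in
standard practice and defaults to the validation threshold, 0.50, exposed
as an argument.

## 3. Nei–Gojobori (1986) synonymous divergence

`ng86_ks()` implements classical NG86 counting:

* **Sites.** At each codon position the synonymous fraction is the number
  of the three possible single-base changes preserving the amino acid,
  divided by three; changes creating a stop codon are never synonymous.
  This makes `S + N = 3L` exactly, an invariant the tests assert. Site
  counts are averaged over the two sequences.
* **Differences.** For each codon pair all minimal substitution pathways
  are enumerated with equal weight; pathways passing through a stop codon
  are excluded (if every pathway is blocked — possible only for some
  three-step pairs — all pathways are used with stop steps counted
  nonsynonymous). Codons containing gaps or ambiguous bases are skipped
  pairwise; a shared terminal stop codon is dropped; an internal stop is
  a hard error naming the codon.
* **Correction.** Jukes–Cantor, `Ks = -(3/4) ln(1 - (4/3) pS)`; `pS ≥
  3/4` is reported as saturated (`Ks = NA`) rather than extrapolated.

The implementation precomputes 64×64 pathway tables once; the test suite
checks it against an independent brute-force oracle (explicit string
mutation, recursive pathway enumeration) to 1e-12 on random 300-codon
pairs. No maximum-likelihood (YN00-style) variant is attempted: the
classical counting method is the stated contract, and ML methods differ
by design, not by bug.

## 4. WGD bins, ages, and Ks peaks

Paralog Ks values split at the conventional breakpoints 0.335 and 1.0:
`(0, 0.335]` is the younger Ad-α event, `(0.335, 1.0]` the older Ad-β,
above 1.0 unassigned. The bins are left-open/right-closed; Ks of exactly
0 is excluded from Ad-α because identical pairs are usually allelic or
tandem artifacts, not WGD remnants. Ages use `age = Ks / (2 rate)` with
the asterid synonymous rate `8.25e-9` per site per year; the boundary
0.335 therefore converts to 20.30 Mya, consistent with the younger
event's published 18–20 Mya range (the acceptance script recomputes
this).

`ks_distribution_peaks()` finds modes of a Gaussian KDE on [0, 3]
evaluated on a 0.001 grid with bandwidth 0.03 (both configurable); modes
below 1% of the tallest density are discarded as numerical ripple in flat
tails — without this floor, floating-point noise in an empty tail
produces hundreds of spurious "modes". Block-level Ks summaries default
to the median per block, with mean available (`block_ks()`), since which
of the two a practitioner uses varies.

## 5. LTR insertion ages

The two long terminal repeats of a retroelement are identical at
insertion; their divergence dates it as `t = K / (2r)` with `r = 1e-8`
substitutions per site per year. `ltr_divergence()` aligns the two
repeats globally with free end gaps, drops gapped columns, and computes
the Kimura two-parameter distance by default (raw p-distance and
Jukes–Cantor are flags, since the correction choice is conventional).
Saturated distances (non-positive logarithm arguments) and unalignable
pairs are flagged, not errored. Free-end-gap alignment can clip a
terminal mismatch, biasing K down by at most a couple of sites per
repeat; at the planted divergences (K ≤ 0.02 on 1 kb repeats) this is
well inside the 15% recovery tolerance the tests enforce.

## 6. k-mer genome profiling

Canonical k-mers (lexicographic minimum of k-mer and reverse complement)
are censused at `k = 17`; even k is rejected because a reverse-complement
palindrome makes canonicalisation ambiguous. The error threshold is the
depth where the species-count decline from depth 1 first bottoms out;
genome size is the retained k-mer volume divided by the homozygous peak
depth (with a guard that promotes the peak to twice its depth when a
comparable peak sits there, i.e. when the detected maximum is actually
the heterozygous half-depth peak). Heterozygosity is reported as the
percentage of retained k-mer species at depths within [0.3, 0.7] of the
homozygous peak — a k-mer-species percentage, deliberately *not*
converted to a per-base rate; for a diploid with per-base heterozygosity
h, the expected species share is `2p/(1+p)` with `p = 1 - (1-h)^k`, which
the simulation tests verify within 20%.

The estimator's discreteness matters: the peak depth is an integer, so a
true k-mer coverage of 26.8 yields a peak at 26 or 27 and a relative size
error of up to ~3%, inside the 5% tolerance asserted at 30× on 1 Mb.

## 7. Syntenic variants and SNP matrices

One-to-one blocks are selected greedily by descending match count (ties
by query coordinate); a record is kept only if it overlaps no kept record
on either genome — deliberately greedy rather than optimal
weighted-interval scheduling, mirroring how practical delta-filtering
behaves; the one-to-one property is asserted on random inputs. Within a
block, mismatch columns are SNPs (adjacent mismatches are separate
events, no MNP merging), each maximal gap run is one indel event of its
length, and events of ≥ 100 bp are logged but excluded from retained
counts. Densities are events × 1000 / aligned (match + mismatch) columns;
indel density counts events, not gap bases, which is the main place
conventions diverge between tools.

SNP matrices (dosage 0/1/2/NA) keep sites with MAF strictly above 0.05
over non-missing alleles and missingness strictly below 0.20 over all
samples; filtering is idempotent. Thinning keeps indices 0, 37, 74, … in
genome order (offset configurable).

## 8. The synthetic generator and what passing tests mean

`simulation_config()` defaults *are* the study conditions: a 5 Mb
single-chromosome ancestor at GC 0.37 carrying 200 multi-exon genes; two
descendant lineages each receiving half of 24 substitutions and 6
small-indel events per kb (sizes 1–10 bp); 30 planted lineage-specific
insertions per genome, 0.6–10 kb, half carrying a complete embedded gene;
30× single-end 150-bp reads with 0.1% substitution error. Determinism is
by construction: every operation draws from a substream derived from the
single seed and a stage name, so identical configurations are
byte-identical and stage order cannot change results.

Choices worth knowing:

* **Events are disjoint.** Substitutions and indels avoid annotated CDS,
  planted segments, and each other (with a one-base spacer), so truth
  classes never overlap and the true pairwise alignment is exactly
  reconstructable (`truth_alignment()`), with planted segments as block
  boundaries. This is what makes "retained variant counts equal truth
  exactly" a meaningful assertion.
* **Duplicate pairs at a target Ks** are planted by inverting the
  Jukes–Cantor correction analytically (`pS = (3/4)(1 - e^{-4Ks/3})`) and
  marking that expected proportion of synonymous positions for a uniform
  draw within the position's synonymous codon class — no rejection
  sampling, and the NG86 estimator is not consulted while planting.
* **LTR pairs at a target K** plant the Jukes–Cantor inverse as an exact
  count of differing sites at random positions (random transition or
  transversion), so the realised divergence is the recorded truth rather
  than a binomial draw around it; at K = 0.005 on 1 kb repeats the
  binomial alternative would leave ~10% noise in the truth itself.
* **Reads** are single-end and uniform because the read-support filter
  needs coverage only.

What the generator does **not** emulate — and therefore what passing
tests do not show about real data: repetitive DNA and transposon
families (the i.i.d. background makes 15-mers nearly unique, so the
mapper faces no repeat ambiguity), inversions and translocations,
GC-biased or position-dependent error profiles, paired-end information,
alternative splicing beyond multiple transcripts of identical strand,
and real aligner idiosyncrasies. On repeat-rich genomes the window
mapper's `max_occ` cutoff and the one-to-one chainer would both face
harder instances than any test here exercises.

Problem sizes in the shipped tests and acceptance script (5 Mb pairs for
the PAV scan, 0.5–1 Mb elsewhere, n = 20–50 per planted class) were
chosen as the smallest sizes at which the binomial/KDE tolerances above
are comfortably non-flaky under a fixed seed.

## 9. Degenerate inputs and numerical conventions

Zero-length CDS genes are skipped with a warning; candidates lacking read
coverage are a hard error naming the genes; all-missing matrix sites are
removed with a warning; fewer than 30 Ks values refuse a KDE; a histogram
with no valley refuses a genome size. Coordinates are 0-based half-open
internally everywhere, converting at the GFF3 (1-based inclusive) and
BED (native) boundaries; strand is recorded but window logic runs on the
forward strand of each assembly, with coverage computed on query
coordinates regardless of strand. Boundary comparisons follow the quoted
conventions exactly: "< 25%", "> 75%", "> 50%", "> 500 bp", "> 5 kb" are
all strict.

## 10. Limitations

* The internal mapper is a coverage instrument, not a general aligner:
  no gapped extension, no split alignments, no mapping quality. For
  publication-grade PAV calls on real assemblies, feed PAF from a real
  aligner; the classification and merging layers are unchanged.
* NG86 is the classical estimator; it ignores transition/transversion
  bias and codon frequencies. Saturated pairs are flagged, not rescued.
* The WGD bin boundaries are fixed conventions, not fitted mixture
  components; `ks_distribution_peaks()` locates modes but does not
  deconvolve overlapping events.
* The k-mer heterozygosity statistic is a species percentage; converting
  it to a per-base rate requires the `2p/(1+p)` relation above and
  error-free, unbiased coverage assumptions that real libraries violate.
* `run_pipeline()` orchestrates the synthetic end-to-end flow and simple
  two-assembly scans; it is a reproducibility harness, not a workflow
  engine.
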