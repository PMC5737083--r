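---
title: "Short inverted repeats and localized somatic mutability: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Short inverted repeats and localized somatic mutability: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirmut)
```

## The model

A short inverted repeat (SIR) is a pair of reverse-complementary arm
sequences separated by a short spacer. On transiently single-stranded DNA the
arms can hybridize into a hairpin stem while the spacer forms the loop.
`sirmut` quantifies whether, in a somatic mutation catalog, the loop domain
is more mutable than its surroundings, and turns that excess into two
inferential products: *highly mutated SIRs* (per-locus binomial enrichment
over the locus's own flanking background) and *SIR hotspots* (spacer
sequences more mutable inside SIRs than identical sequences not flanked by
palindromic arms). Hotspot mutation counts per sample then serve as a cheap
marker of mismatch-repair deficiency (MSI) or APOBEC activity.

## Detection

The scanner considers windows `left arm + spacer + reverse complement of the
left arm` with spacer lengths 4–8 bp and arm lengths 6–25 bp by default —
loops shorter than 4 bp are sterically disfavored, stems beyond ~25 bp add
no stability — and requires exact arm complementarity (mismatch-tolerant or
gapped stems are out of scope). Three rules reduce raw windows to the final
SIR set, in this order:

1. **Per-extent canonicalization.** Windows spanning the identical genomic
   interval are one hairpin read several ways (an 18-mer can be arm 7/loop 4,
   arm 6/loop 6, or arm 5/loop 8). The most stable category is kept: loop as
   short as possible (≥ 4 bp), arm as long as possible. For a fixed extent
   the two criteria coincide.
2. **Pure-A/T spacer filter** (configurable, on by default): spacers with no
   C or G are removed.
3. **Overlap resolution.** At low-complexity loci SIRs chain into overlapping
   clusters; only the longest survives (ties: leftmost start, then smaller
   spacer). Ties are broken deterministically so runs are reproducible.

Any window containing N is never emitted. Only the forward strand is
scanned: an inverted repeat is the same double-stranded object on both
strands, and the test suite checks that scanning the reverse complement of a
chromosome yields the mirror-image coordinate set. Internally coordinates
are 0-based half-open; serialized tables are 1-based inclusive, BED output
0-based half-open.

A deliberate wrinkle: `enumerate_ir_decompositions()` exposes an `arm_floor`
argument separate from the detection arm range, because the canonical
worked example (`AGGCTAGCTGGCTAGCCT`) counts a 5 bp-arm category even though
detection starts at 6 bp arms. The default floor is the configured arm
minimum; pass 1 to enumerate every palindromic split.

## Domains and densities

Each SIR contributes three disjoint domains: the spacer, the two arms, and
two flanking control windows (100 bp each side; 1000 bp for rearrangement
breakpoints, which are too sparse for 100 bp windows). Controls are
truncated at chromosome ends, other SIR bodies are carved out of them, and N
positions are excluded from length denominators. Mutations are assigned by
point containment — the mutated base for substitutions, the first affected
base (position after the left-aligned anchor) for indels, the breakpoint
position for rearrangements. A point inside an SIR body takes that SIR's
domain even when it also sits in a neighbor's control window; a point in two
SIRs' control windows is labelled once (nearest SIR, ties leftmost) for
global densities, but counts once per SIR when each SIR's own background is
estimated. Density is mutations per bp per sample-genome, reported per Mb.

The distance-to-center profile normalizes, at each offset from the SIR
center, by the number of SIRs contributing a valid position at that offset
(availability-normalized, not raw counts). For even spacers the center is
the left-of-middle position — stated explicitly because any fixed choice is
defensible and only a fixed choice is reproducible.

## Enrichment statistics

The per-SIR test treats every spacer position in every sample as a Bernoulli
trial: with `L` the spacer length, `n` the cohort size and `d` the per-bp
per-sample mutation rate in that SIR's own control windows, the p-value is
the exact binomial upper tail `P[X >= k]` for `X ~ Binomial(L * n, d)`.
Expressing `d` per position-sample is what makes it a probability and the
parameterization coherent. Only SIRs with at least one spacer mutation form
the tested family; Benjamini–Hochberg correction is applied within the
family and SIRs at `q <= 0.01` are flagged. A background rate of zero with a
positive count yields `p = 0` by convention; SIRs with no usable control
sequence are excluded with a message. Overlapping flagged SIRs collapse
into one genomic site represented by the longest member (ties leftmost);
abutting SIRs share no base and remain separate sites.

The hotspot test pools each spacer sequence with its reverse complement —
a spacer and its reverse complement are the same double-stranded sequence —
and compares occurrences inside SIR spacers against every exact occurrence
lying wholly outside any SIR. Per-sequence pooling (not per-location
testing) defines the family; per-location results are available from the
per-SIR table. Sequences with no out-of-SIR occurrence are reported
untestable rather than silently dropped. These per-sequence tests form a
second BH family, separate from the per-SIR family.

Odds ratios of spacer versus control mutability are computed from the 2×2
table of mutated versus non-mutated position-sample units, with the
Haldane–Anscombe 0.5 correction when a cell is empty and a Wald 95% CI on
the log odds ratio. Multiple mutations at one position-sample collapse to
"mutated" (rare at realistic densities).

## Sample classification

Hotspot sites partition by spacer composition: A/T-only sites are
informative for MSI, GC-containing sites for APOBEC. A sample is flagged
MSI at ≥ 16 mutated A/T-only sites and APOBEC at ≥ 7 mutated GC-containing
sites (both configurable; a site counts once however many mutations hit
it). These counts were calibrated against a genome-scale bank of ~283
sites; on desk-scale simulations the bank is far smaller, so simulation
exercises specificity while threshold boundary behavior is tested with
constructed site banks.

There is a tension worth naming: detection removes pure-A/T spacers by
default, yet A/T-only hotspot sites are the MSI-informative half of the
classifier. The package keeps the filter configurable; MSI-oriented
analyses run detection with `drop_pure_at = FALSE`.

Signature-phenotype clustering uses Ward linkage on Euclidean distance of
exposure proportions (the linkage/metric is a package choice; nothing in
the procedure pins it down) cut at k = 5, and names clusters by mean
signature content with a 20% proportion floor: signatures 2/13 → APOBEC,
6/20/26 → MSI, both → APOBEC+MSI, 3 → BRCA, otherwise Others.

## The synthetic cohort

The generator is first-class, tested code: it defines the conditions under
which every downstream claim is checked.

* **Genome.** One chromosome of i.i.d. bases at a target GC (default 0.4,
  40–200 kb in the shipped analyses). Planted SIRs are placed in
  equal-width slots so loci are separated by more than twice the control
  width, keeping each plant's controls free of other plants. Two rejection
  screens keep the truth manifest exact: the planted arm+spacer sequence is
  redrawn until it scans (after overlap resolution) as exactly its intended
  category, and the background around each plant is redrawn until no
  unplanted SIR comes within a control width. Nested arm-trimmed sub-SIRs
  of a plant are unavoidable and are exactly what the longest-SIR rule
  removes, so the screens compare the resolved set.
* **Mutations.** Per sample, independent per-position Bernoulli draws at the
  background density (default 2×10⁻³ per bp per sample across 120 samples —
  orders of magnitude above real cohorts so that desk-scale sequence carries
  comparable counting statistics), multiplied by the planted fold inside
  planted spacers (default 1.35, the domain-level effect size the method is
  built to detect; hotspot plants carry their own folds). APOBEC-like
  samples put 75% of their expected mass on TCN-context C (either strand,
  alt T/G), scaled by the local rate so folds carry through; MSI-like
  samples add 1-bp deletions at A/T mononucleotide runs (length ≥ 5) and
  planted A/T-only spacers; flat samples are uniform. Each sample's stream
  derives from the master seed by counter, so enlarging the cohort never
  perturbs existing samples; at most one substitution per sample-position.
* **What it does not emulate.** Chromatin- or replication-timing covariation
  of mutation rate, low-complexity and repeat structure of real genomes
  (background SIR density here is ~1200–1600/Mb versus 2000–3000/Mb in real
  sequence), arm/spacer GC contrasts, indel length spectra beyond 1 bp, and
  rearrangement mechanisms (breakpoints are uniform if enabled). Passing
  tests therefore demonstrate correctness of the machinery and parameter
  recovery under known truth — not that real genomes meet these
  assumptions.

## Numerical choices

* Binomial tails come from `pbinom(..., lower.tail = FALSE)`; the suite
  checks them against a direct term-by-term summation oracle to 10⁻¹²
  relative tolerance, including a large-trials boundary case.
* BH adjustment is `p.adjust(..., "BH")`, checked against the literal
  step-up definition on 1000 random vectors.
* Zero-background and zero-length denominators yield documented conventions
  (`p = 0` with positive counts; `NA` densities), never division errors.
* Overlap clustering uses interval algebra with `min.gapwidth = 0` where
  "overlap" must mean sharing a base.
* The quadratic density–GC fit is ordinary least squares and refuses
  rank-deficient designs.

## Problem sizes

The shipped analyses and acceptance checks run on one CPU: scanner-oracle
equivalence on 200 sequences of 500 bp; type-I control pooled over 20
replicates of (40 kb, 40 plants, 60 samples); fold recovery pooled over 20
replicates of (50 kb, 50 plants, 120 samples, 2×10⁻³), sized so the pooled
standard error of the fold (~0.03–0.05) sits well inside the ±0.1
acceptance band; hotspot power over 3 planted sequences × 5 replicates with
≥ 30 expected spacer mutations per sequence. These sizes are the package's
chosen study conditions for its claims.

## Known limitations

Perfect-match arms only; single point assignment per mutation; no
thermodynamic stability model (stability enters only through the
shortest-loop/longest-arm preference); per-signature attribution uses
generator labels or exposure weighting, not posterior per-mutation
assignment; the classifier thresholds are fixed cohort-scale constants, not
re-estimated from data.
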