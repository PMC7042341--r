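---
title: "Methods: fragment calling, pool deconvolution and response statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fragment calling, pool deconvolution and response statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neofrag)
```

## The problem

During chemotherapy-induced apoptosis, caspases cleave a subset of the
tumour-cell proteome. The resulting fragments can be processed and
cross-presented far more efficiently than their folded parent proteins, so
self proteins that are tolerated in live cells can act as *non-mutated
neoantigens* once fragmented. `neofrag` implements the analysis chain that
turns this observation into candidate targets: call fragmented proteins from
SILAC quantitation of apoptotic versus live cells, design an
overlapping-peptide library over the fragment evidence, pool the peptides in
a deconvolvable matrix, and summarise the T-cell responses and survival
association measured against those pools.

## Fragment calling from SILAC GeLC-MS

**Quantitation model.** Each protein row carries an apoptotic/live abundance
ratio, the theoretical molecular weight of the intact chain (MWcal, kDa),
and the apparent weight range (MWexp, kDa) of the gel section its peptide
evidence came from. In the forward experiment apoptotic cells are
heavy-labelled, so the ratio is heavy/light; the reverse (label-swap)
replicate inverts this. One-channel detections — no detectable live-channel
partner — are represented by a configurable cap (default 100, the value
quantitation software prints for such rows) with a `capped` flag; whether
printed 100s are a software cap or a computed value is not documented
upstream, and the cap interpretation is the conservative one.

**Classification rule.** An entry is FRAGMENTED when

* `mwexp_hi < mwcal` (strict; the gel section lies wholly below the intact
  mass), and
* the entry is apoptotic-enriched: ratio > 1 (strict) or capped.

This molecular-weight rule takes precedence over the abundance thresholds:
a fragment call is never demoted by its ratio, which matters because
genuinely fragmented proteins can show ratios barely above 1 (the packaged
table contains a 1.01 example). Entries that fail the MW rule are
UPREGULATED above a 2-fold increase, DOWNREGULATED below 0.5, else
UNCHANGED. Only the upregulation side of the window (a greater-than-2-fold
increase) is fixed by the protocol this implements; a symmetric 2-fold
window is used for the downregulated class because the source data
distinguish downregulation from no change, which a single threshold cannot.

**Gel sections.** The protocol cuts the lane into 16 sections spanning
5–250 kDa but does not publish the cut positions. The default is 17
log-spaced breakpoints over that range — SDS-PAGE migration is roughly
logarithmic in mass — and the boundaries are a single configuration entry
(`nf_config()$gel_section_boundaries`) shared by the classifier and the
synthetic generator, so they can be replaced by measured positions. Sections
are half-open `[lo, hi)` intervals indexed from the lightest band; masses
below 5 kDa fall into the lightest band, masses at or above 250 kDa are an
error.

**Peak-pair matching.** Peak lists are treated as singly charged centroids
(MALDI context; no charge deconvolution). Candidate pairs are peaks whose
mass difference is within a tolerance (default 0.05 Da) of one of the five
label shifts computed from isotope-mass arithmetic
(Δ(^13^C−^12^C) = 1.003355 Da, Δ(^15^N−^14^N) = 0.997035 Da): one Lys 6.02,
one Arg 10.01, two Lys 12.04, Lys+Arg 16.03, two Arg 20.02 Da. Pairs are
accepted greedily by smallest deviation from the nominal shift, ties broken
by lower light m/z, each peak used at most once. The greedy rule is a
documented heuristic: it always returns admissible, disjoint pairs, but on
adversarial inputs it can return fewer pairs than a maximum matching would.

**Replicate concordance** intersects fragment calls by accession, never by
gene symbol — printed gene names are not reliable join keys (the packaged
table itself spells one gene two ways across its blocks).

## Peptide library

Around every MS-identified peptide (minimum six residues, the instrument's
identification floor) a region of 20 flanking residues on each side is
selected and clipped to the protein; overlapping or adjacent expanded
regions of one protein are merged before tiling, so no residue is
synthesised twice. Regions are tiled with 20-mers stepping by
`length − overlap` = 8 residues. If the last stepped tile misses the region
end, one extra tile is *right-anchored* to end exactly there — keeping every
tile full length, which is what synthesis panels want — so the tile count
for a region of R ≥ 20 residues is `(R−20)/8 + 1` when 8 divides R−20 and
`floor((R−20)/8) + 2` otherwise. Regions shorter than 20 residues yield one
whole-region tile flagged `short` rather than being dropped. Tile ids
(`accession_start`) are deterministic so pool designs are reproducible.

## Pool matrix and deconvolution

Each peptide goes into exactly two pools, no two peptides share the same
pool pair, and pool sizes stay within one of each other; with 12 pools the
capacity is choose(12, 2) = 66 peptides, and 37 peptides fill ten pools of 6
and two of 7.

The constructor is worth a note. A purely local greedy rule — "give the next
tile the unused pair with the least-loaded pools" — can strand the last two
least-loaded pools on a pair that is already used, breaking the balance
guarantee (with 6 pools and 6 tiles it produces a load spread of 2, and at
37/12 it yields pool sizes 5–7). `design_pools()` therefore assigns, at each
load level, an exact maximum matching of the unused pairs among the
least-loaded pools (lexicographic tie-breaks), falling back to the
least-loaded partner when no within-level pair remains. A sweep over 3–13
pools and every prefix size confirms the max−min ≤ 1 balance everywhere.
The seed only permutes which tile receives which pair.

Deconvolution returns every tile whose two pools are positive, and flags the
result ambiguous unless that candidate set is the unique minimal explanation
of the readout: each positive pool covered, and every candidate essential
(contributing a pool no other candidate covers). Counting covering subsets
reduces to that essentiality check, which keeps the test exact without
enumerating 2^k subsets. Ambiguity is reported, never silently resolved —
re-testing single peptides is a wet-lab step outside this package.

## Response and survival statistics

* **Net response** = max(stimulated − unstimulated, 0) percentage points.
  Whether published plots show raw or subtracted percentages is not stated;
  subtracted is adopted throughout.
* **Responder floor**: no numeric responder cut-off is published; the
  default is net ≥ 0.01 percentage points (closed threshold), configurable
  and logged.
* **Magnitude** is the arithmetic mean of net responses across patients per
  (pool, subset, cytokine, timepoint); missing cells are excluded pairwise
  with the count reported, never imputed. The dual-cytokine channel
  (IFN-γ⁺TNF-α⁺) is an independent measurement, not derived from the
  single-cytokine channels.
* **Responder fold change** between the post-checkpoint and
  post-chemotherapy stages uses ratio sentinels: positive/0 → `Inf`,
  0/0 → `NaN`.
* **Group comparisons**: classical pooled-variance two-sample t (Welch by
  flag) with zero-variance sentinels (t = 0, p = 1 for equal means;
  t = ±Inf, p = 0 otherwise), and a thin one-way ANOVA wrapper for the
  across-stage comparison. These are supporting statistics.
* **Survival**: patients are median-split on a response level; values
  strictly above the median are HIGH, ties at the median go LOW ("above the
  median" is read as strict exceedance). Kaplan–Meier curves use the
  product-limit estimator and the comparison is the Mantel–Cox log-rank
  statistic `(ΣO − ΣE)² / ΣV`, two-sided from chi-square(1), with the
  standard simultaneous-risk-set tie convention and censoring at an event
  time counted after the event. Both are computed via the `survival`
  package behind this module's interface; hand-derived values (e.g.
  chi-square 49/17 for HIGH events {1, 2} vs LOW {3, 4}) pin the convention
  in the tests. One property worth stating precisely: appending a censored
  subject *before* the first event leaves the statistic unchanged (it never
  enters a risk set), but a censored subject after the last event does
  change it, because it inflates every risk set.

## What the synthetic generator emulates

The generator replaces patient and raw MS data so every stage is testable
offline. Its defaults are the study conditions, chosen once:

* **Proteome**: 200 proteins, uniform residue composition, lengths uniform
  on 100–900 residues (masses ≈ 11–107 kDa, safely inside the 5–250 kDa gel
  range).
* **Classes**: 8% fragmented, 30% upregulated, 50% downregulated, remainder
  unchanged — mirroring the observed predominance of regulation over
  fragmentation. True ratios are log-uniform (2.5–30 up, its reciprocal
  down, ≈1 unchanged, 2–30 fragmented); 30% of fragmented proteins are
  one-channel (capped) detections.
* **Fragmentation** is deliberately minimal caspase emulation: cleavage
  C-terminal to a randomly chosen aspartate (uniform fallback without a D),
  the fragment being the shorter side, with mass from standard average
  residue masses + water. Sites are resampled until the fragment lands at
  least one gel section below the intact protein (fallback: lightest
  fragment), and fragments of at least six residues receive one
  MS-identified evidence peptide (≤12 residues) inside them. Full
  DEVD-motif specificity is unnecessary for exercising the classifier.
* **SILAC noise**: true ratios × independent lognormal(0, σ = 0.25) noise
  per orientation. The molecular-weight side of the fragment rule is
  noise-free by construction (the gel section is derived from the true
  fragment mass), so classification errors come from ratio noise alone; at
  σ = 0 both orientations reproduce the truth exactly, which the tests use
  as the label-swap concordance limit.
* **Cohort**: 14 patients at T0/T1, 12 continuing to T2 (matching the
  treated-cohort structure); per patient × timepoint × subset × cytokine ×
  pool, background near 0.02 ± 0.005 percentage points and a stage effect
  (T0 0.02, T1 0.15, T2 0.40 percentage points) confined to pools containing
  truth-positive tiles, under lognormal(0, 0.25) effect noise. PD-1 within
  specific cells follows 20 → 45 → 18 percent means (rise after
  chemotherapy, fall under checkpoint blockade). The truth-positive tiles
  are drawn so that their combined pool readout deconvolves uniquely —
  emulating how pool matrices are planned around resolvable positives — with
  a default of two positives per cohort.
* **Survival**: exponential months with baseline hazard 1/30 per month
  (mean 30 months in the low-response group, consistent with the reported
  overall-survival scale), divided by a hazard ratio of 3 for patients whose
  CD8 IFN-γ net response at T2 exceeds the cohort median; independent
  exponential censoring calibrated to 20% in the baseline group.

What it does **not** emulate: isotope envelopes or raw spectra, retention
time, shared-peptide protein inference, decoy FDR, flow-cytometry gating,
HLA restriction, or checkpoint pharmacology. Passing tests therefore
demonstrate the internal consistency and statistical behaviour of the
pipeline under its assumed data model, not instrument-level fidelity.

## Problem sizes used by the test suite

The suite establishes the operating characteristics at sizes chosen to make
the checks sharp but quick: fragment-recovery F1 on one seeded 200-protein
proteome at default noise (the observed F1 is 1.0, since only ratio noise
can flip a call); cohort magnitude ordering T0 < T1 < T2 over 100 seeded
cohort replicates; log-rank power at hazard ratio 3 and calibration at
hazard ratio 1 over 500 seeded replicates each at n = 60 — the study's own
cohort (n = 12 at T2) is far below the size where the split reliably reaches
significance, as the README example shows honestly.

## Known limitations

* The greedy peak-pair matcher is heuristic (see above); lists with heavy
  near-nominal interference can be under-paired.
* Multi-peptide proteins spanning several gel sections are reduced upstream
  to one MWexp range; this package consumes that single range and takes no
  position on the reduction rule beyond documenting the convention.
* The responder floor and the gel-section boundaries are conventions, not
  published values; both are configuration entries precisely so that they
  can be replaced when the underlying values are known.
* Deconvolution identifies candidates; confirming them (single-peptide
  re-testing) is outside the package.
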