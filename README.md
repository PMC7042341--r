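# neofrag

Tumour cells killed by chemotherapy do not just die: caspases chop up part
of their proteome, and some of those fragments behave as *non-mutated
neoantigens* — self proteins that become immunogenic only in their cleaved,
apoptotic form. `neofrag` implements the computational side of a
target-discovery platform built around that observation, for proteomics and
tumour-immunology analysts:

1. **Fragment calling from SILAC GeLC-MS.** Apoptotic (heavy-labelled) and
   live (light-labelled) tumour cells are compared in one mass spectrum.
   A protein identified in a gel section whose apparent molecular weight
   range lies strictly below the theoretical weight of the intact chain
   (MWexp < MWcal), while being enriched in the apoptotic channel
   (apoptotic/live ratio > 1, or a one-channel detection), is called
   **FRAGMENTED**; otherwise the 2-fold abundance window separates
   UPREGULATED / DOWNREGULATED / UNCHANGED. Label-swap (forward/reverse)
   replicates are intersected by accession. Heavy/light peak pairs are
   matched by the five nominal label shifts of ^13^C~6~-Lys /
   ^13^C~6~^15^N~4~-Arg tryptic peptides (6.02, 10.01, 12.04, 16.03,
   20.02 Da).
2. **Epitope library and pool matrix.** Around each MS-identified peptide a
   ±20-residue region is selected, merged, and tiled into 20-mers
   overlapping by 12 residues; tiles are distributed into a 2-of-N pool
   matrix (each peptide in exactly two pools, every pool pair unique, pool
   sizes within one of each other) so a positive pool pair identifies a
   single peptide, with explicit ambiguity flagging on deconvolution.
3. **Response and survival statistics.** Net cytokine responses
   (stimulated − unstimulated, floored at 0), per-pool cohort magnitude
   (mean across patients), responder fold changes between treatment stages,
   PD-1 kinetics within antigen-specific T cells, and a median-split
   Kaplan–Meier / Mantel–Cox log-rank comparison of overall survival by CD8
   response level.
4. **A seeded synthetic-data generator** producing proteomes with
   caspase-type (post-aspartate) fragments, forward/reverse SILAC tables
   with lognormal ratio noise, and patient cohorts with staged effects
   (T0 < T1 < T2), PD-1 rise-then-fall, and survival coupled to CD8
   response — so the whole pipeline is testable with no patient or raw MS
   data.

## Worked example

```r
library(neofrag)

# classify the packaged reference quantitation table (forward SILAC block)
quant_fwd <- read_quant_table(
  system.file("extdata", "table1_forward.tsv", package = "neofrag"),
  orientation = "forward")
calls_fwd <- classify_quant(quant_fwd)
table(calls_fwd$label)
#> FRAGMENTED
#>         16

calls_rev <- classify_quant(read_quant_table(
  system.file("extdata", "table1_reverse.tsv", package = "neofrag"),
  orientation = "reverse"))
replicate_concordance(calls_fwd, calls_rev)
#> [1] "P07602" "P53634" "P63261" "Q86UE4" "Q8IZ41" "Q8NGV7"
```

All 16 forward entries and 11 reverse entries of the packaged table are
fragment calls, and six accessions — dipeptidyl peptidase 1, cytoplasmic
actin 2, olfactory receptor 5H2, RASEF, protein LYRIC and the proactivator
polypeptide — are concordant between the label-swap replicates.

```r
design <- design_pools(paste0("pep", sprintf("%02d", 1:37)), n_pools = 12)
design
#> Two-of-N pool design: 37 tiles in 12 pools
#> pool sizes: 7 6 6 6 6 6 6 7 6 6 6 6

deconvolve_pools(design, positive_pools = c(3, 9))
#> $positive_pools: 3 9
#> $candidate_tiles: "pep21"
#> $ambiguous: FALSE
```

37 peptides fill ten pools of 6 and two pools of 7; a positive pool pair
points at exactly one peptide.

```r
ex <- simulate_experiment(sim_config(rng_seed = 42))
calls <- classify_quant(ex$silac$forward)
tp <- sum(calls$label == "FRAGMENTED" & ex$truth$class == "FRAGMENTED")
fp <- sum(calls$label == "FRAGMENTED" & ex$truth$class != "FRAGMENTED")
fn <- sum(calls$label != "FRAGMENTED" & ex$truth$class == "FRAGMENTED")
2 * tp / (2 * tp + fp + fn)
#> [1] 1

fit <- survival_by_response(ex$cohort$survival)
c(fit$test$chi_square, fit$test$p)
#> [1] 1.02 0.312
```

On a 200-protein synthetic proteome at default noise the fragment calls
recover the generating truth perfectly (F1 = 1; the molecular-weight rule is
noise-free by construction, so errors arise only from ratio noise). The
log-rank comparison on the 12 simulated T2 patients is *not* significant —
expected at that cohort size; the power properties of the test are
established at n = 60 in the test suite.

## Documentation

The methods vignette (`vignettes/neofrag-methods.Rmd`) describes the
classification model and its assumptions, the pool-matrix constructor, the
statistical conventions, what the synthetic generator does and does not
emulate, and known limitations.
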