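# nanolayers

Nanoscale image-analysis toolkit for layered membrane fluorescence:
super-resolution reconstruction from temporal confocal stacks,
intensity-weighted spatial clustering statistics, and nanometre-scale
inter-layer distance estimation, with seeded synthetic generators that
provide ground truth for every stage.

The package grew out of a concrete biological problem: the mosquitocidal
*Bacillus thuringiensis* toxins Cry11Aa and Cyt1Aa act synergistically on
*Aedes aegypti* larval midgut cells, and during synergism the two proteins
organise into distinct layers a few tens of nanometres apart on the apical
microvilli — below the diffraction limit of confocal microscopy. Resolving
that architecture takes three analysis stages, each implemented and
testable here:

1. **`srrf_core`** — reconstruct a super-resolved image from a stack of
   ~100 frames of one plane: per-frame *radiality maps* (gradient
   convergence on a magnified grid; defaults ring radius 0.5, magnification
   10, 8 ring axes) integrated by the second-order temporal cumulant at
   lag 1 (TRAC2), which cancels static structure and keeps blinking
   emitters.
2. **`ripley_stats`** — quantify spatial organisation of one channel's
   intensity field with an intensity-weighted, Besag edge-corrected
   Ripley K,

   `K(r) = A Σ_{i≠j} w_i w_j e_i(r) 1(d_ij ≤ r) / (Σ w)²`,

   normalised against a within-window intensity-permutation null:
   `K̃(r) = (K − mean_null)/SD_null`, compared to 1st/99th-percentile
   envelopes (200 permutations, Δr = 25 nm). Per-radius classification is
   clustered / random / dispersed; the group summary statistic is
   argmax(K̃), compared across conditions by Kruskal–Wallis with Dunn–Holm
   post hoc tests.
3. **`carpet_align`** — measure the signed distance between two protein
   layers: rotate the membrane horizontal, cut the ROI into 25 nm-wide
   perpendicular line profiles ("intensity carpets"), undo membrane
   stretching/folding by aligning each column to a reference via the
   paired correlation function `pCF(∂y) = ⟨F(y,0)F(y+∂y,∂r)⟩ /
   (⟨F(y,0)⟩⟨F(y,∂r)⟩) − 1`, then read the inter-layer distance per column
   from the argmax of the paired cross-correlation (pCCF) with sub-bin
   quadratic refinement. Negative distances face the cytoplasm; summary
   mean ± SEM is taken over cellular replicates and modes of the pooled
   distribution are detected by kernel density.

Supporting modules: `synthgen` (blinking emitter stacks, deformed
two-layer membranes, CSR/Thomas/hard-core point fields — all seeded, all
carrying their ground truth as metadata), `quant_stats` (ROI fluorescence
comparisons, dye degree-of-labeling, Tabashnik synergism factor), and a
pipeline layer (`run_demo_synergy_layers()`, TIFF/CSV/JSON I/O, and a thin
CLI at `inst/cli/nanolayers.R` with `simulate | srrf | ripley | carpet |
quant | demo` subcommands).

## Worked example

Measure a 26 nm inter-layer offset from 30 simulated two-channel membrane
ROIs (10 × 5 µm, Gaussian-process deformation of 200 nm amplitude, Poisson
noise), and compute the synergism factor of the published crystal-mixture
LC50s:

```r
library(nanolayers)

dd <- layer_distance_experiment(n_carpets = 30, offset_nm = -26, seed = 11)
dd
#> <distance_distribution> 11955 distances, 30 replicates: mean -26.1 nm (SEM 0.19)
#>   modes at: -26.3 nm

sf <- tabashnik_sf(lc50_a = 329.3, lc50_b = 679.23, observed = 51.53)
round(sf$theoretical_lc50, 2)   # 443.56  (harmonic additive expectation, ng/ml)
round(sf$synergism_factor, 1)   # 8.6     (> 1: synergism)
```

The distance summary recovers the injected −26 nm offset with
sub-nanometre bias and the cytoplasm-facing (negative) sign; the detected
single mode sits at the injected offset. Simulating the inverted geometry
(`offset_nm = 26`) flips the sign, mirroring the behaviour of the
non-oligomerising mutant condition.

A full end-to-end demonstration — wild-type-like and inverted membrane
pairs plus clustered and random point fields — is one call:

```r
res <- run_demo_synergy_layers(pipeline_config(seed = 1), n_carpets = 8)
res$summary$wt_mean_nm    # ~ -26 (nm)
res$summary$mut_mean_nm   # ~ +26 (nm)
res$summary$thomas_argmax_nm  # submicron argmax of K~ for the clustered field
```

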