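# ringseg

Automatic tree-ring boundary delineation on stained wood microsections,
with the evaluation framework quantitative wood anatomy (QWA) needs to
trust such delineations.

## The problem

QWA measures wood at the cellular level — vessel lumen areas, cell
patterns — from high-resolution RGB scans of stained microsections
(typically 1.63 µm/px). Every measurement must be assigned to a calendar
year, which means every annual ring boundary must be delineated on images
that are tens of thousands of pixels tall. Manual delineation is slow and
operator-dependent; naive pixel-level comparison of two delineations is
useless (two perfect 1-px lines drawn 1 px apart share zero pixels), so
assessing an automatic method also needs boundary-level criteria.

`ringseg` provides:

- a **2-D UNETR** semantic-segmentation network — a vision-transformer
  encoder over 16×16 image patches with learned positional embeddings,
  feeding a convolutional decoder through skip connections at four encoder
  depths — built from scratch in R (BLAS-backed forward and backward
  passes, Adam optimizer), trained with the **Focal Tversky loss**

  L(Y, Ŷ) = (1 − TI)^γ,  TI = Σyᵢŷᵢ / (Σyᵢŷᵢ + α Σyᵢ(1−ŷᵢ) + β Σ(1−yᵢ)ŷᵢ + ε)

  with α = 0.7, β = 0.3, γ = 0.75, ε = 1e−12;
- whole-image inference with an **overlap-tile** strategy (90 % overlap by
  default), **test-time augmentation** over the dihedral group of order 4
  (per-pixel maximum of the 8 aligned outputs), min–max normalization and
  a 0.2 probability threshold;
- post-processing to 1-px boundary paths: Zhang–Suen **skeletonization**
  and **Discrete Skeleton Evolution** pruning (end-branches contributing
  < 100 px to the maximal-disk shape reconstruction are removed);
- the four-criterion **QWA evaluation**: pixel agreement
  (precision/recall/F1/IoU), spacing of per-boundary mean positions (px
  and µm), vessel-to-ring mismatch counts, and expert-label agreement
  summaries;
- a seeded **synthetic microsection generator** (tall cores, wavy dark
  fiber bands, semi-ring-porous vessel fields with ~120 vessels per ring)
  so the whole pipeline is testable end to end with known ground truth.

## Worked example

The demonstration pipeline generates annotated synthetic cores, trains a
tiny UNETR (K = 32, 4 transformer layers) on ~190 patches of 256×256,
segments three held-out cores, reduces the masks to boundary paths and
evaluates them against the ground truth — about 5 minutes on one CPU:

```r
library(ringseg)
res <- run_pipeline(demo_pipeline_config("demo_out", seed = 42))
res$summary
#>   n_true_boundaries n_matched n_manual_only n_predicted_only
#> 1                 6         6             0                0
#>   mean_center_distance_px mean_center_distance_um mean_vessel_mismatch
#> 1               0.6141842                 1.00112                    0
```

All 6 true boundaries were recovered; the mean distance between the true
and predicted per-boundary mean positions is ~0.6 px (~1 µm at
1.63 µm/px), and no vessel changed its ring assignment — the quantity QWA
actually cares about.

The same stages are scriptable from a shell via `exec/ringseg`
(`generate | predict | postprocess | evaluate | demo`), e.g.

```sh
Rscript exec/ringseg demo --out demo_out --seed 42
```

The evaluation utilities also reproduce summary-table arithmetic directly:

```r
px_to_um(35.85)                        # 58.4355 -> printed 58.43
relative_vessel_divergence(1.18, 120)  # 0.983 % (< 1 %)
```

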