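# reorientr

Analysis of hippocampal CA1 place-cell activity during **spatial
reorientation** in a two-context task. Disoriented mice relocating a
buried reward in two visually distinct but geometrically identical
rectangular chambers must recognise *which* chamber they are in (context
recognition, from wall features) and recover their facing direction
within it (heading retrieval, from geometry). Because a rectangle has
180° rotational symmetry, CA1 place maps of disoriented animals flip
between two orientations across trials; a minority of cells additionally
remaps across contexts. `reorientr` implements the complete analysis
chain for quantifying both processes, plus a ground-truth synthetic
session generator so every stage is testable without raw recordings.

For neuroscientists analysing position-tracked spike trains or
deconvolved calcium event trains from repeated short trials in
symmetric environments.

## What it computes

- **Rate maps** — occupancy-normalised 1 cm maps with a 2 cm/s speed
  filter, Gaussian smoothing (σ = 3 cm), a 0.05 s occupancy mask, and a
  homography-based alignment of video coordinates to the canonical
  20 × 30 cm chamber frame; anisotropic compression to 20 × 20 squares.
- **Best-match rotation (BMR)** — the quarter-turn θ ∈ {0°, 90°, 180°,
  270°} maximising the pixel-wise Pearson correlation between two trial
  maps; per-cell BMR proportions (66 pairwise comparisons per 12-trial
  session), ensemble coherency tables ranked 1st–4th against the 25%
  chance share, and joint 1st/2nd-BMR distributions.
- **Center-out angles** — place-field detection at the map's 95th
  percentile (4-connected components), rate-weighted centroids, angle
  doubling (2θ mod 360) and mean resultant lengths for axial statistics.
- **FI/FS classification** — per-context 0/180 map alignment (exhaustive
  search), across-context *context similarity*
  r = max(corr(A, B), corr(A, rot₁₈₀B)); feature-sensitive cells at
  r ≤ 0.3, feature-insensitive above. The threshold is recomputable from
  the decile curve of within- vs across-context correlations through an
  asymptotic regression y(x) = a − (a − b)e^(−cx) and its half-life
  ln 2/c, root, and maximal-growth locus.
- **Population similarity and decoding** — per-pixel normalized dot
  products between stacked context representations; leave-one-out
  context prediction from firing location, and linear SVM decoding of
  heading (C vs G) and context (A vs B) from center-out angles or mean
  firing rates, including cross-day transfer over registered cells.
- **Rate remapping** — per-cell |Δ mean rate| matrices over all trial
  pairs, summarised within vs across contexts.
- **Behaviour** — dig proportions over the C/G/N/F corners and
  Bernoulli/Beta Bayes factors:

  BF = [ (b − a)⁻¹ ∫ₐᵇ θᶻ(1 − θ)^(N−z) dθ ] / [ θ₀ᶻ(1 − θ₀)^(N−z) ],

  with (θ₀, a, b) = (0.5, 0.5, 0.9) for the rewarded-axis (C/G) model
  and (0.25, 0.25, 0.9) for the correct-corner (C) model; group evidence
  is the product over animals and decisions use the exact ln 3 ≈ 1.1
  bounds.

## Worked example

```r
library(reorientr)

cfg   <- sim_config(n_animals = 1, n_days = 1, seed = 11)
study <- generate_study(cfg)
b     <- study$animals[[1]][[1]]

sq <- session_rate_maps(b, square = TRUE)
bmr_proportions(session_bmr(sq))$animal
#>     0    90   180   270
#> 0.435 0.053 0.456 0.056

sc <- session_context_similarity(sq, b$trials)
table(sc$class)
#> FI FS
#> 16  4
mean(sc$similarity[sc$class == "FI"]); mean(sc$similarity[sc$class == "FS"])
#> 0.994
#> -0.123

maps <- session_rate_maps(b)
predict_context_by_location(maps, b$trials,
                            sc$cell_id[sc$class == "FS"])$accuracy
#> 1

ang <- session_center_out_angles(maps)
predict_heading_from_alignment(ang, b$trials)$accuracy
#> 0.889

behavior_bayes_factors(cbind(animal = 1, b$trials), "cg")$log_bf_group
#> 1.19
```

Reading these numbers: 89% of the ensemble's pairwise best-match
rotations fall on the geometric axis (0° + 180° ≈ 0.44 + 0.46), i.e. the
map aligns to chamber geometry; 16 of 20 cells are stable across
contexts (mean similarity 0.99) while 4 remap (−0.12 ≤ 0.3 → FS), and
those 4 suffice to predict the context of every withheld trial; the
ensemble's orientation predicts the C-vs-G dig on 89% of rewarded-axis
trials; and with 9 of 12 first digs on the rewarded axis the session's
log Bayes factor (1.19) already crosses the ln 3 ≈ 1.1 evidence bound
for learning. A full multi-stage run with CSV/JSON outputs:
`run_pipeline(cfg, "run/")` or
`Rscript scripts/run_pipeline.R --config cfg.yaml --out run/`.

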