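---
title: "Quantifying heading retrieval and context recognition in CA1 place cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying heading retrieval and context recognition in CA1 place cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reorientr)
```

## The problem

A disoriented animal re-entering a familiar rectangular chamber faces two
separable problems: recognising *which* chamber it is in (context
recognition, driven by visual features on the walls) and recovering its
facing direction within it (heading retrieval, driven by the chamber's
geometry). Because a rectangle has two-fold rotational symmetry, geometry
alone cannot distinguish a corner from its diagonal twin; hippocampal CA1
place maps in disoriented animals accordingly flip between two orientations
0° and 180° apart from trial to trial. `reorientr` implements the full
analysis chain that quantifies this behaviour from position and event
data: rate maps, map-rotation statistics, a feature-sensitivity cell
taxonomy, population and support-vector decoders, rate-remapping measures,
and Bayes-factor scoring of the digging behaviour itself — together with a
synthetic-session generator carrying complete ground truth, so every stage
can be validated without access to recordings.

## Rate maps

Positions are first mapped to a canonical 20 × 30 cm chamber frame by a
four-point homography (`align_positions()`), so that the short wall next
to the rewarded corner occupies the same canonical side in both contexts.
Maps are built on 1 cm × 1 cm pixels from samples faster than 2 cm/s;
activity (spike counts or deconvolved event weights) and occupancy are
binned separately, each smoothed with an isotropic Gaussian kernel
(σ = 3 cm, truncated at 4σ and renormalised inside the chamber so no
density bleeds through the walls), and divided. Pixels with smoothed
occupancy under 0.05 s are masked and never enter correlations,
percentiles, or information sums.

Two readings of "divide then smooth" exist; we smooth numerator and
denominator separately and then divide (`smooth_mode = "separate"`),
which avoids ratios of noisy single-bin counts; `smooth_mode = "ratio"`
switches to smoothing the raw quotient. Place fields are 4-connected
components of sampled pixels above the map's 95th percentile (percentile
by linear interpolation over sampled pixels only); callers that need one
field per trial use the largest. The angle from the map center to a
field's rate-weighted centroid (`center_out_angle`, atan2 convention,
wrapped to [0, 360)) summarises the map's orientation without any square
compression.

## Rotation statistics

For pairwise map comparisons, the rectangular map is compressed to a
20 × 20 square by re-binning the raw data anisotropically (x in 1 cm
bins, y in 1.5 cm bins) — not by resampling the smoothed map. The
best-match rotation (BMR) between two trials is the quarter-turn of one
map (0°, 90°, 180°, 270°) maximising the Pearson correlation over
jointly sampled pixels, with masks rotating alongside the data. Ties
break to the smallest angle; comparisons with fewer than 20 joint pixels,
or with zero variance on either side, are undefined rather than silently
zero. A 12-trial session yields 66 pairwise comparisons per cell; with a
rectangle's symmetry, a geometry-aligned ensemble concentrates its BMRs
on {0°, 180°}.

Ensemble coherency is the share of simultaneously recorded cells (active
in both trials of a pair) with the same BMR, ranked 1st–4th per pair;
chance is 25% per rotation. Center-out angle differences use angle
doubling (2θ mod 360) to collapse the axial bimodality before computing
the mean resultant length.

## Feature-sensitive and feature-insensitive cells

Within each context, a cell's trial maps are aligned by assigning each
trial 0° or 180° to maximise the mean pairwise correlation — an
exhaustive search over the 2^(k−1) assignments, which is exact and cheap
at k ≤ 6 trials. The two per-context average maps are then aligned to
each other (best of 0°/180°), and the resulting correlation is the
cell's *context similarity*. Cells at or below 0.3 are feature-sensitive
(FS; they remap across contexts); above it, feature-insensitive (FI).
The score is defined only for cells with a detected field in at least
one trial of each context.

Two subtleties deserve emphasis. First, a cell whose maps all rotate
exactly 180° across contexts is indistinguishable from a stable cell,
because the across-context alignment absorbs the flip; such cells
classify as FI. This is an acknowledged property of the method, and it is
why the synthetic generator's FS cells default to a 90° across-context
offset — remapping to the *opposite geometric axis*, which no 0/180
alignment can absorb (a 180° offset remains available in
`sim_config(fs_context_offset_deg = 180)` as the degenerate case).
Second, the 0.3 threshold is recomputable rather than fixed: cells are
split into deciles of the similarity distribution, the Pearson R between
within- and across-context correlations is computed per decile, and an
asymptotic regression y(x) = a − (a − b)·e^(−cx) is fitted to the
ten-point curve (Levenberg–Marquardt, 16 deterministic starts over a
log-spaced rate grid; a constant series is reported as a fit failure, not
silently patched). The selected decile is the one containing the curve's
half-life (ln 2/c), root, and maximal-relative-growth locus — the left
edge of the positive domain, since y′/y is decreasing wherever y > 0;
when the root does not exist (a and b of one sign) the remaining features
decide and the result is flagged. The threshold is that decile's upper
empirical boundary. When features disagree the lowest feature decile is
used, which is the conservative (most selective) choice.

## Population similarity and context prediction

Each cell's two average aligned maps — with the context-B average rotated
by the cell's across-context alignment, since per-cell alignment is
otherwise only defined up to a global flip — are stacked into cells ×
pixels matrices per context. At each pixel the across-cell activity
vectors give a normalized dot product (cosine) in [0, 1]; pixels with a
zero vector in either context are flagged undefined. FI populations sit
near 1; FS populations sit visibly lower.

Leave-one-out context prediction compares a withheld trial's map to each
context's average (recomputed without the withheld trial) by mean
per-cell cosine, allowing the withheld map its best of 0°/180° against
each candidate. We additionally hold out the withheld trial's *partner* —
the other context's trial of the same within-context ordinal — so both
averages pool equally many trials; an unbalanced comparison is biased
toward the context with the larger (hence less noisy) average, which at
six trials per context is a multi-point accuracy artifact. Exact ties are
broken by a seeded uniform draw and recorded per trial.

## Decoders

Heading (C vs G first dig), context (A vs B), and error-trial (N vs F)
decoders share one engine: a linear-kernel soft-margin SVM (cost 1, no
feature standardisation) under an empirical class prior, validated
leave-one-out; cross-day decoding fits once on a training day and
predicts the test day over the registered-cell intersection. Features are
per-cell (sin θ, cos θ) of the center-out angle (undefined angles
zero-imputed) or per-cell mean firing rates (speed-filtered event weight
over speed-filtered time). Rate decoding admits cells with fields in at
least 4 trials, two per context.

Two numerical choices matter here. (1) In cost-sensitive SVM
formulations, a class prior enters as prior_c divided by the class's
training frequency; under the *empirical* prior that ratio is 1, so the
correct implementation is uniform observation weights — a plain fit.
Weighting classes by their frequencies instead double-counts the majority
class and drives the leave-one-out null expectation several points below
50% at ~10 trials. (2) Chance calibration uses independent
equal-probability relabelling of each trial rather than permutation:
under a fixed permuted label multiset, removing a trial tilts the
training majority against its own class, a well-known pessimistic bias of
leave-one-out at small N; under independent relabelling the held-out
label is independent of everything the model saw, making 50% exact. For
the same reason the calibration evaluates every draw (folds whose
training set is single-class predict that class) instead of discarding
degenerate label vectors, which would condition the held-out label on the
training counts.

## Rate remapping

Per cell, the 12 × 12 matrix of absolute mean-rate differences between
trials, split into within-context (A–A and B–B pooled) and
across-context pairs, and averaged per cell and per animal. No
normalisation by pooled rate is applied. A peak-rate variant
(`trial_rate_stats(..., "peak")`) gives the same qualitative ordering.

## Digging behaviour

First-dig proportions over the four corners (C correct, G geometric
twin, N near, F far), rewarded- vs unrewarded-axis shares, and two
Bernoulli Bayes-factor models: the C/G model (success = dig on the
rewarded axis; point null θ = 0.5 vs uniform alternative on (0.5, 0.9))
and the C model (success = dig exactly in C, contexts pooled; null 0.25,
alternative uniform on (0.25, 0.9)). The marginal likelihood integral is
evaluated in closed form through regularised incomplete-beta differences
on the log scale; numeric quadrature is kept as a test oracle only.
Animals multiply (logs add) into a group Bayes factor; decisions use the
exact ln 3 ≈ 1.1 thresholds. Trials without a scorable dig are excluded
from N (the trial budget is 3 minutes; the sources are silent on
non-digging trials, and excluding them leaves the Bernoulli likelihood
well-defined).

## The synthetic-session generator

`generate_study()` emulates the statistical structure the analyses
assume, with complete ground truth. Per animal and day: 12 trials
alternating contexts A and B in a 20 × 30 cm chamber (the 2:3 aspect
ratio is what makes the 1 cm / 1.5 cm compression square). Trajectories
are bounded correlated random walks (Ornstein–Uhlenbeck velocity,
τ = 1 s, stationary per-axis SD 6 cm/s, reflective walls), giving
realistic mouse speeds with ~5% of time below the 2 cm/s threshold so
the speed filter is exercised. Each trial draws an ensemble orientation
uniformly from {0°, 180°} (disoriented entry); each cell follows it with
probability `coherence_by_day`, else takes the opposite orientation.
Activity is an inhomogeneous Poisson process on the frame grid around a
Gaussian place field rotated by the cell's applied orientation about the
chamber center — plus the FS context offset in context B — scaled by the
day's across-context rate gain in context B.

Defaults (chosen once as plausible study conditions, not tuned): 90 s
trials at 20 Hz; 16 FI + 4 FS cells (a 20% FS minority, an
electrophysiology-scale simultaneous ensemble); field σ 4 cm; peak 8 Hz
over a 0.2 Hz baseline; coherence (0.85, 0.90, 0.95) across days 1–3;
rate gain (1.0, 1.5, 2.0); day-1 dig weights (0.375, 0.375, 0.125,
0.125) over C/G/N/F shifting mass onto C on later days; dig–orientation
coupling 0.8; FS identity retention 0.3, with dropped FS slots refilled
from the FI pool so the FS fraction stays constant (dynamic FS
ensembles). Field centers are rejection-sampled at least 6 cm from the
chamber center: edge-biased fields match how disoriented mice sample the
chamber, and a field at the rotation center would make orientation
unidentifiable for any method. Every stochastic step consumes a named
stream seeded from the master seed per (animal, day, trial, stage), so
identical configs are bit-identical and stages can be regenerated
independently.

What the generator does *not* emulate: non-Poisson spiking statistics,
theta phase, within-trial nonstationarity, behavioural sampling biases
tied to reward approach, calcium-indicator dynamics, or registration
errors across days (identities are exact by construction). Passing tests
on generator output therefore validate the *analysis chain* — its
geometry, estimators and decision rules — not the biological claims
themselves.

## Problem sizes used in the test-suite and acceptance computations

Parameter-recovery and calibration checks run on reduced sessions
(typically 10–15 cells, 45–60 s trials, 20 Hz) and modest replicate
counts (6–8 sessions for recovery checks, several hundred replicates for
chance calibrations, 1000 replicate sessions of 12 cells for the
headline chance-level computation in `scripts/acceptance.R`). These sizes
were chosen as the smallest at which each quantity's sampling error is
comfortably inside the assertion bands; the chance-level quantities are
invariant to session size by construction.

## Known limitations

- Classification confidence degrades near the 0.3 similarity threshold;
  the decile model quantifies but does not remove this.
- With six trials per context, leave-one-out decoders have coarse
  (1/n-trial) accuracy resolution per session; session-level accuracies
  are meaningful only in aggregate.
- The within-context alignment search is exhaustive and exact for ≤ 8
  field-bearing trials per context; beyond that its cost doubles per
  trial (2^(k−1) assignments).
- Only the asymptotic-regression family is implemented for the
  threshold-selection curve; `fit_asymptotic_regression()` reports AIC,
  RSE and log-likelihood so alternative families fitted elsewhere can be
  compared on equal terms.

## End-to-end run

```{r pipeline, eval = FALSE}
cfg <- sim_config(n_animals = 2, seed = 1)
res <- run_pipeline(cfg, "run/")
list.files("run/")
```

The run directory contains per-stage CSV/JSON tables (trial records, BMR
proportions, context-similarity scores and the threshold-model report,
location- and rate-based prediction accuracies, rate-remapping
summaries, dig proportions and Bayes factors) plus a manifest echoing
the configuration; a rerun with the same config reproduces every file
byte for byte.
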