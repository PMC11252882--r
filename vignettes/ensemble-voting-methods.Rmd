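---
title: "Ensemble majority voting for tile-level invasive-cancer detection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble majority voting for tile-level invasive-cancer detection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilevote)
```

# The problem and the model

Whole-slide images (WSIs) of H&E-stained breast tissue are analysed as
regular grids of square tiles (598 × 598 px at 20X, about 271 × 271 µm).
Each tile is to be classified as containing invasive carcinoma (IC) or not.
Rather than relying on a single classifier, an ensemble of $T$ base models
is used, each trained on its own division of the training slides, and their
binarized outputs are aggregated by majority vote.

The statistical rationale is the binomial success model: if each of $T$
voters is independently correct with probability $p$, the probability that
a strict majority is correct is

$$p_{\mathrm{ens}} = \sum_{k=\lfloor T/2\rfloor + 1}^{T} \binom{T}{k}
p^k (1-p)^{T-k},$$

which exceeds $p$ whenever $p > 0.5$ and tends to 1 as $T$ grows. For even
$T$ an exact tie ($k = T/2$) is counted as a failure by this formula; the
voting implementation instead flags ties and breaks them deterministically
(see below). `ensemble_success_probability()` implements the closed form;
`verify_theory()` reconciles it with simulation. Because the closed form
treats ties as failures, the reconciliation compares it against the
empirical *strict-majority* success rate (the fraction of tiles on which
more than half of the votes are correct); the tie-broken prediction
accuracy is reported alongside and is slightly higher for even $T$.

# Tile labeling from polygon annotations

Pathologist annotations are polygons (GeoJSON, possibly overlapping, with
holes) in WSI pixel coordinates, each carrying a class from an open
vocabulary. A tile receives a class when the *center* of the tile lies
inside a polygon of that class; the binary label is 1 iff any of its
classes is in the configured IC set, by default *invasive cancer* and
*invasive lobular cancer*. Design choices:

* **Boundary convention.** A center exactly on a polygon edge counts as
  inside (closed polygons). This is deterministic and matches the usual
  "covers" semantics of geometry libraries. Holes exclude centers strictly
  inside them; hole boundaries still count as inside.
* **Minimum-area option.** The primary rule is pure center containment
  (`min_area_fraction = 0`). A minimum tile–polygon overlap fraction is
  exposed as a knob for stricter labeling, computed by clipping the polygon
  to the tile rectangle (Sutherland–Hodgman) and applying the shoelace
  formula; it is off by default because no principled default value exists.
* **Class matching.** IC-set matching is case-insensitive after whitespace
  normalisation; unknown classes are kept verbatim so downstream tables
  (the multi-label confusion matrix) can enumerate them.
* **Coordinates.** 0-based pixels, half-open tile boxes $[x_0, x_1)$.

The point-in-polygon primitive is an even-odd ray-casting test implemented
in the package (no planar polygon-clipping dependency is used), and is
verified in the test suite against an independently written scalar
crossing-number oracle on randomized scenes.

# Partitioning slides

Slides are split 80/20 into training and held-out test sets, stratified on
the joint cross of the clinical covariates (NHG grade, ER, HER2, Ki67, with
"missing" as its own level). Per-stratum test counts are apportioned by
largest remainder so the total equals `round(test_fraction * n)` exactly.

The training slides are then divided into $N$ equal groups (one per base
model), again respecting the covariates: within each joint stratum the
slides are shuffled with a seeded RNG and dealt round-robin to divisions,
with each stratum continuing from the offset where the previous stratum
stopped. This makes two invariants provable rather than probable: global
division sizes differ by at most 1, and within every stratum the
per-division counts differ by at most 1. Joint stratification is the
strictest deterministic reading of "keeping the proportions of clinical
features"; a looser marginal scheme would not support the ≤ 1 imbalance
guarantee. Seeds are mandatory arguments everywhere; there is no hidden
global RNG state.

# The base-model simulator

Training ten InceptionV3-class CNNs is a GPU-scale task and their softmax
outputs are not guaranteed to be calibrated. The simulator therefore
emulates exactly the properties the downstream pipeline depends on, and
nothing else:

* `p_correct` — the probability that the model's vote (score binarized at
  its own `true_threshold` $\tau^*$) matches the tile label;
* `true_threshold` — the planted Dice-optimal cutoff. Placing it away from
  0.5 emulates miscalibrated softmax outputs, which is what makes per-model
  threshold calibration necessary in the first place;
* `concentration` — sharpness of the score distribution. Scores are drawn
  by inverse CDF on the chosen side of $\tau^*$: above it from a Beta(c, 1)
  density stretched onto $[\tau^*, 1]$ (mass accumulating towards 1), below
  it from the mirrored Beta(1, c) on $[0, \tau^*]$. The default c = 2 keeps
  enough density near the threshold for calibration to be a nontrivial
  estimation problem while still giving confident scores;
* `rho` — a shared-draw mixture weight: with probability `rho` a per-tile
  shared draw (correctness indicator and quantile, drawn once per tile)
  replaces the model's own draw. This induces measurable vote correlation,
  letting tests demonstrate how the binomial prediction degrades when its
  independence assumption is violated. `rho = 0` gives conditionally
  independent votes.

All randomness derives from one seed: the shared per-tile stream is drawn
first, then each model's stream in column order, so a score matrix is fully
reproducible. The real-CNN adapter contract (`cnn_adapter_contract()`)
documents how trained networks would slot in; it is documentation only.

What the simulator does *not* emulate: spatial correlation of errors along
IC region borders, stain and scanner batch effects, or tissue-dependent
difficulty. Passing tests therefore validate the aggregation, calibration
and evaluation machinery, not clinical performance on real slides.

# Threshold calibration

Each model's continuous scores are binarized at a model-specific threshold
chosen to maximise the Dice score, $2TP/(2TP+FP+FN)$, of its predictions on
the pooled tiles of all training divisions *except its own* (model $i$
trains on division $i$). The held-out test slides are never touched.

Because Dice as a function of the threshold is piecewise constant and can
only change at observed score values, the search over the midpoints of
consecutive distinct sorted scores, plus the endpoints 0 and 1, is exact —
equivalent to scanning all real thresholds. This is asserted in the tests
against a dense $10^{-3}$-step grid. Ties are broken towards the smallest
threshold, favouring sensitivity for cancer detection; the choice is
documented and configurable by post-processing the returned candidates.
Pooling (one Dice over all out-of-division tiles jointly, rather than a
per-division average) is used because divisions are equal-sized and pooled
Dice is the quantity the ensemble is evaluated on. The Dice of the IC class
alone is optimized, matching the single Dice row reported for the ensemble
evaluation; a macro average over both classes would change little for the
balanced synthetic studies but is not what the evaluation reports.

Degenerate inputs are defined, not special-cased away: with no positives
anywhere Dice is defined as 1; identical scores collapse the candidate set
to the endpoints; an empty out-of-division pool is a hard error.

# Voting, agreement, and ties

Votes follow $t_i(x) = \mathbf{1}[\hat y_i(x) \ge \tau_i]$ — the threshold
value itself votes 1. The ensemble predicts 1 when the vote sum strictly
exceeds $T/2$. With the default $T = 10$ an exact 5–5 tie is possible; it
is flagged (`tie_flag`) and broken by comparing the tile's mean raw score
with the mean of the calibrated thresholds (≥ maps to 1). The rule is
deterministic, uses only information already available, and is reported so
downstream analyses can treat tied tiles separately.

Agreement is the number of models voting for the *true* class:
$a(x) = \sum_k t_k(x)$ on IC tiles and $n - \sum_k t_k(x)$ otherwise, so 0
is total disagreement with the ground truth and $n$ unanimity. Where no
ground truth exists (deployment), the package reports `self_agreement` —
votes for the *predicted* class, always in $\lceil n/2 \rceil..n$ — and
keeps the two clearly apart.

# Evaluation

Accuracy, Dice, specificity and precision are computed per slide and
pooled, for the ensemble and for a designated single base model (default:
model 1, with its own calibrated threshold — the closest match to a
single-classifier baseline this framework admits). Ratios with zero
denominators (e.g. precision on a slide with no predicted IC) are reported
as not available (`NA`), never imputed as 0. The per-slide comparison
reports the fraction of slides where ensemble accuracy is *strictly*
higher; ties are counted as non-wins and reported separately.

# Visualisations

Three displays, each with a CSV twin so numeric checks never depend on
pixels:

* **Glyph overlay** — per tile, a square outline coloured by the true
  class, a filled diamond on a greyscale ramp encoding agreement (black = 0,
  white = $n$; grey level $= \mathrm{round}(255\, a/n)$), and an X coloured
  by the prediction. Orange (`#FF8C00`) is IC, blue (`#1F77B4`) not IC; the
  hex values are package choices. Glyph sizes are 90 % / 60 % / 40 % of the
  tile cell so the three glyphs stay legible when stacked.
* **Agreement histogram** — tile counts at each agreement value 0..$n$,
  split by true class.
* **Multi-label confusion matrix** — for every annotation class (classes
  overlap, so a tile counts toward each of its labels; unannotated tiles
  form their own row), the percentage and count predicted IC vs not IC,
  plus per-class totals as a bar chart.

PNG rendering is deterministic given fixed inputs and library versions,
but byte-level reproducibility is only asserted for the CSV tables, since
font rasterisation may differ across graphics stacks.

# Synthetic studies

`synthetic_study_spec()` / `generate_study()` create complete desk-scale
studies: per-slide tile grids, overlapping multi-class annotation blobs
(IC plus confusable classes such as DCIS), clinical covariates drawn from
typical breast-cancer cohort marginals, and a simulated score matrix — in
exactly the file formats the rest of the pipeline reads. Blobs are
randomized star-convex polygons (random radii at fixed angular steps),
giving ragged borders where center-rule labeling is genuinely nontrivial.
The generator computes its intended tile labels with the same center rule
it exports, so the key round-trip property — relabeling from the emitted
GeoJSON reproduces the intended labels exactly — tests the serialisation
path without requiring a second geometry implementation.

The realized IC tile fraction is controlled by bisection on a global blob
radius multiplier (default target 0.3, tolerance 0.03), chosen because the
blob construction scales continuously with the multiplier; this replaces a
sampling-based knob whose error would be hard to bound.

Default study conditions: 10 base models with `p_correct = 0.8`,
`true_threshold = 0.5`, `concentration = 2`, `rho = 0`; 30 × 30 tile
grids; IC fraction ≈ 0.3. The end-to-end demo uses 50 slides so that the
80/20 split leaves 40 training slides for 10 divisions and 10 held-out
slides of 900 tiles each for evaluation. The theory checks use 50,000
simulated tiles (Monte-Carlo SE below 0.002 near $p_{\mathrm{ens}}$ ≈
0.97) and threshold recovery uses 10,000 pooled tiles at
`p_correct = 0.95`, where the planted cutoff is recovered to well within
0.05.

# Worked example

```{r demo}
specs <- lapply(1:10, function(i)
  sim_model_spec(sprintf("model%02d", i), p_correct = 0.8))
spec <- synthetic_study_spec(n_wsis = 50, grid_rows = 30, grid_cols = 30,
                             model_specs = specs, seed = 501)
out <- end_to_end_demo(spec, N = 10, seed = 502,
                       dir = file.path(tempdir(), "tilevote-demo"))
out$report
ensemble_success_probability(10, 0.8)
```

The pooled ensemble accuracy lands near the closed-form strict-majority
prediction of about 0.967 — above it, because Dice-optimal thresholds and
the tie-break rule both add a little over binarizing at the planted
threshold — while the single model stays near its nominal 0.8, and the
ensemble wins on every held-out slide.

# Known limitations

* The binomial theory assumes independent, equally accurate voters; real
  CNNs trained on overlapping slide distributions are positively
  correlated, and the simulator's `rho` exists precisely to show the
  resulting degradation. Empirical ensemble gains on real data will be
  smaller than the closed form suggests.
* Center-rule labeling is noisy at IC region borders; the minimum-area
  option mitigates but cannot remove this.
* Evaluation is per tile. Slide-level or patient-level decision rules, and
  patient-aware partitioning (multiple slides per patient), are out of
  scope because no patient linkage is modelled.
* Only binary IC / not-IC classification is supported; a multi-class
  problem would be decomposed into several binary ones.
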