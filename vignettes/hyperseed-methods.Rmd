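---
title: "Seed variety identification from hyperspectral reflectance: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed variety identification from hyperspectral reflectance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Crop-seed varieties that look alike to the eye can still differ in
internal composition (protein, starch, oil, water), and those
differences leave a signature in visible/near-infrared reflectance.
A push-broom hyperspectral camera images a tray of seeds as a cube —
two spatial axes and one spectral axis of 176 bands spanning
400–1000 nm — and the mean spectrum over one seed's pixels becomes a
176-point feature vector for that seed. `hyperseed` implements the
full analysis from raw cube to variety call: reflectance calibration,
seed segmentation, spectral pretreatment, representative train/test
splitting, data-driven wavelength selection, and a random-subspace
ensemble classifier, with evaluation by overall precision and Cohen's
kappa.

The reference layout throughout is six varieties with 60 seeds each
(360 samples), split 270/90 into training and prediction sets.

## Ingest

Raw sensor counts become reflectance via black/white correction
against a dark-current frame and a white (PTFE) reference frame:

$$R = \frac{I_{raw} - I_{dark}}{I_{white} - I_{dark}}$$

computed elementwise by `reflectance_correct()`. A pixel where the
white and dark frames coincide has no usable dynamic range; the
function refuses with an error naming the pixel, rather than emitting
an `Inf` that would poison downstream means.

Seeds are segmented by thresholding a grey image (`segment_seeds()`).
The grey image is the per-pixel mean reflectance over all bands —
robust, band-agnostic, and available whatever the instrument — with a
`gray_band` argument for the single-band alternative. The default
threshold 0.1 separates seeds from a low-reflectance background panel.
Components are labelled with 8-connectivity (diagonal contact joins a
region, which matters for elongated seed tips at coarse resolution)
and components under `min_pixels = 30` are discarded as specks. Each
seed's spectrum is the arithmetic per-band mean over its pixels
(`mean_spectrum()`).

Deposited per-variety tables (60 rows × 176 columns each) are read by
`read_spectra_table()`; the file-to-variety mapping comes from an
explicit manifest rather than filename parsing, because filenames in
deposited archives are not a contract.

## Pretreatment

Three row-wise pretreatments are provided (`preprocess_fit()` /
`preprocess_apply()`):

* **SNV** — each spectrum centred by its own mean and divided by its
  own standard deviation. The divisor is the sample convention
  (n − 1); this is a pure convention and is configurable, and SNV is
  idempotent under it.
* **MSC** — each spectrum regressed on a reference spectrum by
  ordinary least squares, $x \approx a + b\,\bar s$, and corrected to
  $(x - a)/b$. The reference is the column mean of the *training*
  spectra only, frozen, and reused for prediction spectra, so the
  correction never sees prediction data. A slope below $10^{-12}$ in
  magnitude (or a constant reference) is an identifiability failure
  and errors out.
* **SG1** — Savitzky–Golay first derivative, window 5, polynomial
  degree 2, derivative order 1, with unit (band-index) spacing. Edge
  points are fitted with the same polynomial over the asymmetric end
  window, so polynomials up to the filter degree are differentiated
  exactly across the whole spectrum — a property the test suite
  checks literally.

## Train/prediction split

`ks_split()` implements the Kennard–Stone max–min rule: seed the
training set with the two samples at greatest Euclidean distance, then
repeatedly add the sample whose minimum distance to the selected set
is largest. The procedure is deterministic; ties break to the lowest
row index. The default split is 270/90 — every published prediction
precision in this setting is a multiple of 1/90, which pins the
prediction-set size. The split runs on the pretreated spectra. Because
the MSC reference must be fitted on training rows only, the pipeline
uses a two-pass scheme: a provisional all-sample pretreatment supplies
the geometry for the split, after which the pretreatment is refitted
on the chosen training rows alone and applied to both sides. A
`stratified` option runs the rule per class instead.

## The PLS core

Both wavelength selectors score candidate band subsets by
cross-validated PLS. Classification is encoded as PLS2 regression on a
one-indicator-per-class matrix; the figure of merit is RMSECV, the
root mean squared error of the held-out indicator predictions. The
SIMPLS algorithm is implemented in compiled code (RcppArmadillo)
because the selectors fit tens of thousands of models: one pass over
the cross-validation folds yields RMSECV for *every* truncation
1..max_lv, and the truncation minimising RMSECV is used — this is how
"latent variables chosen by cross-validation up to a cap" is realised
without a second nested loop. The caps follow the reference settings:
25 latent variables and 10 folds inside CARS, 40 and 11 inside IRIV.
When deflation exhausts the covariance early (rank-deficient input),
the last reachable coefficient matrix is carried forward so every
requested truncation stays defined, and a requested component count
above `min(n − 1, p)` is clipped with a warning.

## CARS

Competitive adaptive reweighted sampling runs N = 80 Monte Carlo
iterations. Each iteration draws 80% of the training rows without
replacement (the Monte Carlo fraction is not stated in the reference
settings; 80% is the conventional choice), fits PLS on the surviving
bands, and ranks bands by the Euclidean norm of their coefficient rows
across the six indicator columns. Retention is governed by the
exponentially decaying ratio

$$r_i = a e^{-k i}, \qquad a = (p/2)^{1/(N-1)}, \qquad
  k = \frac{\ln(p/2)}{N-1},$$

whose boundary conditions are $r_1 = 1$ (all $p$ bands can survive the
first run) and $r_N = 2/p$ (two bands at the last). Forced selection
keeps the top $\lceil r_i p \rceil$ bands by coefficient magnitude;
adaptive reweighted sampling then draws $\lceil r_i p \rceil$ times
with replacement among them with probability proportional to
magnitude, duplicates collapsing. Two implementation details matter
and are deliberate:

* the ARS draw count is $\lceil r_i p \rceil$ with $p$ the *original*
  band count — tying the draw count to the current subset size makes
  the subset contract geometrically regardless of the decay schedule;
* every iteration's subset is scored by RMSECV on the full training
  rows under **one** CV partition drawn per selection, and the full
  band set competes as iteration 0. The argmin therefore compares
  subsets rather than fold assignments, and the returned subset can
  never score worse than the full-band model.

The winner is the subset with minimal RMSECV. On data where a few
noise bands cost PLS nothing, the RMSECV valley over subset size is
nearly flat and the winning subset retains some uninformative bands;
this is a property of the minimal-RMSECV rule itself, and the test
suite asserts enrichment of informative bands rather than purity.

## IRIV

Iteratively retaining informative variables is model population
analysis. Each round draws a binary inclusion matrix (K = 1000 rows,
one column per surviving band, cells set with probability 1/2,
re-drawn so every model keeps at least two bands and every band
appears in both arms), scores each row's band subset by RMSECV under
one fold partition per round, and assesses band $j$ by

$$\mathrm{DMEAN}_j = \overline{\mathrm{RMSECV}}_{\text{without } j}
  - \overline{\mathrm{RMSECV}}_{\text{with } j},$$

with a two-sided Mann–Whitney U test between the two model
subpopulations at $\alpha = 0.05$. Bands are classified strong
(DMEAN > 0, significant), weak (DMEAN > 0, not significant),
uninformative (DMEAN ≤ 0, not significant) or interfering (DMEAN ≤ 0,
significant); the last two groups are removed and the round repeats
until nothing is removed. A final backward elimination deletes
surviving weak bands one at a time while the full-model RMSECV does
not worsen, so the returned set is the strong bands plus any weak band
whose removal costs accuracy.

A design choice: the original formulation of the method evaluates, for
every band, a paired complement model for each of the K rows — roughly
$K(p+1)$ cross-validated fits in the first round, three orders of
magnitude beyond the rest of the pipeline combined. This package
compares the two subpopulations already present in the K-model
population (rows containing $j$ against rows excluding $j$). The
taxonomy, the DMEAN statistic and the rank test are unchanged; the
estimator of the with/without contrast is unpaired instead of paired.
Because the Mann–Whitney statistic depends only on ranks, the
classification is invariant to any monotone rescaling of RMSECV.

## Base classifiers and the random-subspace ensemble

Four base classifiers are wrapped behind one score interface
(`train_base()` / `predict_base()`, per-class scores in [0, 1] summing
to one): LDA (`MASS::lda`, posterior probabilities); KNN with 20
neighbours under the Minkowski order-2 metric — the reference settings
say the vote weight "equals the distance", which taken literally would
up-weight far neighbours, so the default is inverse-distance weighting
with `equal` and `inverse_squared` switches; a linear SVM with box
constraint 3, multiclass by one-vs-one with scores from normalised
pairwise votes (deterministic, unlike probability calibration); and a
Gini decision tree grown unconstrained then pruned along its
complexity path to at most 20 splits, since `rpart` exposes no direct
split cap.

`train_rsel()` builds the random-subspace ensemble: each of N members
draws d feature indices uniformly without replacement (members may
overlap; all training rows are used), trains the base classifier on
that subspace, and receives a weight. The reference description keeps
or drops members "in line with performance" without a formula; here
the weight is the member's stratified 5-fold cross-validated training
accuracy, members below chance (1/6 for six classes) are dropped, and
the remaining weights are renormalised to sum to one. Uniform
weighting is available for ablation. Prediction is the weighted
average of member score matrices — a convex combination, so ensemble
scores are bounded by the member extremes — with argmax labels and
ties resolved to the lowest class index. The headline operating points
are N = 25, d = 63 on full bands; N = 19, d = 53 after CARS; and
N = 33, d = 53 after IRIV; `grid_search_rsel()` reproduces the
member-count × dimension sweep used to choose them. When selection
returns fewer than d bands, d is clipped and the ensemble degenerates
gracefully toward the single base classifier.

## Evaluation

`confusion()` counts with a fixed class order; `precision_overall()`
is the trace fraction (the published "precision" values are k/90 on
the prediction set, i.e. overall accuracy — macro-averaged per-class
precision is also available); `kappa_statistic()` is Cohen's
$\kappa = (p_o - p_e)/(1 - p_e)$, returned as 0 with a warning in the
degenerate all-mass-in-one-marginal case. `repeat_and_average()` runs
a seed-indexed pipeline ten times (consecutive seeds), reporting
per-repeat precision and kappa, their means, and both the pooled
confusion matrix and the kappa of the pooled matrix — the published
protocol averages over ten loops, and pooled-vs-averaged kappa is
reported both ways since the original is ambiguous. Within the
pipeline the repeats reseed the classifier/ensemble; wavelength
selection is fitted once per run at the base seed, since repeating the
selector would dominate runtime without informing the model
comparison.

## The synthetic generator

`synth_config()` / `sample_dataset()` emulate the statistical
structure the analysis relies on, so every stage is testable without
instrument data: six classes × 60 seeds × 176 bands on 400–1000 nm. A
single smooth base reflectance curve (sum of broad Gaussian bumps,
scaled into [0.1, 0.9]) is shared by all classes. Class structure
lives in a contiguous discriminative window (default indices 79–99,
roughly 668–735 nm — the red-edge region where real varieties
separate): each class adds an ordered level of a broad bump (so the
mean curves stack, as real variety spectra do) plus its own narrow
bump at a class-specific position within the window. Ten isolated
informative bands outside the window receive small class-specific
offsets. Every sampled seed then gets a multiplicative gain
$a_i \sim N(1, 0.05)$, an additive offset $b_i \sim N(0, 0.02)$ and
per-band noise $N(0, 0.005)$ — precisely the distortion family MSC
and SNV are defined to remove, which makes the pretreatments testable
by construction.

Two calibration notes, both fixed once and not revisited:

* An earlier single-shape window (one bump, ordered levels only)
  placed all six class means along one latent direction. That is a
  worst case for PLS-DA — the indicator of a middle class is
  non-monotone in the single discriminant score — and left the
  selectors' RMSECV nearly flat. The per-class narrow bumps spread the
  class directions across several dimensions, as composition
  differences in real seeds do.
* `class_sep = 0.004` anchors the operating regime at the
  *post-selection* single LDA: ~0.93 prediction precision after
  MSC → IRIV, with full-band LDA clearly lower (~0.74) and the
  ensemble at or above the single model. Anchoring on full-band LDA
  instead drives every post-selection model to 1.0 and the comparison
  collapses.

What the generator does **not** emulate: wavelength-correlated noise,
instrument striping and scatter that MSC only approximately removes,
class differences spread over many overlapping absorption features,
and between-seed morphology effects on the ROI mean. Passing tests on
synthetic data therefore demonstrate that the machinery recovers
planted structure under the stated noise model — not that real
spectra will reach any particular accuracy.

## Numerical choices and degenerate inputs

* All stochastic stages take an explicit integer seed and restore the
  caller's RNG state; identical seeds give bit-identical selections,
  ensembles, datasets and reports (the written `report.json` differs
  only in its timestamp field).
* Ties: argmax ties to the lowest class index; Kennard–Stone ties to
  the lowest row index (with a warning when the farthest pair is
  ambiguous).
* Errors are typed (`hyperseed_*` condition classes) and name the
  offending row/pixel/file: constant spectra under SNV, degenerate MSC
  slopes, empty segmentation masks, shape mismatches, classes with
  fewer than two LDA training samples, ensembles whose members all
  fall below the acceptance threshold.
* Problem sizes in the test suite are chosen to exercise the
  full-sized study conditions where the claim depends on them (the
  end-to-end recovery runs the full 360 × 176 layout over ten seeds)
  and reduced layouts elsewhere (for example 72 × 40 tables for
  contract tests), which keeps the whole suite in a few minutes.

## Known limitations

* The minimal-RMSECV rule in CARS does not guarantee a pure subset
  when extra bands are nearly free for PLS; see the CARS section.
* IRIV's subpopulation contrast is an unpaired estimate of the
  original paired statistic; with K = 1000 models per round the
  practical difference is the estimator's variance, not its sign.
* The ENVI reader covers the plain uncompressed header + BSQ/BIL/BIP
  binary layouts with data types 2/4/5/12 only.
* With fewer selected bands than the configured subspace dimension,
  the ensemble's members coincide and the ensemble equals the single
  base classifier; the report is still valid, just not an ensemble
  gain.
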