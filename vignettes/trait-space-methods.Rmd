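---
title: "From cytometry events to trait-space fingerprints: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From cytometry events to trait-space fingerprints: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytotraits)
```

`cytotraits` analyses individual-level (per-cell) functional traits of
pigmented microbes measured by flow cytometry, and uses laboratory
treatment responses as *fingerprints* to interpret natural-community
samples. This vignette explains the models behind each stage, the
parameters that matter, and the numerical decisions taken where the
methodology leaves the implementer room.

## 1. Gating: isolating the target population

Raw optical intensities (peak heights, instrument units) are strongly
right-skewed, so clustering operates on `log10(x + 1)`-transformed
channels; `back_transform()` restores the original values exactly
(`10^y - 1`), and trait derivation always happens on the original scale.

The target population is found by hierarchical density-based clustering
(the HDBSCAN algorithm), implemented in this package: per-point core
distances from the `min_samples`-nearest neighbour, a minimum spanning
tree of the mutual-reachability graph (compiled code; the distance work is
O(n²) but memory stays O(n)), a condensed cluster tree at
`min_cluster_size`, and excess-of-mass cluster selection. Two decisions
deserve note:

* **The tree root is a selectable cluster.** Excluding the root forces at
  least two clusters whenever any split exists, which misbehaves on a
  homogeneous sample; with the root included, a single Gaussian-like cloud
  yields one cluster containing essentially all events, while separated
  populations and debris still split correctly.
* **Target selection.** Among clusters holding at least `min_cluster_frac`
  (default 5%) of events, the largest cluster whose median phycocyanin
  fluorescence exceeds the overall clustered median is chosen (cyanobacteria
  are phycocyanin-bright); if none is that bright, the brightest candidate
  wins. Noise events (label −1) are excluded.

Defaults: `min_cluster_size` = 1% of events (floor 25), `min_samples` = 10.
These are deliberately conservative smoothing parameters; the published
workflows this follows do not report values.

For field samples, a bead calibration (`calibrate_size()`) fits a
least-squares line through (log FSC median, log diameter) pairs of beads of
known size, and `size_gate()` keeps events whose calibrated diameter lies
in the **closed** interval [0.5, 10] µm — the permissive reading of a
"between 0.5 and 10 µm" single-cell fraction — so that large colonies and
aggregates are excluded before any community-level comparison.

## 2. Traits, collinearity and standardisation

Eight functional traits are derived per event: cell size (FSC), granularity
(SSC), gas-vesicle fraction, phycocyanin (FL670), phycocyanin per size
(FL670/FSC), chlorophyll-a (FL692), chlorophyll-a per size (FL692/FSC) and
the phycocyanin:chlorophyll-a ratio. The gas-vesicle trait divides a
cell-volume proxy by granularity; since optical sizing models are
instrument-specific, the proxy is `FSC^β` with configurable exponent β
(default 1, i.e. a pure FSC/SSC ratio). Events with a zero in a denominator
channel are dropped and counted.

`collinearity_filter()` prunes redundant optical channels by greedy
elimination on absolute Pearson correlation of log10 values (threshold
0.8): the strongest offending pair is resolved first by dropping the member
with the larger mean absolute correlation to the remaining candidates.
Ecologically meaningful traits are protected by a keep list — chlorophyll-a
and phycocyanin fluorescence stay in even though they correlate strongly,
because they answer different physiological questions. The procedure is
deterministic given column order.

Each trait is then log10-transformed and z-standardised. The z-score uses
the **population** standard deviation (ddof 0) so that standardisation is
bitwise reproducible and exactly invertible; `standardize_traits()` returns
the fitted model so field data can be transported into culture-anchored
coordinates unchanged.

## 3. The integrated phenotype

`fit_pca()` performs an uncentred PCA of the standardised traits (the
fitted standardisation already removes means). Axes are ordered by variance
and signed so the largest-magnitude loading of each axis is positive,
making runs comparable. Because the eight traits are log-linear
combinations of four channels, the trait matrix has rank four; the
remaining axes carry (numerically) zero variance and are reported as such.

Axis significance uses a permutation test: each trait column is permuted
independently (destroying correlation, keeping marginals) and axis *j* is
significant when its observed eigenvalue exceeds the (1 − α) quantile of
the permuted *j*-th eigenvalues (α = 0.05, `n_perm` = 999 by default; the
pipeline uses 199, which resolves α = 0.05 comfortably). This is a
deliberate simplification of published PCA-significance test batteries: the
statistic (raw eigenvalue against its permutation null) is explicit and
cheap, and on null data the expected number of significant axes is α·d, as
verified by simulation in the test suite. Hypervolumes are always built on
at least the first two axes even if only one reaches significance.

Treatment-replicate profiles (mean standardised trait per replicate) feed
k-means clustering; the number of clusters is chosen by an **explicit**
elbow rule — the k maximising the second difference of the within-cluster
sum-of-squares curve. Each k is additionally warm-started from the previous
solution's centers plus the farthest point, which guarantees the WSS curve
is non-increasing. Note the rule's honest limitation: it compares curvature
across k, so when planted groups are at strongly unequal distances the
largest curvature can sit at a smaller k than the number of planted groups;
with roughly equidistant groups it recovers the planted count exactly.

Events are equally weighted in the PCA regardless of per-sample event
counts; with the generator's balanced design this is immaterial, and
subsampling to equal n is a caller-side option (pass a subsetted trait
matrix).

## 4. Hypervolumes and functional diversity

For each treatment replicate, a product (axis-aligned) Gaussian KDE is
built on its PCA scores, with per-dimension Silverman bandwidths
`h_j = σ_j (4 / ((d + 2) n))^{1/(d+4)}`. The functional space is the
highest-density region holding `q` = 95% of the KDE's probability mass.
Because points sampled from the KDE each carry equal probability mass, the
density threshold is located as the (1 − q) quantile of the KDE density
evaluated at KDE-drawn sample points (default 10,000). Two point sets are
then produced:

* **In-region KDE samples** drive the inverse-density volume estimator
  `V = q · mean(1 / f̂)`; for x distributed as f̂ restricted to the region,
  `E[1/f̂] = vol/q`, so the estimator is unbiased.
* **Uniform support points** (default `500·d`): in-region samples are
  thinned with acceptance probability `t / f̂(x)`, which flattens them to a
  uniform distribution inside the region — the constant-density
  representation the kernel FD indices assume.

The indices are then: **richness** = V; **evenness** = the overlap
`∫ min(f̂/q, 1/V)` between the normalised restricted KDE and the uniform
density on the region (estimated as `V · mean(min(f̂/q, 1/V))` over the
uniform support; 1 = perfectly regular occupation); **dispersion** = mean
Euclidean distance of the uniform support points from their centroid; and
**Jaccard overlap** = intersection/union, with the intersection estimated
symmetrically as the average of `V_A · frac(A's support inside B)` and
`V_B · frac(B's support inside A)`.

Every constructor takes a mandatory seed; identical seeds give bitwise
identical hypervolumes (so `J(A, A)` = 1 exactly). On 2-D instances the
Monte-Carlo indices agree with a dense-grid brute-force integration of the
identical KDE within 5% (the grid integrator lives in the test suite as an
oracle only), and for standard-normal scores the volume matches the
closed-form smoothed-Gaussian ellipsoid `π · χ²₂(0.95) · (1 + h²)`.

A subtlety worth stating: thresholding on the *probability mass of the
KDE* is not the same as retaining the 95% densest *data points* — for a
Gaussian the mass-weighted data-point rule would retain a region roughly
half the size. The probability-mass definition is the one consistent with
the kernel-hypervolume methodology this package follows and with the
closed form above.

## 5. Treatment comparisons and bioassays

Because the replicate-level FD design is small (5 treatments × 4
replicates = 20 observations) and indices need not be normal, treatment
differences use the Kruskal-Wallis test (tie-corrected, chi-square
approximation) with Conover-Iman post hoc comparisons on the pooled
midranks, Benjamini-Hochberg correction across all 10 treatment pairs, and
a significance threshold of 0.01. Kruskal-Wallis is delegated to
`stats::kruskal.test`; the Conover-Iman statistic is implemented here (no
suitable implementation ships with the environment's packages) and is
checked against brute-force rank computation in the tests.

Nutrient-limitation bioassays are interpreted with a standard addition
logic: per-replicate growth `g = ln(day4/day0)/4`, one-sided Welch tests of
each addition (+N, +P, +NP) against control at α = 0.05, N or P called
limiting when its own addition responds, and N+P co-limitation when only
the combined addition does. Because growth is a log-ratio, lognormal
fluorescence noise makes the per-replicate growth exactly normal, and the
test's false-call rate calibrates at α in simulation.

## 6. The synthetic-data generator as study design

The generator's defaults *are* the study conditions the pipeline is
validated under, chosen once:

* **Design**: 5 treatments (control, high_pCO2, low_N, low_P, low_L) × 4
  replicates; 28 weekly field samples; 2,000 events per sample by default.
* **Channels**: lognormal with medians FSC 5000, SSC 2000, FL670 8000,
  FL692 4000 (arbitrary instrument units) and log-scale sd 0.35; the two
  pigment channels correlate at ρ = 0.8 on the log scale; 14 distractor
  channels (4 of them collinear "area" copies of informative channels, the
  rest independent noise) give the collinearity filter realistic input.
* **Effects** (multiplicative on channel medians): nitrogen limitation
  lowers granularity (×0.5) and the pigments (phycocyanin ×0.2,
  chlorophyll-a ×0.35 — accessory pigments degrade first) and raises cell
  size (×1.5, arrested growth); phosphorus and light limitation raise
  pigments and granularity and lower cell size; high pCO2 is a mild
  control-like shift. Per-treatment spread multipliers (low_N 0.5 <
  control 0.85 < low_L 1.0 < high_pCO2 1.15 < low_P 1.4) set the designed
  ordering of functional richness, with nitrogen limitation narrowest and
  phosphorus limitation widest.
* **Debris**: 10% of events from a broad uniform-on-log cloud 1–3 decades
  below the target, separable by ≥10× in at least one channel.
* **Field series**: each sample's effect vector interpolates
  *geometrically* (log-linearly, since effects are multiplicative) between
  the low_N and low_L rows. The interpolation weight is linear in the
  TN:light covariate with the nitrogen-limited phenotype at *low* TN:light
  — nitrogen limitation occurs when nitrogen is scarce relative to light —
  so the distance to the nitrogen fingerprint increases, and the distance
  to the light fingerprint decreases, with TN:light. Metadata carries
  TN = gradient × light at a fixed light of 30 µmol photons m⁻² s⁻¹ and a
  high, constant TP (no phosphorus story in the field design). A 5%
  large-colony fraction (~14 µm equivalent) exercises the size gate.
* **Bioassay**: base growth 0.10 d⁻¹, relieved-limitation growth
  0.35 d⁻¹, three replicates, lognormal day-4 noise (sd 0.1), giving a
  ~10-sd designed contrast.

What the generator does **not** emulate: instrument drift and spectral
spillover, doublets/coincidence, colony-level trait structure beyond a
token large-particle fraction, non-lognormal debris shapes, genotypic
mixtures, or seasonal autocorrelation in the field series. Passing tests
therefore demonstrate that the estimators and decision rules recover known
structure under the assumed statistical model — not that gating will be
correct on any particular instrument's files.

## 7. Problem sizes, determinism and limitations

The test suite and the acceptance script run the full design at 1,200
events per sample, 199 permutations and 10,000-point KDE threshold
samples; these sizes keep every Monte-Carlo estimator's error comfortably
inside the tolerances asserted while remaining quick on one core. All
stochastic stages draw their seeds from a single master seed through a
counter-based fan-out, so end-to-end reruns are numerically identical.

Known limitations: the O(n²) distance kernels are meant for per-sample
event counts in the 10³–10⁴ range, not raw million-event files (gate on a
subsample, or pre-gate upstream); hypervolumes in more than ~4 dimensions
suffer the usual KDE curse of dimensionality; the Jaccard estimator's
accuracy degrades for vanishingly small intersections (values below ~0.01
are best read as "disjoint"); and no spillover compensation or absolute
pigment quantification is attempted — traits stay in relative instrument
units throughout.
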