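---
title: "Models and methods behind fadyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fadyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

fadyn quantifies three readouts of cell-matrix adhesion biology: focal
adhesion (FA) morphometrics from fixed-cell fluorescence images, single-cell
migration speed from nuclei time-lapses, and traction forces from
micropillar-array movies. This vignette explains the models, the tunable
parameters, the numerical choices, and what the synthetic generators do and
do not emulate.

## Focal-adhesion segmentation and features

The FA channel is smoothed with a Gaussian (`gaussian_sigma_px`, default
1 px), and background is removed by greyscale morphological opening with a
disc (`rolling_ball_radius_px`, default 10 px) — the morphological analogue
of rolling-ball background estimation. Detection proceeds by watershed-masked
clustering: an intensity watershed partitions the above-floor signal into
basins around local maxima (maxima closer in height than `watershed_h`,
default 10% of the dynamic range, merge), and each basin is masked down to
its bright core by an Otsu threshold computed inside the basin. The final
threshold is applied to the background-subtracted *unsmoothed* intensities
so object areas keep their unblurred extent; in particular an isolated
3-pixel speck stays below the 4-pixel minimum-area filter
(`min_area_px = 4`, i.e. 0.46 µm² at the default 0.339 µm pixel), which
exists to exclude sub-resolution specks from the adhesion statistics.

The noise floor is estimated from the raw image (median absolute deviation)
and attenuated by the analytic factor $1/(2\sigma\sqrt{\pi})$ for the
smoothing width, so blank or noise-only fields yield zero objects.

Per-object features use the second central moments of pixel coordinates
with eigenvalues $\lambda_1 \ge \lambda_2$:

* `elongation` $= 1 - \lambda_2/\lambda_1$ (0 for a disc),
* `extension` $= \lambda_1 / \text{area}$,
* `dispersion` $= 4\pi(\lambda_1+\lambda_2)/\text{area}^2$,
* `orientation_deg` = principal-axis angle from the +x axis in [−90, 90),
* `compact_factor` $= 4\pi\,\text{area}/\text{perimeter}^2$.

These names are conventional in FA-screen software but their exact formulas
vary between tools; the definitions above are the package's documented
choice and are deliberately simple moment expressions. The perimeter is the
Manhattan boundary-edge count corrected by $\pi/4$ (the exact correction for
isotropically oriented boundaries) and floored at the isoperimetric minimum
$2\sqrt{\pi\,\text{area}}$, which keeps the compact factor in (0, 1] even
for 4-pixel objects where digital perimeter estimators otherwise overshoot.

Nuclei are segmented by Gaussian blur, Otsu threshold, hole filling, and a
watershed on the distance transform (splits touching nuclei with distinct
peaks). Fields with fewer than 3 nuclei are excluded from all FA statistics.

## Signed Kolmogorov–Smirnov screening

Each gene contributes three comparisons: baseline vs pooled control,
drug-induced assembly vs the gene's own baseline, and washout-induced
disassembly vs the gene's own drug condition. The statistic is the classical
two-sample $D$ with a sign taken from $F_\mathrm{ref}-F_\mathrm{test}$ at
the argmax (positive = test sample shifted to larger areas). ECDFs are
right-continuous, so ties are handled consistently.

Because pooled per-adhesion samples run to tens of thousands, p-values
underflow doubles; the asymptotic Kolmogorov survival function
$Q(\lambda)=2\sum_k(-1)^{k-1}e^{-2k^2\lambda^2}$ is therefore evaluated
entirely in the log₁₀ domain (leading term $-2\lambda^2/\ln 10$ with an
explicit alternating-series correction), with the Jacobi-transformed series
on the small-$\lambda$ branch so p-values near 1 are also accurate. The
branch switch sits at $\lambda = 1.18$.

Hit categories are assigned in priority order — `increase` (signed
$D > 0.1$, $p < 10^{-40}$), `decrease` ($D < -0.075$, $p < 10^{-25}$), then
`assembly_blocked` if the drug comparison shows no change, then
`disassembly_blocked` if the drug response is significant but washout shows
no change. The "no change" band ($|D| < 0.05$ or $\log_{10}p > -10$) is a
configurable stand-in for what screens usually resolve by visual
inspection; it is reported with every run. Deselected genes (removed from
follow-up for reasons outside the statistics) are subtracted from the
increase/decrease totals in the summary bookkeeping.

## Migration

Tracking links each labelled nucleus in frame $t{+}1$ to the frame-$t$
label with maximal pixel overlap, one-to-one, greedily by overlap with
centroid distance as tie-break; unmatched labels start new tracks and a
track ends at its first miss. This conservative rule cannot teleport
identities across gaps, which is the property the speed statistics need.
Per-cell speed is the mean Euclidean step divided by the frame interval
(10–14 min supported per movie), computed separately for the pre- and
post-stimulation phases; tracks shorter than `min_steps = 5` steps are
dropped. Populations are compared with Kruskal–Wallis (tie-corrected) and
Dunn's pairwise $z$ statistics with Bonferroni adjustment. The normality
consensus follows the three-test rule (Lilliefors-corrected KS,
D'Agostino–Pearson $K^2$, Shapiro–Wilk; normal only if all three fail to
reject at $\alpha = 0.05$).

## Micropillar traction forces

Pillar mechanics use the Euler–Bernoulli cylindrical cantilever
$k = 3\pi E r^4/(4h^3)$; the default array (4.1 µm height, 2 µm diameter,
4 µm pitch) carries the printed stiffness 65.8 nN/µm, which the package
accepts as the force-conversion constant rather than recomputing it. The
array-level effective modulus uses the sphere-indentation equivalence
$E_\mathrm{eff} = 9k/(4\pi r)$, giving 47.2 kPa.

Pillar tops are localized by difference-of-Gaussians band-pass, local
maxima above 30% of the band-passed range, and intensity-weighted centroids
in a window with the window-border median subtracted as local background.
On rendered discs at 0.2 µm pixels and SNR 20 this localizes to ~0.01 µm
RMS, i.e. sub-nN force precision at 65.8 nN/µm.

The reference grid is fitted on pillars *outside* the cell footprint:
orientation from nearest-neighbour angles folded into the 60° sector
(circular mean), integer lattice indices by rounding in the basis, then
iterated trimmed least squares for origin and basis vectors. Deflections
are observed minus lattice-predicted positions; anything beyond half the
pitch is flagged as a mis-assignment and excluded. Tracking links
detections to active tracks by ascending displacement under a 2 µm gate,
keeping unmatched tracks alive for one extra frame (2-frame gap retry);
at 4 µm pitch with sub-micron deflections the greedy assignment is
equivalent to the optimal one. Cell coupling means inside the actin mask in
at least half the frames; among coupled pillars the top 5% by time-averaged
deflection magnitude (at least one) are selected.

### Autocorrelation half-times

For each selected pillar the force-magnitude series is mean-subtracted and
its autocovariance computed with the lag-unbiased $1/(n-k)$ normalization.
Covariance curves are averaged across pillars *before* a single
normalization at lag 0, and the pooled curve is fitted with
$a\,e^{-\lambda t} + c$ over the first 2 h (25 points at 5-min frames);
the half-time is $\ln 2/\lambda$ of the decaying component.

Two numerical choices here deserve justification, both driven by the
length of the series (80 frames):

* *Pooling before normalization.* Normalizing each pillar's curve by its
  own noisy lag-0 variance and then averaging produces a ratio bias that
  attenuates the apparent decay time by tens of percent at these series
  lengths; dividing the pooled covariance by the pooled variance avoids it.
* *The offset term.* Estimating each series' mean from the series itself
  shifts every lag of the autocovariance down by approximately
  $\mathrm{Var}(\bar x)$, a constant; without an offset the fit converts
  that shift into a faster decay. The offset absorbs it exactly while
  leaving $\lambda$ interpretable. The half-time is reported for the
  exponential component, not for the offset-inclusive curve.

The fit itself is profiled least squares: for fixed $\lambda$ the model is
linear in $(a, c)$, so the profile SSE is minimized over $\lambda$ by a
grid bracket plus golden-section refinement — deterministic and free of
convergence failures.

With these choices the full pipeline (render → detect → grid → track →
select → autocorrelate) recovers the closed-form half-time of a planted
2-D Ornstein–Uhlenbeck (OU) deflection process within 25% across seeds.
The closed form used as the oracle: for component correlation
$c(t)=e^{-t/\tau}$, the magnitude (Rayleigh) correlation is
$\rho_R(t) = \bigl({}_2F_1(-\tfrac12,-\tfrac12;1;c^2) - 1\bigr)/(4/\pi-1)$,
whose half-time is $\approx 0.32\,\tau$ — approximately half of
$\tau\ln 2$, because magnitude correlation tracks the *squared* component
correlation.

### Condition comparisons

Per-pillar mean forces are compared with Welch's unequal-variance t-test.
Half-times are compared by the extra-sum-of-squares F statistic between a
shared fit and separate fits to the two conditions' mean curves. The 25
lag points of an autocorrelation curve are strongly correlated, so the
classical $F$ distribution is badly anticonservative for this statistic
(~80% null rejections in simulation); the reported p-value is therefore
calibrated by permuting pillars between conditions (199 permutations by
default; pillars are exchangeable under the null), with the parametric
p-value retained as `p_parametric`. Measured null rejection at
$\alpha=0.05$ is ~5%, and planted 22- vs 45-min half-times are detected.

## Synthetic data: what it emulates, and what it does not

The generators are seeded (identical configuration + seed gives
bit-identical output) and every object carries ground truth.

* **FA fields**: adhesions are anisotropic Gaussian spots (aspect ratio
  1–4) in an annulus near the cell edge — peripheral, elongated, tangential
  — with true areas log-normal in µm² (meanlog 0, sdlog 0.6, i.e. median
  1 µm², chosen as a realistic screen-scale median) scaled by the condition
  multiplier. Spot placement enforces separations that grow with spot
  extent, because adhesions are discrete structures; the same unit-scale
  separations are used for every multiplier so identical seeds give
  identical geometries across conditions. Noise is Poisson shot noise plus
  Gaussian read noise parameterized by a single SNR.
* **Migration movies**: persistent random walks (heading diffusion 0.45
  rad/frame) at the configured pre-/post-stimulation speeds, reflected at
  the field margin; nuclei exclude each other by contact repulsion with
  collision-induced turning, since overlapping nuclei are rare in
  sub-confluent assays. True speeds are recomputed from the realized
  coordinates, so wall and contact effects are part of the ground truth.
* **Pillar movies**: a hexagonal lattice (default 4 µm pitch) rendered as
  soft-edged 2-µm discs at 0.2 µm pixels; pillars under a circular cell
  footprint follow a stationary 2-D OU process (exact discretization),
  matching the exponential-autocorrelation structure the half-time analysis
  assumes; detections are emitted with localization noise and dropped at
  the configured miss rate. Defaults (80 frames × 5 min, sd 0.3 µm,
  τ = 30 min) reflect a several-nN, slowly remodelling traction field.

Not emulated: clustered or merging adhesions, uneven illumination, cell
division and death, pillar-array fabrication defects, and photobleaching.
Passing tests therefore demonstrate correctness of the measurement chain
under the stated statistical structure, not robustness to every artefact of
real microscopy; the QC surface (nuclei counts, residual RMS of the grid
fit, tracking coverage) is the intended first line of defence on real data.

## Problem sizes

The test-suite and acceptance runs use desk-scale versions of the study
design: screens of 3–21 genes at up to 1500 adhesions per condition,
migration movies of 30–50 cells over 25–40 frames, pillar movies of
144–400 pillars over 80 frames, 200-replicate null calibrations, and
200-image localization batches. These sizes were chosen so that every
stochastic check is measured with adequate precision while a full run
remains a desk-scale computation.

## Known limitations

* The "no change" band in hit calling is a quantitative stand-in for a
  partly visual decision; its defaults are explicit and configurable.
* Dimensionless shape features follow the package's own moment
  definitions; compare absolute values across tools with care.
* The migration tracker deliberately has no gap closing; dividing or
  transiently lost cells yield split tracks rather than risky joins.
* The half-time comparison's permutation p-value requires per-pillar
  curves; comparing fits on pre-averaged curves alone falls back to the
  anticonservative parametric p.
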