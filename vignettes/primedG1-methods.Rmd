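---
title: "Models and methods behind primedG1"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind primedG1}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primedG1)
```

# Scope

primedG1 analyses single-cell reporter imaging of the Rb–E2F commitment
decision: per-cell quantification of multi-channel frames, classification
and alignment of live-cell traces, and kinetic inference of
phosphorylation-site preference on Rb. Because raw imaging data of this
kind is rarely shareable at full scale, the package pairs every analysis
stage with a synthetic generator that plants known ground truth; all
validation in the test suite runs against those planted truths. This
vignette records the models, the tunable parameters, and the design
decisions that were genuinely open.

# The two-site kinetic model and the PSP curve

Each phosphosite is treated as an independent two-state species with
phosphorylation rate α (min⁻¹) and dephosphorylation rate β (min⁻¹):

$$\frac{dx}{dt} = \alpha_1(1-x) - \beta_1 x, \qquad
  \frac{dy}{dt} = \alpha_2(1-y) - \beta_2 y.$$

Both equations are linear, so `simulate_two_site()` uses the exact
solution $x(t) = x_{eq} + (x_0 - x_{eq})e^{-(\alpha+\beta)t}$ with
$x_{eq} = \alpha/(\alpha+\beta)$; a deSolve integration serves as an
independent cross-check in the tests, never as the implementation.

Under kinase non-selectivity ($\alpha_1 = \alpha_2$), eliminating α from
the two equilibria gives

$$y = \frac{x}{\mathrm{PSP}_{coeff} + (1-\mathrm{PSP}_{coeff})\,x},
  \qquad \mathrm{PSP}_{coeff} = \beta_2/\beta_1,$$

a one-parameter curve through (0,0) and (1,1) that is the identity when
the coefficient is 1 and bends below the diagonal when site *x* is
dephosphorylated more slowly (hence phosphorylated first). The
coefficient is therefore directly the relative dephosphorylation rate; no
absolute rate needs to be known.

**PSP fit.** `fit_psp()` does ordinary nonlinear least squares of *y* on
the curve, restricted to pairs with both normalized fractions in
[0.1, 0.9]. The window excludes the saturated tails, where the curve
carries no information about the coefficient and where normalization
error dominates; it is applied to *both* axes. The loss is unweighted:
plots of such data are usually density-coloured, but nothing in the
estimator requires density weighting, and unweighted least squares keeps
the estimator transparent. The standard error comes from the asymptotic
covariance of the fit. At least 10 in-window pairs are required.

**Normalization.** `normalize_phospho()` divides each cell's phospho
signal by its total-Rb signal and scales so that the mean ratio over
S-phase cells equals 1 — in S phase Rb is hyperphosphorylated, so each
site is fully occupied and serves as its own saturation standard. The
operation is idempotent and invariant to rescaling either fluorophore.

# Decay fitting and the phosphatase preference ratio

`fit_exp_decay()` fits $v(t) = p + A e^{-kt}$ per replicate and
summarizes $k$ as mean ± s.e. across replicates (the biological
replicate, not the timepoint, is the unit of variation). The plateau term
exists because incomplete dephosphorylation is common in perturbation
experiments, but it is **not identifiable** from short windows: over
0–60 min a 40-min half-life completes only 1.5 half-lives, and plateau,
amplitude and rate trade off almost freely (in simulation, free-plateau
fits gave ~16% median half-life error on noiseless-shaped data with 5%
noise — an identifiability artifact, not a noise effect). For
acute-kinase-inhibition experiments, where dephosphorylation runs to
completion, the right model is the zero-plateau one
(`fix_plateau_zero = TRUE`), and that is what the package's own
validation uses; the free plateau remains the default for generic data.

`rate_ratio()` forms $k_{fast}/k_{slow}$ with first-order propagation
$\mathrm{se} = r\sqrt{(\mathrm{se}_f/k_f)^2 + (\mathrm{se}_s/k_s)^2}$.
One honest caveat: with 3 replicates the s.e. of each rate has only 2
degrees of freedom, so an interval of ±1 propagated s.e. covers the true
ratio only about two-thirds of the time even in the best case; it should
be read as a scale of uncertainty, not a confidence interval.

**Shared experiment noise.** The decay generator applies one multiplicative
noise draw per (replicate, timepoint) to *all* sites by default
(`shared_noise = TRUE`): in iterative immunofluorescence the sites are
measured in the same cells and imaging session, so experiment-level
fluctuations are common to all sites within a replicate. Independent
per-site noise is available as a switch.

# Hill and Deming fits

`fit_hill()` fits $b + A\,a^n/(K^n + a^n)$ of phospho fraction against
CDK2 activity. Baseline and amplitude are free because normalized
phospho spans roughly 0–1 but with background; bounds keep $n \in (0,20]$
and $K$ within the data range. The residual surface in $n$ has local
minima (a shallow-slope solution with $K$ at the data edge), so the fit
multi-starts over $n_0 \in \{1, 2, 4, 8, 14\}$ and keeps the best RSS.
Because single-cell immunofluorescence is heavily scattered, a
binned-median mode (`binned = TRUE`, equal-count bins) is provided as
well; both modes recover planted coefficients in the tests.

`deming_fit()` implements the closed-form errors-in-variables slope for
error-variance ratio δ,

$$\hat\beta = \frac{s_{yy} - \delta s_{xx} +
  \sqrt{(s_{yy}-\delta s_{xx})^2 + 4\delta s_{xy}^2}}{2 s_{xy}},$$

with δ = 1 by default (two normalized fluorescence axes are comparably
noisy) and a leave-one-out jackknife for the slope s.e. When both axes
carry equal noise, ordinary least squares is attenuated by the
reliability factor $\lambda = \sigma^2_{true}/(\sigma^2_{true} +
\sigma^2_{err})$ while the Deming slope stays unbiased — the test suite
checks both statements against their analytic values.

# Image quantification

The measurement chain follows standard practice for epifluorescence
time-lapse pipelines:

* **Flatfield**: division by the illumination bias normalized to mean 1.
  When no measured bias exists, `estimate_bias_field()` builds one from
  the smoothed per-pixel low percentile across many frames.
* **Local background**: per-block 10th percentile (block 128 px),
  bilinearly interpolated between block centres and subtracted, negatives
  clipped. Block-percentile is robust as long as background occupies
  more than the percentile fraction of every block. Subtracting the
  background before ratio measurements matters: a residual additive
  offset biases the cytoplasm/nucleus ratio towards 1.
* **Segmentation**: global Otsu threshold on log intensity, watershed on
  the distance transform to split touching nuclei, area gating. The
  original pipeline this emulates was custom and unpublished in detail;
  Otsu + distance-transform watershed is the standard, testable
  substitute. Masks are 8-connected, labels contiguous, coordinates
  0-based at pixel centres internally (1-based in R indexing).
* **Cytoplasmic ring**: pixels whose Euclidean distance to their nearest
  nucleus lies in (0.65, 3.25] µm and that are nearer that nucleus than
  any other. Distances and the nearest-nucleus rule are computed
  *exactly* (per-label boundary-pixel distances within bounding boxes)
  rather than with a propagation approximation, so ring/region
  disjointness and the equidistant-boundary property hold pixel-exactly.
  CDK2 activity = ring median / nuclear mean; empty rings (crowding, or
  inner = outer) yield a missing value with a reason code. All ring
  pixels enter the median, including zeros.
* **Whole-cell regions**: nearest-nucleus expansion to at most 15.6 µm;
  regions partition their union.
* **FISH counting**: white top-hat with a Euclidean-ball kernel of radius
  round-half-up(1.3 µm / pixel size), absolute threshold on the filtered
  image, and a per-region count of *foreground pixels* (not connected
  components). The absolute threshold is a required parameter: its value
  is instrument-dependent and is not hard-coded. EBImage's grayscale
  morphology clips intensities to [0, 1], so the image is rescaled
  around the filter. Micron-to-pixel conversions round half away from
  zero.
* **Round registration**: integer shift by FFT cross-correlation, with a
  normalized-correlation floor below which alignment is flagged failed;
  fixed-round cells map onto live labels by nearest shifted centroid.

# Synthetic data: what it emulates, and what it does not

The generators define the study conditions used throughout the tests.

**Frames.** Nuclei are disks with per-cell log-normal intensity, assigned
by pixel centre; an optional Gaussian PSF (σ = 0.5 µm) is applied to the
nuclear-marker and FISH channels, where sub-pixel softness matters for
segmentation realism. The translocation-reporter channel is left
unblurred and its nuclear compartment extends 2 px beyond the chromatin
disk: the chromatin (Hoechst/H2B) mask is biologically smaller than the
nuclear envelope, and the guard band guarantees that a segmentation mask
within ~1.5 px of the chromatin boundary still samples pure nuclear
reporter signal — this is what makes the render-then-measure round trip
exact and lets the tests demand ratio recovery within 2%. Vignetting is
a radial quadratic field; noise is Poisson shot noise (via a photon
gain) plus Gaussian read noise. Pixel size defaults to 0.65 µm/px (20×
objective with 2×2 binning); the exact calibration is configurable.

**Traces.** The trace model is phenomenological scaffolding, not a
mechanistic claim: committed cells show a CDK2 rise, an intermediate E2F
plateau of variable duration, a joint late rise of both activities over
the final ~3 h, and a degron-reporter drop at S entry; reversing cells
decay from the plateau; undecided cells hold it. Activities are on a
normalized 0–1 convention (the 0.65 CDK2 threshold refers to this
scale), sampled every 12 min over 40 h. Fate fractions default to
0.60/0.25/0.15 committed/reversing/undecided; G1 length (E2F activation
to S entry) is log-normal with median 12 h and log-sd 0.4, which
populates all four analysis strata (5–10, 10–15, 15–20, 20–25 h).
Measurement noise is multiplicative log-normal with CV 0.05 per frame —
typical for well-exposed reporter imaging. The degron reporter
accumulates slowly and drops exponentially at S entry with a 15 min
half-life: CRL4^Cdt2-mediated degradation of PIP-degron reporters is
fast relative to a 12-min frame interval, and a half-life near the
detector's 5-frame window would put every detection on a knife edge.
By construction the time from CDK2 onset to the 0.65 level inherits the
G1-length variability while the 0.65-to-S-entry leg is nearly constant —
the qualitative signature of a late-engaging positive feedback.

What the generator does **not** emulate: cell motility and division,
segmentation-confusing debris, photobleaching, spatially correlated
backgrounds, or any feedback between the reporters. Passing tests
therefore demonstrate correctness of the measurement and inference
chain, not robustness to every real-data pathology.

**Snapshots.** Each G1 cell draws a shared α from a log-normal
(meanlog 0, sdlog 1, β₁ = 1), giving equilibrium fractions that sweep the
PSP curve; the S-phase subpopulation is generated in the saturating
limit (fractions exactly 1), so noiseless normalization is exact.
Observed signals are fraction × total-Rb × log-normal noise.

# Event detection and fate rules

* **Onset**: first time the 3-frame-median-smoothed signal exceeds the
  baseline median + 3·MAD and stays above for ≥3 frames. The activation
  threshold is not numerically defined by the phenomenon itself; this
  baseline-relative rule is the documented, configurable choice.
* **S entry**: first local maximum of the smoothed degron trace from
  which the signal falls ≥50% within ≤5 frames; the returned time is the
  maximum (degradation start). Both the drop fraction and window are
  configurable.
* **Fates**, applied in order over a 40 h horizon: S_enter if a degron
  drop occurs by the horizon; else E2F_reverse if E2F activated and the
  post-peak minimum of the smoothed signal fell *strictly* below half the
  peak (a minimum at exactly half stays undecided — the strict reading of
  "more than half"); else undecided if activated; else never_activated.
  The peak is the maximum of the 3-frame-median-smoothed E2F signal
  before the horizon.

Alignment re-indexes anchored traces to time-before-anchor and averages
per stratum; it is exactly invariant to a global clock shift, and the
pointwise s.e. is computed over the cells contributing at each offset.

# Numerical choices and problem sizes

Ties in track linking resolve by distance then lower label id; the
nearest-nucleus rule breaks exact distance ties towards the lower label.
Decay fits start from a log-linear slope estimate; Hill fits multi-start
as above; all nonlinear fits use Levenberg–Marquardt (minpack.lm) with
parameter bounds stated in the function documentation. Degenerate inputs
(blank frames, empty strata, constant signals, empty rings) return empty
or flagged results rather than errors wherever a real pipeline would
encounter them routinely.

Validation sizes were chosen to exercise the estimators at realistic
scale while keeping the whole suite fast: 50-seed recovery studies with
2,000 cells for the PSP and Hill fits, 100 seeds for rate-ratio
calibration, 20 frames of 200 cells for the image round trip, and
300-cell populations for fate accuracy. These are the package's own
validation conditions, stated here so they can be reproduced exactly.

# Known limitations

* The per-replicate s.e. of decay rates has 2 degrees of freedom at 3
  replicates; ±1 propagated s.e. on the rate ratio is not an 80–95%
  interval (see above).
* Segmentation is 2-D, threshold-based and not learning-based; heavily
  overlapping nuclei beyond the watershed's reach will merge.
* The trace generator's parameters are conventions, not fits to real
  trace statistics; absolute activity units are arbitrary.
* Hill-fit standard errors are asymptotic and ignore the multi-start
  selection step.
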