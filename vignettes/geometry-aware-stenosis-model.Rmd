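---
title: "Methods: a geometry-aware lumped stenosis model"
author: "stenoshape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a geometry-aware lumped stenosis model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

A stenotic lesion embedded in an arterial network is represented as a 0D
element with the quadratic pressure–flow law

$$\Delta p \;=\; K_v\,h_1(q) + K_t\,h_2(q^2), \qquad
h_1(q) = \frac{8\mu l_s}{\pi a_0^4}\,q, \qquad
h_2(q^2) = \frac{\rho}{2}\left(\frac{q}{\pi a_0^2}\right)^2 .$$

The viscous coefficient $K_v$ scales the fully developed (Poiseuille-like)
loss, the expansion coefficient $K_t$ the inertial loss from flow separation
and reattachment downstream of the throat. Classical lumped models derive
$K_v, K_t$ from two or three scalar geometric features under a cosinusoidal
lesion assumption. Here both coefficients are instead *learned* as functions
of a low-dimensional statistical shape code $\alpha$, so irregular lesion
morphologies inform the prediction.

Model constants (defaults): blood density $\rho = 1060$ kg m$^{-3}$,
viscosity $\mu = 0.0035$ Pa s, reference radius $a_0 = 1.5$ mm, lesion
length $l_s = 10$ mm, baseline straight length $l_{ext} = 40$ mm, aortic
pressure 100 mmHg.

## Synthetic lesion cohorts

Each vessel is built on 20 equidistant cross-sectional planes (1 mm apart;
plane $i$ at $z = (i-1)$ mm). Severity $S_{sev} = 1 - a_s/a_0$ is drawn from
a Sobol low-discrepancy sequence scaled to $[0.3, 0.8]$ — the clinically
ambiguous window — so severities cover the range near-uniformly (102–103
samples per decile at $n = 1024$). One dimension suffices, so the generator
uses the first Sobol dimension (the base-2 radical-inverse sequence) with a
seeded random digital shift; the shift randomizes the points while exactly
preserving their dyadic stratification.

A single focal lesion occupies the central segment: boundary planes
$s_{sten} \sim U\{6..10\}$, $e_{sten} \sim U\{11..15\}$, and the
minimum-severity plane
$c_{sten} = s_{sten} + 2 + T(\beta(e_{sten}-s_{sten}-3))$ with
$\beta \sim U[0,1)$ and $T$ truncation toward zero. When the initial region
spans only planes 10–11 the center can land on plane 12, which is accepted
(it widens the lesion variety). Within the region the radius follows a noisy
Gaussian taper

$$a_i = a_0 - (a_0 - a_s)\,
  e^{-(i - c_{sten})^2 / (2\sigma^2)}\,(1 + \varepsilon_i),$$

with width $\sigma \sim U[1,3]$ (sharp to gradual) and independent
$\varepsilon_i \sim U[-0.1, 0.1]$; no noise at $c_{sten}$, which always
receives exactly $a_s$. Radii are not clamped from below at $a_s$ (noise may
slightly undercut it next to the throat) but must stay positive; the noise
vector is redrawn on violation. For reference-data generation a cylindrical
outflow extension of ten reference diameters (30 mm) is appended, giving a
35 mm total outlet extension past the lesion segment.

Surfaces are lofted by sweeping a natural cubic spline through the plane
radii around the axis on a fixed grid (default 4 axial samples per mm,
32 circumferential). The loft interpolant is a deliberate, documented choice
— CAD lofting behavior is tool-specific — and the spline may undershoot
between knots of sharply tapered lesions; see the oracle notes below.
Axial bookkeeping: plane $i$ sits at $(i-1)$ mm, so the 20-plane vessel
spans 19 mm; the nominal constants $l_s = 10$ mm and $l_{ext} = 40$ mm are
used as stated in the loss terms rather than forced to agree with
plane-count arithmetic.

## Statistical shape model

Because all cohort members share one vertex grid, template-to-target
correspondence is exact by construction, and the shape model is PCA on
per-vertex displacement fields from the straight-tube template (flattened
x/y/z blocks). This replaces diffeomorphic registration (LDDMM momenta)
pipelines: with correspondence given, displacement PCA preserves the
pipeline's contract — geometry in, compact coefficient vector $\alpha$ out —
without an external registration tool, at the cost of not smoothing the
per-plane noise the way a deformation kernel would.

Implementation notes: the mean uses all $N_{su}$ shapes; variances use the
$N_{su}-1$ denominator; the eigendecomposition goes through the
$N_{su}\times N_{su}$ Gram matrix when the ambient dimension is larger
(identical modes, much cheaper at $3N_v \approx 7400$); each mode's sign is
fixed so its largest-magnitude component is positive (PCA signs are
arbitrary, and reproducible $\alpha$ requires a convention). Five modes are
kept by default, which captures about 95% of total cohort variance at
$n = 1024$ in this representation; a cumulative-variance rule
(`n_modes = "auto"`, target 0.90) is available.

One structural consequence of correspondence-by-construction is worth
knowing: the loft is *linear* in the plane radii, and only the ten lesion
planes (6–15) ever deviate from the reference radius, so the cohort's
displacement fields span an (at most) ten-dimensional subspace regardless of
cohort size. The full PCA basis is therefore small, full-basis
reconstruction is exact to machine precision, and "five modes" means five of
roughly ten — not five of a thousand as it would after a general-purpose
registration stage.

## Reference pressure-drop data: the flow oracle

The package generates its own reference (flow, pressure-drop) samples with a
deterministic, geometry-dependent oracle rather than a flow solver. For each
geometry it defines

* $k_v^\ast = \frac{1}{l_s}\int (a_0/a(z))^4\,dz$ — the lesion-window
  average of the local Poiseuille resistance ratio, integrated by
  trapezoidal quadrature (20 subdivisions/mm) on the splined radius over the
  10 mm window in which each lesion plane (6–15) owns its 1 mm cell (the
  window is defined this way so that a straight tube gives exactly
  $k_v^\ast = 1$ and a uniformly narrowed lesion gives $(a_0/a_s)^4$);
* $k_t^\ast = ((a_0/a_{min})^2 - 1)^2$ — the Borda–Carnot sudden-expansion
  coefficient at the minimal *plane* radius. The plane minimum (not the
  spline minimum) is used deliberately: the natural spline can ring below
  the true plane radii between knots of sharp lesions, and the expansion
  coefficient should reflect the lesion, not the interpolant.

and emits $\Delta p_{sten} = k_v^\ast h_1(q) + k_t^\ast h_2(q^2)$ at 13
Reynolds numbers (0.1–500; $q = Re\,\mu\pi a_0/(2\rho)$), plus the
Poiseuille baseline $8\mu l_{ext} q/(\pi a_0^4)$ and their sum as the total
drop. Optional knobs add multiplicative log-normal noise, a
Reynolds-proportional model-mismatch term, and random convergence failures.
Samples with $\Delta p_{sten} > 60$ mmHg are *flagged* (not deleted) as
non-physiological; the fitter drops flagged rows by default. Because the
noise-free oracle lies exactly in the model family, downstream stages can be
tested by parameter recovery — which is also the oracle's limitation: it
reproduces the *structure* of viscous/expansion losses, not secondary flow,
Reynolds-dependent $K_v$, or transition effects a Navier–Stokes solver would
show. Passing recovery tests therefore validates the pipeline's machinery,
not its fidelity to real hemodynamics. Externally supplied reference tables
in the same CSV schema can be swapped in unchanged.

## Loss-coefficient fitting and its intrinsic bias

Per geometry, samples are split at $Re = 10$ ($Re = 10$ itself belongs to
the inertial subset). $K_v$ is a through-origin least-squares fit of
$\Delta p$ on $h_1(q)$ over $Re < 10$; $K_t$ is a through-origin fit of the
residual $\Delta p - K_v h_1(q)$ on $h_2(q^2)$ over $Re \ge 10$. Negative
fits are reported with a warning, never clipped.

This two-regime procedure is *not* exact even on noise-free in-model data:
the quadratic term does not vanish at $Re \le 1$, so

$$\hat K_v = k_v^\ast + k_t^\ast\,
  \frac{\sum_{low} h_1 h_2}{\sum_{low} h_1^2},$$

a closed-form bias of about $4.6\times 10^{-3}\,k_t^\ast$ with the default
constants (and a corresponding residual-propagation bias in $\hat K_t$
whose size grows as the 60 mmHg cap removes high-Reynolds samples). For
lesions whose expansion coefficient dominates ($k_t^\ast/k_v^\ast \sim 10$,
sharp severe throats) the relative $K_v$ bias reaches several percent. The
unit tests assert this closed form exactly rather than pretending the
procedure is unbiased.

## Coefficient regression

Two exact Gaussian-process regressors map $\alpha$ to $K_v$ and to $K_t$.
The kernel is $C\,k_{base} + \sigma^2\,[i=j]$ with $k_{base}$ RBF or Matérn
($\nu \in \{0.5, 1.5, 2.5\}$) over per-dimension (ARD) length scales
$\ell_d$, each initialized at 1 and bounded to $[10^{-3}, 10^5]$; $C$ is
bounded to $[10^{-1}, 10^5]$ and the white-noise variance to
$[10^{-6}, 10]$. The white term enters only the training kernel's diagonal,
never cross-covariances; the reported predictive variance includes it.
Features may be polynomially enriched (degree 2 adds squares and pairwise
interactions — 20 features from 5 modes; degree 3 all cubic monomials) and
are standardized with training statistics so that unit length-scale
initialization is meaningful across enriched features. Targets may be
log-transformed as $y = \ln(K + 10^{-6})$.

Hyperparameters ($\ell$, $C$, $\sigma^2$) are refined by maximizing the log
marginal likelihood (L-BFGS-B with analytic gradients, multi-start: the
configured values plus starts drawn log-uniformly across the $C/\sigma^2$
bounds). Model configuration — degree, log transform, kernel family, $\nu$,
and the $C/\sigma^2$ starting values — is chosen by a 20-trial search with
5-fold cross validation, minimizing mean CV MSE *on the transformed target
scale*; the sampler is a Tree-structured-Parzen-Estimator-style proposal
(10 random startup trials, top-25% "good" density, candidates scored by the
good/bad density ratio), with a pure seeded random sampler available. The
Reynolds number is deliberately not an input feature; the element keeps one
$(K_v, K_t)$ pair per geometry.

Back-transform convention: for log-trained models the point prediction is
the log-normal *median* $e^{\mu} - 10^{-6}$, not the log-normal mean
$e^{\mu + \sigma^2/2}$. At extrapolative queries the GP's log-scale
predictive standard deviation can exceed 2, and the mean convention then
inflates predictions by an $e^{\sigma^2/2}$ factor of an order of magnitude,
which destroys identity-line agreement precisely on the extreme lesions one
cares about. The mean convention remains available
(`gpr_predict(..., back_transform = "mean")`); the reported predictive
standard deviation is the log-normal standard deviation in either case.

## The 0D element, network coupling, and FFR

Given a trained bundle, $\Delta p = \hat K_v h_1(q) + \hat K_t h_2(q^2)$,
with predictive uncertainty propagated from the two posteriors under an
independence assumption. For embedding in a pulse-wave network the element
exposes the resistance form $R(q) = \hat K_v\,8\mu l_s/(\pi a_0^4) +
\hat K_t\,\rho/(2\pi^2 a_0^4)\,q_{sm}$, where $q_{sm}$ is an
under-relaxed flow magnitude, $q_{sm}^n = 0.3\,q_{sm}^{n-1} + 0.7\,|q^n|$,
damping near-zero and reversed systolic flow; the signed instantaneous flow
multiplies $R$, so reversed flow yields a reversed drop. The smoothed
magnitude is initialized at $|q_1|$ to avoid a startup transient. FFR is
$1 - \Delta p / P_{aorta}$ with $P_{aorta} = 100$ mmHg (a fixed-flow
surrogate, reported per sample and unclipped); waveform-driven runs report
the time-averaged FFR. A parameterized two-phase coronary-like waveform
generator is included as a fixture for exercising the element; it is not a
physiological model, and no 1D pulse-wave solver is included. The classical
geometry-based comparator (with explicit $K_v, K_t$ inputs, since its
original coefficient correlations are external to this package) is provided
for benchmarking.

## Evaluation conventions

"$R^2_{y=x}$" takes residuals about the identity line, so bias is penalized
(the fitted-line variant is available behind a flag). Calibration is
summarized as RMSE divided by the mean predictive standard deviation (1 =
well calibrated; the regressors here are typically overconfident, ratios of
2–4). FFR agreement uses the clinical 0.02 tolerance and the 0.80 ischemia
threshold (ischemic = positive class, scored by predicted drop). AUCs use
the Mann–Whitney statistic with 0.5 tie credit; paired AUC differences use
the DeLong covariance, two-sided, with $p = 1$ returned for identical score
vectors.

## Problem sizes, tolerances and degenerate inputs

The bundled tests and the acceptance script run desk-scale problem sizes
chosen as the package's own defaults: cohorts of 1024 geometries for
shape-model variance summaries, 100–250 geometries for recovery and
end-to-end checks with a 200/50 geometry-level train/test split (the split
is stratified by severity decile to stabilize small-test-set metrics), 20
search trials with 5-fold CV. Exact identities are asserted at
$10^{-12}$–$10^{-14}$; PCA-vs-oracle agreement at $10^{-8}$; quadrature uses
at least 20 subdivisions per mm. Degenerate inputs are rejected loudly:
empty regimes name the geometry and regime, non-positive radii abort
generation (noise redrawn), log transforms guard their domain, zero-variance
references and single-class labels are metric errors. Cholesky
factorizations retry once with a $10^{-10}$-scaled jitter before failing.

## Known limitations

* The oracle is structural, not physical: no secondary flow, no
  Reynolds-dependent viscous coefficient, no unsteady/inertial term, and the
  quasi-steady element cannot capture transient pressure–flow dynamics.
* Axisymmetric, single-focal lesions only — no eccentricity, curvature,
  bifurcations, or multi-lesion interaction.
* The two-regime fit carries the closed-form truncation bias described
  above; it is the field's standard procedure and is reproduced as such.
* Held-out identity-line R² at the 200/50 scale has high split-to-split
  variance (the statistic is dominated by the few most severe lesions);
  results at this scale should be read as indicative, with the larger
  default cohort preferred for stable estimates.
* Five displacement-PCA modes carry less information about the throat
  radius than their variance share suggests: the expansion coefficient is a
  fourth-power function of the narrowest radius, so its regression is
  intrinsically harder than the viscous one — visible in every evaluation
  as $R^2(K_t) < R^2(K_v)$.
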