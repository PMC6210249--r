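---
title: "Measuring daily greenspace exposure over activity spaces and modeling its health effects"
author: "greenexp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring daily greenspace exposure over activity spaces and modeling its health effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Most studies of greenspace and health measure exposure over a fixed
spatial unit — the residential neighborhood, a census tract, a buffer
around the home. People, however, spend large parts of their day
elsewhere: at work, in transit, at shops and gyms. Fixing the contextual
unit to the residence misattributes exposure (the *uncertain geographic
context problem*): two people in the same building can experience very
different green environments if one works in a park-rich district and the
other commutes through an industrial corridor.

`greenexp` implements an individual-level alternative. Each participant
reports a 24-hour activity diary — stay points (home, work, restaurants,
fitness places, ...) with the hours spent at each, and travel routes with
their duration. The diary defines a personal *activity space*, and
greenspace exposure is measured over that space, weighted by the time
actually spent in each part of it. The exposure measure then enters a
structural equation model (SEM) in which physical activity mediates the
effect of exposure on physical, mental, and social health.

## Activity spaces and the exposure indicators

The activity space is the union of two kinds of buffers, kept as separate
weighted components:

* a **1000 m disc** around every stay point, carrying weight $t_i/24$,
  the fraction of the day spent there;
* a single **500 m corridor** around all travel routes of the day
  (each route segment is buffered and the buffers merged), carrying
  weight $t_t/24$.

Because the day is fully partitioned, $\sum_i t_i + t_t = 24$ h and the
weights sum to one; the package validates this to $10^{-9}$ hours and
refuses diaries that break it, reporting the residual.

Three indicators are measured against a polygon layer (vegetation,
physical-activity sites, and accessibility-target greenspaces, all in a
planar metric CRS):

* **GE1, vegetation coverage** — the time-weighted covered fraction
  $\sum_i \frac{S_{v,i}}{S_{b1000}}\frac{t_i}{24} +
  \frac{S_{v,t}}{S_{b500}}\frac{t_t}{24}$, where $S_{v,i}$ is the
  vegetation area intersecting buffer $i$;
* **GE2, physical-activity-site coverage** — the same functional with the
  PA-site polygons;
* **GE3, accessibility** — the mean Euclidean distance (m) from each stay
  point to the nearest greenspace polygon (zero inside one). Travel
  segments do not enter GE3: the average runs over activity sites only.

Design choices worth spelling out:

* **Stay buffers are not unioned.** The coverage functional sums
  per-buffer terms independently, so overlapping stay buffers
  double-count by construction. That is intentional: it follows the
  formula as printed, which treats each stay's context separately.
* **All travel merges into one buffer** with a single $t_t/24$ weight,
  because the functional carries exactly one travel term. $S_{b500}$ is
  defined as the area of the *merged* travel polygon.
* **GE3 searches the whole layer** by default: a greenspace just outside
  the 1000 m buffer is still the nearest one. A `within_buffer_only`
  flag restricts the search to the buffer for sensitivity analyses;
  stays with nothing in reach then drop out of the average with a
  warning.
* **Coverages are exact up to polygon resolution.** Discs are regular
  64-gons (area within 0.16% of $\pi r^2$, comfortably inside the 0.5%
  documented tolerance); travel corridors are unions of convex capsules.
  Intersection areas come from convex clipping plus an exact
  union-by-slab-decomposition algorithm, so on rectangle fixtures the
  indicators match rectangle arithmetic to $10^{-9}$ relative error.

The geometry kernel (clipping, union areas, point-to-polygon distances)
is compiled code under `src/`; no geographic CRS handling is done in the
package — reprojection is the caller's job.

## Behavior scoring

Weekly physical activity is scored IPAQ-style from self-reported minutes:
$\mathrm{MET} = 3.5\,w + 4.0\,m + 8.0\,v$ (brisk walking, moderate,
vigorous). Levels cut at 600 and 1500 MET-min/week. The printed ranges
share endpoints ("0–600", "600–1500", ">1500"); the package assigns both
boundaries to the intermediate class — $[0,600)$, $[600,1500]$,
$(1500,\infty)$ — because the activity recommendation is *met* at 600.
The three model indicators are PA1 = total weekly minutes, PA2 = sessions
per week summed across intensity classes (the instrument does not say
whether frequency is per class; summing is the package's reading), PA3 =
MET-minutes.

Health enters as 13 Likert items (1–5): three physical-health items
(SF-36 subset), five mental-health items (WHO-5), five social-health
items (cohesion/trust scales). The bodily-pain item is reverse-coded
($6-x$) before modeling so every indicator points toward better health;
the source instrument is pain-coded and silent on this, and reversing is
what keeps all loadings interpretable and positive. Reliability checks
(Cronbach's $\alpha$ pooled over the 13 items to mirror the single
published value, plus per-scale $\alpha$, KMO, and Bartlett's
sphericity test) are computed before any model is fit.

## The structural equation model

Five latents: greenspace exposure (GE1–GE3), physical activity (PA1–PA3),
and physical, mental, social health. The structural part carries the
seven hypothesized paths — GE to each health dimension, GE to PA, and PA
to each health dimension — plus two freed error covariances
(accessibility with frequency; frequency with self-rated physical
health). First loadings anchor each latent at 1; latent variances are
free. With 19 indicators that is 190 sample moments and 47 free
parameters: df = 143.

Estimation minimizes the normal-theory discrepancy
$F = \ln|\Sigma(\theta)| + \mathrm{tr}(S\Sigma^{-1}) - \ln|S| - p$
by BFGS with analytic gradients (every $\partial\Sigma/\partial\theta_k$
is rank-two, so gradients and the expected information reduce to inner
products). Numerical choices:

* the sample covariance is rescaled to unit variances before
  optimization and estimates are mapped back afterwards — ML estimates
  are equivariant under diagonal scaling, and the rescaling keeps the
  problem well conditioned when indicators mix fractions ($10^{-2}$)
  and meters ($10^{2}$); a dedicated test verifies that rescaling an
  indicator by 1000 leaves $F$, all indices, and the standardized
  solution unchanged;
* start values on that correlation scale: free loadings 1 (i.e. equal to
  their anchor), structural paths 0.1, latent variances 0.4, error
  variances 0.5, error covariances 0;
* convergence requires the max absolute gradient of $F$ below $10^{-6}$,
  with up to four BFGS restarts; non-positive-definite trial
  covariances get a large penalty value and an eigenvalue-floored
  gradient;
* standard errors come from the inverse expected information
  $\mathcal{I}_{kl} = \frac{N-1}{2}\mathrm{tr}(\Sigma^{-1}\Sigma_k
  \Sigma^{-1}\Sigma_l)$; critical ratios are estimate/SE with two-sided
  normal p-values.

The index battery is the usual one: CMIN $=(N-1)F$ and CMIN/DF, GFI and
AGFI from $\mathrm{tr}[(\Sigma^{-1}S-I)^2]$, RMR, RMSEA, and NFI / PNFI /
CFI / PCFI against the independence model ($F_0 = -\ln|R|$,
df$_0 = p(p-1)/2$). One deliberate deviation from AMOS convention: RMR
is computed on the correlation metric, so that it — like every other
index reported — is invariant to indicator units. Saturated and
just-identified limits behave as expected ($F=0$, RMR $=0$, RMSEA $=0$,
GFI $=1$); df $=0$ fits report RMSEA $=0$ and an undefined CMIN/DF.

Paths whose p-value exceeds $\alpha = 0.05$ are *pruned for the effect
decomposition only*: their estimates stay in the output, but their
standardized effect is set to 0.00, mirroring the convention of treating
unsupported hypotheses as zero in further analysis. Effects then follow
path algebra on the standardized coefficients: total $=(I-B)^{-1}-I$,
direct $=B$, indirect = total − direct; with one mediator the indirect
effect is exactly the product of its two paths. Reported tables round
half-up to three decimals (banker's rounding would differ at ties);
additivity holds exactly on the unrounded values.

Control variables (demographics) are deliberately omitted from the core
model: the source analysis lists them without specifying how they enter,
and the mediation structure is identified without them. The model syntax
(`sem_model()`) accepts arbitrary measurement/structural specifications,
so users can add observed covariates as single-indicator latents if they
wish; the package does not claim either variant as canonical.

## The synthetic cohort and what it does (not) show

No survey data are distributed, so the package ships a generator whose
defaults *are* the study conditions: 1003 participants, the weekday time
budget (residence 13.20 h, work 7.89 h, travel 2.07 h, five minor
classes totalling 0.84 h), about 14.4 recorded items per person
(participants follow a closed home → work → stops → home tour, so items
≈ 2 × stays and minor-stop counts are Poisson with means proportional
to their time budgets — the item-count distribution itself is not
reported anywhere and Poisson is the package's choice), a 10 km × 10 km
window at 30% vegetation cover, and the published standardized loadings
and paths as latent ground truth (GE 0.70/0.87/0.08, PA 0.83/0.14/0.82;
GE→PA 0.14, GE→MH 0.21, GE→SH 0.17, PA→PH 0.13, PA→MH 0.13, the two
unsupported paths zero). Greenspace polygons are random non-overlapping
rectangles — chosen so every area in a test oracle is exact rectangle
arithmetic — with a west-to-east density gradient so that home location
induces correlated GE1/GE2/−GE3 measurements, i.e. a common exposure
factor. Likert items discretize standardized indicator scores at normal
quintile cut points, which keeps the Pearson-covariance attenuation mild
enough for ML-SEM on product-moment covariances (the estimator used
throughout, matching common practice for 5-point items). The simulated
PA log is built by inverting the MET formula, so scoring it reproduces
the simulated duration and volume targets exactly. PA-log scales
(duration 200 ± 80 min/week, volume 900 ± 450 MET-min/week) give a
realistic low/intermediate/high split of roughly 20/70/10%.

Two recovery regimes are tested routinely:

* **measurement-model closure** — surveys drawn directly from the ground
  truth at $n = 1000$, 50 seeds: the median absolute error of the seven
  standardized structural paths stays below 0.05;
* **full pipeline closure** — geometry included at $n = 2000$: generated
  layers → diaries → buffers → exposure → composite-driven survey →
  scoring → ML fit recovers every structural path within ±0.08. The
  residual bias here is real and documented: effects are injected on the
  equally-weighted standardized exposure composite, while the SEM
  estimates paths from the latent factor behind GE1–GE3, and the
  composite correlates imperfectly with that factor. The attenuation is
  a property of the emulation, not of the estimator, and its size varies
  with the realized layer: seeds whose polygon placement yields weaker
  intercorrelations among the measured indicators produce a noisier
  exposure factor and visibly larger path attenuation at a given $n$.

What passing these tests shows: the estimation machinery is consistent,
the exposure geometry is exact, and the whole chain holds together under
known truth. What it does not show: anything about real survey data —
real diaries have location error and unreported gaps, real greenspace is
not rectangles, real Likert items are not discretized normals, and the
published estimates come from data that were never deposited. The
cross-implementation check (an independent NumPy/SciPy ML fitter shipped
under `inst/reference/`, agreeing on estimates and all seven fit indices
to $10^{-3}$ on a fixture covariance) guards the estimator, not the
science.

## Problem sizes and runtime

Default test sizes were chosen so the whole suite runs in about two
minutes on one core: cohorts of 200–300 diaries for budget invariants,
1003 for the time-budget calibration check, 2000 for pipeline closure,
$n = 1000 \times 50$ seeds for the recovery battery. Exposure
measurement costs roughly 40 ms per participant-day at the default
polygon densities; the ML fit of the 47-parameter model takes well under
a second.

## Known limitations

* Vector-only geometry: raster vegetation must be polygonized before
  use; there is no NDVI or image-classification support.
* Euclidean accessibility only — no road-network distances.
* No polychoric/WLSMV estimation for the Likert block, no bootstrap
  confidence intervals for indirect effects; both are out of scope.
* Stay buffers are never clipped to a study boundary, so $S_{b1000}$ is
  constant across stays; near a coastline or study-area edge that
  overstates the denominator.
* The generator emulates structure, not place: no road networks, no real
  geography.
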