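# greenexp

Activity-space greenspace exposure, physical activity, and health
mediation modeling.

## What this is for

Residential buffers and census tracts misstate personal environmental
exposure because people move: the green environment someone actually
experiences in a day depends on where they stay, for how long, and which
routes they travel. `greenexp` is for researchers in health geography and
environmental epidemiology who want to

1. measure **individual daily greenspace exposure** from 24-hour activity
   diaries: each stay point gets a 1000 m buffer weighted by the share of
   the day spent there, all travel routes share one merged 500 m buffer,
   and exposure indicators are averaged over those time-weighted buffers;
2. score **weekly physical activity** (IPAQ MET-minutes and
   low/intermediate/high levels) and standard short health scales
   (physical, mental, social);
3. fit a **structural equation model** in which physical activity
   mediates the effect of greenspace exposure on the three health
   dimensions, with fit indices, significance-based path pruning, and a
   direct/indirect/total effect decomposition.

Since survey data of this kind are rarely shareable, the package also
ships a synthetic-cohort generator with a known latent ground truth, so
the entire pipeline is testable end to end — including parameter
recovery of the structural paths.

## The model

Exposure is the time-weighted coverage

GE1 = Σᵢ (Sᵥᵢ / S_b1000)(tᵢ/24) + (Sᵥₜ / S_b500)(tₜ/24),  with  Σᵢ tᵢ + tₜ = 24 h,

(analogously GE2 for physical-activity sites), and GE3 = (D₁+…+Dₙ)/n,
the mean distance from each activity site to its nearest greenspace.
Physical activity is scored as MET-min/week = 3.5·walk + 4.0·moderate +
8.0·vigorous, cut at 600 and 1500. The SEM has five latents — greenspace
exposure (GE1–GE3), physical activity (duration, frequency, intensity),
physical / mental / social health (13 Likert items) — seven structural
paths (GE→{PH,MH,SH,PA}, PA→{PH,MH,SH}), two freed error covariances,
and is estimated by maximum likelihood on the sample covariance
(Σ(θ) = ΛΦΛ′ + Θ, F = ln|Σ| + tr(SΣ⁻¹) − ln|S| − p), 47 free
parameters, df = 143. Effects decompose as total = (I−B)⁻¹ − I over the
standardized, significance-pruned paths.

## Worked example

The mediation arithmetic on a known standardized path matrix:

```r
library(greenexp)
B <- matrix(0, 5, 5, dimnames = rep(list(c("GE","PA","PH","MH","SH")), 2))
B["PA","GE"] <- 0.14; B["MH","GE"] <- 0.21; B["SH","GE"] <- 0.17
B["PH","PA"] <- 0.13; B["MH","PA"] <- 0.13
effect_decomposition(B)
#> standardized effects of GE
#>  exposure outcome direct indirect total
#>        GE      PH   0.00    0.018 0.018
#>        GE      MH   0.21    0.018 0.228
#>        GE      SH   0.17    0.000 0.170
```

The indirect effect on physical health is the mediated product
0.14 × 0.13 ≈ 0.018: exposure raises activity, activity raises physical
health. A full synthetic run — generate a cohort, measure exposure
geometrically, simulate and score the survey, fit the SEM:

```r
res <- run_pipeline(cohort_config(n_participants = 300, seed = 2))
res$fit
#> sem fit: F = 0.49819, chi2 = 148.96, df = 143, N = 300 (converged)
#> structural paths (standardized):
#>   PA~GE       0.073  (C.R.   1.22, p 0.2222)
#>   PH~GE       0.018  (C.R.   0.28, p 0.7795)
#>   ...
```

At n = 300 the small true paths (0.13–0.21) are not individually
significant — as expected; at the survey's actual size (n = 1003, see
`analysis/`) the five true nonzero paths come back significant and the
two structurally-zero ones do not.

The `analysis/` directory holds the staged workflow
(`01_simulate_cohort.R` … `05_report.R`), each a thin driver over the
package functions that prints what it found and writes its tables under
`results/`.

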