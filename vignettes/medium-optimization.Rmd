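---
title: "Two-stage statistical optimization of fermentation media"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage statistical optimization of fermentation media}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fermopt)
```

## The problem

Microbial pigment and metabolite yields depend on many culture variables at
once — carbon and nitrogen sources, salts, pH, inoculum size, aeration (via
culture volume), incubation time. Full factorial exploration of eleven such
variables at two levels would need 2^11 runs. The classical sequential
design-of-experiments workflow gets there in under 30: a **Plackett–Burman
(PB) screen** identifies the few variables with large main effects, then a
**Box–Behnken (BB) response-surface experiment** models the response as a
quadratic in just those variables and locates its maximum inside the
explored region.

`fermopt` implements both stages as a tested pipeline and ships, as worked
fixtures, the design tables of a melanin-production case study in the
halotolerant black yeast *Hortaea werneckii* AS1, where this workflow
roughly doubled the melanin yield (to 0.938 g/L, 1.45-fold over the basal
medium's 0.646 g/L).

## Stage 1: Plackett–Burman screening

A PB design examines up to $N-1$ factors in $N$ runs ($N$ a multiple of 4)
at two coded levels $\pm 1$; columns are balanced and mutually orthogonal,
so each factor's effect is estimated free of linear contamination by the
others. `pbDesign()` builds the matrix from the standard cyclic first-row
generator (supported run counts: 8, 12, 16, 20, 24); the case-study table
itself is shipped verbatim via `caseStudyPB()`, because a published matrix
— whatever generator produced it — is the ground truth for reproduction,
while the generator covers new experiments.

The **main effect** of factor $i$ is

$$E_{x_i} = \frac{\sum M_{i+} - \sum M_{i-}}{N/2},$$

the difference between the mean response at its high and low levels.
Significance is judged by the equal-variance unpaired two-sample
$t$-statistic between the two groups of runs,

$$t_i = \frac{\bar y_{+} - \bar y_{-}}
            {\sqrt{s^2_p\,(1/n_+ + 1/n_-)}},$$

with the pooled variance $s^2_p$ on $n_+ + n_- - 2$ degrees of freedom,
classified against a small table of tabulated critical values (defaults
3.70, 2.446, 1.94, 1.372 for the 1%, 5%, 10% and 20% levels at 10 df;
`tThresholds()` makes the table replaceable). Classification is boundary
inclusive: $|t|$ exactly equal to a critical value earns that level.

Two numerical decisions matter here:

* **Center runs are excluded** from both statistics. A run with every
  factor at its midpoint belongs to neither the high nor the low group; the
  published per-factor statistics of the case study are only reproduced
  with its appended center trial excluded, which confirms that convention.
* $t$ is computed on the **single response recorded per run** (groups of 6
  vs 6 for the 12-run design, 10 df). The case-study methods mention
  duplicate trials, but the table prints one value per run, and computing
  on those printed values reproduces the published 2.53 and 2.47 exactly.
  One published entry (the trace-element $|t|$ of 1.0) differs from the
  printed-response computation (≈ 0.98), consistent with the original
  statistics having been computed on unrounded yields; the reproduction
  report flags that entry with a ±0.05 band rather than "correcting" data.

Ranking for the follow-up stage orders factors by $|t|$ (ties by
$|E_{x_i}|$, then input order) and carries each factor's effect **sign**
forward: a positive effect says to explore upward from the current high
level, a negative one downward. In the case study this selects CaCl₂ (+),
culture volume (+) and trace-element solution (−).

```{r screen}
cs <- caseStudyPB()
screening <- pbScreen(cs$design, cs$response)
selectSignificant(screening, 3)
```

## Stage 2: Box–Behnken response surface

The BB design places runs at the midpoints of the edges of the coded cube
(every non-center run varies exactly two factors at $\pm 1$, the rest at 0)
plus replicated center runs — 15 runs for 3 factors with 3 centers. Natural
levels map affinely onto coded ones: for the case study, CaCl₂
{0.375, 0.75, 1.125} g/L, trace element {0.25, 0.5, 0.75} mL/L, culture
volume {75, 150, 225} mL per 500-mL flask, each onto $\{-1, 0, +1\}$.

The response is modelled by the full second-order polynomial in coded
variables,

$$Y = \beta_0 + \sum_i \beta_i X_i + \sum_{i<j} \beta_{ij} X_i X_j
      + \sum_i \beta_{ii} X_i^2,$$

fitted by QR least squares on the expanded model matrix. All ten terms are
always retained — no stepwise elimination — matching how such models are
reported in the fermentation-optimization literature. Fitting is done
**only in coded units**; natural-unit values are derived by substitution
for reporting, which preserves the design's orthogonality during
estimation. On a BB design that orthogonality forces the linear and
interaction coefficients to equal simple contrast estimates
($\sum X_i y / \sum X_i^2$), and `fitQuadratic()` verifies that identity
internally on every BB fit.

```{r fit}
bb <- caseStudyBB()
fit <- fitQuadratic(bb$design, bb$response)
fit
```

Refitting the shipped two-decimal responses reproduces the published
intercept (0.64 — also the mean of the three center runs) and the CaCl₂ ×
trace-element interaction (−0.045) exactly, because those two quantities
are determined by the printed numbers alone. The other eight coefficients
and $R^2$ (0.870 here vs 0.853 published) deviate by up to ≈ 0.02,
again consistent with the original fit having used unrounded yields. The
reproduction report (`caseStudyReport()`) therefore pins the two exact
quantities and applies ±0.03 bands to the rest, printing that caveat in
the report body.

## Locating the optimum

The fitted quadratic is maximized over the coded cube $[-1, 1]^k$ by
**exact face enumeration** rather than a numerical solver: every subset of
coordinates is fixed at a bound, the stationary point of the restricted
quadratic is solved from its normal equations and kept when it lies inside
the face, and all corners are included. A quadratic restricted to a face is
again a quadratic, so every local maximum is either a face-interior
stationary point or sits on a lower-dimensional face; the enumeration
therefore finds the exact global maximum with no tolerance or starting
point to choose, and degenerate (singular) restricted Hessians simply
contribute no interior candidate — their maxima surface on smaller faces.
For $k \le 5$ this is at most $3^5 = 243$ tiny linear solves.

```{r optimize}
published <- caseStudyModel()
opt <- maximizeOverBox(published)
opt
verificationReport(published, opt, observed = 0.938, basal = 0.646)
```

On the case study's published polynomial the maximum sits at the coded
corner $(+1, -1, +1)$ — natural levels CaCl₂ 1.125 g/L, trace element
0.25 mL/L, volume 225 mL — with predicted yield 0.99375 ≈ 0.994 g/L,
matching the reported optimum; the wet-lab verification yield of
0.938 g/L (5.6% below prediction) and the 1.45-fold gain over basal are
treated as measured inputs, not computed claims. `surfaceGrid()` exports
41 × 41 prediction grids over any factor pair (others fixed at 0, the
convention used for published 3-D surface plots) for plotting.

## What the synthetic generator emulates

`simulatePB()` and `simulateBB()` generate datasets with known ground
truth. PB responses follow
$y_r = \mu + \sum_j (E_j/2)\,x_{rj} + \varepsilon_r$ so factor $j$'s
expected main effect is exactly $E_j$; BB responses are a known quadratic
evaluated at the coded runs plus noise. Noise is i.i.d. Gaussian by
default because the downstream analysis (pooled $t$, ordinary least
squares) implicitly assumes homoscedastic errors; a Student-$t$ option
supports robustness checks. The baseline $\mu$ defaults to 0.338 g/L, the
grand mean of the case-study screening responses, so simulated yields live
on a realistic scale. Responses are clamped at zero only when a
`nonnegative` flag is set — off by default so estimator checks remain
unbiased — and, accordingly, only the file-reading path enforces
nonnegativity of measured yields.

The generator emulates the *statistical* structure the two stages assume:
additive main effects, a smooth quadratic surface, homoscedastic
run-to-run noise. It does not emulate growth kinetics, non-additive
biology (thresholds, saturation outside the design region), heteroscedasticity
of real yield measurements, or replicate structure. Passing parameter-recovery
tests therefore demonstrates that the estimators are correct under the model's
own assumptions — not that the quadratic model is adequate for any particular
organism; that is what verification runs are for.

Default simulation conditions mirror the case study: the 12-run, 11-factor
screen with a planted 0.3 g/L effect, and the 15-run, 3-factor BB design
with the published polynomial as truth, both at noise σ = 0.05 g/L (about
the scale suggested by the spread of the case study's center runs,
0.58–0.69 g/L). The recovery checks run 500 replicates of each — small
enough to re-run casually, large enough that coverage proportions are
stable to a couple of percent.

## Numerical choices and limitations

* Coded levels are stored as exact small integers (−1/0/+1), so balance
  and orthogonality checks use exact comparisons, not float tolerances.
* Natural-level CSV files must use each factor's exact low/center/high
  values; anything else is an error with a line number, not a silent
  nearest-level snap.
* Zero pooled variance in a screening group yields $t = \pm\infty$ with a
  warning when the effect is nonzero, and $t = 0$ when it is zero.
* Rank-deficient model matrices abort the fit naming the collinear
  columns.
* PB generation covers run counts 8–24 (the sizes with standard cyclic
  generators); BB construction covers 3–5 factors. Fold-over PB, central
  composite and D-optimal designs are out of scope, as are ANOVA
  decompositions, canonical/ridge analysis and confidence intervals on the
  optimum location.
* `foldChange()` simply ratios whatever two yields it is given; where
  published fold figures disagree across a study's sections, the package
  does not arbitrate.
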