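---
title: "Modelling developmental trajectories of cortical thickness with IQ moderation"
author: "cortdev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling developmental trajectories of cortical thickness with IQ moderation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortdev)
```

## The scientific problem

In developmental case-control neuroimaging, a recurring question is whether
the anatomical signature of a disorder is uniform across the cohort or
varies with a moderating trait. The canonical example, and the one this
package is built around, is attention-deficit/hyperactivity disorder (ADHD)
and IQ: both are heritable, they co-segregate in families, and typical
development shows positive correlations between IQ and brain measures. If
those correlations are disrupted in cases, then "the" ADHD brain phenotype
may actually be several phenotypes — for instance, a globally smaller but
developmentally normal cortex at higher IQ, versus a *delayed* cortical
maturation at lower IQ.

Answering this requires three pieces of machinery, all implemented here:

1. **Volumetric moderation models.** Covariate-adjusted group comparisons
   of global measures (volumes, surface area, mean thickness, white-matter
   FA), extended with a dimensional IQ main effect and an IQ x group
   interaction, and repeated within IQ subgroups formed by a median split.
2. **Vertexwise trajectory modelling.** At every vertex of a cortical
   surface, thickness is modelled as a flexible function of age with a
   locally-weighted running-line smoother; the flexibility (effective
   degrees of freedom) is chosen by a parsimony rule; groups are compared
   by asking whether two separate curves explain the data significantly
   better than one shared curve, with false-discovery-rate control across
   vertices.
3. **A calibrated synthetic cohort generator.** The original cohort data
   are not redistributable, so the package ships a generator that
   reproduces the published *statistical structure* — cell means and SDs,
   within-group IQ correlations, a peaked thickness-by-age trajectory with
   group-specific distortions, and spatially smooth vertex noise — so that
   every stage of the analysis can be exercised, calibrated and stress-
   tested end to end.

## The running-line smoother and its effective degrees of freedom

The trajectory engine is a locally-weighted running-line smoother: the fit
at age $x_0$ is the value at $x_0$ of a weighted least-squares line fitted
to the $k = \lceil \text{span} \cdot n \rceil$ nearest observations, with
tricube weights on distance scaled by the $k$-th nearest distance. Because
each fitted value is a fixed linear combination of the observations, the
whole fit is a linear operator $S$ ("smoother matrix"), and its flexibility
is summarised by the **effective degrees of freedom**
$\mathrm{df} = \mathrm{tr}(S)$. The constant fit has df 1, the global
least-squares line df 2, and running-line smooths interpolate above 2.
Rows of $S$ reproduce affine functions exactly — a property the test suite
checks at every span, and which an independent brute-force per-row weighted
least-squares construction confirms to $10^{-10}$.

Fractional df targets (2.2, 2.4, ...) require inverting the span-to-df
map. Two numerical facts shape the implementation of `spanForDf()`:

* for span $\le 1$ the neighbour count $k$ is discrete, so
  $\mathrm{tr}(S)$ is a *step function* of span;
* for span $> 1$ all points are in every neighbourhood and the tricube
  distance scale is inflated by the span (the standard loess
  continuation), so $\mathrm{tr}(S)$ decreases *continuously* to 2.

Targets below the df at span 1 are therefore found by bisection on the
continuous branch (to within 0.01 df); larger targets snap to the nearest
achievable neighbour count and are flagged (`exact = FALSE`) when the gap
exceeds the tolerance. Nested F tests always use the *achieved* trace, so
the inference stays internally consistent whichever branch produced the
fit.

## Parsimony selection along the df ladder

Model complexity per group is chosen by a forward walk along the ladder
df = 1, 2, 2.2, 2.4, ..., 5 (`dfLadder()`). Each candidate is compared to
its immediate predecessor with the approximate F statistic for linear
smoothers,

$$F = \frac{(\mathrm{RSS}_{small} - \mathrm{RSS}_{big}) /
            (\mathrm{df}_{big} - \mathrm{df}_{small})}
           {\mathrm{RSS}_{big} / (n - \mathrm{df}_{big})},$$

and the walk stops at the first step that fails to reject at
$\alpha = 0.05$; the chosen fit is the last significant improvement. For
the 1-versus-2 step this is exactly the classical regression slope test,
which is why its simulated type-I error sits at the nominal 5% (one of the
package's acceptance checks). Negative numerators — possible with
smoothers — are clamped to $F = 0$, $p = 1$, the conservative
non-rejection.

Two design points were genuinely open and are worth recording:

* **Step comparisons are against the immediate predecessor**, not against
  all smaller candidates. This is the literal forward-stepwise reading of
  "keep the least df that still beats simpler fits". A consequence worth
  knowing: a signal that is orthogonal to a straight line over the age
  window (for example a peak exactly mid-window with no net trend) can
  stall the walk at df 1, because the constant-versus-line gate never
  fires. Over the age range used here this matters little — developmental
  thickness trajectories peak early and decline, so they carry a clear
  linear component — but it is a structural property of the procedure, not
  a bug.
* **The ladder tops out at df 5** by default. Cortical age trajectories in
  this age range are at most cubic-like; the ceiling is configurable.

## Comparing trajectories between groups

At each vertex the test of "do the groups share one developmental curve?"
fits three models, each with its own parsimony selection: the pooled
sample (one curve — the null), and each group separately (two curves — the
alternative). The statistic is

$$F = \frac{(\mathrm{RSS}_{pooled} - \mathrm{RSS}_{g1} - \mathrm{RSS}_{g2}) / \Delta df}
           {(\mathrm{RSS}_{g1} + \mathrm{RSS}_{g2}) / (n - df_{g1} - df_{g2})},
  \qquad \Delta df = df_{g1} + df_{g2} - df_{pooled},$$

with a companion signed statistic
$\mathrm{sign}(\overline{\hat f_{g2} - \hat f_{g1}}) \sqrt F$ (mean fitted
difference over a 50-point age grid; case minus control under the default
factor coding), giving a t-like map whose sign says which group is
thicker. If the pooled selection is at least as complex as the two group
fits combined ($\Delta df \le 0$), the vertex is reported as degenerate
with $p = 1$ — again the conservative choice.

Vertex p-values are corrected with the Benjamini-Hochberg step-up rule
across all vertices of both hemispheres jointly (the conservative reading;
per-hemisphere control is available by subsetting), and the per-hemisphere
*critical statistic* — the smallest absolute signed statistic among
rejected vertices — is reported alongside, mirroring how surface analyses
conventionally summarise their threshold.

Calibration facts, established by simulation in the test suite and worth
stating plainly:

* under a **constant-mean null** the test is approximately calibrated but
  measurably *liberal* (empirical size ~0.08 at nominal 0.05 with 30 per
  group): selecting each group's df adaptively before testing occasionally
  overfits one group;
* under the **curved null** that the generator actually produces (both
  groups share one peaked trajectory), the same machinery is
  *conservative* (empirical size ~0.03), because parsimony selection
  underfits the shared curve and inflates the error estimate;
* consequently the vertexwise pipeline's realized false discovery
  proportion under the global-null cohort stays below the nominal level —
  the property that matters for the map-level inference, and one of the
  package's acceptance checks.

Covariates (sex, handedness, scan slice thickness) are residualized out of
the thickness maps before trajectory fitting by default (`residualize =
TRUE`); the trajectory machinery itself is age-only, matching how
smoothing-based developmental fits are usually run, and the flag exists
because the choice is genuinely debatable.

## The volumetric models

Global measures are analysed by ordinary least squares with treatment
coding (reference: control, male, right-handed, thick-slice scan):
`outcome ~ group + age + sex + hand + slice_dummy`, optionally with
`group:age`, and — for the dimensional analyses — `iq + iq:group` after
excluding upper-tail IQ outliers by the one-sided 1.5 IQR rule (the
sparsely populated very-high-IQ region; the rule is one-sided on purpose,
the lower tail is already bounded by the inclusion floor of 70).
Per-term p-values are Type II F tests; adjusted group means evaluate the
fit at the sample's covariate means. Ventricle volumes, being
right-skewed, are modelled on the natural log scale, with adjusted means
reported on both scales; the back-transformed adjusted mean approximates
the distribution's median, not its mean, which the tests check against
the generator's moment-matched log-normal.

The median split assigns the subject sitting exactly at the whole-sample
median to the *below*-median group (so subgroup IQ ranges look like
75–102 / 103–138 around a median of 102). Derived quantities — percent
volumetric reduction $100 (\bar x_{ctrl} - \bar x_{case})/\bar x_{ctrl}$,
the cortical gray-matter proxy thickness x area (mm x cm² = 0.1 ml), and
the age-corrected medication duration (months used divided by months since
age 60 months) — are plain arithmetic with validated domains.

## What the synthetic generator emulates — and what it does not

`simulateCohort()` draws four cells (diagnosis x IQ subgroup) of equal
size. Ages are uniform on 6–15 years with one law for all cells; IQ comes
from per-cell truncated normals that respect both the inclusion floor (70)
and the median-split boundary (below: at most 102; above: at least 103).
Volumetric measures are drawn around per-cell target means/SDs; the three
measures with a targeted IQ correlation (control gray matter r = .31,
control FA r = .38, case mean thickness r = −.25) are instead generated
from the group-level target around a regression on standardized IQ, which
makes both the correlation and the implied subgroup means emerge jointly
(the published cell means are numerically consistent with exactly this
structure). Ventricles are moment-matched log-normals.

Thickness maps are the cell-specific trajectory evaluated at the subject's
age plus spatially smoothed Gaussian noise. The trajectory is

$$f(a) = b + A\exp\!\left(-\frac{(a - p)^2}{2w^2}\right)
           - s\,\max(0, a - p),$$

a single interior peak with a linear post-peak decline. Defaults:
baseline $b = 3.375$ mm, amplitude $A = 0.15$ mm, peak age $p = 8.5$ y,
width $w = 2$ y, decline $s = 0.045$ mm/y (about 1.3%/year, mid-range for
adolescent cortical thinning), vertex noise SD 0.05 mm. These were chosen
once, on two grounds: (i) the grand mean over the age range is ~3.34 mm
and the *between-subject* SD of mean thickness — trajectory spread plus
noise — comes out near 0.10 mm, the scale a cross-sectional cohort table
reports; and (ii) the curve peaks early and declines visibly within the
analysis window, as typical development does, so the parsimony walk can
see it. The two case-specific distortions are a peak delay
(`peakShift`, applied only at `affectedVertices`, for cases below median
IQ) and a uniform intercept drop (`interceptOffset`, for cases above
median IQ) — delayed maturation versus stable global thinning.

The noise field is white Gaussian noise smoothed on the mesh with a
graph-geodesic Gaussian kernel and rescaled to keep the marginal per-vertex
SD at `noiseSd`; smoothing therefore buys spatial correlation, not
variance reduction. The kernel's FWHM is expressed in mesh distance units
(a physical "20 mm" has no meaning on a toy sphere); the default — twice
the mean edge length — makes the smoothing span a couple of graph edges,
preserving the *role* of surface smoothing (spatially correlated noise,
neighbour correlation rising with FWHM) rather than its physical scale.

The toy surface itself is a pair of closed sphere-like triangulations
(two poles plus stacked rings; exactly the icosahedron at 12 vertices per
hemisphere), which keeps Euler's formula, near-6 mean degree, and
hemisphere separation true by construction while staying small enough to
analyse in milliseconds.

**What the generator deliberately does not model:** subject-level global
thickness offsets (noise is independent across subjects and vertices after
smoothing), spatial heterogeneity of the trajectory outside the affected
cluster, registration/segmentation error, scanner or site effects,
correlation between the volumetric table and the thickness maps beyond
their shared phenotypes, and realistic cortical geometry. Passing the
package's tests therefore demonstrates that the *procedures* are correct
and calibrated under the stated generative model — it does not certify
performance on real surfaces, where residual SDs are larger, noise is
non-Gaussian, and trajectories vary regionally.

## Numerical choices and degenerate inputs

* Seeds: one master seed fans out to fixed per-stage offsets (mesh,
  cohort, volumetrics, thickness), so any stage can be re-run
  independently and the whole pipeline is bit-reproducible.
* Ties in age are handled by the bandwidth definition (distance to the
  k-th neighbour); if a neighbourhood is entirely tied, the row falls
  back to a locally-weighted mean.
* A local design with zero weighted age variance falls back to the
  weighted mean rather than an unstable slope.
* `spanForDf` bisection stops early once within 0.003 df of the target;
  results are deterministic for fixed inputs.
* Degenerate designs error loudly and specifically: all-equal ages for
  df >= 2 fits, constant IQ in dimensional models, empty IQ subgroups in
  the median split, aliased GLM terms. Constant *nuisance* covariates in
  a GLM subsample are dropped silently (they carry no information);
  a degenerate group or IQ term is an error, never a drop.
* Perfect GLM fits (zero residual variance) report NA p-values instead of
  dividing by zero.
* The FDR step never sees NA: degenerate trajectory tests contribute
  p = 1, which can only make the procedure more conservative.

## Problem sizes used for validation

The test-suite and acceptance-script simulations use the cohort scale the
analyses are designed for: 40–90 subjects per fit, 45 per group for the
vertexwise calibration (500 vertices, 500 replicates for the FDR check;
5000 replicates for the ladder-step size check; 100 seeds for the
cluster-recovery check at 300 vertices). These sizes give Monte-Carlo
standard errors comfortably below the tolerances being asserted while
keeping the full validation run in the tens of minutes on one CPU.

## Known limitations

* The adaptive-selection size distortion described above (liberal under a
  constant truth, conservative under a curved truth) is inherent to
  test-after-selection; the package reports it honestly rather than
  correcting it, as the selection *is* the procedure under study.
* The signed statistic's sign comes from the mean fitted difference over
  the age grid; trajectories that cross can yield a small mean difference
  with a large F — read the sign as "which group is thicker on average
  over the window", not as a complete description of the difference.
* `estimatePeakAge()` returns the grid argmax of the chosen fit; for fits
  selected as constant or monotone the "peak" sits at a window boundary
  and should be interpreted accordingly.
* Fractional df above the span-1 trace are only approximately achievable
  (discrete neighbour counts); the achieved df is always reported and
  used.
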