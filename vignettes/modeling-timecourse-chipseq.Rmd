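---
title: "Modeling time-course ChIP-seq coverage with sigmoids"
author: "chipTurnover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling time-course ChIP-seq coverage with sigmoids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipTurnover)
```

# The model

Time-resolved ChIP-seq (and related assays such as ChEC-seq or XR-seq)
measures sequencing coverage at a set of genomic loci across an ordered
series of time points. Occupancy at a locus is bounded — binding
saturates at some maximal level and bottoms out at vacancy or a basal
level — and induction systems typically show a lag before signal
accumulates. Coverage trajectories at a locus are therefore modeled with
the four/five-parameter log-logistic sigmoid

$$ y = d + \frac{a - d}{\left(1 + e^{b\,(x - c)}\right)^{f}} $$

with time $x$, coverage $y$, plateaus $a$ and $d$, steepness $b$
(the *incorporation rate index*, IRI), location $c$, and asymmetry
factor $f > 0$. Two derived quantities summarize a locus:

* the **inflection point**, the root of the second derivative,
  $x = c - \ln(f)/b$ (exactly $c$ when $f = 1$);
* the **turnover time index (TTI)**, the time at which the curve crosses
  the plateau midpoint $(a + d)/2$, with closed form
  $\mathrm{TTI} = c + \ln(2^{1/f} - 1)/b$ (again exactly $c$ when
  $f = 1$). The TTI is interpretable as the binding half-life at the
  locus.

Both closed forms are verified in the test suite against independent
numeric oracles (bisection on the model evaluation, and a root of a
finite-difference second derivative).

## Sign convention and the $f = 1$ symmetry

When $f = 1$ the model is invariant under swapping $a \leftrightarrow d$
while negating $b$: both parameterizations describe the identical curve.
The sign of $b$ is therefore only identified up to this swap. The
package canonicalizes every fit so that *increasing* curves (rises)
carry $b < 0$ and decreasing curves (falls) $b > 0$; the reported
lower/upper asymptotes are then $\min(a,d)$ / $\max(a,d)$. Without this
canonicalization the two-fold verification step (below) would sometimes
eliminate loci because of an arbitrary parameterization choice rather
than the data.

# Fitting

By default the asymmetry factor is fixed at $f = 1$ (the 4P model);
freeing it (5P) is opt-in because an asymmetric response needs a clear
biological rationale (for example a feedback-modulated induction).
Least-squares fits use bounded Levenberg–Marquardt
(`minpack.lm::nlsLM`), with an L-BFGS-B refinement as fallback. A
Poisson objective (maximizing $\sum_t y_t \ln \hat y_t - \hat y_t$ with
$\hat y$ floored at $10^{-9}$) is available for raw counts, limiting the
leverage of large-count observations; it deliberately rejects
continuous normalized input, directing users to least squares.

Numerical choices:

* **Bounds.** Both plateaus are constrained to $[0, 3\max(y)]$ —
  coverage cannot be negative; $c \in [t_\mathrm{first} - \Delta,
  t_\mathrm{last} + \Delta]$ with $\Delta$ the sampled span;
  $|b| \le 10^3$; $f \in [0.1, 10]$ when free.
* **Starting values.** Plateaus from the first/last observations; $c$
  from the first crossing of the series' midrange beyond the relevant
  extremum; $|b|$ from the steepest observed finite-difference slope
  through the logistic identity (slope at inflection $= |b| \cdot
  \mathrm{range}/4$). This seed is scale-invariant in $y$; seeding the
  slope proportionally to the coverage range itself traps the optimizer
  in step-like local optima for high-coverage loci.
* **Two-direction starts.** The optimizer is started from both an
  increasing and a decreasing configuration and the better optimum is
  kept, so the verified direction reflects the data rather than the
  starting guess. One perturbed restart is attempted on
  non-convergence; persistent failure is reported as
  `converged = FALSE`, never as an error.
* **Standard errors.** From the Gauss–Newton curvature of the objective
  at the optimum (observed information for the Poisson objective).
* **Degenerate inputs.** Constant series cannot constrain a sigmoid and
  raise a flat-data error at the fitting level; at the pipeline level
  such loci are categorized `flat` and receive the linear fit only.

An ordinary least-squares line is always fit alongside the sigmoid;
its residuals are directly comparable and flag loci whose temporal
behavior is not sigmoidal at all.

# Category prediction and verification

Each locus is predicted into one of six behaviors — *rise*, *fall*,
*hill* (rise then fall), *valley* (fall then rise), *undefined
rise/fall*, or (after verification) *eliminated* — from the order in
time of its absolute minimum and maximum coverage. Ties take the
earliest time point, which favors the simpler single-sigmoid path.

Two thresholds steer the promotion from single to double sigmoid:

* `plateauRangeFraction` (default **0.1**): a point beyond an extremum
  whose deviation from the extremum value exceeds this fraction of the
  locus's overall coverage range is *genuine* (changing meaningfully
  over time) rather than plateau fluctuation. The default is a
  range-relative reading: 10% of the locus range tolerates typical
  background jitter without hiding real declines. The CLI exposes it in
  percent (`-L 5` → 0.05).
* `leadingTrailingMin` (default **1**): the number of genuine points
  beyond the extremum that must be *exceeded* to call a hill or valley,
  so by default at least two genuine trailing points are required.
  Setting 0 lets a single genuine trailing point trigger a hill, which
  is necessary when hills peak as early as the second time point. Both
  sides are checked symmetrically (trailing points after the second
  extremum, or leading points before the first), and either side
  suffices.

Raising either threshold can only shrink the set of hill/valley calls —
a monotonicity the test suite asserts on a fixed noisy simulation.

Loci whose extrema are adjacent in time with no plateau evidence at
either end are demoted to *undefined* and modeled by a single sigmoid in
the direction of their extrema order.

Hills are then fit as two sigmoids — an increasing one up to and
including the absolute maximum, a decreasing one from the maximum
onward (the extremum sample is shared by both segments; valleys are
symmetric about the minimum) — yielding separate `TTI_rise` and
`TTI_fall`. Segments shorter than the 4P model allows are fit with
reduced parameter sets: three points pin the early plateau at the
segment's first value; two points pin both plateaus and fit only $b$
and $c$. This keeps early-peaking hills modelable instead of silently
demoting them; the price is that such segments carry no standard
errors.

Finally, **verification**: the final category equals the prediction
only if every fitted segment's direction matches what the prediction
demands and the fit converged; otherwise the locus is *eliminated*.
This two-fold check removes false positives — e.g. a locus whose
extrema order suggests a rise but whose best-fitting sigmoid falls.
Eliminated loci are retained in the output with a flag, so no locus is
ever silently lost.

# Normalization

Raw coverage (mean per-base read depth over the locus, CIGAR-aware,
excluding secondary/supplementary/unmapped records, strand-blind) is
made comparable across time points by dividing each time point by the
maximum coverage over a set of sampled non-peak *background* intervals
— true background sequencing levels, uninfluenced by the biology at the
peaks. The scale is per time point, because its purpose is correcting
sequencing-depth differences between libraries. By default 10,000
background intervals of the median peak length are sampled uniformly
from the genome complement of the peaks under a recorded seed. A
per-base **mean** (not sum) is used so loci of different lengths are
comparable; the length-independence of downstream accuracy is asserted
in the tests.

Optional input controls are scaled by their own maximum over background
plus peak regions (input has no expected peaks; an exhaustive
genome-wide scan would add cost without changing the maximum
materially) and subtracted from the experiment, floored at zero. The
floor can zero-inflate poor-quality data; no remedy is applied —
instead, a pre-normalized counts table (e.g. from DiffBind/DESeq2/edgeR)
can be supplied, which bypasses the whole chain. User-defined per-time
scale values (spike-in workflows) are also accepted. Replicates are
combined by the elementwise mean after normalization.

# The synthetic benchmark

The built-in generator emulates a rise/fall benchmark on a toy
three-chromosome genome, sampled at 11 time points (0–10, relative
units):

| group | inflection | IRI | varied dimension |
|-------|-----------|-----|------------------|
| 2L.1  | 5         | −0.5, −0.75, −1.0, −1.5, −2.0, −3.0 | steepness |
| 2L.2  | 1 … 9     | −3  | inflection time |
| 2R    | 4.5       | −1.5 | peak length (250–4000 bp) |
| 3R    | 5.5       | −1.5 | upper asymptote (2–50) |

Falls mirror rises with IRIs of the corresponding absolute value. Where
a group does not vary a dimension, peak length defaults to 500 bp and
the upper asymptote to 10 coverage units — round values inside the
varied grids; the lower plateau is 0, matching the non-negativity
constraint. Noise is additive Poisson background with mean 1 per cell,
approximating 1X random background coverage; a parametric noise model
keeps the generator fully reproducible without read-level simulation.
What this does *not* emulate: biological variability between loci,
mappability and GC structure, or read-level error profiles — so passing
benchmarks demonstrate modeling accuracy under random background noise,
not robustness to every artifact of real data. Fixture BAMs, when
emitted, stack `round(coverage)` whole-locus reads, reproducing the
target depth to within 0.5; locus length consequently has no effect on
the matrix pathway at all, which is why the "no length trend" check is
structural rather than statistical.

The default scale is 20 loci per grid level (1,000 loci for the
combined rise+fall design) — small enough for routine re-runs while
leaving every grid level populated; the full 1,000-per-chromosome scale
is available by raising `nPerLevel`.

Recovery is scored as the percent deviation
$100\,|\mathrm{TTI}_{\mathrm{fit}} - c_{\mathrm{true}}|/c_{\mathrm{true}}$.
On the default noisy benchmark the median deviation sits around 3%,
and the characteristic failure modes are reproduced: accuracy degrades
when the true inflection lies outside the sampled window, improves with
the upper asymptote (signal-to-noise), and is untouched by peak length.

# Reduced-time-point designs

Sparser designs are expressed purely by subsetting `timePoints`
(staggered `{0,2,4,6,8,10}`, the first six `{0..5}`, or first-and-last
`{0,6,7,8,9,10}`). The first-six design is the built-in demonstration
of window blindness: loci with inflection 9 fitted on times 0–5 show
median deviations an order of magnitude above loci with inflection 3.

# Known limitations

* Oscillating (multi-hill) and step-like (rise–plateau–rise) behaviors
  are out of scope; such loci will be forced into the nearest supported
  shape or eliminated.
* The Poisson objective requires integer-like inputs; there is no
  negative-binomial objective, so overdispersed counts are better
  normalized upstream and fit by least squares.
* Two-point hill segments are underdetermined by construction; their
  parameters are anchored to the observed end values and should be read
  as descriptive, not inferential (no standard errors).
* Background-maximum scaling assumes the sampled background intervals
  capture true non-signal coverage; for genomes saturated with signal,
  user-defined scale values are the safer route.
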