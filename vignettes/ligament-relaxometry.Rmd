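---
title: "Methods: quantitative T1rho/T2 relaxometry of the cruciate ligaments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative T1rho/T2 relaxometry of the cruciate ligaments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligrelax)
```

## The measurement model

Magnitude MR signal prepared with a spin-lock pulse of duration $t_{SL}$
(T1$\rho$ mapping) or read out at echo time $t_E$ (T2 mapping) decays
mono-exponentially in well-behaved tissue:

$$ S(t) = S_0 \, e^{-t/T}, $$

with $T$ the relaxation time in ms. Per voxel we observe $S$ at the
schedule times (defaults: TSL 1/10/20/35 ms, TE 6.5/13.4/27.0/40.7 ms) and
estimate $(S_0, T)$ by non-linear least squares. Two gates remove voxels a
reader should not trust:

1. **Noise floor.** If any sample lies below the estimated noise floor the
   voxel is excluded (`below_noise_floor`) before fitting — at low signal
   the magnitude operation rectifies noise and biases the decay tail.
2. **Fit quality.** $R^2 = 1 - SS_{res}/SS_{tot}$ (with $SS_{tot}$ about
   the sample mean, the conventional reading for a non-linear fit) below
   0.8 excludes the voxel (`poor_fit`).

The floor is estimated as mean + 2 SD of background (air) intensities
pooled over all contrasts. For a Rayleigh background with channel SD
$\sigma$ this converges to $(\sqrt{\pi/2} + 2\sqrt{2-\pi/2})\,\sigma
\approx 2.56\sigma$. A percentile fallback (of the first contrast volume)
exists for datasets without an air mask.

### Fitting: initialisation, bounds, convergence

The fit is seeded by log-linear regression of $\log S$ on $t$ (exact on
noiseless decays; a non-negative slope is flagged as non-decaying) and
refined by a Levenberg–Marquardt iteration on $(S_0, T)$, vectorised over
all voxels of a map so a full cohort fits in seconds. Numerical choices:

* $T$ bounded to [1, 2000] ms. A fit pinned at a bound is reported
  `not_converged` rather than silently clipped; quality rejection
  ($R^2 < 0.8$) is assessed first, so an implausible chance fit to noise is
  labelled by the reason a reader cares about.
* Convergence: relative SSE change below $10^{-8}$, at most 200
  iterations; a voxel whose damping has grown past $10^9$ without an
  acceptable step has stalled and is treated as converged at its current
  optimum.
* Degenerate inputs: constant signal has $SS_{tot} = 0$ and is assigned
  $R^2 = 0$ (rejected); non-positive samples are clamped only inside the
  log-linear seed, never in the objective.

Property tests verify the fitter attains the global optimum of a dense
variable-projection grid search (for fixed $T$ the optimal $S_0$ is closed
form, so a fine $T$ grid bounds the attainable SSE independently).

### Attainable precision

Precision at the study's signal-to-noise ratio is bounded by the
information in four samples. With the default TSL schedule, $S_0 = 100$
and channel noise $\sigma = 2$ (SNR 50), the Cramér–Rao bound for
$\mathrm{sd}(\hat T)$ grows from roughly 1.4 ms at $T = 30$ ms to 3 ms at
$T = 50$ ms, because the schedule's longest time (35 ms) samples barely one
time constant of slow decays. Voxel-level estimates therefore carry a
median absolute error between about 1 and 2 ms across that range — an
acquisition-design limit, not a fitting deficiency — while *regional means*
over a few hundred voxels are accurate to a few tenths of a ms (the small
positive bias of magnitude-noise NLLS included). The test suite asserts
exactly this decomposition.

## Geometry

**Registration.** Contrast volumes can be rigidly aligned (6 DOF:
translations in mm, rotations in degrees about the volume centre) to the
first contrast by minimising the mean squared intensity difference with a
two-level multiresolution Nelder–Mead search and trilinear resampling.
Same-modality contrasts justify the MSD metric. Out-of-volume samples are
zero-filled and the metric denominator is the fixed voxel count: letting
the valid-sample set vary with the transform puts a spurious minimum at
the identity. The phantom is simulated pre-aligned, so registration is off
by default and tested as a contract (identity recovery, apply-then-recover
round trips within half a voxel).

**Thirds partition.** Each ligament mask is split along the craniocaudal
axis of the image: the continuous interval from the first in-mask slice to
one past the last is divided into three equal half-open sub-intervals, and
each in-mask voxel is assigned by its slice centre ($i + 0.5$). This makes
the split deterministic for any span: a 9-slice ligament splits 3/3/3, a
10-slice one 3/4/3, and region extents never differ by more than one
slice. The most caudal third is *distal* (tibial end) for both ligaments,
matching the anatomical convention; the axis is taken from configuration
or image metadata, never guessed from the data. An axis-based split is
used rather than a 3D centreline — it is the operational reading of
"maximal length in the craniocaudal direction" and is reproducible on
masks of any shape.

**Summaries.** Per region and for the whole mask: mean, SD and median over
quality-passing voxels only. The SD uses the population ($n$) denominator
by default (configurable); a region with fewer than 5 included voxels is
flagged missing rather than summarised.

## The phantom

The synthetic module generates what the analysis assumes, with knobs where
the science has free parameters:

* **Masks**: tubes of radius 2.5 voxels around 3-point spline centrelines,
  oblique to the craniocaudal axis, disjoint for ACL and PCL, in a
  $64^3$ grid at 1 mm isotropic spacing. Only the topology (elongated,
  oblique) matters for partition testing; anatomical fidelity is a
  non-goal.
* **Subject truth**: per (group, ligament, parameter), the three region
  values are drawn from normals with the configured means/SDs (defaults
  reproduce the published subregional table for 15 OA and 6 control
  subjects), truncated below at 1 ms. Draws are independent across
  regions.
* **Signal**: $S_0 = 100$ inside the masks (no proton-density structure),
  Rician magnitude noise everywhere with channel SD 2 (SNR 50), the
  standard model for magnitude MRI; the background is thus Rayleigh, which
  is what the noise-floor estimator assumes. At this SNR exclusion rates at
  truth are near zero, so QC tests can inject pathologies deliberately.
* **Raters**: the second reader and the second timepoint are simulated by
  randomly flipping boundary voxels of the first reader's mask until a
  Dice target is met (defaults 0.85 inter-rater, 0.92 intra-rater). Only
  Dice-decreasing flips are candidates, so overlap is monotone in the flip
  count and the calibration terminates deterministically.

Every stochastic step is a pure function of (inputs, seed); sub-seeds are
derived by hashing the base seed with subject/ligament/parameter indices,
so cohorts are bit-reproducible and any subject can be regenerated alone.

**What the phantom does not emulate** — and hence what passing tests do
*not* establish about real data: within-subject correlation of region
values (real subjects who are high distally tend to be high proximally;
independent draws make the repeated-measures tests conservative in power),
partial-volume and boundary-tissue effects, $B_1$/$B_0$ field
inhomogeneity, magic-angle elevation in obliquely oriented fibres, motion,
and any spatial texture inside regions (truth maps are piecewise
constant). The reliability analysis sees rater variation only through mask
geometry, not through reader-specific intensity interpretation.

A consequence worth knowing: an occasional low draw (e.g. a distal T2 of
~6 ms) legitimately pushes the longest echo below the noise floor and
excludes that subject's region wholesale. The cohort analyses drop such
subjects from the affected cell with a console notice and report the cell's
actual $n$; the low-level `rm_anova` contract still rejects incomplete
matrices.

## Statistics

* **Routing.** Per cell, Shapiro–Wilk on each condition at $\alpha=0.05$;
  any violation routes to the Friedman test. Otherwise Mauchly's test on
  the orthonormal-contrast covariance; violation applies the
  Greenhouse–Geisser correction $\hat\varepsilon \in [1/(k-1), 1]$ to the
  F-test degrees of freedom. Effect sizes: partial $\eta^2$ on ANOVA
  routes, Kendall's $W = \chi^2_r / (n(k-1))$ on the Friedman route. A
  matrix with zero within-subject variance (identical conditions per
  subject) short-circuits to $F = 0$, $p = 1$.
* **Exact small-sample tests.** The Friedman null for $n \le 8$ tie-free
  subjects is computed by dynamic-programming convolution over the $k!$
  per-subject rank permutations — identical to enumerating all $(k!)^n$
  configurations, feasible at the study's control-group size ($n = 6$).
  The Wilcoxon signed-rank null for $n \le 20$ is the subset-sum
  distribution over all $2^n$ sign patterns (two-sided: doubled smaller
  tail, capped at 1); zero differences are dropped before ranking. Both
  are cross-checked against the base-R implementations where those apply.
* **Percentage differences** are $100(\text{distal} - \text{other}) /
  \text{other}$. The formula is not written anywhere authoritative; since
  only ranks enter the between-group test, any strictly monotone variant
  gives the same H for fixed pairings — this one is chosen for
  interpretability, and it is deliberately not antisymmetric.
* **Kruskal–Wallis** uses pooled mid-ranks, the tie-correction factor
  $1 - \sum(t^3-t)/(N^3-N)$ only when ties exist, and reports per-group
  mean ranks (they satisfy $\sum n_i \bar R_i = N(N+1)/2$). A helper
  reconstructs the unique integer rank sums — and hence H — from mean
  ranks printed to one decimal, which is how published two-group rows are
  verified.
* **ICC.** Single-measures absolute agreement from the two-way mean
  squares, $(MS_R - MS_E)/(MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E))$;
  the random- vs mixed-effects distinction (inter vs intra-rater design)
  shares the point estimate and is kept as metadata. Confidence intervals
  use the McGraw–Wong F-based method, computed in a form that stays finite
  as the estimate approaches 1. Bands: below 0.4 poor, 0.4–0.75 (closed)
  fair-to-good, above 0.75 excellent.
* **No multiplicity correction** anywhere, matching the exploratory
  design; $\alpha = 0.05$ throughout.

## Pipeline and problem sizes

`run_all` orchestrates simulate → (register) → fit → regions → stats,
with per-subject failures isolated and tabulated rather than aborting the
cohort, byte-identical outputs on re-runs, and a run manifest recording
the package version, seed and a configuration hash. The statistics
interchange format is a long CSV (subject, group, ligament, parameter,
region, rater, timepoint, value_ms), the volumes NIfTI-1, configs YAML,
manifests JSON.

The test suite exercises the full default cohort — 21 subjects at $64^3$,
both parameters, three mask readings each — which completes in about a
minute on one CPU; unit and property tests use $24^3$–$32^3$ grids, 300–
2000 Monte-Carlo replicates, and 7-subject cohorts, sizes chosen so each
statistical assertion has comfortable margin over its Monte-Carlo error.

## Known limitations

* Mono-exponential decay only; no multi-component or magic-angle
  modelling.
* Rigid registration with an MSD metric assumes same-modality contrasts
  and pre-oriented volumes; mutual information is not implemented.
* The exact Friedman path requires tie-free rows (mid-ranks fall back to
  the asymptotic $\chi^2$), and exactness stops at $n = 8$ / $n = 20$
  (Wilcoxon) where the DP lattices grow.
* The phantom's independent region draws understate the within-subject
  concordance of real ligaments, so observed repeated-measures power on
  synthetic cohorts is a lower bound for comparable real effects.
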