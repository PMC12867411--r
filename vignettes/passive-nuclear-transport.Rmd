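---
title: "Quantifying passive nuclear transport from two-channel time lapses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying passive nuclear transport from two-channel time lapses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucflux)
```

## The measurement problem

Permeabilized-cell uptake assays measure how fast fluorescent cargo of a
given molecular weight (MW) passes through nuclear pore complexes. The
plasma membrane is perforated (digitonin or streptolysin O), a
cell-impermeant DNA stain marks the nuclei of successfully permeabilized
cells at time zero, cargo is added, and the cargo channel is imaged over
tens of seconds to minutes. Per nucleus, three model-free metrics
summarize the uptake curve:

* **T1/2** — the time at which the fitted nuclear intensity first
  reaches half of its total (plateau) uptake;
* **normalized Y1/2** — the nuclear intensity at T1/2 divided by the
  peri-nuclear intensity at the same time, a per-cell normalization that
  cancels how strongly that particular cell was permeabilized;
* **maximum uptake rate** — the maximum of the analytic derivative of
  the polynomial fitted to the nuclear trace.

Cross-MW ratios of per-line medians, `metric_MWhigh / metric_MWlow`,
remove any cell-line-specific multiplicative factor (pore count, nuclear
geometry, organelle content): if the per-pore contribution is `UD_MW`
and the line carries `N` pores, `(UD_high · N)/(UD_low · N)` depends on
the cargo pair only. Entries whose direction contradicts size-dependent
(Fickian) diffusion — or that sit inside a small equality band — are
flagged non-Fickian.

## The generative model

The synthetic-data module exists so that every stage can be verified
against known truth. A field is a set of elliptical nuclei on a jittered
grid (sub-confluent epithelium); each nucleus is permeabilized with
probability `permeabilized_fraction`, and permeabilized nuclei are
stained bright (probability `well_defined_fraction`) or dim. Cargo
influx follows a first-order exchange across the nuclear envelope,

$$\frac{dF_n}{dt} = k\,\left(F_{peri} - \frac{F_n}{P}\right),
\qquad k = UD_{MW}\cdot N,$$

with the peri-nuclear bath stepping instantaneously to the bath level at
cargo addition (permeabilized cells are cytosol-free, so small dextrans
equilibrate within seconds; an exponential approach is available but
non-default). The closed-form nuclear trace is
$F_n(t) = P\,B\,(1 - e^{-(k/P)t})$: the half-time is
$\ln 2 \cdot P / k$ and the long-time nuclear:peri ratio is the
partition coefficient $P \ge 1$ (the "molecular sink" behaviour of
nuclei; default 2). Unit diffusion follows Stokes-like scaling
`UD = ud_scale / r_h`, with the hydrodynamic radius growing as
`MW^0.5` for random-coil dextrans and `MW^(1/3)` for globular cargo, so
the default truth is strictly Fickian; per-cargo overrides inject
non-Fickian behaviour for classifier validation.

Detector physics: all cargo signal decays as `exp(-bleach_rate · t)`;
pixel values receive scaled-Poisson shot noise (variance
`shot_scale · mean`, default 4) plus Gaussian read noise (default sd 25
counts), then are clipped and quantized to the bit depth (default
16-bit, so a saturated pixel is 65,535 and traces are rescaled by that
maximum). `bleach_rate` defaults to 0: acquisition filters in this kind
of assay are chosen precisely so that bleaching is negligible, and a
nonzero default would bias the plateau-referenced T1/2 by construction.
Bleaching is still simulated and tested — the peri normalization cancels
it, since both channels decay by the same factor.

What the generator does **not** emulate: optical point-spread blur in
the cargo channel, cell motility or focus drift, z-structure, nuclear
shape irregularity beyond ellipses, active (receptor-mediated)
transport, and spatial heterogeneity of the bath. Passing tests
therefore demonstrate correctness of the measurement chain under the
stated model, not robustness to every real-microscope artifact.

## Segmentation choices

The nuclear-stain frame is background-subtracted (rolling-ball via
grayscale opening, radius 50 px, replicate-padded at the borders) and
Gaussian-blurred (sigma 2 px). Otsu's threshold — an exhaustive
between-class-variance maximization over 256 bins — captures the bright,
well-defined nuclei; their footprint, dilated by twice the blur sigma so
that blurred halos cannot survive as ring-shaped false objects, is
blanked, and Otsu runs a second time on the remainder to capture the dim
population. No third pass is taken: it would capture background and
cytosol. Pass-2 objects must additionally clear a contrast floor
(object mean at least 8 background MADs above the residual background
median), so a field containing only bright nuclei yields an empty
second pass rather than noise blobs.

Objects are filtered on area (50–5000 px²) and circularity
`4πA/P² ≥ 0.6`, with the perimeter estimated by a two-direction Crofton
count `P = (π/4)(n_h + n_v)`; a digital disk of radius 10 scores ≈ 0.92.

The peri-nuclear ring of nucleus *i* is its mask dilated by 3 px ("just
beyond" the boundary) minus all nucleus pixels, with pixels contested by
two rings assigned to neither — splitting them would bias both cells'
normalizations. When a cell mask exists (simulations), the ring is
further confined to the parent cell, found as the cell label the nucleus
majority-overlaps; on real data without a cell channel the
dilation-minus-nuclei bound applies alone, which is logged as a known
deviation from the within-cell ideal.

QC follows the protocol rule: at least 60% of cells permeabilized and at
least 30% with distinct, well-defined staining; failing runs are refused
unless explicitly overridden.

## Kinetics choices

Traces are mean intensities over the nucleus mask (eroded by 1 px:
threshold masks land at the half-maximum contour of the blurred stain,
and edge pixels mix in cytosolic bath signal, which would bias T1/2 low
by more than 10% at typical radii) and over the ring, rescaled by
`2^bit_depth - 1`. Both are fitted with degree-5 least-squares
polynomials on a centred/scaled time axis (the degree is configurable;
five follows common practice for saturating uptake curves and is tested
to track a noiseless exponential to better than 1% of plateau over the
default 8-half-time span). Fitted values are clipped to the observed
range to suppress end oscillation; the derivative uses the analytic
polynomial coefficients on a 10×-oversampled grid restricted to the
observed span.

"Total uptake" is the fitted value at the final frame; a trace whose
derivative at the final frame still exceeds 10% of its maximum is
flagged censored, and a trace whose rise is below three residual
standard deviations is flagged no-uptake (flagged nuclei are excluded
from population medians). T1/2 is the first upward crossing of
half-plateau with linear interpolation between frames. Two genuinely
open conventions are settled as follows and exposed in configuration:
normalized Y1/2 evaluates nuclear and peri fits **at the same time**
T1/2 (the only time-consistent reading of a Y-level ratio), and the
maximum rate is computed on the un-normalized nuclear fit (the uptake
curve itself is plotted in raw rescaled counts).

Acquisition in the assay is cargo-specific (0.56 s framing over 45 s for
the free dye, 1.08 s over 130.26 s for dextrans, 6.43 s over 20 min for
the intercalating drug). For simulation studies spanning orders of
magnitude in rate, `adaptive_acquisition()` mirrors this by imaging each
condition over 8 true half-times in ~76 frames, so every condition is
resolved with the same relative sampling and fit bias cancels in
cross-condition ratios.

## Ratiometrics and classification

Population medians (not means — the per-nucleus distributions are
heavy-tailed) are computed per line × cargo × metric; ratios use all
ordered MW pairs and are reported as log10. The expected Fickian
directions are: half-time ratio positive (heavier = slower), max-rate
ratio negative, normalized-Y1/2 ratio negative under the assumption that
nuclear packing density falls with molecule size (explicit in the assay
design, but debatable — the expected sign is a configuration option).
The equality band defaults to ±0.02 log10 units: the star rule says
"equal or faster", and medians carry sampling noise, so exact zero
cannot be the only trigger. Fold changes against an untreated control
use means (the "average response") with standard errors propagated in
quadrature.

## Statistics

The factorial stage fits `value ~ tissue * pathology * mw` per nucleus
and reports Type II sums of squares (cell counts differ widely between
conditions in real data; Type II is invariant to that imbalance and
reduces to the classical decomposition on balanced designs, which the
tests verify against a direct mean-decomposition oracle at 1e-8).
T-tests are Welch by default; p-values are reported uncorrected and
flagged as such. Null calibration draws each replicate's seed from one
master stream — consecutive-integer seeding of the Mersenne twister
produced measurably correlated replicate streams in testing.

## GUV control

A protein-free vesicle only transports dye through its chemically
induced pores, so its half-time must increase strictly with cargo size
under Stokes scaling — this is the assay's resolving-power control. The
trace is the inside/outside mean-intensity ratio per 25 ms frame,
normalized to the trace's own maximum. The protocol sentence describing
the normalization admits a literal per-frame reading (each frame
normalized to itself), which flattens every trace to 1 and destroys the
kinetics; it is implemented as a non-default option and rejected as the
default. Traces whose raw ratio never reaches 0.1 are censored — the
no-entrance behaviour of unpermeabilized vesicles.

## Problem sizes and reproducibility

Simulation studies in the test-suite and acceptance script use fields of
12 nuclei at 160×160 px, ~200 nuclei per rate constant for half-time
recovery (rates 0.02–0.5 s⁻¹), 20 seeded factorial replicates for the
non-Fickian classifier, 1000 null replicates for type-I calibration, and
20 seeds × 3 MWs for the GUV control — sizes chosen so each study gives
stable medians and rates while the whole suite runs on a laptop-class
machine. Every stochastic step takes an explicit seed; grids derive
per-field seeds reproducibly from a master seed, and identical seeds
give bit-identical stacks.

## Known limitations

* The polynomial-fit T1/2 carries a small systematic bias (~3–4% at the
  default sampling) that cancels in ratios but not in absolute values.
* Ring normalization assumes the ring samples cytosol at bath level; in
  crowded fields contested-pixel removal can leave small rings, and
  nuclei whose ring is empty are skipped with a warning.
* The two-pass detector assumes exactly two stained populations; a
  third genuine population would be absorbed into the dim class or
  rejected by the contrast floor.
* Non-Fickian classification is directional, not inferential: no test
  statistic is attached to a star, by design.
* The generator's partition coefficient does not depend on MW, so
  synthetic normalized-Y1/2 ratios sit in the equality band and are
  starred by construction; T1/2 and max rate are the discriminating
  metrics for synthetic classifier studies (and the classifier's
  Fickian-null acceptance checks are defined over those two).
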