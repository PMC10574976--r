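---
title: "Assessing scoliosis brace pressure from back-surface thermography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing scoliosis brace pressure from back-surface thermography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermobrace)
```

## The physical and statistical model

A scoliosis brace treats the spinal curve by pressing on prescribed regions
of the back. Under near-adiabatic conditions, mechanical stress on tissue
produces a proportional local temperature change (the thermoelastic
effect), so a brace that has been exerting adequate pressure leaves a
slightly warmer region on the skin that remains detectable by an infrared
camera for a short time — of the order of a minute — after the brace is
removed. `thermobrace` operationalises this observation as a within-patient
two-sample comparison:

* **ROI #1** is the rectangle, drawn by the clinician on the *visual* (RGB)
  image, where the brace is prescribed to push. Selection happens on the
  RGB image rather than the thermal one to avoid confirmation bias.
* **ROI #2** is the reflection of ROI #1 about the backbone axis. Because
  back-surface temperature varies strongly between patients (and even
  across one back, with perfusion, metabolism and ambient conditions), an
  absolute temperature criterion would not transfer across patients; the
  contralateral mirror region provides a built-in control at the same
  height of the same back.
* Both rectangles are mapped onto the thermal grid, jointly normalised to
  grayscale, partitioned into $N \times M$ subregions, and summarised by
  the two vectors $v_1, v_2 \in [0,1]^{L}$, $L = N M$, of subregion means.
* A pooled-variance two-sample Student's t-test on $2L - 2$ degrees of
  freedom compares the vectors. The output is **adequate (1)** exactly when
  the two-sided p-value is strictly below the decision threshold *and*
  $\bar v_1 > \bar v_2$; otherwise **inadequate (0)**.

The t-test is two-sided with the direction handled by the explicit mean
condition, rather than one-sided, so that a *significantly colder* thrust
region — which would contradict the physical reading — is never rewarded:
it classifies as inadequate. The comparison is unpaired: although the
partition grids of the two ROIs correspond spatially, the vectors are
treated as two groups, which is the weaker assumption (a paired test would
additionally assume that subregion-level deviations are comparable across
the mirrored anatomy). An advisory $\chi^2$ goodness-of-fit check of each
vector against a fitted normal (equal-probability bins,
$k = \max(4, \lceil\sqrt{L}\rceil)$, $k - 3$ degrees of freedom) is logged
as a warning when it rejects; it never blocks the test, since at the
typical $L = 16$ its power is modest and the t-test is robust to mild
non-normality.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `nRows`, `nCols` | 4, 4 | — | partition counts; $L = 16$ balances spatial resolution against per-subregion averaging for thermal ROIs a few tens of pixels wide |
| `threshold` | 0.05 | — | decision threshold on the p-value; trainable by grid search |
| grid | 0.005–0.500, 1000 points | — | linearly spaced, endpoints included (step $\approx 4.955\times10^{-4}$) |
| `nSubsets`, `perClass` | 10, 10 | — | balanced-subset construction for the imbalanced 26/10 dataset |
| `coverageK` | 2 | — | coverage factor; expanded uncertainty at $\approx$ 95 % confidence |
| emissivity | 0.97 | — | human skin; carried as metadata only, the camera outputs calibrated temperatures |

Grayscale normalisation is **joint over the ROI pair**: per-ROI min–max
scaling would drive both vector means towards the same value and erase the
between-ROI difference the decision tests; joint scaling is the only
normalisation under which "ROI #1 is warmer than ROI #2" survives the
conversion. A side benefit, asserted by the test suite, is exact
invariance to any constant temperature offset applied to both ROIs — the
camera's per-acquisition bias (accuracy ±3 °C) therefore cannot change a
p-value. Degenerate zero-range pairs map to a constant 0.5, which yields
$t = 0$, $p = 1$ and an inadequate call.

Coordinates follow one convention everywhere: 0-based pixels, x = column,
y = row, origin top-left, rectangles half-open $[x_0, x_0+w) \times
[y_0, y_0+h)$. RGB-to-thermal mapping is pure anisotropic scaling (the two
streams come from one rigidly attached device): origin by floor, extent by
round-half-up with a minimum of one pixel, clipped to the thermal frame.
Floor and round-half-up (implemented as $\lfloor x + 0.5\rfloor$, never
banker's rounding) make the mapping bit-reproducible across platforms.
The backbone axis is modelled as a single vertical column; obliquely
running spines are out of scope.

## The evaluation machinery

With only 10 inadequate instances against 26 adequate ones, a single
cross-validation would be dominated by the majority class. Instead, ten
balanced subsets are built: each takes all 10 minority (label 0) instances
plus 10 majority instances sampled without replacement, subset $i$ seeded
with `seed + i − 1` so the draws differ across subsets but the whole
construction is reproducible. Each subset undergoes leave-one-out
cross-validation: for every held-out record, the threshold maximising
classification accuracy on the remaining 19 records is found on the grid
(ties broken towards the *smallest* value — deterministic and
conservative, declaring the fewest positives) and applied to the held-out
record. Per subset this yields an accuracy $A_i$ (a multiple of 5 % at
$k=20$ folds) and a type-A standard uncertainty
$u_i = s_i/\sqrt{n} = \sqrt{\hat p(1-\hat p)/(n-1)} \cdot 100\,\%$ from the
binary fold outcomes. The subset results combine into
$\bar A = \tfrac1n\sum A_i$ with first-order propagated uncertainty
$u_m = \sqrt{\sum u_i^2}/n$ and expanded uncertainty $U = k\,u_m$, $k = 2$.

All quantities are carried at full precision; rounding to one decimal is
presentation only. One behaviour of this scheme is worth knowing: if all
records of a subset are identical, the trained classifier is constant, and
under leave-one-out the held-out record is always the *minority* label of
the training fold — accuracy is then 0 %, not 50 %. This is the standard
LOOCV constant-classifier artifact, and the test suite pins it down.

## What the phantom emulates — and what it does not

The synthetic generator produces the thermal grid

$$T(x,y) = T_0 + g\,y + \Delta T\,
  e^{-\left((x-c_x)^2+(y-c_y)^2\right)/2\sigma^2} + b + \varepsilon(x,y),$$

quantised to 0.1 °C steps, with defaults $T_0 = 33$ °C, vertical gradient
$g = 0.002$ °C/px, hot-spot spread $\sigma = 6$ thermal pixels (so the
±2σ thrust ROI is 24 px wide, within the 10–30 px range typical of these
cameras), sensor noise $\varepsilon \sim \mathcal N(0, 0.1^2)$ °C matching
the camera's 100 mK thermal sensitivity, and a per-image bias
$b \sim \mathcal U(-3, 3)$ °C matching its stated accuracy. The three
camera specifications — sensitivity, accuracy, digitisation — map onto the
three standard error components: noise, bias, quantisation. The visual
companion is a flat skin-toned 1440 × 1080 image; its content is never
used quantitatively, it exists so the coordinate mapping (scale 1/9) is
exercised end to end. The hot-spot amplitude $\Delta T$ stands in for the
thermoelastic temperature rise; tissue constants and stress tensors are
not modelled, and no quantitative $\Delta T$ for adequate pressure is
established clinically — the study default of 1.0 °C is a free parameter
chosen to give the t-test power near 1 at the default noise level, and
every experiment states its $\Delta T$ explicitly. Labels follow class
membership (adequate-class records keep label 1 even in no-signal control
studies where $\Delta T = 0$ for both classes).

The phantom deliberately omits: anatomically realistic torso geometry and
curvature, irregular pressure-pad shapes (the decision consumes only
subregion means, so shape detail is secondary), time-resolved cooling
after brace removal, and sweat/metabolic confounders. Tests passing on
phantoms therefore demonstrate the correctness and calibration of the
*pipeline*, not clinical performance on real backs.

## Numerical choices and a calibration subtlety

* Null calibration: with threshold $th$, a no-signal phantom is called
  adequate when the two-sided p-value falls below $th$ *and* the thrust
  ROI happens to be the warmer one — under a symmetric null, a fraction
  $th/2$ of cases. This expectation presumes the t-test's iid null. The
  phantom's default vertical gradient is a deterministic trend *shared* by
  both ROIs (they sit at the same rows); it inflates both within-group
  variances without shifting the group difference, making the test
  conservative: at $th = 0.05$ the measured false-adequacy rate drops from
  $\approx 0.025$ (flat baseline) to $\approx 0.010$ (default gradient,
  n = 2000). The calibration experiment in the test suite therefore
  samples the flat-baseline null, where the $th/2$ law holds within
  Monte-Carlo error, and separately asserts one-sided conservativeness
  under the gradient — the safe direction clinically, since it can only
  *under*-call adequacy.
* Problem sizes in the suite: 2000 phantoms for null calibration, 10
  study replicates of 36 records each for signal recovery (mean LOOCV
  accuracy 100 % at $\Delta T = 1.0$ °C, chance level $50 \pm 10$ % at
  $\Delta T = 0$), 500 records for the null p-value uniformity check, 100
  random vector pairs for the t-test oracle comparison at $10^{-9}$.
* `p == threshold` classifies as inadequate (strict comparison), and the
  smallest-maximiser tie-break makes the grid search invariant to
  duplicated grid values.
* The canonical thermal file format is a comma-separated text matrix of
  °C values with a JSON metadata sidecar — exact, diffable, and free of
  vendor decoding; a 16-bit count image with affine calibration
  (`T = offset + scale × count`) is accepted as a second dialect.

## Known limitations

The backbone axis must be vertical; registration is pure scaling with no
lens-distortion or parallax correction; ROI selection is an explicit
coordinate input, not automated; the decision threshold learned by grid
search transfers across patients only as well as the score distribution
does; and the phantom's spatial simplicity means classification accuracies
on synthetic studies are upper bounds on what heterogeneous clinical data
can deliver.
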