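---
title: "Methods: stereo depth and distance sampling in stereotrap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stereo depth and distance sampling in stereotrap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereotrap)
```

## The problem

Estimating the abundance of unmarked animal populations from camera traps
requires the *effective area* each camera surveys, which in turn is inferred
from the distances at which animals are observed. A stereo camera trap
measures those distances directly: two horizontally displaced cameras see
each scene point at slightly different image columns, and that column offset
(the disparity, in pixels) is inversely proportional to metric depth. This
package implements the analysis chain from rectified stereo frames to a
fitted detection function, with a synthetic-scene generator standing in for
field recordings so that every stage is testable against exact ground truth.

## Stereo model

For a calibrated rig with baseline $b$ (m) and focal length $f$ (px),

$$z = \frac{b\,f}{d},$$

where $d$ is the disparity in px and $z$ the depth in m. Matching uses a
sum-squared-difference cost volume over rectified pairs: for pixel $(i, j)$
($i$ = column, $j$ = row, 0-based) and candidate disparity
$d \in \{0, \dots, D-1\}$,

$$V(i,j,d) = \sum_{\Delta j = -c}^{c}
  \bigl(a(i,\, j+\Delta j) - b(i-d,\, j+\Delta j)\bigr)^2 ,$$

i.e. a one-pixel-wide column patch of height $2c+1$, with the right image
searched leftward. The per-pixel disparity is the winner-take-all argmin
over valid cells, ties broken toward the smaller disparity.

Choices worth knowing about:

* **Border policy.** Cells whose patch or shifted column leaves the image
  are invalid (`NaN`), never clamped — clamping silently biases the
  winner-take-all readout near borders, precisely where synthetic
  constant-shift tests would otherwise look clean.
* **Patch shape.** The default is the literal 1-wide column patch above. A
  square $(2c+1)\times(2c+1)$ window is available via
  `square_window = TRUE` for robustness on weak texture, but it is off by
  default so the implementation matches the printed formula and the
  brute-force oracle exactly.
* **Sub-pixel refinement.** A standard three-point parabola over
  $(d-1, d, d+1)$, applied only when all three cells are valid and the
  parabola is convex. Disabled by default so integer oracles stay exact.
* **Zero disparity maps to invalid depth**, not to `Inf`: a `NaN` marker
  flows harmlessly through medians and quantiles downstream, an infinite
  depth would not.
* **Coordinate origin.** Nothing upstream fixes an origin, so the package
  fixes one: 0-based, $x$ = column, in every file format and CLI option;
  1-based `[row, column]` only inside R matrices.

## Quality metrics

Sparse ground truth (e.g. laser-rangefinder distances to recognizable
objects) is compared **in disparity space**: the ground-truth distance is
converted via $d = bf/z$ and subtracted from the predicted disparity.
Comparing in depth space instead would amplify far-field errors
quadratically (depth error grows as $z^2/bf$ per pixel of disparity error),
making the aggregate dominated by the farthest point. Endpoint error (EPE)
is the mean absolute disparity error; RMSE the root mean square. RMSE ≥ EPE
always (power-mean inequality), with equality exactly for constant
magnitude errors — the suite checks this as a property.

Temporal stability of a disparity sequence is the flow-compensated mean
absolute frame-to-frame difference

$$E_t = \frac{1}{(N_T - 1)\,N_P} \sum_{n=2}^{N_T} \sum_{(x,y)}
  \bigl|D(x,y,n) - D(x - m_x,\, y - m_y,\, n-1)\bigr| ,$$

with $(m_x, m_y)$ the optical flow from frame $n$ back to frame $n-1$. The
flow source is pluggable (external 2-channel fields, or an integer
block-matching fallback); the warped coordinate is resolved by
nearest-neighbour rounding, since bilinear lookups would blur across
invalid-pixel boundaries. Pixels warping out of frame or onto invalid
values are skipped and the per-term normalizer shrinks accordingly — the
printed formula fixes $N_P$, but says nothing about borders, so this
implementation renormalizes per term and documents it. Consequences tested:
$E_t$ is invariant under adding a constant to all frames, scales linearly
under positive scaling, and equals a direct two-loop computation when the
flow is zero.

## Motion-adaptive frame sampling

Videos are sampled either at a fixed rate (every `round(fps/rate)`-th
frame) or adaptively: each frame's foreground ratio — the fraction of
pixels occupied by moving objects — is accumulated until a threshold $\tau$
(default 0.10) is reached; that frame is selected and the accumulator
resets to zero. More movement therefore yields denser samples; for constant
ratio $r$ the period is exactly $\lceil \tau / r \rceil$ frames. The
reset-to-zero reading (rather than carrying the remainder) is the simplest
consistent with "accumulate until the threshold is reached" and is fixed
here so results are reproducible. A slack of $10^{-12}$ on the threshold
comparison keeps float accumulation (ten times 0.01) from slipping past
$\tau$ by one frame.

Foreground comes from the classic per-pixel Gaussian-mixture background
model. No canonical parameter set exists for camera-trap footage, so this
package adopts the family's textbook defaults and exposes all of them:
$K = 3$ components, learning rate $\alpha = 0.005$, match threshold
$2.5\sigma$, background weight threshold $0.7$, plus an initial variance of
$0.1^2$ and a variance floor of $0.005^2$ on $[0,1]$ intensities. Two
additional choices the study leaves open: the first 50 frames only
initialize the model and are ineligible for selection (otherwise the first
frame of every clip is trivially sampled), and a $3\times 3$ morphological
opening suppresses salt noise in the mask before the ratio is taken (both
configurable). The update rule uses a constant $\rho = \alpha$ for the
matched component's mean/variance — the common simplification of the
original likelihood-weighted update — and renormalizes weights after every
frame; a scalar replica of one pixel's weight dynamics serves as the
absorption-time oracle in the tests.

## From detections to distances

Detections are inputs (instance masks, or MegaDetector-style JSON boxes
normalized to the image, converted on read to 0-based half-open pixel
corners). Fusion with depth:

* **Masks:** the median of valid depths under the mask. Robust to boundary
  leak onto the background and to invalid night-time holes, which are
  simply excluded.
* **Boxes:** the 25th percentile of valid depths inside the box (the median
  of the lower half). A box around an animal necessarily includes
  background *beyond* it, so the plain median is biased far whenever the
  animal fills less than half the box; the lower quartile returns the
  animal's depth whenever it fills at least half. The statistic is
  configurable, and the synthetic suite verifies the $\ge 50\%$-fill case.
* **Support:** distances resting on fewer than 20 valid depth pixels are
  reported missing (flagged, not dropped) — below that the statistic is
  dominated by matching noise in underexposed regions.
* No confidence cutoff is published for this chain; the default gate is
  0.2, exposed in configuration.

## Distance sampling

Observed distances are truncated to $[w_l, w_r]$ (defaults 3 m and 11 m:
nearer animals may stand below the camera's field of view, and the left
truncation is deliberately not rescaled away) and binned into $K$ equal
intervals (default 7), left-closed with a closed final edge. The detection
function is either

* uniform key with cosine adjustments,
  $g(r) = \dfrac{1 + \sum_j a_j \cos(j \pi r_s)}{1 + \sum_j a_j}$, with the
  *left-truncation-shifted* scaled distance
  $r_s = (r - w_l)/(w_r - w_l)$ — the software this emulates does not print
  its convention for left-truncated uniform keys, so this one is fixed
  here; it guarantees $g(w_l) = 1$, i.e. certain detection at the nearest
  visible distance; or
* half-normal, $g(r) = \exp(-r^2 / 2\sigma^2)$.

Under point-transect geometry the area element grows linearly in $r$, so
the probability of a detected animal falling in bin $k$ is
$p_k = \int_{\text{bin}} r\,g(r)\,dr \big/ \int_{w_l}^{w_r} r\,g(r)\,dr$
(the camera's angular field of view multiplies both integrals and cancels).
Fitting maximizes the binned multinomial log-likelihood
$\ell = \sum_k n_k \log p_k$ subject to $0 \le g \le 1$ checked on a
512-point grid. Monotonicity of $g$ is *not* enforced, mirroring the cited
software's behaviour for cosine adjustments. For the single-order uniform
key this feasible set is the interval $[0, 1]$ and the likelihood is
linear-fractional in $a_1$ (the moment integrals are precomputed once), so
the optimizer is a dense grid pass followed by local refinement —
deterministic and verified against an exhaustive $10^{-3}$-step grid-search
oracle with an independent Riemann-sum likelihood. Multi-order specs use
multi-start Nelder–Mead from a fixed start set; the half-normal scale is a
bounded search over $\log\sigma$. An optimum at the feasibility edge (e.g.
$\hat a_1 = 0$ for annulus-proportional counts) is flagged
`boundary = TRUE`. Integrals use composite Simpson quadrature with relative
tolerance $10^{-8}$; reported alongside the MLE are AIC, a $\chi^2$
goodness-of-fit on $K - 1 - \dim\theta$ degrees of freedom, and the average
detection probability
$\bar P = \int_{w_l}^{w_r} g(r)\, 2r \, dr \big/ (w_r^2 - w_l^2)$.

The simulator draws from $f(r) \propto r\,g(r)$ by rejection with a uniform
proposal — the envelope $r\,g(r) \le w_r$ is exact because every accepted
model has $g \le 1$ — so simulation-based recovery tests are unbiased by
construction.

No published field fit exists to reproduce at desk scale, so correctness
rests on the closed-form annulus fixed point ($a_1 = 0$, $\bar P = 1$),
oracle equivalence, and parameter recovery from simulations at the default
design (3–11 m, 7 bins).

## The synthetic world

`scene_spec()` describes what the tests feed every stage: an i.i.d.
uniform-noise background plane at 20 m with circular "animal" blobs at
3–11 m, a rig with 0.5 m baseline (the mid-range of a configurable-baseline
rail) and a focal length chosen so disparities stay within a desk-scale
search range (80–160 px m product; at $bf = 160$, every depth in 3–11 m
lands between 15 and 53 px). I.i.d. texture guarantees unique SSD minima
with overwhelming probability, which is what makes exact shift-recovery
assertions meaningful. Rendering shifts each constant-depth region leftward
by its disparity rounded to an integer pixel; the returned ground-truth map
carries the *exact* $bf/z$, so geometric consistency is exact while
rendered correspondence is quantized — recovery tests therefore either use
integer-disparity depths, or budget the quantization (at most
$0.5/d$ relative) inside their 2–4% depth tolerances. Occluded left pixels
and dis-occluded right pixels are tracked and excluded from scoring, as are
pixels whose matching patch straddles a depth discontinuity (no single
disparity is correct for them under a patch matcher).

What a green suite does **not** establish: performance under photometric
noise between the two cameras (gain/vignetting differences), non-integer
sub-pixel texture motion, slanted or curved surfaces, repetitive texture,
or any property of learned matchers — the stereo stage here is the
classical baseline, and error figures published for neural matchers on
real field recordings are properties of those recordings and matchers, not
of this code. Night degradation is emulated only as textureless
constant-intensity holes.

## Numerical conventions collected

| Quantity | Choice |
|---|---|
| Invalid marker | `NaN` everywhere, including PFM files |
| WTA ties | smallest disparity wins |
| Sub-pixel | off by default; convex three-point parabola when on |
| Warp lookup in $E_t$ | nearest-neighbour; out-of-frame terms skipped, per-term renormalization |
| Accumulator threshold | $\ge \tau - 10^{-12}$ |
| Quadrature | composite Simpson, relative tolerance $10^{-8}$, doubling from 16 intervals |
| Fit convergence | $10^{-9}$ interval tolerance (single parameter), `reltol` $10^{-10}$ Nelder–Mead (multi) |
| Constraint grid | 512 points over $[w_l, w_r]$ |
| Min. fusion support | 20 valid depth pixels |
| File coordinates | 0-based, half-open boxes, $x$ = column |

## Known limitations

* The matcher is $O(W H D (2c+1))$ in pure vectorized R; it is meant for
  the desk-scale resolutions the tests use, not for full-resolution field
  frames.
* PGM/PFM only; no PNG/TIFF/HEVC decoding (no reader available in the
  target environment, and video codecs are out of scope).
* The distance-sampling stage stops at the detection probability; effort,
  snapshot moments, availability bias and density variance are out of
  scope.
* Calibration and rectification grids are consumed, never estimated.
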