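---
title: "Methods: reconstructing single-cell Erk-KTR kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reconstructing single-cell Erk-KTR kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erkktr)
```

## The measurement and the models

A kinase translocation reporter (KTR) converts kinase activity into a
spatial signal: phosphorylation drives the reporter out of the nucleus, so
the ratio of mean cytoplasmic to mean nuclear reporter fluorescence (C/N)
rises when the kinase is active. `erkktr` reconstructs per-cell C/N
trajectories from two-channel movies (a nuclear dye defining the nucleus,
the reporter defining the signal) and condenses each trajectory into a
small number of kinetic parameters.

Each normalized trajectory r(t), with t in seconds relative to the
stimulation event and r = 1 enforced at the pre-stimulation reference
frame, is described by a delayed-exponential approach to equilibrium:

$$r(t) = \begin{cases} 1 & t \le t_{on} \\
R_{eq} + (1-R_{eq})\,e^{-k_{on}(t-t_{on})} & t > t_{on} \end{cases}$$

* `k_on` (1/s): trans-localization rate, how fast the reporter
  redistributes once the response starts;
* `t_on` (s): onset delay after stimulation;
* `R_eq` (dimensionless): equilibrium C/N ratio; 1 means no response.

Cells whose response is transient — the C/N pattern recovers toward
baseline within the movie, as senescent cells do — get a second branch
that switches at `t_off` (s) to an exponential return with rate `k_off`
(1/s):

$$r(t) = 1 + \big(r(t_{off}) - 1\big)\,e^{-k_{off}(t - t_{off})}, \qquad t > t_{off}$$

where $r(t_{off})$ is the value of the first branch at the switch point:
continuity at both breakpoints is structural, never fitted. Both models
are implemented in `eval_monotone()` / `eval_recovery()` and assume the
baseline is stationary (ratio 1 before stimulation) and that a single
onset and, at most, a single switch-off describe the trajectory; damped
oscillations or repeated pulses are out of scope.

## Pipeline stages and their assumptions

**Registration** (`register_movie()`): integer-pixel translation
maximizing the FFT cross-correlation of each frame's dye channel against a
reference frame, applied identically to both channels. Shifts are cyclic;
content rolled across an edge is not re-imaged, so registration is meant
for small stage drift (a few pixels), not large excursions. Constant
frames yield a zero offset with a warning.

**Background** (`subtract_background()`, `estimate_background()`): a
scalar per frame, either a stated constant, a frame percentile, or — the
pipeline default — the median over pixels outside every nucleus and ring.
The median of Gaussian noise about a flat background is unbiased, which
matters because a residual background offset biases the C/N ratio toward
1 by inflating both means.

**Segmentation** (`segment_nuclei()`): Otsu threshold on the dye frame
(or a fixed threshold), 4-connected component labeling, hole filling,
removal of components below `min_area_px` (default 30 px), relabeling
1..n in column-major raster order of first pixel. Touching nuclei are not
declumped; the synthetic generator keeps nuclei separated, and on real
data merged nuclei surface as tracking gaps rather than silent errors.

**Cytoplasm rings** (`make_cytoplasm_rings()`): the cytoplasm of a cell
is every non-nucleus pixel whose exact Euclidean distance to that cell's
nucleus is at most `ring_width_px` (default 5 px, which is ~1.1 µm at the
default 0.22 µm/px). The Euclidean metric (distance-transform threshold)
is used rather than a Chebyshev/square dilation because the physical
statement "a ~1.1 µm band" is isotropic; a square structuring element
would overshoot along diagonals. Pixels within reach of two nuclei go to
the nearer one, exact ties to the lower label, so rings are pairwise
disjoint and C/N is unambiguous. Nuclei within `ring_width_px` of the
image edge are flagged (`border`), and flagged cells are excluded from
fitting by default since their rings are truncated.

**Tracking** (`link_tracks()`): frame-to-frame minimum-cost assignment on
centroid Euclidean distance, solved exactly by a Jonker-Volgenant
shortest-augmenting-path implementation of the Hungarian/Munkres
algorithm (`solve_assignment()`); its optimality is enforced in the test
suite by an exhaustive permutation oracle on random instances up to 6x6,
with and without forbidden links. Costs use distance only — no area or
intensity terms — as the minimal reading of assignment-based tracking;
links beyond `max_link_dist_px` (default 15 px) are forbidden, ending one
track and starting another. `max_gap` (default 0) allows a track to
survive that many consecutive missed frames, recorded as missing rather
than interpolated. Mitosis and lineage are out of scope.

**Quantification** (`measure_cn()`, `normalize_trace()`): C/N is the
arithmetic mean of the background-subtracted reporter over the ring
divided by the mean over the nucleus. Normalization divides by the value
at the single frame `stimulation_frame - 1` — the frame just prior to
stimulation, not an average of baseline frames. Whether intensities are
background-subtracted before ratioing is configurable
(`background` argument); for a uniform background the normalized ratio is
unaffected, which the test suite asserts on synthetic data. Traces whose
reference value is undefined or non-positive are excluded with an explicit
reason rather than silently dropped. Undefined interior values stay
undefined; fitting simply omits those time points.

**Fitting** (`fit_trace()`): bounded Levenberg-Marquardt least squares
(`minpack.lm::nls.lm`) with multi-start initialization, because the
breakpoint parameters make the SSE surface multimodal: `t_on` starts on 5
equally spaced knots over the first half of the observed window, `k_on`
on {1e-3, 1e-2, 1e-1} 1/s, `R_eq` from the trace's tail mean; the
recovery model adds `k_off` starts {1e-3, 1e-2} and `t_off` starts at the
observed peak and mid-tail. Bounds: rates in [1e-5, 1] 1/s (generous for
a 30-min window), `t_on` in [0, t_max], `t_off` parameterized as
`t_on + dt` with `dt` in [1, t_max] so the ordering constraint is a box
constraint, `R_eq` in [0.1, 10]. The best SSE wins; near-ties go to the
smaller `k_on`. `t_on` is fitted continuously, not snapped to frame
times. Pre-stimulation points are included in the fit — they constrain
the baseline branch — since they carry the same measurement noise as
post-stimulation points and the model explicitly describes them.

Traces with no discernible rise are not fitted: if the 90th percentile of
the post-stimulation values exceeds 1 by less than
`max(flat_tol, 3 * noise_hat)` — `flat_tol` defaulting to 0.02 normalized
units and `noise_hat` estimated robustly as `mad(diff(r))/sqrt(2)` — the
trace is returned with an `unidentifiable` flag and no parameter
estimates, because `R_eq` and `k_on` are not separately identifiable on a
flat trace.

**Variant selection** (`select_variant()`): the recovery model is chosen
iff (a) the trace's post-peak decline exceeds `decline_frac` (default
0.25) of its rise, and (b) the recovery fit improves the SSE by at least
`sse_improvement` (default 10%) over the monotone fit. Condition (a)
prevents the two extra parameters from absorbing noise on monotone
traces; condition (b) prevents labeling a trace transient on shape alone
when the fit does not support it. No selection criterion is inherited
from prior art here; both thresholds are configuration with these
documented defaults.

**Group statistics** (`classify_cell_status()`, `compare_groups()`):
cell status is classified from doubling time (DT, days) and SA-β-Gal
positivity (%): young = DT in [1, 2] and SA-β-Gal < 1%; mid-old = DT in
[5, 7] and < 5%; old = DT > 14 and > 65%. The DT bands are closed as
printed and the gaps between them (e.g. DT in (2, 5)) map to
`unclassified` — such intermediate cells belong to no defined status, and
inventing a boundary for them would manufacture classifications the
definitions do not support. Parameters are compared pairwise with a
one-tailed Mann-Whitney U test: exact by full enumeration of rank
arrangements when n1 + n2 <= 12 without ties, otherwise a normal
approximation with tie and continuity correction. The direction of each
one-sided alternative must be declared in the call — an automatic choice
would turn a one-tailed test into a hidden two-tailed one. p values are
per comparison; no multiple-testing correction is applied, and the JSON
report says so. A two-tailed equal-variance Student's t test
(`student_t_two_tailed()`) is provided for normally distributed samples,
but the Mann-Whitney test is the default.

## What the synthetic generator emulates — and what it does not

`simulate_movie()` renders two-channel movies with known ground truth:

* **Schedule**: one frame every 15 s for 30 min after stimulation
  (121 post-stimulation frames) plus `n_prestim_frames` baseline frames
  (default 4; at least one is required for normalization, and the true
  number used in such acquisitions is generally unstated, so it is
  configurable).
* **Cells**: hard (non-anti-aliased) disks of radius `nucleus_radius_px`
  (default 8 px) in the dye channel, so pixel-count oracles are exact.
  The reporter channel renders the nucleus at a constant level and the
  ring at that level times the cell's true C/N — only the ratio is
  physically meaningful, so the split is a free choice.
* **Kinetics**: three archetypes mirror the in-vitro cell states — young
  (k_on 0.015-0.05 1/s, t_on 30-90 s, R_eq 2-3.5), mid-old (k_on
  0.005-0.02, t_on 60-150, R_eq 1.5-2.5), and old, which adds recovery
  (k_off 0.002-0.01 1/s, t_off 300-700 s). These ranges produce
  responses that develop, and for old cells visibly recover, within the
  30-min window; they are generator conventions, not measured population
  values.
* **Noise and motion**: additive Gaussian pixel noise (default), with a
  Poisson mode as an alternative; Gaussian is the default because the
  trace-level noise it induces is analytically calibratable —
  `noise_sd_for_trace_sd()` inverts the delta-method variance of the
  ratio-of-mask-means, including the shared reference-frame term (which
  appears as a trace-wide correlated component rather than per-frame
  jitter). Motion is a per-cell isotropic Gaussian random walk with a
  hard-core constraint: a step that would bring two nucleus centers
  closer than `2r + 4` px is resampled (up to 20 proposals, then the
  cell pauses that frame), so nuclei never merge; a global per-frame
  drift can be added for registration tests.

Not emulated: photobleaching, shot-noise camera gain, out-of-focus blur,
cytoplasm texture outside the ring, cell division, apoptosis, or cells
detaching. Passing tests on this generator therefore demonstrates the
correctness of the measurement and inference chain — segmentation
geometry, tracking optimality, ratio extraction, fitting — under the
stated noise model, not robustness to every imaging artifact of real
microscopy.

## Numerical choices and degenerate inputs

* Frames, rows, and columns are 1-based; `stimulation_frame` is the first
  post-stimulation frame, so frame k has time
  `(k - stimulation_frame) * frame_interval_s` and the reference frame is
  `stimulation_frame - 1`.
* Ring membership uses the exact Euclidean distance transform; ties in
  the nearest-nucleus assignment go to the lower label, making the result
  deterministic and order-independent.
* The assignment solver encodes forbidden links as a finite penalty
  larger than any achievable total, padded to a square matrix with
  zero-cost dummies: the solution maximizes the number of allowed links
  first, then minimizes distance.
* All-zero or constant frames register with zero offset and a warning;
  empty label images yield empty (not failing) masks, tracks, and traces.
* 16-bit TIFF export quantizes intensities to 1 part in 65535 of the
  configured scale; the test suite verifies that a write/read round trip
  changes reconstructed parameters negligibly.

## Validation problem sizes

The test suite validates the pipeline end to end at the acquisition
schedule above: a noiseless 20-cell stationary movie (recovery of every
cell's k_on, t_on, R_eq to within 5%, in practice machine precision, and
100% track-truth agreement), and a noisy 100-cell movie (trace noise SD
0.05 normalized units, random-walk motion 1 px/frame) for median
parameter-recovery error and variant-selection accuracy. Solver
optimality is checked on 500 random gated cost matrices against
exhaustive enumeration, ring geometry against brute-force pixel
enumeration for radii 8, 10, and 15 px, and the Mann-Whitney
implementation against full rank enumeration (all sample-size splits with
n1 + n2 <= 10) plus a 1000-replicate type-I calibration at alpha = 0.05.
`scripts/acceptance.R` re-runs the same computations from scratch and
writes the measured quantities as JSON.

## Known limitations

* No declumping: touching nuclei merge into one label and break tracks.
* Cyclic registration cannot recover content that drifted out of frame.
* The piecewise models describe a single onset and at most one
  switch-off; oscillatory Erk dynamics would need a different model
  class.
* The recovery switch `t_off` is identifiable only when the movie
  actually contains the decline; responses that switch off near the end
  of acquisition fit poorly and should be read with their SSE.
* Group comparisons assume independent cells; repeated imaging of the
  same field or well introduces dependence the Mann-Whitney test does not
  model.
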