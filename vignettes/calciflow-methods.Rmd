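---
title: "calciflow: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{calciflow: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

calciflow analyses miniature two-photon calcium imaging video in a
streaming, frame-by-frame fashion: each incoming frame is rigidly
motion-corrected, a preprocessed copy feeds a blob-based neuron
detector, and the uncorrupted corrected frame feeds per-neuron
delta-F/F trace extraction.  This vignette explains the models behind
each stage, the parameters that matter, the synthetic ground-truth
generator used for validation, and the numerical decisions taken where
the design was genuinely open.

## The dataflow skeleton

The pipeline is expressed in a small parameterized synchronous dataflow
(PSDF) runtime (`dfActor()`, `dfEdge()`, `dfGraph()`, `runPSDF()`).
Actors fire only when every input FIFO holds a token; every firing
consumes and produces exactly one token per port; token payloads are
passed by reference, never copied.  The scheduler is single-threaded
and demand-driven: at each step the most downstream enabled actor that
has not yet fired in the current iteration fires, and one iteration
corresponds to one processed frame.  FIFO capacity is logically
unbounded with a watermark warning; with the unit-rate graph used here
queues never grow beyond a single token per edge.

Two graphs cooperate.  The *body* graph is the processing chain
(`ImgSrc -> MotionCorrection -> Fork -> {SignalExtraction,
Preprocessing -> NeuronDetection -> Fork -> SignalExtraction}`).  The
*subinit* graph holds the `SetParams` actor, which calibrates the blob
detector on training frames; its output port is bound at construction
time to the `NeuronDetection` actor's parameter, and `runPSDF()`
transmits the calibrated value before the body graph starts.  In
real-time operation the body iteration count equals the number of
analysis frames, so the subinit graph executes exactly once up front.

## Motion correction

Frames from head-mounted microscopes shake by up to about ten pixels
per frame and occasionally rotate a few degrees.  The Motion Correction
actor estimates a rigid warp W(x) = R(theta)(x - c) + c + t between the
current frame and a reference frame by maximizing the enhanced
correlation coefficient (ECC), a normalized zero-mean correlation that
is invariant to global brightness and contrast changes.  Estimation
runs on copies downsampled by a factor of 2 per axis (a quarter of the
pixels), and only the estimation is downsampled: corrected frames are
produced at full resolution and translations are rescaled accordingly.
Because gradient-based ECC iterations cannot jump ten-pixel shifts on
sparse blob scenes, the iteration is seeded with an integer-shift FFT
cross-correlation (computed on a further 2x coarsening), and for the
Euclidean model with a coarse rotation sweep (default +/- 10 degrees in
2-degree steps, each scored by its best FFT shift).  The Gauss-Newton
update uses backtracking step control: a step that lowers the ECC value
is halved up to four times.  Plain forward-additive updates oscillate
and diverge on sharp sparse scenes, and the backtracking variant
converges on the same fixed point when the plain update converges.  The
iteration cap is 50 and the convergence tolerance on the coefficient is
1e-4.

Rotation is handled *selectively*: the cheap translation-only model
runs first, and the Euclidean model runs only when the translated
frame's correlation C1 with the reference fails an adaptive gate.  The
gates follow the correlation-history rule tau = mean - p * sd over the
100 most recent accepted correlations (CoHisQ), with p = 2 for the
translation gate and p = 10 for the (strictly looser) Euclidean accept
gate; sd is the population standard deviation of the queue contents.
Before the queue holds 10 values the translation gate uses a fixed 0.85
floor and the Euclidean gate a 0.3 floor.  The strict warm-up on the
translation side matters: if an early rotated frame is accepted by a
permissive translation gate, the (mis-corrected) frame becomes the
reference and the error cascades.  With the 0.85 floor such frames fall
through to the Euclidean stage instead.

The reference frame starts as the first analysis frame and is replaced
by the accepted frame after every acceptance.  A realigned reference
carries a zero-filled border band where content moved out of view; the
actor therefore tracks a validity mask for the reference and excludes
masked pixels from both warp estimation and the gating correlations.
Without the mask, the static border band dominates the correlation and
estimates lock onto it rather than onto the tissue.  When both gates
fail, the frame is declared failed, a diagnostic
`motion correction failed at frame k` is appended to the experiment
log, and the reference frame is emitted instead.  Shift candidates are
bounded by a configurable `maxShift` (default 30 px; set it to the
rig's motion range) — on sparse scenes an unbounded cross-correlation
peak can propose an alignment of the wrong blobs that still passes the
permissive Euclidean gate and corrupts the reference.  After ten
consecutive failures the corrector re-seeds the reference from the
current frame and logs the new epoch; without re-seeding, a stream
that momentarily loses all content could never re-acquire alignment.

The "motion detected" predicate treats estimated |tx| or |ty| >= 0.5 px
or |theta| >= 0.05 degrees as motion.  Sub-pixel warping is bilinear
with zero fill.  Both accepted C1 and C2 values feed CoHisQ; failed
frames push nothing.

One property of these scenes is worth knowing: frame-to-frame Pearson
correlations are depressed not only by misalignment but also by genuine
content change (a newly firing neuron at intensity 128 dominates the
pixel variance), so accepted correlations legitimately range from about
0.7 on burst frames to 1.0 on quiet ones.  The adaptive gates absorb
this spread; small rotations (< ~0.5 degrees) on burst frames can still
slip through the translation gate, which bounds the achievable mean
angular error at roughly 1e-3 to 1e-2 degrees rather than zero.

## Preprocessing (detection branch only)

The detection branch smooths each corrected frame with a 3 x 3 Gaussian
(sigma from the usual kernel-size rule, 0.8 for size 3), applies a
3 x 3 median filter, subtracts a wide Gaussian low-pass background
estimate (kernel 31, sigma 5), clamps negatives to zero, and min-max
normalizes to [0, 255] via (I - Imin) * 255 / (Imax - Imin).  The wide
low-pass removes the diffuse glow of deep out-of-focus neurons while
preserving blobs at the ~7 px neuron scale.  "Equalization" is exactly
the min-max formula; histogram equalization is not used.  A constant
frame normalizes to zeros (divide-by-zero guard).  The stage order is
fixed as listed.  Signal extraction never sees preprocessed pixels.

## Neuron detection and training

The detector binarizes the preprocessed frame at every threshold from 0
to 255 in steps of `thresholdStep` (initially 10), extracts connected
components (4-connectivity) at each level, filters them by pixel area
in [aMin, aMax] and by three shape measures in [0, 1] — circularity
4*pi*A/P^2 with P the boundary-pixel count (minimum 0.5), inertia ratio
= minor/major second-moment eigenvalue (minimum 0.3), and convexity =
area / digital convex-hull area (minimum 0.5) — and groups components
across levels whose centres lie within `minDist` = 10 px.  A group
accepts at most one component per level, and groups must appear at at
least `minRepeatability` = 2 levels; this is the standard multi-level
blob-detector convention, and it is what suppresses one-level noise
islands (two same-level islands merged into one "group" would otherwise
fake a repeat and place a detection in the dark gap between them).  A
detection's centre is the mean of its grouped centres; its radius is
the furthest-point distance of the largest contributing component.

In training mode the actor maintains a persistent detection matrix
delta_p.  New detections within d = 2 px (in both x and y) of a
persisted row are repeats and are dropped; survivors are newly
discovered neurons and are appended.  delta_p never shrinks.  In
real-time mode the actor emits the frozen training matrix — the neuron
set is fixed when initialization ends — with an opt-in flag to keep
accumulating.  Detected neurons are identified by their discovery
order, which also indexes signal-table columns.

The `SetParams` calibration starts from aMin = pi*(0.5 r)^2 and
aMax = pi*(2 r)^2 for a user-supplied rough radius r (default 3.4 px)
and progressively loosens (aMin x 0.8, aMax x 1.25, thresholdStep x 0.8
with floor 1, at most 20 iterations) until the cumulative count over
the training frames reaches the target T_n = 5.  Loosening, rather than
tightening, is used because tightening from a permissive start admits
spurious blobs before the target is reached.

## Signal extraction

For each neuron i the raw signal is the mean intensity over the circle
of radius delta[i, 3] centred at (delta[i, 1], delta[i, 2]) in the
*unpreprocessed* corrected frame (pixels whose centres lie in the
circle, boundary inclusive).  The output is
beta[i] = (F(i) - F0) / F0, where the baseline F0 is the mean of the
W = 50 preceding raw values after discarding window values above three
times the window median — without the exclusion, calcium transients
inflate F0 and compress subsequent beta values.  beta is 0 before a
neuron's first detection and while the window is empty.  The
denominator of the ratio is floored at 1 intensity unit: on
zero-background data the baseline of a quiescent neuron falls to the
noise level, and a guard that zeroed beta outright whenever F0 was
sub-floor was found to suppress exactly the onset transients after
quiescence that the trace exists to report (halving the trace/spike
correlation); flooring the denominator keeps the division safe while
preserving those transients.  A continuously recorded stream has no
natural anchoring event for F0, so the rolling window is used; W is
configurable.

## The simulator

Validation uses synthetic recordings with complete ground truth.  A
network of 100 leaky integrate-and-fire neurons is split into group A
(no parents, externally stimulated) and group B (one or two group-A
parents).  The membrane potential follows
dV/dt = (Vrest - V)/lambda + theta * lambda * (-0.5) * eps with eps
standard normal, integrated with an Euler step of one frame; the noise
term is implemented literally (its sign is immaterial because eps is
symmetric).  A spike fires when V crosses the threshold, resets V to
Vrest, and silences the neuron for the refractory period.  Parent
spikes and stimulus events add w = 0.2 to V.  Constants not fixed by
the study design are Vrest = 0, Vthreshold = 1, lambda = 10 frames,
refractory = 5 frames, stimRate = 0.02, and theta = 0.045, the last
chosen once so that the group-A baseline rate is about 2% per frame;
all are configurable.  A `silent` argument sets chosen thresholds
unreachable, reproducing a fixed count of inactive neurons
deterministically (the 97-active worked configuration).

Masks are rough ellipses placed on a 400 x 400 grid with bounding
widths/heights drawn around 6.84 x 6.76 px (the size statistics of the
mask set being emulated), a 16-px border margin so that injected motion
keeps neurons in view, and rejection of pixel-identical or fully
contained placements.  Rendering sets a neuron's trace to 128 at spike
frames and decays it by 2^(-1/8) per frame (half-life 8 frames);
overlapping masks compose by per-pixel maximum, which preserves the
"set to 128" semantics.  Output is clamped to [0, 255].

Rigid motion is injected per frame: translations uniform in
[-10, 10] px per axis (drift regimes: "small" U[-3, 3], "large"
U over [-10, -7] and [7, 10], and a constant-trajectory mode moving
1 px/frame along a rectangular path within the +/- 10 px box), plus,
with probability P_rot percent, a rotation uniform in +/- alpha_rot
degrees about the image centre (bilinear, zero fill).  The first frame
is left unmoved so the ground-truth track is anchored to the clean
coordinate frame.  Noise is added after motion (it models the sensor):
a white "shot" field with sd = shot level x 1.0 and a temporally
autocorrelated field, AR(1) per pixel with coefficient 0.8 and marginal
sd = colored level x 0.4, initialized at stationarity.  The sNNcMM
label grammar maps digits to multipliers of the base sd (s03c05 = shot
0.3, colored 0.5); frames are quantized to 8-bit.  Simulations also
render `warmupFrames` = 100 discarded frames first, so frame 1 shows
steady-state activity rather than a dark field — without warm-up the
first reference frame is nearly empty and motion correction has nothing
to align against, a situation no real recording presents.

What the generator does *not* emulate: neuropil contamination,
one-photon background haze, photobleaching, non-rigid deformation, and
correlated (structured) noise.  Passing the simulation study therefore
validates the pipeline mechanics and its noise/motion robustness, not
performance on data dominated by those effects.

## Evaluation harness

Motion accuracy is reported as mean/max absolute x, y (pixels) and
angle (degrees) errors between the recovered and injected tracks over
successfully corrected frames only, plus the failure-rate percentage.
Detection accuracy matches detected circles to ground-truth masks
one-to-one (a candidate pair requires the detection centre inside the
mask; pairs are assigned nearest-first by centre-to-centroid distance)
and scores pixel-level recall (matched pixels / all ground-truth
pixels) and precision (matched pixels / all detected-circle pixels),
pooled over neurons by default, with F1 = 2uv/(u+v).  The detection
rate is matched-active / active x 100.

The trace signal-to-noise measure correlates each matched neuron's
delta-F/F trace with its ground-truth spike train (mean = Rs), then
repeats 1000 times the draw of one random same-radius circular region
per neuron (re-drawn until at most 20% of its pixels overlap any truth
mask), extracts that region's delta-F/F with the same baseline rule,
and correlates it with the neuron's spike train; the grand mean is Rn
and the figure of merit is 10*log10(Rs/Rn).  Degenerate
(zero-variance) traces contribute a correlation of 0.  Rn deserves a
caveat: it is a near-zero null whose only systematic (positive)
component comes from the residual mask overlap the draws permit —
regions brushing a neuron related to the tested one inherit a little
of its activity.  Forbidding overlap entirely leaves a null that is
statistically indistinguishable from zero, whose sign varies from seed
to seed and whose logarithm is therefore meaningless; the permitted
overlap keeps Rn small but stably positive, at the cost of an
interpretable but seed-sensitive decibel figure.  The robust reading
of the measure is the order of magnitude of Rs/Rn, not its exact
decibel value.

## Problem sizes used in validation

The packaged acceptance workflow runs the nine-configuration noise
study at 400 x 400 with 100 neurons and 600-frame sequences (400
frames for the clean displacement-error run); the in-suite checks use
the same field with a subset of the noise grid, plus smaller 96-128 px
fixtures for unit-level properties.  Field size matters: the
100%-detection property depends on the absolute number of neurons in
view (misses concentrate on neurons that fire once or twice, and more
neurons per field mean more re-detection opportunities for each), so
detection-rate claims are validated at the study scale, not on shrunken
fields.  These sizes are the package's validation choices and all
counts scale with them.

## Known limitations

Overlapping neurons are detected as single blobs (no demixing); the
neuron set is frozen after training by default, so neurons first active
later are missed unless continued accumulation is enabled; rotation
recovery degrades beyond the +/- 10 degree sweep bound; and the
delta-F/F baseline window trades bias for adaptivity — slow drifts in
brightness on the scale of the window are absorbed into F0.
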