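# calciflow

Real-time neuron detection and neural-signal extraction for miniature
two-photon calcium imaging, structured as a parameterized synchronous
dataflow (PSDF) pipeline.

Head-mounted miniature microscopes stream hundreds of megabytes of
video per session from behaving animals; closed-loop experiments need
the neurons in that stream found, and their activity read out, at
acquisition rate.  calciflow implements a streaming pipeline for that
problem, aimed at experimenters who want a frame-by-frame analysis
chain they can validate quantitatively and rewire actor by actor:

- **Motion correction** — rigid alignment (translation + selective
  rotation) by maximization of the *enhanced correlation coefficient*
  (ECC) on 2x-downsampled copies, with adaptive acceptance gates
  `tau = mean(CoHisQ) - p * sd(CoHisQ)` computed from the 100 most
  recent accepted frame correlations (p = 2 for the translation gate,
  p = 10 for the Euclidean fallback), reference-frame update on every
  acceptance, and per-frame failure logging.
- **Preprocessing** (detection branch only) — 3x3 Gaussian + 3x3
  median filtering, wide-Gaussian background subtraction, min-max
  normalization `(I - Imin) * 255 / (Imax - Imin)`.
- **Neuron detection** — multi-threshold blob detection (connected
  components at every intensity level, area bounds `[Amin, Amax]`,
  circularity/inertia/convexity filters, cross-level grouping) with a
  *training mode* that accumulates a persistent n x 3 detection matrix
  (x, y, radius), deduplicating repeats within a d-pixel tolerance.
- **Parameter adaptation** — a subinit-graph `SetParams` actor that
  progressively loosens `Amin`, `Amax` and the threshold step on
  training frames until a target neuron count T_n = 5 is reached, and
  delivers the calibrated values through PSDF parameter bindings.
- **Signal extraction** — per-neuron delta-F/F,
  `beta[i] = (F(i) - F0)/F0`, with a rolling 50-frame baseline that
  excludes transient values above 3x the window median.
- **Simulator** — ground-truthed videos from a 100-neuron leaky
  integrate-and-fire network
  (`dV/dt = (Vrest - V)/lambda + theta * lambda * (-0.5) * eps`),
  mask-based rendering with a 128 spike intensity and an 8-frame decay
  half-life, rigid motion/drift injection, and shot plus AR(1) colored
  noise ("s03c05" = shot 0.3 x 1.0, colored 0.5 x 0.4).
- **Evaluation** — motion-error reports (Mx, My, Mrot, failure rate),
  pixel-level detection precision/recall/F1 against truth masks, and a
  trace signal-to-noise measure `10*log10(Rs/Rn)` against a
  1000-repetition random-region null.

## Worked example

Simulate a noisy recording with ground truth, run the full pipeline in
training mode, and score it:

```r
library(calciflow)

b <- simulateCalciumVideo(nNeurons = 100, T = 300, dim = c(400, 400),
                          noise = parseNoiseLabel("s03c05"),
                          motion = motionConfig(10, 25, 6.3153),
                          silent = 1:3, seed = 1)
res <- runInitialization(frames(b), pipelineConfig(nTrainingFrames = 30))

sc <- detectionScore(res$delta, neuronMasks(b),
                     activeMasks = activeNeurons(b))
me <- motionError(res$track, motionTrack(b), res$statuses)
cat(sprintf("matched %d of %d active neurons (%.0f%%), pixel recall %.2f\n",
            sum(sc$matches$mask %in% activeNeurons(b)),
            length(activeNeurons(b)), sc$detectionRate, sc$v))
cat(sprintf("motion error: Mx %.2f px, My %.2f px, Mrot %.4f deg, fail %.1f%%\n",
            me$meanMx, me$meanMy, me$meanMrot, me$rateFail))
```

```
matched 89 of 89 active neurons (100%), pixel recall 0.89
motion error: Mx 0.57 px, My 0.71 px, Mrot 0.0077 deg, fail 0.0%
```

Every active neuron is recovered (the three silenced neurons are,
correctly, never counted as active); residual alignment error is well
under a pixel against injected translations of up to 10 px and
rotations up to 6.3 degrees; `res$signals` holds the delta-F/F table
(one row per frame, one column per detected neuron) and `res$log` the
experiment log, including any `motion correction failed at frame k`
diagnostics.  The run takes about a minute on one core.

A thin command-line wrapper with `simulate` / `init` / `run` /
`evaluate` subcommands is installed at
`system.file("scripts", "calciflow-cli.R", package = "calciflow")`.

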