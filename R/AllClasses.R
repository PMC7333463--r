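#' SimulationBundle: a ground-truthed simulated calcium-imaging video
#'
#' Container for one simulated experiment: the rendered video (after
#' motion and noise injection), the ground-truth spike matrix, neuron
#' masks, the per-frame injected motion track, an optional motion-free
#' noise-free reference video, and the echoed generator configuration.
#' Bundles are reproducible bit-exactly from (config, seed).
#'
#' @slot frames H x W x T array of 8-bit frames.
#' @slot spikes nNeurons x T binary spike matrix.
#' @slot masks a `maskSet` (see [generateMasks()]).
#' @slot motionTrack data.frame(frame, tx, ty, theta) ground-truth motion.
#' @slot cleanFrames H x W x T array, or a 0 x 0 x 0 array when dropped.
#' @slot config echoed generator configuration list.
#'
#' @aliases frames spikes neuronMasks motionTrack cleanFrames simConfig
#' @exportClass SimulationBundle
setOldClass("maskSet")
setClass("SimulationBundle",
  representation(frames = "array", spikes = "matrix", masks = "maskSet",
                 motionTrack = "data.frame", cleanFrames = "array",
                 config = "list"))

setValidity("SimulationBundle", function(object) {
  msg <- character(0)
  T <- dim(object@frames)[3]
  if (ncol(object@spikes) != T) {
    msg <- c(msg, "spike matrix columns must equal frame count")
  }
  if (nrow(object@spikes) != length(object@masks$pix)) {
    msg <- c(msg, "spike matrix rows must equal number of masks")
  }
  if (nrow(object@motionTrack) != T) {
    msg <- c(msg, "motion track length must equal frame count")
  }
  if (!all(object@spikes %in% c(0L, 1L))) {
    msg <- c(msg, "spike matrix must be binary")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn SimulationBundle-class the video as an H x W x T array.
#' @param object,x a `SimulationBundle`.
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))
#' @rdname SimulationBundle-class
#' @export
setMethod("frames", "SimulationBundle", function(object) object@frames)

#' @describeIn SimulationBundle-class ground-truth spike matrix.
#' @export
setGeneric("spikes", function(object) standardGeneric("spikes"))
#' @rdname SimulationBundle-class
#' @export
setMethod("spikes", "SimulationBundle", function(object) object@spikes)

#' @describeIn SimulationBundle-class ground-truth neuron mask set.
#' @export
setGeneric("neuronMasks", function(object) standardGeneric("neuronMasks"))
#' @rdname SimulationBundle-class
#' @export
setMethod("neuronMasks", "SimulationBundle", function(object) object@masks)

#' @describeIn SimulationBundle-class injected ground-truth motion track.
#' @export
setGeneric("motionTrack", function(object) standardGeneric("motionTrack"))
#' @rdname SimulationBundle-class
#' @export
setMethod("motionTrack", "SimulationBundle", function(object) object@motionTrack)

#' @describeIn SimulationBundle-class motion/noise-free reference video.
#' @export
setGeneric("cleanFrames", function(object) standardGeneric("cleanFrames"))
#' @rdname SimulationBundle-class
#' @export
setMethod("cleanFrames", "SimulationBundle", function(object) object@cleanFrames)

#' @describeIn SimulationBundle-class echoed generator configuration.
#' @export
setGeneric("simConfig", function(object) standardGeneric("simConfig"))
#' @rdname SimulationBundle-class
#' @export
setMethod("simConfig", "SimulationBundle", function(object) object@config)

#' @describeIn SimulationBundle-class indices of neurons with >= 1 spike.
#' @export
setGeneric("activeNeurons", function(object) standardGeneric("activeNeurons"))
#' @rdname SimulationBundle-class
#' @export
setMethod("activeNeurons", "SimulationBundle", function(object) {
  which(rowSums(object@spikes) > 0)
})

setMethod("show", "SimulationBundle", function(object) {
  d <- dim(object@frames)
  cat("SimulationBundle:", d[1], "x", d[2], "px,", d[3], "frames,",
      nrow(object@spikes), "neurons (",
      length(activeNeurons(object)), "active )\n")
  nz <- object@config$noise
  cat("  noise: shot", nz$shotLevel, "x", nz$shotSigmaBase,
      ", colored", nz$coloredLevel, "x", nz$coloredSigmaBase, "\n")
  mo <- object@config$motion
  cat("  motion:", mo$driftMode, "translation +/-", mo$translationRange,
      "px, pRot", mo$pRot, "%, alphaRot", mo$alphaRot, "deg\n")
})
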