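## SetParams actor (subinit graph): progressive-loosening calibration of
## the blob detector's aMin, aMax and thresholdStep on training frames
## until a target neuron count is reached.

#' Parameter-adaptation configuration
#'
#' @param targetNeurons target detected-neuron count T_n (empirically 5).
#' @param initialParams starting [blobParams()]; pre-initialized from the
#'   image size and rough neuron size ([preinitBlobParams()]).
#' @param aMinFactor,aMaxFactor,stepFactor per-iteration multiplicative
#'   relaxation factors (shrink aMin, grow aMax, shrink thresholdStep;
#'   thresholdStep floors at 1).
#' @param maxIterations loosening iteration cap.
#' @return list of class `adaptConfig`.
#' @export
adaptConfig <- function(targetNeurons = 5, initialParams = blobParams(),
                        aMinFactor = 0.8, aMaxFactor = 1.25,
                        stepFactor = 0.8, maxIterations = 20) {
  if (targetNeurons < 1) stop("config error: targetNeurons >= 1")
  if (aMinFactor >= 1 || aMaxFactor <= 1 || stepFactor >= 1) {
    stop("config error: relaxation factors must strictly loosen")
  }
  if (maxIterations < 1) stop("config error: maxIterations >= 1")
  structure(list(targetNeurons = targetNeurons,
                 initialParams = initialParams,
                 aMinFactor = aMinFactor, aMaxFactor = aMaxFactor,
                 stepFactor = stepFactor, maxIterations = maxIterations),
            class = "adaptConfig")
}

#' Pre-initialize blob parameters from a rough neuron radius
#'
#' Heuristic starting point for adaptation: aMin = pi (0.5 r)^2 and
#' aMax = pi (2 r)^2 for a user-supplied rough neuron radius r.
#'
#' @param roughRadius rough neuron radius in pixels.
#' @param thresholdStep initial binarization step.
#' @return a [blobParams()].
#' @export
preinitBlobParams <- function(roughRadius = 3.4, thresholdStep = 10) {
  blobParams(aMin = pi * (0.5 * roughRadius)^2,
             aMax = pi * (2 * roughRadius)^2,
             thresholdStep = thresholdStep)
}

.loosen <- function(params, cfg) {
  params$aMin <- params$aMin * cfg$aMinFactor
  params$aMax <- params$aMax * cfg$aMaxFactor
  params$thresholdStep <- max(params$thresholdStep * cfg$stepFactor, 1)
  params
}

#' Calibrate blob parameters on training frames
#'
#' Iterates: run training-mode detection over the training frames with
#' the current parameters; if the cumulative detected-neuron count
#' reaches the target, stop and return the parameters; otherwise apply
#' one loosening step.  After `maxIterations` the loosest parameters are
#' returned with a warning.  The detected count is non-decreasing across
#' loosening iterations.
#'
#' @param trainingFrames list of preprocessed frames (>= 1).
#' @param config an [adaptConfig()].
#' @param d training proximity tolerance (see [newTrainingState()]).
#' @return calibrated [blobParams()], with attribute `detected` (the
#'   cumulative count at acceptance) and `iterations`.
#' @export
adaptBlobParams <- function(trainingFrames, config = adaptConfig(), d = 2) {
  if (length(trainingFrames) == 0) {
    stop("config error: empty training set")
  }
  params <- config$initialParams
  for (it in seq_len(config$maxIterations)) {
    st <- newTrainingState(d = d, mode = "training")
    count <- 0L
    for (f in trainingFrames) {
      eta <- detectBlobs(f, params)
      count <- nrow(trainingUpdate(eta, st))
      if (count >= config$targetNeurons) break  # early stop within sweep
    }
    if (count >= config$targetNeurons) {
      attr(params, "detected") <- count
      attr(params, "iterations") <- it
      return(params)
    }
    if (it < config$maxIterations) params <- .loosen(params, config)
  }
  warning("parameter adaptation hit maxIterations before reaching target")
  attr(params, "detected") <- count
  attr(params, "iterations") <- config$maxIterations
  params
}

#' SetParams actor for the subinit graph
#'
#' Holds the training frames in its state and, when fired, emits the
#' calibrated [blobParams()] on its (unconnected) output port
#' `params_out`, from which PSDF bindings deliver values into body-graph
#' actor parameters.
#'
#' @param name actor name.
#' @param trainingFrames list of preprocessed training frames.
#' @param config an [adaptConfig()].
#' @param d training proximity tolerance.
#' @return a [dfActor()].
#' @export
setParamsActor <- function(name, trainingFrames, config = adaptConfig(),
                           d = 2) {
  dfActor(name, outputs = "params_out",
          state = list(trainingFrames = trainingFrames, config = config,
                       d = d),
          fire = function(inputs, actor) {
            p <- adaptBlobParams(actor$state$trainingFrames,
                                 actor$state$config, actor$state$d)
            list(params_out = p)
          })
}
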