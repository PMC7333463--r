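## System-level graph: ImgSrc -> MotionCorrection -> Fork1 ->
## {SignalExtraction, Preprocess -> NeuronDetection -> Fork2 ->
## {SignalExtraction, detection sink}}, with SetParams in the subinit
## graph delivering calibrated blob parameters through PSDF bindings.

#' Pipeline configuration
#'
#' Bundles the per-actor configurations and run-mode switches.
#'
#' @param preproc a [preprocConfig()].
#' @param blob initial [blobParams()] (replaced by the subinit binding
#'   when initialization runs).
#' @param adapt an [adaptConfig()] for the SetParams actor.
#' @param d training proximity tolerance in pixels.
#' @param p1,p2,downsampleFactor,mcMaxShift motion-correction settings
#'   ([newMCState()]).
#' @param motionCorrection enable/disable the Motion Correction actor
#'   (disable for pre-registered input).
#' @param window,floor baseline parameters ([newBaselineState()]).
#' @param nTrainingFrames frames handed to SetParams for calibration.
#' @param keepCorrected keep corrected frames in the run result.
#' @return list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(preproc = preprocConfig(),
                           blob = preinitBlobParams(),
                           adapt = NULL, d = 2, p1 = 2, p2 = 10,
                           downsampleFactor = 2, mcMaxShift = 30,
                           motionCorrection = TRUE,
                           window = 50, floor = 1, nTrainingFrames = 100,
                           keepCorrected = FALSE) {
  if (is.null(adapt)) adapt <- adaptConfig(initialParams = blob)
  structure(list(preproc = preproc, blob = blob, adapt = adapt, d = d,
                 p1 = p1, p2 = p2, downsampleFactor = downsampleFactor,
                 mcMaxShift = mcMaxShift,
                 motionCorrection = motionCorrection, window = window,
                 floor = floor, nTrainingFrames = nTrainingFrames,
                 keepCorrected = keepCorrected),
            class = "pipelineConfig")
}

.framesAsList <- function(frames) {
  if (is.list(frames)) return(frames)
  if (is(frames, "SimulationBundle")) frames <- frames(frames)
  lapply(seq_len(dim(frames)[3]), function(t) {
    f <- frames[, , t]
    storage.mode(f) <- "double"
    f
  })
}

#' Build the body graph for a run
#'
#' @param frameList list of input frames.
#' @param config a [pipelineConfig()].
#' @param mode `"training"` or `"realtime"` detection mode.
#' @param delta frozen detection matrix for real-time runs.
#' @return a [dfGraph()] ready for [dfRunIteration()] / [runPSDF()].
#' @export
buildBodyGraph <- function(frameList, config, mode = "training",
                           delta = NULL) {
  src <- imgSrcActor("ImgSrc", frameList)

  mc <- dfActor("MotionCorrection", inputs = "in1", outputs = "out1",
                params = list(enabled = config$motionCorrection),
                state = list(mc = NULL, results = list()),
                fire = function(inputs, actor) {
                  f <- inputs$in1
                  if (!isTRUE(actor$params$enabled)) {
                    res <- list(frame = f,
                                warp = c(tx = 0, ty = 0, theta = 0),
                                correlation = 1, status = "disabled",
                                tau1 = NA, tau2 = NA,
                                frameIndex = length(actor$state$results) + 1L)
                  } else {
                    if (is.null(actor$state$mc)) {
                      actor$state$mc <- newMCState(
                        f, p1 = actor$params$p1, p2 = actor$params$p2,
                        downsampleFactor = actor$params$downsampleFactor,
                        maxShift = actor$params$maxShift)
                    }
                    res <- correctFrame(f, actor$state$mc, actor$graph,
                                        actor$name)
                    dfLog(actor$graph, actor$name, formatMCLogLine(res))
                  }
                  actor$state$results[[length(actor$state$results) + 1L]] <-
                    res[c("warp", "correlation", "status", "frameIndex")]
                  list(out1 = res$frame)
                })
  mc$params$p1 <- config$p1
  mc$params$p2 <- config$p2
  mc$params$downsampleFactor <- config$downsampleFactor
  mc$params$maxShift <- config$mcMaxShift

  fork1 <- forkActor("Fork1", 2L)

  pre <- dfActor("Preprocessing", inputs = "in1", outputs = "out1",
                 params = list(config = config$preproc),
                 fire = function(inputs, actor) {
                   list(out1 = preprocessFrame(inputs$in1,
                                               actor$params$config))
                 })

  det <- dfActor("NeuronDetection", inputs = "in1", outputs = "out1",
                 params = list(blob = config$blob),
                 state = list(ts = newTrainingState(d = config$d,
                                                    mode = mode)),
                 fire = function(inputs, actor) {
                   list(out1 = fireDetection(inputs$in1, actor$state$ts,
                                             actor$params$blob))
                 })
  if (!is.null(delta)) det$state$ts$deltaP <- delta

  fork2 <- forkActor("Fork2", 2L)

  sig <- dfActor("SignalExtraction", inputs = c("frame_in", "delta_in"),
                 outputs = "out1",
                 state = list(bs = newBaselineState(config$window,
                                                    config$floor)),
                 fire = function(inputs, actor) {
                   list(out1 = extractSignals(inputs$frame_in,
                                              inputs$delta_in,
                                              actor$state$bs))
                 })

  detSink <- sinkActor("DetectionOut")
  sigSink <- sinkActor("SignalOut")

  dfGraph(
    actors = list(src, mc, fork1, pre, det, fork2, sig, detSink, sigSink),
    edges = list(
      dfEdge(c("ImgSrc", "out1"), c("MotionCorrection", "in1")),
      dfEdge(c("MotionCorrection", "out1"), c("Fork1", "in1")),
      dfEdge(c("Fork1", "out1"), c("SignalExtraction", "frame_in")),
      dfEdge(c("Fork1", "out2"), c("Preprocessing", "in1")),
      dfEdge(c("Preprocessing", "out1"), c("NeuronDetection", "in1")),
      dfEdge(c("NeuronDetection", "out1"), c("Fork2", "in1")),
      dfEdge(c("Fork2", "out1"), c("SignalExtraction", "delta_in")),
      dfEdge(c("Fork2", "out2"), c("DetectionOut", "in1")),
      dfEdge(c("SignalExtraction", "out1"), c("SignalOut", "in1"))
    ),
    kind = "body"
  )
}

.collectRun <- function(graph, frameList, config) {
  mcRes <- graph$actors$MotionCorrection$state$results
  statuses <- vapply(mcRes, `[[`, "", "status")
  track <- data.frame(
    frame = seq_along(mcRes),
    tx = vapply(mcRes, function(r) unname(r$warp[1]), 0),
    ty = vapply(mcRes, function(r) unname(r$warp[2]), 0),
    theta = vapply(mcRes, function(r) unname(r$warp[3]), 0)
  )
  deltas <- graph$actors$DetectionOut$state$items
  betas <- graph$actors$SignalOut$state$items
  list(
    delta = if (length(deltas)) deltas[[length(deltas)]] else
      data.frame(x = numeric(0), y = numeric(0), radius = numeric(0)),
    signals = signalTable(betas),
    track = track,
    statuses = statuses,
    correlations = vapply(mcRes, `[[`, 0, "correlation"),
    log = runLog(graph),
    blobParams = graph$actors$NeuronDetection$params$blob
  )
}

#' Run initialization (training) mode
#'
#' Executes the PSDF pair: the subinit graph (a single SetParams actor)
#' calibrates the blob parameters on the first `nTrainingFrames`
#' motion-corrected, preprocessed frames, the calibrated values are
#' transmitted into the Neuron Detection actor through parameter
#' bindings, and the body graph then runs one iteration per frame with
#' detection in training mode, accumulating the persistent detection
#' matrix (signals are extracted throughout; columns for late-discovered
#' neurons are zero before discovery).
#'
#' @param frames input video: list of frames, H x W x T array, or a
#'   [SimulationBundle-class].
#' @param config a [pipelineConfig()].
#' @return list with elements delta (final detection matrix), signals,
#'   track, statuses, correlations, log, blobParams (calibrated), and
#'   optionally corrected (list of corrected frames when
#'   `config$keepCorrected`).
#' @export
runInitialization <- function(frames, config = pipelineConfig()) {
  frameList <- .framesAsList(frames)
  nTrain <- min(config$nTrainingFrames, length(frameList))
  ## training frames for SetParams: motion-corrected + preprocessed with
  ## an independent corrector (calibration must not disturb the run)
  calmc <- newMCState(frameList[[1]], p1 = config$p1, p2 = config$p2,
                      downsampleFactor = config$downsampleFactor,
                      maxShift = config$mcMaxShift)
  trainPre <- lapply(frameList[seq_len(nTrain)], function(f) {
    g <- if (config$motionCorrection) correctFrame(f, calmc)$frame else f
    preprocessFrame(g, config$preproc)
  })
  subinit <- dfGraph(list(setParamsActor("SetParams", trainPre,
                                         config$adapt, config$d)),
                     kind = "subinit")
  body <- buildBodyGraph(frameList, config, mode = "training")
  if (config$keepCorrected) .attachCorrectedCapture(body)
  runPSDF(body, subinit,
          bindings = list(list(port = "SetParams.params_out",
                               targets = list(c("NeuronDetection", "blob")))),
          nBodyIterations = length(frameList))
  out <- .collectRun(body, frameList, config)
  if (config$keepCorrected) {
    out$corrected <- body$actors$CorrectedOut$state$items
  }
  out
}

## Optional capture of corrected frames: widen Fork1 to fan-out 3 with a
## sink on the extra output.
.attachCorrectedCapture <- function(body) {
  corSink <- sinkActor("CorrectedOut")
  fork1 <- forkActor("Fork1", 3L)
  body$actors$Fork1$outputs <- fork1$outputs
  body$actors$Fork1$fire <- fork1$fire
  corSink$graph <- body
  body$actors$CorrectedOut <- corSink
  body$edges <- c(body$edges,
                  list(dfEdge(c("Fork1", "out3"), c("CorrectedOut", "in1"))))
  body$order <- .dfTopoOrder(body)
  invisible(body)
}

#' Run real-time mode
#'
#' The body graph runs one iteration per analysis frame with the
#' detection matrix frozen at its trained value (the subinit graph is
#' effectively disabled: the body iteration count equals the number of
#' analysis frames).
#'
#' @inheritParams runInitialization
#' @param delta frozen detection matrix from training.
#' @return as [runInitialization()].
#' @export
runRealtime <- function(frames, delta, config = pipelineConfig()) {
  frameList <- .framesAsList(frames)
  body <- buildBodyGraph(frameList, config, mode = "realtime", delta = delta)
  if (config$keepCorrected) .attachCorrectedCapture(body)
  runPSDF(body, subinit = NULL, bindings = list(),
          nBodyIterations = length(frameList))
  out <- .collectRun(body, frameList, config)
  if (config$keepCorrected) {
    out$corrected <- body$actors$CorrectedOut$state$items
  }
  out
}

#' One-call experiment: initialization followed by statistics
#'
#' Convenience wrapper used by the evaluation workflows: runs
#' initialization/training over the whole recording (the configuration
#' used for the simulated studies, where every frame contributes to
#' discovery) and returns the run result.
#'
#' @inheritParams runInitialization
#' @export
runExperiment <- function(frames, config = pipelineConfig()) {
  runInitialization(frames, config)
}
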