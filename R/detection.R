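## Neuron Detection actor: multi-threshold blob detection with size and
## shape filters, plus the training-mode accumulation of a persistent
## detection matrix.

#' Blob detector parameters
#'
#' The detector binarizes the frame at every threshold from
#' `minThreshold` (fixed at 0 in all standard configurations) to
#' `maxThreshold` in steps of `thresholdStep`, extracts connected
#' components at each level, filters them by pixel area (in
#' [`aMin`, `aMax`]) and shape (circularity, inertia ratio, convexity, all
#' in [0, 1]), and merges components across levels whose centres lie
#' within `minDist` pixels.  A blob's radius is the distance between its
#' centre and the furthest blob pixel from the centre.
#'
#' @param minThreshold,maxThreshold,thresholdStep binarization levels.
#' @param aMin,aMax blob area bounds in pixels (aMin < aMax).
#' @param circularityMin,inertiaMin,convexityMin shape filter minima.
#' @param minDist centre distance below which cross-threshold blobs merge.
#' @param minRepeatability minimum number of threshold levels at which a
#'   group must appear (2, the blob-detector convention; suppresses
#'   single-level noise specks).
#' @return list of class `blobParams`.
#' @export
blobParams <- function(minThreshold = 0, maxThreshold = 255,
                       thresholdStep = 10, aMin = 20, aMax = 400,
                       circularityMin = 0.5, inertiaMin = 0.3,
                       convexityMin = 0.5, minDist = 10,
                       minRepeatability = 2) {
  if (minThreshold < 0 || minThreshold >= maxThreshold) {
    stop("config error: need 0 <= minThreshold < maxThreshold")
  }
  if (thresholdStep <= 0) stop("config error: thresholdStep > 0")
  if (thresholdStep > maxThreshold - minThreshold) {
    stop("config error: thresholdStep exceeds threshold range")
  }
  if (aMin >= aMax) stop("config error: need aMin < aMax")
  structure(list(minThreshold = minThreshold, maxThreshold = maxThreshold,
                 thresholdStep = thresholdStep, aMin = aMin, aMax = aMax,
                 circularityMin = circularityMin, inertiaMin = inertiaMin,
                 convexityMin = convexityMin, minDist = minDist,
                 minRepeatability = minRepeatability),
            class = "blobParams")
}

## Connected components above one threshold with per-component
## statistics.  Returns a data.frame (x, y, radius, area, circularity,
## inertia, convexity); coordinates are 0-based (x = column, y = row),
## centres sub-pixel.  All statistics except convexity are computed
## vectorised over components; convexity (convex-hull based) is computed
## only for components that survive the other shape filters.
.blobsAtLevel <- function(frame, level, aMin, aMax, shapes = TRUE) {
  H <- nrow(frame)
  res <- cpp_blob_level(frame, level, aMin, aMax)
  st <- res$stats
  if (nrow(st) == 0) {
    return(data.frame(x = numeric(0), y = numeric(0), radius = numeric(0),
                      area = numeric(0), circularity = numeric(0),
                      inertia = numeric(0), convexity = numeric(0)))
  }
  area <- st[, 1]
  out <- data.frame(x = st[, 2], y = st[, 3], radius = st[, 4],
                    area = area, circularity = 1, inertia = 1,
                    convexity = 1)
  if (!shapes) return(out)
  ## inertia ratio: minor/major eigenvalue of the second central moments
  tr <- st[, 5] + st[, 6]
  disc <- sqrt(pmax(tr^2 / 4 - (st[, 5] * st[, 6] - st[, 7]^2), 0))
  lmax <- tr / 2 + disc
  out$inertia <- ifelse(lmax > 0, pmax(tr / 2 - disc, 0) / lmax, 1)
  ## circularity 4*pi*A/P^2 with P = boundary pixel count
  out$circularity <- ifelse(st[, 8] > 0,
                            pmin(4 * pi * area / st[, 8]^2, 1), 1)
  ## convexity: area / digital convex-hull pixel count
  out$convexity <- ifelse(st[, 9] > 0, pmin(area / st[, 9], 1), 1)
  out
}

#' Detect blobs in a preprocessed frame
#'
#' Multi-threshold blob detection (see [blobParams()]).  Components
#' passing the area and shape filters at each level are grouped across
#' levels by centre proximity; each group becomes one detection with
#' centre = mean of the grouped centres and radius = the furthest-point
#' distance of the largest contributing component.
#'
#' @param frame preprocessed frame (numeric matrix).
#' @param params a [blobParams()].
#' @return detection matrix: data.frame(x, y, radius), one row per
#'   detected neuron, 0-based sub-pixel coordinates.
#' @export
detectBlobs <- function(frame, params = blobParams()) {
  levels <- seq(params$minThreshold, params$maxThreshold,
                by = params$thresholdStep)
  ## running group accumulators (mean centre, repeat count, radius of the
  ## largest contributing component).  A group accepts at most one
  ## component per threshold level, so the repeat count is the number of
  ## distinct levels at which the blob was found.
  gn <- 0L
  gcx <- gcy <- gcnt <- gbest <- grad <- glv <- numeric(0)
  mind2 <- params$minDist^2
  for (lv in levels) {
    blobs <- .blobsAtLevel(frame, lv, params$aMin, params$aMax)
    if (nrow(blobs) == 0) next
    ok <- blobs$circularity >= params$circularityMin &
      blobs$inertia >= params$inertiaMin &
      blobs$convexity >= params$convexityMin
    blobs <- blobs[ok, , drop = FALSE]
    for (i in seq_len(nrow(blobs))) {
      gi <- 0L
      if (gn > 0L) {
        d2 <- (gcx[1:gn] / gcnt[1:gn] - blobs$x[i])^2 +
          (gcy[1:gn] / gcnt[1:gn] - blobs$y[i])^2
        d2[glv[1:gn] == lv] <- Inf  # one component per level per group
        w <- which.min(d2)
        if (d2[w] < mind2) gi <- w
      }
      if (gi > 0L) {
        gcx[gi] <- gcx[gi] + blobs$x[i]
        gcy[gi] <- gcy[gi] + blobs$y[i]
        gcnt[gi] <- gcnt[gi] + 1
        glv[gi] <- lv
        if (blobs$area[i] > gbest[gi]) {
          gbest[gi] <- blobs$area[i]
          grad[gi] <- blobs$radius[i]
        }
      } else {
        gn <- gn + 1L
        gcx[gn] <- blobs$x[i]; gcy[gn] <- blobs$y[i]; gcnt[gn] <- 1
        gbest[gn] <- blobs$area[i]; grad[gn] <- blobs$radius[i]
        glv[gn] <- lv
      }
    }
  }
  keep <- which(gcnt >= params$minRepeatability)
  if (length(keep) == 0) {
    return(data.frame(x = numeric(0), y = numeric(0), radius = numeric(0)))
  }
  data.frame(x = gcx[keep] / gcnt[keep], y = gcy[keep] / gcnt[keep],
             radius = grad[keep])
}

#' Training-mode state of the Neuron Detection actor
#'
#' @param d proximity tolerance in pixels: a new detection whose position
#'   differs from a persisted row by at most `d` in both x and y is a
#'   repeat of that neuron (the "slight motion" tolerance).
#' @param mode `"training"` or `"realtime"`.
#' @return an environment of class `trainingState` holding the persistent
#'   detection matrix `deltaP`.
#' @export
newTrainingState <- function(d = 2, mode = c("training", "realtime")) {
  mode <- match.arg(mode)
  s <- new.env(parent = emptyenv())
  s$deltaP <- data.frame(x = numeric(0), y = numeric(0), radius = numeric(0))
  s$d <- d
  s$mode <- mode
  class(s) <- "trainingState"
  s
}

#' Accumulate newly discovered neurons (training mode)
#'
#' Removes from `eta` every detection within the `d`-pixel box tolerance
#' of some persisted row, appends the survivors (newly discovered
#' neurons) to the persistent matrix, and returns the updated matrix.
#' The persistent matrix never shrinks during training.
#'
#' @param eta detection matrix from [detectBlobs()].
#' @param state a [newTrainingState()]; updated in place.
#' @return the updated persistent detection matrix.
#' @export
trainingUpdate <- function(eta, state) {
  stopifnot(state$mode == "training")
  dp <- state$deltaP
  if (nrow(eta) > 0 && nrow(dp) > 0) {
    repeats <- vapply(seq_len(nrow(eta)), function(i) {
      any(abs(dp$x - eta$x[i]) <= state$d & abs(dp$y - eta$y[i]) <= state$d)
    }, NA)
    eta <- eta[!repeats, , drop = FALSE]
  }
  if (nrow(eta) > 0) {
    state$deltaP <- rbind(dp, eta)
    rownames(state$deltaP) <- NULL
  }
  state$deltaP
}

#' One firing of the Neuron Detection actor
#'
#' Training mode: run [detectBlobs()] then [trainingUpdate()], emitting
#' the cumulative persistent matrix.  Real-time mode: emit the frozen
#' matrix from training (the neuron set is fixed after initialization;
#' per-frame detections are not re-matched).  With
#' `continueAccumulation = TRUE` real-time firings keep accumulating.
#'
#' @param frame preprocessed frame.
#' @param state a [newTrainingState()].
#' @param params a [blobParams()].
#' @param continueAccumulation allow real-time growth of the matrix.
#' @return the detection matrix to emit.
#' @export
fireDetection <- function(frame, state, params = blobParams(),
                          continueAccumulation = FALSE) {
  if (state$mode == "training" || continueAccumulation) {
    eta <- detectBlobs(frame, params)
    if (state$mode == "realtime") {
      state$mode <- "training"
      on.exit(state$mode <- "realtime")
    }
    return(trainingUpdate(eta, state))
  }
  if (nrow(state$deltaP) == 0) {
    warning("real-time firing before any training: empty detection matrix")
  }
  state$deltaP
}
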