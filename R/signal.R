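## Signal Extraction actor: per-neuron relative-intensity (delta-F/F)
## traces from motion-corrected frames and the detection matrix.

#' Pixels covered by a circular ROI
#'
#' All pixels whose centre lies within the circle (inclusive boundary).
#'
#' @param dim c(H, W) frame dimensions.
#' @param x,y 0-based centre coordinates.
#' @param radius circle radius in pixels; a radius below 1 covers at
#'   least the single nearest pixel.
#' @return 1-based integer indices into the H x W matrix.
#' @export
roiPixels <- function(dim, x, y, radius) {
  H <- dim[1]; W <- dim[2]
  x0 <- max(0, floor(x - radius)); x1 <- min(W - 1, ceiling(x + radius))
  y0 <- max(0, floor(y - radius)); y1 <- min(H - 1, ceiling(y + radius))
  if (x0 > x1 || y0 > y1) stop("ROI circle fully outside frame")
  xs <- rep(x0:x1, each = y1 - y0 + 1)
  ys <- rep(y0:y1, times = x1 - x0 + 1)
  inside <- (xs - x)^2 + (ys - y)^2 <= radius^2
  idx <- xs[inside] * H + ys[inside] + 1L
  if (length(idx) == 0) {
    ## degenerate disk: nearest pixel
    idx <- round(clamp(x, 0, W - 1)) * H + round(clamp(y, 0, H - 1)) + 1L
  }
  as.integer(idx)
}

#' Mean intensity over a circular ROI
#'
#' @param frame numeric matrix.
#' @inheritParams roiPixels
#' @return mean pixel value across all pixels in the circle.
#' @export
roiMean <- function(frame, x, y, radius) {
  mean(frame[roiPixels(dim(frame), x, y, radius)])
}

#' Initialize baseline state for streaming signal extraction
#'
#' The baseline F0 of neuron i at frame t is the mean of that neuron's
#' raw ROI means over the `window` frames immediately preceding t, after
#' excluding window values above 3x the window median (so calcium
#' transients do not inflate the baseline).  While the window is empty
#' beta is 0; the denominator of (F - F0)/F0 is floored at `floor`
#' intensity units so that a dark baseline cannot blow up - or zero
#' out - the trace.
#'
#' @param window baseline window length W in frames.
#' @param floor denominator floor (divide-by-zero guard).
#' @return an environment of class `baselineState`.
#' @export
newBaselineState <- function(window = 50, floor = 1) {
  s <- new.env(parent = emptyenv())
  s$window <- window
  s$floor <- floor
  s$history <- list()   # one numeric vector of past raw means per neuron
  s$firstSeen <- integer(0)
  s$frameIndex <- 0L
  class(s) <- "baselineState"
  s
}

.dffOne <- function(raw, history, window, floorv) {
  m <- length(history)
  if (m == 0) return(0)
  w <- tail(history, window)
  med <- median(w)
  keep <- if (med > 0) w[w <= 3 * med] else w
  if (length(keep) == 0) keep <- w
  f0 <- mean(keep)
  if (!is.finite(f0)) return(0)
  ## the denominator is floored: a dark baseline must not zero out the
  ## very onset transients the trace exists to report
  (raw - f0) / max(f0, floorv)
}

#' Extract the delta-F/F vector for one frame
#'
#' One firing of the Signal Extraction actor: for each neuron i in the
#' detection matrix, F(i) is the ROI mean in the motion-corrected frame
#' and beta[i] = (F(i) - F0)/F0 with the rolling baseline of
#' [newBaselineState()].  beta[i] is 0 before neuron i's first detection
#' (rows appended to the matrix mid-stream start their history at the
#' frame where they first appear).
#'
#' @param frame motion-corrected (unpreprocessed) frame.
#' @param delta detection matrix data.frame(x, y, radius).
#' @param state a [newBaselineState()]; updated in place.
#' @return numeric beta vector, one entry per detection-matrix row.
#' @export
extractSignals <- function(frame, delta, state) {
  state$frameIndex <- state$frameIndex + 1L
  n <- nrow(delta)
  beta <- numeric(n)
  if (n == 0) return(beta)
  for (i in seq_len(n)) {
    if (i > length(state$history)) {
      state$history[[i]] <- numeric(0)
      state$firstSeen[i] <- state$frameIndex
    }
    raw <- roiMean(frame, delta$x[i], delta$y[i], delta$radius[i])
    beta[i] <- .dffOne(raw, state$history[[i]], state$window, state$floor)
    h <- state$history[[i]]
    if (length(h) >= state$window) h <- h[-1]
    state$history[[i]] <- c(h, raw)
  }
  beta
}

#' Assemble a signal table from per-frame beta vectors
#'
#' @param betas list of beta vectors (possibly of growing length when the
#'   detection matrix grew during training).
#' @return matrix with one row per frame and one column per neuron
#'   (training discovery order); entries before a neuron's first
#'   detection are 0.
#' @export
signalTable <- function(betas) {
  L <- length(betas)
  nu <- if (L) max(vapply(betas, length, 0L)) else 0L
  out <- matrix(0, L, nu)
  for (k in seq_len(L)) {
    b <- betas[[k]]
    if (length(b)) out[k, seq_along(b)] <- b
  }
  colnames(out) <- if (nu) paste0("n", seq_len(nu)) else character(0)
  out
}

#' Bulk delta-F/F from raw ROI-mean traces
#'
#' Vectorised equivalent of running [extractSignals()] over a whole
#' recording: applies the same rolling-window baseline to each column of
#' a frames x ROIs matrix of raw ROI means.
#'
#' @param traces T x n matrix of raw ROI means.
#' @param window baseline window length.
#' @param floor F0 floor.
#' @return T x n matrix of delta-F/F values.
#' @export
dffFromTraces <- function(traces, window = 50, floor = 1) {
  cpp_dff_traces(as.matrix(traces), as.integer(window), floor)
}
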