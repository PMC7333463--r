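## Motion Correction actor: translation-first ECC alignment with selective
## Euclidean (translation + rotation) fallback, correlation-history
## adaptive acceptance thresholds (CoHisQ), reference-frame update on
## every acceptance, and failure logging.

#' Correlation history queue (CoHisQ)
#'
#' Ring buffer of the `capacity` most recent accepted frame correlations.
#' The running mean and standard deviation (population sd over the queue
#' contents) are maintained incrementally and are recomputed exactly when
#' requested via [cohisqStats()].
#'
#' @param capacity queue capacity (100 most recent values).
#' @return an environment of class `cohisq`.
#' @export
newCoHisQ <- function(capacity = 100L) {
  q <- new.env(parent = emptyenv())
  q$capacity <- as.integer(capacity)
  q$values <- numeric(0)
  q$sum <- 0
  q$sumsq <- 0
  class(q) <- "cohisq"
  q
}

#' Push an accepted correlation value into a CoHisQ
#' @param q a [newCoHisQ()].
#' @param value correlation in [-1, 1].
#' @export
pushCorrelation <- function(q, value) {
  if (length(q$values) == q$capacity) {
    old <- q$values[1]
    q$values <- q$values[-1]
    q$sum <- q$sum - old
    q$sumsq <- q$sumsq - old^2
  }
  q$values <- c(q$values, value)
  q$sum <- q$sum + value
  q$sumsq <- q$sumsq + value^2
  invisible(q)
}

#' Incremental mean and population sd of a CoHisQ
#' @param q a [newCoHisQ()].
#' @return c(n, mean, sd).
#' @export
cohisqStats <- function(q) {
  n <- length(q$values)
  if (n == 0L) return(c(n = 0, mean = NA_real_, sd = NA_real_))
  m <- q$sum / n
  v <- q$sumsq / n - m^2
  if (v < 1e-12) v <- 0  # cancellation guard for near-constant queues
  c(n = n, mean = m, sd = sqrt(v))
}

#' Adaptive acceptance threshold (correlation gate)
#'
#' tau = mean(CoHisQ) - p * sd(CoHisQ), with the population sd over the
#' current queue contents.  During warm-up (fewer than `warmupN` queued
#' values) a fixed floor is returned, at the low end of the correlation
#' range observed in successful corrections.
#'
#' @param q a [newCoHisQ()].
#' @param p threshold multiplier (2 for the translation gate, 10 for the
#'   Euclidean gate; the larger multiplier gives the strictly looser gate
#'   whenever sd > 0).
#' @param warmupN queue length below which the floor applies.
#' @param floor warm-up threshold value.
#' @return threshold tau.
#' @export
adaptiveThreshold <- function(q, p, warmupN = 10L, floor = 0.3) {
  st <- cohisqStats(q)
  if (st[1] < warmupN) return(floor)
  unname(st[2] - p * st[3])
}

#' Pearson correlation between two frames
#'
#' Zero-mean normalized correlation over all pixels; defined as 0 when
#' either frame is constant.
#'
#' @param a,b numeric matrices of identical shape.
#' @param mask optional logical matrix restricting the correlation to
#'   valid pixels (used to ignore the zero-filled band of realigned
#'   frames).
#' @return correlation in [-1, 1].
#' @export
frameCorrelation <- function(a, b, mask = NULL) {
  if (!all(dim(a) == dim(b))) stop("structural error: shape mismatch")
  if (is.null(mask)) {
    av <- as.vector(a); bv <- as.vector(b)
  } else {
    av <- a[mask]; bv <- b[mask]
    if (length(av) < 16) return(0)
  }
  n <- length(av)
  ma <- sum(av) / n; mb <- sum(bv) / n
  va <- sum(av * av) / n - ma^2
  vb <- sum(bv * bv) / n - mb^2
  if (va <= 0 || vb <= 0) return(0)
  r <- (sum(av * bv) / n - ma * mb) / sqrt(va * vb)
  min(max(r, -1), 1)
}

#' Initialize motion-correction state
#'
#' @param referenceFrame initial reference frame F_r (the first analysis
#'   frame).
#' @param p1,p2 threshold multipliers for the translation and Euclidean
#'   gates; must satisfy p1 < p2.
#' @param downsampleFactor estimation-only downsample factor (>= 1).
#' @param minShift,minAngle "motion detected" predicate: a warp counts as
#'   motion when |tx| or |ty| >= minShift pixels or |theta| >= minAngle
#'   degrees.
#' @param maxIter,eps ECC iteration cap and convergence tolerance.
#' @param maxShift largest plausible per-axis translation in pixels
#'   (see [eccAlign()]); configure to the rig's motion range.
#' @param warmupFloor1,warmupFloor2 gate values used while CoHisQ holds
#'   fewer than 10 entries.  The translation gate warms up strict (0.85)
#'   so that frames that translation-only alignment cannot explain fall
#'   through to the Euclidean stage instead of corrupting the reference;
#'   the Euclidean accept gate warms up at 0.3, the low end of the
#'   correlation range observed in successful corrections.
#' @return an environment of class `mcState`.
#' @export
newMCState <- function(referenceFrame, p1 = 2, p2 = 10,
                       downsampleFactor = 2, minShift = 0.5,
                       minAngle = 0.05, maxIter = 50, eps = 1e-4,
                       warmupFloor1 = 0.85, warmupFloor2 = 0.3,
                       maxShift = 30) {
  if (p1 >= p2) stop("config error: p1 must be < p2")
  if (downsampleFactor < 1) stop("config error: downsampleFactor >= 1")
  s <- new.env(parent = emptyenv())
  s$ref <- referenceFrame
  s$refMask <- matrix(TRUE, nrow(referenceFrame), ncol(referenceFrame))
  s$cohisq <- newCoHisQ(100L)
  s$p1 <- p1; s$p2 <- p2
  s$downsampleFactor <- downsampleFactor
  s$minShift <- minShift; s$minAngle <- minAngle
  s$maxIter <- maxIter; s$eps <- eps
  s$warmupFloor1 <- warmupFloor1; s$warmupFloor2 <- warmupFloor2
  s$maxShift <- maxShift
  s$frameIndex <- 0L
  s$failStreak <- 0L
  s$reseedAfter <- 10L
  class(s) <- "mcState"
  s
}

.motionDetected <- function(warp, state) {
  isTRUE(warp$converged) &&
    (abs(warp$tx) >= state$minShift || abs(warp$ty) >= state$minShift ||
       abs(warp$theta) >= state$minAngle)
}

## Valid-pixel mask of alignRigid(frame, tx, ty, theta): for pure
## translations the region is a rectangle, computed analytically; for
## rotations the unit image is warped.
.warpValidMask <- function(dim, tx, ty, theta) {
  H <- dim[1]; W <- dim[2]
  if (theta == 0) {
    m <- matrix(FALSE, H, W)
    x0 <- max(0, ceiling(-tx)); x1 <- min(W - 1, floor(W - 1 - tx))
    y0 <- max(0, ceiling(-ty)); y1 <- min(H - 1, floor(H - 1 - ty))
    if (x0 <= x1 && y0 <= y1) m[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1)] <- TRUE
    return(m)
  }
  alignRigid(matrix(1, H, W), tx, ty, theta) > 0.999
}

#' Motion-correct one frame
#'
#' One firing of the Motion Correction actor: (1) translation-only ECC
#' estimate; if motion is detected the shifted frame F_s is formed and
#' C1 = corr(F_s, F_r) evaluated, otherwise C1 = corr(F_c, F_r); (2) if
#' C1 >= tau1 the result is accepted, F_r is replaced by the accepted
#' frame and C1 is pushed into CoHisQ; (3) otherwise the costlier
#' Euclidean estimate runs, giving F_s' and C2, accepted against the
#' looser gate tau2; (4) otherwise the firing fails: a diagnostic
#' "motion correction failed at frame k" is recorded and the reference
#' frame F_r is produced as output.
#'
#' @param frame current frame F_c.
#' @param state a [newMCState()]; updated in place.
#' @param graph optional [dfGraph()] whose log receives diagnostics.
#' @param actorName name used in log lines.
#' @return list of class `mcResult`: frame (corrected output), warp
#'   (c(tx, ty, theta)), correlation, status (one of `"no_motion"`,
#'   `"translation_ok"`, `"euclidean_ok"`, `"failed"`), tau1, tau2,
#'   frameIndex.
#' @export
correctFrame <- function(frame, state, graph = NULL, actorName = "MC") {
  state$frameIndex <- state$frameIndex + 1L
  k <- state$frameIndex
  tau1 <- adaptiveThreshold(state$cohisq, state$p1,
                            floor = state$warmupFloor1)
  tau2 <- adaptiveThreshold(state$cohisq, state$p2,
                            floor = state$warmupFloor2)
  dimF <- dim(frame)
  wT <- eccAlign(frame, state$ref, "translation",
                 downsampleFactor = state$downsampleFactor,
                 maxIter = state$maxIter, eps = state$eps,
                 refMask = state$refMask, maxShift = state$maxShift)
  if (.motionDetected(wT, state)) {
    fs <- alignRigid(frame, wT$tx, wT$ty, 0)
    fsMask <- .warpValidMask(dimF, wT$tx, wT$ty, 0)
    c1 <- frameCorrelation(fs, state$ref, state$refMask & fsMask)
    accepted <- fs
    warp <- c(tx = wT$tx, ty = wT$ty, theta = 0)
    status <- "translation_ok"
  } else {
    fsMask <- matrix(TRUE, dimF[1], dimF[2])
    c1 <- frameCorrelation(frame, state$ref, state$refMask)
    accepted <- frame
    warp <- c(tx = 0, ty = 0, theta = 0)
    status <- "no_motion"
  }
  if (c1 >= tau1) {
    state$ref <- accepted
    state$refMask <- fsMask
    state$failStreak <- 0L
    pushCorrelation(state$cohisq, c1)
    res <- list(frame = accepted, warp = warp, correlation = c1,
                status = status, tau1 = tau1, tau2 = tau2, frameIndex = k)
  } else {
    wE <- eccAlign(frame, state$ref, "euclidean",
                   downsampleFactor = state$downsampleFactor,
                   maxIter = state$maxIter, eps = state$eps,
                   refMask = state$refMask, maxShift = state$maxShift)
    if (.motionDetected(wE, state)) {
      fs2 <- alignRigid(frame, wE$tx, wE$ty, wE$theta)
      fs2Mask <- .warpValidMask(dimF, wE$tx, wE$ty, wE$theta)
      warp2 <- c(tx = wE$tx, ty = wE$ty, theta = wE$theta)
    } else {
      fs2 <- frame
      fs2Mask <- matrix(TRUE, dimF[1], dimF[2])
      warp2 <- c(tx = 0, ty = 0, theta = 0)
    }
    c2 <- frameCorrelation(fs2, state$ref, state$refMask & fs2Mask)
    if (c2 >= tau2) {
      state$ref <- fs2
      state$refMask <- fs2Mask
      state$failStreak <- 0L
      pushCorrelation(state$cohisq, c2)
      res <- list(frame = fs2, warp = warp2, correlation = c2,
                  status = "euclidean_ok", tau1 = tau1, tau2 = tau2,
                  frameIndex = k)
    } else {
      msg <- sprintf("motion correction failed at frame %d", k)
      if (!is.null(graph)) dfLog(graph, actorName, msg)
      res <- list(frame = state$ref, warp = c(tx = NA_real_, ty = NA_real_,
                                              theta = NA_real_),
                  correlation = c2, status = "failed", tau1 = tau1,
                  tau2 = tau2, frameIndex = k)
      ## sustained failure (e.g. the scene went dark, or the stream
      ## jumped): restart alignment from the current frame so the
      ## corrector can recover; the new epoch is logged
      state$failStreak <- state$failStreak + 1L
      if (state$failStreak >= state$reseedAfter) {
        state$ref <- frame
        state$refMask <- matrix(TRUE, dimF[1], dimF[2])
        state$failStreak <- 0L
        if (!is.null(graph)) {
          dfLog(graph, actorName,
                sprintf("reference reseeded at frame %d", k))
        }
      }
    }
  }
  class(res) <- "mcResult"
  res
}

#' Format a motion-correction log line
#'
#' One line per event:
#' `frame=<k> status=<s> corr=<c> tau1=<t1> tau2=<t2> tx=<tx> ty=<ty> theta=<th>`.
#'
#' @param res an `mcResult` from [correctFrame()].
#' @return character line.
#' @export
formatMCLogLine <- function(res) {
  sprintf("frame=%d status=%s corr=%.6f tau1=%.6f tau2=%.6f tx=%.4f ty=%.4f theta=%.5f",
          res$frameIndex, res$status, res$correlation, res$tau1, res$tau2,
          res$warp[1], res$warp[2], res$warp[3])
}
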