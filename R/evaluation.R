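## Metrics harness: motion-correction error, pixel-level detection
## accuracy and trace signal-to-noise against simulator ground truth.

#' Motion-correction error report
#'
#' Per-frame absolute displacement and angle errors between an estimated
#' and a ground-truth motion track.  Means and maxima are computed over
#' successfully corrected frames only: failed frames are excluded from
#' the error averages and counted in the failure rate.
#'
#' @param estimated data.frame(frame, tx, ty, theta) recovered track.
#' @param truth data.frame(frame, tx, ty, theta) injected track.
#' @param statuses character vector of per-frame statuses from
#'   [correctFrame()]; frames with status "failed" are excluded.
#' @return list of class `motionErrorReport`: per-frame errors (mx, my,
#'   mrot with NA at failures), meanMx, maxMx, meanMy, maxMy, meanMrot,
#'   maxMrot, rateFail (percent).
#' @export
motionError <- function(estimated, truth, statuses = NULL) {
  if (nrow(estimated) != nrow(truth)) {
    stop("structural error: track length mismatch")
  }
  if (is.null(statuses)) statuses <- rep("ok", nrow(truth))
  ok <- statuses != "failed"
  mx <- abs(estimated$tx - truth$tx)
  my <- abs(estimated$ty - truth$ty)
  mrot <- abs(estimated$theta - truth$theta)
  mx[!ok] <- NA; my[!ok] <- NA; mrot[!ok] <- NA
  structure(list(
    mx = mx, my = my, mrot = mrot,
    meanMx = mean(mx, na.rm = TRUE), maxMx = suppressWarnings(max(mx, na.rm = TRUE)),
    meanMy = mean(my, na.rm = TRUE), maxMy = suppressWarnings(max(my, na.rm = TRUE)),
    meanMrot = mean(mrot, na.rm = TRUE),
    maxMrot = suppressWarnings(max(mrot, na.rm = TRUE)),
    rateFail = 100 * sum(!ok) / length(ok)
  ), class = "motionErrorReport")
}

#' F1 score from precision and recall
#'
#' @param u precision; @param v recall.
#' @return harmonic mean 2uv/(u+v) (0 when both are 0).
#' @export
f1Score <- function(u, v) {
  ifelse(u + v == 0, 0, 2 * u * v / (u + v))
}

#' Match detections to ground-truth masks
#'
#' Greedy one-to-one matching: a detection is a candidate match for a
#' mask when its (rounded) centre lies inside the mask; candidate pairs
#' are assigned nearest-first by centre-to-mask-centroid distance.
#'
#' @param delta detection matrix data.frame(x, y, radius).
#' @param masks a `maskSet`.
#' @return data.frame(detection, mask, dist) of matched pairs.
#' @export
matchDetections <- function(delta, masks) {
  H <- masks$dim[1]
  pairs <- list()
  for (i in seq_len(nrow(delta))) {
    px <- round(delta$x[i]); py <- round(delta$y[i])
    if (px < 0 || py < 0 || px >= masks$dim[2] || py >= H) next
    idx <- px * H + py + 1
    for (j in seq_along(masks$pix)) {
      if (idx %in% masks$pix[[j]]) {
        d <- sqrt((delta$x[i] - masks$info$cx[j])^2 +
                    (delta$y[i] - masks$info$cy[j])^2)
        pairs[[length(pairs) + 1L]] <- c(i, j, d)
      }
    }
  }
  if (length(pairs) == 0) {
    return(data.frame(detection = integer(0), mask = integer(0),
                      dist = numeric(0)))
  }
  pm <- do.call(rbind, pairs)
  pm <- pm[order(pm[, 3]), , drop = FALSE]
  usedD <- logical(nrow(delta)); usedM <- logical(length(masks$pix))
  keep <- logical(nrow(pm))
  for (k in seq_len(nrow(pm))) {
    i <- pm[k, 1]; j <- pm[k, 2]
    if (!usedD[i] && !usedM[j]) {
      usedD[i] <- TRUE; usedM[j] <- TRUE
      keep[k] <- TRUE
    }
  }
  pm <- pm[keep, , drop = FALSE]
  data.frame(detection = as.integer(pm[, 1]), mask = as.integer(pm[, 2]),
             dist = pm[, 3])
}

#' Pixel-level detection accuracy
#'
#' Matches detected circles to ground-truth masks one-to-one (see
#' [matchDetections()]), then scores pixel overlap.  With
#' `pooled = TRUE` (default) recall is the summed matched-pixel count
#' divided by the total ground-truth pixel count and precision the
#' summed matched-pixel count divided by the total detected-circle pixel
#' count; `pooled = FALSE` averages per matched neuron.
#'
#' @param delta detection matrix.
#' @param masks ground-truth `maskSet`.
#' @param activeMasks optional indices of active (detectable) masks; the
#'   detection rate is matched-active / active x 100.
#' @param pooled pool pixels across neurons or average per neuron.
#' @return list of class `detectionScore`: precision u, recall v, f1,
#'   matches, detectionRate.
#' @export
detectionScore <- function(delta, masks, activeMasks = NULL, pooled = TRUE) {
  m <- matchDetections(delta, masks)
  circPix <- lapply(seq_len(nrow(delta)), function(i) {
    roiPixels(masks$dim, delta$x[i], delta$y[i], delta$radius[i])
  })
  if (is.null(activeMasks)) activeMasks <- seq_along(masks$pix)
  inter <- integer(nrow(m))
  recalls <- precisions <- numeric(nrow(m))
  for (k in seq_len(nrow(m))) {
    ci <- circPix[[m$detection[k]]]
    mi <- masks$pix[[m$mask[k]]]
    inter[k] <- length(intersect(ci, mi))
    recalls[k] <- inter[k] / length(mi)
    precisions[k] <- inter[k] / length(ci)
  }
  if (pooled) {
    totTruth <- sum(lengths(masks$pix))
    totDet <- sum(lengths(circPix))
    v <- if (totTruth > 0) sum(inter) / totTruth else 0
    u <- if (totDet > 0) sum(inter) / totDet else 0
  } else {
    v <- if (length(recalls)) mean(recalls) else 0
    u <- if (length(precisions)) mean(precisions) else 0
  }
  matchedActive <- sum(m$mask %in% activeMasks)
  structure(list(u = u, v = v, f1 = f1Score(u, v), matches = m,
                 detectionRate = 100 * matchedActive / length(activeMasks)),
            class = "detectionScore")
}

#' Trace signal-to-noise against a random-region null
#'
#' R_s is the mean Pearson correlation between each matched neuron's
#' extracted delta-F/F trace and its ground-truth spike train.  The null
#' R_n repeats, `nRep` times, the draw of one random same-radius circular
#' region per neuron (overlapping any truth mask by at most 20% of its
#' pixels), extracts that region's delta-F/F from the corrected frames
#' with the same baseline rule, and correlates it with the neuron's spike
#' train; R_n is the grand mean.  Degenerate (constant) traces contribute
#' a correlation of 0.  snrDb = 10 log10(R_s / R_n), reported as NA
#' (undefined) when R_n <= 0.
#'
#' @param signals L x nu delta-F/F matrix from the pipeline.
#' @param spikeTrains nNeurons x T ground-truth spike matrix.
#' @param frames corrected video as an H x W x T array (or npix x T
#'   matrix) used for random-region traces.
#' @param masks truth `maskSet`.
#' @param matches data.frame(detection, mask) linking signal columns to
#'   spike rows (from [matchDetections()]).
#' @param delta detection matrix (for region radii).
#' @param nRep number of random-region repetitions (1000).
#' @param seed RNG seed for region draws.
#' @param window,floor baseline parameters, as used by the pipeline.
#' @param maxOverlap maximum fraction of region pixels allowed on masks.
#' @return list of class `snrReport`: rs, rn, snrDb, nRep.
#' @export
snrReport <- function(signals, spikeTrains, frames, masks, matches, delta,
                      nRep = 1000, seed = 1, window = 50, floor = 1,
                      maxOverlap = 0.2) {
  H <- masks$dim[1]; W <- masks$dim[2]
  if (length(dim(frames)) == 3) {
    dim(frames) <- c(H * W, dim(frames)[3])
  }
  if (!is.double(frames)) storage.mode(frames) <- "double"
  T <- ncol(frames)
  corr0 <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0) return(0)
    cor(a, b)
  }
  rsVals <- vapply(seq_len(nrow(matches)), function(k) {
    tr <- signals[, matches$detection[k]]
    sp <- spikeTrains[matches$mask[k], seq_len(nrow(signals))]
    corr0(tr, sp)
  }, 0)
  rs <- mean(rsVals)
  maskAll <- logical(H * W)
  maskAll[unlist(masks$pix)] <- TRUE
  .withSeed(seed, {
    repMeans <- numeric(nRep)
    radii <- delta$radius[matches$detection]
    spRows <- lapply(seq_len(nrow(matches)), function(k) {
      spikeTrains[matches$mask[k], seq_len(T)]
    })
    for (r in seq_len(nRep)) {
      vals <- numeric(nrow(matches))
      for (k in seq_len(nrow(matches))) {
        rad <- radii[k]
        repeat {
          cx <- runif(1, rad, W - 1 - rad)
          cy <- runif(1, rad, H - 1 - rad)
          idx <- roiPixels(c(H, W), cx, cy, rad)
          if (mean(maskAll[idx]) <= maxOverlap) break
        }
        raw <- cpp_roi_trace(frames, idx)
        dff <- cpp_dff_traces(matrix(raw, ncol = 1), as.integer(window),
                              floor)[, 1]
        vals[k] <- corr0(dff, spRows[[k]])
      }
      repMeans[r] <- mean(vals)
    }
    rn <- mean(repMeans)
    structure(list(rs = rs, rn = rn,
                   snrDb = if (rn > 0) 10 * log10(rs / rn) else NA_real_,
                   nRep = nRep, repMeans = repMeans),
              class = "snrReport")
  })
}

#' Frame-by-frame RMSE between two videos
#'
#' @param a,b H x W x T arrays of identical shape.
#' @return numeric vector of per-frame root-mean-square pixel differences.
#' @export
framewiseRMSE <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("structural error: shape mismatch")
  T <- dim(a)[3]
  vapply(seq_len(T), function(t) {
    sqrt(mean((a[, , t] - b[, , t])^2))
  }, 0)
}
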