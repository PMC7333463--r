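## Enhanced-correlation-coefficient (ECC) rigid image alignment.
## estimate-only: eccAlign() never modifies frames.  The estimator works
## on downsampled copies (estimation-only downsampling; translations are
## rescaled to full resolution), seeds the iteration with an FFT
## integer-shift cross-correlation (plus a coarse rotation sweep for the
## Euclidean model), then maximizes the enhanced correlation coefficient
## by forward-additive Gauss-Newton updates.

## Integer-shift estimate via FFT cross-correlation of mean-subtracted
## images; returns c(tx, ty, score).  Pixels where `mask` is FALSE
## (e.g. the zero-filled band of a previously warped reference) are
## excluded from the reference side.
.fftShift <- function(cur, ref, mask = NULL, maxShift = Inf) {
  H <- nrow(ref); W <- ncol(ref)
  if (is.null(mask)) {
    a <- ref - mean(ref)
  } else {
    a <- (ref - mean(ref[mask])) * mask
  }
  b <- cur - mean(cur)
  cc <- Re(fft(fft(b) * Conj(fft(a)), inverse = TRUE)) / (H * W)
  if (is.finite(maxShift)) {
    ## suppress implausibly large shifts before picking the peak
    sy <- c(0:(H - 1)); sy[sy > H / 2] <- sy[sy > H / 2] - H
    sx <- c(0:(W - 1)); sx[sx > W / 2] <- sx[sx > W / 2] - W
    cc[abs(sy) > maxShift, ] <- -Inf
    cc[, abs(sx) > maxShift] <- -Inf
  }
  pk <- arrayInd(which.max(cc), dim(cc))
  sy <- pk[1] - 1L; sx <- pk[2] - 1L
  if (sy > H / 2) sy <- sy - H
  if (sx > W / 2) sx <- sx - W
  denom <- sqrt(sum(a^2) * sum(b^2))
  score <- if (denom > 0) max(cc) / denom else 0
  c(tx = sx, ty = sy, score = score)
}

## FFT shift estimate on a 2x block-mean coarsening of the inputs; the
## returned shift is rescaled to the input resolution.
.fftShiftCoarse <- function(cur, ref, mask = NULL, maxShift = Inf) {
  curC <- cpp_block_mean(cur, 2L)
  refC <- cpp_block_mean(ref, 2L)
  maskC <- if (is.null(mask)) NULL else cpp_block_mean(mask + 0, 2L) > 0.999
  if (!is.null(maskC) && mean(maskC) < 0.25) maskC <- NULL
  est <- .fftShift(curC, refC, maskC, maxShift / 2)
  c(est[1] * 2, est[2] * 2, est[3])
}

## Central-difference gradients, replicated borders.
.gradients <- function(img) {
  H <- nrow(img); W <- ncol(img)
  gx <- (img[, c(2:W, W)] - img[, c(1, 1:(W - 1))]) / 2
  gy <- (img[c(2:H, H), ] - img[c(1, 1:(H - 1)), ]) / 2
  list(gx = gx, gy = gy)
}

## One ECC Gauss-Newton solve at a fixed resolution, with backtracking
## step control (a proposed update that lowers the correlation
## coefficient is halved up to four times, which prevents the
## overshoot oscillation that plain forward-additive updates exhibit on
## sharp sparse scenes).  Returns the warp parameters
## p = (tx, ty, theta[deg]), the final enhanced correlation coefficient
## rho, and a convergence flag.
.eccRefine <- function(cur, ref, p0, model, maxIter, eps, mask = NULL) {
  H <- nrow(ref); W <- ncol(ref)
  ctr <- frameCenter(ref)
  xs <- rep(0:(W - 1), each = H)
  ys <- rep(0:(H - 1), times = W)
  u <- xs - ctr[1]; v <- ys - ctr[2]
  gr <- .gradients(cur)
  tmpl <- as.vector(ref)
  maskv <- if (is.null(mask)) rep(TRUE, H * W) else as.vector(mask)

  ## evaluate rho (and the pieces needed for a Gauss-Newton step) at p
  evalAt <- function(p, needStep = TRUE) {
    th <- p[3] * pi / 180
    ct <- cos(th); st <- sin(th)
    wx <- ct * u - st * v + ctr[1] + p[1]
    wy <- st * u + ct * v + ctr[2] + p[2]
    iw <- cpp_bilinear_sample(cur, wx, wy)
    ok <- !is.na(iw) & maskv
    if (sum(ok) < 64) return(NULL)
    ir <- tmpl[ok]; ir <- ir - mean(ir)
    iwz <- iw[ok]; iwz <- iwz - mean(iwz)
    nIr <- sqrt(sum(ir^2)); nIw <- sqrt(sum(iwz^2))
    if (nIr == 0 || nIw == 0) return(NULL)
    corrv <- sum(ir * iwz)
    out <- list(rho = corrv / (nIr * nIw))
    if (!needStep) return(out)
    gxw <- cpp_bilinear_sample(gr$gx, wx[ok], wy[ok])
    gyw <- cpp_bilinear_sample(gr$gy, wx[ok], wy[ok])
    gxw[is.na(gxw)] <- 0; gyw[is.na(gyw)] <- 0
    J <- if (model == "translation") {
      cbind(gxw, gyw)
    } else {
      dthx <- (-st * u[ok] - ct * v[ok]) * pi / 180
      dthy <- (ct * u[ok] - st * v[ok]) * pi / 180
      cbind(gxw, gyw, gxw * dthx + gyw * dthy)
    }
    Hinv <- tryCatch(solve(crossprod(J)), error = function(e) NULL)
    if (is.null(Hinv)) return(out)
    imgProj <- crossprod(J, iwz)
    tmplProj <- crossprod(J, ir)
    lambdaN <- sum(iwz^2) - t(imgProj) %*% Hinv %*% imgProj
    lambdaD <- corrv - t(tmplProj) %*% Hinv %*% imgProj
    if (lambdaD[1] <= 0) return(out)  # ECC criterion divergence
    err <- (lambdaN[1] / lambdaD[1]) * ir - iwz
    dp <- as.vector(Hinv %*% crossprod(J, err))
    if (model == "translation") dp <- c(dp, 0)
    out$dp <- dp
    out
  }

  p <- p0
  converged <- FALSE
  curEval <- evalAt(p)
  if (is.null(curEval)) return(list(p = p, rho = 0, converged = FALSE))
  for (iter in seq_len(maxIter)) {
    if (is.null(curEval$dp)) break
    dp <- curEval$dp
    cand <- NULL
    for (half in 1:4) {
      cand <- evalAt(p + dp)
      if (!is.null(cand) && cand$rho >= curEval$rho - 1e-9) break
      dp <- dp / 2
      cand <- NULL
    }
    if (is.null(cand)) {  # no improving step: treat as converged locally
      converged <- TRUE
      break
    }
    p <- p + dp
    if (abs(cand$rho - curEval$rho) < eps) {
      curEval <- cand
      converged <- TRUE
      break
    }
    curEval <- cand
  }
  list(p = p, rho = curEval$rho, converged = converged)
}

#' Estimate a rigid warp between two frames (ECC)
#'
#' Estimates the warp W(x) = R(theta)(x - c) + c + t maximizing the
#' enhanced correlation coefficient between the reference frame and the
#' warped current frame: when the current frame is the reference moved by
#' [applyRigidMotion()] with (tx, ty, theta), the same (tx, ty, theta) is
#' recovered.  Estimation runs on copies downsampled by
#' `downsampleFactor` per axis; returned translations are rescaled to
#' full resolution.  The frames themselves are never modified.
#'
#' @param cur current frame F_c (numeric matrix).
#' @param ref reference frame F_r, same shape.
#' @param model `"translation"` (translation-only) or `"euclidean"`
#'   (translation + rotation).
#' @param downsampleFactor linear shrink factor (>= 1) for estimation.
#' @param maxIter ECC iteration cap.
#' @param eps convergence tolerance on the correlation coefficient.
#' @param thetaMax,thetaStep coarse rotation sweep bound/step (degrees)
#'   used to seed the Euclidean model.
#' @param refMask optional logical matrix marking valid reference pixels;
#'   pixels outside the mask (the zero-filled band left by a previous
#'   realignment of the reference) are excluded from estimation.
#' @param maxShift largest plausible per-axis translation in full-
#'   resolution pixels; shift candidates beyond it are suppressed and an
#'   estimate exceeding it is flagged unreliable.
#' @return list of class `warpParams`: tx, ty, theta (degrees), model,
#'   rho (final ECC value on the downsampled grid), converged.
#'   Non-convergence flags the warp unreliable; downstream correlation
#'   gates absorb it.
#' @export
eccAlign <- function(cur, ref, model = c("translation", "euclidean"),
                     downsampleFactor = 2, maxIter = 50, eps = 1e-4,
                     thetaMax = 10, thetaStep = 2, refMask = NULL,
                     maxShift = 30) {
  model <- match.arg(model)
  if (!all(dim(cur) == dim(ref))) stop("structural error: shape mismatch")
  f <- downsampleFactor
  curD <- downsampleFrame(cur, f)
  refD <- downsampleFrame(ref, f)
  maskD <- if (is.null(refMask)) NULL else {
    downsampleFrame(refMask + 0, f) > 0.999
  }
  if (!is.null(maskD) && mean(maskD) < 0.25) maskD <- NULL  # degenerate
  if (sd(curD) == 0 || sd(refD) == 0) {
    return(structure(list(tx = 0, ty = 0, theta = 0, model = model,
                          rho = 0, converged = FALSE),
                     class = "warpParams"))
  }
  if (model == "translation") {
    ## integer init on a further 2x-coarsened grid (cheap FFT), refined
    ## by ECC at the estimation resolution
    init <- .fftShiftCoarse(curD, refD, maskD, maxShift / f)
    fit <- .eccRefine(curD, refD, c(init[1], init[2], 0), "translation",
                      maxIter, eps, maskD)
  } else {
    ## coarse sweep over rotation, each with its best integer shift
    ctr <- frameCenter(curD)
    best <- NULL
    for (th in seq(-thetaMax, thetaMax, by = thetaStep)) {
      rot <- cpp_sample_rigid(curD, 0, 0, th, ctr[1], ctr[2], 0)
      cand <- .fftShiftCoarse(rot, refD, maskD, maxShift / f)
      if (is.null(best) || cand[3] > best$score) {
        ## shift found between rotated-current and ref composes with the
        ## rotation: W = shift o rotation => t = R(th) applied first
        best <- list(theta = th, tx = cand[1], ty = cand[2],
                     score = cand[3])
      }
    }
    thr <- best$theta * pi / 180
    t0 <- c(cos(thr) * best$tx - sin(thr) * best$ty,
            sin(thr) * best$tx + cos(thr) * best$ty)
    fit <- .eccRefine(curD, refD, c(t0[1], t0[2], best$theta),
                      "euclidean", maxIter, eps, maskD)
  }
  conv <- fit$converged &&
    abs(fit$p[1] * f) <= maxShift && abs(fit$p[2] * f) <= maxShift
  structure(list(tx = fit$p[1] * f, ty = fit$p[2] * f,
                 theta = if (model == "translation") 0 else fit$p[3],
                 model = model, rho = fit$rho, converged = conv),
            class = "warpParams")
}
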