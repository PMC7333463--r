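## Small shared helpers. Frames are numeric matrices indexed [row, col] =
## [y, x]; pixel coordinates are 0-based with x = column, y = row, so pixel
## (x, y) lives at frame[y + 1, x + 1].

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Geometric centre of a frame
#'
#' Rotation in this package is always applied about the image centre,
#' defined as ((W-1)/2, (H-1)/2) in 0-based (x, y) pixel coordinates.
#'
#' @param frame numeric matrix.
#' @return numeric vector c(cx, cy).
#' @export
frameCenter <- function(frame) {
  c(cx = (ncol(frame) - 1) / 2, cy = (nrow(frame) - 1) / 2)
}

#' Apply a rigid transform to frame content
#'
#' Moves the content of `frame` by the forward rigid map
#' M(x) = R(theta)(x - c) + c + t: a feature at position p appears at M(p)
#' in the output.  Sampling is bilinear; pixels drawn from outside the
#' frame are filled with `fill`.  The inverse operation (alignment) is
#' [alignRigid()].
#'
#' @param frame numeric matrix.
#' @param tx,ty translation in pixels (x = columns, y = rows).
#' @param theta rotation in degrees, counter-clockwise about the centre.
#' @param fill fill value for out-of-frame samples.
#' @return transformed numeric matrix of the same shape.
#' @export
applyRigidMotion <- function(frame, tx, ty, theta = 0, fill = 0) {
  ctr <- frameCenter(frame)
  ## moved(y) = frame(M^-1(y)); M^-1(y) = R(-theta)(y - c) + c - R(-theta) t
  thr <- -theta * pi / 180
  ct <- cos(thr); st <- sin(thr)
  tx2 <- -(ct * tx - st * ty)
  ty2 <- -(st * tx + ct * ty)
  cpp_sample_rigid(frame, tx2, ty2, -theta, ctr[1], ctr[2], fill)
}

#' Resample a frame under an estimated rigid warp
#'
#' Produces F_s with F_s(x) = frame(W(x)), W(x) = R(theta)(x - c) + c + t.
#' When (tx, ty, theta) equal the motion injected by [applyRigidMotion()],
#' the output realigns the frame with the original (up to interpolation).
#'
#' @inheritParams applyRigidMotion
#' @return realigned numeric matrix.
#' @export
alignRigid <- function(frame, tx, ty, theta = 0, fill = 0) {
  ctr <- frameCenter(frame)
  cpp_sample_rigid(frame, tx, ty, theta, ctr[1], ctr[2], fill)
}

## Downsample by a linear factor: integer factors use exact block means,
## fractional factors fall back to EBImage bilinear resizing.
downsampleFrame <- function(frame, factor) {
  if (factor <= 1) return(frame)
  if (abs(factor - round(factor)) < 1e-9) {
    return(cpp_block_mean(frame, as.integer(round(factor))))
  }
  h <- floor(nrow(frame) / factor)
  w <- floor(ncol(frame) / factor)
  as.matrix(EBImage::resize(frame, w = h, h = w, antialias = TRUE))
}

## Quantize a float frame to 8-bit integer values in [0, 255].
quantize8 <- function(frame) {
  round(clamp(frame, 0, 255))
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
}
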