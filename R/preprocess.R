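## Preprocessing actor: denoise, background-suppress and
## contrast-normalize a motion-corrected frame *for detection only*; the
## unpreprocessed corrected frame still feeds signal extraction.

#' Preprocessing configuration
#'
#' @param gaussianKernel odd side length of the Gaussian smoothing kernel
#'   (3, sized to avoid distorting small neurons).
#' @param medianKernel odd side length of the median filter (3).
#' @param backgroundKernel odd side length of the wide Gaussian low-pass
#'   used as the spatial background estimate (31).
#' @return list of class `preprocConfig`.
#' @export
preprocConfig <- function(gaussianKernel = 3, medianKernel = 3,
                          backgroundKernel = 31) {
  for (k in c(gaussianKernel, medianKernel, backgroundKernel)) {
    if (k < 1 || k %% 2 != 1) stop("config error: kernels must be odd >= 1")
  }
  structure(list(gaussianKernel = gaussianKernel,
                 medianKernel = medianKernel,
                 backgroundKernel = backgroundKernel),
            class = "preprocConfig")
}

## 1-D Gaussian kernel matching the usual ksize -> sigma rule
## sigma = 0.3 * ((ksize - 1)/2 - 1) + 0.8; outer() of it gives the
## separable 2-D kernel.
.gaussKernel1d <- function(ksize) {
  sigma <- 0.3 * ((ksize - 1) / 2 - 1) + 0.8
  r <- (ksize - 1) / 2
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  g / sum(g)
}

.gaussKernel <- function(ksize) {
  g <- .gaussKernel1d(ksize)
  outer(g, g)
}

#' Min-max intensity normalization
#'
#' Per-pixel (I - I_min) * 255 / (I_max - I_min).  A constant frame maps
#' to all zeros (division-by-zero guard).
#'
#' @param frame nonempty numeric matrix.
#' @return frame scaled into [0, 255].
#' @export
normalizeMinMax <- function(frame) {
  if (length(frame) == 0) stop("structural error: empty frame")
  lo <- min(frame); hi <- max(frame)
  if (hi == lo) return(matrix(0, nrow(frame), ncol(frame)))
  (frame - lo) * 255 / (hi - lo)
}

#' Preprocess a frame for neuron detection
#'
#' Pipeline: 3x3 Gaussian smoothing, 3x3 median filter, subtraction of a
#' wide Gaussian low-pass background estimate (clamped at 0), then
#' min-max normalization into [0, 255].  Background subtraction removes
#' the diffuse glow of deep, out-of-focus neurons while preserving small
#' bright blobs; the output feeds detection only.
#'
#' @param frame grayscale numeric matrix (intensities in [0, 255]).
#' @param config a [preprocConfig()].
#' @return preprocessed frame in [0, 255].
#' @export
preprocessFrame <- function(frame, config = preprocConfig()) {
  kmax <- max(config$gaussianKernel, config$medianKernel,
              config$backgroundKernel)
  if (nrow(frame) < kmax || ncol(frame) < kmax) {
    stop("structural error: frame smaller than largest kernel")
  }
  f <- cpp_sep_filter(frame, .gaussKernel1d(config$gaussianKernel))
  if (config$medianKernel > 1) {
    f <- cpp_median_filter(f, as.integer((config$medianKernel - 1) / 2))
  }
  bg <- cpp_sep_filter(f, .gaussKernel1d(config$backgroundKernel))
  f <- pmax(f - bg, 0)
  normalizeMinMax(f)
}
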