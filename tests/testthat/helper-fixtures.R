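## Shared fixtures, all generated in code.

## Smooth random texture with full-frame support (for warp estimation).
makeTexture <- function(n = 160, seed = 42) {
  set.seed(seed)
  tex <- matrix(rnorm(n * n), n, n)
  tex <- calciflow:::cpp_sep_filter(tex, calciflow:::.gaussKernel1d(11))
  normalizeMinMax(tex)
}

## Frame with rendered disks on black background.
makeDiskFrame <- function(dim = c(64, 64),
                          disks = data.frame(x = 50, y = 60, r = 4,
                                             value = 200)) {
  f <- matrix(0, dim[1], dim[2])
  for (i in seq_len(nrow(disks))) {
    xs <- rep(0:(dim[2] - 1), each = dim[1])
    ys <- rep(0:(dim[1] - 1), times = dim[2])
    inside <- (xs - disks$x[i])^2 + (ys - disks$y[i])^2 <= disks$r[i]^2
    f[which(inside)] <- disks$value[i]
  }
  f
}

## Small simulation bundle shared across tests (cheap: 64x64, 12 neurons).
smallBundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulateCalciumVideo(
        nNeurons = 24, T = 250, dim = c(96, 96),
        noise = noiseConfig(0.1, 0.5),
        motion = motionConfig(4, 10, 3), seed = 5,
        warmupFrames = 60, ensureActive = TRUE)
    }
    cache
  }
})

## Brute-force connected components (4-connectivity) oracle: returns a
## data.frame(x, y, area) of components of frame > level.
ccOracle <- function(frame, level) {
  H <- nrow(frame); W <- ncol(frame)
  on <- frame > level
  seen <- matrix(FALSE, H, W)
  out <- list()
  for (x0 in seq_len(W)) for (y0 in seq_len(H)) {
    if (!on[y0, x0] || seen[y0, x0]) next
    queue <- list(c(y0, x0))
    seen[y0, x0] <- TRUE
    pix <- list()
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      pix[[length(pix) + 1L]] <- p
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= H && q[2] >= 1 && q[2] <= W &&
            on[q[1], q[2]] && !seen[q[1], q[2]]) {
          seen[q[1], q[2]] <- TRUE
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
    pm <- do.call(rbind, pix)
    out[[length(out) + 1L]] <- data.frame(
      x = mean(pm[, 2] - 1), y = mean(pm[, 1] - 1), area = nrow(pm))
  }
  if (length(out) == 0) {
    return(data.frame(x = numeric(0), y = numeric(0), area = numeric(0)))
  }
  do.call(rbind, out)
}
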