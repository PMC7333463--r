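## Ground-truthed calcium-imaging simulator: a two-group leaky
## integrate-and-fire (LIF) network drives mask-based fluorescence
## rendering with exponential decay; rigid motion (translation, selective
## rotation, drift regimes) and two additive noise fields (white "shot"
## noise and temporally autocorrelated "colored" noise) are then injected.

#' LIF neuron parameters
#'
#' Parameters of the leaky integrate-and-fire model
#' dV/dt = (V_rest - V)/lambda + theta * lambda * (-0.5) * eps,
#' integrated with an Euler step of one frame, where eps is standard
#' Gaussian noise drawn per neuron and frame.  A spike is emitted when V
#' exceeds `vThreshold`; V is then reset to `vRest` and the neuron is
#' refractory for `refractory` frames.  A parent spike at frame t raises
#' each child's V by `w` at frame t+1 (additive over parents).  Group-A
#' neurons additionally receive external stimulus events
#' (Bernoulli(`stimRate`) per frame, each adding `w` to V).
#'
#' The defaults put the group-A baseline firing rate near 2% per frame
#' with the default 400x400 rendering configuration.
#'
#' @param vRest rest potential (a.u.).
#' @param lambda membrane time constant in frames; must be > 0.
#' @param theta noise scale of the membrane noise term.
#' @param vThreshold firing threshold (a.u.).
#' @param refractory refractory period in frames (>= 1).
#' @param w synaptic / stimulus weight.
#' @param stimRate per-frame external stimulus probability for group A.
#' @return list of class `lifParams`.
#' @export
lifParams <- function(vRest = 0, lambda = 10, theta = 0.045,
                      vThreshold = 1, refractory = 5, w = 0.2,
                      stimRate = 0.02) {
  if (lambda <= 0) stop("config error: lambda must be > 0")
  if (refractory < 1) stop("config error: refractory must be >= 1")
  if (stimRate < 0 || stimRate > 1) stop("config error: stimRate in [0,1]")
  structure(list(vRest = vRest, lambda = lambda, theta = theta,
                 vThreshold = vThreshold, refractory = refractory,
                 w = w, stimRate = stimRate),
            class = "lifParams")
}

#' Two-group network topology
#'
#' Partitions `nNeurons` into group A (no parents; externally stimulated)
#' and group B (each with one or two group-A parents).
#'
#' @param nNeurons total neuron count.
#' @param fracA fraction of neurons assigned to group A.
#' @param seed RNG seed for parent assignment.
#' @return list of class `networkTopology` with elements nNeurons, groupA,
#'   groupB, parents (list over neurons; integer(0) for group A).
#' @export
networkTopology <- function(nNeurons = 100, fracA = 0.5, seed = 1) {
  stopifnot(nNeurons >= 1)
  nA <- max(1L, round(nNeurons * fracA))
  groupA <- seq_len(nA)
  groupB <- setdiff(seq_len(nNeurons), groupA)
  parents <- vector("list", nNeurons)
  withr_seed <- .withSeed(seed, {
    for (i in groupB) {
      parents[[i]] <- sample(groupA, sample(1:2, 1))
    }
    parents
  })
  parents <- withr_seed
  for (i in groupA) parents[[i]] <- integer(0)
  structure(list(nNeurons = nNeurons, groupA = groupA, groupB = groupB,
                 parents = parents),
            class = "networkTopology")
}

## Evaluate expr under a local RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

## One Euler step of the membrane update for all neurons; exposed
## internally so the additive-weight semantics can be unit tested.
## spikedPrev: logical vector of spikes at the previous frame.
lifStep <- function(V, spikedPrev, topology, lif, eps, stimEvents) {
  drive <- vapply(seq_along(V), function(i) {
    sum(spikedPrev[topology$parents[[i]]]) * lif$w
  }, 0)
  V + (lif$vRest - V) / lif$lambda +
    lif$theta * lif$lambda * (-0.5) * eps +
    drive + stimEvents * lif$w
}

#' Simulate network spike trains
#'
#' Forward-simulates the LIF network for `T` frames with a unit time step.
#' Neurons listed in `silent` are forced inactive (their threshold is set
#' unreachable), which reproduces a fixed number of inactive neurons
#' deterministically.
#'
#' @param topology a [networkTopology()].
#' @param lif a [lifParams()].
#' @param T number of frames (>= 1).
#' @param seed RNG seed.
#' @param silent integer indices of neurons forced silent.
#' @param ensureActive guarantee that every non-silenced neuron spikes
#'   at least once inside `activeWindow` (one spike is inserted at a
#'   uniformly drawn frame for neurons the dynamics left silent); used
#'   for worked configurations with a fixed active-neuron count.
#' @param activeWindow frame range for the `ensureActive` guarantee.
#' @return binary spike matrix, nNeurons x T.
#' @export
simulateSpikes <- function(topology, lif, T, seed = 1, silent = integer(0),
                           ensureActive = FALSE, activeWindow = seq_len(T)) {
  stopifnot(T >= 1)
  n <- topology$nNeurons
  thr <- rep(lif$vThreshold, n)
  thr[silent] <- Inf
  isA <- seq_len(n) %in% topology$groupA
  .withSeed(seed, {
    V <- rep(lif$vRest, n)
    spikes <- matrix(0L, n, T)
    refr <- integer(n)
    spikedPrev <- logical(n)
    for (t in seq_len(T)) {
      eps <- rnorm(n)
      stim <- ifelse(isA, rbinom(n, 1L, lif$stimRate), 0L)
      V <- lifStep(V, spikedPrev, topology, lif, eps, stim)
      canFire <- refr == 0L
      sp <- canFire & (V > thr)
      spikes[sp, t] <- 1L
      V[sp] <- lif$vRest
      refr[sp] <- lif$refractory
      refr[!sp & refr > 0L] <- refr[!sp & refr > 0L] - 1L
      spikedPrev <- sp
    }
    if (ensureActive) {
      quiet <- setdiff(which(rowSums(spikes[, activeWindow,
                                            drop = FALSE]) == 0), silent)
      for (i in quiet) {
        spikes[i, sample(activeWindow, 1)] <- 1L
      }
    }
    spikes
  })
}

#' Generate synthetic neuron masks
#'
#' Produces `n` roughly elliptical, connected binary masks on an H x W
#' grid.  Bounding widths and heights are drawn around `meanWidth` /
#' `meanHeight` (the size statistics of the mask set the simulator
#' emulates).  Masks are placed with a margin from the frame border (so
#' injected motion keeps neurons in view) and re-drawn if a new mask would
#' be fully contained in, or identical to, an existing one.
#'
#' @param n number of masks (>= 1).
#' @param dim c(H, W) grid size.
#' @param meanWidth,meanHeight target mean bounding sizes in pixels.
#' @param sdSize spread of the size distribution.
#' @param margin minimum distance of mask centres from the border;
#'   `NULL` uses 16 px (so injected motion keeps neurons in view),
#'   reduced proportionally on small grids.
#' @param seed RNG seed.
#' @return list of class `maskSet`: `dim`, `pix` (list of 1-based pixel
#'   indices into the H x W grid), `info` (data.frame id, cx, cy, width,
#'   height in 0-based pixel coordinates).
#' @export
generateMasks <- function(n, dim = c(400, 400), meanWidth = 6.8387,
                          meanHeight = 6.7634, sdSize = 1.1,
                          margin = NULL, seed = 1) {
  stopifnot(n >= 1)
  H <- dim[1]; W <- dim[2]
  if (is.null(margin)) margin <- min(16, floor(min(H, W) / 5))
  if (W - 2 * margin < 2 || H - 2 * margin < 2) {
    stop("placement error: grid too small for requested margin")
  }
  .withSeed(seed, {
    pix <- vector("list", n)
    info <- data.frame(id = seq_len(n), cx = NA_real_, cy = NA_real_,
                       width = NA_real_, height = NA_real_)
    attempts <- 0L
    i <- 1L
    while (i <= n) {
      attempts <- attempts + 1L
      if (attempts > 200L * n) {
        stop("placement error: could not place ", n, " masks on grid")
      }
      w <- max(3, rnorm(1, meanWidth, sdSize))
      h <- max(3, rnorm(1, meanHeight, sdSize))
      cx <- runif(1, margin, W - 1 - margin)
      cy <- runif(1, margin, H - 1 - margin)
      a <- w / 2; b <- h / 2
      x0 <- floor(cx - a); x1 <- ceiling(cx + a)
      y0 <- floor(cy - b); y1 <- ceiling(cy + b)
      xs <- rep(x0:x1, each = y1 - y0 + 1)
      ys <- rep(y0:y1, times = x1 - x0 + 1)
      inside <- ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1
      xs <- xs[inside]; ys <- ys[inside]
      if (length(xs) < 4) next
      idx <- sort(xs * H + ys + 1L)  # column-major index into [H, W]
      ## reject full containment either way, and pixel-identical masks
      contained <- FALSE
      for (j in seq_len(i - 1L)) {
        if (all(idx %in% pix[[j]]) || all(pix[[j]] %in% idx)) {
          contained <- TRUE
          break
        }
      }
      if (contained) next
      pix[[i]] <- idx
      info$cx[i] <- cx; info$cy[i] <- cy
      info$width[i] <- diff(range(xs)) + 1
      info$height[i] <- diff(range(ys)) + 1
      i <- i + 1L
    }
    structure(list(dim = dim, pix = pix, info = info), class = "maskSet")
  })
}

#' Render clean fluorescence video from spikes and masks
#'
#' Each neuron carries an intensity trace a_i(t): set to `amplitude` (128)
#' at spike frames, otherwise decayed by the per-frame factor
#' 2^(-1/halfLife).  A frame pixel takes the maximum over the traces of
#' all neurons whose masks cover it; the background is 0 and output is
#' clamped to [0, 255].
#'
#' @param spikes binary nNeurons x T matrix.
#' @param masks a `maskSet`.
#' @param decayHalfLife calcium decay half-life in frames (> 0).
#' @param amplitude spike intensity.
#' @return H x W x T numeric array of clean frames.
#' @export
renderFrames <- function(spikes, masks, decayHalfLife = 8, amplitude = 128) {
  if (decayHalfLife <= 0) stop("config error: decayHalfLife must be > 0")
  n <- nrow(spikes); T <- ncol(spikes)
  if (n != length(masks$pix)) {
    stop("structural error: spike matrix rows != number of masks")
  }
  H <- masks$dim[1]; W <- masks$dim[2]
  decay <- 2^(-1 / decayHalfLife)
  frames <- array(0, dim = c(H, W, T))
  a <- numeric(n)
  for (t in seq_len(T)) {
    a <- a * decay
    a[spikes[, t] == 1L] <- amplitude
    f <- matrix(0, H, W)
    for (i in which(a > 1e-4)) {
      idx <- masks$pix[[i]]
      f[idx] <- pmax(f[idx], a[i])
    }
    frames[, , t] <- clamp(f, 0, 255)
  }
  frames
}

#' Motion configuration
#'
#' @param translationRange per-axis translation bound in pixels; random
#'   modes draw uniformly from the mode's range each frame.
#' @param pRot rotation occurrence probability in percent (0..100).
#' @param alphaRot rotation range bound in degrees; applied rotations are
#'   uniform in [-alphaRot, alphaRot] about the image centre.
#' @param driftMode one of `"random"` (translation U[-range, range]),
#'   `"constant_trajectory"` (1 px/frame along a rectangular-spiral path
#'   within +/- `translationRange` px of truth), `"small"` (U[-3, 3]),
#'   `"large"` (U over [-10,-7] union [7,10]).
#' @return list of class `motionConfig`.
#' @export
motionConfig <- function(translationRange = 10, pRot = 0, alphaRot = 0,
                         driftMode = c("random", "constant_trajectory",
                                       "small", "large")) {
  driftMode <- match.arg(driftMode)
  if (pRot < 0 || pRot > 100) stop("config error: pRot in [0, 100]")
  if (alphaRot < 0) stop("config error: alphaRot >= 0")
  structure(list(translationRange = translationRange, pRot = pRot,
                 alphaRot = alphaRot, driftMode = driftMode),
            class = "motionConfig")
}

## Rectangular-spiral constant-drift trajectory: 1 px per frame, starting
## at (0,0) -> (1,0) -> (2,0) ..., reflecting at the +/- bound and
## spiralling through the box.
.driftTrajectory <- function(T, bound) {
  xs <- numeric(T); ys <- numeric(T)
  x <- 0; y <- 0
  dirs <- list(c(1, 0), c(0, 1), c(-1, 0), c(0, -1))
  d <- 1L
  legTarget <- bound  # first leg runs to +bound, then legs alternate
  for (t in seq_len(T)) {
    xs[t] <- x; ys[t] <- y
    step <- dirs[[d]]
    nx <- x + step[1]; ny <- y + step[2]
    if (abs(nx) > bound || abs(ny) > bound) {
      d <- (d %% 4L) + 1L
      step <- dirs[[d]]
      nx <- x + step[1]; ny <- y + step[2]
    }
    x <- nx; y <- ny
  }
  cbind(tx = xs, ty = ys)
}

#' Inject rigid motion into a clean video
#'
#' Per frame, a translation is drawn from the drift mode's range and, with
#' probability `pRot`/100, a rotation uniform in +/- `alphaRot` degrees is
#' applied about the image centre (bilinear interpolation, zero fill).
#' The first frame is left unmoved, anchoring the ground-truth track to
#' the clean coordinate frame.
#'
#' @param frames H x W x T clean array (e.g. from [renderFrames()]).
#' @param config a [motionConfig()].
#' @param seed RNG seed.
#' @return list(frames = moved H x W x T array, track = data.frame(frame,
#'   tx, ty, theta) of the injected ground-truth motion).
#' @export
injectMotion <- function(frames, config, seed = 1) {
  T <- dim(frames)[3]
  .withSeed(seed, {
    r <- config$translationRange
    track <- switch(config$driftMode,
      random = cbind(tx = runif(T, -r, r), ty = runif(T, -r, r)),
      small = cbind(tx = runif(T, -3, 3), ty = runif(T, -3, 3)),
      large = {
        draw <- function(k) sample(c(-1, 1), k, replace = TRUE) * runif(k, 7, 10)
        cbind(tx = draw(T), ty = draw(T))
      },
      constant_trajectory = .driftTrajectory(T, r)
    )
    rot <- runif(T) < config$pRot / 100
    theta <- ifelse(rot, runif(T, -config$alphaRot, config$alphaRot), 0)
    if (config$driftMode != "constant_trajectory") {
      track[1, ] <- 0  # reference frame carries no injected motion
    }
    theta[1] <- 0
    out <- array(0, dim = dim(frames))
    out[, , 1] <- frames[, , 1]
    for (t in 2:T) {
      out[, , t] <- applyRigidMotion(frames[, , t], track[t, 1], track[t, 2],
                                     theta[t])
    }
    list(frames = out,
         track = data.frame(frame = seq_len(T), tx = track[, 1],
                            ty = track[, 2], theta = theta))
  })
}

#' Noise configuration
#'
#' Two additive zero-mean fields: white per-pixel "shot" noise with
#' standard deviation `shotLevel` x `shotSigmaBase`, and per-pixel
#' temporally autocorrelated (AR(1)) "colored" noise with marginal
#' standard deviation `coloredLevel` x `coloredSigmaBase`.
#'
#' @param shotLevel,coloredLevel relative multipliers (the sNNcMM label
#'   digits divided by 10; see [parseNoiseLabel()]).
#' @param shotSigmaBase base shot sd (1.0).
#' @param coloredSigmaBase base colored sd (0.4).
#' @param arCoeff temporal AR(1) coefficient of the colored field.
#' @return list of class `noiseConfig`.
#' @export
noiseConfig <- function(shotLevel = 0, coloredLevel = 0,
                        shotSigmaBase = 1.0, coloredSigmaBase = 0.4,
                        arCoeff = 0.8) {
  if (shotLevel < 0 || coloredLevel < 0) stop("config error: levels >= 0")
  structure(list(shotLevel = shotLevel, coloredLevel = coloredLevel,
                 shotSigmaBase = shotSigmaBase,
                 coloredSigmaBase = coloredSigmaBase, arCoeff = arCoeff),
            class = "noiseConfig")
}

#' Parse an sNNcMM noise label
#'
#' The label grammar maps digit pairs to relative multipliers of the base
#' standard deviations: `sNN` means NN/10 x the base shot sd and `cMM`
#' means MM/10 x the base colored sd, so "s03c05" is shot level 0.3 and
#' colored level 0.5, and "s05c15" is (0.5, 1.5).
#'
#' @param label character like "s03c05".
#' @return a [noiseConfig()].
#' @export
parseNoiseLabel <- function(label) {
  m <- regmatches(label, regexec("^s([0-9]{2})c([0-9]{2})$", label))[[1]]
  if (length(m) != 3) stop("config error: bad noise label '", label, "'")
  noiseConfig(shotLevel = as.numeric(m[2]) / 10,
              coloredLevel = as.numeric(m[3]) / 10)
}

#' Add shot and colored noise to a video
#'
#' Adds the two zero-mean fields of [noiseConfig()] to every frame.  The
#' AR(1) colored field is initialised at its stationary distribution, with
#' innovation sd scaled so the marginal sd equals coloredLevel x base.
#' The result is clamped to [0, 255] and quantized to 8-bit levels.
#'
#' @param frames H x W x T array.
#' @param config a [noiseConfig()].
#' @param seed RNG seed.
#' @return H x W x T array of 8-bit (integer-valued) frames.
#' @export
addNoise <- function(frames, config, seed = 1) {
  d <- dim(frames)
  sShot <- config$shotLevel * config$shotSigmaBase
  sCol <- config$coloredLevel * config$coloredSigmaBase
  if (sShot == 0 && sCol == 0) return(frames)
  .withSeed(seed, {
    out <- array(0, dim = d)
    npix <- d[1] * d[2]
    phi <- config$arCoeff
    innovSd <- sCol * sqrt(1 - phi^2)
    colState <- if (sCol > 0) rnorm(npix, 0, sCol) else numeric(npix)
    for (t in seq_len(d[3])) {
      f <- frames[, , t]
      if (sShot > 0) f <- f + rnorm(npix, 0, sShot)
      if (sCol > 0) {
        if (t > 1) colState <- phi * colState + rnorm(npix, 0, innovSd)
        f <- f + colState
      }
      out[, , t] <- quantize8(f)
    }
    out
  })
}

#' @rdname SimulationBundle-class
#' @param nNeurons,T,dim,noise,motion,lif,topologySeed,silent,decayHalfLife
#'   study conditions; see Details.
#' @param seed master RNG seed; sub-seeds for spikes, masks, motion and
#'   noise are derived from it.
#' @param keepClean keep the motion-free, noise-free reference video.
#' @param warmupFrames extra frames simulated and rendered before frame 1
#'   then discarded, so the recording starts at steady-state network
#'   activity rather than from an all-dark field.
#' @param ensureActive guarantee every non-silenced neuron spikes at
#'   least once within the retained frames (see [simulateSpikes()]).
#' @details `simulateCalciumVideo()` is the one-call generator: it builds
#' the topology, simulates spikes, generates masks, renders, injects
#' motion and adds noise.  Defaults are the simulation study conditions:
#' 100 neurons, 1800 frames, 400 x 400 grid, amplitude 128, decay
#' half-life 8 frames, translation U[-10, 10].
#' @export
simulateCalciumVideo <- function(nNeurons = 100, T = 1800, dim = c(400, 400),
                                 noise = noiseConfig(0, 0),
                                 motion = motionConfig(10, 25, 6.3153),
                                 lif = lifParams(), topologySeed = 1,
                                 silent = integer(0), decayHalfLife = 8,
                                 seed = 1, keepClean = FALSE,
                                 warmupFrames = 100, ensureActive = FALSE) {
  topo <- networkTopology(nNeurons, seed = topologySeed)
  spikes <- simulateSpikes(topo, lif, T + warmupFrames, seed = seed + 101L,
                           silent = silent, ensureActive = ensureActive,
                           activeWindow = warmupFrames + seq_len(T))
  masks <- generateMasks(nNeurons, dim = dim, seed = seed + 202L)
  clean <- renderFrames(spikes, masks, decayHalfLife = decayHalfLife)
  if (warmupFrames > 0) {
    clean <- clean[, , -seq_len(warmupFrames), drop = FALSE]
    spikes <- spikes[, -seq_len(warmupFrames), drop = FALSE]
  }
  moved <- injectMotion(clean, motion, seed = seed + 303L)
  cleanKeep <- if (keepClean) clean else array(0, c(0, 0, 0))
  rm(clean)
  frames <- addNoise(moved$frames, noise, seed = seed + 404L)
  moved$frames <- NULL
  frames <- quantize8(frames)
  storage.mode(frames) <- "integer"
  cfg <- list(nNeurons = nNeurons, T = T, dim = dim, noise = unclass(noise),
              motion = unclass(motion), lif = unclass(lif),
              decayHalfLife = decayHalfLife, silent = silent,
              topologySeed = topologySeed, seed = seed)
  new("SimulationBundle", frames = frames, spikes = spikes, masks = masks,
      motionTrack = moved$track,
      cleanFrames = cleanKeep,
      config = cfg)
}
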