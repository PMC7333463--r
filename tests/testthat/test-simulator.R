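## Simulator: LIF dynamics, rendering, motion and noise injection.

test_that("a driveless network at rest never fires", {
  topo <- networkTopology(10, seed = 1)
  lif <- lifParams(theta = 0, stimRate = 0)
  spk <- simulateSpikes(topo, lif, 200, seed = 2)
  expect_equal(sum(spk), 0)
})

test_that("parent spikes add w per parent to the child potential", {
  topo <- networkTopology(4, fracA = 0.5, seed = 1)
  topo$parents[[3]] <- c(1L, 2L)   # child 3 with two group-A parents
  lif <- lifParams(theta = 0, stimRate = 0)
  V <- rep(0, 4)
  spiked <- c(TRUE, TRUE, FALSE, FALSE)
  V2 <- calciflow:::lifStep(V, spiked, topo, lif, eps = rep(0, 4),
                            stimEvents = rep(0, 4))
  expect_equal(V2[3], 2 * lif$w)   # both parents fired: +0.4
  expect_equal(V2[1], 0)           # group A receives no synaptic drive
})

test_that("refractoriness separates spikes by at least the refractory period", {
  topo <- networkTopology(20, seed = 3)
  lif <- lifParams(theta = 0.12, refractory = 5)
  spk <- simulateSpikes(topo, lif, 400, seed = 4)
  for (i in seq_len(nrow(spk))) {
    tt <- which(spk[i, ] == 1)
    if (length(tt) > 1) expect_gte(min(diff(tt)), lif$refractory)
  }
})

test_that("group-A firing rate matches an independent scalar simulation of the membrane equation", {
  lif <- lifParams()
  ## brute-force scalar oracle: one neuron, no synapses, long run
  scalarRate <- function(lif, n = 1e5, seed = 9) {
    set.seed(seed)
    V <- lif$vRest; refr <- 0L; fires <- 0L
    for (t in seq_len(n)) {
      V <- V + (lif$vRest - V) / lif$lambda +
        lif$theta * lif$lambda * (-0.5) * rnorm(1) +
        rbinom(1, 1, lif$stimRate) * lif$w
      if (refr == 0L && V > lif$vThreshold) {
        fires <- fires + 1L
        V <- lif$vRest
        refr <- lif$refractory
      } else if (refr > 0L) refr <- refr - 1L
    }
    fires / n
  }
  oracle <- scalarRate(lif)
  topo <- networkTopology(40, fracA = 1, seed = 1)  # all group A
  spk <- simulateSpikes(topo, lif, 2500, seed = 7)
  rate <- mean(spk)
  ## Monte-Carlo agreement between the two independent simulations
  se <- sqrt(oracle * (1 - oracle) * (1 / length(spk) + 1 / 1e5))
  expect_lt(abs(rate - oracle), 5 * se + 0.003)
})

test_that("rendered traces follow the closed-form decay 128 * 2^(-dt/8)", {
  masks <- generateMasks(1, dim = c(32, 32), margin = 8, seed = 1)
  spikes <- matrix(0L, 1, 20); spikes[1, 1] <- 1L
  v <- renderFrames(spikes, masks, decayHalfLife = 8)
  px <- masks$pix[[1]][1]
  traces <- vapply(1:20, function(t) v[, , t][px], 0)
  expect_equal(traces[1], 128)
  expect_equal(traces[9], 64)                     # half-life 8 frames
  expect_equal(traces[2], 128 * 2^(-1 / 8))       # ~117.4
  expect_equal(traces, 128 * 2^(-(0:19) / 8), tolerance = 1e-12)
})

test_that("rendering without spikes gives an all-zero video", {
  masks <- generateMasks(3, dim = c(32, 32), margin = 8, seed = 2)
  v <- renderFrames(matrix(0L, 3, 5), masks, 8)
  expect_true(all(v == 0))
})

test_that("overlapping masks compose by per-pixel maximum", {
  masks <- generateMasks(1, dim = c(32, 32), margin = 10, seed = 3)
  masks$pix[[2]] <- masks$pix[[1]]   # identical footprint
  masks$info <- rbind(masks$info, masks$info)
  spikes <- matrix(0L, 2, 3)
  spikes[1, 1] <- 1L   # neuron 1 spikes at t=1 -> 128, decays
  spikes[2, 3] <- 1L   # neuron 2 spikes at t=3 -> back to 128
  v <- renderFrames(spikes, masks, 8)
  px <- masks$pix[[1]][1]
  expect_equal(v[, , 3][px], 128)    # max(decayed, fresh 128)
})

test_that("mask sets match the target size statistics and are pairwise distinct", {
  masks <- generateMasks(100, dim = c(400, 400), seed = 11)
  expect_lt(abs(mean(masks$info$width) - 6.8387) / 6.8387, 0.10)
  expect_lt(abs(mean(masks$info$height) - 6.7634) / 6.7634, 0.10)
  ## exhaustive pairwise audit: no two masks pixel-identical, none
  ## fully contained in another
  for (i in 1:99) for (j in (i + 1):100) {
    expect_false(all(masks$pix[[i]] %in% masks$pix[[j]]))
    expect_false(all(masks$pix[[j]] %in% masks$pix[[i]]))
  }
})

test_that("single mask generation yields one connected component", {
  masks <- generateMasks(1, dim = c(40, 40), margin = 10, seed = 4)
  f <- matrix(0, 40, 40)
  f[masks$pix[[1]]] <- 1
  cc <- ccOracle(f, 0)
  expect_equal(nrow(cc), 1)
})

test_that("rotation occurrence matches the configured probability", {
  frames <- renderFrames(matrix(rbinom(2 * 400, 1, 0.05), 2, 400),
                         generateMasks(2, c(48, 48), margin = 12, seed = 5), 8)
  mv <- injectMotion(frames, motionConfig(5, pRot = 10, alphaRot = 5.16),
                     seed = 6)
  nRot <- sum(mv$track$theta != 0)
  ## binomial 99% CI around 10% of 400 frames
  expect_gt(nRot, 400 * 0.10 - 3 * sqrt(400 * 0.1 * 0.9))
  expect_lt(nRot, 400 * 0.10 + 3 * sqrt(400 * 0.1 * 0.9))
  expect_true(all(abs(mv$track$theta) <= 5.16))
})

test_that("pRot = 0 injects no rotation anywhere", {
  frames <- array(runif(24 * 24 * 6, 0, 255), c(24, 24, 6))
  mv <- injectMotion(frames, motionConfig(3, 0, 0), seed = 1)
  expect_true(all(mv$track$theta == 0))
})

test_that("constant drift follows the unit-step trajectory", {
  frames <- array(0, c(30, 30, 6))
  mv <- injectMotion(frames, motionConfig(10, 0, 0,
                                          driftMode = "constant_trajectory"),
                     seed = 1)
  expect_equal(mv$track$tx[1:3], c(0, 1, 2))
  expect_equal(mv$track$ty[1:3], c(0, 0, 0))
  expect_true(all(abs(mv$track$tx) <= 10 & abs(mv$track$ty) <= 10))
  ## 1 px per frame along the path
  steps <- sqrt(diff(mv$track$tx)^2 + diff(mv$track$ty)^2)
  expect_true(all(steps == 1))
})

test_that("small and large drift draw from their stated ranges", {
  frames <- array(0, c(24, 24, 200))
  sm <- injectMotion(frames, motionConfig(10, 0, 0, driftMode = "small"),
                     seed = 2)$track
  expect_true(all(abs(sm$tx[-1]) <= 3 & abs(sm$ty[-1]) <= 3))
  lg <- injectMotion(frames, motionConfig(10, 0, 0, driftMode = "large"),
                     seed = 3)$track
  expect_true(all(abs(lg$tx[-1]) >= 7 & abs(lg$tx[-1]) <= 10))
  expect_true(all(abs(lg$ty[-1]) >= 7 & abs(lg$ty[-1]) <= 10))
})

test_that("injected motion is invertible up to interpolation error", {
  cb <- matrix(0, 100, 100)
  cb[(row(cb) %/% 10 + col(cb) %/% 10) %% 2 == 0] <- 200
  moved <- applyRigidMotion(cb, 4.5, -3.25, 2.5)
  rec <- alignRigid(moved, 4.5, -3.25, 2.5)
  inner <- 20:80
  rmse <- sqrt(mean((rec[inner, inner] - cb[inner, inner])^2))
  ## interpolation-noise bound for a double bilinear resampling of a
  ## 200-amplitude checkerboard
  expect_lt(rmse, 30)
  ## integer translation is exact away from the border
  movedI <- applyRigidMotion(cb, 3, -2, 0)
  recI <- alignRigid(movedI, 3, -2, 0)
  expect_equal(recI[inner, inner], cb[inner, inner], tolerance = 1e-12)
})

test_that("noise fields have the configured marginal standard deviations", {
  z <- array(128, c(50, 50, 8))
  cfg <- noiseConfig(shotLevel = 0.5, coloredLevel = 1.5)
  noisy <- addNoise(z, cfg, seed = 8)
  resid <- noisy - 128
  total <- sd(resid)
  expected <- sqrt((0.5 * 1)^2 + (1.5 * 0.4)^2)
  ## quantization to 8-bit adds ~1/12 variance
  expect_lt(abs(total - sqrt(expected^2 + 1 / 12)), 0.05)
  ## colored field alone, via a shot-free configuration
  cNoisy <- addNoise(z, noiseConfig(0, 1.5), seed = 9)
  expect_lt(abs(sd(cNoisy - 128) - sqrt((1.5 * 0.4)^2 + 1 / 12)), 0.05)
})

test_that("zero noise levels leave the video untouched", {
  z <- array(runif(1000, 0, 255), c(10, 10, 10))
  expect_identical(addNoise(z, noiseConfig(0, 0), seed = 1), z)
})

test_that("noise labels parse via the sNNcMM grammar", {
  cfg <- parseNoiseLabel("s05c15")
  expect_equal(cfg$shotLevel, 0.5)
  expect_equal(cfg$coloredLevel, 1.5)
  cfg2 <- parseNoiseLabel("s01c05")
  expect_equal(cfg2$shotLevel, 0.1)
  expect_equal(cfg2$coloredLevel, 0.5)
  expect_error(parseNoiseLabel("x0c05"), "config error")
})

test_that("bundles are bit-exact reproducible from (config, seed)", {
  b1 <- simulateCalciumVideo(nNeurons = 6, T = 15, dim = c(48, 48),
                             noise = noiseConfig(0.3, 0.5),
                             motion = motionConfig(5, 20, 4), seed = 21,
                             warmupFrames = 10)
  b2 <- simulateCalciumVideo(nNeurons = 6, T = 15, dim = c(48, 48),
                             noise = noiseConfig(0.3, 0.5),
                             motion = motionConfig(5, 20, 4), seed = 21,
                             warmupFrames = 10)
  expect_identical(frames(b1), frames(b2))
  expect_identical(spikes(b1), spikes(b2))
  expect_identical(motionTrack(b1), motionTrack(b2))
})

test_that("forced-silent neurons never spike and bundles validate", {
  b <- smallBundle()
  expect_true(validObject(b))
  b3 <- simulateCalciumVideo(nNeurons = 8, T = 30, dim = c(48, 48),
                             silent = c(2, 5), seed = 3, warmupFrames = 20)
  expect_equal(sum(spikes(b3)[c(2, 5), ]), 0)
  expect_false(any(c(2, 5) %in% activeNeurons(b3)))
})
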