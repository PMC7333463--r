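## Evaluation harness: motion errors, detection scores, SNR, RMSE.

test_that("motion error means match hand arithmetic and exclude failures", {
  est <- data.frame(frame = 1:5, tx = c(1, 2, 0, 4, 1),
                    ty = c(0, 1, 0, 2, 2), theta = c(0, 0, 0, 1, 0))
  tru <- data.frame(frame = 1:5, tx = c(1, 1, 3, 3, 1),
                    ty = c(0, 0, 1, 1, 0), theta = c(0, 0, 0.5, 0.5, 0))
  statuses <- c("ok", "ok", "failed", "ok", "ok")
  me <- motionError(est, tru, statuses)
  expect_equal(me$meanMx, mean(c(0, 1, 1, 0)))
  expect_equal(me$meanMy, mean(c(0, 1, 1, 2)))
  expect_equal(me$meanMrot, mean(c(0, 0, 0.5, 0)))
  expect_equal(me$rateFail, 20)              # 1 of 5 frames
  expect_true(is.na(me$mx[3]))               # failed frame excluded
  ## perfect tracks give all-zero means
  me0 <- motionError(tru, tru, rep("ok", 5))
  expect_equal(me0$meanMx + me0$meanMy + me0$meanMrot + me0$rateFail, 0)
  ## 1 failure in 200 frames -> 0.5%
  longTrack <- data.frame(frame = 1:200, tx = 0, ty = 0, theta = 0)
  expect_equal(motionError(longTrack, longTrack,
                           c("failed", rep("ok", 199)))$rateFail, 0.5)
  expect_error(motionError(est, tru[1:3, ]), "length mismatch")
})

test_that("the F1 identity holds exactly, including the printed worked examples", {
  expect_equal(f1Score(0.7166, 0.7259), 0.7212, tolerance = 5e-5)
  expect_equal(f1Score(0.7246, 0.6944), 0.7092, tolerance = 5e-5)
  expect_equal(f1Score(0.5, 0.5), 0.5)       # u = v -> f1 = u
  set.seed(33)
  u <- runif(200, 0.01, 1); v <- runif(200, 0.01, 1)
  expect_equal(f1Score(u, v), 2 * u * v / (u + v), tolerance = 1e-15)
  expect_equal(f1Score(0, 0), 0)
})

test_that("perfectly tiling detections score u = v = f1 = 1", {
  masks <- structure(list(dim = c(40, 40), pix = list(), info = NULL),
                     class = "maskSet")
  delta <- data.frame(x = c(10, 28), y = c(12, 30), radius = c(3, 3))
  masks$pix <- lapply(1:2, function(i) {
    roiPixels(c(40, 40), delta$x[i], delta$y[i], delta$radius[i])
  })
  masks$info <- data.frame(id = 1:2, cx = delta$x, cy = delta$y,
                           width = 6, height = 6)
  sc <- detectionScore(delta, masks)
  expect_equal(sc$u, 1)
  expect_equal(sc$v, 1)
  expect_equal(sc$f1, 1)
  expect_equal(sc$detectionRate, 100)
})

test_that("matching is one-to-one, nearest-first, and requires centre-in-mask", {
  masks <- structure(list(dim = c(40, 40),
                          pix = list(roiPixels(c(40, 40), 10, 10, 4)),
                          info = data.frame(id = 1, cx = 10, cy = 10,
                                            width = 8, height = 8)),
                     class = "maskSet")
  ## two detections inside the same mask: only the nearer one matches
  delta <- data.frame(x = c(10.5, 12.5), y = c(10, 10), radius = c(3, 3))
  m <- matchDetections(delta, masks)
  expect_equal(nrow(m), 1)
  expect_equal(m$detection, 1L)
  ## a detection whose centre is outside every mask never matches
  far <- data.frame(x = 30, y = 30, radius = 3)
  expect_equal(nrow(matchDetections(far, masks)), 0)
})

test_that("SNR identities and permutation invariance hold", {
  ## R_s = R_n -> 0 dB; R_s = 10 R_n -> 10 dB (via the formula on a
  ## report built from known parts)
  expect_equal(10 * log10(0.2 / 0.2), 0)
  expect_equal(10 * log10(10 * 0.000011 / 0.000011), 10)
  b <- smallBundle()
  res <- runExperiment(frames(b),
                       pipelineConfig(nTrainingFrames = 10,
                                      mcMaxShift = 10,
                                      keepCorrected = TRUE))
  m <- matchDetections(res$delta, neuronMasks(b))
  skip_if(nrow(m) < 3)
  corrv <- simplify2array(res$corrected)
  s1 <- snrReport(res$signals, spikes(b), corrv, neuronMasks(b), m,
                  res$delta, nRep = 100, seed = 5)
  ## permuting neuron order leaves R_s unchanged
  perm <- sample(nrow(m))
  s2 <- snrReport(res$signals, spikes(b), corrv, neuronMasks(b),
                  m[perm, ], res$delta, nRep = 100, seed = 5)
  expect_equal(s1$rs, s2$rs, tolerance = 1e-12)
  expect_equal(s1$nRep, 100)
  ## extracted traces correlate with their own spike trains far above
  ## the random-region null (wide margin: the null at this fixture size
  ## is noisy)
  expect_gt(s1$rs, 0.05)
  expect_gt(s1$rs, abs(s1$rn) * 5)
})

test_that("random regions respect the mask-overlap bound", {
  masks <- structure(list(dim = c(30, 30),
                          pix = list(roiPixels(c(30, 30), 15, 15, 6)),
                          info = data.frame(id = 1, cx = 15, cy = 15,
                                            width = 12, height = 12)),
                     class = "maskSet")
  maskAll <- logical(900); maskAll[masks$pix[[1]]] <- TRUE
  set.seed(44)
  for (i in 1:200) {
    repeat {
      cx <- runif(1, 4, 25); cy <- runif(1, 4, 25)
      idx <- roiPixels(c(30, 30), cx, cy, 4)
      if (mean(maskAll[idx]) <= 0.2) break
    }
    expect_lte(mean(maskAll[idx]), 0.2)
  }
})

test_that("framewise RMSE matches direct arithmetic", {
  a <- array(0, c(2, 2, 3))
  b <- a
  expect_equal(framewiseRMSE(a, b), c(0, 0, 0))
  b2 <- a + 1
  expect_equal(framewiseRMSE(a, b2), c(1, 1, 1))
  a[, , 1] <- matrix(c(1, 2, 3, 4), 2)
  b3 <- array(0, c(2, 2, 3))
  expect_equal(framewiseRMSE(a, b3)[1], sqrt(mean(c(1, 4, 9, 16))))
  expect_error(framewiseRMSE(a, array(0, c(2, 2, 2))), "shape mismatch")
})
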