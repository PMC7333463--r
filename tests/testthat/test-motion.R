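## Motion correction: ECC estimation, correlation gates, CoHisQ, and the
## full per-frame decision flow.

test_that("identity frames give a zero warp", {
  tex <- makeTexture()
  w <- eccAlign(tex, tex, "translation")
  expect_lt(abs(w$tx), 0.05)
  expect_lt(abs(w$ty), 0.05)
  expect_equal(w$theta, 0)
})

test_that("integer shifts are recovered within 0.5 px and agree with an exhaustive oracle", {
  tex <- makeTexture()
  ## independent oracle: exhaustive integer-shift cross-correlation in
  ## the spatial domain over the interior window
  shiftOracle <- function(cur, ref, rng = 6) {
    inner <- 41:120
    best <- c(0, 0); bestC <- -Inf
    for (sx in -rng:rng) for (sy in -rng:rng) {
      cc <- cor(as.vector(cur[inner + sy, inner + sx]),
                as.vector(ref[inner, inner]))
      if (cc > bestC) { bestC <- cc; best <- c(sx, sy) }
    }
    best
  }
  for (shift in list(c(3, -2), c(-5, 4))) {
    mv <- applyRigidMotion(tex, shift[1], shift[2], 0)
    oracle <- shiftOracle(mv, tex)
    expect_equal(oracle, shift)     # oracle itself recovers the truth
    w <- eccAlign(mv, tex, "translation")
    expect_lt(abs(w$tx - shift[1]), 0.5)
    expect_lt(abs(w$ty - shift[2]), 0.5)
  }
})

test_that("rotations are recovered within 0.5 degrees and agree with a grid-search oracle", {
  tex <- makeTexture()
  mv <- applyRigidMotion(tex, 0, 0, 4)
  ## independent oracle: grid search over theta in 0.1-degree steps
  inner <- 41:120
  scores <- vapply(seq(-10, 10, by = 0.1), function(th) {
    rec <- alignRigid(mv, 0, 0, th)
    cor(as.vector(rec[inner, inner]), as.vector(tex[inner, inner]))
  }, 0)
  oracleTheta <- seq(-10, 10, by = 0.1)[which.max(scores)]
  expect_lt(abs(oracleTheta - 4), 0.2)
  w <- eccAlign(mv, tex, "euclidean")
  expect_lt(abs(w$theta - 4), 0.5)
  expect_lt(abs(w$theta - oracleTheta), 0.5)
})

test_that("fractional estimation downsampling recovers shifts too", {
  ## the alternative 1.67x factor exercises the resampling-based path
  tex <- makeTexture()
  mv <- applyRigidMotion(tex, 3, -2, 0)
  w <- eccAlign(mv, tex, "translation", downsampleFactor = 1.67)
  expect_lt(abs(w$tx - 3), 0.5)
  expect_lt(abs(w$ty + 2), 0.5)
})

test_that("estimation does not modify the input frames", {
  tex <- makeTexture()
  mv <- applyRigidMotion(tex, 2, 1, 0)
  mvCopy <- mv + 0; texCopy <- tex + 0
  eccAlign(mv, tex, "translation")
  expect_identical(mv, mvCopy)
  expect_identical(tex, texCopy)
})

test_that("frame correlation matches the direct Pearson formula", {
  a <- matrix(c(0, 1, 2, 3, 4, 5, 6, 7, 8), 3)
  b <- matrix(c(1, 2, 4, 3, 5, 4, 7, 7, 9), 3)
  expect_equal(frameCorrelation(a, b), cor(as.vector(a), as.vector(b)))
  expect_equal(frameCorrelation(a, a), 1)
  expect_equal(frameCorrelation(a, -a), -1)
  expect_equal(frameCorrelation(matrix(5, 3, 3), a), 0)  # constant frame
  expect_error(frameCorrelation(a, matrix(0, 2, 2)), "shape mismatch")
})

test_that("adaptive thresholds implement mean - p * sd over the queue", {
  q <- newCoHisQ()
  for (i in 1:100) pushCorrelation(q, 0.8)
  expect_equal(adaptiveThreshold(q, 2), 0.8)            # sigma = 0
  q2 <- newCoHisQ()
  for (i in 1:100) pushCorrelation(q2, if (i %% 2) 0.6 else 1.0)
  ## alternating 0.6/1.0: mean 0.8, population sd 0.2 -> tau = 0.4
  expect_equal(adaptiveThreshold(q2, 2), 0.4)
  ## the p = 10 gate is strictly looser than the p = 2 gate when sd > 0
  expect_lt(adaptiveThreshold(q2, 10), adaptiveThreshold(q2, 2))
  ## warm-up floor before 10 values
  q3 <- newCoHisQ()
  pushCorrelation(q3, 0.9)
  expect_equal(adaptiveThreshold(q3, 2, floor = 0.3), 0.3)
})

test_that("CoHisQ incremental statistics equal a from-scratch recomputation", {
  set.seed(31)
  q <- newCoHisQ(100L)
  vals <- runif(250, 0.3, 1)
  for (i in seq_along(vals)) {
    pushCorrelation(q, vals[i])
    st <- cohisqStats(q)
    keep <- tail(vals[1:i], 100)
    expect_equal(unname(st[1]), length(keep))
    expect_equal(unname(st[2]), mean(keep), tolerance = 1e-9)
    expect_equal(unname(st[3]),
                 sqrt(mean((keep - mean(keep))^2)), tolerance = 1e-9)
  }
  expect_lte(length(q$values), 100)
})

test_that("a static video yields no-motion results with correlation 1 and no failures", {
  tex <- makeTexture(96)
  st <- newMCState(tex)
  for (k in 1:5) {
    r <- correctFrame(tex, st)
    expect_equal(r$status, "no_motion")
    expect_equal(r$correlation, 1)
  }
  expect_equal(motionError(
    data.frame(frame = 1:5, tx = 0, ty = 0, theta = 0),
    data.frame(frame = 1:5, tx = 0, ty = 0, theta = 0),
    rep("no_motion", 5))$rateFail, 0)
})

test_that("a pure-noise frame mid-stream fails with a logged frame index", {
  tex <- makeTexture(96)
  st <- newMCState(tex)
  g <- dfGraph(list(dfActor("MC")), kind = "body")
  correctFrame(tex, st, g)
  set.seed(40)
  noise <- matrix(runif(96 * 96, 0, 255), 96, 96)
  r <- correctFrame(noise, st, g)
  expect_equal(r$status, "failed")
  expect_identical(r$frame, st$ref)        # output is the reference frame
  log <- runLog(g)
  expect_true(any(grepl("motion correction failed at frame 2", log$info)))
})

test_that("translation motion on simulator video is recovered within 1 px mean", {
  ## translation-only motion, no noise; maxShift set to the rig's range
  b <- simulateCalciumVideo(nNeurons = 40, T = 60, dim = c(128, 128),
                            motion = motionConfig(4, 0, 0), seed = 6,
                            warmupFrames = 60, ensureActive = TRUE)
  fr <- frames(b); tr <- motionTrack(b)
  st <- newMCState(matrix(as.double(fr[, , 1]), 128, 128), maxShift = 10)
  n <- 60
  est <- data.frame(frame = 1:n, tx = 0, ty = 0, theta = 0)
  statuses <- rep("no_motion", n)
  for (k in 2:n) {
    r <- correctFrame(matrix(as.double(fr[, , k]), 128, 128), st)
    est[k, 2:4] <- r$warp
    statuses[k] <- r$status
  }
  me <- motionError(est, tr[1:n, ], statuses)
  expect_lt(me$meanMx, 1)
  expect_lt(me$meanMy, 1)
})

test_that("tightening p1 only converts accepts into euclidean attempts, never the reverse", {
  b <- smallBundle()
  fr <- frames(b)
  runStatuses <- function(p1) {
    st <- newMCState(matrix(as.double(fr[, , 1]), 96, 96), p1 = p1)
    vapply(2:25, function(k) {
      correctFrame(matrix(as.double(fr[, , k]), 96, 96), st)$status
    }, "")
  }
  loose <- runStatuses(2)
  tight <- runStatuses(0.5)
  ## every frame accepted at the translation gate under the tight
  ## multiplier was also accepted under the loose one
  transTight <- tight %in% c("translation_ok", "no_motion")
  transLoose <- loose %in% c("translation_ok", "no_motion")
  expect_true(all(!transTight | transLoose))
})

test_that("failed frames push nothing into CoHisQ", {
  tex <- makeTexture(96)
  st <- newMCState(tex)
  correctFrame(tex, st)
  n0 <- length(st$cohisq$values)
  set.seed(41)
  correctFrame(matrix(runif(96 * 96, 0, 255), 96, 96), st)
  expect_equal(length(st$cohisq$values), n0)
})
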