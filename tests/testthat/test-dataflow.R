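## Dataflow runtime: firing rules, token bookkeeping, reference passing,
## PSDF parameter binding.

passThrough <- function(name) {
  dfActor(name, inputs = "in1", outputs = "out1",
          fire = function(inputs, actor) list(out1 = inputs$in1))
}

chainGraph <- function(delayBC = 0L) {
  a <- imgSrcActor("a", as.list(1:10))
  b <- passThrough("b")
  cc <- sinkActor("c")
  dfGraph(list(a, b, cc),
          list(dfEdge(c("a", "out1"), c("b", "in1")),
               dfEdge(c("b", "out1"), c("c", "in1"), delay = delayBC,
                      initial = if (delayBC) list("init") else NULL)))
}

test_that("enabling follows token availability along a chain", {
  g <- chainGraph()
  expect_true(dfEnabled(g, "a"))     # source: no inputs
  expect_false(dfEnabled(g, "b"))    # empty input FIFO
  expect_false(dfEnabled(g, "c"))
  dfFire(g, "a")
  expect_true(dfEnabled(g, "b"))
  expect_false(dfEnabled(g, "c"))    # hand-simulated token counts
  dfFire(g, "b")
  expect_true(dfEnabled(g, "c"))
  expect_error(dfEnabled(g, "nosuch"), "unknown actor")
})

test_that("an initial-token delay enables the sink before any firing", {
  g <- chainGraph(delayBC = 1L)
  expect_true(dfEnabled(g, "c"))
})

test_that("firing a non-enabled actor is a scheduling error", {
  g <- chainGraph()
  expect_error(dfFire(g, "b"), "scheduling error")
})

test_that("tokens pass by reference and FIFOs preserve order", {
  payload <- new.env()
  payload$frame <- matrix(1:4, 2)
  src <- imgSrcActor("src", list(payload, "second"))
  fork <- forkActor("fork", 2L)
  s1 <- sinkActor("s1"); s2 <- sinkActor("s2")
  g <- dfGraph(list(src, fork, s1, s2),
               list(dfEdge(c("src", "out1"), c("fork", "in1")),
                    dfEdge(c("fork", "out1"), c("s1", "in1")),
                    dfEdge(c("fork", "out2"), c("s2", "in1"))))
  dfRunIteration(g)
  ## fork produced the identical payload reference on each output
  expect_identical(s1$state$items[[1]], payload)
  expect_identical(s2$state$items[[1]], payload)
  dfRunIteration(g)
  expect_identical(s1$state$items[[2]], "second")
})

test_that("token conservation holds on every edge after every firing", {
  g <- chainGraph(delayBC = 1L)
  checkConservation <- function() {
    for (e in g$edges) {
      expect_equal(dfTokens(e), e$produced - e$consumed + e$delay)
    }
  }
  for (i in 1:12) {
    ## fire any enabled actor (downstream-first), then re-check
    for (nm in g$order) {
      if (dfEnabled(g, nm)) {
        dfFire(g, nm)
        break
      }
    }
    checkConservation()
  }
})

test_that("schedule admissibility: replaying the run log never fires a non-enabled actor", {
  g <- chainGraph()
  for (i in 1:6) dfRunIteration(g)
  log <- runLog(g)
  fired <- log$actor[log$event == "fire"]
  ## independent token-count simulator over the same firing sequence
  tokens <- c(ab = 0, bc = 0)
  for (nm in fired) {
    if (nm == "b") {
      expect_gte(tokens["ab"], 1)
      tokens["ab"] <- tokens["ab"] - 1
      tokens["bc"] <- tokens["bc"] + 1
    } else if (nm == "c") {
      expect_gte(tokens["bc"], 1)
      tokens["bc"] <- tokens["bc"] - 1
    } else {
      tokens["ab"] <- tokens["ab"] + 1
    }
  }
})

test_that("deadlocked iterations are reported with a token snapshot", {
  b <- passThrough("b")
  cc <- sinkActor("c")
  ## b's input is never fed: iteration cannot complete
  g <- dfGraph(list(b, cc),
               list(dfEdge(c("b", "out1"), c("c", "in1"))))
  expect_error(dfRunIteration(g), "deadlock.*tokens", perl = TRUE)
})

test_that("PSDF binding pushes subinit outputs into body actor parameters", {
  emitter <- dfActor("SetP", outputs = "params_out",
                     fire = function(inputs, actor) list(params_out = 30))
  subinit <- dfGraph(list(emitter), kind = "subinit")
  det <- dfActor("Det", params = list(aMin = 5),
                 fire = function(inputs, actor) list())
  body <- dfGraph(list(det), kind = "body")
  ## n = 0 body iterations: only the subinit runs and parameters are set
  out <- runPSDF(body, subinit,
                 bindings = list(list(port = "SetP.params_out",
                                      targets = list(c("Det", "aMin")))),
                 nBodyIterations = 0L)
  expect_equal(body$actors$Det$params$aMin, 30)
  expect_equal(body$actors$Det$firings, 0L)
  expect_equal(out$bound[["SetP.params_out"]], 30)
})

test_that("invalid bindings are structural errors", {
  emitter <- dfActor("SetP", outputs = "params_out",
                     fire = function(inputs, actor) list(params_out = 1))
  subinit <- dfGraph(list(emitter), kind = "subinit")
  det <- dfActor("Det", params = list(aMin = 5),
                 fire = function(inputs, actor) list())
  body <- dfGraph(list(det), kind = "body")
  expect_error(
    runPSDF(body, subinit,
            bindings = list(list(port = "SetP.params_out",
                                 targets = list(c("Det", "nope"))))),
    "unknown parameter")
  expect_error(
    runPSDF(body, subinit,
            bindings = list(list(port = "SetP.params_out",
                                 targets = list(c("Ghost", "aMin"))))),
    "unknown body actor")
})

test_that("pipeline graph emits one signal row per frame", {
  b <- smallBundle()
  fl <- lapply(1:10, function(t) {
    f <- frames(b)[, , t]; storage.mode(f) <- "double"; f
  })
  cfg <- pipelineConfig(nTrainingFrames = 3)
  res <- runRealtime(fl, data.frame(x = 40, y = 40, radius = 4), cfg)
  expect_equal(nrow(res$signals), 10)
  expect_equal(ncol(res$signals), 1)
})

test_that("the Motion Correction actor can be disabled for pre-registered input", {
  b <- smallBundle()
  fl <- lapply(1:6, function(t) {
    f <- frames(b)[, , t]; storage.mode(f) <- "double"; f
  })
  cfg <- pipelineConfig(nTrainingFrames = 2, motionCorrection = FALSE)
  res <- runRealtime(fl, data.frame(x = 40, y = 40, radius = 4), cfg)
  expect_true(all(res$statuses == "disabled"))
  expect_true(all(res$track$tx == 0 & res$track$theta == 0))
})
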