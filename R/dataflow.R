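## Minimal dataflow runtime: actors with firing rules, FIFO edges with
## initial-token delays, reference-passing tokens, a demand-driven
## single-threaded scheduler, and PSDF body/subinit graph pairs with
## dynamic parameter rebinding.  Actors, edges and graphs are environments
## because they are mutable, stateful runtime objects.

#' Create a dataflow actor
#'
#' An actor is a computational task with named input and output ports,
#' per-port token consumption/production counts (one token per firing on
#' every port unless stated otherwise), a named parameter list, and private
#' state that persists across firings (the dataflow-equivalent of a
#' self-loop edge).
#'
#' @param name unique actor name within a graph.
#' @param inputs,outputs character vectors of port names.
#' @param fire function(inputs, actor) called once per firing with a named
#'   list holding one consumed token payload per input port; must return a
#'   named list with one payload per output port.  `actor` is the actor
#'   environment, giving access to `actor$params`, `actor$state` and
#'   `actor$graph` (for logging via [dfLog()]).
#' @param params named list of actor parameters (rebindable via PSDF).
#' @param state arbitrary initial private state.
#' @return an environment of class `dfActor`.
#' @export
dfActor <- function(name, inputs = character(), outputs = character(),
                    fire = function(inputs, actor) list(),
                    params = list(), state = list()) {
  a <- new.env(parent = emptyenv())
  a$name <- name
  a$inputs <- inputs
  a$outputs <- outputs
  a$fire <- fire
  a$params <- params
  a$state <- state
  a$firings <- 0L
  class(a) <- "dfActor"
  a
}

#' Create a FIFO dataflow edge
#'
#' @param from,to length-2 character vectors c(actor, port).
#' @param delay nonnegative integer count of initial tokens; initial token
#'   payloads are `NULL` unless `initial` supplies a list of payloads.
#' @param initial optional list of initial token payloads (length `delay`).
#' @return an environment of class `dfEdge`.
#' @export
dfEdge <- function(from, to, delay = 0L, initial = NULL) {
  stopifnot(length(from) == 2L, length(to) == 2L, delay >= 0L)
  e <- new.env(parent = emptyenv())
  e$from <- from
  e$to <- to
  e$delay <- as.integer(delay)
  if (is.null(initial)) initial <- rep(list(NULL), delay)
  stopifnot(length(initial) == delay)
  e$queue <- initial
  e$produced <- 0L
  e$consumed <- 0L
  class(e) <- "dfEdge"
  e
}

#' Assemble a dataflow graph
#'
#' Validates port references, computes a downstream-first actor order for
#' the demand-driven scheduler, and attaches a shared run log.
#'
#' @param actors list of [dfActor()] objects.
#' @param edges list of [dfEdge()] objects.
#' @param kind `"body"` or `"subinit"`.
#' @return an environment of class `dfGraph`.
#' @export
dfGraph <- function(actors, edges = list(), kind = c("body", "subinit")) {
  kind <- match.arg(kind)
  g <- new.env(parent = emptyenv())
  g$actors <- setNames(actors, vapply(actors, function(a) a$name, ""))
  if (anyDuplicated(names(g$actors))) stop("duplicate actor names")
  g$edges <- edges
  g$kind <- kind
  g$log <- list()
  g$step <- 0L
  for (e in edges) {
    for (ref in list(e$from, e$to)) {
      if (!ref[1] %in% names(g$actors)) {
        stop("edge references unknown actor '", ref[1], "'")
      }
    }
    if (!e$from[2] %in% g$actors[[e$from[1]]]$outputs) {
      stop("unknown output port ", e$from[1], ":", e$from[2])
    }
    if (!e$to[2] %in% g$actors[[e$to[1]]]$inputs) {
      stop("unknown input port ", e$to[1], ":", e$to[2])
    }
  }
  for (a in actors) a$graph <- g
  g$order <- .dfTopoOrder(g)
  class(g) <- "dfGraph"
  g
}

## Downstream-first (reverse topological) order; cycles through delayed
## edges are broken by ignoring edges with delay > 0.
.dfTopoOrder <- function(g) {
  nm <- names(g$actors)
  succ <- setNames(vector("list", length(nm)), nm)
  indeg <- setNames(integer(length(nm)), nm)
  for (e in g$edges) {
    if (e$delay > 0L) next
    succ[[e$from[1]]] <- c(succ[[e$from[1]]], e$to[1])
    indeg[e$to[1]] <- indeg[e$to[1]] + 1L
  }
  order <- character(0)
  ready <- nm[indeg == 0L]
  while (length(ready)) {
    n <- ready[1]; ready <- ready[-1]
    order <- c(order, n)
    for (s in succ[[n]]) {
      indeg[s] <- indeg[s] - 1L
      if (indeg[s] == 0L) ready <- c(ready, s)
    }
  }
  if (length(order) < length(nm)) order <- c(order, setdiff(nm, order))
  rev(order)
}

.inEdges <- function(g, actor) {
  Filter(function(e) identical(e$to[1], actor), g$edges)
}
.outEdges <- function(g, actor) {
  Filter(function(e) identical(e$from[1], actor), g$edges)
}

#' Current token occupancy of an edge
#' @param edge a [dfEdge()].
#' @return integer number of queued tokens.
#' @export
dfTokens <- function(edge) length(edge$queue)

#' Firing rule: is an actor enabled?
#'
#' True iff every connected input port holds at least one token (the
#' consumption count of every port in this runtime is one token per
#' firing) and every output edge has capacity.  FIFO capacity is logically
#' unbounded; a watermark warning is emitted when an output queue exceeds
#' `watermark` tokens, but the actor remains enabled.
#'
#' @param graph a [dfGraph()].
#' @param actor actor name.
#' @param watermark queue-length warning threshold.
#' @return logical.
#' @export
dfEnabled <- function(graph, actor, watermark = 1000L) {
  if (!actor %in% names(graph$actors)) {
    stop("unknown actor '", actor, "'")
  }
  a <- graph$actors[[actor]]
  ins <- .inEdges(graph, actor)
  connected <- vapply(ins, function(e) e$to[2], "")
  ## every input port must be fed by an edge carrying a token
  for (p in a$inputs) {
    es <- ins[connected == p]
    if (length(es) == 0L) return(FALSE)
    if (any(vapply(es, dfTokens, 0L) < 1L)) return(FALSE)
  }
  for (e in .outEdges(graph, actor)) {
    if (dfTokens(e) > watermark) {
      warning("edge ", e$from[1], "->", e$to[1], " exceeds watermark")
    }
  }
  TRUE
}

#' Fire an enabled actor
#'
#' Consumes one token per input port, invokes the actor's `fire` function,
#' and produces one token per output port.  Payloads are passed by
#' reference: the payload object dequeued downstream is the identical R
#' object that was enqueued.  Firing a non-enabled actor is a scheduling
#' error.
#'
#' @inheritParams dfEnabled
#' @return invisibly, the named list of produced payloads.
#' @export
dfFire <- function(graph, actor) {
  if (!dfEnabled(graph, actor)) {
    stop("scheduling error: actor '", actor, "' fired while not enabled")
  }
  a <- graph$actors[[actor]]
  ins <- .inEdges(graph, actor)
  inputs <- list()
  for (p in a$inputs) {
    e <- ins[[which(vapply(ins, function(e) e$to[2], "") == p)[1]]]
    inputs[[p]] <- e$queue[[1]]
    e$queue <- e$queue[-1]
    e$consumed <- e$consumed + 1L
  }
  out <- a$fire(inputs, a)
  for (p in a$outputs) {
    if (!p %in% names(out)) {
      stop("actor '", actor, "' did not produce on port '", p, "'")
    }
  }
  outs <- .outEdges(graph, actor)
  for (e in outs) {
    e$queue <- c(e$queue, list(out[[e$from[2]]]))
    e$produced <- e$produced + 1L
  }
  a$firings <- a$firings + 1L
  graph$step <- graph$step + 1L
  graph$log[[length(graph$log) + 1L]] <-
    list(step = graph$step, actor = actor, event = "fire", info = "")
  ## outputs on ports with no edge are captured as graph port values
  ## (used as subinit graph outputs for PSDF parameter binding)
  edged <- vapply(outs, function(e) e$from[2], "")
  for (p in setdiff(a$outputs, edged)) {
    if (is.null(graph$portValues)) graph$portValues <- list()
    graph$portValues[[paste(actor, p, sep = ".")]] <- out[[p]]
  }
  invisible(out)
}

#' Append a diagnostic message to the graph run log
#'
#' @param graph a [dfGraph()] (or an actor's `$graph`).
#' @param actor actor name.
#' @param message message text; by convention keyed by frame index.
#' @export
dfLog <- function(graph, actor, message) {
  graph$log[[length(graph$log) + 1L]] <-
    list(step = graph$step, actor = actor, event = "message", info = message)
  invisible(NULL)
}

#' Retrieve the run log as a data.frame
#' @param graph a [dfGraph()].
#' @return data.frame with columns step, actor, event, info.
#' @export
runLog <- function(graph) {
  if (length(graph$log) == 0L) {
    return(data.frame(step = integer(), actor = character(),
                      event = character(), info = character()))
  }
  data.frame(
    step = vapply(graph$log, `[[`, 0L, "step"),
    actor = vapply(graph$log, `[[`, "", "actor"),
    event = vapply(graph$log, `[[`, "", "event"),
    info = vapply(graph$log, `[[`, "", "info")
  )
}

#' Run one iteration of a graph
#'
#' One iteration fires every actor exactly once (all actors in this
#' runtime have unit rates).  The scheduler is demand-driven and
#' single-threaded: at each step the most downstream enabled actor not yet
#' fired this iteration is fired.  If no actor is enabled before the
#' iteration completes, a deadlock error is raised with a snapshot of the
#' token counts.
#'
#' @param graph a [dfGraph()].
#' @return invisibly, the graph.
#' @export
dfRunIteration <- function(graph) {
  pending <- graph$order
  while (length(pending)) {
    fired <- FALSE
    for (nm in pending) {
      if (dfEnabled(graph, nm)) {
        dfFire(graph, nm)
        pending <- setdiff(pending, nm)
        fired <- TRUE
        break
      }
    }
    if (!fired) {
      snap <- vapply(graph$edges, function(e) {
        sprintf("%s:%s->%s:%s=%d", e$from[1], e$from[2], e$to[1], e$to[2],
                dfTokens(e))
      }, "")
      stop("deadlock: no actor enabled; tokens [",
           paste(snap, collapse = ", "), "]")
    }
  }
  invisible(graph)
}

#' Execute a PSDF body/subinit graph pair
#'
#' Runs the subinit graph for one iteration, transmits each captured
#' subinit output-port value to its bound body-actor parameters, then runs
#' the body graph for `nBodyIterations` iterations.  In real-time
#' operation the body iteration count equals the number of analysis
#' frames, so the subinit graph executes exactly once up front and is
#' effectively disabled for the remainder of the run.
#'
#' @param body body [dfGraph()].
#' @param subinit subinit [dfGraph()] or `NULL`.
#' @param bindings list of bindings, each
#'   `list(port = "Actor.port", targets = list(c(bodyActor, paramName), ...))`.
#' @param nBodyIterations nonnegative integer.
#' @return invisibly, a list with the two graphs and the bound values.
#' @export
runPSDF <- function(body, subinit = NULL, bindings = list(),
                    nBodyIterations = 0L) {
  stopifnot(nBodyIterations >= 0L)
  ## validate bindings before running anything
  for (b in bindings) {
    for (tgt in b$targets) {
      if (!tgt[1] %in% names(body$actors)) {
        stop("binding targets unknown body actor '", tgt[1], "'")
      }
      if (!tgt[2] %in% names(body$actors[[tgt[1]]]$params)) {
        stop("binding targets unknown parameter '", tgt[2], "' of actor '",
             tgt[1], "'")
      }
    }
  }
  bound <- list()
  if (!is.null(subinit)) {
    dfRunIteration(subinit)
    for (b in bindings) {
      if (is.null(subinit$portValues) ||
          !b$port %in% names(subinit$portValues)) {
        stop("subinit produced no value on port '", b$port, "'")
      }
      val <- subinit$portValues[[b$port]]
      for (tgt in b$targets) {
        body$actors[[tgt[1]]]$params[[tgt[2]]] <- val
        dfLog(body, tgt[1],
              sprintf("param %s bound from subinit port %s", tgt[2], b$port))
      }
      bound[[b$port]] <- val
    }
  }
  for (i in seq_len(nBodyIterations)) dfRunIteration(body)
  invisible(list(body = body, subinit = subinit, bound = bound))
}

#' Fork (broadcast) actor
#'
#' Consumes one token and produces the identical payload reference on each
#' of its `fanout` outputs (fan-out is fixed at construction).
#'
#' @param name actor name.
#' @param fanout number of output ports, named out1..outN.
#' @return a [dfActor()].
#' @export
forkActor <- function(name, fanout = 2L) {
  outs <- paste0("out", seq_len(fanout))
  dfActor(name, inputs = "in1", outputs = outs,
          fire = function(inputs, actor) {
            setNames(rep(list(inputs$in1), length(actor$outputs)),
                     actor$outputs)
          })
}

#' Image-source actor
#'
#' Each firing yields (a reference to) the next frame of the stream, in
#' index order.  Firing past the end of the stream is a stream error.
#'
#' @param name actor name.
#' @param frames list of frames, or a frame-stream closure as returned by
#'   [readFrameStream()].
#' @return a [dfActor()].
#' @export
imgSrcActor <- function(name, frames) {
  nextFrame <- if (is.function(frames)) frames else {
    local({
      i <- 0L
      function() {
        i <<- i + 1L
        if (i > length(frames)) stop("stream error: no frame ", i)
        frames[[i]]
      }
    })
  }
  dfActor(name, outputs = "out1", state = list(getter = nextFrame),
          fire = function(inputs, actor) {
            list(out1 = actor$state$getter())
          })
}

#' Sink actor collecting every consumed payload
#' @param name actor name.
#' @return a [dfActor()]; collected payloads are in `actor$state$items`.
#' @export
sinkActor <- function(name) {
  dfActor(name, inputs = "in1",
          state = list(items = list()),
          fire = function(inputs, actor) {
            actor$state$items[[length(actor$state$items) + 1L]] <- inputs$in1
            list()
          })
}
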