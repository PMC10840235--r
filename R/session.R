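# Session scopes and the reactive cycle: resolve deferred properties in a
# session's private variable environment, re-render, and dispatch browser
# events to native R callbacks.
#
# Each connected client owns one SessionScope. Its `vars` environment holds
# private copies of the declared session variables; deferred chart properties
# and event callbacks are evaluated with `vars` first on the search path, so
# `gene <- k` inside a click handler mutates only that client's copy.

new_scope <- function(app, session_id, token = new_token()) {
  scope <- new.env(parent = emptyenv())
  scope$app <- app
  scope$session_id <- session_id
  scope$token <- token
  scope$vars <- list2env(app$session_vars, parent = baseenv())
  scope$epoch <- 0L
  scope$resolved <- list()    # chart_id -> ResolvedChart
  scope$fragments <- list()   # chart_id -> RenderedFragment
  scope$widget_state <- list()
  scope$queue <- list()       # pending EventMessages, FIFO
  scope$processing <- FALSE
  scope$outbox <- list()      # WireMessages awaiting transport
  scope$log <- character()
  scope$open <- TRUE
  class(scope) <- "lc_scope"
  scope
}

#' @export
print.lc_scope <- function(x, ...) {
  cat(sprintf("<chartlink session %s (%s): vars %s>\n", x$session_id,
              if (x$open) "open" else "closed",
              paste(ls(x$vars), collapse = ", ")))
  invisible(x)
}

#' Read or set a session variable
#'
#' Handlers normally assign session variables directly (their evaluation
#' environment is the scope), but tests and scripted drivers can use these
#' accessors.
#'
#' @param scope an open session scope.
#' @param name variable name.
#' @param value new value.
#' @return `session_get` returns the variable's value in this session.
#' @export
session_get <- function(scope, name) get(name, envir = scope$vars, inherits = FALSE)

#' @rdname session_get
#' @export
session_set <- function(scope, name, value) {
  assign(name, value, envir = scope$vars)
  invisible(scope)
}

resolution_error <- function(chart_id, prop, parent_msg) {
  structure(class = c("lc_resolution_error", "error", "condition"),
            list(message = sprintf("chart '%s': property '%s' failed to resolve: %s",
                                   chart_id, prop, parent_msg),
                 call = NULL, chart_id = chart_id, property = prop))
}

#' Resolve a chart's properties in a session scope
#'
#' Evaluates every deferred property exactly once in the session's variable
#' environment, broadcasts scalar point-wise properties, validates the result
#' and stamps it with the scope's epoch counter. A failing deferred
#' expression raises a resolution error naming the chart and property; the
#' session itself stays alive.
#'
#' @param chart an `lc_chart` (or its chart id).
#' @param scope the session scope to evaluate in.
#' @return A `ResolvedChart`: `list(chart_id, kind, layers, page, epoch)`
#'   where `layers` maps layer id to concrete property lists.
#' @export
resolve_chart <- function(chart, scope) {
  if (is.character(chart)) chart <- chart_by_id(scope$app, chart)
  stopifnot(inherits(chart, "lc_chart"), inherits(scope, "lc_scope"))
  scope$epoch <- scope$epoch + 1L

  eval_props <- function(props) {
    out <- list()
    for (nm in names(props)) {
      v <- tryCatch(prop_eval(props[[nm]], scope), error = function(e) {
        stop(resolution_error(chart$chart_id, nm, conditionMessage(e)))
      })
      out[[nm]] <- v
    }
    out
  }

  layers <- list()
  for (layer in chart$layers) {
    p <- eval_props(layer$properties)
    p <- broadcast_props(layer$layer_type, p)
    layers[[layer$layer_id]] <- p
  }
  if (chart$kind == "widget") {
    # live widget state (per session) overrides the declared default value
    st <- scope$widget_state[[chart$chart_id]]
    if (!is.null(st)) layers[["L0"]][["value"]] <- st
  }

  resolved <- structure(list(chart_id = chart$chart_id, kind = chart$kind,
                             widget_type = chart$widget_type,
                             input_kind = chart$input_kind,
                             layer_types = vapply(chart$layers,
                                                  function(l) l$layer_type, ""),
                             layers = layers,
                             page = eval_props(chart$page_props),
                             epoch = scope$epoch),
                        class = "lc_resolved")
  errs <- validate_resolved(chart, layers)
  if (length(errs)) {
    stop(resolution_error(chart$chart_id, "(validation)",
                          paste(errs, collapse = "; ")))
  }
  scope$resolved[[chart$chart_id]] <- resolved
  resolved
}

chart_by_id <- function(app, id) {
  app$charts[[id]] %||% stop(sprintf("unknown chart id '%s'", id), call. = FALSE)
}

#' Re-resolve and re-render charts for one session
#'
#' The reactive step of the framework: the named charts are re-resolved
#' (re-evaluating their deferred properties against the session's current
#' variables) and re-rendered; charts not named are untouched, byte for byte.
#' The new fragments are cached on the scope and queued on its outbox as
#' update frames for the transport.
#'
#' @param ids character vector of chart ids.
#' @param scope the session to update; inside an event callback it defaults
#'   to the session the event came from.
#' @return Named list of [RenderedFragment][render_chart]s for the known ids,
#'   invisibly. Unknown ids raise an error (after the known ones have been
#'   updated).
#' @export
update_charts <- function(ids, scope = current_scope()) {
  stopifnot(inherits(scope, "lc_scope"))
  app <- scope$app
  unknown <- setdiff(ids, names(app$charts))
  out <- list()
  for (id in setdiff(ids, unknown)) {
    frag <- render_chart(resolve_chart(app$charts[[id]], scope))
    scope$fragments[[id]] <- frag
    scope$outbox <- c(scope$outbox,
                      list(wire_message("update", scope$token,
                                        list(container = id,
                                             markup = frag$markup))))
    out[[id]] <- frag
  }
  if (length(unknown)) {
    stop(sprintf("unknown chart id(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  invisible(out)
}

#' Register (or replace) an event handler
#'
#' @param chart_id,layer_id identify the handler slot; `layer_id` defaults to
#'   the first layer.
#' @param event_type `"click"`, `"hover"` or `"input_change"`.
#' @param callback for point/line/bar clicks a `function(k)` receiving the
#'   1-based element index; for heatmap cells a `function(rc)` receiving
#'   `c(row, col)` (1-based); for input changes a `function(value)`.
#' @param app the app handle.
#' @return `TRUE`, invisibly.
#' @export
register_handler <- function(chart_id, layer_id = "L0",
                             event_type = c("click", "hover", "input_change"),
                             callback, app = default_app()) {
  event_type <- match.arg(event_type)
  stopifnot(is.function(callback))
  chart <- chart_by_id(app, chart_id)
  li <- which(vapply(chart$layers, function(l) l$layer_id, "") == layer_id)
  if (!length(li)) {
    stop(sprintf("chart '%s' has no layer '%s'", chart_id, layer_id),
         call. = FALSE)
  }
  chart$layers[[li]]$handlers[[event_type]] <- callback
  invisible(TRUE)
}

#' Construct an event message
#'
#' The wire carries 0-based element indices (DOM convention); [dispatch_event()]
#' converts to 1-based before invoking R callbacks.
#'
#' @param session_id session id or scope.
#' @param chart_id,layer_id target chart and layer.
#' @param event_type `"click"`, `"hover"` or `"input_change"`.
#' @param payload 0-based element index, 0-based `c(row, col)` for heatmap
#'   cells, or the new widget state for `input_change`.
#' @return An `lc_event` message.
#' @export
event_message <- function(session_id, chart_id, layer_id = "L0",
                          event_type = c("click", "hover", "input_change"),
                          payload = NULL) {
  event_type <- match.arg(event_type)
  if (inherits(session_id, "lc_scope")) session_id <- session_id$session_id
  structure(list(session_id = session_id, chart_id = chart_id,
                 layer_id = layer_id, event_type = event_type,
                 payload = payload),
            class = "lc_event")
}

# Bounds check against the session's current resolved chart. Returns NULL if
# acceptable, else a diagnostic string.
event_bounds_error <- function(msg, scope) {
  res <- scope$resolved[[msg$chart_id]]
  if (is.null(res)) return(sprintf("chart '%s' not resolved yet", msg$chart_id))
  if (msg$event_type == "input_change") return(NULL)
  p <- res$layers[[msg$layer_id]]
  if (is.null(p)) return(sprintf("chart '%s' has no layer '%s'",
                                 msg$chart_id, msg$layer_id))
  lt <- res$layer_types[[match(msg$layer_id, names(res$layers))]]
  k <- msg$payload
  if (lt == "heatmap") {
    if (length(k) != 2L) return("heatmap event payload must be (row, col)")
    dims <- dim(p$value)
    if (any(k < 0) || k[1] >= dims[1] || k[2] >= dims[2]) {
      return(sprintf("heatmap index (%d,%d) out of bounds for %dx%d",
                     k[1], k[2], dims[1], dims[2]))
    }
    return(NULL)
  }
  n <- element_count(lt, p)
  if (length(k) != 1L || k < 0 || k >= n) {
    return(sprintf("element index %s out of bounds for layer of size %d",
                   paste(k, collapse = ","), n))
  }
  NULL
}

# number of interactive elements a layer exposes
element_count <- function(layer_type, p) {
  switch(layer_type,
         scatter = , beeswarm = length(p$y),
         line = , path = n_series(p$y),
         abline = length(p$a),
         hline = length(p$h),
         vline = length(p$v),
         bars = length(p$value),
         hist = if (!is.null(p$nbins)) p$nbins else 10L,
         dens = 1L,
         heatmap = length(p$value),
         1L)
}

n_series <- function(y) if (is.matrix(y)) ncol(y) else 1L

#' Dispatch a user-interaction event to its native R callback
#'
#' Events are queued per session and processed FIFO by a single consumer, so
#' callbacks for one session run serially in arrival order (a callback that
#' itself triggers dispatch just grows the queue). The registered callback
#' runs with the session's variable environment on its search path, so plain
#' `<-` assignments to session variables stay private to the session.
#'
#' Out-of-bounds indices reject the message (logged, session intact); a
#' missing handler is a silent no-op; an error inside a callback is caught,
#' logged with chart and session context, and leaves the session usable.
#'
#' @param msg an [event_message()].
#' @param scope the session scope the event belongs to.
#' @return Invisibly, `TRUE` if a callback ran, `FALSE` otherwise.
#' @export
dispatch_event <- function(msg, scope) {
  stopifnot(inherits(msg, "lc_event"), inherits(scope, "lc_scope"))
  scope$queue <- c(scope$queue, list(msg))
  if (scope$processing) return(invisible(TRUE))  # consumer already draining
  scope$processing <- TRUE
  on.exit(scope$processing <- FALSE)
  ran_any <- FALSE
  while (length(scope$queue)) {
    m <- scope$queue[[1L]]
    scope$queue <- scope$queue[-1L]
    ran_any <- run_event(m, scope) || ran_any
  }
  invisible(ran_any)
}

run_event <- function(msg, scope) {
  app <- scope$app
  chart <- app$charts[[msg$chart_id]]
  if (is.null(chart)) {
    log_entry(scope, sprintf("event for unknown chart '%s' dropped", msg$chart_id))
    return(FALSE)
  }
  err <- event_bounds_error(msg, scope)
  if (!is.null(err)) {
    log_entry(scope, sprintf("event rejected (%s/%s %s): %s", msg$chart_id,
                             msg$layer_id, msg$event_type, err))
    return(FALSE)
  }
  li <- which(vapply(chart$layers, function(l) l$layer_id, "") == msg$layer_id)
  cb <- if (length(li)) chart$layers[[li]]$handlers[[msg$event_type]] else NULL
  if (is.null(cb)) return(FALSE)   # no handler registered: silent no-op

  payload <- msg$payload
  if (msg$event_type == "input_change") {
    scope$widget_state[[msg$chart_id]] <- payload
  } else {
    payload <- payload + 1L        # wire is 0-based; R callbacks are 1-based
  }
  # Run the callback with the session's variables first on its search path:
  # reads see the session's copies, and `gene <<- k` assigns the session's
  # copy, never a true global. update_charts() called without a scope inside
  # the callback targets this session.
  run <- function() {
    prev <- .chartlink_state$current_scope
    .chartlink_state$current_scope <- scope
    on.exit(.chartlink_state$current_scope <- prev, add = TRUE)
    with_scope_parent(scope, environment(cb), function() {
      environment(cb) <- scope$vars
      cb(payload)
    })
  }
  ok <- tryCatch({ run(); TRUE },
                 error = function(e) {
                   log_entry(scope, sprintf(
                     "callback error (chart '%s', session %s): %s",
                     msg$chart_id, scope$session_id, conditionMessage(e)))
                   scope$outbox <- c(scope$outbox, list(wire_message(
                     "error", scope$token,
                     list(message = conditionMessage(e), chart = msg$chart_id))))
                   FALSE
                 })
  ok
}

#' The session scope whose callback is currently running
#'
#' Valid only inside an event callback; this is what lets a handler call
#' `update_charts("A2")` without naming its session.
#' @return The current `lc_scope`.
#' @export
current_scope <- function() {
  .chartlink_state$current_scope %||%
    stop("no session scope is current (not inside an event callback)",
         call. = FALSE)
}
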