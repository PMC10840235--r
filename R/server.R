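# Embedded session server. The wire protocol is one JSON text frame per
# message, {kind, token, body}, with kinds hello/event/update/error/bye.
# Sessions are transport-agnostic: every scope owns an outbox of frames, and
# a transport (the in-process driver used by tests and scripted clients, or
# the optional httpuv HTTP+WebSocket backend) delivers them. All event
# handling runs through handle_message() either way, so headless runs
# exercise exactly the code paths a browser does.

#' Build / parse wire messages
#'
#' @param kind one of `"hello"`, `"event"`, `"update"`, `"error"`, `"bye"`.
#' @param token session token.
#' @param body named list payload.
#' @return `wire_message()` returns an `lc_wire` list; `wire_encode()` a JSON
#'   string; `wire_decode()` parses one frame (erroring on malformed JSON or
#'   unknown kinds).
#' @export
wire_message <- function(kind, token, body = list()) {
  kind <- match.arg(kind, c("hello", "event", "update", "error", "bye"))
  structure(list(kind = kind, token = token, body = body), class = "lc_wire")
}

#' @rdname wire_message
#' @param msg an `lc_wire` message.
#' @export
wire_encode <- function(msg) {
  stopifnot(inherits(msg, "lc_wire"))
  as.character(jsonlite::toJSON(unclass(msg), auto_unbox = TRUE, null = "null"))
}

#' @rdname wire_message
#' @param frame a single JSON text frame.
#' @export
wire_decode <- function(frame) {
  x <- tryCatch(jsonlite::fromJSON(frame, simplifyVector = TRUE),
                error = function(e) stop("malformed frame: not valid JSON",
                                         call. = FALSE))
  if (!is.list(x) || is.null(x$kind) || is.null(x$token)) {
    stop("malformed frame: missing kind or token", call. = FALSE)
  }
  if (!x$kind %in% c("hello", "event", "update", "error", "bye")) {
    stop(sprintf("malformed frame: unknown kind '%s'", x$kind), call. = FALSE)
  }
  wire_message(x$kind, x$token, as.list(x$body) %||% list())
}

#' Start an app
#'
#' Marks the app as running and, if `port` is given, binds an HTTP endpoint
#' (serving the page, the browser shim and registered static assets) plus a
#' WebSocket channel endpoint at `/ws` via the httpuv package. With
#' `port = NULL` the app runs headlessly: sessions are opened in-process with
#' [open_session()] and driven with [handle_message()] — the same code path a
#' browser client takes.
#'
#' @param app an [lc_app()] handle (its page and charts must be declared).
#' @param host interface to bind; loopback by default, so exposing an app to
#'   colleagues is an explicit choice.
#' @param port TCP port, or `NULL` for headless operation.
#' @return The handle, invisibly. Fails if the port is already in use.
#' @export
start_app <- function(app, host = "127.0.0.1", port = NULL) {
  stopifnot(inherits(app, "lc_app"))
  if (app$running) stop("app already running; stop_app() first", call. = FALSE)
  if (!is.null(port)) {
    if (!requireNamespace("httpuv", quietly = TRUE)) {
      stop("serving over HTTP requires the httpuv package", call. = FALSE)
    }
    app$server <- tryCatch(
      httpuv::startServer(host, port, httpuv_app(app)),
      error = function(e) stop(sprintf("cannot bind port %d: %s", port,
                                       conditionMessage(e)), call. = FALSE))
  }
  app$host <- host
  app$port <- port
  app$running <- TRUE
  invisible(app)
}

#' Open a session
#'
#' Creates a fresh scope with private copies of the declared session
#' variables, resolves and renders every chart for it, and queues the initial
#' frames (a hello carrying the session token, then one update per chart) on
#' its outbox. Tokens are single-use: a stale token never reattaches.
#'
#' @param app a running app handle.
#' @param client optional transport send function `function(frame_text)`;
#'   when present, queued frames are flushed through it.
#' @return The new `lc_scope`, or an error if the session limit is reached.
#' @export
open_session <- function(app, client = NULL) {
  stopifnot(inherits(app, "lc_app"))
  if (!app$running) stop("app is not running", call. = FALSE)
  if (length(app$sessions) >= app$max_sessions) {
    stop(sprintf("session limit reached (%d); please try again later",
                 app$max_sessions), call. = FALSE)
  }
  sid <- sprintf("s%03d", length(app$sessions) + 1L)
  scope <- new_scope(app, sid)
  scope$send <- client
  app$sessions[[scope$token]] <- scope
  scope$outbox <- list(wire_message("hello", scope$token,
                                    list(session = sid)))
  update_charts(names(app$charts), scope)
  flush_outbox(scope)
  scope
}

flush_outbox <- function(scope) {
  if (is.null(scope$send)) return(invisible(NULL))
  for (m in scope$outbox) scope$send(wire_encode(m))
  scope$outbox <- list()
  invisible(NULL)
}

#' Drain a session's pending outbound frames
#'
#' The in-process transport: returns and clears the frames queued since the
#' last call. Tests and scripted clients use this to observe exactly what a
#' browser would receive.
#'
#' @param scope a session scope.
#' @return List of `lc_wire` messages.
#' @export
take_outbox <- function(scope) {
  out <- scope$outbox
  scope$outbox <- list()
  out
}

#' Handle one inbound wire frame
#'
#' Parses the frame, locates the session by token and dispatches: event
#' frames go through [dispatch_event()] and any resulting update frames are
#' queued for (only) that session; bye closes the session. Malformed frames
#' produce an error frame and a log entry but never kill the server; frames
#' for unknown/closed sessions are dropped with a log entry.
#'
#' @param app the app handle.
#' @param frame one JSON text frame.
#' @return Invisibly, the list of frames queued for the session in response.
#' @export
handle_message <- function(app, frame) {
  msg <- tryCatch(wire_decode(frame), error = function(e) e)
  if (inherits(msg, "error")) {
    log_entry(app, sprintf("malformed frame dropped: %s", conditionMessage(msg)))
    return(invisible(list(wire_message("error", "",
                                       list(message = conditionMessage(msg))))))
  }
  scope <- app$sessions[[msg$token]]
  if (is.null(scope) || !scope$open) {
    log_entry(app, sprintf("frame for unknown or closed session '%s' dropped",
                           msg$token))
    return(invisible(list()))
  }
  n0 <- length(scope$outbox)
  if (msg$kind == "bye") {
    close_session(app, scope)
    return(invisible(list()))
  }
  if (msg$kind == "event") {
    b <- msg$body
    payload <- b$payload
    if (identical(b$event_type, "click") || identical(b$event_type, "hover")) {
      payload <- as.integer(unlist(payload))
    }
    ev <- tryCatch(
      event_message(scope, b$chart_id, b$layer_id %||% "L0",
                    b$event_type, payload),
      error = function(e) e)
    if (inherits(ev, "error")) {
      log_entry(app, sprintf("bad event frame: %s", conditionMessage(ev)))
      scope$outbox <- c(scope$outbox, list(wire_message(
        "error", scope$token, list(message = conditionMessage(ev)))))
    } else {
      dispatch_event(ev, scope)
    }
  }
  out <- if (length(scope$outbox) > n0) scope$outbox[-seq_len(n0)] else list()
  flush_outbox(scope)
  invisible(out)
}

close_session <- function(app, scope) {
  scope$open <- FALSE
  scope$outbox <- c(scope$outbox, list(wire_message("bye", scope$token)))
  flush_outbox(scope)
  app$sessions[[scope$token]] <- NULL
  invisible(NULL)
}

#' Register a static asset route
#'
#' Serves extra files (CSS, images, scripts) alongside the page. The media
#' type is inferred from the file extension; unknown extensions are served as
#' generic binary.
#'
#' @param app the app handle.
#' @param route URL path, e.g. `"/style.css"`.
#' @param content_or_path raw vector / character content, or a path to a file
#'   on disk.
#' @return `TRUE` invisibly.
#' @export
serve_static <- function(app, route, content_or_path) {
  stopifnot(is.character(route), length(route) == 1L, startsWith(route, "/"))
  if (route %in% c("/", "/ws", "/chartlink-shim.js")) {
    stop(sprintf("route '%s' collides with a reserved endpoint", route),
         call. = FALSE)
  }
  content <- if (is.raw(content_or_path)) {
    content_or_path
  } else if (is.character(content_or_path) && length(content_or_path) == 1L &&
             file.exists(content_or_path)) {
    readBin(content_or_path, "raw", file.size(content_or_path))
  } else {
    charToRaw(paste(content_or_path, collapse = "\n"))
  }
  app$static[[route]] <- list(content = content, type = media_type(route))
  invisible(TRUE)
}

media_type <- function(path) {
  switch(tolower(tools::file_ext(path)),
         css = "text/css", js = "application/javascript",
         html = "text/html", svg = "image/svg+xml",
         png = "image/png", jpg = , jpeg = "image/jpeg",
         json = "application/json",
         "application/octet-stream")
}

#' Stop an app
#'
#' Sends bye to every open session, closes them, and releases the port.
#' Idempotent: stopping a stopped app is a no-op.
#'
#' @param app the app handle.
#' @return `TRUE` invisibly.
#' @export
stop_app <- function(app) {
  if (!app$running) return(invisible(TRUE))
  for (scope in app$sessions) close_session(app, scope)
  if (!is.null(app$server)) {
    app$server$stop()
    app$server <- NULL
  }
  app$running <- FALSE
  invisible(TRUE)
}

#' Re-render charts for every open session
#'
#' [update_charts()] targets one session (the triggering client); this
#' broadcast variant re-resolves and re-renders the named charts for all open
#' sessions, e.g. after the underlying dataset changed.
#'
#' @param app the app handle.
#' @param ids chart ids to update.
#' @return Invisibly, `TRUE`.
#' @export
broadcast_update <- function(app, ids) {
  for (scope in app$sessions) {
    update_charts(ids, scope)
    flush_outbox(scope)
  }
  invisible(TRUE)
}

# ---- httpuv backend --------------------------------------------------------

app_page_html <- function(app, config = NULL) {
  # a throwaway scope renders the initial (default-variable) fragments
  tmp <- new_scope(app, "s000")
  frags <- list()
  for (id in names(app$charts)) {
    frags[[id]] <- render_chart(resolve_chart(app$charts[[id]], tmp))
  }
  render_page(app$page, frags, config = config)
}

shim_path <- function() {
  system.file("shim", "chartlink-shim.js", package = "chartlink")
}

httpuv_app <- function(app) {
  list(
    call = function(req) {
      path <- req$PATH_INFO
      if (path == "/") {
        return(list(status = 200L,
                    headers = list("Content-Type" = "text/html; charset=utf-8"),
                    body = app_page_html(app, config = list(endpoint = "/ws"))))
      }
      if (path == "/chartlink-shim.js") {
        return(list(status = 200L,
                    headers = list("Content-Type" = "application/javascript"),
                    body = paste(readLines(shim_path(), warn = FALSE),
                                 collapse = "\n")))
      }
      st <- app$static[[path]]
      if (!is.null(st)) {
        return(list(status = 200L, headers = list("Content-Type" = st$type),
                    body = st$content))
      }
      list(status = 404L, headers = list("Content-Type" = "text/plain"),
           body = "not found")
    },
    onWSOpen = function(ws) {
      scope <- tryCatch(open_session(app, client = function(txt) ws$send(txt)),
                        error = function(e) {
                          ws$send(wire_encode(wire_message("error", "",
                            list(message = conditionMessage(e)))))
                          ws$close()
                          NULL
                        })
      if (is.null(scope)) return(invisible(NULL))
      ws$onMessage(function(binary, message) {
        handle_message(app, message)
      })
      ws$onClose(function() {
        if (scope$open) close_session(app, scope)
      })
    }
  )
}
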