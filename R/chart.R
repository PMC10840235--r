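# Chart declaration and the app-level chart registry.
#
# An app handle owns a page, a chart registry, the declared session-variable
# defaults, and the open sessions. Charts and the handle are environments:
# declaring or re-declaring a chart mutates the registry in place, which is
# the natural interaction model for an exploratory tool (re-run a constructor
# line, get the new chart).

.chartlink_state <- new.env(parent = emptyenv())

#' Create an app handle
#'
#' An app handle holds the page layout, the chart registry, the per-session
#' variable template and all open sessions. It is also the first argument of
#' [start_app()]. The most recently created handle becomes the default used
#' by the chart constructors.
#'
#' @param page a [page_spec()]; defaults to an empty page to which containers
#'   are added automatically as charts are declared.
#' @param session_vars named list of session variables and their defaults.
#'   Every session opened on this app receives its own private copy of each.
#' @param max_sessions maximum number of concurrently open sessions.
#' @return An object of class `lc_app`.
#' @examples
#' app <- lc_app(session_vars = list(gene = 1))
#' lc_scatter(x = 1:3, y = 4:6, place = "A1", app = app)
#' @export
lc_app <- function(page = page_spec(), session_vars = list(),
                   max_sessions = 50L) {
  if (length(session_vars) && (is.null(names(session_vars)) ||
                               any(!nzchar(names(session_vars))))) {
    stop("session_vars must be a fully named list", call. = FALSE)
  }
  app <- new.env(parent = emptyenv())
  app$page <- page
  app$charts <- list()
  app$session_vars <- session_vars
  app$sessions <- list()
  app$max_sessions <- as.integer(max_sessions)
  app$running <- FALSE
  app$server <- NULL
  app$host <- NULL
  app$port <- NULL
  app$static <- list()
  app$log <- character()
  class(app) <- "lc_app"
  .chartlink_state$default_app <- app
  app
}

#' @export
print.lc_app <- function(x, ...) {
  state <- if (!x$running) "" else if (is.null(x$port)) ", running headless"
  else sprintf(", serving on %s:%s", x$host, x$port)
  cat(sprintf("<chartlink app: %d chart(s), %d open session(s)%s>\n",
              length(x$charts), length(x$sessions), state))
  invisible(x)
}

#' Return (or create) the default app handle
#' @return The `lc_app` most recently created, or a fresh one.
#' @export
default_app <- function() {
  if (is.null(.chartlink_state$default_app)) lc_app() else .chartlink_state$default_app
}

new_layer <- function(layer_id, layer_type, properties, handlers = list()) {
  structure(list(layer_id = layer_id, layer_type = layer_type,
                 properties = properties, handlers = handlers),
            class = "lc_layer")
}

split_handlers <- function(args) {
  handlers <- list()
  keep <- list()
  nms <- names(args) %||% rep("", length(args))
  for (i in seq_along(args)) {
    slot <- if (nzchar(nms[i])) handler_slot_for(nms[i]) else NULL
    if (!is.null(slot)) {
      cb <- args[[i]]
      if (!is.function(cb)) stop(sprintf("%s must be a function", nms[i]), call. = FALSE)
      handlers[[slot]] <- cb
    } else {
      keep[[length(keep) + 1L]] <- args[[i]]
      names(keep)[length(keep)] <- nms[i]
    }
  }
  list(handlers = handlers, props = keep)
}

#' Declare a chart
#'
#' Low-level constructor behind the `lc_*` family. Validates property names
#' against the schema for `chart_type` (unknown names are an immediate error;
#' missing required names too), stores deferred properties unevaluated, and
#' registers the chart under its placement id. Re-declaring a chart at the
#' same placement replaces it.
#'
#' @param chart_type one of [constructor_roster()].
#' @param place container id on the page (also the chart id), e.g. `"A1"`.
#' @param properties named list of property values; entries may be wrapped by
#'   [dat()] for deferred evaluation.
#' @param handlers named list of callbacks: `click`, `hover`, `input_change`.
#' @param app the app handle to register the chart on.
#' @return The registered chart (class `lc_chart`), invisibly.
#' @export
new_chart <- function(chart_type, place, properties = list(),
                      handlers = list(), app = default_app()) {
  chart_type <- match.arg(chart_type, c(.layer_types, .widget_types))
  assert_token(place, "place")
  props <- normalise_props(properties)
  check_prop_names(chart_type, props)
  if (length(handlers)) {
    bad <- setdiff(names(handlers), .event_types)
    if (length(bad)) {
      stop(sprintf("unknown event type(s): %s; valid: %s",
                   paste(bad, collapse = ", "),
                   paste(.event_types, collapse = ", ")), call. = FALSE)
    }
  }

  page_idx <- names(props) %in% .page_props
  chart <- new.env(parent = emptyenv())
  chart$chart_id <- place
  chart$kind <- if (is_widget_type(chart_type)) "widget" else "plot"
  chart$widget_type <- if (chart$kind == "widget") chart_type else NULL
  chart$page_props <- props[page_idx]
  chart$layers <- list()
  class(chart) <- "lc_chart"

  if (chart$kind == "plot") {
    chart$layers <- list(new_layer("L0", chart_type, props[!page_idx], handlers))
  } else {
    # widgets have exactly one layer-equivalent payload
    chart$layers <- list(new_layer("L0", chart_type, props[!page_idx], handlers))
    if (chart_type == "input") {
      kind <- prop_eval(props[["type"]])
      if (!is.character(kind) || length(kind) != 1L || !kind %in% .input_kinds) {
        stop(sprintf("input type must be one of: %s",
                     paste(.input_kinds, collapse = ", ")), call. = FALSE)
      }
      chart$input_kind <- kind
    }
  }

  if (!place %in% vapply(app$page$containers, `[[`, "", "id")) {
    app$page <- add_container(app$page, place)
  }
  app$charts[[place]] <- chart
  invisible(chart)
}

#' @export
print.lc_chart <- function(x, ...) {
  cat(sprintf("<chartlink %s '%s': %s>\n", x$kind, x$chart_id,
              paste(vapply(x$layers, function(l) l$layer_type, ""), collapse = "+")))
  invisible(x)
}

#' Add a layer to an existing plot chart
#'
#' Appends a layer (e.g. a reference [hline][lc_hline] under a scatter) with a
#' fresh layer id; existing layers are untouched. Widgets cannot receive
#' layers.
#'
#' @param chart a plot chart returned by a constructor.
#' @param layer_type one of the eleven plot layer types.
#' @param ... layer properties (named, or wrapped in [dat()]) and optional
#'   `on_click` / `on_hover` callbacks for the new layer.
#' @return The chart, invisibly (modified in place).
#' @export
add_layer <- function(chart, layer_type, ...) {
  stopifnot(inherits(chart, "lc_chart"))
  if (chart$kind != "plot") {
    stop(sprintf("cannot add a plot layer to widget '%s'", chart$chart_id),
         call. = FALSE)
  }
  layer_type <- match.arg(layer_type, .layer_types)
  sp <- split_handlers(list(...))
  props <- normalise_props(sp$props)
  check_prop_names(layer_type, props, page_level = FALSE)
  layer_id <- paste0("L", length(chart$layers))
  chart$layers <- c(chart$layers, list(new_layer(layer_id, layer_type, props,
                                                 sp$handlers)))
  invisible(chart)
}

make_constructor <- function(type) {
  force(type)
  function(..., place, app = default_app()) {
    sp <- split_handlers(list(...))
    new_chart(type, place, properties = sp$props, handlers = sp$handlers,
              app = app)
  }
}

#' Chart and widget constructors
#'
#' One constructor per entry of [constructor_roster()]. Each takes named
#' properties (wrap data-dependent ones in [dat()] to defer them), optional
#' `on_click` / `on_hover` / `on_change` callbacks, a `place` container id and
#' an `app` handle.
#'
#' Required properties: `x`, `y` for scatter/line/path; `y` for beeswarm;
#' `a`, `b` for abline; `h` for hline; `v` for vline; `value` for
#' bars/hist/dens/heatmap; `type` for input; `content` for html; `src` for
#' image.
#'
#' @param ... named properties, [dat()] blocks and event callbacks.
#' @param place container id on the page (doubles as the chart id).
#' @param app app handle (defaults to the most recently created one).
#' @return The registered chart, invisibly.
#' @examples
#' app <- lc_app(session_vars = list(gene = 1))
#' m <- matrix(rnorm(40), nrow = 10)
#' lc_scatter(x = rowMeans(m), y = m[, 1] - m[, 2], place = "A1", app = app,
#'            on_click = function(k) invisible(k))
#' lc_scatter(dat(y = m[gene, ]), x = 1:4, place = "A2", app = app)
#' @name constructors
NULL

#' @rdname constructors
#' @export
lc_scatter <- make_constructor("scatter")
#' @rdname constructors
#' @export
lc_beeswarm <- make_constructor("beeswarm")
#' @rdname constructors
#' @export
lc_line <- make_constructor("line")
#' @rdname constructors
#' @export
lc_path <- make_constructor("path")
#' @rdname constructors
#' @export
lc_abline <- make_constructor("abline")
#' @rdname constructors
#' @export
lc_hline <- make_constructor("hline")
#' @rdname constructors
#' @export
lc_vline <- make_constructor("vline")
#' @rdname constructors
#' @export
lc_bars <- make_constructor("bars")
#' @rdname constructors
#' @export
lc_hist <- make_constructor("hist")
#' @rdname constructors
#' @export
lc_dens <- make_constructor("dens")
#' @rdname constructors
#' @export
lc_heatmap <- make_constructor("heatmap")
#' @rdname constructors
#' @export
lc_colourSlider <- make_constructor("colourSlider")
#' @rdname constructors
#' @export
lc_input <- make_constructor("input")
#' @rdname constructors
#' @export
lc_html <- make_constructor("html")
#' @rdname constructors
#' @export
lc_image <- make_constructor("image")
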