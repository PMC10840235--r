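# Shape validation of resolved (concretely evaluated) chart properties.
# Runs after every resolution; collects every violation rather than stopping
# at the first, and never throws — bad data comes back as a structured error
# list so a live session survives a buggy deferred expression.

.pointwise_props <- c("color", "size", "label", "opacity")

#' Validate the resolved properties of a chart
#'
#' Checks per-layer length and dimension consistency of concretely evaluated
#' properties: point-wise vectors (`x`, `y`, `color`, `size`, `label`,
#' `opacity`) must share one length (scalars are broadcast before this check),
#' a heatmap `value` must be a matrix whose row/column label counts match its
#' dimensions, and bar labels must match the value count. All violations are
#' reported, not just the first; any input yields a result, never an error.
#'
#' @param chart an `lc_chart`.
#' @param resolved named list: for each layer id, a named list of concrete
#'   property values (as produced by [resolve_chart()]).
#' @return A character vector of violations; length zero means the chart is
#'   valid.
#' @export
validate_resolved <- function(chart, resolved) {
  tryCatch(validate_resolved_impl(chart, resolved),
           error = function(e) sprintf("invalid input: %s", conditionMessage(e)))
}

validate_resolved_impl <- function(chart, resolved) {
  errs <- character()
  say <- function(layer, fmt, ...) {
    errs <<- c(errs, sprintf("layer %s: %s", layer, sprintf(fmt, ...)))
  }
  if (!inherits(chart, "lc_chart")) return("invalid input: not an lc_chart")
  if (chart$kind == "widget") return(errs)

  for (layer in chart$layers) {
    p <- resolved[[layer$layer_id]]
    if (is.null(p)) {
      errs <- c(errs, sprintf("layer %s: no resolved properties", layer$layer_id))
      next
    }
    lt <- layer$layer_type
    if (lt %in% c("scatter", "beeswarm", "line", "path")) {
      lens <- vapply(intersect(c("x", "y", .pointwise_props), names(p)),
                     function(nm) length(p[[nm]]), 0L)
      lens <- lens[lens > 0L]
      n <- if (lt == "beeswarm") length(p$y) else
        max(length(p$x), length(p$y))
      for (nm in names(lens)) {
        if (lens[[nm]] != n) {
          say(layer$layer_id, "property '%s' has length %d, expected %d",
              nm, lens[[nm]], n)
        }
      }
    } else if (lt %in% c("abline", "hline", "vline")) {
      key <- switch(lt, abline = "a", hline = "h", vline = "v")
      n <- length(p[[key]])
      if (lt == "abline" && length(p$b) != n) {
        say(layer$layer_id, "property 'b' has length %d, expected %d",
            length(p$b), n)
      }
      if (!is.null(p$color) && !length(p$color) %in% c(1L, n)) {
        say(layer$layer_id, "property 'color' has length %d, expected %d",
            length(p$color), n)
      }
    } else if (lt == "bars") {
      n <- length(p$value)
      for (nm in intersect(c("label", "color"), names(p))) {
        if (!length(p[[nm]]) %in% c(1L, n)) {
          say(layer$layer_id, "property '%s' has length %d, expected %d",
              nm, length(p[[nm]]), n)
        }
      }
    } else if (lt %in% c("hist", "dens")) {
      if (!is.numeric(p$value) || !length(p$value)) {
        say(layer$layer_id, "property 'value' must be a non-empty numeric vector")
      }
    } else if (lt == "heatmap") {
      v <- p$value
      if (!is.matrix(v)) {
        say(layer$layer_id, "property 'value' must be a matrix")
      } else {
        if (!is.null(p$rowLabels) && length(p$rowLabels) != nrow(v)) {
          say(layer$layer_id, "row label count %d != %d",
              length(p$rowLabels), nrow(v))
        }
        if (!is.null(p$colLabels) && length(p$colLabels) != ncol(v)) {
          say(layer$layer_id, "column label count %d != %d",
              length(p$colLabels), ncol(v))
        }
        if (!is.null(p$rowOrder) &&
            !setequal(p$rowOrder, seq_len(nrow(v)))) {
          say(layer$layer_id, "rowOrder is not a permutation of 1..%d", nrow(v))
        }
        if (!is.null(p$colOrder) &&
            !setequal(p$colOrder, seq_len(ncol(v)))) {
          say(layer$layer_id, "colOrder is not a permutation of 1..%d", ncol(v))
        }
      }
    }
  }
  errs
}

# Broadcast scalar point-wise properties (color, size, ...) to length n.
broadcast_props <- function(layer_type, p) {
  n <- switch(layer_type,
              scatter = , line = , path = max(length(p$x), length(p$y)),
              beeswarm = length(p$y),
              bars = length(p$value),
              NULL)
  if (is.null(n)) return(p)
  for (nm in intersect(.pointwise_props, names(p))) {
    if (length(p[[nm]]) == 1L && n > 1L) p[[nm]] <- rep(p[[nm]], n)
  }
  p
}
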