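# Property schemas: which property names each layer/widget type accepts and
# which are required. Unknown names are hard errors at declaration (typo
# safety in an interactive tool); length/shape consistency is checked only at
# resolve time, because a deferred property has no value until then.

.layer_types <- c("scatter", "beeswarm", "line", "path", "abline", "hline",
                  "vline", "bars", "hist", "dens", "heatmap")
.widget_types <- c("colourSlider", "input", "html", "image")

# Page-level properties accepted by every chart.
.page_props <- c("title", "width", "height", "axisTitleX", "axisTitleY",
                 "logScaleX", "logScaleY", "domainX", "domainY")

# Per-layer property schema: required + optional (point-wise props are
# broadcast / length-checked at resolve time).
.layer_schema <- list(
  scatter  = list(required = c("x", "y"),
                  optional = c("color", "size", "label", "opacity")),
  beeswarm = list(required = c("y"),
                  optional = c("x", "color", "size", "label", "opacity")),
  line     = list(required = c("x", "y"),
                  optional = c("color", "width", "label")),
  path     = list(required = c("x", "y"),
                  optional = c("color", "width", "label")),
  abline   = list(required = c("a", "b"), optional = c("color", "width")),
  hline    = list(required = c("h"), optional = c("color", "width")),
  vline    = list(required = c("v"), optional = c("color", "width")),
  bars     = list(required = c("value"),
                  optional = c("label", "color")),
  hist     = list(required = c("value"),
                  optional = c("nbins", "limits", "color")),
  dens     = list(required = c("value"),
                  optional = c("bandwidth", "color")),
  heatmap  = list(required = c("value"),
                  optional = c("rowLabels", "colLabels", "palette",
                               "rowOrder", "colOrder", "highlight"))
)

.widget_schema <- list(
  colourSlider = list(required = character(),
                      optional = c("palette", "domain", "value")),
  input        = list(required = c("type"),
                      optional = c("labels", "value", "min", "max", "step")),
  html         = list(required = c("content"), optional = character()),
  image        = list(required = c("src"), optional = c("width", "height"))
)

.input_kinds <- c("button", "checkbox", "radio", "range", "text")

.event_types <- c("click", "hover", "input_change")

handler_slot_for <- function(arg_name) {
  switch(arg_name,
         on_click = "click",
         on_hover = "hover",
         on_change = "input_change",
         NULL)
}

is_widget_type <- function(type) type %in% .widget_types
is_layer_type <- function(type) type %in% .layer_types

schema_for <- function(type) {
  .layer_schema[[type]] %||% .widget_schema[[type]] %||%
    stop(sprintf("unknown chart type '%s'; valid types: %s", type,
                 paste(c(.layer_types, .widget_types), collapse = ", ")),
         call. = FALSE)
}

check_prop_names <- function(type, props, page_level = TRUE) {
  sch <- schema_for(type)
  valid <- c(sch$required, sch$optional, if (page_level) .page_props)
  unknown <- setdiff(names(props), valid)
  if (length(unknown)) {
    stop(sprintf("unknown propert%s for %s: %s; valid names: %s",
                 if (length(unknown) > 1L) "ies" else "y", type,
                 paste(unknown, collapse = ", "),
                 paste(valid, collapse = ", ")), call. = FALSE)
  }
  missing <- setdiff(sch$required, names(props))
  if (length(missing)) {
    stop(sprintf("required property absent: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' The public chart and widget constructor roster
#'
#' Returns the names of the chart/widget types for which the package exports a
#' constructor (`lc_scatter()`, `lc_beeswarm()`, ..., `lc_image()`): eleven
#' plot layer types and four widget types, fifteen in all.
#'
#' @return A character vector of length 15, duplicate-free and stable across
#'   calls.
#' @examples
#' constructor_roster()
#' @export
constructor_roster <- function() {
  c(.layer_types, .widget_types)
}
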