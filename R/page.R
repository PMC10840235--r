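# Page layout: an ordered list of containers, each identified by an id that
# charts reference as their placement. Containers may carry custom HTML
# (headlines, explanatory text) passed through verbatim.

#' Describe an HTML page layout
#'
#' @param containers character vector of container ids, or a list of
#'   `list(id =, html =)` entries where `html` is custom markup rendered
#'   verbatim before the chart.
#' @param title page title.
#' @return An object of class `lc_page`.
#' @examples
#' page_spec(c("A1", "A2"), title = "Differential expression explorer")
#' @export
page_spec <- function(containers = list(), title = "chartlink app") {
  if (is.character(containers)) {
    containers <- lapply(containers, function(id) list(id = id, html = NULL))
  }
  ids <- vapply(containers, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate container id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  structure(list(containers = containers, title = title), class = "lc_page")
}

add_container <- function(page, id, html = NULL) {
  stopifnot(inherits(page, "lc_page"))
  ids <- vapply(page$containers, `[[`, "", "id")
  if (id %in% ids) return(page)
  page$containers <- c(page$containers, list(list(id = id, html = html)))
  page
}

#' @export
print.lc_page <- function(x, ...) {
  cat(sprintf("<chartlink page '%s': containers %s>\n", x$title,
              paste(vapply(x$containers, `[[`, "", "id"), collapse = ", ")))
  invisible(x)
}
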