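# Server-side SVG rendering. Fragments are deterministic text: fixed element
# order, fixed 2-decimal coordinate formatting, no timestamps or random ids,
# so identical resolved input yields byte-identical markup. Every interactive
# element carries a stable identifier
#     lc-{chart}-{layer}-{index}            (points, lines, bars, bins)
#     lc-{chart}-{layer}-{row}-{col}        (heatmap cells)
# with 0-based data indices; the browser shim parses these back into event
# messages, so the grammar is a bit-exact contract.

.default_size <- c(400, 400)
.margin <- 40
.default_point_color <- "#444444"
.default_palette <- c("#0571b0", "#f7f7f7", "#ca0020")

elem_id <- function(chart, layer, ...) {
  paste("lc", chart, layer, ..., sep = "-")
}

#' Render a resolved chart to an SVG fragment
#'
#' @param resolved a `ResolvedChart` from [resolve_chart()].
#' @param scales optional named list with `x` and/or `y` [scale_new()] scales;
#'   by default scales are derived from the resolved data (domains snapped to
#'   round tick limits).
#' @return A `RenderedFragment`: `list(markup, id_map, size, diagnostics)`
#'   where `id_map` is a data frame mapping `(layer, index)` to element
#'   identifiers, bijectively, and `diagnostics$skipped` counts elements
#'   dropped for non-finite coordinates.
#' @export
render_chart <- function(resolved, scales = NULL) {
  stopifnot(inherits(resolved, "lc_resolved"))
  if (resolved$kind == "widget") return(render_widget(resolved))

  page <- resolved$page
  w <- page$width %||% .default_size[1]
  h <- page$height %||% .default_size[2]
  m <- .margin
  plot_x <- c(m, w - m)
  plot_y <- c(h - m, m)   # device y grows downward; value axis inverts

  only_heatmap <- all(resolved$layer_types == "heatmap")
  sc <- if (only_heatmap) NULL else
    derive_scales(resolved, plot_x, plot_y, scales)

  body <- character()
  id_layer <- character(); id_index <- character(); id_elem <- character()
  skipped <- 0L
  note_ids <- function(layer, idx, elems) {
    id_layer <<- c(id_layer, rep(layer, length(idx)))
    id_index <<- c(id_index, as.character(idx))
    id_elem <<- c(id_elem, elems)
  }

  for (i in seq_along(resolved$layers)) {
    lid <- names(resolved$layers)[i]
    lt <- resolved$layer_types[[i]]
    p <- resolved$layers[[i]]
    out <- switch(lt,
      scatter  = svg_points(resolved$chart_id, lid, p, sc),
      beeswarm = svg_beeswarm(resolved$chart_id, lid, p, sc),
      line     = svg_series(resolved$chart_id, lid, p, sc, sort_x = TRUE),
      path     = svg_series(resolved$chart_id, lid, p, sc, sort_x = FALSE),
      abline   = svg_abline(resolved$chart_id, lid, p, sc),
      hline    = svg_refline(resolved$chart_id, lid, p$h, "h", p, sc, plot_x),
      vline    = svg_refline(resolved$chart_id, lid, p$v, "v", p, sc, plot_y),
      bars     = svg_bars(resolved$chart_id, lid, p, sc, plot_y),
      hist     = svg_hist(resolved$chart_id, lid, p, sc, plot_y),
      dens     = svg_dens(resolved$chart_id, lid, p, sc),
      heatmap  = svg_heatmap(resolved$chart_id, lid, p, plot_x, plot_y),
      stop(sprintf("unrenderable layer type '%s'", lt)))
    body <- c(body, out$markup)
    if (length(out$index)) note_ids(lid, out$index, out$elems)
    skipped <- skipped + (out$skipped %||% 0L)
  }

  axes <- if (only_heatmap) character() else
    svg_axes(sc, plot_x, plot_y, page)
  title <- if (!is.null(page$title)) {
    sprintf('<text class="lc-title" x="%s" y="%s" text-anchor="middle" font-size="14">%s</text>',
            fmt_num(w / 2), fmt_num(m / 2 + 5), xml_escape(page$title))
  } else character()

  markup <- paste0(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d" data-chart="%s">',
            round(w), round(h), round(w), round(h), resolved$chart_id),
    paste(c(title, axes, body), collapse = ""),
    "</svg>")

  structure(list(markup = markup,
                 id_map = data.frame(layer = id_layer, index = id_index,
                                     elem_id = id_elem,
                                     stringsAsFactors = FALSE),
                 size = c(width = w, height = h),
                 diagnostics = list(skipped = skipped)),
            class = "lc_fragment")
}

#' @export
print.lc_fragment <- function(x, ...) {
  cat(sprintf("<chartlink fragment: %d bytes, %d interactive element(s)>\n",
              nchar(x$markup), nrow(x$id_map)))
  invisible(x)
}

# ---- scale derivation ------------------------------------------------------

collect_axis_values <- function(resolved, axis) {
  vals <- list()
  for (i in seq_along(resolved$layers)) {
    lt <- resolved$layer_types[[i]]
    p <- resolved$layers[[i]]
    v <- if (axis == "x") {
      switch(lt,
             scatter = , beeswarm = , line = , path = p$x,
             vline = p$v,
             hist = {
               b <- histogram_bins(p$value, p$nbins %||% 10L, p$limits)
               range(b$edges)
             },
             dens = {
               k <- gaussian_kde(p$value, p$bandwidth)
               range(k$grid)
             },
             bars = NULL,
             NULL)
    } else {
      switch(lt,
             scatter = , beeswarm = , line = , path = p$y,
             hline = p$h,
             hist = {
               b <- histogram_bins(p$value, p$nbins %||% 10L, p$limits)
               c(0, max(b$counts, 1L))
             },
             dens = {
               k <- gaussian_kde(p$value, p$bandwidth)
               c(0, max(k$density))
             },
             bars = c(0, p$value),
             NULL)
    }
    if (!is.null(v)) vals[[length(vals) + 1L]] <- v
  }
  vals
}

axis_scale <- function(vals, range_dev, log_scale = FALSE, forced_domain = NULL) {
  if (any(vapply(vals, function(v) is.character(v) || is.factor(v), TRUE))) {
    cats <- unique(unlist(lapply(vals, as.character)))
    return(scale_new("categorical", cats, range_dev))
  }
  num <- unlist(lapply(vals, as.numeric), use.names = FALSE)
  num <- num[is.finite(num)]
  dom <- forced_domain %||% (if (length(num)) range(num) else c(0, 1))
  if (dom[1] == dom[2]) dom <- dom + c(-0.5, 0.5)
  if (log_scale) {
    if (any(dom <= 0)) stop("log axis needs strictly positive data", call. = FALSE)
    return(scale_new("log", dom, range_dev))
  }
  ticks <- nice_ticks(dom, 5L)
  scale_new("linear", c(min(ticks), max(ticks)), range_dev)
}

derive_scales <- function(resolved, plot_x, plot_y, scales = NULL) {
  page <- resolved$page
  xs <- scales$x %||% axis_scale(collect_axis_values(resolved, "x"), plot_x,
                                 isTRUE(page$logScaleX), page$domainX)
  ys <- scales$y %||% axis_scale(collect_axis_values(resolved, "y"), plot_y,
                                 isTRUE(page$logScaleY), page$domainY)
  list(x = xs, y = ys)
}

scale_ticks <- function(s, n = 5L) {
  if (s$kind == "categorical") return(s$domain)
  if (s$kind == "log") {
    k <- nice_ticks(log10(s$domain), n)
    return(10^k)
  }
  t <- nice_ticks(s$domain, n)
  t[t >= min(s$domain) - 1e-9 & t <= max(s$domain) + 1e-9]
}

# ---- layer renderers -------------------------------------------------------

finite_mask <- function(...) {
  vs <- list(...)
  Reduce(`&`, lapply(vs, function(v) if (is.numeric(v)) is.finite(v) else !is.na(v)))
}

svg_points <- function(chart, lid, p, sc, cx = NULL, cy = NULL) {
  n <- length(p$y)
  cx <- cx %||% scale_apply(sc$x, p$x)
  cy <- cy %||% scale_apply(sc$y, p$y)
  col <- p$color %||% rep(.default_point_color, n)
  if (!is.character(col)) col <- map_colors(col, .default_palette)
  size <- p$size %||% rep(3, n)
  if (length(size) == 1L) size <- rep(size, n)
  op <- p$opacity %||% rep(1, n)
  if (length(op) == 1L) op <- rep(op, n)
  ok <- finite_mask(cx, cy)
  idx <- which(ok) - 1L
  markup <- sprintf(
    '<circle id="%s" class="lc-point" cx="%s" cy="%s" r="%s" fill="%s" fill-opacity="%s"/>',
    elem_id(chart, lid, idx), fmt_num(cx[ok]), fmt_num(cy[ok]),
    fmt_num(size[ok]), col[ok], fmt_num(op[ok]))
  list(markup = markup, index = idx, elems = elem_id(chart, lid, idx),
       skipped = sum(!ok))
}

svg_beeswarm <- function(chart, lid, p, sc) {
  n <- length(p$y)
  cy <- scale_apply(sc$y, p$y)
  size <- p$size %||% rep(3, n)
  if (length(size) == 1L) size <- rep(size, n)
  center <- if (!is.null(p$x)) scale_apply(sc$x, p$x) else
    rep(mean(sc$x$range), n)
  cx <- numeric(n)
  for (g in unique(center)) {
    sel <- which(center == g)
    cx[sel] <- g + beeswarm_offsets(cy[sel], max(size[sel]))
  }
  svg_points(chart, lid, p, sc, cx = cx, cy = cy)
}

series_matrix <- function(p) {
  y <- p$y
  if (!is.matrix(y)) y <- matrix(y, ncol = 1L)
  y
}

svg_series <- function(chart, lid, p, sc, sort_x) {
  y <- series_matrix(p)
  x <- p$x
  ns <- ncol(y)
  col <- p$color %||% rep(.default_point_color, ns)
  if (length(col) == 1L) col <- rep(col, ns)
  wd <- p$width %||% rep(1.5, ns)
  if (length(wd) == 1L) wd <- rep(wd, ns)
  markup <- character(); idx <- integer(); skipped <- 0L
  for (j in seq_len(ns)) {
    xi <- x; yi <- y[, j]
    if (sort_x) { o <- order(xi); xi <- xi[o]; yi <- yi[o] }
    cx <- scale_apply(sc$x, xi); cy <- scale_apply(sc$y, yi)
    ok <- finite_mask(cx, cy)
    skipped <- skipped + sum(!ok)
    pts <- paste(fmt_num(cx[ok]), fmt_num(cy[ok]), sep = ",", collapse = " ")
    markup <- c(markup, sprintf(
      '<polyline id="%s" class="lc-line" points="%s" fill="none" stroke="%s" stroke-width="%s"/>',
      elem_id(chart, lid, j - 1L), pts, col[j], fmt_num(wd[j])))
    idx <- c(idx, j - 1L)
  }
  list(markup = markup, index = idx, elems = elem_id(chart, lid, idx),
       skipped = skipped)
}

line_style <- function(p, n) {
  col <- p$color %||% rep("#888888", n)
  if (length(col) == 1L) col <- rep(col, n)
  wd <- p$width %||% rep(1, n)
  if (length(wd) == 1L) wd <- rep(wd, n)
  list(col = col, wd = wd)
}

svg_abline <- function(chart, lid, p, sc) {
  n <- length(p$a)
  st <- line_style(p, n)
  dom <- sc$x$domain
  markup <- character()
  for (i in seq_len(n)) {
    y0 <- p$a[i] + p$b[i] * dom[1]
    y1 <- p$a[i] + p$b[i] * dom[2]
    markup <- c(markup, sprintf(
      '<line id="%s" class="lc-refline" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"/>',
      elem_id(chart, lid, i - 1L),
      fmt_num(scale_apply(sc$x, dom[1])), fmt_num(scale_apply(sc$y, y0)),
      fmt_num(scale_apply(sc$x, dom[2])), fmt_num(scale_apply(sc$y, y1)),
      st$col[i], fmt_num(st$wd[i])))
  }
  idx <- seq_len(n) - 1L
  list(markup = markup, index = idx, elems = elem_id(chart, lid, idx))
}

svg_refline <- function(chart, lid, at, dir, p, sc, span_dev) {
  n <- length(at)
  st <- line_style(p, n)
  pos <- scale_apply(if (dir == "h") sc$y else sc$x, at)
  markup <- if (dir == "h") {
    sprintf('<line id="%s" class="lc-refline" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"/>',
            elem_id(chart, lid, seq_len(n) - 1L),
            fmt_num(rep(span_dev[1], n)), fmt_num(pos),
            fmt_num(rep(span_dev[2], n)), fmt_num(pos),
            st$col, fmt_num(st$wd))
  } else {
    sprintf('<line id="%s" class="lc-refline" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"/>',
            elem_id(chart, lid, seq_len(n) - 1L),
            fmt_num(pos), fmt_num(rep(span_dev[1], n)),
            fmt_num(pos), fmt_num(rep(span_dev[2], n)),
            st$col, fmt_num(st$wd))
  }
  idx <- seq_len(n) - 1L
  list(markup = markup, index = idx, elems = elem_id(chart, lid, idx))
}

svg_bars <- function(chart, lid, p, sc, plot_y) {
  v <- p$value
  n <- length(v)
  labels <- p$label %||% as.character(seq_len(n))
  col <- p$color %||% rep("#7f9ecb", n)
  if (length(col) == 1L) col <- rep(col, n)
  xs <- scale_new("categorical", labels, sc$x$range)
  centers <- scale_apply(xs, labels)
  bw <- 0.8 * abs(diff(sc$x$range)) / n
  y0 <- scale_apply(sc$y, 0)
  y1 <- scale_apply(sc$y, v)
  idx <- seq_len(n) - 1L
  markup <- sprintf(
    '<rect id="%s" class="lc-bar" x="%s" y="%s" width="%s" height="%s" fill="%s"/>',
    elem_id(chart, lid, idx), fmt_num(centers - bw / 2),
    fmt_num(pmin(y0, y1)), fmt_num(rep(bw, n)), fmt_num(abs(y1 - y0)), col)
  list(markup = markup, index = idx, elems = elem_id(chart, lid, idx))
}

svg_hist <- function(chart, lid, p, sc, plot_y) {
  b <- histogram_bins(p$value, p$nbins %||% 10L, p$limits)
  n <- length(b$counts)
  x0 <- scale_apply(sc$x, b$edges[-(n + 1L)])
  x1 <- scale_apply(sc$x, b$edges[-1L])
  y0 <- scale_apply(sc$y, 0)
  y1 <- scale_apply(sc$y, b$counts)
  col <- p$color %||% "#7f9ecb"
  idx <- seq_len(n) - 1L
  markup <- sprintf(
    '<rect id="%s" class="lc-bin" x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="#ffffff"/>',
    elem_id(chart, lid, idx), fmt_num(x0), fmt_num(pmin(y0, y1)),
    fmt_num(x1 - x0), fmt_num(abs(y1 - y0)), rep(col, n))
  list(markup = markup, index = idx, elems = elem_id(chart, lid, idx))
}

svg_dens <- function(chart, lid, p, sc) {
  k <- gaussian_kde(p$value, p$bandwidth)
  cx <- scale_apply(sc$x, k$grid)
  cy <- scale_apply(sc$y, k$density)
  pts <- paste(fmt_num(cx), fmt_num(cy), sep = ",", collapse = " ")
  col <- p$color %||% "#444444"
  markup <- sprintf(
    '<polyline id="%s" class="lc-dens" points="%s" fill="none" stroke="%s" stroke-width="1.5"/>',
    elem_id(chart, lid, 0L), pts, col)
  list(markup = markup, index = 0L, elems = elem_id(chart, lid, 0L))
}

svg_heatmap <- function(chart, lid, p, plot_x, plot_y) {
  v <- p$value
  nr <- nrow(v); nc <- ncol(v)
  pal <- p$palette %||% .default_palette
  cols <- matrix(map_colors(as.numeric(v), pal), nr, nc)
  row_order <- p$rowOrder %||% seq_len(nr)
  col_order <- p$colOrder %||% seq_len(nc)
  # display origin top-left: first (ordered) row at the top
  top <- min(plot_y); left <- plot_x[1]
  ch <- (max(plot_y) - min(plot_y)) / nr
  cw <- (plot_x[2] - plot_x[1]) / nc
  markup <- character(nr * nc)
  elems <- character(nr * nc)
  index <- character(nr * nc)
  pos_r <- match(seq_len(nr), row_order)  # display slot of data row r
  pos_c <- match(seq_len(nc), col_order)
  q <- 0L
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      q <- q + 1L
      id <- elem_id(chart, lid, r - 1L, cc - 1L)
      markup[q] <- sprintf(
        '<rect id="%s" class="lc-cell" x="%s" y="%s" width="%s" height="%s" fill="%s"/>',
        id, fmt_num(left + (pos_c[cc] - 1) * cw),
        fmt_num(top + (pos_r[r] - 1) * ch),
        fmt_num(cw), fmt_num(ch), cols[r, cc])
      elems[q] <- id
      index[q] <- paste0(r - 1L, "-", cc - 1L)
    }
  }
  if (!is.null(p$highlight) && length(p$highlight) == 2L &&
      all(is.finite(p$highlight))) {
    hr <- p$highlight[1]; hc <- p$highlight[2]
    markup <- c(markup, sprintf(
      '<rect class="lc-highlight" x="%s" y="%s" width="%s" height="%s" fill="none" stroke="#000000" stroke-width="2"/>',
      fmt_num(left + (pos_c[hc] - 1) * cw), fmt_num(top + (pos_r[hr] - 1) * ch),
      fmt_num(cw), fmt_num(ch)))
  }
  list(markup = markup, index = index, elems = elems)
}

# ---- axes ------------------------------------------------------------------

svg_axes <- function(sc, plot_x, plot_y, page) {
  out <- character()
  y0 <- max(plot_y)  # bottom of plot area in device units
  out <- c(out, sprintf(
    '<line class="lc-axis" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#000000"/>',
    fmt_num(plot_x[1]), fmt_num(y0), fmt_num(plot_x[2]), fmt_num(y0)))
  out <- c(out, sprintf(
    '<line class="lc-axis" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#000000"/>',
    fmt_num(plot_x[1]), fmt_num(min(plot_y)), fmt_num(plot_x[1]), fmt_num(y0)))

  xt <- scale_ticks(sc$x)
  xpos <- scale_apply(sc$x, xt)
  xlab <- if (sc$x$kind == "categorical") xml_escape(xt) else fmt_label(xt)
  out <- c(out, sprintf(
    '<line class="lc-tick" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#000000"/><text class="lc-ticklabel" x="%s" y="%s" text-anchor="middle" font-size="10">%s</text>',
    fmt_num(xpos), fmt_num(y0), fmt_num(xpos), fmt_num(y0 + 5),
    fmt_num(xpos), fmt_num(y0 + 16), xlab))

  yt <- scale_ticks(sc$y)
  ypos <- scale_apply(sc$y, yt)
  ylab <- if (sc$y$kind == "categorical") xml_escape(yt) else fmt_label(yt)
  out <- c(out, sprintf(
    '<line class="lc-tick" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#000000"/><text class="lc-ticklabel" x="%s" y="%s" text-anchor="end" font-size="10">%s</text>',
    fmt_num(plot_x[1] - 5), fmt_num(ypos), fmt_num(plot_x[1]), fmt_num(ypos),
    fmt_num(plot_x[1] - 7), fmt_num(ypos + 3), ylab))

  if (!is.null(page$axisTitleX)) {
    out <- c(out, sprintf(
      '<text class="lc-axistitle" x="%s" y="%s" text-anchor="middle" font-size="12">%s</text>',
      fmt_num(mean(plot_x)), fmt_num(y0 + 32), xml_escape(page$axisTitleX)))
  }
  if (!is.null(page$axisTitleY)) {
    out <- c(out, sprintf(
      '<text class="lc-axistitle" x="%s" y="%s" text-anchor="middle" font-size="12" transform="rotate(-90 %s %s)">%s</text>',
      fmt_num(plot_x[1] - 28), fmt_num(mean(plot_y)),
      fmt_num(plot_x[1] - 28), fmt_num(mean(plot_y)),
      xml_escape(page$axisTitleY)))
  }
  out
}

# ---- widgets ---------------------------------------------------------------

render_widget <- function(resolved) {
  chart <- resolved$chart_id
  p <- resolved$layers[["L0"]]
  wt <- resolved$widget_type
  id0 <- elem_id(chart, "L0", 0L)
  markup <- switch(wt,
    html = as.character(p$content),
    image = sprintf('<img id="%s" class="lc-image" src="%s"%s%s/>', id0,
                    xml_escape(p$src),
                    if (!is.null(p$width)) sprintf(' width="%s"', p$width) else "",
                    if (!is.null(p$height)) sprintf(' height="%s"', p$height) else ""),
    colourSlider = {
      pal <- p$palette %||% .default_palette
      sprintf('<div class="lc-colourslider"><input id="%s" type="range" min="0" max="1" step="0.01" value="%s" data-lc-widget="%s"/><span class="lc-palette">%s</span></div>',
              id0, fmt_num(as.numeric(p$value %||% 0.5)), chart,
              paste(pal, collapse = ","))
    },
    input = render_input(resolved, chart))
  idx <- if (identical(wt, "html")) character() else "0"
  elems <- if (identical(wt, "html")) character() else id0
  if (identical(wt, "input")) {
    k <- resolved$input_kind
    labels <- resolved$layers[["L0"]]$labels
    nel <- if (k %in% c("button", "checkbox", "radio")) max(1L, length(labels)) else 1L
    idx <- as.character(seq_len(nel) - 1L)
    elems <- elem_id(chart, "L0", seq_len(nel) - 1L)
  }
  structure(list(markup = markup,
                 id_map = data.frame(layer = rep("L0", length(idx)),
                                     index = idx, elem_id = elems,
                                     stringsAsFactors = FALSE),
                 size = c(width = NA_real_, height = NA_real_),
                 diagnostics = list(skipped = 0L)),
            class = "lc_fragment")
}

render_input <- function(resolved, chart) {
  p <- resolved$layers[["L0"]]
  kind <- resolved$input_kind
  labels <- p$labels %||% ""
  value <- p$value
  one <- function(i, inner) inner
  if (kind == "button") {
    paste0(vapply(seq_along(labels), function(i) sprintf(
      '<button id="%s" class="lc-input" data-lc-widget="%s">%s</button>',
      elem_id(chart, "L0", i - 1L), chart, xml_escape(labels[i])), ""),
      collapse = "")
  } else if (kind %in% c("checkbox", "radio")) {
    checked <- if (kind == "checkbox") {
      v <- value %||% rep(FALSE, length(labels))
      rep_len(as.logical(v), length(labels))
    } else {
      seq_along(labels) == (value %||% 1L)
    }
    paste0(vapply(seq_along(labels), function(i) sprintf(
      '<label><input id="%s" class="lc-input" type="%s" name="%s"%s data-lc-widget="%s"/>%s</label>',
      elem_id(chart, "L0", i - 1L), kind, chart,
      if (checked[i]) ' checked="checked"' else "", chart,
      xml_escape(labels[i])), ""), collapse = "")
  } else if (kind == "range") {
    sprintf('<input id="%s" class="lc-input" type="range" min="%s" max="%s" step="%s" value="%s" data-lc-widget="%s"/>',
            elem_id(chart, "L0", 0L), p$min %||% 0, p$max %||% 1,
            p$step %||% 0.01, value %||% p$min %||% 0, chart)
  } else {  # text
    sprintf('<input id="%s" class="lc-input" type="text" value="%s" data-lc-widget="%s"/>',
            elem_id(chart, "L0", 0L), xml_escape(as.character(value %||% "")),
            chart)
  }
}

# ---- page composition and export ------------------------------------------

#' Compose rendered fragments into an HTML page
#'
#' @param page a [page_spec()].
#' @param fragments named list of `RenderedFragment`s, names = chart ids
#'   (each id must match a container on the page).
#' @param shim_src URL of the browser shim script (referenced exactly once).
#' @param config optional list injected as the shim configuration (channel
#'   endpoint, session token).
#' @return A single HTML5 document as a character string.
#' @export
render_page <- function(page, fragments, shim_src = "/chartlink-shim.js",
                        config = NULL) {
  stopifnot(inherits(page, "lc_page"))
  ids <- vapply(page$containers, `[[`, "", "id")
  missing <- setdiff(names(fragments), ids)
  if (length(missing)) {
    stop(sprintf("no container for chart(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  body <- character()
  for (cont in page$containers) {
    if (!is.null(cont$html)) body <- c(body, cont$html)
    inner <- if (cont$id %in% names(fragments)) fragments[[cont$id]]$markup else ""
    body <- c(body, sprintf('<div id="%s" class="lc-container">%s</div>',
                            cont$id, inner))
  }
  cfg <- if (!is.null(config)) {
    sprintf('<script>window.CHARTLINK=%s;</script>',
            jsonlite::toJSON(config, auto_unbox = TRUE))
  } else ""
  paste0("<!DOCTYPE html><html><head><meta charset=\"utf-8\"/><title>",
         xml_escape(page$title), "</title></head><body>",
         paste(body, collapse = ""),
         cfg,
         sprintf('<script src="%s"></script>', shim_src),
         "</body></html>")
}

#' Export a resolved chart as a standalone SVG file
#'
#' @inheritParams render_chart
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_svg <- function(resolved, scales = NULL, path) {
  frag <- render_chart(resolved, scales)
  if (resolved$kind == "widget") {
    stop("widgets render to HTML, not SVG; nothing to export", call. = FALSE)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
                            frag$markup, "\n")), con)
  invisible(path)
}
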