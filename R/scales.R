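# Scales, axis ticks and color mapping. Pure functions, no I/O.

#' Construct a scale
#'
#' Maps data values to device coordinates. Linear scales are affine; log
#' scales are affine in log10 of the value; categorical scales place each
#' category at the center of an equal-width slot.
#'
#' @param kind `"linear"`, `"log"` or `"categorical"`.
#' @param domain numeric pair (linear/log; endpoints distinct and finite, log
#'   domain strictly positive) or character vector of categories.
#' @param range numeric output pair in device units. The first domain endpoint
#'   maps exactly to `range[1]`; device y-ranges are typically decreasing
#'   because the SVG origin is top-left.
#' @return An object of class `lc_scale`.
#' @examples
#' s <- scale_new("linear", c(0, 10), c(0, 500))
#' scale_apply(s, 2.5)  # 125
#' @export
scale_new <- function(kind = c("linear", "log", "categorical"), domain, range) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(range), length(range) == 2L, all(is.finite(range)))
  if (kind == "categorical") {
    domain <- as.character(domain)
    if (!length(domain) || anyDuplicated(domain)) {
      stop("categorical domain must be a non-empty set of distinct categories",
           call. = FALSE)
    }
  } else {
    stopifnot(is.numeric(domain), length(domain) == 2L)
    if (!all(is.finite(domain)) || domain[1] == domain[2]) {
      stop("scale domain must have distinct finite endpoints", call. = FALSE)
    }
    if (kind == "log" && any(domain <= 0)) {
      stop("log scale domain must be strictly positive", call. = FALSE)
    }
  }
  structure(list(kind = kind, domain = domain, range = range),
            class = "lc_scale")
}

#' Apply a scale to data values
#'
#' Values outside a numeric domain are clamped to its endpoints, so offscreen
#' points render at the plot boundary rather than disappearing.
#'
#' @param scale an [scale_new()] object.
#' @param v values to map (numeric, or categories for a categorical scale).
#' @return Numeric device coordinates, same length as `v`; `NA` maps to `NA`.
#' @export
scale_apply <- function(scale, v) {
  stopifnot(inherits(scale, "lc_scale"))
  d <- scale$domain
  r <- scale$range
  if (scale$kind == "categorical") {
    i <- match(as.character(v), d)
    return(r[1] + (i - 0.5) / length(d) * (r[2] - r[1]))
  }
  if (scale$kind == "log") {
    if (any(!is.na(v) & v <= 0)) {
      stop("log scale applied to non-positive value", call. = FALSE)
    }
    v <- log10(v)
    d <- log10(d)
  }
  v <- pmin(pmax(v, min(d)), max(d))
  r[1] + (v - d[1]) / (d[2] - d[1]) * (r[2] - r[1])
}

#' Round axis ticks
#'
#' Chooses a step size s from \{1, 2, 5\} x 10^k — the largest such step not
#' exceeding `span / target_count` — and returns consecutive multiples of s
#' covering the domain.
#'
#' @param domain numeric pair (finite; order-free).
#' @param target_count requested number of intervals, >= 2.
#' @return Sorted, duplicate-free numeric ticks spanning the domain; a
#'   zero-width domain yields the single value.
#' @examples
#' nice_ticks(c(0, 100), 5)  # 0 20 40 60 80 100
#' @export
nice_ticks <- function(domain, target_count = 5L) {
  stopifnot(is.numeric(domain), length(domain) == 2L, all(is.finite(domain)),
            target_count >= 2L)
  lo <- min(domain); hi <- max(domain)
  if (lo == hi) return(lo)
  s <- tick_step(hi - lo, target_count)
  first <- floor(lo / s + 1e-9) * s
  last <- ceiling(hi / s - 1e-9) * s
  ticks <- seq(first, last, by = s)
  # kill floating noise so multiples of s print cleanly
  round(ticks / s) * s
}

tick_step <- function(span, target_count) {
  raw <- span / target_count
  k <- floor(log10(raw))
  cands <- c(1, 2, 5, 10) * 10^k
  max(cands[cands <= raw * (1 + 1e-9)])
}

#' Map values to colors through a palette
#'
#' Numeric values interpolate piecewise-linearly between equally spaced
#' palette anchors in sRGB component space (components rounded to integers);
#' categorical values map category i to color i, recycling the palette with a
#' warning if there are more categories than colors. Missing values map to
#' `na_color`.
#'
#' @param values numeric vector (with `domain`) or factor/character vector.
#' @param palette character vector of sRGB hex colors (>= 2 for numeric use).
#' @param domain numeric pair for continuous mapping; defaults to the finite
#'   range of `values`.
#' @param na_color color used for missing values.
#' @return Character vector of `#rrggbb` colors, same length as `values`.
#' @examples
#' map_colors(0.5, c("#000000", "#ffffff"), domain = c(0, 1))  # "#808080"
#' @export
map_colors <- function(values, palette, domain = NULL, na_color = "#cccccc") {
  stopifnot(is.character(palette), length(palette) >= 1L)
  if (!all(grepl("^#[0-9a-fA-F]{6}$", palette))) {
    stop("palette entries must be #rrggbb hex colors", call. = FALSE)
  }
  if (is.numeric(values)) {
    if (length(palette) < 2L) {
      stop("continuous color mapping needs >= 2 palette colors", call. = FALSE)
    }
    if (is.null(domain)) {
      fin <- values[is.finite(values)]
      domain <- if (length(fin)) range(fin) else c(0, 1)
    }
    if (domain[1] == domain[2]) domain <- domain + c(-0.5, 0.5)
    t <- (values - domain[1]) / (domain[2] - domain[1])
    t <- pmin(pmax(t, 0), 1)
    ramp <- grDevices::colorRamp(palette, space = "rgb", interpolate = "linear")
    out <- rep(na_color, length(values))
    ok <- !is.na(t)
    if (any(ok)) {
      rgb <- round(ramp(t[ok]))
      out[ok] <- tolower(grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3],
                                        maxColorValue = 255))
    }
    out
  } else {
    f <- as.factor(values)
    k <- nlevels(f)
    if (k > length(palette)) {
      warning(sprintf("palette has %d colors for %d categories; recycling",
                      length(palette), k), call. = FALSE)
    }
    cols <- rep_len(palette, max(k, 1L))
    out <- cols[as.integer(f)]
    out[is.na(out)] <- na_color
    out
  }
}
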