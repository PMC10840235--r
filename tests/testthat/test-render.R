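# SVG rendering: element cardinality, identifier contract, determinism,
# page composition and export.

resolve_in_fresh_scope <- function(build) {
  app <- lc_app()
  ch <- build(app)
  resolve_chart(ch, chartlink:::new_scope(app, "s1"))
}

test_that("a scatter renders one identified element per point", {
  res <- resolve_in_fresh_scope(function(app)
    lc_scatter(x = c(1, 2, 3), y = c(4, 5, 6), place = "A1", app = app))
  frag <- render_chart(res)
  expect_equal(nrow(frag$id_map), 3L)
  expect_setequal(frag$id_map$elem_id, paste0("lc-A1-L0-", 0:2))
  for (id in frag$id_map$elem_id) {
    expect_equal(lengths(regmatches(frag$markup,
      gregexpr(sprintf('id="%s"', id), frag$markup, fixed = TRUE))), 1L)
  }
})

test_that("a heatmap renders one cell per matrix entry with row-col ids", {
  res <- resolve_in_fresh_scope(function(app)
    lc_heatmap(value = matrix(1:6, 2, 3), place = "H1", app = app))
  frag <- render_chart(res)
  expect_equal(nrow(frag$id_map), 6L)
  expect_true("lc-H1-L0-1-2" %in% frag$id_map$elem_id)
  expect_setequal(frag$id_map$index,
                  c("0-0", "0-1", "0-2", "1-0", "1-1", "1-2"))
})

test_that("rendering is deterministic and id maps are bijective (seeded fuzz)", {
  for (s in 1:20) {
    res <- random_resolved_chart(s)
    f1 <- render_chart(res)
    f2 <- render_chart(res)
    expect_identical(f1$markup, f2$markup, info = paste("seed", s))
    # bijectivity: one row per interactive element, no collisions,
    # and each identifier appears exactly once in the markup
    expect_false(anyDuplicated(f1$id_map$elem_id) > 0, info = paste("seed", s))
    n_elems <- sum(vapply(seq_along(res$layers), function(i) {
      chartlink:::element_count(res$layer_types[[i]], res$layers[[i]])
    }, 0L))
    expect_equal(nrow(f1$id_map), n_elems, info = paste("seed", s))
    hits <- gregexpr("id=\"lc-[^\"]+\"", f1$markup)[[1]]
    expect_equal(length(hits), n_elems, info = paste("seed", s))
  }
})

test_that("non-finite coordinates are skipped and counted", {
  res <- resolve_in_fresh_scope(function(app)
    lc_scatter(x = c(1, NA, 3, Inf), y = c(1, 2, NaN, 4), place = "A1",
               app = app))
  frag <- render_chart(res)
  expect_equal(frag$diagnostics$skipped, 2L)  # Inf clamps; NA/NaN drop
  expect_equal(nrow(frag$id_map), 2L)
})

test_that("exported SVG round-trips and parses as XML", {
  res <- resolve_in_fresh_scope(function(app)
    lc_scatter(x = 1:4, y = 4:1, title = "t", axisTitleX = "x<&>",
               place = "A1", app = app))
  path <- withr::local_tempfile(fileext = ".svg")
  export_svg(res, path = path)
  reread <- readChar(path, file.size(path), useBytes = TRUE)
  frag <- render_chart(res)
  expect_identical(reread,
                   paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
                          frag$markup, "\n"))
  doc <- xml2::read_xml(path)
  expect_identical(xml2::xml_name(doc), "svg")
  # empty scatter still yields a valid SVG with axes
  res0 <- resolve_in_fresh_scope(function(app)
    lc_scatter(x = numeric(0), y = numeric(0), place = "A0", app = app))
  path0 <- withr::local_tempfile(fileext = ".svg")
  export_svg(res0, path = path0)
  expect_s3_class(xml2::read_xml(path0), "xml_document")
  expect_match(readChar(path0, file.size(path0)), "lc-axis")
})

test_that("render_page places fragments in container order with one shim reference", {
  page <- page_spec(list(list(id = "A1", html = "<h1>Two charts</h1>"),
                         list(id = "A2", html = NULL)), title = "demo")
  res1 <- resolve_in_fresh_scope(function(app)
    lc_scatter(x = 1, y = 1, place = "A1", app = app))
  res2 <- resolve_in_fresh_scope(function(app)
    lc_bars(value = c(1, 2), place = "A2", app = app))
  html <- render_page(page, list(A1 = render_chart(res1),
                                 A2 = render_chart(res2)))
  expect_match(html, "^<!DOCTYPE html>")
  expect_match(html, "<h1>Two charts</h1>", fixed = TRUE)  # verbatim custom HTML
  expect_lt(regexpr('id="A1"', html), regexpr('id="A2"', html))
  expect_equal(length(gregexpr("chartlink-shim.js", html)[[1]]), 1L)
  expect_error(render_page(page, list(ZZ = render_chart(res1))),
               "no container.*ZZ")
})

test_that("widgets render as HTML with identified input elements", {
  app <- lc_app()
  w <- lc_input(type = "radio", labels = c("a", "b", "c"), value = 2L,
                place = "W1", app = app)
  frag <- render_chart(resolve_chart(w, chartlink:::new_scope(app, "s1")))
  expect_equal(nrow(frag$id_map), 3L)
  expect_match(frag$markup, 'id="lc-W1-L0-1"[^>]*checked')
  h <- lc_html(content = "<p>hello</p>", place = "W2", app = app)
  fh <- render_chart(resolve_chart(h, chartlink:::new_scope(app, "s2")))
  expect_identical(fh$markup, "<p>hello</p>")
})
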