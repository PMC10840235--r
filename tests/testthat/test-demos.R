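# Demo apps: construction, linkage behavior, widget round trips, SVG export
# and the served shim contract.

small_ma <- list(n_genes = 400L, n_patients = 6L)

test_that("unknown demo names list the valid ones", {
  expect_error(build_demo("volcano"), "ma_plot.*drugscreen.*cor_heatmap.*plate_qc")
})

test_that("ma_plot clicks switch the expression chart to the clicked gene", {
  app <- build_demo("ma_plot", params = small_ma, seed = 21)
  start_app(app)
  s <- open_session(app)
  lcpm <- app$demo_data$lcpm
  f_ma <- s$fragments[["A1"]]$markup
  out <- send_click(app, s, "A1", 41L)   # wire 0-based -> gene 42
  expect_identical(session_get(s, "gene"), 42L)
  expect_equal(unname(s$resolved[["A2"]]$layers$L0$y), unname(lcpm[42, ]))
  expect_identical(s$fragments[["A1"]]$markup, f_ma)
  expect_identical(out[[1]]$kind, "update")
  expect_identical(out[[1]]$body$container, "A2")
  # expression chart groups by condition on a categorical axis
  expect_identical(s$resolved[["A2"]]$layers$L0$x,
                   app$demo_data$dataset$samples$condition)
  stop_app(app)
})

test_that("the drugscreen chain walks heatmap -> scatter -> curves -> plate", {
  app <- build_demo("drugscreen", seed = 31)
  start_app(app)
  s <- open_session(app)
  send_click(app, s, "D", c(4L, 9L))     # heatmap cell -> drugs 5, 10
  expect_identical(session_get(s, "d1"), 5L)
  expect_identical(session_get(s, "d2"), 10L)
  expect_equal(unname(s$resolved[["C"]]$layers$L0$x),
               unname(app$demo_data$scores[5, ]))
  send_click(app, s, "C", 2L)            # cell line 3
  expect_identical(session_get(s, "cl"), 3L)
  # observed viabilities on the curve chart come from drug 5, cell line 3
  v <- app$demo_data$viability[[3]]
  v5 <- v[v$drug == 5, ]
  expect_equal(s$resolved[["B1"]]$layers$L0$y,
               v5$viability[order(v5$conc_idx)])
  # hover on a curve point highlights exactly the design-table well
  send_click(app, s, "B1", 3L, type = "hover")  # conc index 4
  hl <- session_get(s, "hl")
  wl <- app$demo_data$screen$wells
  w <- wl[wl$cell_line == 3 & !is.na(wl$drug) & wl$drug == 5 &
            wl$conc_idx == 4, ]
  expect_identical(unname(hl), c(w$row, w$col))
  expect_equal(length(gregexpr("lc-highlight",
                               s$fragments[["A"]]$markup)[[1]]), 1L)
  stop_app(app)
})

test_that("plate_qc reassigns well status through the radio input", {
  app <- build_demo("plate_qc", seed = 8)
  start_app(app)
  s <- open_session(app)
  send_click(app, s, "P1", c(1L, 2L))    # select well (2, 3)
  expect_identical(unname(session_get(s, "sel")), c(2L, 3L))
  f0 <- s$fragments[["P1"]]$markup
  send_click(app, s, "W1", 4L, type = "input_change")
  roles <- session_get(s, "roles")
  expect_identical(roles[2, 3], "positive")
  expect_false(identical(s$fragments[["P1"]]$markup, f0))
  stop_app(app)
})

test_that("cor_heatmap links cells to sample-pair scatters", {
  app <- build_demo("cor_heatmap",
                    params = list(n_genes = 500L, n_keep = 300L,
                                  n_patients = 5L), seed = 12)
  start_app(app)
  s <- open_session(app)
  send_click(app, s, "A1", c(3L, 7L))
  expect_identical(session_get(s, "s1"), 4L)
  expect_identical(session_get(s, "s2"), 8L)
  expect_equal(unname(s$resolved[["A2"]]$layers$L0$x),
               unname(app$demo_data$lcpm[, 4]))
  # heatmap uses the clustering order
  expect_equal(sort(app$demo_data$order), seq_len(ncol(app$demo_data$lcpm)))
  stop_app(app)
})

test_that("every demo's full click sequence keeps id maps bijective", {
  specs <- list(
    list(name = "ma_plot", params = small_ma,
         clicks = list(list("A1", 3L))),
    list(name = "drugscreen", params = list(),
         clicks = list(list("D", c(1L, 2L)), list("C", 0L), list("B1", 0L))),
    list(name = "cor_heatmap",
         params = list(n_genes = 300L, n_keep = 200L, n_patients = 4L),
         clicks = list(list("A1", c(0L, 1L)))),
    list(name = "plate_qc", params = list(),
         clicks = list(list("P1", c(0L, 0L)))))
  for (spec in specs) {
    app <- build_demo(spec$name, params = spec$params, seed = 5)
    start_app(app)
    s <- open_session(app)
    for (cl in spec$clicks) {
      type <- if (identical(cl[[1]], "B1")) "hover" else "click"
      send_click(app, s, cl[[1]], cl[[2]], type = type)
    }
    for (id in names(s$fragments)) {
      im <- s$fragments[[id]]$id_map
      expect_false(anyDuplicated(im$elem_id) > 0,
                   info = paste(spec$name, id))
    }
    expect_length(s$log, 0L)
    stop_app(app)
  }
})

test_that("export_demo_svgs writes XML-parseable chart files", {
  dir <- withr::local_tempdir()
  paths <- export_demo_svgs("ma_plot", dir, params = small_ma, seed = 3)
  expect_setequal(basename(paths), c("A1.svg", "A2.svg"))
  for (p in paths) {
    expect_s3_class(xml2::read_xml(p), "xml_document")
  }
})

test_that("the shim script ships the identifier grammar the renderer emits", {
  shim <- readLines(chartlink:::shim_path(), warn = FALSE)
  src <- paste(shim, collapse = "\n")
  # the shim's parse regex matches point and heatmap identifiers the
  # renderer produces, and rejects background ids
  expect_match(src, "lc-([A-Za-z0-9_.]+)-(L\\d+)", fixed = TRUE)
  expect_match(src, "parseElementId")
  expect_match(src, "input_change")
  app <- lc_app()
  lc_scatter(x = 1, y = 1, place = "A1", app = app)
  html <- chartlink:::app_page_html(app)
  expect_equal(length(gregexpr("chartlink-shim.js", html)[[1]]), 1L)
})
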