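# Deferred-property resolution, update locality and event dispatch.

test_that("deferred row selection resolves against the session's variables", {
  set.seed(1)
  m <- matrix(rnorm(32), nrow = 8)
  app <- lc_app(session_vars = list(gene = 2L))
  ch <- lc_scatter(dat(y = m[gene, ]), x = 1:4, place = "A2", app = app)
  scope <- chartlink:::new_scope(app, "s1")
  res <- resolve_chart(ch, scope)
  expect_equal(res$layers$L0$y, m[2, ])
  session_set(scope, "gene", 5L)
  expect_equal(resolve_chart(ch, scope)$layers$L0$y, m[5, ])
})

test_that("charts with only immediate properties resolve to declared values", {
  app <- lc_app()
  ch <- lc_scatter(x = c(1, 2, 3), y = c(4, 5, 6), place = "A1", app = app)
  res <- resolve_chart(ch, chartlink:::new_scope(app, "s1"))
  expect_identical(res$layers$L0$x, c(1, 2, 3))
  expect_identical(res$layers$L0$y, c(4, 5, 6))
})

test_that("a failing deferred expression names the chart and property", {
  app <- lc_app()
  ch <- lc_scatter(dat(y = stop("boom")), x = 1:3, place = "A9", app = app)
  scope <- chartlink:::new_scope(app, "s1")
  err <- tryCatch(resolve_chart(ch, scope), error = function(e) e)
  expect_s3_class(err, "lc_resolution_error")
  expect_match(conditionMessage(err), "A9")
  expect_match(conditionMessage(err), "'y'")
})

test_that("update_charts touches only the named charts and is idempotent", {
  app <- tiny_app()
  start_app(app)
  scope <- open_session(app)
  f_a1 <- scope$fragments[["A1"]]$markup
  f_a2 <- scope$fragments[["A2"]]$markup
  session_set(scope, "gene", 6L)
  update_charts("A2", scope)
  expect_identical(scope$fragments[["A1"]]$markup, f_a1)   # locality
  expect_false(identical(scope$fragments[["A2"]]$markup, f_a2))
  # unchanged scope -> byte-identical re-render
  g <- scope$fragments[["A2"]]$markup
  update_charts("A2", scope)
  expect_identical(scope$fragments[["A2"]]$markup, g)
  # partial failure: known id updated, unknown named in the error
  session_set(scope, "gene", 3L)
  expect_error(update_charts(c("A2", "nope"), scope), "nope")
  expect_equal(scope$resolved[["A2"]]$layers$L0$y, app$demo_data$m[3, ])
  stop_app(app)
})

test_that("click dispatch mutates only the session's variables and linked chart", {
  app <- tiny_app()
  start_app(app)
  scope <- open_session(app)
  f_a1 <- scope$fragments[["A1"]]$markup
  dispatch_event(event_message(scope, "A1", "L0", "click", 4L), scope)  # wire 0-based
  expect_identical(session_get(scope, "gene"), 5L)                      # R 1-based
  expect_equal(scope$resolved[["A2"]]$layers$L0$y, app$demo_data$m[5, ])
  expect_identical(scope$fragments[["A1"]]$markup, f_a1)
  stop_app(app)
})

test_that("out-of-bounds indices are rejected without touching the scope", {
  app <- tiny_app()
  start_app(app)
  scope <- open_session(app)
  dispatch_event(event_message(scope, "A1", "L0", "click", 10L), scope)
  expect_identical(session_get(scope, "gene"), 1L)
  expect_match(scope$log, "out of bounds", all = FALSE)
  dispatch_event(event_message(scope, "A1", "L0", "click", -1L), scope)
  expect_identical(session_get(scope, "gene"), 1L)
  stop_app(app)
})

test_that("handler registration replaces prior handlers per slot", {
  app <- tiny_app()
  start_app(app)
  scope <- open_session(app)
  hits <- new.env(); hits$a <- 0L; hits$b <- 0L
  register_handler("A1", "L0", "click", function(k) hits$a <- hits$a + 1L,
                   app = app)
  dispatch_event(event_message(scope, "A1", "L0", "click", 0L), scope)
  expect_identical(hits$a, 1L)
  register_handler("A1", "L0", "click", function(k) hits$b <- hits$b + 1L,
                   app = app)
  dispatch_event(event_message(scope, "A1", "L0", "click", 0L), scope)
  expect_identical(c(hits$a, hits$b), c(1L, 1L))  # old handler gone
  # slot separation: hover handler does not fire on click
  register_handler("A1", "L0", "hover", function(k) hits$a <- hits$a + 100L,
                   app = app)
  dispatch_event(event_message(scope, "A1", "L0", "click", 0L), scope)
  expect_identical(hits$a, 1L)
  # no handler on A2 -> silent no-op
  expect_silent(dispatch_event(event_message(scope, "A2", "L0", "click", 0L),
                               scope))
  expect_error(register_handler("ZZ", "L0", "click", identity, app = app),
               "unknown chart")
  stop_app(app)
})

test_that("a callback error is caught, logged and leaves the session alive", {
  app <- tiny_app()
  start_app(app)
  scope <- open_session(app)
  register_handler("A1", "L0", "click", function(k) stop("user bug"),
                   app = app)
  dispatch_event(event_message(scope, "A1", "L0", "click", 0L), scope)
  expect_match(scope$log, "user bug", all = FALSE)
  expect_true(scope$open)
  # session still serviceable
  register_handler("A1", "L0", "click", function(k) gene <<- k, app = app)
  dispatch_event(event_message(scope, "A1", "L0", "click", 2L), scope)
  expect_identical(session_get(scope, "gene"), 3L)
  stop_app(app)
})

test_that("queued events run serially in arrival order", {
  app <- lc_app(session_vars = list(trail = integer()))
  lc_scatter(x = 1:10, y = 1:10, place = "A1", app = app,
             on_click = function(k) trail <<- c(trail, k))
  start_app(app)
  scope <- open_session(app)
  for (k in c(3L, 1L, 7L, 7L, 2L)) {
    dispatch_event(event_message(scope, "A1", "L0", "click", k - 1L), scope)
  }
  expect_identical(session_get(scope, "trail"), c(3L, 1L, 7L, 7L, 2L))
  stop_app(app)
})

test_that("determinism: identical spec and scope state give identical fragments", {
  app1 <- tiny_app(seed = 99L)
  app2 <- tiny_app(seed = 99L)
  start_app(app1); start_app(app2)
  s1 <- open_session(app1); s2 <- open_session(app2)
  expect_identical(s1$fragments[["A1"]]$markup, s2$fragments[["A1"]]$markup)
  expect_identical(s1$fragments[["A2"]]$markup, s2$fragments[["A2"]]$markup)
  stop_app(app1); stop_app(app2)
})
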