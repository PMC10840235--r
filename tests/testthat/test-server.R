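# Wire protocol, session lifecycle, isolation and the HTTP backend.

test_that("wire messages encode to single JSON frames and decode back", {
  m <- wire_message("event", "tok123",
                    list(chart_id = "A1", layer_id = "L0",
                         event_type = "click", payload = 5L))
  frame <- wire_encode(m)
  expect_false(grepl("\n", frame))
  back <- wire_decode(frame)
  expect_identical(back$kind, "event")
  expect_identical(back$token, "tok123")
  expect_identical(back$body$chart_id, "A1")
  expect_error(wire_decode("{not json"), "not valid JSON")
  expect_error(wire_decode('{"token":"t"}'), "missing kind")
  expect_error(wire_decode('{"kind":"warp","token":"t"}'), "unknown kind")
})

test_that("sessions start from the declared defaults with equal initial fragments", {
  app <- tiny_app(session_vars = list(gene = 1L))
  start_app(app)
  s1 <- open_session(app)
  s2 <- open_session(app)
  expect_identical(session_get(s1, "gene"), 1L)
  expect_identical(session_get(s2, "gene"), 1L)
  expect_false(identical(s1$token, s2$token))
  expect_identical(s1$fragments[["A2"]]$markup, s2$fragments[["A2"]]$markup)
  # client A clicks; client B's state and fragments are untouched
  b_frag <- s2$fragments[["A2"]]$markup
  send_click(app, s1, "A1", 4L)
  expect_identical(session_get(s1, "gene"), 5L)
  expect_identical(session_get(s2, "gene"), 1L)
  expect_identical(s2$fragments[["A2"]]$markup, b_frag)
  stop_app(app)
})

test_that("two interleaved clients replay to the same scopes as solo runs", {
  run <- function(streams) {
    app <- tiny_app(session_vars = list(gene = 1L, trail = integer()))
    register_handler("A1", "L0", "click", function(k) {
      gene <<- k
      trail <<- c(trail, k)
      update_charts("A2")
    }, app = app)
    start_app(app)
    scopes <- lapply(streams, function(.) open_session(app))
    # interleave deterministically by a seeded schedule
    set.seed(1234)
    order <- sample(rep(seq_along(streams), lengths(streams)))
    cursor <- rep(1L, length(streams))
    for (who in order) {
      k <- streams[[who]][cursor[who]]
      cursor[who] <- cursor[who] + 1L
      send_click(app, scopes[[who]], "A1", k)
    }
    out <- lapply(scopes, function(s)
      list(gene = session_get(s, "gene"), trail = session_get(s, "trail"),
           frag = s$fragments[["A2"]]$markup))
    stop_app(app)
    out
  }
  set.seed(77)
  streams <- list(sample(0:7, 50, TRUE), sample(0:7, 50, TRUE))
  joint <- run(streams)
  solo1 <- run(streams[1])[[1]]
  solo2 <- run(streams[2])[[1]]
  expect_identical(joint[[1]]$trail, solo1$trail)
  expect_identical(joint[[2]]$trail, solo2$trail)
  expect_identical(joint[[1]]$gene, solo1$gene)
  expect_identical(joint[[2]]$gene, solo2$gene)
  expect_identical(joint[[1]]$frag, solo1$frag)
  expect_identical(joint[[2]]$frag, solo2$frag)
})

test_that("malformed frames and stale tokens never kill the app", {
  app <- tiny_app()
  start_app(app)
  s <- open_session(app)
  out <- handle_message(app, "garbage{{{")
  expect_identical(out[[1]]$kind, "error")
  expect_match(app$log, "malformed", all = FALSE)
  # session still usable after the garbage frame
  send_click(app, s, "A1", 2L)
  expect_identical(session_get(s, "gene"), 3L)
  # frames for closed sessions are dropped with a log entry
  tok <- s$token
  handle_message(app, wire_encode(wire_message("bye", tok)))
  expect_false(s$open)
  out2 <- handle_message(app, click_frame(s, "A1", 1L))
  expect_length(out2, 0L)
  expect_match(app$log, "unknown or closed session", all = FALSE)
  # tokens are single-use: reopening yields a fresh token
  s2 <- open_session(app)
  expect_false(identical(s2$token, tok))
  stop_app(app)
})

test_that("the session limit triggers a polite refusal", {
  app <- lc_app(max_sessions = 2L)
  lc_scatter(x = 1, y = 1, place = "A1", app = app)
  start_app(app)
  open_session(app)
  open_session(app)
  expect_error(open_session(app), "session limit reached")
  stop_app(app)
})

test_that("stop_app is idempotent and says bye to open sessions", {
  app <- tiny_app()
  start_app(app)
  sent <- list()
  s <- open_session(app, client = function(frame) {
    sent[[length(sent) + 1L]] <<- frame
  })
  n0 <- length(sent)
  stop_app(app)
  kinds <- vapply(sent[(n0 + 1):length(sent)],
                  function(f) wire_decode(f)$kind, "")
  expect_true("bye" %in% kinds)
  expect_silent(stop_app(app))
  expect_false(app$running)
})

test_that("the HTTP backend serves the page, the shim and static assets", {
  skip_if_not_installed("httpuv")
  app <- tiny_app()
  serve_static(app, "/style.css", "body { margin: 0; }")
  png_bytes <- as.raw(c(0x89, 0x50, 0x4e, 0x47, 13, 10, 26, 10, 1, 2, 3))
  serve_static(app, "/img.png", png_bytes)
  expect_error(serve_static(app, "/ws", "x"), "reserved")
  port <- httpuv::randomPort()
  start_app(app, port = port)
  expect_error(start_app(tiny_app(), port = port), "cannot bind")

  fetch <- function(path) {
    con <- socketConnection("127.0.0.1", port, open = "r+b", blocking = FALSE)
    on.exit(close(con))
    writeLines(c(sprintf("GET %s HTTP/1.1", path), "Host: 127.0.0.1",
                 "Connection: close", ""), con, sep = "\r\n")
    buf <- raw()
    for (i in 1:100) {
      httpuv::service(20L)
      chunk <- readBin(con, "raw", 65536L)
      buf <- c(buf, chunk)
      if (length(buf) && length(chunk) == 0L && i > 3) break
    }
    rawToChar(buf)
  }
  page <- fetch("/")
  expect_match(page, "200 OK")
  expect_match(page, 'id="A1"')
  expect_match(page, 'id="A2"')
  css <- fetch("/style.css")
  expect_match(css, "text/css")
  expect_match(css, "body { margin: 0; }", fixed = TRUE)
  img <- fetch("/img.png")
  expect_true(grepl("image/png", img, useBytes = TRUE))
  expect_true(grepl("Content-Length: 11", img, useBytes = TRUE))
  shim <- fetch("/chartlink-shim.js")
  expect_match(shim, "parseElementId")
  missing <- fetch("/nope.txt")
  expect_match(missing, "404")
  stop_app(app)
  # port is released: same port binds again
  app2 <- tiny_app()
  start_app(app2, port = port)
  stop_app(app2)
})
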