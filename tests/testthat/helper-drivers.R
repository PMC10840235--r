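# Scripted-client helpers: build small apps and synthesize the wire frames a
# browser would send.

tiny_app <- function(session_vars = list(gene = 1L), n = 8L, p = 4L,
                     seed = 42L) {
  set.seed(seed)
  m <- matrix(rnorm(n * p), nrow = n,
              dimnames = list(paste0("g", 1:n), paste0("s", 1:p)))
  app <- lc_app(session_vars = session_vars)
  lc_scatter(x = rowMeans(m), y = m[, 1] - m[, 2], place = "A1", app = app,
             on_click = function(k) {
               gene <<- k
               update_charts("A2")
             })
  lc_scatter(dat(y = m[gene, ]), x = seq_len(p), place = "A2", app = app)
  app$demo_data <- list(m = m)
  app
}

click_frame <- function(scope, chart, payload, type = "click", layer = "L0") {
  wire_encode(wire_message("event", scope$token,
                           list(chart_id = chart, layer_id = layer,
                                event_type = type, payload = payload)))
}

send_click <- function(app, scope, chart, payload, type = "click",
                       layer = "L0") {
  handle_message(app, click_frame(scope, chart, payload, type, layer))
}

# a resolved one-layer scatter with random content, for renderer fuzzing
random_resolved_chart <- function(seed) {
  set.seed(seed)
  n <- sample(1:40, 1)
  app <- lc_app()
  ch <- lc_scatter(x = rnorm(n), y = rnorm(n),
                   color = sample(c("#ff0000", "#00ff00", "#0000ff"), n, TRUE),
                   size = runif(n, 1, 5),
                   place = paste0("R", seed), app = app)
  if (seed %% 3 == 0) add_layer(ch, "hline", h = rnorm(2))
  if (seed %% 4 == 0) add_layer(ch, "line", x = sort(rnorm(5)), y = rnorm(5))
  resolve_chart(ch, chartlink:::new_scope(app, "s1"))
}
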