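# chartlink

Linked interactive charts for R, with every event handler written in plain R.

Exploratory analysis of omics-scale data constantly runs into the same wall:
a summary plot (an MA plot, a correlation heatmap, a drug-score matrix)
compresses thousands of underlying observations into one point or cell, and
checking any single one of them means editing plotting code, re-running it,
and looking again. *Linking* removes that loop: click a gene in the MA plot
and a second chart immediately shows that gene's per-sample expression;
click a heatmap cell and see the scatter it summarises; hover a
dose-response point and see the microtiter well it came from. chartlink
provides the building blocks for such apps — and keeps all the logic in R,
so a click handler can run any computation the analyst already has.

## How it works

- **Declarative charts, deferred properties.** Fifteen constructors
  (`lc_scatter`, `lc_beeswarm`, `lc_line`, `lc_path`, `lc_abline`,
  `lc_hline`, `lc_vline`, `lc_bars`, `lc_hist`, `lc_dens`, `lc_heatmap`,
  `lc_colourSlider`, `lc_input`, `lc_html`, `lc_image`) take property maps.
  A property wrapped in `dat()` is stored unevaluated and re-evaluated in
  the session's scope on every update — `dat(y = counts[gene, ])` re-reads
  the session's current `gene`.
- **Sessions.** Each connected client gets private copies of the declared
  session variables. Callbacks run with those variables in scope: `gene <<- k`
  mutates only that client's copy, then `update_charts("A2")` re-resolves
  and re-renders chart A2 for that client alone.
- **Server-side SVG.** Charts render deterministically to SVG text with
  stable element identifiers (`lc-{chart}-{layer}-{index}`, heatmap cells
  `lc-{chart}-{layer}-{row}-{col}`). A small static browser shim forwards
  DOM events over a JSON wire protocol and swaps replacement fragments in;
  the whole pipeline also runs headlessly, which is how the tests drive it.
- **Statistics kernels.** Tick placement, histogram binning, Gaussian KDE
  (Silverman bandwidth), greedy beeswarm layout, complete-linkage heatmap
  ordering, and — for the demos — CPM, a paired-t differential-expression
  summary with BH adjustment, Spearman sample correlation, 4PL
  dose-response fitting and an area-based drug sensitivity score.

## A worked example

```r
library(chartlink)
set.seed(1)
counts <- matrix(rnbinom(8 * 6, mu = 50, size = 10), nrow = 8,
                 dimnames = list(paste0("gene", 1:8), paste0("s", 1:6)))
logcpm <- cpm(counts, log = TRUE)

app <- lc_app(session_vars = list(gene = 1))
lc_scatter(x = rowMeans(logcpm), y = logcpm[, 1] - logcpm[, 2],
           place = "A1", app = app,
           on_click = function(k) { gene <<- k; update_charts("A2") })
lc_scatter(dat(y = logcpm[gene, ]), x = 1:6, place = "A2", app = app)

start_app(app)            # add port = 8080 to serve it to a browser
s <- open_session(app)    # headless scripted client
s$fragments[["A2"]]
#> <chartlink fragment: 3437 bytes, 6 interactive element(s)>

# simulate the browser clicking the 5th point of A1 (wire indices are 0-based)
handle_message(app, wire_encode(wire_message("event", s$token,
  list(chart_id = "A1", layer_id = "L0", event_type = "click", payload = 4L))))
session_get(s, "gene")
#> [1] 5
round(s$resolved[["A2"]]$layers$L0$y, 3)
#>     s1     s2     s3     s4     s5     s6
#> 16.537 16.803 17.260 17.138 16.997 17.350
```

The click handler set `gene` to 5 in this session, and chart A2 now resolves
to gene 5's log-CPM values — exactly row 5 of `logcpm`. Chart A1's fragment
is byte-identical to before the click: updates touch only the charts they
name.

## Demo apps

Four fully wired apps, each backed by a seeded synthetic-data generator
(paired tumor/normal negative-binomial expression data; a 96-well drug
screen with latent drug clusters):

```r
app <- build_demo("ma_plot", seed = 1)      # MA plot -> per-sample expression
app <- build_demo("drugscreen", seed = 1)   # heatmap -> scores -> curves -> plate
app <- build_demo("cor_heatmap", seed = 1)  # Spearman heatmap -> sample pairs
app <- build_demo("plate_qc", seed = 1)     # plate map + status reassignment
run_demo("ma_plot", port = 8080)            # same, served at http://127.0.0.1:8080/
```

A thin CLI does the same from a shell
(`Rscript inst/cli/chartlink-demo.R demo ma_plot --port 8080 --seed 1`), and
`export_demo_svgs("ma_plot", "out/")` writes the initial charts as SVG files.

See `vignette("chartlink-methods")` for the reactive model, the frozen
numerical conventions and what the synthetic generators do and do not
emulate.

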