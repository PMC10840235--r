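---
title: "chartlink: design and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chartlink: design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chartlink)
```

chartlink builds *linked* interactive charts: an overview chart (an MA plot,
a correlation heatmap) is connected to detail charts so that clicking a data
item in one changes what the others display. The defining constraint is that
every event handler is ordinary R: a click in the browser ends up calling a
plain R function, which mutates per-session state and asks named charts to
re-render. This vignette records the model behind that, the conventions the
package freezes, and what the bundled synthetic demos do and do not show.

## The reactive model

A chart is a declarative object: a type (one of the fifteen in
`constructor_roster()`), a placement id on the page, and a property map.
Properties come in two flavors:

* **immediate** — evaluated once, at declaration;
* **deferred** — wrapped in `dat()`, stored as an unevaluated expression and
  re-evaluated on every resolution.

A session scope holds one connected client's private copies of the session
variables declared at app start. Deferred expressions are evaluated with the
scope's variable environment first on the search path and the declaring
script's environment behind it, so `dat(y = counts[gene, ])` re-reads the
session's current `gene` but still sees the script's `counts`. Event
callbacks run the same way: reading a session variable sees the session's
copy, and assigning with `<<-` writes the session's copy — never a true
global, which is what makes concurrent clients safe. Within one session,
events are queued and consumed FIFO by a single consumer, so handler effects
are serial and deterministic; across sessions there is no shared mutable
state at all.

There is deliberately no automatic dependency tracking: a handler names the
charts to refresh (`update_charts("A2")`). This keeps the update graph
explicit in the analyst's code and makes the locality guarantee trivial to
state — a chart not named in an update is byte-identical afterwards.

## Rendering

Charts are rendered server-side to SVG text. This is a deliberate departure
from client-side drawing: the entire pipeline — resolve, validate, render,
diff — runs headlessly in R, which makes every interactive behavior testable
without a browser, and reduces the browser shim to event forwarding and
`innerHTML` replacement. The costs are whole-fragment updates (no
incremental DOM surgery) and desk-scale rather than WebGL-scale point
counts; both are acceptable for exploratory use.

Determinism is a contract: fixed 400x400 device units with 40-unit margins,
two-decimal coordinate formatting, no timestamps or generated ids, element
order fixed by data order. Identical resolved input gives byte-identical
markup, which turns "the other chart did not change" into a string equality.
Every interactive element carries the identifier
`lc-{chart}-{layer}-{index}` (heatmap cells: `...-{row}-{col}`), 0-based on
the wire; this grammar is shared verbatim with the browser shim, and the R
side converts to 1-based indices before invoking callbacks. Non-finite
coordinates drop their element and are counted in a diagnostics field;
values outside an axis domain clamp to the plot boundary.

## Geometry and statistics conventions

The paperless parts of chart drawing each have several defensible
conventions; the package freezes one of each so tests can be exact:

* **Ticks** — step `s` is the largest of {1, 2, 5} x 10^k not exceeding
  span/target; ticks are consecutive multiples of `s` covering the domain.
* **Histogram** — equal-width bins, left-closed/right-open, last bin closed;
  counts conserve the in-range sample size.
* **Density** — Gaussian KDE, `f(g) = (1/nh) sum phi((g - x_i)/h)`, default
  bandwidth Silverman's rule `0.9 min(sd, IQR/1.34) n^(-1/5)`, with a
  `1e-3 (|mean| + 1)` fallback for degenerate data.
* **Beeswarm** — greedy placement in value order (ties keep input order);
  each point takes the smallest-magnitude perpendicular offset keeping all
  centers at least two radii apart, ties broken toward positive offsets.
* **Heatmap order** — leaf order of complete-linkage hierarchical
  clustering on Euclidean distances (`stats::hclust`); rows are the first
  index and display top-left, the matrix-printing convention.
* **Colors** — piecewise-linear interpolation between palette anchors in
  sRGB components (rounded, lowercase hex). A perceptual space would look
  better and test worse; bit-exactness won.

## The session server

The wire protocol is one JSON text frame per message, `{kind, token, body}`
with kinds hello/event/update/error/bye. Sessions are transport-agnostic:
every scope owns an outbox of frames, and the transport — the in-process
driver used by tests and scripted clients, or the optional httpuv
HTTP+WebSocket backend — only moves frames. Headless runs therefore
exercise exactly the code path a browser does, including malformed-frame
handling (error frame, session survives) and callback exceptions (logged
with chart and session context, session survives). Session tokens are
128-bit values drawn from R's seedable RNG, single-use, and the server
binds loopback unless told otherwise; exposing an app is an explicit
choice. Updates triggered by an event go only to the session that raised
it; `broadcast_update()` exists for dataset-level changes.

## The synthetic demos

The demos need data with known truth, so each ships a generator.

**Expression generator.** Emulates a paired oral-cancer design: 17 patients,
one normal and one tumor sample each (a third condition can be emitted but
the MA demo compares two). Counts are negative binomial; gene base means are
log-normal on the CPM scale (meanlog 3, sdlog 1.6 — a realistic dynamic
range of roughly 1–1000 CPM); dispersion is `0.05 + 1/mean`, the usual
decreasing mean-dispersion profile; library sizes are log-normal (sdlog
0.3) around two million reads. A fraction `frac_de = 0.1` of genes receives
a `Normal(0, 2)` log2 effect in tumor samples — symmetric, so up- and
down-regulation are equally represented.

The demo's DE summary is the three-value reduction the MA app needs:
mean log2-CPM, the mean within-patient log2-CPM difference, and a paired
two-sided t-test on those differences with Benjamini–Hochberg adjustment
(zero-variance differences give p = 1 by convention). It is deliberately
*not* a moderated-variance pipeline; re-implementing one is out of scope,
and the app only needs a per-gene triple. One consequence surfaced during
design: with 10% of genes at effect-sd 2, observed column sums are
composition-shifted in tumor samples, and normalising by them biases every
null gene's fold change enough to destroy FDR control. The generator
therefore records its true sequencing depths and the summary normalises by
the dataset's library sizes; robust scale estimation (TMM,
median-of-ratios) — the real-data answer to the same problem — is out of
scope. `cpm()` itself defaults to column sums for raw matrices.

**Drug-screen generator.** One 96-well plate per cell line: 12 drugs x 7
log-spaced concentrations (1 nM–10 uM) row-major in columns 1–11, three
vehicle and three full-kill control wells in the last column. True
dose-response curves are 4PL; drugs belong to three latent mechanism
clusters sharing a per-cell-line sensitivity profile, so sensitivity scores
correlate within clusters — which is what makes the correlation heatmap
show structure. Signals are `plate scale x viability` plus Gaussian noise
(sd 0.05 on the viability scale), with an optional additive edge artifact.

Viability is anchored to the on-plate controls
(`(signal - mean(kill)) / (mean(vehicle) - mean(kill))`, clipped to
[-0.1, 1.5]). The 4PL fit is bounded least squares (`a` in [0.5, 1.5], `d`
in [-0.1, 1], `c0` within the tested range x [0.01, 100], `b` in [0.1, 10])
over `(a, d, log c0, log b)` with L-BFGS-B, starting from `a = 1`, `d = 0`,
`c0 =` the geometric concentration mean, `b = 1`, plus a small multi-start
over slopes and inflections; data with viability variance below 1e-6
short-circuit to the flat model. The drug score is the normalised
inhibition area — the mean over log10 concentration of `max(0, 1 - f(c))`
on 101 log-spaced points — a simplified area-under-curve summary, not the
refined published drug-sensitivity score, and it is labelled as such.

**What passing tests show, and what they do not.** The generators are pure
functions of their seeds and match the demos' statistical assumptions by
construction: no batch effects, no patient-level expression covariance, no
count outliers, no plate drift beyond the optional edge term, noise
honestly Gaussian. Green tests therefore certify the framework's contracts
(linking, isolation, determinism) and the internal consistency of the
analysis steps — not that a plain paired t-test or control-anchored
normalisation is adequate for any real dataset.

## Problem sizes and numerical notes

Tests and the acceptance script run the MA demo at its full default size
(8000 genes, 17 patients) and the drug screen at 12 x 8 x 7; statistical
checks use 2000-gene datasets, 20 replicates for the FDR property and 100
seeded replicates for layout and fit properties — sizes at which every
property is stable across seeds while the whole suite stays in the tens of
seconds. Degenerate inputs are defined, not accidental: zero-width domains
yield a single tick, empty scatters render axes, zero-variance samples give
missing correlations rather than errors, and a failing deferred expression
raises an error naming the chart and property while the session lives on.

## Known limitations

No dependency tracking between charts; no zoom/pan or multi-point brushing;
whole-fragment updates only; sRGB (not perceptual) color interpolation;
single-linkage alternatives (Ward, average) not exposed; sessions do not
survive reconnects (a reload is a fresh session); and the WebSocket backend
is optional — without it the package is a fully functional headless engine.
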