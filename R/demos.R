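# Demo apps, each assembled from the framework plus a synthetic-data
# generator, reproducing the canonical linked-chart workflows: an MA plot
# linked to per-sample expression, a drug-screen pipeline walked backwards
# from a correlation heatmap down to the raw plate, a sample-correlation
# heatmap linked to sample-pair scatters, and a plate-QC app with input
# widgets.

.demo_names <- c("ma_plot", "drugscreen", "cor_heatmap", "plate_qc")

#' Build a demo app
#'
#' Returns a fully wired (but not yet served) app handle; pass it to
#' [start_app()] and open sessions, or drive it headlessly with
#' [open_session()] / [handle_message()].
#'
#' * `ma_plot` — MA scatter of a synthetic paired tumor/normal experiment;
#'   clicking a gene switches the linked chart to that gene's per-sample
#'   log-CPM values (session variable `gene`).
#' * `drugscreen` — drug-drug score-correlation heatmap; click a cell to see
#'   the two drugs' scores across cell lines; click a cell line point to see
#'   both dose-response curves; hover a curve point to highlight the
#'   originating plate well.
#' * `cor_heatmap` — sample-sample Spearman heatmap (cluster-ordered); click
#'   a cell to scatter the two samples' log-CPM values against each other.
#' * `plate_qc` — plate heatmap colored by well status, a dose-response
#'   detail chart for the selected well, and a radio input that reassigns
#'   the well's status.
#'
#' @param name one of `"ma_plot"`, `"drugscreen"`, `"cor_heatmap"`,
#'   `"plate_qc"`.
#' @param params named list overriding generator arguments (e.g. `n_genes`,
#'   `n_drugs`).
#' @param seed RNG seed for the generators.
#' @return An [lc_app()] handle with charts and handlers registered; the
#'   generated data is attached as `app$demo_data`.
#' @export
build_demo <- function(name, params = list(), seed = 1L) {
  if (!is.character(name) || length(name) != 1L || !name %in% .demo_names) {
    stop(sprintf("unknown demo '%s'; valid names: %s",
                 paste(name, collapse = ","),
                 paste(.demo_names, collapse = ", ")), call. = FALSE)
  }
  switch(name,
         ma_plot = demo_ma_plot(params, seed),
         drugscreen = demo_drugscreen(params, seed),
         cor_heatmap = demo_cor_heatmap(params, seed),
         plate_qc = demo_plate_qc(params, seed))
}

demo_arg <- function(params, name, default) params[[name]] %||% default

demo_ma_plot <- function(params, seed) {
  ds <- gen_expression(n_genes = demo_arg(params, "n_genes", 8000L),
                       n_patients = demo_arg(params, "n_patients", 17L),
                       frac_de = demo_arg(params, "frac_de", 0.1),
                       effect_sd = demo_arg(params, "effect_sd", 2),
                       seed = seed)
  de <- de_summary(ds)
  lcpm <- cpm(ds$counts, ds$lib_sizes, log = TRUE)
  cond <- ds$samples$condition
  cond_col <- map_colors(cond, c("#1b9e77", "#d95f02"))

  app <- lc_app(page_spec(title = "Differential expression explorer"),
                session_vars = list(gene = 1L))
  lc_scatter(x = de$aveExpr, y = de$log2FC,
             color = significance_colors(de), size = 2,
             axisTitleX = "average expression (log2 CPM)",
             axisTitleY = "log2 fold change", title = "MA plot",
             on_click = function(k) {
               gene <<- k
               update_charts("A2")
             },
             place = "A1", app = app)
  lc_scatter(dat(y = lcpm[gene, ], title = paste0("expression of ", rownames(lcpm)[gene])),
             x = cond, color = cond_col, size = 3,
             axisTitleY = "log2 CPM",
             place = "A2", app = app)
  app$demo_data <- list(dataset = ds, de = de, lcpm = lcpm)
  app
}

demo_drugscreen <- function(params, seed) {
  screen <- gen_drug_screen(
    n_drugs = demo_arg(params, "n_drugs", 12L),
    n_cell_lines = demo_arg(params, "n_cell_lines", 8L),
    n_conc = demo_arg(params, "n_conc", 7L),
    n_clusters = demo_arg(params, "n_clusters", 3L),
    noise_sd = demo_arg(params, "noise_sd", 0.05),
    edge_effect = demo_arg(params, "edge_effect", 0),
    seed = seed)
  red <- screen_scores(screen)
  scores <- red$scores
  cmat <- score_correlation(scores)
  ord <- cluster_order(cmat, "rows")
  conc <- screen$conc
  grid <- 10^seq(log10(min(conc)), log10(max(conc)), length.out = 60L)
  wl <- screen$wells

  viab_of <- function(dr, l) {
    v <- red$viability[[l]]
    v <- v[v$drug == dr, ]
    v[order(v$conc_idx), ]
  }
  curve_of <- function(dr, l) {
    ft <- red$fits[[dr, l]]
    fourpl(grid, ft$a, ft$d, ft$c0, ft$b)
  }
  well_rc <- function(dr, ci, l) {
    w <- wl[wl$cell_line == l & !is.na(wl$drug) & wl$drug == dr &
              wl$conc_idx == ci, ]
    c(w$row[1], w$col[1])
  }
  plate_signal <- function(l) {
    w <- wl[wl$cell_line == l, ]
    m <- matrix(NA_real_, .plate_rows, .plate_cols)
    m[cbind(w$row, w$col)] <- w$signal
    m
  }

  app <- lc_app(page_spec(title = "Drug screen back-tracker"),
                session_vars = list(d1 = 1L, d2 = 2L, cl = 1L,
                                    hl = c(NA_integer_, NA_integer_)))
  lc_heatmap(value = cmat, rowOrder = ord, colOrder = ord,
             title = "drug-drug score correlation",
             on_click = function(rc) {
               d1 <<- rc[1]; d2 <<- rc[2]
               update_charts(c("C", "B1", "B2"))
             },
             place = "D", app = app)
  lc_scatter(dat(x = scores[d1, ], y = scores[d2, ],
                 axisTitleX = paste("drug", d1, "score"),
                 axisTitleY = paste("drug", d2, "score"),
                 title = paste("drugs", d1, "vs", d2, "across cell lines")),
             size = 3,
             on_click = function(k) {
               cl <<- k
               update_charts(c("B1", "B2", "A"))
             },
             place = "C", app = app)
  b1 <- lc_scatter(
    dat(x = viab_of(d1, cl)$conc, y = viab_of(d1, cl)$viability,
        title = paste("drug", d1, "on cell line", cl)),
    size = 3, logScaleX = TRUE, axisTitleX = "concentration (uM)",
    axisTitleY = "viability",
    on_hover = function(k) {
      hl <<- well_rc(d1, k, cl)
      update_charts("A")
    },
    place = "B1", app = app)
  add_layer(b1, "line", dat(x = grid, y = curve_of(d1, cl)), color = "#d62728")
  b2 <- lc_scatter(
    dat(x = viab_of(d2, cl)$conc, y = viab_of(d2, cl)$viability,
        title = paste("drug", d2, "on cell line", cl)),
    size = 3, logScaleX = TRUE, axisTitleX = "concentration (uM)",
    axisTitleY = "viability",
    on_hover = function(k) {
      hl <<- well_rc(d2, k, cl)
      update_charts("A")
    },
    place = "B2", app = app)
  add_layer(b2, "line", dat(x = grid, y = curve_of(d2, cl)), color = "#d62728")
  lc_heatmap(dat(value = plate_signal(cl), highlight = hl,
                 title = paste("plate: cell line", cl)),
             place = "A", app = app)
  app$demo_data <- list(screen = screen, scores = scores, cor = cmat,
                        order = ord, fits = red$fits,
                        viability = red$viability, well_rc = well_rc)
  app
}

demo_cor_heatmap <- function(params, seed) {
  ds <- gen_expression(n_genes = demo_arg(params, "n_genes", 10000L),
                       n_patients = demo_arg(params, "n_patients", 17L),
                       frac_de = demo_arg(params, "frac_de", 0.1),
                       effect_sd = demo_arg(params, "effect_sd", 2),
                       seed = seed)
  n_keep <- min(demo_arg(params, "n_keep", 8000L), nrow(ds$counts))
  ds <- subset_genes(ds, n_keep, seed = seed)
  lcpm <- cpm(ds$counts, ds$lib_sizes, log = TRUE)
  smat <- spearman_matrix(lcpm)
  ord <- cluster_order(smat, "rows")
  snames <- ds$samples$sample

  app <- lc_app(page_spec(title = "Sample correlation explorer"),
                session_vars = list(s1 = 1L, s2 = 2L))
  lc_heatmap(value = smat, rowOrder = ord, colOrder = ord,
             rowLabels = snames, colLabels = snames,
             title = "Spearman correlation between samples",
             on_click = function(rc) {
               s1 <<- rc[1]; s2 <<- rc[2]
               update_charts("A2")
             },
             place = "A1", app = app)
  lc_scatter(dat(x = lcpm[, s1], y = lcpm[, s2],
                 axisTitleX = paste("log2 CPM,", snames[s1]),
                 axisTitleY = paste("log2 CPM,", snames[s2])),
             size = 1.5, opacity = 0.5,
             place = "A2", app = app)
  app$demo_data <- list(dataset = ds, lcpm = lcpm, spearman = smat, order = ord)
  app
}

demo_plate_qc <- function(params, seed) {
  screen <- gen_drug_screen(
    n_drugs = demo_arg(params, "n_drugs", 12L),
    n_cell_lines = demo_arg(params, "n_cell_lines", 3L),
    noise_sd = demo_arg(params, "noise_sd", 0.05),
    seed = seed)
  wl <- screen$wells[screen$wells$cell_line == 1L, ]
  role_levels <- c("sample", "empty", "negative", "positive")
  roles0 <- matrix("empty", .plate_rows, .plate_cols)
  roles0[cbind(wl$row, wl$col)] <- wl$role
  viab <- normalize_viability(wl)

  well_xy <- function(sel) {
    w <- viab[viab$row == sel[1] & viab$col == sel[2], ]
    if (nrow(w) != 1L || is.na(w$drug)) return(list(x = numeric(), y = numeric()))
    v <- viab[viab$drug == w$drug, ]
    v <- v[order(v$conc_idx), ]
    list(x = v$conc, y = v$viability)
  }

  app <- lc_app(page_spec(title = "Plate QC"),
                session_vars = list(sel = c(1L, 1L), roles = roles0))
  lc_heatmap(dat(value = matrix(match(roles, role_levels), .plate_rows, .plate_cols),
                 highlight = sel),
             palette = c("#2c7bb6", "#ffffbf", "#abd9e9", "#d7191c"),
             title = "plate layout by well status",
             on_click = function(rc) {
               sel <<- rc
               update_charts("P2")
             },
             place = "P1", app = app)
  lc_scatter(dat(x = well_xy(sel)$x, y = well_xy(sel)$y,
                 title = paste0("dose-response through well (", sel[1],
                                ",", sel[2], ")")),
             size = 3, logScaleX = TRUE,
             axisTitleX = "concentration (uM)", axisTitleY = "viability",
             place = "P2", app = app)
  lc_input(type = "radio", labels = role_levels, value = 1L,
           on_change = function(v) {
             r <- roles
             r[sel[1], sel[2]] <- role_levels[v]
             roles <<- r
             update_charts("P1")
           },
           place = "W1", app = app)
  app$demo_data <- list(screen = screen, roles = roles0, viability = viab,
                        role_levels = role_levels)
  app
}

#' Run a demo app in a browser
#'
#' Builds the demo, starts the embedded server and (optionally) blocks
#' servicing requests until interrupted.
#'
#' @inheritParams build_demo
#' @param host,port where to serve; see [start_app()].
#' @param block keep servicing requests until interrupted (for scripts).
#' @return The running app handle, invisibly.
#' @export
run_demo <- function(name, host = "127.0.0.1", port = 8080L,
                     params = list(), seed = 1L, block = FALSE) {
  app <- build_demo(name, params, seed)
  start_app(app, host = host, port = port)
  message(sprintf("serving '%s' demo at http://%s:%d/", name, host, port))
  if (block) {
    on.exit(stop_app(app))
    while (TRUE) httpuv::service(250L)
  }
  invisible(app)
}

#' Export a demo's initial charts as SVG files
#'
#' Opens a headless session on the demo app and writes each plot chart's
#' initially rendered fragment as `<chart id>.svg`.
#'
#' @inheritParams build_demo
#' @param out_dir output directory (created if missing).
#' @return Character vector of the written paths, invisibly.
#' @export
export_demo_svgs <- function(name, out_dir, params = list(), seed = 1L) {
  app <- build_demo(name, params, seed)
  start_app(app)
  on.exit(stop_app(app))
  scope <- open_session(app)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (id in names(app$charts)) {
    res <- scope$resolved[[id]]
    if (res$kind != "plot") next
    path <- file.path(out_dir, paste0(id, ".svg"))
    export_svg(res, path = path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
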