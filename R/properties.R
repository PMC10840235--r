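# Chart properties are either immediate (a concrete value fixed at declaration
# time) or deferred (an unevaluated expression re-evaluated in a session's
# scope on every update). Deferred properties are what make chart linking
# work: a property can reference a session variable, and updating the chart
# re-reads the variable's current value for that session only.

#' Mark chart properties for deferred evaluation
#'
#' Wraps named chart properties so that they are stored unevaluated and
#' re-evaluated in the current session's scope every time the chart is
#' resolved (at first render and on every [update_charts()] call). Session
#' variables declared via `session_vars` in [lc_app()] shadow variables of the
#' same name from the calling environment, which is how a click handler that
#' assigns a session variable changes what a linked chart displays.
#'
#' @param ... named properties; each is captured as an expression, not a value.
#' @return An object of class `lc_deferred_props` to pass to a chart
#'   constructor or [add_layer()].
#' @examples
#' counts <- matrix(1:12, nrow = 3)
#' # y is re-read from row `gene` of `counts` on every update:
#' p <- dat(x = 1:4, y = counts[gene, ])
#' @export
dat <- function(...) {
  exprs <- as.list(substitute(list(...)))[-1L]
  if (length(exprs) && (is.null(names(exprs)) || any(!nzchar(names(exprs))))) {
    stop("all arguments to dat() must be named", call. = FALSE)
  }
  env <- parent.frame()
  out <- lapply(exprs, function(e) prop_deferred(e, env))
  class(out) <- "lc_deferred_props"
  out
}

prop_immediate <- function(value) {
  structure(list(value = value), class = c("lc_prop_immediate", "lc_prop"))
}

prop_deferred <- function(expr, env) {
  structure(list(expr = expr, env = env),
            class = c("lc_prop_deferred", "lc_prop"))
}

is_deferred <- function(p) inherits(p, "lc_prop_deferred")

# Evaluate one property in a session scope. Session variables shadow the
# expression's lexical environment: the expression is evaluated in the
# scope's variable environment, temporarily re-parented onto the capture
# environment so data objects from the declaring script stay visible.
prop_eval <- function(p, scope = NULL) {
  if (!inherits(p, "lc_prop")) return(p)
  if (!is_deferred(p)) return(p$value)
  enclos <- p$env %||% baseenv()
  if (is.null(scope)) return(eval(p$expr, envir = new.env(parent = enclos)))
  with_scope_parent(scope, enclos, function() eval(p$expr, envir = scope$vars))
}

# All evaluation inside a session is serial, so re-parenting the session's
# variable environment for the duration of one evaluation is safe.
with_scope_parent <- function(scope, parent, fn) {
  old <- parent.env(scope$vars)
  parent.env(scope$vars) <- parent %||% baseenv()
  on.exit(parent.env(scope$vars) <- old, add = TRUE)
  fn()
}

#' @export
print.lc_prop_deferred <- function(x, ...) {
  cat("<deferred property> ", deparse1(x$expr), "\n", sep = "")
  invisible(x)
}

#' @export
print.lc_prop_immediate <- function(x, ...) {
  cat("<immediate property>\n")
  utils::str(x$value)
  invisible(x)
}

# Normalise a user-supplied property list (constructor `...`) into a named
# map of lc_prop objects. `lc_deferred_props` entries are spliced in.
normalise_props <- function(args) {
  props <- list()
  for (i in seq_along(args)) {
    a <- args[[i]]
    nm <- names(args)[i] %||% ""
    if (inherits(a, "lc_deferred_props")) {
      for (j in seq_along(a)) props[[names(a)[j]]] <- a[[j]]
    } else {
      if (!nzchar(nm)) {
        stop("chart properties must be named (or wrapped in dat())", call. = FALSE)
      }
      props[[nm]] <- if (inherits(a, "lc_prop")) a else prop_immediate(a)
    }
  }
  props
}
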