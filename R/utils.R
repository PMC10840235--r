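# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
is_token <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) && nzchar(x) &&
    grepl("^[A-Za-z0-9_.]+$", x)
}

assert_token <- function(x, what) {
  if (!is_token(x)) {
    stop(sprintf("%s must be a single alphanumeric token, got %s",
                 what, deparse1(x)), call. = FALSE)
  }
  invisible(x)
}

# Deterministic numeric formatting for markup: fixed decimals, no scientific
# notation, "-0.00" normalised to "0.00".
fmt_num <- function(x, digits = 2L) {
  out <- sprintf(paste0("%.", digits, "f"), x)
  out[out == paste0("-0.", strrep("0", digits))] <- paste0("0.", strrep("0", digits))
  out
}

# Tick labels: shortest fixed representation without trailing zeros.
fmt_label <- function(x) {
  out <- formatC(x, format = "fg", digits = 10, flag = "#")
  out <- sub("\\.?0+$", "", out)
  out[x == 0] <- "0"
  out
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

# 128-bit random token from R's RNG so integration tests can seed it.
new_token <- function() {
  paste(sprintf("%08x", sample.int(.Machine$integer.max, 4L)), collapse = "")
}

log_entry <- function(handle_or_scope, msg) {
  env <- handle_or_scope
  env$log <- c(env$log, msg)
  invisible(msg)
}
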