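# Internal helpers shared across modules.

stop_usage <- function(...) {
  stop(structure(class = c("grn_usage_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_validation <- function(...) {
  stop(structure(class = c("grn_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_format <- function(...) {
  stop(structure(class = c("grn_format_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_dimension <- function(...) {
  stop(structure(class = c("grn_dimension_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Detect comma vs tab delimiter from the first line of a text file.
detect_delim <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) return(",")
  if (grepl("\t", first)) "\t" else ","
}

# Column-standardize a matrix; constant columns become all-zero and are
# reported in the "constant" attribute by column id.
standardize_columns <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  const <- sdv == 0 | !is.finite(sdv)
  sdv[const] <- 1
  Z <- sweep(sweep(X, 2L, mu, "-"), 2L, sdv, "/")
  Z[, const] <- 0
  attr(Z, "constant") <- colnames(X)[const] %||% which(const)
  Z
}

# Full-precision numeric formatting used by all text writers so that
# write -> read round-trips are exact.
format_full <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1L))
}

write_lines_lf <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
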