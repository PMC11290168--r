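#' Binary SNP-to-gene annotation mask
#'
#' A J x G binary matrix M with M[j, g] = 1 when level-1 variable j (a SNP)
#' belongs to level-2 group g (a gene). Row order is treated as a proxy for
#' genomic order when grouping unannotated SNPs into intergenic regions.
#'
#' @param values J x G matrix with entries in \{0, 1\}.
#' @param row_ids length-J unique level-1 identifiers.
#' @param col_ids length-G unique level-2 identifiers.
#' @return An object of class \code{annotation_mask}: an integer matrix with
#'   dimnames \code{list(row_ids, col_ids)}.
#' @export
annotation_mask <- function(values, row_ids = rownames(values),
                            col_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(row_ids) || is.null(col_ids))
    stop_usage("annotation mask requires row and column identifiers")
  if (nrow(values) != length(row_ids) || ncol(values) != length(col_ids))
    stop_dimension("mask dimensions do not match identifier lengths")
  storage.mode(values) <- "integer"
  dimnames(values) <- list(as.character(row_ids), as.character(col_ids))
  class(values) <- c("annotation_mask", class(matrix()))
  validate_mask(values)
  values
}

#' @rdname annotation_mask
#' @param x object to validate.
#' @export
validate_mask <- function(x) {
  stopifnot(inherits(x, "annotation_mask"))
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop_validation("mask must have at least one row and one column")
  bad <- which(is.na(x) | !(x %in% c(0L, 1L)), arr.ind = TRUE)
  if (nrow(bad))
    stop_validation("non-binary mask entry at (row ", bad[1L, 1L],
                    ", column ", bad[1L, 2L], ")")
  if (anyDuplicated(rownames(x)))
    stop_validation("duplicate level-1 ids in mask rows")
  if (anyDuplicated(colnames(x)))
    stop_validation("duplicate level-2 ids in mask columns")
  invisible(x)
}

#' Read an annotation mask from delimited text
#'
#' Layout: header row carries the level-2 (gene) ids; the first column of
#' each body row is the level-1 (SNP) id; remaining entries must parse to
#' 0 or 1. Comma and tab delimiters auto-detected.
#'
#' @param path path to a CSV/TSV file.
#' @return An [annotation_mask].
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop_usage("file not found: ", path)
  delim <- detect_delim(path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop_format("mask file needs a header and body: ", path)
  cells <- strsplit(lines, delim, fixed = TRUE)
  header <- cells[[1L]]
  col_ids <- header[-1L]
  width <- length(header)
  body <- cells[-1L]
  raggedness <- which(vapply(body, length, integer(1L)) != width)
  if (length(raggedness))
    stop_format("ragged mask row(s): ", paste(raggedness, collapse = ", "))
  row_ids <- vapply(body, `[[`, character(1L), 1L)
  vals <- matrix(NA_integer_, nrow = length(body), ncol = length(col_ids))
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.integer(body[[i]][-1L]))
    bad <- which(is.na(v) | !(v %in% c(0L, 1L)))
    if (length(bad))
      stop_validation("non-binary mask entry at (row ", i, ", column ",
                      bad[1L], ")")
    vals[i, ] <- v
  }
  annotation_mask(vals, row_ids, col_ids)
}

#' Write an annotation mask as CSV
#' @param mask an [annotation_mask].
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  validate_mask(mask)
  header <- paste(c("id", colnames(mask)), collapse = ",")
  body <- vapply(seq_len(nrow(mask)), function(i) {
    paste(c(rownames(mask)[i], mask[i, ]), collapse = ",")
  }, character(1L))
  write_lines_lf(c(header, body), path)
}
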