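#' Per-variable importance scores at one molecular level
#'
#' A score table pairs molecular variable identifiers with an importance
#' score: a posterior inclusion probability (PIP, in \code{[0, 1]}) or a
#' p-value (in \code{(0, 1]}). Level 1 conventionally holds SNP-level
#' variables and level 2 gene-level (group) variables.
#'
#' @param ids character vector of unique, non-empty variable identifiers.
#' @param scores numeric vector, same length as \code{ids}.
#' @param level integer molecular level, 1 or 2.
#' @param score_kind \code{"pip"} or \code{"pvalue"}.
#' @return An object of class \code{score_table}: a data.frame with columns
#'   \code{id} and \code{score} and attributes \code{level} and
#'   \code{score_kind}.
#' @export
score_table <- function(ids, scores, level, score_kind = c("pip", "pvalue")) {
  score_kind <- match.arg(score_kind)
  ids <- as.character(ids)
  scores <- as.numeric(scores)
  if (length(ids) != length(scores))
    stop_dimension("ids and scores differ in length (", length(ids), " vs ",
                   length(scores), ")")
  level <- as.integer(level)
  if (!level %in% c(1L, 2L)) stop_usage("level must be 1 or 2")
  tab <- data.frame(id = ids, score = scores, stringsAsFactors = FALSE)
  attr(tab, "level") <- level
  attr(tab, "score_kind") <- score_kind
  class(tab) <- c("score_table", "data.frame")
  validate_score_table(tab)
  tab
}

#' @rdname score_table
#' @param x object to validate.
#' @export
validate_score_table <- function(x) {
  stopifnot(inherits(x, "score_table"))
  ids <- x$id
  if (any(!nzchar(ids)))
    stop_validation("score table contains empty id strings")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop_validation("duplicate ids in score table: ",
                    paste(dup, collapse = ", "))
  kind <- attr(x, "score_kind")
  s <- x$score
  if (any(!is.finite(s)))
    stop_validation("non-finite scores at rows: ",
                    paste(which(!is.finite(s)), collapse = ", "))
  bad <- if (kind == "pip") s < 0 | s > 1 else s <= 0 | s > 1
  if (any(bad))
    stop_validation(kind, " score out of range at row(s) ",
                    paste(which(bad), collapse = ", "))
  invisible(x)
}

#' Read a score table from delimited text
#'
#' The file must contain columns named exactly \code{"id"} and
#' \code{"score"}; column order is free and extra columns are ignored.
#' Comma and tab delimiters are auto-detected.
#'
#' @param path path to a CSV/TSV file.
#' @param level molecular level (1 or 2) to label the table with.
#' @param score_kind \code{"pip"} or \code{"pvalue"}.
#' @return A [score_table].
#' @export
read_score_table <- function(path, level, score_kind = c("pip", "pvalue")) {
  score_kind <- match.arg(score_kind)
  if (!file.exists(path)) stop_usage("file not found: ", path)
  delim <- detect_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, colClasses = "character",
                          check.names = FALSE)
  for (col in c("id", "score")) {
    if (!col %in% names(df))
      stop_format("missing required column \"", col, "\" in ", path)
  }
  scores <- suppressWarnings(as.numeric(df$score))
  if (nrow(df) && any(is.na(scores)))
    stop_format("unparseable score at row(s) ",
                paste(which(is.na(scores)), collapse = ", "), " in ", path)
  score_table(df$id, scores, level = level, score_kind = score_kind)
}

#' Write a score table as CSV
#'
#' Emits UTF-8, LF line endings, full numeric precision, columns
#' \code{id,score}.
#'
#' @param table a [score_table].
#' @param path output path.
#' @export
write_score_table <- function(table, path) {
  validate_score_table(table)
  lines <- c("id,score",
             if (nrow(table))
               paste(table$id, format_full(table$score), sep = ","))
  write_lines_lf(lines, path)
}

#' Select significant identifiers by threshold
#'
#' For PIP tables, an entry is significant when its score is greater than
#' or equal to the cutoff (the median probability model rule with the
#' conventional cutoff 0.5 is inclusive). For p-value tables an entry is
#' significant when its score is less than or equal to the cutoff.
#'
#' @param table a [score_table].
#' @param cutoff numeric cutoff; in \code{[0, 1]} for PIPs and
#'   \code{(0, 1]} for p-values.
#' @return Character vector of significant ids in table order.
#' @export
threshold_scores <- function(table, cutoff) {
  validate_score_table(table)
  kind <- attr(table, "score_kind")
  if (kind == "pip") {
    if (cutoff < 0 || cutoff > 1)
      stop_usage("pip cutoff must lie in [0, 1], got ", cutoff)
    table$id[table$score >= cutoff]
  } else {
    if (cutoff <= 0 || cutoff > 1)
      stop_usage("pvalue cutoff must lie in (0, 1], got ", cutoff)
    table$id[table$score <= cutoff]
  }
}
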