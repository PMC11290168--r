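#' Individual-level genotype/phenotype dataset
#'
#' Holds the N x J genotype matrix X (allele dosages in \{0, 1, 2\}, missing
#' allowed before imputation), the length-N phenotype vector y, and optional
#' covariates and family labels.
#'
#' @param X numeric N x J matrix; entries 0/1/2 or NA (real-valued dosages
#'   appear after family-mean imputation).
#' @param y numeric length-N phenotype.
#' @param covariates optional N x C numeric matrix with column names.
#' @param family optional length-N character family labels.
#' @param sample_ids optional length-N sample identifiers.
#' @param variable_ids optional length-J variable identifiers.
#' @return An object of class \code{genotype_dataset}.
#' @export
genotype_dataset <- function(X, y, covariates = NULL, family = NULL,
                             sample_ids = rownames(X),
                             variable_ids = colnames(X)) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X)
  if (length(y) != n)
    stop_dimension("X has ", n, " rows but y has length ", length(y))
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(n))
  if (is.null(variable_ids)) variable_ids <- paste0("snp_", seq_len(ncol(X)))
  if (anyDuplicated(variable_ids))
    stop_validation("duplicate variable ids")
  dimnames(X) <- list(as.character(sample_ids), as.character(variable_ids))
  if (anyNA(y)) stop_validation("phenotype y contains missing values")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    storage.mode(covariates) <- "double"
    if (nrow(covariates) != n)
      stop_dimension("covariates have ", nrow(covariates),
                     " rows, expected ", n)
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("covar_", seq_len(ncol(covariates)))
  }
  if (!is.null(family)) {
    family <- as.character(family)
    if (length(family) != n)
      stop_dimension("family labels have length ", length(family),
                     ", expected ", n)
  }
  obj <- structure(list(X = X, y = y, covariates = covariates,
                        family = family),
                   class = "genotype_dataset")
  obj
}

#' @rdname genotype_dataset
#' @param x a \code{genotype_dataset}.
#' @param ... ignored.
#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: N = %d samples, J = %d variables, %d missing entries\n",
              nrow(x$X), ncol(x$X), sum(is.na(x$X))))
  if (!is.null(x$covariates))
    cat("covariates:", paste(colnames(x$covariates), collapse = ", "), "\n")
  if (!is.null(x$family))
    cat("families:", length(unique(x$family)), "\n")
  invisible(x)
}

n_missing <- function(data) sum(is.na(data$X))

#' Read a genotype dataset from delimited text files
#'
#' \code{x_path} holds the genotype matrix with a header of variable ids and
#' a leading \code{id} column of sample ids; entries must be 0, 1, 2, the
#' missing token \code{"NA"}, or an empty field. \code{y_path} holds one
#' phenotype value per row (optionally with a header line \code{y} or
#' \code{id,y} pairs); covariates and family labels are optional side files
#' aligned by row order.
#'
#' @param x_path genotype CSV/TSV.
#' @param y_path phenotype CSV/TSV.
#' @param covar_path optional covariate CSV/TSV with header.
#' @param family_path optional one-column family label file.
#' @return A [genotype_dataset] (missing entries preserved as \code{NA};
#'   imputation is an explicit preprocessing step).
#' @export
read_genotype_dataset <- function(x_path, y_path, covar_path = NULL,
                                  family_path = NULL) {
  for (p in c(x_path, y_path, covar_path, family_path))
    if (!file.exists(p)) stop_usage("file not found: ", p)
  delim <- detect_delim(x_path)
  xdf <- utils::read.table(x_path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", na.strings = NULL)
  if (!"id" %in% names(xdf))
    stop_format("genotype file must have a leading \"id\" column: ", x_path)
  sample_ids <- xdf$id
  xdf$id <- NULL
  X <- matrix(NA_real_, nrow = nrow(xdf), ncol = ncol(xdf),
              dimnames = list(sample_ids, names(xdf)))
  for (j in seq_len(ncol(xdf))) {
    raw <- xdf[[j]]
    miss <- raw %in% c("NA", "")
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(!miss & (is.na(v) | !(v %in% c(0, 1, 2))))
    if (length(bad))
      stop_format("unparseable genotype at (row ", bad[1L], ", column ", j,
                  ") in ", x_path)
    v[miss] <- NA_real_
    X[, j] <- v
  }
  ydf <- utils::read.table(y_path, header = FALSE, sep = detect_delim(y_path),
                           stringsAsFactors = FALSE)
  ycol <- ydf[[ncol(ydf)]]
  if (is.character(ycol) && suppressWarnings(is.na(as.numeric(ycol[1L]))))
    ycol <- ycol[-1L]  # header line
  y <- as.numeric(ycol)
  if (length(y) != nrow(X))
    stop_dimension("X has ", nrow(X), " rows but y has ", length(y),
                   " values")
  covariates <- NULL
  if (!is.null(covar_path)) {
    covariates <- as.matrix(utils::read.table(covar_path, header = TRUE,
                                              sep = detect_delim(covar_path)))
  }
  family <- NULL
  if (!is.null(family_path)) {
    family <- readLines(family_path, warn = FALSE)
    family <- family[nzchar(family)]
    if (identical(family[1L], "family")) family <- family[-1L]
  }
  genotype_dataset(X, y, covariates = covariates, family = family)
}

#' Write a genotype dataset to CSV files
#'
#' @param data a [genotype_dataset].
#' @param x_path,y_path output paths for X and y.
#' @param covar_path,family_path optional output paths.
#' @export
write_genotype_dataset <- function(data, x_path, y_path, covar_path = NULL,
                                   family_path = NULL) {
  X <- data$X
  header <- paste(c("id", colnames(X)), collapse = ",")
  body <- vapply(seq_len(nrow(X)), function(i) {
    row <- X[i, ]
    cells <- ifelse(is.na(row), "NA",
                    ifelse(row == round(row), sprintf("%d", as.integer(row)),
                           format_full(row)))
    paste(c(rownames(X)[i], cells), collapse = ",")
  }, character(1L))
  write_lines_lf(c(header, body), x_path)
  write_lines_lf(c("y", format_full(data$y)), y_path)
  if (!is.null(covar_path) && !is.null(data$covariates)) {
    cv <- data$covariates
    write_lines_lf(c(paste(colnames(cv), collapse = ","),
                     apply(cv, 1L, function(r) paste(format_full(r), collapse = ","))),
                   covar_path)
  }
  if (!is.null(family_path) && !is.null(data$family))
    write_lines_lf(c("family", data$family), family_path)
  invisible(NULL)
}
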