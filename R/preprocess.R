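#' @name preprocess
#' @title Genotype preprocessing operators
#' @description
#' The dataset-preparation steps applied to individual-level genotype data
#' before variable selection: family-mean imputation of missing genotypes,
#' minor-allele-frequency filtering, covariate residualization of the
#' phenotype, intergenic grouping of unannotated SNPs, and construction of
#' the gene-level design matrix. Each operator is deterministic; operators
#' that change the variable set return a \code{preprocess_report} in the
#' \code{"report"} attribute.
NULL

new_report <- function(n_imputed = 0L, snps_removed_maf = character(),
                       snps_removed_monomorphic = character(),
                       covariates_used = character(),
                       intergenic_groups_created = character(),
                       fallback_global_mean = character()) {
  structure(list(n_imputed = as.integer(n_imputed),
                 snps_removed_maf = snps_removed_maf,
                 snps_removed_monomorphic = snps_removed_monomorphic,
                 covariates_used = covariates_used,
                 intergenic_groups_created = intergenic_groups_created,
                 fallback_global_mean = fallback_global_mean),
            class = "preprocess_report")
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat("preprocess_report:\n")
  cat("  imputed entries:     ", x$n_imputed, "\n")
  cat("  removed (MAF):       ", length(x$snps_removed_maf), "\n")
  cat("  removed (monomorph): ", length(x$snps_removed_monomorphic), "\n")
  cat("  covariates used:     ", paste(x$covariates_used, collapse = ", "), "\n")
  cat("  intergenic groups:   ", length(x$intergenic_groups_created), "\n")
  invisible(x)
}

#' Impute missing genotypes by the within-family mean
#'
#' Each missing entry of X is replaced by the mean observed dosage of that
#' SNP within the sample's family. Imputed values are real-valued means and
#' are not re-rounded to \{0, 1, 2\}, preserving dosage information. When a
#' SNP is unobserved in an entire family, the across-family mean of that SNP
#' is used and the fallback is flagged in the report. Pass
#' \code{global = TRUE} to impute with the across-family mean when no family
#' labels exist.
#'
#' @param data a [genotype_dataset].
#' @param global use the global per-SNP mean instead of family means.
#' @return The imputed [genotype_dataset] with a \code{preprocess_report}
#'   in \code{attr(, "report")}.
#' @export
impute_family_mean <- function(data, global = FALSE) {
  X <- data$X
  miss <- is.na(X)
  if (!any(miss)) {
    attr(data, "report") <- new_report()
    return(data)
  }
  all_missing <- colSums(!miss) == 0L
  if (any(all_missing))
    stop_validation("SNP(s) missing in every sample: ",
                    paste(colnames(X)[all_missing], collapse = ", "))
  if (is.null(data$family) && !global)
    stop_usage("family labels are absent; call with global = TRUE to ",
               "impute with the across-family mean")
  global_means <- colMeans(X, na.rm = TRUE)
  fallback <- character()
  if (global || is.null(data$family)) {
    for (j in which(colSums(miss) > 0L))
      X[miss[, j], j] <- global_means[j]
  } else {
    fam <- data$family
    for (f in unique(fam)) {
      rows <- which(fam == f)
      sub_miss <- miss[rows, , drop = FALSE]
      for (j in which(colSums(sub_miss) > 0L)) {
        obs <- X[rows, j][!sub_miss[, j]]
        if (length(obs)) {
          X[rows[sub_miss[, j]], j] <- mean(obs)
        } else {
          X[rows[sub_miss[, j]], j] <- global_means[j]
          fallback <- union(fallback,
                            paste0(colnames(X)[j], "@", f))
        }
      }
    }
  }
  out <- genotype_dataset(X, data$y, covariates = data$covariates,
                          family = data$family)
  attr(out, "report") <- new_report(n_imputed = sum(miss),
                                    fallback_global_mean = fallback)
  out
}

#' Filter SNPs by minor allele frequency
#'
#' Retains SNP j iff \code{min(f_j, 1 - f_j) > min_maf} with
#' \code{f_j = mean(X[, j]) / 2}; the inequality is strict ("above" the
#' threshold), so a SNP sitting exactly at the cutoff is removed.
#' Monomorphic SNPs (f in \{0, 1\}) are always removed. Column order of
#' survivors is preserved.
#'
#' @param data an imputed [genotype_dataset] (no missing entries).
#' @param min_maf minimum minor allele frequency, in \code{[0, 0.5)};
#'   default 0.05.
#' @return Filtered [genotype_dataset] with report attribute.
#' @export
filter_maf <- function(data, min_maf = 0.05) {
  if (min_maf < 0 || min_maf >= 0.5)
    stop_usage("min_maf must lie in [0, 0.5)")
  X <- data$X
  if (anyNA(X)) stop_usage("impute missing genotypes before MAF filtering")
  f <- colMeans(X) / 2
  maf <- pmin(f, 1 - f)
  mono <- f == 0 | f == 1
  low <- !mono & maf <= min_maf
  keep <- !(mono | low)
  if (!any(keep)) stop_validation("MAF filter removed every SNP (empty design)")
  out <- genotype_dataset(X[, keep, drop = FALSE], data$y,
                          covariates = data$covariates, family = data$family)
  attr(out, "report") <- new_report(
    snps_removed_maf = colnames(X)[low],
    snps_removed_monomorphic = colnames(X)[mono])
  out
}

#' Residualize the phenotype on covariates
#'
#' Replaces y with the residuals of an ordinary least-squares fit of y on
#' an intercept plus the dataset's covariates; X is unchanged. Residuals
#' sum to zero and are orthogonal to each covariate column.
#'
#' @param data a [genotype_dataset] with covariates.
#' @return The dataset with residualized y; \code{attr(, "report")} lists
#'   the covariates used.
#' @export
residualize_phenotype <- function(data) {
  if (is.null(data$covariates))
    stop_usage("no covariates present to residualize on")
  # constant covariates lie in the intercept's span; absorb them
  cv <- data$covariates
  keep <- apply(cv, 2L, stats::sd) > 0
  C <- cbind(`(Intercept)` = 1, cv[, keep, drop = FALSE])
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) {
    drop_cols <- colnames(C)[qrC$pivot[(qrC$rank + 1L):ncol(C)]]
    stop_validation("rank-deficient covariates; collinear column(s): ",
                    paste(drop_cols, collapse = ", "))
  }
  res <- qr.resid(qrC, data$y)
  out <- genotype_dataset(data$X, res, covariates = data$covariates,
                          family = data$family)
  attr(out, "report") <- new_report(covariates_used = colnames(data$covariates))
  out
}

#' Group unannotated SNPs into intergenic regions
#'
#' Every level-1 variable whose mask row is all zeros is assigned to a
#' synthetic level-2 group named \code{intergenic_<k>}; one group is created
#' per maximal run of consecutive unannotated rows, with mask row order
#' standing in for genomic order. Annotated rows are unchanged and the
#' result has no all-zero rows (so every SNP has a group).
#'
#' @param mask an [annotation_mask].
#' @return The augmented [annotation_mask]; created group ids are in
#'   \code{attr(, "report")$intergenic_groups_created}.
#' @export
assign_intergenic <- function(mask) {
  validate_mask(mask)
  zero_row <- rowSums(mask) == 0L
  if (!any(zero_row)) {
    attr(mask, "report") <- new_report()
    return(mask)
  }
  runs <- rle(as.vector(zero_row))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  new_cols <- list()
  k <- 0L
  for (r in which(runs$values)) {
    k <- k + 1L
    col <- integer(nrow(mask))
    col[starts[r]:ends[r]] <- 1L
    new_cols[[paste0("intergenic_", k)]] <- col
  }
  vals <- cbind(unclass(mask), do.call(cbind, new_cols))
  out <- annotation_mask(vals, rownames(mask),
                         c(colnames(mask), names(new_cols)))
  attr(out, "report") <- new_report(
    intergenic_groups_created = names(new_cols))
  out
}

#' Build the gene-level design matrix
#'
#' The level-2 (gene) design aggregates the column-standardized genotypes of
#' each group's member SNPs and re-standardizes the aggregate:
#' \code{H[, g] = standardize( sum_j M[j, g] * X_std[, j] )}. Groups whose
#' aggregate is constant (e.g. empty mask columns) yield an all-zero column
#' and are flagged in the \code{"constant"} attribute.
#'
#' @param data a [genotype_dataset]; its variable ids must equal the mask
#'   row ids.
#' @param mask an [annotation_mask].
#' @return N x G numeric matrix with column names = mask column ids.
#' @export
build_group_features <- function(data, mask) {
  ids_x <- colnames(data$X); ids_m <- rownames(mask)
  if (!identical(ids_x, ids_m)) {
    first_bad <- c(setdiff(ids_x, ids_m), setdiff(ids_m, ids_x),
                   ids_x[ids_x != ids_m])[1L]
    stop_validation("variable ids do not match mask rows; first mismatch: ",
                    first_bad)
  }
  Xs <- standardize_columns(data$X)
  H_raw <- Xs %*% unclass(mask)
  H <- standardize_columns(H_raw)
  colnames(H) <- colnames(mask)
  H
}
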