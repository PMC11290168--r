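#' In silico knockout specification
#'
#' Names the nodes to delete from a fitted network before refitting. Level
#' is resolved against the current dataset/mask: an id among the variable
#' ids is a level-1 (SNP) deletion, an id among the mask columns a level-2
#' (gene) deletion.
#'
#' @param ids character vector of node ids to delete (no duplicates).
#' @param note free-text annotation stored with the record.
#' @return An object of class \code{perturbation}.
#' @export
perturbation <- function(ids, note = "") {
  ids <- as.character(ids)
  if (!length(ids)) stop_usage("perturbation needs at least one id")
  if (anyDuplicated(ids))
    stop_validation("duplicate ids in perturbation: ",
                    paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(list(deleted = ids, note = note,
                 timestamp = format(Sys.time(), tz = "UTC",
                                    "%Y-%m-%dT%H:%M:%SZ")),
            class = "perturbation")
}

#' Propagate a knockout into the genotype data and mask
#'
#' Deleting a level-1 node removes its column from X and its row from the
#' mask. Deleting a level-2 node removes its mask column; any SNP left with
#' an all-zero annotation row is re-assigned to a synthetic intergenic group
#' via [assign_intergenic] rather than deleted, preserving the level-1
#' design (the cascade is recorded). Phenotype, samples and covariates are
#' untouched.
#'
#' @param data a [genotype_dataset].
#' @param mask an [annotation_mask] aligned with \code{data}.
#' @param p a [perturbation].
#' @return List with \code{data}, \code{mask}, and \code{cascade} (ids of
#'   intergenic groups created by gene deletion).
#' @export
apply_perturbation <- function(data, mask, p) {
  stopifnot(inherits(p, "perturbation"))
  snp_ids <- colnames(data$X)
  gene_ids <- colnames(mask)
  lvl1 <- p$deleted[p$deleted %in% snp_ids]
  lvl2 <- p$deleted[p$deleted %in% gene_ids]
  unknown <- setdiff(p$deleted, c(lvl1, lvl2))
  if (length(unknown))
    stop_validation("perturbation id(s) not present: ",
                    paste(unknown, collapse = ", "))
  keep_snps <- setdiff(snp_ids, lvl1)
  if (!length(keep_snps))
    stop_validation("perturbation would delete every level-1 variable")
  keep_genes <- setdiff(gene_ids, lvl2)
  if (!length(keep_genes))
    stop_validation("perturbation would delete every level-2 group")
  X2 <- data$X[, keep_snps, drop = FALSE]
  M2 <- annotation_mask(unclass(mask)[keep_snps, keep_genes, drop = FALSE],
                        keep_snps, keep_genes)
  cascade <- character()
  if (any(rowSums(M2) == 0L)) {
    M2 <- assign_intergenic(M2)
    cascade <- attr(M2, "report")$intergenic_groups_created
  }
  data2 <- genotype_dataset(X2, data$y, covariates = data$covariates,
                            family = data$family)
  list(data = data2, mask = M2, cascade = cascade,
       deleted_level1 = lvl1, deleted_level2 = lvl2)
}

#' Knockout, refit, rebuild, and diff
#'
#' The full in silico perturbation loop: fit the backend on the original
#' data, build the "before" network, apply the knockout to (X, M), refit
#' the same backend with the same configuration, rebuild the network with
#' the same thresholds and connectivity, and diff the two networks. Deleted
#' ids can never reappear in the after network (asserted on every run); a
#' non-converged refit is recorded in the result, not hidden.
#'
#' @param data a [genotype_dataset].
#' @param mask an [annotation_mask].
#' @param p a [perturbation].
#' @param backend backend name (see [register_backend]); default
#'   \code{"ssvi"}.
#' @param config a [backend_config].
#' @param grn_params list of [build_grn] arguments (cutoffs, modes, layout).
#' @param before optional precomputed "before" state, a list with elements
#'   \code{result} and \code{grn}, to avoid refitting the unperturbed data.
#' @return An object of class \code{perturbation_record}: the perturbation,
#'   both GRNs, the [diff_grn] result, cascade info, backend/config echo.
#' @export
perturb_and_rerun <- function(data, mask, p, backend = "ssvi",
                              config = backend_config(),
                              grn_params = list(), before = NULL) {
  fn <- get_backend(backend)
  build_args <- function(result, mask, level_data)
    do.call(build_grn, c(list(result = result, mask = mask,
                              level_data = level_data), grn_params))
  level_data_for <- function(data, mask) {
    need_sparse <- any(vapply(grn_params[c("l1_mode", "l2_mode")],
                              function(m) {
                                if (is.null(m)) FALSE
                                else if (inherits(m, "connectivity_mode"))
                                  m$mode == "sparse"
                                else identical(m, "sparse")
                              }, logical(1L)))
    if (!need_sparse) return(list())
    list(l1 = standardize_columns(data$X),
         l2 = build_group_features(data, mask))
  }
  if (is.null(before)) {
    res_before <- fn(data, mask, config)
    grn_before <- build_args(res_before, mask, level_data_for(data, mask))
  } else {
    res_before <- before$result
    grn_before <- before$grn
  }
  applied <- apply_perturbation(data, mask, p)
  res_after <- fn(applied$data, applied$mask, config)
  grn_after <- build_args(res_after, applied$mask,
                          level_data_for(applied$data, applied$mask))
  leak <- intersect(p$deleted, grn_after$nodes$id)
  if (length(leak))
    stop_validation("internal error: deleted node(s) present after rerun: ",
                    paste(leak, collapse = ", "))
  structure(list(perturbation = p,
                 before = grn_before, after = grn_after,
                 diff = diff_grn(grn_before, grn_after),
                 cascade = applied$cascade,
                 result_before = res_before, result_after = res_after,
                 backend = backend, config = config,
                 grn_params = grn_params),
            class = "perturbation_record")
}

#' @export
print.perturbation_record <- function(x, ...) {
  cat("perturbation_record: deleted",
      paste(x$perturbation$deleted, collapse = ", "), "\n")
  print(x$diff)
  invisible(x)
}

#' Persist a perturbation record
#'
#' Writes the record as JSON next to the two GRN files; input files are
#' fingerprinted (MD5) so that [replay] can detect stale records.
#'
#' @param record a \code{perturbation_record}.
#' @param dir output directory (created if needed).
#' @param inputs named list of input file paths to fingerprint
#'   (\code{x}, \code{y}, \code{mask}, optionally \code{covariates},
#'   \code{family}).
#' @return The record path, invisibly.
#' @export
write_perturbation_record <- function(record, dir, inputs) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  before_path <- file.path(dir, "grn_before.json")
  after_path <- file.path(dir, "grn_after.json")
  write_grn(record$before, before_path)
  write_grn(record$after, after_path)
  hashes <- lapply(inputs, function(p) unname(tools::md5sum(p)))
  obj <- list(
    schema_version = 1L,
    perturbation = list(deleted = as.list(record$perturbation$deleted),
                        note = record$perturbation$note,
                        timestamp = record$perturbation$timestamp),
    backend = record$backend,
    backend_version = as.character(utils::packageVersion("grnperturb")),
    config = unclass(record$config),
    grn_params = serialize_grn_params(record$grn_params),
    cascade = as.list(record$cascade),
    inputs = inputs,
    input_md5 = hashes,
    grn_before = "grn_before.json",
    grn_after = "grn_after.json")
  path <- file.path(dir, "perturbation_record.json")
  write_lines_lf(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                  null = "null", pretty = TRUE), path)
  invisible(path)
}

serialize_grn_params <- function(gp) {
  lapply(gp, function(v) if (inherits(v, "connectivity_mode")) unclass(v) else v)
}

deserialize_grn_params <- function(gp) {
  for (nm in intersect(c("l1_mode", "l2_mode"), names(gp))) {
    v <- gp[[nm]]
    if (is.list(v))
      gp[[nm]] <- connectivity_mode(v$mode, v$edge_threshold)
  }
  gp
}

#' Replay a stored perturbation
#'
#' Re-reads the recorded inputs, verifies their fingerprints, re-executes
#' the recorded perturbation with the recorded backend configuration, and
#' checks that the regenerated after-network is identical to the stored
#' one. Inputs whose MD5 changed raise a stale-record error; a record
#' written by a different package version replays with a warning.
#'
#' @param record_path path to \code{perturbation_record.json}.
#' @return The regenerated \code{perturbation_record}.
#' @export
replay <- function(record_path) {
  if (!file.exists(record_path)) stop_usage("file not found: ", record_path)
  obj <- jsonlite::fromJSON(record_path, simplifyVector = FALSE)
  dir <- dirname(record_path)
  for (nm in names(obj$inputs)) {
    p <- obj$inputs[[nm]]
    if (!file.exists(p)) stop_usage("recorded input missing: ", p)
    if (!identical(unname(tools::md5sum(p)), obj$input_md5[[nm]]))
      stop_validation("stale record: input \"", nm,
                      "\" changed on disk (", p, ")")
  }
  ver <- as.character(utils::packageVersion("grnperturb"))
  if (!identical(obj$backend_version, ver))
    warning("record written by backend version ", obj$backend_version,
            ", replaying with ", ver, call. = FALSE)
  data <- read_genotype_dataset(obj$inputs$x, obj$inputs$y,
                                covar_path = obj$inputs$covariates,
                                family_path = obj$inputs$family)
  mask <- read_mask(obj$inputs$mask)
  cfg <- backend_config(pi = obj$config$pi, h2 = obj$config$h2,
                        sigma_beta2 = obj$config$sigma_beta2,
                        tol = obj$config$tol,
                        max_iterations = obj$config$max_iterations,
                        seed = obj$config$seed)
  p <- perturbation(unlist(obj$perturbation$deleted),
                    note = obj$perturbation$note %||% "")
  rec <- perturb_and_rerun(data, mask, p, backend = obj$backend,
                           config = cfg,
                           grn_params = deserialize_grn_params(obj$grn_params))
  stored_after <- read_grn(file.path(dir, obj$grn_after))
  if (!isTRUE(all.equal(rec$after, stored_after)))
    stop_validation("replay mismatch: regenerated after-GRN differs from ",
                    "the stored one")
  rec
}
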