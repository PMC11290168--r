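# Composite pipeline: prep -> select -> build (-> perturb), with a
# self-describing output directory (effective config, input fingerprints,
# per-stage timings, JSON-lines log).

#' Pipeline run configuration
#'
#' Collects every pipeline parameter. Values may come from a flat
#' \code{key: value} config file and/or explicit arguments; explicit
#' arguments win. The effective configuration is serialized into every
#' output directory.
#'
#' @param x,y,mask,covariates,family input file paths (x/y/mask required
#'   unless \code{simulate = TRUE}).
#' @param simulate generate inputs with [simulate_dataset] instead of
#'   reading files.
#' @param method backend name, \code{"ssvi"} or \code{"minsnp"}.
#' @param l1_threshold,l2_threshold significance cutoffs (default 0.5,
#'   the median probability model for PIPs).
#' @param l1_connectivity,l2_connectivity within-level modes
#'   (default none / complete).
#' @param edge_threshold tau for sparse modes (default 0.1).
#' @param layout layout hint (default \code{"layout_with_kk"}).
#' @param pi,h2,tol,max_iterations backend hyperparameters.
#' @param min_maf MAF filter threshold (default 0.05).
#' @param delete optional character vector of node ids to knock out after
#'   the first build.
#' @param seed integer seed.
#' @param out output directory.
#' @param config_file optional flat key: value file supplying defaults.
#' @return An object of class \code{run_config} (a named list).
#' @export
run_config <- function(x = NULL, y = NULL, mask = NULL, covariates = NULL,
                       family = NULL, simulate = FALSE, method = "ssvi",
                       l1_threshold = 0.5, l2_threshold = 0.5,
                       l1_connectivity = "none",
                       l2_connectivity = "complete",
                       edge_threshold = 0.1, layout = "layout_with_kk",
                       pi = NULL, h2 = 0.5, tol = 1e-4,
                       max_iterations = 500L, min_maf = 0.05,
                       delete = NULL, seed = 1L, out = "grn_run",
                       config_file = NULL) {
  explicit <- as.list(match.call())[-1L]
  explicit$config_file <- NULL
  cfg <- list(x = x, y = y, mask = mask, covariates = covariates,
              family = family, simulate = simulate, method = method,
              l1_threshold = l1_threshold, l2_threshold = l2_threshold,
              l1_connectivity = l1_connectivity,
              l2_connectivity = l2_connectivity,
              edge_threshold = edge_threshold, layout = layout,
              pi = pi, h2 = h2, tol = tol,
              max_iterations = as.integer(max_iterations),
              min_maf = min_maf, delete = delete, seed = as.integer(seed),
              out = out)
  if (!is.null(config_file)) {
    file_vals <- read_flat_config(config_file)
    for (nm in names(file_vals)) {
      if (!nm %in% names(cfg))
        stop_usage("unknown config key \"", nm, "\" in ", config_file)
      # flags/arguments override file values
      if (!nm %in% names(explicit)) cfg[[nm]] <- file_vals[[nm]]
    }
  }
  structure(cfg, class = "run_config")
}

# Flat "key: value" config files; types inferred (logical, numeric,
# comma-separated vectors, strings).
read_flat_config <- function(path) {
  if (!file.exists(path)) stop_usage("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl(":", ln, fixed = TRUE))
      stop_format("config line is not key: value — \"", ln, "\"")
    key <- trimws(sub(":.*$", "", ln))
    val <- trimws(sub("^[^:]*:", "", ln))
    out[[key]] <- parse_config_value(val)
  }
  out
}

parse_config_value <- function(val) {
  if (val %in% c("true", "TRUE", "yes")) return(TRUE)
  if (val %in% c("false", "FALSE", "no")) return(FALSE)
  if (val %in% c("null", "NULL", "")) return(NULL)
  if (grepl(",", val, fixed = TRUE))
    return(trimws(strsplit(val, ",", fixed = TRUE)[[1L]]))
  num <- suppressWarnings(as.numeric(val))
  if (!is.na(num)) return(num)
  val
}

log_line <- function(con, stage, message, ...) {
  entry <- list(time = format(Sys.time(), tz = "UTC", "%Y-%m-%dT%H:%M:%OS3Z"),
                stage = stage, message = message, ...)
  writeLines(jsonlite::toJSON(entry, auto_unbox = TRUE), con)
  message(sprintf("[%s] %s", stage, message))
}

#' Run the end-to-end pipeline
#'
#' Executes preprocessing (imputation if needed, MAF filter, covariate
#' residualization if covariates exist, intergenic grouping), variable
#' selection, GRN construction, and optionally a knockout-and-rerun step.
#' The output directory receives one score CSV per level, the GRN as JSON
#' and GraphML, the preprocessing report, the effective configuration with
#' input fingerprints, a JSON-lines run log with per-stage timings, and —
#' if a perturbation was requested — the after-GRN, the diff and the
#' perturbation record. On failure a \code{FAILED} marker file is left in
#' the directory and the error re-raised.
#'
#' @param config a [run_config].
#' @return The output directory path, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(out, "run.log.jsonl"), open = "wt")
  on.exit(close(logf), add = TRUE)
  ok <- FALSE
  on.exit({
    if (!ok) writeLines("pipeline failed; see run.log.jsonl",
                        file.path(out, "FAILED"))
  }, add = TRUE)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    log_line(logf, name, sprintf("done in %.2fs", timings[[name]]))
    res
  }

  # --- inputs ---
  input_files <- list()
  if (isTRUE(config$simulate)) {
    sim <- stage("simulate",
                 simulate_dataset(seed = config$seed, h2 = config$h2))
    data <- sim$data; mask <- sim$mask
    truth_path <- file.path(out, "truth.json")
    write_lines_lf(jsonlite::toJSON(unclass(sim$truth), auto_unbox = TRUE,
                                    digits = NA), truth_path)
  } else {
    if (is.null(config$x) || is.null(config$y) || is.null(config$mask))
      stop_usage("x, y and mask paths are required unless simulate: true")
    for (nm in c("x", "y", "mask", "covariates", "family")) {
      p <- config[[nm]]
      if (!is.null(p)) {
        if (!file.exists(p)) stop_usage("input not found: ", p)
        input_files[[nm]] <- p
      }
    }
    data <- stage("read", read_genotype_dataset(config$x, config$y,
                                                covar_path = config$covariates,
                                                family_path = config$family))
    mask <- read_mask(config$mask)
  }

  # --- effective config + fingerprints (written before heavy work) ---
  cfg_obj <- unclass(config)
  cfg_obj$input_md5 <- lapply(input_files, function(p)
    unname(tools::md5sum(p)))
  cfg_obj$package_version <- as.character(utils::packageVersion("grnperturb"))
  write_lines_lf(jsonlite::toJSON(cfg_obj, auto_unbox = TRUE, digits = NA,
                                  null = "null", pretty = TRUE),
                 file.path(out, "run_config.json"))

  # --- prep ---
  reports <- list()
  data <- stage("prep", {
    if (anyNA(data$X)) {
      data <- impute_family_mean(data, global = is.null(data$family))
      reports$impute <- attr(data, "report")
    }
    data <- filter_maf(data, min_maf = config$min_maf)
    reports$maf <- attr(data, "report")
    if (!is.null(data$covariates)) {
      data <- residualize_phenotype(data)
      reports$residualize <- attr(data, "report")
    }
    data
  })
  mask <- annotation_mask(
    unclass(mask)[colnames(data$X), , drop = FALSE],
    colnames(data$X), colnames(mask))
  empty_genes <- colSums(mask) == 0L
  if (any(empty_genes))
    mask <- annotation_mask(unclass(mask)[, !empty_genes, drop = FALSE],
                            rownames(mask), colnames(mask)[!empty_genes])
  mask <- assign_intergenic(mask)
  reports$intergenic <- attr(mask, "report")
  write_lines_lf(jsonlite::toJSON(lapply(reports, unclass),
                                  auto_unbox = TRUE, pretty = TRUE),
                 file.path(out, "preprocess_report.json"))

  # --- select ---
  bcfg <- backend_config(pi = config$pi, h2 = config$h2, tol = config$tol,
                         max_iterations = config$max_iterations,
                         seed = config$seed)
  fn <- get_backend(config$method)
  result <- stage("select", fn(data, mask, bcfg))
  write_score_table(result$level1, file.path(out, "scores_level1.csv"))
  write_score_table(result$level2, file.path(out, "scores_level2.csv"))

  # --- build ---
  l1_mode <- as_connectivity(config$l1_connectivity,
                             if (identical(config$l1_connectivity, "sparse"))
                               config$edge_threshold)
  l2_mode <- as_connectivity(config$l2_connectivity,
                             if (identical(config$l2_connectivity, "sparse"))
                               config$edge_threshold)
  level_data <- list()
  if (l1_mode$mode == "sparse") level_data$l1 <- standardize_columns(data$X)
  if (l2_mode$mode == "sparse") level_data$l2 <- build_group_features(data, mask)
  g <- stage("build",
             build_grn(result, mask,
                       l1_cutoff = config$l1_threshold,
                       l2_cutoff = config$l2_threshold,
                       l1_mode = l1_mode, l2_mode = l2_mode,
                       level_data = level_data, layout = config$layout))
  write_grn(g, file.path(out, "grn.json"), "json")
  write_grn(g, file.path(out, "grn.graphml"), "graphml")

  # --- perturb (optional) ---
  if (!is.null(config$delete) && length(config$delete)) {
    p <- perturbation(config$delete)
    rec <- stage("perturb",
                 perturb_and_rerun(data, mask, p, backend = config$method,
                                   config = bcfg,
                                   grn_params = list(
                                     l1_cutoff = config$l1_threshold,
                                     l2_cutoff = config$l2_threshold,
                                     l1_mode = l1_mode, l2_mode = l2_mode,
                                     layout = config$layout),
                                   before = list(result = result, grn = g)))
    pdir <- file.path(out, "perturbation")
    if (length(input_files)) {
      write_perturbation_record(rec, pdir, inputs = input_files)
    } else {
      dir.create(pdir, showWarnings = FALSE, recursive = TRUE)
      write_grn(rec$before, file.path(pdir, "grn_before.json"))
      write_grn(rec$after, file.path(pdir, "grn_after.json"))
    }
    diff_obj <- list(
      nodes_added = as.list(rec$diff$nodes_added),
      nodes_removed = as.list(rec$diff$nodes_removed),
      nodes_persisting = rec$diff$nodes_persisting,
      edges_added = rec$diff$edges_added,
      edges_removed = rec$diff$edges_removed,
      cascade = as.list(rec$cascade))
    write_lines_lf(jsonlite::toJSON(diff_obj, auto_unbox = TRUE,
                                    digits = NA, pretty = TRUE),
                   file.path(pdir, "diff.json"))
  }

  write_lines_lf(jsonlite::toJSON(timings, auto_unbox = TRUE, digits = NA),
                 file.path(out, "timings.json"))
  ok <- TRUE
  invisible(out)
}
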