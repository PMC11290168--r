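#' Within-level connectivity mode
#'
#' How nodes on one molecular level are connected among themselves:
#' \code{"none"} (no within-level edges), \code{"complete"} (all pairs), or
#' \code{"sparse"} (pairs whose absolute Pearson correlation across the
#' level's data columns reaches \code{edge_threshold}).
#'
#' @param mode one of \code{"none"}, \code{"sparse"}, \code{"complete"}.
#' @param edge_threshold tau in \code{[0, 1]}; required iff
#'   \code{mode = "sparse"}.
#' @return An object of class \code{connectivity_mode}.
#' @export
connectivity_mode <- function(mode = c("none", "sparse", "complete"),
                              edge_threshold = NULL) {
  mode <- match.arg(mode)
  if (mode == "sparse") {
    if (is.null(edge_threshold))
      stop_usage("sparse connectivity requires an edge_threshold")
    if (edge_threshold < 0 || edge_threshold > 1)
      stop_usage("edge_threshold must lie in [0, 1]")
  } else if (!is.null(edge_threshold)) {
    stop_usage("edge_threshold is only meaningful for sparse connectivity")
  }
  structure(list(mode = mode, edge_threshold = edge_threshold),
            class = "connectivity_mode")
}

as_connectivity <- function(x, edge_threshold = NULL) {
  if (inherits(x, "connectivity_mode")) x
  else connectivity_mode(x, edge_threshold)
}

#' Undirected within-level edges by correlation thresholding
#'
#' Connects nodes a, b at the same level iff the absolute Pearson
#' correlation of their data columns is at least \code{tau}; the edge weight
#' is \code{|r|}. Constant columns have all their correlations treated as 0
#' (no edges) and are returned in the \code{"constant"} attribute.
#'
#' @param level_data N x K numeric matrix whose columns correspond to
#'   \code{node_ids} (matched by column name).
#' @param node_ids node identifiers to consider.
#' @param tau correlation threshold in \code{[0, 1]}.
#' @return data.frame(source, target, weight) with source < target; zero
#'   rows when no pair qualifies.
#' @export
sparse_within_edges <- function(level_data, node_ids, tau) {
  if (nrow(level_data) < 3L)
    stop_usage("need n >= 3 samples to estimate correlations")
  missing_cols <- setdiff(node_ids, colnames(level_data))
  if (length(missing_cols))
    stop_usage("level_data lacks column(s): ",
               paste(missing_cols, collapse = ", "))
  D <- level_data[, node_ids, drop = FALSE]
  const <- apply(D, 2L, stats::sd) == 0
  out <- data.frame(source = character(), target = character(),
                    weight = numeric(), stringsAsFactors = FALSE)
  k <- length(node_ids)
  if (k >= 2L) {
    R <- suppressWarnings(stats::cor(D))
    R[!is.finite(R)] <- 0
    # constant columns carry no correlation signal: never edged
    eligible <- tcrossprod(!const)
    idx <- which(upper.tri(R) & eligible & abs(R) >= tau, arr.ind = TRUE)
    if (nrow(idx)) {
      out <- data.frame(source = node_ids[idx[, 1L]],
                        target = node_ids[idx[, 2L]],
                        weight = abs(R[idx]), stringsAsFactors = FALSE)
    }
  }
  attr(out, "constant") <- node_ids[const]
  out
}

within_edges_for_mode <- function(mode, node_ids, level_data, level_label) {
  if (length(node_ids) < 2L || mode$mode == "none") {
    return(data.frame(source = character(), target = character(),
                      weight = numeric(), stringsAsFactors = FALSE))
  }
  if (mode$mode == "complete") {
    pairs <- utils::combn(node_ids, 2L)
    return(data.frame(source = pairs[1L, ], target = pairs[2L, ],
                      weight = NA_real_, stringsAsFactors = FALSE))
  }
  if (is.null(level_data))
    stop_usage("sparse connectivity at ", level_label,
               " requires the level's data matrix")
  sparse_within_edges(level_data, node_ids, mode$edge_threshold)
}

#' Build a two-level GRN from selection scores
#'
#' Nodes are the variables passing their level's significance threshold
#' (PIPs: score >= cutoff; p-values: score <= cutoff). A directed
#' cross-level edge j -> g is drawn iff the mask annotates SNP j to gene g
#' and both endpoints are significant. Within-level edges follow each
#' level's [connectivity_mode]. A significant SNP with no significant
#' annotated gene stays in the network with zero cross-level edges and is
#' flagged \code{orphan}.
#'
#' @param result a [selection_result].
#' @param mask an [annotation_mask] covering the score-table ids.
#' @param l1_cutoff,l2_cutoff significance cutoffs per level.
#' @param l1_mode,l2_mode [connectivity_mode]s (or mode strings).
#' @param level_data optional list with elements \code{l1} and/or \code{l2}:
#'   data matrices (columns named by variable id) for sparse modes —
#'   typically the genotype matrix and the gene-level design.
#' @param layout optional layout hint name (see [layout_hint]).
#' @return A [grn] whose metadata records thresholds, connectivity modes
#'   and backend.
#' @export
build_grn <- function(result, mask, l1_cutoff = 0.5, l2_cutoff = 0.5,
                      l1_mode = "none", l2_mode = "complete",
                      level_data = list(), layout = NULL) {
  l1_mode <- as_connectivity(l1_mode)
  l2_mode <- as_connectivity(l2_mode)
  validate_mask(mask)
  if (l1_mode$mode == "sparse" && is.null(level_data$l1))
    stop_usage("sparse connectivity at level 1 requires level_data$l1")
  if (l2_mode$mode == "sparse" && is.null(level_data$l2))
    stop_usage("sparse connectivity at level 2 requires level_data$l2")
  tab1 <- result$level1; tab2 <- result$level2
  not_in_mask <- setdiff(tab1$id, rownames(mask))
  if (length(not_in_mask))
    stop_usage("level-1 id(s) absent from mask rows: ",
               paste(utils::head(not_in_mask, 3L), collapse = ", "))
  sig1 <- threshold_scores(tab1, l1_cutoff)
  sig2 <- threshold_scores(tab2, l2_cutoff)
  kind1 <- attr(tab1, "score_kind"); kind2 <- attr(tab2, "score_kind")
  score1 <- stats::setNames(tab1$score, tab1$id)
  score2 <- stats::setNames(tab2$score, tab2$id)

  # cross-level edges restricted to the mask support between significant
  # endpoints
  cross <- data.frame(source = character(), target = character(),
                      stringsAsFactors = FALSE)
  if (length(sig1) && length(sig2)) {
    sub <- unclass(mask)[sig1, intersect(sig2, colnames(mask)), drop = FALSE]
    hit <- which(sub == 1L, arr.ind = TRUE)
    if (nrow(hit))
      cross <- data.frame(source = rownames(sub)[hit[, 1L]],
                          target = colnames(sub)[hit[, 2L]],
                          stringsAsFactors = FALSE)
  }
  orphan1 <- setdiff(sig1, unique(cross$source))

  nodes <- rbind(
    if (length(sig1))
      data.frame(id = sig1, level = 1L, score = unname(score1[sig1]),
                 score_kind = kind1, significant = TRUE,
                 orphan = sig1 %in% orphan1, stringsAsFactors = FALSE),
    if (length(sig2))
      data.frame(id = sig2, level = 2L, score = unname(score2[sig2]),
                 score_kind = kind2, significant = TRUE, orphan = FALSE,
                 stringsAsFactors = FALSE))

  w1 <- within_edges_for_mode(l1_mode, sig1, level_data$l1, "level 1")
  w2 <- within_edges_for_mode(l2_mode, sig2, level_data$l2, "level 2")
  edges <- rbind(
    if (nrow(cross))
      data.frame(source = cross$source, target = cross$target,
                 directed = TRUE, kind = "cross_level", weight = NA_real_,
                 stringsAsFactors = FALSE),
    if (nrow(w1))
      data.frame(source = w1$source, target = w1$target, directed = FALSE,
                 kind = "within_level", weight = w1$weight,
                 stringsAsFactors = FALSE),
    if (nrow(w2))
      data.frame(source = w2$source, target = w2$target, directed = FALSE,
                 kind = "within_level", weight = w2$weight,
                 stringsAsFactors = FALSE))

  memberships <- lapply(stats::setNames(sig1, sig1), function(j)
    colnames(mask)[unclass(mask)[j, ] == 1L])

  meta <- list(l1_cutoff = l1_cutoff, l2_cutoff = l2_cutoff,
               l1_connectivity = l1_mode$mode,
               l2_connectivity = l2_mode$mode,
               backend = result$backend)
  if (!is.null(l1_mode$edge_threshold))
    meta$l1_edge_threshold <- l1_mode$edge_threshold
  if (!is.null(l2_mode$edge_threshold))
    meta$l2_edge_threshold <- l2_mode$edge_threshold
  g <- grn(nodes = nodes, edges = edges, memberships = memberships,
           metadata = meta)
  if (!is.null(layout)) g <- layout_hint(g, layout)
  g
}

#' Difference between two GRNs
#'
#' Set algebra on node ids and canonicalized edges (undirected edges compare
#' by their sorted endpoint pair). Nodes present in both networks report
#' their score change.
#'
#' @param before,after [grn]s built with the same score kinds.
#' @return An object of class \code{grn_diff} with \code{nodes_added},
#'   \code{nodes_removed}, \code{nodes_persisting} (data.frame with
#'   \code{score_before}, \code{score_after}, \code{delta}),
#'   \code{edges_added}, \code{edges_removed}.
#' @export
diff_grn <- function(before, after) {
  validate_grn(before); validate_grn(after)
  ids_b <- before$nodes$id; ids_a <- after$nodes$id
  added <- setdiff(ids_a, ids_b)
  removed <- setdiff(ids_b, ids_a)
  common <- intersect(ids_b, ids_a)
  sb <- stats::setNames(before$nodes$score, ids_b)
  sa <- stats::setNames(after$nodes$score, ids_a)
  persisting <- data.frame(id = common,
                           score_before = unname(sb[common]),
                           score_after = unname(sa[common]),
                           delta = unname(sa[common] - sb[common]),
                           stringsAsFactors = FALSE)
  keys_b <- edge_keys(before$edges); keys_a <- edge_keys(after$edges)
  fmt_edge <- function(edges, keys, keep) {
    e <- edges[keys %in% keep, c("source", "target", "kind"), drop = FALSE]
    rownames(e) <- NULL
    e
  }
  structure(list(nodes_added = added, nodes_removed = removed,
                 nodes_persisting = persisting,
                 edges_added = fmt_edge(after$edges, keys_a,
                                        setdiff(keys_a, keys_b)),
                 edges_removed = fmt_edge(before$edges, keys_b,
                                          setdiff(keys_b, keys_a))),
            class = "grn_diff")
}

#' @export
print.grn_diff <- function(x, ...) {
  cat(sprintf("grn_diff: +%d/-%d nodes (%d persisting), +%d/-%d edges\n",
              length(x$nodes_added), length(x$nodes_removed),
              nrow(x$nodes_persisting), nrow(x$edges_added),
              nrow(x$edges_removed)))
  invisible(x)
}
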