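#' Two-level gene regulatory network container
#'
#' Nodes carry a molecular level (1 = SNP, 2 = gene/group), a score (PIP or
#' p-value), a significance flag and, for level-1 nodes, the list of level-2
#' groups they are annotated to. Edges are either directed cross-level edges
#' (SNP -> gene, following the annotation mask) or undirected within-level
#' edges. Rendering attributes (colors, shapes) are intentionally not stored;
#' level, score and significance are sufficient for any renderer.
#'
#' @param nodes data.frame with columns \code{id}, \code{level},
#'   \code{score}, \code{score_kind}, \code{significant} and optionally
#'   \code{orphan}.
#' @param edges data.frame with columns \code{source}, \code{target},
#'   \code{directed}, \code{kind}, \code{weight} (weight may be NA).
#' @param memberships named list: level-1 id -> character vector of level-2
#'   group ids.
#' @param metadata list of run parameters (thresholds, connectivity modes,
#'   backend name, layout hint).
#' @return An object of class \code{grn}.
#' @export
grn <- function(nodes = NULL, edges = NULL, memberships = list(),
                metadata = list()) {
  if (is.null(nodes))
    nodes <- data.frame(id = character(), level = integer(),
                        score = numeric(), score_kind = character(),
                        significant = logical(), orphan = logical(),
                        stringsAsFactors = FALSE)
  if (is.null(edges))
    edges <- data.frame(source = character(), target = character(),
                        directed = logical(), kind = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  if (!"orphan" %in% names(nodes)) nodes$orphan <- FALSE
  if (!"weight" %in% names(edges)) edges$weight <- NA_real_
  nodes$level <- as.integer(nodes$level)
  # canonical form: memberships keyed in node order, empty entries dropped
  memberships <- memberships[lengths(memberships) > 0L]
  memberships <- memberships[intersect(nodes$id, names(memberships))]
  if (!length(memberships)) memberships <- list()
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  g <- structure(list(nodes = nodes, edges = edges,
                      memberships = memberships, metadata = metadata),
                 class = "grn")
  validate_grn(g)
  g
}

# Canonical key for an edge: undirected edges sort their endpoints.
edge_keys <- function(edges) {
  if (!nrow(edges)) return(character())
  vapply(seq_len(nrow(edges)), function(i) {
    a <- edges$source[i]; b <- edges$target[i]
    if (!edges$directed[i]) {
      p <- sort(c(a, b)); a <- p[1L]; b <- p[2L]
    }
    paste(a, b, edges$kind[i], sep = "\r")
  }, character(1L))
}

#' @rdname grn
#' @param g object to validate.
#' @export
validate_grn <- function(g) {
  stopifnot(inherits(g, "grn"))
  nodes <- g$nodes; edges <- g$edges
  if (anyDuplicated(nodes$id))
    stop_validation("duplicate node ids in GRN")
  if (!all(nodes$level %in% c(1L, 2L)))
    stop_validation("node levels must be 1 or 2")
  if (nrow(edges)) {
    missing_ep <- setdiff(c(edges$source, edges$target), nodes$id)
    if (length(missing_ep))
      stop_validation("edge endpoint(s) not present as nodes: ",
                      paste(missing_ep, collapse = ", "))
    if (any(edges$source == edges$target))
      stop_validation("self-edges are not allowed")
    lvl <- stats::setNames(nodes$level, nodes$id)
    cross <- edges$kind == "cross_level"
    if (any(cross & (!edges$directed |
                     lvl[edges$source] != 1L | lvl[edges$target] != 2L)))
      stop_validation("cross-level edges must be directed level-1 -> level-2")
    within <- edges$kind == "within_level"
    if (any(within & (edges$directed |
                      lvl[edges$source] != lvl[edges$target])))
      stop_validation("within-level edges must be undirected, same level")
    if (anyDuplicated(edge_keys(edges)))
      stop_validation("duplicate edges after canonicalization")
  }
  invisible(g)
}

#' @rdname grn
#' @param x a \code{grn}.
#' @param ... ignored.
#' @export
print.grn <- function(x, ...) {
  n1 <- sum(x$nodes$level == 1L); n2 <- sum(x$nodes$level == 2L)
  cat(sprintf("grn: %d level-1 + %d level-2 nodes, %d cross-level and %d within-level edges\n",
              n1, n2, sum(x$edges$kind == "cross_level"),
              sum(x$edges$kind == "within_level")))
  if (length(x$metadata))
    cat("metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  invisible(x)
}

#' Attach a layout hint to a GRN
#'
#' Stores the name of the layout a renderer should use; no coordinates are
#' computed here.
#'
#' @param g a [grn].
#' @param name one of \code{"layout_with_kk"}, \code{"layout_bipartite"},
#'   \code{"layout_circle"}.
#' @return The GRN with \code{metadata$layout} set (last call wins).
#' @export
layout_hint <- function(g, name) {
  choices <- c("layout_with_kk", "layout_bipartite", "layout_circle")
  if (!name %in% choices)
    stop_usage("unknown layout \"", name, "\"; options: ",
               paste(choices, collapse = ", "))
  g$metadata$layout <- name
  g
}
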