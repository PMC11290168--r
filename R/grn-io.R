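# GRN serialization: versioned JSON schema and GraphML.
#
# The JSON layout ("schema_version": 1) is the stable exchange format that
# perturbation records reference; GraphML is provided for graph tools
# (igraph, Cytoscape, Gephi). Both round-trip nodes, edges, memberships and
# metadata exactly.

GRN_SCHEMA_VERSION <- 1L

#' Write a GRN to disk
#'
#' @param g a [grn].
#' @param path output path.
#' @param format \code{"json"} (versioned schema) or \code{"graphml"}.
#' @return \code{path}, invisibly.
#' @export
write_grn <- function(g, path, format = c("json", "graphml")) {
  format <- match.arg(format)
  validate_grn(g)
  if (format == "json") write_grn_json(g, path) else write_grn_graphml(g, path)
  invisible(path)
}

#' Read a GRN from disk
#'
#' @param path a file produced by [write_grn] (format auto-detected from the
#'   extension unless given).
#' @param format \code{"json"} or \code{"graphml"}.
#' @return A [grn]; reading validates all GRN invariants.
#' @export
read_grn <- function(path, format = NULL) {
  if (!file.exists(path)) stop_usage("file not found: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml"
              else "json"
  }
  if (!format %in% c("json", "graphml"))
    stop_usage("unknown GRN format \"", format, "\"")
  if (format == "json") read_grn_json(path) else read_grn_graphml(path)
}

node_record <- function(nodes, memberships, i) {
  id <- nodes$id[i]
  list(id = id,
       level = nodes$level[i],
       score = nodes$score[i],
       score_kind = nodes$score_kind[i],
       significant = nodes$significant[i],
       orphan = nodes$orphan[i],
       group_memberships = as.list(memberships[[id]] %||% character()))
}

write_grn_json <- function(g, path) {
  obj <- list(
    schema_version = GRN_SCHEMA_VERSION,
    nodes = lapply(seq_len(nrow(g$nodes)), node_record,
                   nodes = g$nodes, memberships = g$memberships),
    edges = lapply(seq_len(nrow(g$edges)), function(i) {
      w <- g$edges$weight[i]
      list(source = g$edges$source[i], target = g$edges$target[i],
           directed = g$edges$directed[i], kind = g$edges$kind[i],
           weight = if (is.na(w)) NULL else w)
    }),
    metadata = g$metadata)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  write_lines_lf(json, path)
}

# jsonlite parses whole numbers as integer; network scores, weights and
# metadata numerics are doubles by contract, so coerce on read.
de_integer <- function(x) {
  if (is.list(x)) lapply(x, de_integer)
  else if (is.integer(x)) as.double(x)
  else x
}

read_grn_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(as.integer(obj$schema_version %||% -1L), GRN_SCHEMA_VERSION))
    stop_validation("unsupported GRN schema_version in ", path)
  nodes <- do.call(rbind, lapply(obj$nodes, function(n) {
    data.frame(id = n$id, level = as.integer(n$level),
               score = as.numeric(n$score), score_kind = n$score_kind,
               significant = isTRUE(n$significant),
               orphan = isTRUE(n$orphan), stringsAsFactors = FALSE)
  }))
  memberships <- stats::setNames(
    lapply(obj$nodes, function(n)
      as.character(unlist(n$group_memberships, use.names = FALSE))),
    vapply(obj$nodes, `[[`, character(1L), "id"))
  edges <- do.call(rbind, lapply(obj$edges, function(e) {
    data.frame(source = e$source, target = e$target,
               directed = isTRUE(e$directed), kind = e$kind,
               weight = if (is.null(e$weight)) NA_real_ else as.numeric(e$weight),
               stringsAsFactors = FALSE)
  }))
  meta <- de_integer(obj$metadata %||% list())
  grn(nodes = nodes, edges = edges, memberships = memberships,
      metadata = meta)
}

# GraphML: node attributes level/score/score_kind/significant/orphan/groups,
# edge attributes kind/weight plus the per-edge "directed" attribute;
# metadata rides along as a JSON-encoded graph-level attribute.
GRAPHML_KEYS <- list(
  list(id = "d_level", domain = "node", name = "level", type = "int"),
  list(id = "d_score", domain = "node", name = "score", type = "double"),
  list(id = "d_score_kind", domain = "node", name = "score_kind", type = "string"),
  list(id = "d_significant", domain = "node", name = "significant", type = "boolean"),
  list(id = "d_orphan", domain = "node", name = "orphan", type = "boolean"),
  list(id = "d_groups", domain = "node", name = "group_memberships", type = "string"),
  list(id = "d_kind", domain = "edge", name = "kind", type = "string"),
  list(id = "d_weight", domain = "edge", name = "weight", type = "double"),
  list(id = "d_metadata", domain = "graph", name = "metadata", type = "string"))

write_grn_graphml <- function(g, path) {
  if (any(grepl("|", c(g$nodes$id, unlist(g$memberships)), fixed = TRUE)))
    stop_validation("identifiers may not contain \"|\" in GraphML export")
  doc <- xml2::xml_new_root("graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  for (k in GRAPHML_KEYS) {
    xml2::xml_add_child(doc, "key", id = k$id, `for` = k$domain,
                        `attr.name` = k$name, `attr.type` = k$type)
  }
  graph <- xml2::xml_add_child(doc, "graph", id = "grn",
                               edgedefault = "directed")
  meta_node <- xml2::xml_add_child(graph, "data", key = "d_metadata")
  xml2::xml_text(meta_node) <- as.character(
    jsonlite::toJSON(g$metadata, auto_unbox = TRUE, digits = NA))
  add_data <- function(parent, key, value) {
    d <- xml2::xml_add_child(parent, "data", key = key)
    xml2::xml_text(d) <- value
  }
  for (i in seq_len(nrow(g$nodes))) {
    nd <- xml2::xml_add_child(graph, "node", id = g$nodes$id[i])
    add_data(nd, "d_level", as.character(g$nodes$level[i]))
    add_data(nd, "d_score", sprintf("%.17g", g$nodes$score[i]))
    add_data(nd, "d_score_kind", g$nodes$score_kind[i])
    add_data(nd, "d_significant", tolower(as.character(g$nodes$significant[i])))
    add_data(nd, "d_orphan", tolower(as.character(g$nodes$orphan[i])))
    add_data(nd, "d_groups",
             paste(g$memberships[[g$nodes$id[i]]] %||% character(),
                   collapse = "|"))
  }
  for (i in seq_len(nrow(g$edges))) {
    ed <- xml2::xml_add_child(graph, "edge",
                              source = g$edges$source[i],
                              target = g$edges$target[i],
                              directed = tolower(as.character(g$edges$directed[i])))
    add_data(ed, "d_kind", g$edges$kind[i])
    if (!is.na(g$edges$weight[i]))
      add_data(ed, "d_weight", sprintf("%.17g", g$edges$weight[i]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

read_grn_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(g = "http://graphml.graphdrawing.org/xmlns")
  get_data <- function(node, key) {
    d <- xml2::xml_find_first(node,
      sprintf(".//g:data[@key='%s']", key), ns)
    if (inherits(d, "xml_missing")) NA_character_ else xml2::xml_text(d)
  }
  node_els <- xml2::xml_find_all(doc, ".//g:graph/g:node", ns)
  ids <- xml2::xml_attr(node_els, "id")
  nodes <- data.frame(
    id = ids,
    level = as.integer(vapply(node_els, get_data, character(1L), "d_level")),
    score = as.numeric(vapply(node_els, get_data, character(1L), "d_score")),
    score_kind = vapply(node_els, get_data, character(1L), "d_score_kind"),
    significant = vapply(node_els, get_data, character(1L), "d_significant") == "true",
    orphan = vapply(node_els, get_data, character(1L), "d_orphan") == "true",
    stringsAsFactors = FALSE)
  groups <- vapply(node_els, get_data, character(1L), "d_groups")
  memberships <- stats::setNames(
    lapply(groups, function(s) {
      if (is.na(s) || !nzchar(s)) character()
      else strsplit(s, "|", fixed = TRUE)[[1L]]
    }), ids)
  edge_els <- xml2::xml_find_all(doc, ".//g:graph/g:edge", ns)
  edges <- if (length(edge_els)) data.frame(
    source = xml2::xml_attr(edge_els, "source"),
    target = xml2::xml_attr(edge_els, "target"),
    directed = xml2::xml_attr(edge_els, "directed") == "true",
    kind = vapply(edge_els, get_data, character(1L), "d_kind"),
    weight = as.numeric(vapply(edge_els, get_data, character(1L), "d_weight")),
    stringsAsFactors = FALSE) else NULL
  meta_el <- xml2::xml_find_first(doc, ".//g:graph/g:data[@key='d_metadata']", ns)
  meta <- if (inherits(meta_el, "xml_missing")) list()
          else de_integer(jsonlite::fromJSON(xml2::xml_text(meta_el),
                                             simplifyVector = FALSE))
  grn(nodes = if (nrow(nodes)) nodes else NULL, edges = edges,
      memberships = memberships, metadata = meta)
}
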