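#' Write a graph to GraphML with deterministic node ordering
#'
#' All graphs the pipeline emits (strain graphs, the pangenome graph, pattern
#' subgraphs) are exchanged as GraphML so they can be loaded into Cytoscape
#' and similar viewers. Vertices are reordered by name before writing, so the
#' same graph always produces a byte-identical file. Node and edge attributes
#' must be single strings, numbers, or logicals; set-valued attributes are
#' serialized with [join_set()] before they reach this writer.
#'
#' @param graph an igraph object whose vertices carry a \code{name} attribute
#' @param path output file path
#' @return the path, invisibly
#' @export
write_graphml <- function(graph, path) {
  stopifnot(igraph::is_igraph(graph))
  if (igraph::vcount(graph) > 0 && is.null(igraph::V(graph)$name)) {
    stop_pg("graph vertices must be named for GraphML export")
  }
  for (a in igraph::vertex_attr_names(graph)) {
    v <- igraph::vertex_attr(graph, a)
    if (!(is.character(v) || is.numeric(v) || is.logical(v))) {
      stop_pg("vertex attribute '%s' has unserializable type '%s'", a, class(v)[1])
    }
  }
  for (a in igraph::edge_attr_names(graph)) {
    v <- igraph::edge_attr(graph, a)
    if (!(is.character(v) || is.numeric(v) || is.logical(v))) {
      stop_pg("edge attribute '%s' has unserializable type '%s'", a, class(v)[1])
    }
  }
  g <- sort_vertices(graph)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a GraphML graph written by [write_graphml()]
#'
#' The write -> read round trip is the identity on the node set, edge set and
#' all attributes. Vertices are re-sorted by name after reading so graph
#' comparisons are stable.
#'
#' @param path path to a GraphML file
#' @return an igraph object
#' @export
read_graphml <- function(path) {
  if (!file.exists(path)) stop_pg("GraphML file not found: %s", path)
  g <- igraph::read_graph(path, format = "graphml")
  if (!is.null(igraph::vertex_attr(g, "id"))) {
    if (is.null(igraph::V(g)$name)) {
      g <- igraph::set_vertex_attr(g, "name",
                                   value = igraph::vertex_attr(g, "id"))
    }
    # the file-level node ids are an artefact of the serialization
    g <- igraph::delete_vertex_attr(g, "id")
  }
  sort_vertices(g)
}

sort_vertices <- function(graph) {
  if (igraph::vcount(graph) < 2) return(graph)
  igraph::permute(graph, order(order(igraph::V(graph)$name)))
}

# Structural equality of two named graphs: same vertices, same (unordered)
# edges, same attributes. Used by tests and the determinism checks.
graph_identical <- function(a, b) {
  va <- sort(igraph::V(a)$name); vb <- sort(igraph::V(b)$name)
  if (!identical(va, vb)) return(FALSE)
  ea <- canonical_edges(a); eb <- canonical_edges(b)
  if (!identical(dim(ea), dim(eb))) return(FALSE)
  if (!identical(sort(names(ea)), sort(names(eb)))) return(FALSE)
  for (cn in names(ea)) {
    # GraphML carries numbers as doubles; integer vs double is not a
    # structural difference
    if (!isTRUE(all.equal(ea[[cn]], eb[[cn]], check.attributes = FALSE))) {
      return(FALSE)
    }
  }
  an <- sort(igraph::vertex_attr_names(a))
  if (!identical(an, sort(igraph::vertex_attr_names(b)))) return(FALSE)
  for (at in an) {
    xa <- igraph::vertex_attr(a, at)[order(igraph::V(a)$name)]
    xb <- igraph::vertex_attr(b, at)[order(igraph::V(b)$name)]
    if (!isTRUE(all.equal(xa, xb))) return(FALSE)
  }
  TRUE
}

canonical_edges <- function(g) {
  if (igraph::ecount(g) == 0) {
    m <- cbind(from = character(0), to = character(0))
  } else {
    e <- igraph::as_edgelist(g)
    m <- cbind(from = pmin(e[, 1], e[, 2]), to = pmax(e[, 1], e[, 2]))
  }
  attrs <- sort(igraph::edge_attr_names(g))
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  for (at in attrs) df[[at]] <- igraph::edge_attr(g, at)
  df <- df[do.call(order, df[c("from", "to", attrs)]), , drop = FALSE]
  rownames(df) <- NULL
  df
}
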