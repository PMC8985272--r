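#' Detect structural patterns on the pangenome graph
#'
#' Runs all five detectors ([find_orphans()], [find_uniques()],
#' [find_variants()], [find_insertions()], [find_indels()]) and bundles
#' their results. All detectors operate on the adjacency structure of the
#' (already w_min-filtered) pangenome graph; self-loops are excluded
#' throughout.
#'
#' @param g pangenome graph with strain sets and partitions assigned
#' @param max_insertion_len maximal inserted path length (default 10)
#' @param max_cycle_len maximal InDel cycle length (default 100)
#' @return a \code{pattern_report} list with elements \code{orphans},
#'   \code{uniques}, \code{variants}, \code{insertions}, \code{indels}
#' @export
detect_patterns <- function(g, max_insertion_len = 10L, max_cycle_len = 100L) {
  structure(list(orphans = find_orphans(g),
                 uniques = find_uniques(g),
                 variants = find_variants(g),
                 insertions = find_insertions(g, max_insertion_len),
                 indels = find_indels(g, max_cycle_len)),
            class = "pattern_report")
}

#' @export
print.pattern_report <- function(x, ...) {
  cat(sprintf(paste0("pattern_report: %d orphans, %d uniques, %d variant ",
                     "groups, %d insertion nodes, %d InDel cycles\n"),
              length(x$orphans), length(x$uniques), length(x$variants),
              nrow(x$insertions), length(x$indels)))
  invisible(x)
}

# Simple adjacency view: drop self-loops (tandem paralogs are recorded but
# excluded from pattern detection).
simple_adjacency <- function(g) {
  igraph::simplify(g, remove.multiple = FALSE, remove.loops = TRUE)
}

#' Find orphan clusters
#'
#' Orphans are clusters present in two or more genomes but without any
#' consistent genomic neighbourhood: nodes with no incident adjacency edge
#' in the filtered pangenome graph. Since detection runs after w_min
#' filtering, raising w_min isolates clusters whose neighbourhoods are
#' supported by too few genomes — exactly how weakly supported, potentially
#' erroneous clusters (or small mobile elements) are singled out.
#'
#' @param g pangenome graph
#' @return sorted character vector of node IDs
#' @export
find_orphans <- function(g) {
  gs <- simple_adjacency(g)
  deg <- igraph::degree(gs)
  sort(igraph::V(g)$name[deg == 0 & igraph::V(g)$n_strains >= 2])
}

#' Find unique clusters
#'
#' Uniques are clusters occurring in exactly one genome, regardless of
#' connectivity — recent horizontal acquisitions, contamination, or
#' annotation artefacts.
#'
#' @param g pangenome graph
#' @return sorted character vector of node IDs
#' @export
find_uniques <- function(g) {
  sort(igraph::V(g)$name[igraph::V(g)$n_strains == 1])
}

#' Find variant bubbles
#'
#' Variants are parallel alternative clusters occupying the same genomic
#' slot: small bubbles whose internal nodes connect to the rest of the graph
#' only through one or two anchor nodes. Internal candidates are nodes of
#' degree 1 or 2 (self-loops excluded); candidates sharing the same exact
#' neighbour set form a group, and groups with at least two internal nodes
#' are reported (a lone node between two anchors is ordinary synteny, not a
#' variant). Typically the members are alleles of one gene that diverged
#' beyond the clustering identity floor. Groups do not require disjoint
#' strain sets, but the shared-strain count is reported so users can filter.
#'
#' @param g pangenome graph
#' @return list of groups, each a list with \code{anchors} (1 or 2 node
#'   IDs), \code{members} (>= 2 node IDs) and \code{shared_strains}
#'   (genomes occurring in more than one member)
#' @export
find_variants <- function(g) {
  gs <- simple_adjacency(g)
  deg <- igraph::degree(gs)
  cand <- which(deg >= 1 & deg <= 2)
  if (!length(cand)) return(list())
  keys <- vapply(cand, function(v) {
    join_set(igraph::V(gs)$name[igraph::neighbors(gs, v)])
  }, "")
  grp <- split(igraph::V(gs)$name[cand], keys)
  grp <- grp[vapply(grp, length, 1L) >= 2]
  if (!length(grp)) return(list())
  out <- lapply(sort(names(grp)), function(k) {
    members <- sort(grp[[k]])
    strains <- unlist(lapply(members, function(m) {
      split_set(igraph::V(g)$strains[match(m, igraph::V(g)$name)])
    }))
    list(anchors = split_set(k), members = members,
         shared_strains = sort(unique(strains[duplicated(strains)])))
  })
  out
}

#' Find insertion bubbles
#'
#' Insertions are rare short gene acquisitions: an anchor pair with a direct
#' edge (the ancestral adjacency kept by most genomes) bridged by an
#' alternative simple path of 1 to \code{max_len} nodes carried by few
#' genomes, where every inserted node belongs to the shell or cloud. Paths
#' containing any core node are not insertions.
#'
#' @param g pangenome graph with partitions assigned
#' @param max_len maximal inserted path length ("small bubbles"; default 10)
#' @return data.frame with one row per inserted node and occurrence:
#'   \code{node}, \code{degree}, \code{weight}, \code{anchor_a},
#'   \code{anchor_b}
#' @export
find_insertions <- function(g, max_len = 10L) {
  gs <- simple_adjacency(g)
  part <- setNames(igraph::V(gs)$partition, igraph::V(gs)$name)
  deg_full <- setNames(igraph::degree(gs), igraph::V(gs)$name)
  wt <- setNames(igraph::V(gs)$avg_per_genome, igraph::V(gs)$name)
  acc <- igraph::V(gs)$name[part %in% c("shell", "cloud")]
  empty <- data.frame(node = character(0), degree = integer(0),
                      weight = numeric(0), anchor_a = character(0),
                      anchor_b = character(0), stringsAsFactors = FALSE)
  if (igraph::ecount(gs) == 0) return(empty)
  el <- igraph::as_edgelist(gs)
  rows <- list()
  for (i in seq_len(nrow(el))) {
    a <- min(el[i, ]); b <- max(el[i, ])
    keep <- unique(c(a, b, acc))
    sub <- igraph::induced_subgraph(gs, keep)
    eid <- igraph::get_edge_ids(sub, c(a, b), error = FALSE)
    if (eid > 0) sub <- igraph::delete_edges(sub, eid)
    paths <- tryCatch(
      igraph::all_simple_paths(sub, from = a, to = b, cutoff = max_len + 1),
      error = function(e) list())
    inserted <- character(0)
    for (p in paths) {
      nn <- igraph::V(sub)$name[p]
      interior <- setdiff(nn, c(a, b))
      if (length(interior) >= 1 && length(interior) <= max_len) {
        inserted <- union(inserted, interior)
      }
    }
    if (length(inserted)) {
      inserted <- sort(inserted)
      rows[[length(rows) + 1L]] <- data.frame(
        node = inserted, degree = as.integer(deg_full[inserted]),
        weight = as.numeric(wt[inserted]), anchor_a = a, anchor_b = b,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$anchor_a, out$anchor_b, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find InDel cycles
#'
#' InDels — insertions or deletions segregating among the genomes, or
#' rearrangements — appear as cycles in the pangenome graph involving more
#' than four nodes, with no restriction on how common the member clusters
#' are. Exhaustive simple-cycle enumeration is exponential, so the detector
#' reports the cycles of a minimum cycle basis (deterministic shortest-first
#' greedy construction) with more than four and at most \code{max_len}
#' nodes. Cycles are reported as ordered node lists starting from the
#' lexicographically smallest node, traversed toward its smaller neighbour.
#'
#' @param g pangenome graph
#' @param max_len maximal reported cycle length (default 100)
#' @return list of character vectors (ordered cycle nodes)
#' @export
find_indels <- function(g, max_len = 100L) {
  gs <- simple_adjacency(g)
  basis <- min_cycle_basis(gs, max_len = max_len)
  basis <- basis[vapply(basis, length, 1L) > 4]
  basis[order(vapply(basis, length, 1L),
              vapply(basis, paste, "", collapse = "\t"))]
}

#' Write the pattern report files
#'
#' Emits the text/tabular forms — \code{orphans.txt} and \code{uniques.txt}
#' (one cluster per line), \code{variants.txt} (one group per line: the
#' anchors, then the member clusters, tab-delimited), \code{indels.txt} (one
#' cycle per line as a tab-delimited cluster list) and \code{insertions.tsv}
#' (node, degree, weight, anchors) — plus one GraphML subgraph per pattern
#' class containing only that pattern's nodes and edges, suitable for
#' overlaying onto the full graph with [highlight_subgraph()].
#'
#' @param report a \code{pattern_report}
#' @param g the pangenome graph the report was computed on
#' @param out_dir output directory (created if needed)
#' @return named character vector of the written file paths, invisibly
#' @export
write_pattern_outputs <- function(report, g, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_lines_det(report$orphans, p("orphans.txt"))
  write_lines_det(report$uniques, p("uniques.txt"))
  write_lines_det(vapply(report$variants, function(v) {
    paste(c(join_set(v$anchors), v$members), collapse = "\t")
  }, ""), p("variants.txt"))
  ins <- report$insertions
  ins_lines <- c(paste(c("node", "degree", "weight", "anchor_a", "anchor_b"),
                       collapse = "\t"),
                 vapply(seq_len(nrow(ins)), function(i) {
                   paste(c(ins$node[i], ins$degree[i], fmt_num(ins$weight[i]),
                           ins$anchor_a[i], ins$anchor_b[i]), collapse = "\t")
                 }, ""))
  write_lines_det(ins_lines, p("insertions.tsv"))
  write_lines_det(vapply(report$indels, paste, "", collapse = "\t"),
                  p("indels.txt"))

  gs <- simple_adjacency(g)
  write_graphml(pattern_subgraph(g, report$orphans), p("orphans.graphml"))
  write_graphml(pattern_subgraph(g, report$uniques), p("uniques.graphml"))
  vnodes <- unique(unlist(lapply(report$variants,
                                 function(v) c(v$anchors, v$members))))
  write_graphml(pattern_subgraph(gs, vnodes, keep_edges = TRUE),
                p("variants.graphml"))
  inodes <- unique(c(ins$node, ins$anchor_a, ins$anchor_b))
  write_graphml(pattern_subgraph(gs, inodes, keep_edges = TRUE),
                p("insertions.graphml"))
  cyc_nodes <- unique(unlist(report$indels))
  cyc_edges <- do.call(rbind, lapply(report$indels, function(cy) {
    cbind(cy, c(cy[-1], cy[1]))
  }))
  write_graphml(cycle_subgraph(gs, cyc_nodes, cyc_edges), p("indels.graphml"))
  invisible(setNames(p(c("orphans.txt", "uniques.txt", "variants.txt",
                         "insertions.tsv", "indels.txt", "orphans.graphml",
                         "uniques.graphml", "variants.graphml",
                         "insertions.graphml", "indels.graphml")),
                     c("orphans", "uniques", "variants", "insertions",
                       "indels", "orphans_graph", "uniques_graph",
                       "variants_graph", "insertions_graph", "indels_graph")))
}

pattern_subgraph <- function(g, nodes, keep_edges = FALSE) {
  if (is.null(nodes) || !length(nodes)) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  sub <- igraph::induced_subgraph(g, nodes)
  if (!keep_edges) sub <- igraph::delete_edges(sub, igraph::E(sub))
  sub
}

cycle_subgraph <- function(gs, nodes, edge_mat) {
  if (is.null(nodes) || !length(nodes)) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  sub <- igraph::induced_subgraph(gs, nodes)
  if (!is.null(edge_mat) && nrow(edge_mat)) {
    want <- unique(paste(pmin(edge_mat[, 1], edge_mat[, 2]),
                         pmax(edge_mat[, 1], edge_mat[, 2]), sep = "\r"))
    el <- igraph::as_edgelist(sub)
    have <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "\r")
    sub <- igraph::delete_edges(sub, which(!(have %in% want)))
  }
  sub
}

#' Overlay a pattern subgraph onto the full pangenome graph
#'
#' Marks the nodes and edges of \code{pattern_graph} in \code{g} with a
#' boolean \code{highlight} attribute; unmatched elements are untouched
#' (\code{highlight = FALSE}). The colouring is left to the viewer.
#'
#' @param g full pangenome graph
#' @param pattern_graph a pattern subgraph whose nodes are all nodes of
#'   \code{g} (missing nodes are an error listing the IDs)
#' @return \code{g} with \code{highlight} vertex and edge attributes
#' @export
highlight_subgraph <- function(g, pattern_graph) {
  pn <- igraph::V(pattern_graph)$name %||% character(0)
  missing <- setdiff(pn, igraph::V(g)$name)
  if (length(missing)) {
    stop_pg("pattern nodes absent from the pangenome graph: %s",
            paste(missing, collapse = ", "))
  }
  g <- igraph::set_vertex_attr(g, "highlight",
                               value = igraph::V(g)$name %in% pn)
  eh <- rep(FALSE, igraph::ecount(g))
  if (igraph::ecount(pattern_graph) > 0 && igraph::ecount(g) > 0) {
    pel <- igraph::as_edgelist(pattern_graph)
    pk <- paste(pmin(pel[, 1], pel[, 2]), pmax(pel[, 1], pel[, 2]), sep = "\r")
    el <- igraph::as_edgelist(g)
    ek <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "\r")
    eh <- ek %in% pk
  }
  igraph::set_edge_attr(g, "highlight", value = eh)
}

#' Remove highlight attributes added by [highlight_subgraph()]
#'
#' @param g a highlighted graph
#' @return \code{g} without \code{highlight} attributes
#' @export
strip_highlight <- function(g) {
  if ("highlight" %in% igraph::vertex_attr_names(g)) {
    g <- igraph::delete_vertex_attr(g, "highlight")
  }
  if ("highlight" %in% igraph::edge_attr_names(g)) {
    g <- igraph::delete_edge_attr(g, "highlight")
  }
  g
}
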