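#' Highlight a group of strains on the pangenome graph
#'
#' Marks the part of the pangenome covered by a group of genomes (a lineage,
#' a metadata group, ...). Nodes and edges of the pangenome graph occurring
#' in any listed strain are marked \code{highlight = "orange"}; adjacencies
#' present in the listed strains' strain graphs but absent from the
#' pangenome graph (they did not reach the minimal edge weight) are added
#' and marked \code{"yellow"}, as are any strain-graph clusters missing from
#' the graph entirely. Existing elements are never removed or re-weighted,
#' and the operation is idempotent. Colours are stored as attribute values
#' rather than renderer instructions, so any GraphML viewer can style them.
#'
#' @param g pangenome graph
#' @param strains character vector of genome IDs (must be input genomes)
#' @param strain_graphs the cohort's strain graphs (subcluster-labelled)
#' @return \code{g} with a \code{highlight} attribute on vertices and edges
#'   ("orange", "yellow" or "")
#' @export
highlight_strains <- function(g, strains, strain_graphs) {
  genome_ids <- vapply(strain_graphs, igraph::graph_attr, "", name = "genome_id")
  unknown <- setdiff(strains, genome_ids)
  if (length(unknown)) stop_pg("unknown strain id: %s", paste(unknown, collapse = ", "))
  sel <- strain_graphs[match(strains, genome_ids)]
  nodes_sel <- unique(unlist(lapply(sel, igraph::vertex_attr, name = "subcluster")))
  pairs_sel <- unique(unlist(lapply(sel, function(sg) {
    ends <- strain_adjacency(sg)
    if (!nrow(ends)) return(character(0))
    lab <- setNames(igraph::V(sg)$subcluster, igraph::V(sg)$name)
    a <- unname(lab[ends[, 1]]); b <- unname(lab[ends[, 2]])
    paste(pmin(a, b), pmax(a, b), sep = "\r")
  })))
  # nodes entirely absent from the graph are added yellow
  new_nodes <- setdiff(nodes_sel, igraph::V(g)$name)
  if (length(new_nodes)) {
    g <- igraph::add_vertices(g, length(new_nodes), name = sort(new_nodes))
  }
  # elements previously restored in yellow are not genuinely part of the
  # filtered pangenome; they keep their yellow mark (idempotence)
  vh <- igraph::vertex_attr(g, "highlight") %||% rep("", igraph::vcount(g))
  vh[is.na(vh)] <- ""
  vh[igraph::V(g)$name %in% setdiff(nodes_sel, new_nodes) & vh != "yellow"] <-
    "orange"
  vh[igraph::V(g)$name %in% new_nodes] <- "yellow"
  g <- igraph::set_vertex_attr(g, "highlight", value = vh)
  eh <- igraph::edge_attr(g, "highlight") %||% rep("", igraph::ecount(g))
  eh[is.na(eh)] <- ""
  if (igraph::ecount(g) > 0 && length(pairs_sel)) {
    el <- igraph::as_edgelist(g)
    ek <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "\r")
    eh[ek %in% pairs_sel & eh != "yellow"] <- "orange"
    missing_pairs <- setdiff(pairs_sel, ek)
  } else {
    missing_pairs <- pairs_sel
  }
  g <- igraph::set_edge_attr(g, "highlight", value = eh)
  if (length(missing_pairs)) {
    missing_pairs <- sort(missing_pairs)
    endsm <- do.call(rbind, strsplit(missing_pairs, "\r", fixed = TRUE))
    g <- igraph::add_edges(g, as.vector(t(endsm)), highlight = "yellow")
  }
  g
}

#' Read clade definition and clade-specific gene set tables
#'
#' Minimal two-column TSV dialects (with header) reduced from
#' phylogenetics-pipeline exports: the clade file has columns
#' \code{clade_id}, \code{genome_id} (one member per row); the gene set file
#' has \code{clade_id}, \code{cluster_id} (one gene per row), listing the
#' genes specifically present in, or specifically absent from, each clade. A
#' clade appearing only in the gene set file is an error.
#'
#' @param clade_file path to the clade definition TSV
#' @param gene_set_file path to the clade-specific gene set TSV
#' @param mode \code{"specifically_present"} or \code{"specifically_absent"}
#'   (what the gene sets represent)
#' @return list of clade specs: \code{clade_id}, \code{members},
#'   \code{gene_set}, \code{mode}
#' @export
read_clades <- function(clade_file, gene_set_file,
                        mode = c("specifically_present", "specifically_absent")) {
  mode <- match.arg(mode)
  cl <- read.delim(clade_file, stringsAsFactors = FALSE)
  gs <- read.delim(gene_set_file, stringsAsFactors = FALSE)
  if (!all(c("clade_id", "genome_id") %in% names(cl))) {
    stop_pg("clade file must have columns clade_id, genome_id")
  }
  if (!all(c("clade_id", "cluster_id") %in% names(gs))) {
    stop_pg("gene set file must have columns clade_id, cluster_id")
  }
  orphan_clades <- setdiff(gs$clade_id, cl$clade_id)
  if (length(orphan_clades)) {
    stop_pg("clade '%s' appears in the gene set file but not in the clade file",
            orphan_clades[1])
  }
  lapply(sort(unique(cl$clade_id)), function(cid) {
    list(clade_id = cid,
         members = sort(unique(cl$genome_id[cl$clade_id == cid])),
         gene_set = sort(unique(gs$cluster_id[gs$clade_id == cid])),
         mode = mode)
  })
}

#' Highlight clades and their specific gene sets on the pangenome graph
#'
#' For each clade, nodes whose strain set intersects the clade's member
#' genomes get the attribute \code{clade_<id> = "member"}; nodes in the
#' clade's gene set additionally get \code{clade_<id>_specific} set to the
#' clade's mode. Attributes are additive across clades. Gene set IDs that
#' are not nodes of the graph produce a warning listing them (paralog
#' splitting may have renamed clusters), not an error.
#'
#' @param g pangenome graph with strain sets populated
#' @param clades list of clade specs from [read_clades()]
#' @return annotated graph
#' @export
highlight_clades <- function(g, clades) {
  node_strains <- lapply(igraph::V(g)$strains, split_set)
  for (cl in clades) {
    member <- vapply(node_strains, function(s) length(intersect(s, cl$members)) > 0,
                     logical(1))
    g <- igraph::set_vertex_attr(g, paste0("clade_", cl$clade_id),
                                 value = ifelse(member, "member", ""))
    missing <- setdiff(cl$gene_set, igraph::V(g)$name)
    if (length(missing)) {
      warning(sprintf("clade %s gene set IDs not in graph: %s", cl$clade_id,
                      paste(missing, collapse = ", ")), call. = FALSE)
    }
    spec <- igraph::V(g)$name %in% cl$gene_set
    g <- igraph::set_vertex_attr(g, paste0("clade_", cl$clade_id, "_specific"),
                                 value = ifelse(spec, cl$mode, ""))
  }
  g
}
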