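#' Build the strain graph of one genome
#'
#' The strain graph has one node per locus of the genome, labelled with its
#' protein cluster. Two edge types are drawn: \emph{adjacency} edges between
#' loci with consecutive ordinals on the same contig (local neighbours on the
#' annotated sequence; contig breaks sever adjacency), and \emph{paralogy}
#' edges forming a clique among the genome's loci that fall in the same
#' cluster. Contigs are linear by default; contigs listed in \code{circular}
#' additionally get a last-to-first adjacency edge closing the ring (only
#' applied for contigs with at least three loci, so no duplicate edge can
#' arise).
#'
#' @param records gene records of one genome, as from [read_gff3()]
#' @param cluster_of named character vector locus_id -> cluster_id covering
#'   every locus (a missing locus is an error naming it)
#' @param circular character vector of contig IDs to treat as circular
#' @return an igraph with vertex attributes \code{genome}, \code{contig},
#'   \code{ordinal}, \code{product}, \code{cluster}, \code{subcluster}
#'   (initially equal to \code{cluster}) and edge attribute \code{type}
#' @export
build_strain_graph <- function(records, cluster_of, circular = character(0)) {
  genome_id <- if (nrow(records)) records$genome_id[1] else NA_character_
  missing <- setdiff(records$locus_id, names(cluster_of))
  if (length(missing)) {
    stop_pg("locus '%s' (genome %s) has no cluster assignment", missing[1], genome_id)
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(records),
                            name = records$locus_id,
                            genome = records$genome_id,
                            contig = records$contig_id,
                            ordinal = records$ordinal,
                            product = records$product,
                            cluster = unname(cluster_of[records$locus_id]),
                            subcluster = unname(cluster_of[records$locus_id]))
  ef <- character(0); et <- character(0)
  for (ctg in unique(records$contig_id)) {
    loci <- records$locus_id[records$contig_id == ctg][
      order(records$ordinal[records$contig_id == ctg])]
    k <- length(loci)
    if (k >= 2) {
      ef <- c(ef, as.vector(rbind(loci[-k], loci[-1])))
      et <- c(et, rep("adjacency", k - 1L))
      if (ctg %in% circular && k >= 3) {
        ef <- c(ef, loci[k], loci[1])
        et <- c(et, "adjacency")
      }
    }
  }
  cl <- unname(cluster_of[records$locus_id])
  for (cid in unique(cl[duplicated(cl)])) {
    loci <- sort(records$locus_id[cl == cid])
    pairs <- utils::combn(loci, 2)
    ef <- c(ef, as.vector(pairs))
    et <- c(et, rep("paralogy", ncol(pairs)))
  }
  if (length(ef)) g <- igraph::add_edges(g, ef, type = et)
  g <- igraph::set_graph_attr(g, "genome_id", genome_id)
  g
}

#' Build all strain graphs of a cohort
#'
#' @param records_list named list of per-genome gene records
#' @param cluster_of locus -> cluster mapping (e.g. \code{cs$cluster_of})
#' @param circular character vector of circular contig IDs (across genomes)
#' @return named list of strain graphs
#' @export
build_strain_graphs <- function(records_list, cluster_of, circular = character(0)) {
  lapply(records_list, build_strain_graph, cluster_of = cluster_of,
         circular = circular)
}

# Adjacency edges of a strain graph as a two-column locus matrix.
strain_adjacency <- function(sg) {
  if (igraph::ecount(sg) == 0) return(cbind(character(0), character(0)))
  e <- igraph::E(sg)[igraph::E(sg)$type == "adjacency"]
  if (!length(e)) return(cbind(character(0), character(0)))
  igraph::ends(sg, e, names = TRUE)
}

# Relabel the subcluster vertex attribute of a strain graph.
relabel_subclusters <- function(sg, sub_of_locus) {
  loci <- igraph::V(sg)$name
  hit <- loci %in% names(sub_of_locus)
  sub <- igraph::V(sg)$subcluster
  sub[hit] <- unname(sub_of_locus[loci[hit]])
  igraph::set_vertex_attr(sg, "subcluster", value = sub)
}
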