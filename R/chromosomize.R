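#' Read a replicon template table
#'
#' Template genomes are finished (or nearly finished) assemblies whose
#' contigs correspond to known replicons. The table has three tab-separated
#' columns: \code{genome_id}, \code{contig_id}, \code{label} (free strings
#' such as \code{chromosome_1} or \code{plasmid_X}), with a header line.
#'
#' @param path TSV path
#' @return data.frame with columns genome_id, contig_id, label
#' @export
read_templates <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome_id", "contig_id", "label")
  if (!all(need %in% names(d))) {
    stop_pg("template file %s must have columns %s", path,
            paste(need, collapse = ", "))
  }
  d[need]
}

#' Assign (sub)clusters to replicons using template genomes
#'
#' For each subcluster, the replicon labels of all its member loci in the
#' template genomes are collected. Exactly one distinct label assigns the
#' subcluster to that replicon; two or more distinct labels (within or
#' across templates, e.g. a repeat present on both chromosomes) give
#' \code{"undetermined"}; a subcluster with no member in any template is
#' \code{"unknown"}. Multiple templates are aggregated by label-set union.
#' Assignment is computed at subcluster level (post paralog split), so a
#' repeat split into replicon-specific contexts can resolve to distinct
#' labels per subcluster.
#'
#' @param templates data.frame as from [read_templates()]
#' @param strain_graphs the cohort's strain graphs (subcluster-labelled)
#' @param g pangenome graph
#' @return named character vector subcluster_id -> class (a replicon label,
#'   "undetermined" or "unknown"), one entry per node of \code{g}
#' @export
assign_chromosomes <- function(templates, strain_graphs, g) {
  genome_ids <- vapply(strain_graphs, igraph::graph_attr, "", name = "genome_id")
  missing_g <- setdiff(unique(templates$genome_id), genome_ids)
  if (length(missing_g)) {
    stop_pg("template genome '%s' is not among the input genomes", missing_g[1])
  }
  for (i in seq_len(nrow(templates))) {
    sg <- strain_graphs[[match(templates$genome_id[i], genome_ids)]]
    if (!(templates$contig_id[i] %in% igraph::V(sg)$contig)) {
      stop_pg("template contig '%s' not found in genome '%s'",
              templates$contig_id[i], templates$genome_id[i])
    }
  }
  occ <- occurrence_table(strain_graphs)
  contig_of <- do.call(rbind, lapply(strain_graphs, function(sg) {
    data.frame(locus = igraph::V(sg)$name, genome = igraph::V(sg)$genome,
               contig = igraph::V(sg)$contig, stringsAsFactors = FALSE)
  }))
  occ$contig <- contig_of$contig[match(occ$locus, contig_of$locus)]
  key <- paste(occ$genome, occ$contig, sep = "\r")
  tkey <- paste(templates$genome_id, templates$contig_id, sep = "\r")
  occ$label <- templates$label[match(key, tkey)]
  labels_by_sub <- lapply(split(occ$label, occ$subcluster),
                          function(x) unique(x[!is.na(x)]))
  nodes <- igraph::V(g)$name
  out <- vapply(nodes, function(s) {
    lab <- labels_by_sub[[s]]
    if (is.null(lab) || length(lab) == 0) "unknown"
    else if (length(lab) == 1) lab
    else "undetermined"
  }, "")
  setNames(out, nodes)
}

#' Annotate graphs with replicon assignments
#'
#' Adds the \code{chromosome_class} attribute to every pangenome node and to
#' every strain-graph locus (via its subcluster's class), the
#' "chromosomizing" step that makes replicon structure visible in graph
#' viewers.
#'
#' @param assignment named vector from [assign_chromosomes()]
#' @param strain_graphs the cohort's strain graphs
#' @param g pangenome graph
#' @return list with annotated \code{pangenome} and \code{strain_graphs}
#' @export
chromosomize_graphs <- function(assignment, strain_graphs, g) {
  g <- igraph::set_vertex_attr(g, "chromosome_class",
                               value = unname(assignment[igraph::V(g)$name]))
  sgs <- lapply(strain_graphs, function(sg) {
    cls <- unname(assignment[igraph::V(sg)$subcluster])
    cls[is.na(cls)] <- "unknown"
    igraph::set_vertex_attr(sg, "chromosome_class", value = cls)
  })
  list(pangenome = g, strain_graphs = sgs)
}
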