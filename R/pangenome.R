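#' Partition thresholds for genome-occupancy classes
#'
#' A cluster present in a fraction \code{f} of the genomes is hard core if
#' \code{f >= hard}, soft core if \code{f >= soft}, shell if
#' \code{f >= shell}, and cloud otherwise. The defaults (0.99 / 0.95 / 0.15)
#' let the hard core absorb occasional losses to sequencing or assembly
#' error, keep the soft core for clusters missing only occasionally, and
#' count anything in less than 15\% of the genomes as cloud. The boundary
#' uses \code{>=} at every threshold and fractions are compared exactly
#' (they are ratios of small integers, so no epsilon is needed).
#'
#' @param hard,soft,shell fractions with 0 < shell < soft < hard <= 1
#' @return a \code{partition_thresholds} list
#' @export
partition_thresholds <- function(hard = 0.99, soft = 0.95, shell = 0.15) {
  if (!(shell > 0 && shell < soft && soft < hard && hard <= 1)) {
    stop_pg("partition thresholds must satisfy 0 < shell < soft < hard <= 1 (got %s/%s/%s)",
            hard, soft, shell)
  }
  structure(list(hard = hard, soft = soft, shell = shell),
            class = "partition_thresholds")
}

#' Build the weighted pangenome graph from strain graphs
#'
#' One node per (sub)cluster label found in the strain graphs. For each
#' unordered pair of labels, the edge weight is the number of distinct
#' genomes in which the two clusters are adjacent (at least one consecutive
#' locus pair mapping to the pair); two adjacencies of the same pair within
#' one genome still contribute 1. Edges with weight below \code{w_min} are
#' omitted, which filters neighbourhoods supported by too few genomes
#' (assembly-error clutter); nodes are never dropped by the filter. A
#' self-loop records a cluster adjacent to itself (tandem copies).
#'
#' Node attributes (strain sets, paralog counts, partition inputs) are
#' populated via [compute_node_attributes()].
#'
#' @param strain_graphs named list of strain graphs covering all genomes
#' @param w_min minimum number of supporting genomes for an edge (>= 1)
#' @param cluster_set optional \code{cluster_set} supplying representative
#'   locus and product annotation per cluster
#' @return an igraph; vertices are (sub)cluster labels, edges carry
#'   \code{weight}, graph attributes record \code{n_genomes}, \code{w_min}
#'   and the genome ID set
#' @export
build_pangenome_graph <- function(strain_graphs, w_min = 1L, cluster_set = NULL) {
  if (w_min < 1) stop_pg("w_min must be >= 1")
  genomes <- vapply(strain_graphs, igraph::graph_attr, "", name = "genome_id")
  labels <- sort(unique(unlist(lapply(strain_graphs, igraph::vertex_attr,
                                      name = "subcluster"))))
  pair_keys <- character(0); pair_genome <- character(0)
  pa <- character(0); pb <- character(0)
  for (sg in strain_graphs) {
    ends <- strain_adjacency(sg)
    if (!nrow(ends)) next
    lab <- setNames(igraph::V(sg)$subcluster, igraph::V(sg)$name)
    a <- unname(lab[ends[, 1]]); b <- unname(lab[ends[, 2]])
    lo <- pmin(a, b); hi <- pmax(a, b)
    key <- paste(lo, hi, sep = "\r")
    keep <- !duplicated(key)
    pair_keys <- c(pair_keys, key[keep])
    pa <- c(pa, lo[keep]); pb <- c(pb, hi[keep])
    pair_genome <- c(pair_genome, rep(igraph::graph_attr(sg, "genome_id"),
                                      sum(keep)))
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(labels), name = labels)
  if (length(pair_keys)) {
    w <- tapply(pair_genome, pair_keys, function(x) length(unique(x)))
    ord <- sort(names(w))
    w <- as.integer(w[ord])
    firsts <- !duplicated(pair_keys)
    a_of <- setNames(pa[firsts], pair_keys[firsts])[ord]
    b_of <- setNames(pb[firsts], pair_keys[firsts])[ord]
    keep <- w >= w_min
    if (any(keep)) {
      g <- igraph::add_edges(g, as.vector(rbind(a_of[keep], b_of[keep])),
                             weight = w[keep])
    }
  }
  g <- igraph::set_graph_attr(g, "n_genomes", length(strain_graphs))
  g <- igraph::set_graph_attr(g, "w_min", as.integer(w_min))
  g <- igraph::set_graph_attr(g, "genomes", join_set(genomes))
  compute_node_attributes(g, strain_graphs, cluster_set)
}

#' Recompute the node attributes of a pangenome graph
#'
#' For every (sub)cluster node, tallies its member loci across the strain
#' graphs: the strain set (genomes containing the cluster), the maximal
#' number of paralogs in any single genome, the total protein count, the
#' average number of proteins per genome carrying the cluster, and the
#' product annotation (copied from the cluster representative when a
#' \code{cluster_set} is supplied, else from the first member locus).
#'
#' @param g pangenome graph
#' @param strain_graphs strain graphs whose \code{subcluster} labels match
#'   the nodes of \code{g}
#' @param cluster_set optional \code{cluster_set} for representative/product
#' @return \code{g} with vertex attributes \code{strains}, \code{n_strains},
#'   \code{max_paralogs}, \code{protein_count}, \code{avg_per_genome},
#'   \code{representative}, \code{product}
#' @export
compute_node_attributes <- function(g, strain_graphs, cluster_set = NULL) {
  occ <- occurrence_table(strain_graphs)
  labels <- igraph::V(g)$name
  occ <- occ[occ$subcluster %in% labels, , drop = FALSE]
  by_lab <- split(occ, occ$subcluster)
  n_strains <- integer(length(labels)); strains <- character(length(labels))
  maxp <- integer(length(labels)); pcount <- integer(length(labels))
  rep_locus <- character(length(labels)); product <- character(length(labels))
  for (i in seq_along(labels)) {
    o <- by_lab[[labels[i]]]
    if (is.null(o) || !nrow(o)) {
      strains[i] <- ""; n_strains[i] <- 0L; maxp[i] <- 0L; pcount[i] <- 0L
      rep_locus[i] <- ""; product[i] <- ""
      next
    }
    strains[i] <- join_set(o$genome)
    n_strains[i] <- length(unique(o$genome))
    maxp[i] <- max(table(o$genome))
    pcount[i] <- nrow(o)
    cl <- o$cluster[1]
    rl <- if (!is.null(cluster_set) && cl %in% cluster_set$clusters$cluster_id) {
      cluster_set$clusters$representative[match(cl, cluster_set$clusters$cluster_id)]
    } else sort(o$locus)[1]
    rep_locus[i] <- rl
    pr <- occ$product[match(rl, occ$locus)]
    if (is.na(pr)) pr <- sort(o$product[nzchar(o$product)])[1] %||% ""
    product[i] <- if (is.na(pr)) "" else pr
  }
  g <- igraph::set_vertex_attr(g, "strains", value = strains)
  g <- igraph::set_vertex_attr(g, "n_strains", value = n_strains)
  g <- igraph::set_vertex_attr(g, "max_paralogs", value = maxp)
  g <- igraph::set_vertex_attr(g, "protein_count", value = pcount)
  g <- igraph::set_vertex_attr(g, "avg_per_genome",
                               value = ifelse(n_strains > 0, pcount / n_strains, 0))
  g <- igraph::set_vertex_attr(g, "representative", value = rep_locus)
  igraph::set_vertex_attr(g, "product", value = product)
}

occurrence_table <- function(strain_graphs) {
  do.call(rbind, lapply(strain_graphs, function(sg) {
    data.frame(locus = igraph::V(sg)$name,
               genome = igraph::V(sg)$genome,
               cluster = igraph::V(sg)$cluster,
               subcluster = igraph::V(sg)$subcluster,
               product = igraph::V(sg)$product,
               stringsAsFactors = FALSE)
  }))
}

#' Assign genome-occupancy partitions to pangenome nodes
#'
#' Computes \code{f = n_strains / n_genomes} per node and labels it
#' \code{hard_core}, \code{soft_core}, \code{shell} or \code{cloud} under
#' the thresholds (see [partition_thresholds()]).
#'
#' @param g pangenome graph with strain sets populated
#' @param thresholds a [partition_thresholds()]
#' @param n_genomes cohort size; defaults to the graph's own record
#' @return \code{g} with a \code{partition} vertex attribute
#' @export
assign_partitions <- function(g, thresholds = partition_thresholds(),
                              n_genomes = igraph::graph_attr(g, "n_genomes")) {
  stopifnot(inherits(thresholds, "partition_thresholds"))
  f <- igraph::V(g)$n_strains / n_genomes
  part <- ifelse(f >= thresholds$hard, "hard_core",
          ifelse(f >= thresholds$soft, "soft_core",
          ifelse(f >= thresholds$shell, "shell", "cloud")))
  igraph::set_vertex_attr(g, "partition", value = part)
}

#' Split paralogous clusters into neighbourhood subclusters
#'
#' A cluster with two or more members in any single genome occupies several
#' genomic locations. The minimal number of unrelated neighbourhoods is
#' determined by building an occurrence graph: one vertex per locus
#' occurrence across all genomes, with two occurrences connected when their
#' flanking cluster sets (the clusters of their adjacent loci, within
#' \code{window} steps on the contig) intersect. Each connected component is
#' one neighbourhood and becomes one subcluster; the original cluster node
#' is replaced by one node per component (IDs suffixed \code{_1},
#' \code{_2}, ... in order of their smallest member locus). Subclusters
#' share the original representative, but strain sets, counts, partitions
#' and incident edges are recomputed from their own occurrences, and the
#' strain graphs are relabelled with the subcluster IDs.
#'
#' Splitting happens on unfiltered adjacency information and the pangenome
#' graph is rebuilt afterwards (re-weighted, then filtered at the graph's
#' \code{w_min}), so rare contexts are split correctly.
#'
#' @param g pangenome graph (from [build_pangenome_graph()])
#' @param strain_graphs the cohort's strain graphs
#' @param cluster_set optional \code{cluster_set} for node annotation
#' @param window flank window size on each side (default 1)
#' @return list with elements \code{pangenome} (rebuilt graph over
#'   subclusters) and \code{strain_graphs} (relabelled)
#' @export
split_paralog_subclusters <- function(g, strain_graphs, cluster_set = NULL,
                                      window = 1L) {
  occ <- occurrence_table(strain_graphs)
  paralogous <- names(which(vapply(split(occ$genome, occ$cluster),
                                   function(x) max(table(x)), 1) >= 2))
  sub_of_locus <- character(0)
  if (length(paralogous)) {
    para_loci <- occ$locus[occ$cluster %in% paralogous]
    flank_of <- flank_map(strain_graphs, para_loci, window)
    for (cid in sort(paralogous)) {
      loci <- occ$locus[occ$cluster == cid]
      comp <- flank_components(loci, flank_of[loci])
      comp_order <- order(vapply(comp, min, ""))
      for (k in seq_along(comp_order)) {
        members <- comp[[comp_order[k]]]
        sub_of_locus[members] <- sprintf("%s_%d", cid, k)
      }
    }
  }
  sgs <- lapply(strain_graphs, relabel_subclusters, sub_of_locus = sub_of_locus)
  pg <- build_pangenome_graph(sgs, w_min = igraph::graph_attr(g, "w_min"),
                              cluster_set = cluster_set)
  list(pangenome = pg, strain_graphs = sgs)
}

# Flanking cluster sets (clusters of loci within `window` adjacency steps)
# for the requested loci, computed one adjacency subgraph per genome.
flank_map <- function(strain_graphs, loci, window) {
  out <- vector("list", length(loci)); names(out) <- loci
  for (sg in strain_graphs) {
    here <- intersect(loci, igraph::V(sg)$name)
    if (!length(here)) next
    adj <- igraph::subgraph_from_edges(
      sg, igraph::E(sg)[igraph::E(sg)$type == "adjacency"],
      delete.vertices = FALSE)
    nbs <- igraph::ego(adj, order = window, nodes = here, mindist = 1)
    cl <- setNames(igraph::V(sg)$cluster, igraph::V(sg)$name)
    for (i in seq_along(here)) {
      out[[here[i]]] <- unique(unname(cl[names(nbs[[i]])]))
    }
  }
  out
}

# Connected components of the shared-flank occurrence graph.
flank_components <- function(loci, flanks) {
  n <- length(loci)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (length(intersect(flanks[[i]], flanks[[j]]))) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  unname(split(loci, roots))
}

#' Run the full graph-construction stage
#'
#' Convenience wrapper chaining [build_pangenome_graph()],
#' [split_paralog_subclusters()] and [assign_partitions()].
#'
#' @param strain_graphs the cohort's strain graphs
#' @param w_min minimum edge support (genomes)
#' @param thresholds a [partition_thresholds()]
#' @param cluster_set optional \code{cluster_set} for node annotation
#' @param split set \code{FALSE} to skip paralog splitting
#' @return list with \code{pangenome} and (possibly relabelled)
#'   \code{strain_graphs}
#' @export
build_pangenome <- function(strain_graphs, w_min = 1L,
                            thresholds = partition_thresholds(),
                            cluster_set = NULL, split = TRUE) {
  pg <- build_pangenome_graph(strain_graphs, w_min = w_min,
                              cluster_set = cluster_set)
  if (split) {
    res <- split_paralog_subclusters(pg, strain_graphs, cluster_set = cluster_set)
    pg <- res$pangenome; strain_graphs <- res$strain_graphs
  }
  pg <- assign_partitions(pg, thresholds)
  list(pangenome = pg, strain_graphs = strain_graphs)
}

#' Write the presence/absence matrix
#'
#' Tabular representation of the presence/absence of every (sub)cluster in
#' every genome: rows are subclusters (sorted by ID), columns are genomes
#' (sorted), cells are 1/0, with a header row of genome IDs.
#'
#' @param g pangenome graph with strain sets populated
#' @param path output TSV path
#' @return the path, invisibly
#' @export
write_presence_absence <- function(g, path) {
  genomes <- split_set(igraph::graph_attr(g, "genomes"))
  labels <- sort(igraph::V(g)$name)
  strains <- igraph::V(g)$strains[order(igraph::V(g)$name)]
  lines <- paste(c("cluster_id", genomes), collapse = "\t")
  for (i in seq_along(labels)) {
    present <- genomes %in% split_set(strains[i])
    lines <- c(lines, paste(c(labels[i], as.integer(present)), collapse = "\t"))
  }
  write_lines_det(lines, path)
}

#' Read a presence/absence matrix written by [write_presence_absence()]
#'
#' @param path TSV path
#' @return integer matrix, rownames = cluster IDs, colnames = genome IDs
#' @export
read_presence_absence <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "integer"
  m
}
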