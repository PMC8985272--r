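# Shared fixtures, generated in code and cached for the whole test session.

.fixture_cache <- new.env(parent = emptyenv())

small_fixture_config <- function(seed = 7L, ...) {
  fixture_config(
    n_genomes = 6L,
    replicons = data.frame(label = c("chromosome_1", "chromosome_2"),
                           n_genes = c(60L, 25L), circular = c(TRUE, TRUE),
                           stringsAsFactors = FALSE),
    n_uniques = 2L, n_orphans = 1L, orphan_carriers = 3L,
    n_variant_pairs = 2L, n_insertions = 1L, insertion_carriers = 2L,
    insertion_length = 3L, indel_loop_lengths = 6L,
    n_paralog_families = 1L, n_cross_replicon_repeats = 1L,
    n_diverged_high = 1L, n_diverged_low = 1L, seed = seed, ...)
}

# Small cohort + one full pipeline run (w_min = 2, the manifest's analysis
# condition), computed once and reused across test files.
small_run <- function() {
  if (is.null(.fixture_cache$small)) {
    co <- generate_cohort(small_fixture_config(),
                          file.path(tempdir(), "pg_small_cohort"))
    res <- run_all(validate_config(overrides = list(
      gff_dir = co$paths$gff_dir, proteins = co$paths$proteins,
      out_dir = file.path(tempdir(), "pg_small_run"),
      w_min = co$config$analysis_w_min,
      templates = co$paths$templates,
      circular_contigs = co$paths$circular,
      max_cycle_len = 20L,   # below the replicon ring sizes of this cohort
      seed = 7L)))
    .fixture_cache$small <- list(cohort = co, run = res)
  }
  .fixture_cache$small
}

# Hand-built gene records for one genome: `layout` gives the cluster label
# of each consecutive gene; contig breaks via a list of layouts.
mk_records <- function(genome, layouts) {
  if (!is.list(layouts)) layouts <- list(layouts)
  out <- list()
  for (ci in seq_along(layouts)) {
    lay <- layouts[[ci]]
    n <- length(lay)
    out[[ci]] <- data.frame(
      genome_id = genome, contig_id = sprintf("%s_c%d", genome, ci),
      ordinal = 0:(n - 1), start = seq(1L, by = 1000L, length.out = n),
      end = seq(900L, by = 1000L, length.out = n), strand = "+",
      locus_id = sprintf("%s_%02d_%02d", genome, ci, seq_len(n)),
      product = "", stringsAsFactors = FALSE)
    attr(out[[ci]], "layout") <- lay
  }
  rec <- do.call(rbind, out)
  attr(rec, "cluster_of") <- setNames(unlist(layouts), rec$locus_id)
  rec
}

# Strain graphs for a list of per-genome layouts.
mk_cohort_graphs <- function(layouts_by_genome, circular = character(0)) {
  recs <- lapply(names(layouts_by_genome),
                 function(g) mk_records(g, layouts_by_genome[[g]]))
  names(recs) <- names(layouts_by_genome)
  cluster_of <- do.call(c, unname(lapply(recs, attr, "cluster_of")))
  list(records = recs,
       cluster_of = cluster_of,
       graphs = build_strain_graphs(recs, cluster_of, circular = circular))
}

# Minimal pangenome graph built directly, for unit-testing detectors and
# partition arithmetic without a cohort.
toy_pangenome <- function(nodes, edges = NULL, n_genomes = 10L) {
  g <- igraph::make_empty_graph(0, directed = FALSE)
  strains <- vapply(nodes$n_strains, function(k)
    paste(sprintf("g%02d", seq_len(k)), collapse = ";"), "")
  g <- igraph::add_vertices(g, nrow(nodes), name = nodes$name,
                            n_strains = nodes$n_strains,
                            strains = strains,
                            partition = nodes$partition %||%
                              rep("shell", nrow(nodes)),
                            avg_per_genome = nodes$avg_per_genome %||%
                              rep(1, nrow(nodes)),
                            max_paralogs = 1L,
                            protein_count = nodes$n_strains,
                            representative = nodes$name, product = "")
  if (!is.null(edges) && nrow(edges)) {
    g <- igraph::add_edges(g, as.vector(t(as.matrix(edges[, 1:2]))),
                           weight = edges$weight %||% rep(1L, nrow(edges)))
  }
  g <- igraph::set_graph_attr(g, "n_genomes", n_genomes)
  g <- igraph::set_graph_attr(g, "w_min", 1L)
  igraph::set_graph_attr(g, "genomes",
                         paste(sprintf("g%02d", seq_len(n_genomes)),
                               collapse = ";"))
}
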