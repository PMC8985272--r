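test_that("strain graph adjacency follows contig structure", {
  one <- mk_cohort_graphs(list(g1 = c("A", "B", "C")))
  sg <- one$graphs$g1
  el <- igraph::as_edgelist(sg)
  keys <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  loci <- igraph::V(sg)$name
  expect_setequal(keys, c(paste(loci[1], loci[2]), paste(loci[2], loci[3])))

  # contig break severs adjacency
  two <- mk_cohort_graphs(list(g1 = list(c("A", "B"), c("C", "D"))))
  expect_equal(igraph::ecount(two$graphs$g1), 2L)
  comp <- igraph::components(two$graphs$g1)
  expect_equal(comp$no, 2L)

  # paralogy clique per (genome, cluster)
  par <- mk_cohort_graphs(list(g1 = c("A", "P", "B", "P")))
  et <- igraph::E(par$graphs$g1)$type
  expect_equal(sum(et == "paralogy"), 1L)
  pe <- igraph::ends(par$graphs$g1, igraph::E(par$graphs$g1)[et == "paralogy"])
  expect_setequal(igraph::vertex_attr(par$graphs$g1, "cluster",
                                      as.vector(pe)), "P")

  # circular contig closes the ring
  rec <- mk_records("g1", c("A", "B", "C", "D"))
  circ <- build_strain_graph(rec, attr(rec, "cluster_of"),
                             circular = "g1_c1")
  expect_equal(igraph::ecount(circ), 4L)

  # missing cluster assignment is an error naming the locus
  expect_error(build_strain_graph(rec, attr(rec, "cluster_of")[-2]),
               rec$locus_id[2])
})

test_that("pangenome edge weights count supporting genomes", {
  lay <- c("c1", "c2", "c3", "c4", "c5")
  co <- mk_cohort_graphs(list(gA = lay, gB = lay))
  pg <- build_pangenome_graph(co$graphs, w_min = 1)
  expect_equal(igraph::vcount(pg), 5L)
  expect_equal(igraph::ecount(pg), 4L)
  expect_true(all(igraph::E(pg)$weight == 2))

  # an edge below w_min disappears, its nodes stay
  co2 <- mk_cohort_graphs(list(gA = c("c1", "c9"), gB = c("c1", "c2"),
                               gC = c("c1", "c2")))
  pg2 <- build_pangenome_graph(co2$graphs, w_min = 2)
  expect_true(all(c("c1", "c2", "c9") %in% igraph::V(pg2)$name))
  expect_equal(igraph::ecount(pg2), 1L)
  expect_error(build_pangenome_graph(co2$graphs, w_min = 0), "w_min")
})

test_that("edge weights equal the brute-force per-genome recount", {
  run <- small_run()
  co <- run$cohort
  recs <- read_gff3_dir(co$paths$gff_dir)
  circ <- utils::read.delim(co$paths$circular)$contig_id
  occ <- pangraphr:::occurrence_table(run$run$strain_graphs)
  label_of <- setNames(occ$subcluster, occ$locus)
  oracle <- brute_edge_weights(recs, label_of, circular = circ)
  # recompute unfiltered, then compare every weight
  pg1 <- build_pangenome_graph(run$run$strain_graphs, w_min = 1)
  got <- graph_edge_weights(pg1)
  expect_setequal(names(got), names(oracle))
  expect_equal(got[sort(names(got))], oracle[sort(names(oracle))],
               ignore_attr = TRUE)
  # weight conservation: summed weights equal per-genome adjacency pair
  # counts (unique label pairs per genome)
  expect_equal(sum(got), sum(oracle))
})

test_that("paralog splitting follows shared-flank neighbourhoods", {
  # two contexts with disjoint flanks in every genome -> 2 subclusters
  lay <- c("u1", "P", "u2", "x", "v1", "P", "v2")
  co <- mk_cohort_graphs(list(gA = lay, gB = lay, gC = lay))
  pg <- build_pangenome_graph(co$graphs, w_min = 1)
  res <- split_paralog_subclusters(pg, co$graphs)
  subs <- grep("^P_", igraph::V(res$pangenome)$name, value = TRUE)
  expect_setequal(subs, c("P_1", "P_2"))
  # occurrence conservation and strain-set union
  ns <- igraph::V(res$pangenome)$protein_count[
    match(subs, igraph::V(res$pangenome)$name)]
  expect_equal(sum(ns), 6L)
  st <- unlist(lapply(subs, function(s) pangraphr::split_set(
    igraph::V(res$pangenome)$strains[match(s, igraph::V(res$pangenome)$name)])))
  expect_setequal(unique(st), c("gA", "gB", "gC"))

  # contexts sharing one flank cluster merge into a single subcluster
  lay2 <- c("u1", "P", "S", "x", "v1", "P", "S")
  co2 <- mk_cohort_graphs(list(gA = lay2, gB = lay2))
  pg2 <- build_pangenome_graph(co2$graphs, w_min = 1)
  res2 <- split_paralog_subclusters(pg2, co2$graphs)
  expect_setequal(grep("^P_", igraph::V(res2$pangenome)$name, value = TRUE),
                  "P_1")

  # tandem copies: the copies flank each other, so they stay one
  # neighbourhood (single subcluster) and leave a self-loop
  lay3 <- c("a", "Q", "Q", "b")
  co3 <- mk_cohort_graphs(list(gA = lay3, gB = lay3))
  pg3 <- build_pangenome_graph(co3$graphs, w_min = 1)
  res3 <- split_paralog_subclusters(pg3, co3$graphs)
  expect_setequal(grep("^Q", igraph::V(res3$pangenome)$name, value = TRUE),
                  "Q_1")
  expect_true(any(igraph::which_loop(res3$pangenome)))

  # distinct disjoint contexts in the same genome split apart
  lay4 <- c("a", "R", "b", "x", "c", "R", "d")
  co4 <- mk_cohort_graphs(list(gA = lay4))
  res4 <- split_paralog_subclusters(
    build_pangenome_graph(co4$graphs, w_min = 1), co4$graphs)
  expect_setequal(grep("^R_", igraph::V(res4$pangenome)$name, value = TRUE),
                  c("R_1", "R_2"))
})

test_that("partition arithmetic follows the occupancy thresholds", {
  g <- toy_pangenome(data.frame(
    name = c("full", "most", "half", "rare", "edge"),
    n_strains = c(100L, 96L, 50L, 10L, 15L)), n_genomes = 100L)
  g <- assign_partitions(g, partition_thresholds(), n_genomes = 100)
  part <- setNames(igraph::V(g)$partition, igraph::V(g)$name)
  expect_equal(unname(part[c("full", "most", "half", "rare")]),
               c("hard_core", "soft_core", "shell", "cloud"))
  # boundary f = shell threshold exactly lands in shell (>= convention)
  expect_equal(unname(part["edge"]), "shell")

  g1 <- toy_pangenome(data.frame(name = "solo", n_strains = 1L), n_genomes = 1L)
  g1 <- assign_partitions(g1, n_genomes = 1)
  expect_equal(igraph::V(g1)$partition, "hard_core")

  expect_error(partition_thresholds(shell = 0.96), "shell < soft")
  # labels are exhaustive and mutually exclusive on a real cohort
  pg <- small_run()$run$pangenome
  expect_true(all(igraph::V(pg)$partition %in%
                    c("hard_core", "soft_core", "shell", "cloud")))
})

test_that("node attributes match an independent tally of the raw records", {
  co <- mk_cohort_graphs(list(g1 = c("A", "K", "B", "K"),
                              g2 = c("A", "K", "B"),
                              g3 = c("A", "K", "B")))
  pg <- build_pangenome_graph(co$graphs, w_min = 1)
  i <- match("K", igraph::V(pg)$name)
  expect_equal(igraph::V(pg)$max_paralogs[i], 2L)
  expect_equal(igraph::V(pg)$protein_count[i], 4L)
  expect_equal(igraph::V(pg)$avg_per_genome[i], 4 / 3)
  j <- match("A", igraph::V(pg)$name)
  expect_equal(igraph::V(pg)$max_paralogs[j], 1L)
  expect_equal(igraph::V(pg)$avg_per_genome[j], 1.0)

  # fixture-wide: independent tally over raw GFF3-derived records
  run <- small_run()
  recs <- read_gff3_dir(run$cohort$paths$gff_dir)
  occ <- pangraphr:::occurrence_table(run$run$strain_graphs)
  tal <- tally_oracle(recs, setNames(occ$subcluster, occ$locus))
  pg2 <- run$run$pangenome
  idx <- match(tal$label, igraph::V(pg2)$name)
  expect_false(anyNA(idx))
  expect_equal(igraph::V(pg2)$n_strains[idx], tal$n_strains)
  expect_equal(igraph::V(pg2)$max_paralogs[idx], tal$max_paralogs)
  expect_equal(igraph::V(pg2)$protein_count[idx], tal$protein_count)
})

test_that("raising w_min never adds edges and never drops nodes", {
  sgs <- small_run()$run$strain_graphs
  prev_edges <- NULL; prev_nodes <- NULL
  for (w in 1:3) {
    pg <- build_pangenome_graph(sgs, w_min = w)
    nodes <- sort(igraph::V(pg)$name)
    edges <- names(graph_edge_weights(pg))
    if (!is.null(prev_edges)) {
      expect_true(all(edges %in% prev_edges))
      expect_lte(length(edges), length(prev_edges))
      expect_identical(nodes, prev_nodes)
    }
    prev_edges <- edges; prev_nodes <- nodes
  }
})
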