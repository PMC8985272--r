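# A reusable toy graph: a core ring c1..c6 plus planted structures, and a
# separate InDel loop component La-Lp-Lq-Lb-Lr-Ls (two alternative 2-gene
# paths between anchors La/Lb).
toy_patterns_graph <- function() {
  nodes <- data.frame(
    name = c(sprintf("c%d", 1:6),       # core ring
             "iso_multi", "iso_single",  # isolated nodes
             "v1", "v2",                 # variant bubble between c2/c5
             "x1", "x2", "x3",           # insertion path between c5/c6
             "La", "Lp", "Lq", "Lb", "Lr", "Ls"),
    n_strains = c(rep(10L, 6), 3L, 1L, 5L, 5L, 2L, 2L, 2L,
                  10L, 6L, 6L, 10L, 4L, 4L),
    partition = c(rep("hard_core", 6), "shell", "cloud",
                  "shell", "shell", "cloud", "cloud", "cloud",
                  "hard_core", "shell", "shell", "hard_core",
                  "shell", "shell"),
    stringsAsFactors = FALSE)
  # variant anchors c2/c5 are not ring-adjacent and no single ring node
  # shares the {c2, c5} neighbour set, so the bubble is a pure variant
  edges <- data.frame(
    from = c(sprintf("c%d", 1:6), "c2", "c2", "v1", "v2",
             "c5", "x1", "x2", "x3",
             "La", "Lp", "Lq", "Lb", "Lr", "Ls"),
    to   = c(sprintf("c%d", c(2:6, 1)), "v1", "v2", "c5", "c5",
             "x1", "x2", "x3", "c6",
             "Lp", "Lq", "Lb", "Lr", "Ls", "La"),
    weight = c(rep(10L, 6), 5L, 5L, 5L, 5L, 2L, 2L, 2L, 2L,
               6L, 6L, 6L, 4L, 4L, 4L),
    stringsAsFactors = FALSE)
  toy_pangenome(nodes, edges, n_genomes = 10L)
}

test_that("orphans are isolated nodes in two or more genomes", {
  g <- toy_patterns_graph()
  expect_equal(find_orphans(g), "iso_multi")
  # a single-genome isolated node is a unique, not an orphan
  expect_false("iso_single" %in% find_orphans(g))
  # one edge disqualifies
  expect_false("x1" %in% find_orphans(g))
})

test_that("uniques are single-genome clusters regardless of connectivity", {
  g <- toy_patterns_graph()
  expect_equal(find_uniques(g), "iso_single")
  g2 <- igraph::set_vertex_attr(g, "n_strains",
                                index = match("v1", igraph::V(g)$name),
                                value = 1L)
  expect_setequal(find_uniques(g2), c("iso_single", "v1"))  # has 2 edges
})

test_that("variant bubbles group internal nodes by their anchor set", {
  g <- toy_patterns_graph()
  vars <- find_variants(g)
  expect_length(vars, 1L)
  expect_setequal(vars[[1]]$members, c("v1", "v2"))
  expect_setequal(vars[[1]]$anchors, c("c2", "c5"))
  # internal nodes have degree <= 2 (self-check of the definition)
  deg <- igraph::degree(g)
  expect_true(all(deg[match(vars[[1]]$members, igraph::V(g)$name)] <= 2))

  # a single node between two anchors is no variant group
  g2 <- igraph::delete_vertices(g, "v2")
  expect_length(find_variants(g2), 0L)

  # dead-end variants hanging off a single anchor
  g3 <- igraph::add_vertices(toy_patterns_graph(), 2,
                             name = c("d1", "d2"), n_strains = c(2L, 2L),
                             strains = c("g01;g02", "g03;g04"),
                             partition = "cloud", avg_per_genome = 1,
                             max_paralogs = 1L, protein_count = 2L,
                             representative = c("d1", "d2"), product = "")
  g3 <- igraph::add_edges(g3, c("c1", "d1", "c1", "d2"), weight = 1L)
  vars3 <- find_variants(g3)
  dead <- vars3[vapply(vars3, function(v) identical(v$anchors, "c1"),
                       logical(1))]
  expect_length(dead, 1L)
  expect_setequal(dead[[1]]$members, c("d1", "d2"))
})

test_that("insertions need a direct anchor edge and shell/cloud interior", {
  g <- toy_patterns_graph()
  ins <- find_insertions(g)
  expect_setequal(ins$node, c("x1", "x2", "x3"))
  expect_true(all(ins$anchor_a == "c5" & ins$anchor_b == "c6"))
  # reported degree equals a recount of incident edges
  deg <- igraph::degree(igraph::simplify(g, remove.loops = TRUE,
                                         remove.multiple = FALSE))
  expect_equal(ins$degree,
               unname(deg[match(ins$node, igraph::V(g)$name)]))

  # a core node on the alternative path disqualifies it
  g2 <- igraph::set_vertex_attr(g, "partition",
                                index = match("x2", igraph::V(g)$name),
                                value = "hard_core")
  expect_equal(nrow(find_insertions(g2)), 0L)

  # the insertion path is bounded by max_len
  expect_equal(nrow(find_insertions(g, max_len = 2)), 0L)
})

test_that("InDel cycles are basis cycles with more than four nodes", {
  g <- toy_patterns_graph()
  ind <- find_indels(g)
  lens <- vapply(ind, length, 1L)
  keys <- vapply(ind, function(cy) paste(sort(cy), collapse = ";"), "")
  # no reported cycle is 4 nodes or fewer (the variant bubble's 4-cycle
  # is excluded)
  expect_true(all(lens > 4))
  # the planted two-path loop is reported as one 6-cycle
  expect_true(paste(sort(c("La", "Lp", "Lq", "Lb", "Lr", "Ls")),
                    collapse = ";") %in% keys)
  # the insertion bubble (direct anchor edge + 3-gene path) is a 5-cycle
  expect_true(paste(sort(c("c5", "c6", "x1", "x2", "x3")),
                    collapse = ";") %in% keys)
  six <- ind[[match(paste(sort(c("La", "Lp", "Lq", "Lb", "Lr", "Ls")),
                          collapse = ";"), keys)]]
  # canonical rotation: starts at smallest node, toward smaller neighbour
  expect_equal(six[1], "La")
  expect_equal(six[2], "Lp")
  # cycle validity: consecutive nodes are connected by edges
  for (cy in ind) {
    pairs <- cbind(cy, c(cy[-1], cy[1]))
    ids <- igraph::get_edge_ids(g, as.vector(t(pairs)), error = FALSE)
    expect_true(all(ids > 0))
    expect_equal(anyDuplicated(cy), 0L)
  }
  # triangles and 4-cycles are never reported
  tri <- toy_pangenome(data.frame(name = c("a", "b", "c"),
                                  n_strains = rep(5L, 3)),
                       data.frame(from = c("a", "b", "c"),
                                  to = c("b", "c", "a"), weight = 1L))
  expect_length(find_indels(tri), 0L)
})

test_that("pattern outputs are deterministic and faithful", {
  g <- toy_patterns_graph()
  rep1 <- detect_patterns(g)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_pattern_outputs(rep1, g, d1)
  write_pattern_outputs(detect_patterns(g), g, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  expect_equal(length(readLines(file.path(d1, "indels.txt"))),
               length(rep1$indels))
  expect_equal(length(readLines(file.path(d1, "orphans.txt"))), 1L)

  # empty report: header-only / empty files plus empty subgraphs
  lonely <- toy_pangenome(data.frame(name = "n1", n_strains = 5L),
                          n_genomes = 10L)
  lonely <- assign_partitions(lonely)
  d0 <- withr::local_tempdir()
  write_pattern_outputs(detect_patterns(lonely), lonely, d0)
  expect_equal(length(readLines(file.path(d0, "indels.txt"))), 0L)
  expect_equal(length(readLines(file.path(d0, "insertions.tsv"))), 1L)
})

test_that("highlight overlays mark exactly the pattern elements", {
  g <- toy_patterns_graph()
  six <- c("La", "Lp", "Lq", "Lb", "Lr", "Ls")
  pat <- igraph::induced_subgraph(g, six)
  h <- highlight_subgraph(g, pat)
  expect_equal(sum(igraph::V(h)$highlight), 6L)
  expect_equal(sum(igraph::E(h)$highlight), 6L)
  # strip is the inverse
  expect_true(pangraphr:::graph_identical(strip_highlight(h), g))
  # empty pattern: nothing marked
  h0 <- highlight_subgraph(g, igraph::make_empty_graph(0, directed = FALSE))
  expect_equal(sum(igraph::V(h0)$highlight), 0L)
  # unknown node is an error listing it
  badp <- toy_pangenome(data.frame(name = "zz", n_strains = 1L))
  expect_error(highlight_subgraph(g, badp), "zz")
})
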