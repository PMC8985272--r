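test_that("mutate_protein hits the target identity deterministically", {
  set.seed(3)
  s <- random_aa_seq(100)
  expect_identical(mutate_protein(s, 1.0, seed = 1), s)
  m <- mutate_protein(s, 0.75, seed = 5)
  id <- sequence_identity(s, m)
  expect_gte(id, 0.73); expect_lte(id, 0.77)
  expect_identical(mutate_protein(s, 0.75, seed = 5),
                   mutate_protein(s, 0.75, seed = 5))
  expect_false(identical(mutate_protein(s, 0.75, seed = 6), m))
  # unattainable on a very short sequence
  expect_error(mutate_protein("MKVA", 0.9, seed = 1), "longer")
  expect_error(mutate_protein(s, 0), "target_identity")
})

test_that("fixture configuration is validated", {
  expect_error(fixture_config(n_uniques = -1), "planted counts")
  expect_error(fixture_config(indel_loop_lengths = 2L), "at least 3")
  expect_error(fixture_config(orphan_carriers = 99L), "carrier")
  expect_error(fixture_config(
    n_cross_replicon_repeats = 1L,
    replicons = data.frame(label = "c1", n_genes = 50L, circular = TRUE)),
    "two replicons")
})

test_that("generated cohorts are deterministic and self-consistent", {
  cfg <- small_fixture_config()
  d1 <- file.path(withr::local_tempdir(), "a")
  d2 <- file.path(withr::local_tempdir(), "b")
  co1 <- generate_cohort(cfg, d1)
  co2 <- generate_cohort(cfg, d2)
  for (rel in c("gff/g01.gff3", "gff/g06.gff3", "proteins.faa",
                "manifest.tsv", "templates.tsv", "clades.tsv")) {
    expect_identical(readLines(file.path(d1, rel)),
                     readLines(file.path(d2, rel)), label = rel)
  }
  # a different seed changes the cohort
  co3 <- generate_cohort(small_fixture_config(seed = 8L),
                         file.path(withr::local_tempdir(), "c"))
  expect_false(identical(readLines(file.path(d1, "proteins.faa")),
                         readLines(file.path(co3$dir, "proteins.faa"))))

  # protein FASTA IDs exactly cover the GFF3 CDS IDs
  recs <- read_gff3_dir(co1$paths$gff_dir)
  prot <- read_protein_fasta(co1$paths$proteins)
  expect_setequal(names(prot), unlist(lapply(recs, `[[`, "locus_id")))

  # variant alleles sit below the clustering floor
  man <- co1$manifest
  prot_by_label <- function(lab) {
    loci <- split_set(man$loci[man$label == lab])
    unname(prot[loci[1]])
  }
  for (k in seq_len(cfg$n_variant_pairs)) {
    expect_lt(sequence_identity(prot_by_label(sprintf("var%d_a", k)),
                                prot_by_label(sprintf("var%d_b", k))), 0.70)
  }
})

test_that("an unplanted circular cohort yields a clean ring pangenome", {
  cfg <- fixture_config(
    n_genomes = 3L,
    replicons = data.frame(label = "chromosome_1", n_genes = 50L,
                           circular = TRUE, stringsAsFactors = FALSE),
    n_uniques = 0L, n_orphans = 0L, n_variant_pairs = 0L, n_insertions = 0L,
    indel_loop_lengths = integer(0), n_paralog_families = 0L,
    n_cross_replicon_repeats = 0L, n_diverged_high = 0L, n_diverged_low = 0L,
    seed = 11L)
  co <- generate_cohort(cfg, withr::local_tempdir())
  recs <- read_gff3_dir(co$paths$gff_dir)
  prot <- read_protein_fasta(co$paths$proteins)
  cs <- iterative_cluster(prot, cascade_config(3, seed = 11L))
  circ <- utils::read.delim(co$paths$circular)$contig_id
  sgs <- build_strain_graphs(recs, cs$cluster_of, circular = circ)
  pg <- build_pangenome(sgs, w_min = 1)$pangenome
  expect_equal(igraph::vcount(pg), 50L)
  expect_equal(igraph::ecount(pg), 50L)        # a single 50-node cycle
  expect_true(all(igraph::E(pg)$weight == 3))
  expect_true(all(igraph::degree(pg) == 2))
  expect_true(all(igraph::V(pg)$partition == "hard_core"))
  # the brute-force recount agrees edge for edge
  occ <- pangraphr:::occurrence_table(sgs)
  oracle <- brute_edge_weights(recs, setNames(occ$subcluster, occ$locus),
                               circular = circ)
  got <- graph_edge_weights(pg)
  expect_equal(got[sort(names(got))], oracle[sort(names(oracle))],
               ignore_attr = TRUE)
  # no structure planted: pattern report is empty
  rep <- detect_patterns(pg, max_cycle_len = 20)
  expect_length(rep$orphans, 0L)
  expect_length(rep$uniques, 0L)
  expect_length(rep$variants, 0L)
  expect_equal(nrow(rep$insertions), 0L)
  expect_length(rep$indels, 0L)
})

test_that("manifest structure matches the configuration counts", {
  run <- small_run()
  man <- run$cohort$manifest
  cfg <- run$cohort$config
  expect_equal(sum(man$type == "unique"), cfg$n_uniques)
  expect_equal(sum(man$type == "orphan"), cfg$n_orphans)
  expect_equal(sum(man$type == "variant" & man$role != "anchor_pair"),
               2L * cfg$n_variant_pairs)
  expect_equal(sum(man$type == "insertion" & man$role != "anchor_pair"),
               cfg$n_insertions * cfg$insertion_length)
  expect_equal(sum(man$type == "backbone"), sum(cfg$replicons$n_genes))
  # manifest loci are real loci of the cohort
  prot <- read_protein_fasta(run$cohort$paths$proteins)
  expect_true(all(unlist(lapply(man$loci, split_set)) %in% names(prot)))
})
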