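test_that("greedy clustering basics", {
  p <- setNames(rep("MKVALLERTAGHW", 5), paste0("x", 1:5))
  cs <- greedy_cluster(p, 0.9)
  expect_equal(nrow(cs$clusters), 1L)
  expect_setequal(cs$members[[1]], names(p))

  q <- c(a1 = "MMMMMMMMMMMMMMMM", b1 = "WWWWWWWWWWWWWWWW")
  cs2 <- greedy_cluster(q, 0.70)
  expect_equal(nrow(cs2$clusters), 2L)

  # partition property: every locus in exactly one cluster
  set.seed(5)
  r <- setNames(replicate(25, random_aa_seq(40)), sprintf("r%02d", 1:25))
  cs3 <- greedy_cluster(r, 0.7)
  expect_equal(sum(cs3$clusters$size), length(r))
  expect_setequal(names(cs3$cluster_of), names(r))
})

test_that("greedy membership satisfies the identity-to-representative bound", {
  set.seed(23)
  base <- replicate(4, random_aa_seq(60))
  prot <- character(0)
  for (f in 1:4) for (k in 1:5) {
    prot[sprintf("f%d_m%d", f, k)] <- mutate_protein(base[f], 0.92,
                                                     seed = f * 10 + k)
  }
  prot <- c(prot, setNames(replicate(10, random_aa_seq(50)),
                           sprintf("bg%02d", 1:10)))
  t <- 0.70
  cs <- greedy_cluster(prot, t)
  seq_of <- prot
  for (i in seq_len(nrow(cs$clusters))) {
    rep_seq <- seq_of[cs$clusters$representative[i]]
    for (m in cs$members[[i]]) {
      # oracle max-match identity bounds the implementation's identity
      # from above, so the >= t guarantee transfers
      expect_gte(nw_oracle(seq_of[m], rep_seq)$max_identity, t)
    }
  }
})

test_that("greedy result matches an exhaustive-alignment reference on clear margins", {
  set.seed(41)
  base <- replicate(3, random_aa_seq(50))
  prot <- character(0)
  for (f in 1:3) for (k in 1:4) {
    prot[sprintf("fam%d_%d", f, k)] <- mutate_protein(base[f], 0.95,
                                                      seed = f * 7 + k)
  }
  prot <- c(prot, setNames(replicate(8, random_aa_seq(45)),
                           sprintf("solo%d", 1:8)))
  got <- lapply(greedy_cluster(prot, 0.70)$members, sort)
  want <- reference_greedy_members(prot, 0.70)
  expect_setequal(vapply(got, paste, "", collapse = ";"),
                  vapply(want, paste, "", collapse = ";"))
})

test_that("cascade retention freezes clusters at the right tiers", {
  expect_error(cascade_config(0), "positive")
  expect_error(cascade_config(4, thresholds = c(0.9, 0.95)), "decreasing")
  expect_error(cascade_config(4, thresholds = c(0.9, 1.2)), "\\(0, 1\\]")
  expect_equal(cascade_config(4)$thresholds, c(0.90, 0.80, 0.75, 0.70))

  # n_genomes = 1: retention is always satisfied, everything freezes at 0.90
  set.seed(9)
  p1 <- setNames(replicate(6, random_aa_seq(40)), sprintf("u%d", 1:6))
  cs1 <- iterative_cluster(p1, cascade_config(1))
  expect_true(all(cs1$clusters$tier == 0.90))

  # family A: one copy per genome at high identity -> frozen at 0.90;
  # family B: 2 copies at ~0.72 mutual identity -> kept only at 0.70
  set.seed(13)
  baseA <- random_aa_seq(80)
  protA <- setNames(lapply(1:4, function(g) mutate_protein(baseA, 0.98, seed = g)),
                    sprintf("A_g%d", 1:4))
  b1 <- random_aa_seq(80)
  protB <- c(B_g1 = b1, B_g2 = mutate_protein(b1, 0.72, seed = 99))
  prot <- c(unlist(protA), protB)
  cs <- iterative_cluster(prot, cascade_config(n_genomes = 4))
  tier_of <- setNames(rep(cs$clusters$tier, cs$clusters$size),
                      unlist(cs$members))
  expect_true(all(tier_of[names(protA)] == 0.90))
  expect_true(all(tier_of[names(protB)] == 0.70))
  expect_equal(length(unique(cs$cluster_of[names(protB)])), 1L)

  # homogeneous input collapses to one cluster in round one
  protH <- setNames(rep(random_aa_seq(50), 5), sprintf("h%d", 1:5))
  csh <- iterative_cluster(protH, cascade_config(4))
  expect_equal(nrow(csh$clusters), 1L)
  expect_equal(csh$clusters$tier, 0.90)

  # genome_count retention counts genomes, not paralogous copies
  protP <- setNames(rep(random_aa_seq(50), 4),
                    c("g1_a", "g1_b", "g1_c", "g2_a"))
  gof <- setNames(c("g1", "g1", "g1", "g2"), names(protP))
  cs_p <- iterative_cluster(protP, cascade_config(3, retention = "protein_count"))
  expect_equal(cs_p$clusters$tier, 0.90)  # 4 proteins >= 3
  cs_g <- iterative_cluster(protP, cascade_config(3, retention = "genome_count"),
                            genome_of = gof)
  expect_equal(cs_g$clusters$tier, 0.70)  # only 2 genomes < 3
})

test_that("random representative choice is seeded, stable and uniform", {
  expect_equal(choose_representative("only", "c1"), "only")
  members <- c("m1", "m2", "m3", "m4")
  expect_identical(choose_representative(members, "c9", seed = 5),
                   choose_representative(members, "c9", seed = 5))
  picks <- vapply(1:10000, function(s)
    choose_representative(members, "c9", seed = s), "")
  freq <- table(picks) / 10000
  expect_true(all(abs(freq - 0.25) <= 0.02))
})

test_that("cluster file and representative FASTA round trip", {
  cs0 <- greedy_cluster(character(0), 0.9)
  f0 <- withr::local_tempfile()
  write_cluster_file(cs0, f0)
  expect_equal(nrow(read_cluster_file(f0)$clusters), 0L)

  set.seed(2)
  prot <- setNames(c(replicate(6, random_aa_seq(40)),
                     rep(random_aa_seq(35), 2)),
                   sprintf("p%02d", 1:8))
  cs <- iterative_cluster(prot, cascade_config(2))
  f <- withr::local_tempfile()
  write_cluster_file(cs, f)
  cs2 <- read_cluster_file(f)
  expect_equal(cs2$clusters[order(cs2$clusters$cluster_id), ],
               cs$clusters[order(cs$clusters$cluster_id), ],
               ignore_attr = TRUE)
  expect_equal(cs2$members[sort(names(cs2$members))],
               lapply(cs$members[sort(names(cs$members))], sort))

  faa <- withr::local_tempfile(fileext = ".faa")
  write_representative_fasta(cs, prot, faa,
                             products = setNames(rep("prod X", 8), names(prot)))
  reps <- read_protein_fasta(faa)
  expect_length(reps, nrow(cs$clusters))
  expect_setequal(names(reps), cs$clusters$cluster_id)
})
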