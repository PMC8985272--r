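#' Configuration for the synthetic cohort generator
#'
#' Describes a cohort of annotated bacterial genomes sharing a collinear
#' core backbone across one or more replicons, with structural features
#' planted at controlled positions: unique genes (one genome), orphan-style
#' mobile genes (several genomes, unrelated positions in each), variant
#' pairs (two alleles of one slot, mutual identity below the clustering
#' floor, split across genome subsets), insertions (contiguous novel genes
#' in a strain subset between anchors kept adjacent elsewhere), InDel loops
#' (two alternative paths between anchors across genome subsets), paralog
#' families (one gene repeated in distinct flank contexts in every genome)
#' and a cross-replicon repeat cassette (an IS-element-like gene pair
#' planted on both replicons, whose shared flank keeps it one subcluster
#' spanning replicons). A subset of backbone families carries per-genome
#' sequence divergence to exercise the clustering cascade tiers.
#'
#' The default cohort is 20 genomes over a 400-gene circular backbone (two
#' circular replicons of 300 and 100 genes) with 5 uniques, 3 orphans (5
#' carriers each), 4 variant pairs, 4 three-gene insertions in 4 carriers,
#' 3 six-node InDel loops and 2 two-context paralog families.
#' \code{analysis_w_min} records the minimum edge weight the planted
#' expectations are defined under: 2, since weight-1 edges are exactly what
#' carries the unrelated neighbourhoods of orphans and uniques.
#'
#' @param n_genomes cohort size
#' @param replicons data.frame with columns \code{label}, \code{n_genes},
#'   \code{circular}
#' @param n_uniques,n_orphans,orphan_carriers planted unique/orphan counts
#' @param n_variant_pairs planted two-allele variant slots
#' @param n_insertions,insertion_carriers,insertion_length planted insertions
#' @param indel_loop_lengths total node count (anchors + both paths) of each
#'   planted InDel loop; lengths 3-4 are allowed to probe the detector's
#'   more-than-four-nodes boundary and are expected \emph{not} to be
#'   reported
#' @param n_paralog_families two-context repeated genes
#' @param n_cross_replicon_repeats IS-like cassettes planted on two replicons
#' @param n_diverged_high,diverged_high_identity,n_diverged_low,diverged_low_identity
#'   backbone families with per-genome divergence at the given target
#'   identity to the family base sequence
#' @param protein_length min/max backbone protein length (residues)
#' @param analysis_w_min the edge-weight floor the manifest expectations
#'   assume
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the configuration and this seed
#' @return a \code{fixture_config} list
#' @export
fixture_config <- function(n_genomes = 20L,
                           replicons = data.frame(
                             label = c("chromosome_1", "chromosome_2"),
                             n_genes = c(300L, 100L),
                             circular = c(TRUE, TRUE),
                             stringsAsFactors = FALSE),
                           n_uniques = 5L,
                           n_orphans = 3L, orphan_carriers = 5L,
                           n_variant_pairs = 4L,
                           n_insertions = 4L, insertion_carriers = 4L,
                           insertion_length = 3L,
                           indel_loop_lengths = c(6L, 6L, 6L),
                           n_paralog_families = 2L,
                           n_cross_replicon_repeats = 1L,
                           n_diverged_high = 3L, diverged_high_identity = 0.98,
                           n_diverged_low = 3L, diverged_low_identity = 0.93,
                           protein_length = c(60L, 120L),
                           analysis_w_min = 2L,
                           seed = 42L) {
  cfg <- list(n_genomes = as.integer(n_genomes), replicons = replicons,
              n_uniques = as.integer(n_uniques),
              n_orphans = as.integer(n_orphans),
              orphan_carriers = as.integer(orphan_carriers),
              n_variant_pairs = as.integer(n_variant_pairs),
              n_insertions = as.integer(n_insertions),
              insertion_carriers = as.integer(insertion_carriers),
              insertion_length = as.integer(insertion_length),
              indel_loop_lengths = as.integer(indel_loop_lengths),
              n_paralog_families = as.integer(n_paralog_families),
              n_cross_replicon_repeats = as.integer(n_cross_replicon_repeats),
              n_diverged_high = as.integer(n_diverged_high),
              diverged_high_identity = diverged_high_identity,
              n_diverged_low = as.integer(n_diverged_low),
              diverged_low_identity = diverged_low_identity,
              protein_length = as.integer(protein_length),
              analysis_w_min = as.integer(analysis_w_min),
              seed = as.integer(seed))
  counts <- c(cfg$n_uniques, cfg$n_orphans, cfg$n_variant_pairs,
              cfg$n_insertions, cfg$n_paralog_families,
              cfg$n_cross_replicon_repeats, cfg$n_diverged_high,
              cfg$n_diverged_low)
  if (any(counts < 0)) stop_pg("planted counts must be >= 0")
  if (cfg$n_genomes < 1) stop_pg("n_genomes must be >= 1")
  if (any(cfg$indel_loop_lengths < 3)) {
    stop_pg("an InDel loop needs at least 3 nodes (2 anchors + 1 path gene)")
  }
  if ((cfg$n_orphans > 0 && cfg$orphan_carriers > cfg$n_genomes) ||
      (cfg$n_insertions > 0 && cfg$insertion_carriers > cfg$n_genomes)) {
    stop_pg("carrier counts cannot exceed n_genomes")
  }
  if (cfg$n_cross_replicon_repeats > 0 && nrow(replicons) < 2) {
    stop_pg("cross-replicon repeats need at least two replicons")
  }
  if (max(cfg$indel_loop_lengths, 0) - 2 > min(replicons$n_genes)) {
    stop_pg("InDel loop longer than the backbone")
  }
  structure(cfg, class = "fixture_config")
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_protein <- function(len) {
  paste(c("M", sample(AA20, len - 1, replace = TRUE)), collapse = "")
}

#' Mutate a protein to a target identity
#'
#' Substitutes residues at sampled positions (no indels, so identity is the
#' exact-position match fraction over equal lengths) until the mutated
#' sequence has identity within 0.02 of the target to the original, as
#' measured by [sequence_identity()]. Used to give backbone families
#' per-genome divergence at controlled cascade tiers.
#'
#' @param seq amino-acid sequence
#' @param target_identity fraction in (0, 1]
#' @param seed integer seed (same seed, same output)
#' @return mutated sequence
#' @export
mutate_protein <- function(seq, target_identity, seed = 1L) {
  if (target_identity <= 0 || target_identity > 1) {
    stop_pg("target_identity must be in (0, 1]")
  }
  if (target_identity == 1) return(seq)
  L <- nchar(seq)
  n_sub <- round((1 - target_identity) * L)
  realized <- (L - n_sub) / L
  if (abs(realized - target_identity) > 0.02) {
    stop_pg("target identity %.2f unattainable within 0.02 on a %d-residue sequence; use a longer seed sequence",
            target_identity, L)
  }
  if (n_sub == 0) return(seq)
  with_seed(seed, {
    chars <- strsplit(seq, "")[[1]]
    pos <- sample(seq_len(L), n_sub)
    for (i in pos) chars[i] <- sample(setdiff(AA20, chars[i]), 1)
    paste(chars, collapse = "")
  })
}

#' Generate a synthetic annotated genome cohort with a truth manifest
#'
#' Emits, under \code{out_dir}: one GFF3 file per genome (\code{gff/}), the
#' combined protein FASTA (\code{proteins.faa}), the replicon template table
#' for the first genome (\code{templates.tsv}), the circular-contig table
#' (\code{circular_contigs.tsv}), clade definition and clade-specific
#' locus tables (\code{clades.tsv}, \code{clade_genes_loci.tsv}; clade 1 is
#' the first half of the cohort and the variant alleles are its specific
#' genes), and the machine-readable truth manifest (\code{manifest.tsv})
#' with one row per planted cluster recording its member loci, carriers and
#' expected partition, pattern class and replicon class. The same
#' configuration and seed always produce byte-identical files.
#'
#' Planted insertions of three or more genes also form cycles of more than
#' four nodes together with their direct anchor edge, so the manifest
#' expects them both as insertions and as InDel cycles.
#'
#' @param cfg a [fixture_config()]
#' @param out_dir output directory (created)
#' @return list with \code{dir}, \code{paths}, \code{config},
#'   \code{manifest} (data.frame), \code{genome_ids}
#' @export
generate_cohort <- function(cfg, out_dir = tempfile("cohort")) {
  stopifnot(inherits(cfg, "fixture_config"))
  plan <- with_seed(cfg$seed, build_cohort_plan(cfg))
  write_cohort(plan, cfg, out_dir)
}

# ---- plan construction (runs inside the seeded RNG scope) -----------------

build_cohort_plan <- function(cfg) {
  n <- cfg$n_genomes
  genomes <- sprintf("g%02d", seq_len(n))
  reps <- cfg$replicons
  lenr <- cfg$protein_length

  # backbone base proteins per slot, per replicon
  slots <- lapply(seq_len(nrow(reps)), function(ri) {
    k <- reps$n_genes[ri]
    list(label = sprintf("bb_r%d_%03d", ri, seq_len(k)),
         seq = vapply(seq_len(k), function(i)
           random_protein(sample(seq(lenr[1], lenr[2]), 1)), ""))
  })

  # gap bookkeeping: gap j of replicon ri sits between slots j and j+1
  # (circular: gap k wraps to slot 1); one structure per gap, with spacing
  free <- lapply(seq_len(nrow(reps)), function(ri) seq_len(reps$n_genes[ri] - 1L))
  take_gap <- function(ri, spacing = 2L) {
    if (!length(free[[ri]])) stop_pg("no free backbone gaps left on replicon %d", ri)
    gsel <- if (length(free[[ri]]) == 1) free[[ri]] else sample(free[[ri]], 1)
    free[[ri]] <<- setdiff(free[[ri]], (gsel - spacing):(gsel + spacing))
    gsel
  }

  # events[[genome]][[replicon]] : list gap -> data.frame(label, seq, product)
  events <- lapply(genomes, function(g) lapply(seq_len(nrow(reps)),
                                               function(ri) list()))
  names(events) <- genomes
  add_event <- function(gs, ri, gap, label, seqv, product) {
    for (g in gs) {
      key <- as.character(gap)
      ev <- events[[g]][[ri]][[key]]
      add <- data.frame(label = label, seq = seqv, product = product,
                        stringsAsFactors = FALSE)
      events[[g]][[ri]][[key]] <<- if (is.null(ev)) add else rbind(ev, add)
    }
  }

  man <- list()
  note <- function(...) man[[length(man) + 1L]] <<- list(...)
  half1 <- genomes[seq_len(ceiling(n / 2))]
  half2 <- setdiff(genomes, half1)
  part_of <- function(k) {
    f <- k / n
    t <- partition_thresholds()
    if (f >= t$hard) "hard_core" else if (f >= t$soft) "soft_core"
    else if (f >= t$shell) "shell" else "cloud"
  }

  # paralog families: same protein at two contexts on replicon 1, all genomes
  for (k in seq_len(cfg$n_paralog_families)) {
    pseq <- random_protein(sample(seq(lenr[1], lenr[2]), 1))
    for (j in 1:2) {
      gap <- take_gap(1L)
      lab <- sprintf("par%d_ctx%d", k, j)
      add_event(genomes, 1L, gap, lab, pseq, "repeat family protein")
      note(structure_id = sprintf("paralog_%d", k), type = "paralog",
           role = sprintf("context_%d", j), label = lab,
           carriers = join_set(genomes), expected_partition = "hard_core",
           expected_pattern = "none", expected_chromosome = reps$label[1],
           expected_subclusters = 2L)
    }
  }

  # cross-replicon cassette: gene pair on replicon 1 AND replicon 2; the
  # shared partner keeps each gene one subcluster spanning both replicons
  for (k in seq_len(cfg$n_cross_replicon_repeats)) {
    sa <- random_protein(sample(seq(lenr[1], lenr[2]), 1))
    sb <- random_protein(sample(seq(lenr[1], lenr[2]), 1))
    for (ri in 1:2) {
      gap <- take_gap(ri)
      add_event(genomes, ri, gap, sprintf("cas%d_a", k), sa,
                "IS200/IS605 family transposase")
      add_event(genomes, ri, gap, sprintf("cas%d_b", k), sb,
                "IS200/IS605 family transposase")
    }
    for (part in c("a", "b")) {
      note(structure_id = sprintf("cassette_%d", k), type = "cassette",
           role = part, label = sprintf("cas%d_%s", k, part),
           carriers = join_set(genomes), expected_partition = "hard_core",
           expected_pattern = "none", expected_chromosome = "undetermined",
           expected_subclusters = 1L)
    }
  }

  # variant pairs: allele A in the first half, allele B in the second half,
  # mutual identity verified < 0.70 (below the final cascade tier)
  for (k in seq_len(cfg$n_variant_pairs)) {
    len <- sample(seq(lenr[1], lenr[2]), 1)
    va <- random_protein(len)
    repeat {
      vb <- random_protein(len)
      if (sequence_identity(va, vb) < 0.70) break
    }
    gap <- take_gap(1L)
    add_event(half1, 1L, gap, sprintf("var%d_a", k), va, "variable surface protein")
    add_event(half2, 1L, gap, sprintf("var%d_b", k), vb, "variable surface protein")
    for (al in c("a", "b")) {
      carr <- if (al == "a") half1 else half2
      note(structure_id = sprintf("variant_%d", k), type = "variant",
           role = paste0("allele_", al), label = sprintf("var%d_%s", k, al),
           carriers = join_set(carr),
           expected_partition = part_of(length(carr)),
           expected_pattern = "variant", expected_chromosome = NA,
           expected_subclusters = 1L)
    }
    note(structure_id = sprintf("variant_%d", k), type = "variant",
         role = "anchor_pair", label = anchor_labels(1L, gap, reps),
         carriers = join_set(genomes), expected_partition = "hard_core",
         expected_pattern = "none", expected_chromosome = reps$label[1],
         expected_subclusters = 1L)
  }

  # insertions: contiguous novel genes in a strain subset between anchors
  # that stay directly adjacent in the other genomes
  for (k in seq_len(cfg$n_insertions)) {
    carr <- sort(sample(genomes, cfg$insertion_carriers))
    gap <- take_gap(1L)
    labs <- sprintf("ins%d_%d", k, seq_len(cfg$insertion_length))
    for (j in seq_along(labs)) {
      add_event(carr, 1L, gap, labs[j],
                random_protein(sample(seq(lenr[1], lenr[2]), 1)),
                "hypothetical protein")
      note(structure_id = sprintf("insertion_%d", k), type = "insertion",
           role = sprintf("insert_%d", j), label = labs[j],
           carriers = join_set(carr),
           expected_partition = part_of(length(carr)),
           expected_pattern = if (cfg$insertion_length >= 3)
             "insertion;indel" else "insertion",
           expected_chromosome = NA, expected_subclusters = 1L)
    }
    note(structure_id = sprintf("insertion_%d", k), type = "insertion",
         role = "anchor_pair", label = anchor_labels(1L, gap, reps),
         carriers = join_set(genomes), expected_partition = "hard_core",
         expected_pattern = "none", expected_chromosome = reps$label[1],
         expected_subclusters = 1L)
  }

  # InDel loops: two alternative paths between anchors; total node count
  # (anchors + both paths) is the configured loop length
  for (k in seq_along(cfg$indel_loop_lengths)) {
    L <- cfg$indel_loop_lengths[k]
    i1 <- ceiling((L - 2) / 2); i2 <- (L - 2) - i1
    g1 <- genomes[seq_len(ceiling(0.6 * n))]
    g2 <- setdiff(genomes, g1)
    gap <- take_gap(1L)
    expect <- if (L > 4) "indel" else "none"
    for (j in seq_len(i1)) {
      lab <- sprintf("indel%d_p1_%d", k, j)
      add_event(g1, 1L, gap, lab,
                random_protein(sample(seq(lenr[1], lenr[2]), 1)),
                "hypothetical protein")
      note(structure_id = sprintf("indel_%d", k), type = "indel",
           role = sprintf("path1_%d", j), label = lab,
           carriers = join_set(g1), expected_partition = part_of(length(g1)),
           expected_pattern = expect, expected_chromosome = NA,
           expected_subclusters = 1L, loop_length = L)
    }
    if (i2 > 0) {
      for (j in seq_len(i2)) {
        lab <- sprintf("indel%d_p2_%d", k, j)
        add_event(g2, 1L, gap, lab,
                  random_protein(sample(seq(lenr[1], lenr[2]), 1)),
                  "hypothetical protein")
        note(structure_id = sprintf("indel_%d", k), type = "indel",
             role = sprintf("path2_%d", j), label = lab,
             carriers = join_set(g2), expected_partition = part_of(length(g2)),
             expected_pattern = expect, expected_chromosome = NA,
             expected_subclusters = 1L, loop_length = L)
      }
    }
    note(structure_id = sprintf("indel_%d", k), type = "indel",
         role = "anchor_pair", label = anchor_labels(1L, gap, reps),
         carriers = join_set(genomes), expected_partition = "hard_core",
         expected_pattern = "none", expected_chromosome = reps$label[1],
         expected_subclusters = 1L, loop_length = L)
  }

  # orphans: same gene, unrelated random position in each carrier genome;
  # spacing 1 keeps occurrences out of adjacent gaps, which would otherwise
  # share a flank slot and give one adjacency two supporting genomes
  for (k in seq_len(cfg$n_orphans)) {
    carr <- sort(sample(genomes, cfg$orphan_carriers))
    oseq <- random_protein(sample(seq(lenr[1], lenr[2]), 1))
    lab <- sprintf("orph%d", k)
    for (g in carr) {
      add_event(g, 1L, take_gap(1L, spacing = 1L), lab, oseq,
                "mobile element protein")
    }
    note(structure_id = sprintf("orphan_%d", k), type = "orphan",
         role = "orphan", label = lab, carriers = join_set(carr),
         expected_partition = part_of(length(carr)),
         expected_pattern = "orphan", expected_chromosome = NA,
         expected_subclusters = 1L)
  }

  # uniques: a novel gene in a single genome
  for (k in seq_len(cfg$n_uniques)) {
    g <- sample(genomes, 1)
    lab <- sprintf("uni%d", k)
    add_event(g, 1L, take_gap(1L, spacing = 0L), lab,
              random_protein(sample(seq(lenr[1], lenr[2]), 1)),
              "hypothetical protein")
    note(structure_id = sprintf("unique_%d", k), type = "unique",
         role = "unique", label = lab, carriers = g,
         expected_partition = part_of(1L), expected_pattern = "unique",
         expected_chromosome = if (g == genomes[1]) NA else "unknown",
         expected_subclusters = 1L)
  }

  # per-genome divergence of selected backbone families
  div <- data.frame(ri = integer(0), slot = integer(0), target = numeric(0))
  if (cfg$n_diverged_high + cfg$n_diverged_low > 0) {
    pick <- sample(seq_len(reps$n_genes[1]),
                   cfg$n_diverged_high + cfg$n_diverged_low)
    div <- data.frame(
      ri = 1L, slot = pick,
      target = c(rep(cfg$diverged_high_identity, cfg$n_diverged_high),
                 rep(cfg$diverged_low_identity, cfg$n_diverged_low)))
  }

  list(genomes = genomes, slots = slots, events = events, manifest_notes = man,
       diverged = div, half1 = half1)
}

anchor_labels <- function(ri, gap, reps) {
  k <- reps$n_genes[ri]
  nxt <- if (gap == k) 1L else gap + 1L
  paste(sprintf("bb_r%d_%03d", ri, c(gap, nxt)), collapse = ";")
}

# ---- file emission (deterministic, no RNG) --------------------------------

write_cohort <- function(plan, cfg, out_dir) {
  dir.create(file.path(out_dir, "gff"), showWarnings = FALSE, recursive = TRUE)
  reps <- cfg$replicons
  genomes <- plan$genomes
  loci_by_label <- list()
  all_seqs <- character(0); all_ids <- character(0)

  for (g in genomes) {
    lines <- c("##gff-version 3")
    counter <- 0L
    for (ri in seq_len(nrow(reps))) {
      contig <- sprintf("%s_r%d", g, ri)
      offset <- 0L
      emit <- function(label, seqv, product) {
        counter <<- counter + 1L
        locus <- sprintf("%s_%05d", g, counter)
        nt <- 3L * nchar(seqv) + 3L
        strand <- if (utf8ToInt(substr(locus, nchar(locus), nchar(locus))) %% 2L)
          "+" else "-"
        lines <<- c(lines, paste(contig, "sim", "CDS", offset + 1L,
                                 offset + nt, ".", strand, "0",
                                 sprintf("ID=%s;product=%s", locus, product),
                                 sep = "\t"))
        offset <<- offset + nt + 50L
        all_ids <<- c(all_ids, locus); all_seqs <<- c(all_seqs, seqv)
        loci_by_label[[label]] <<- c(loci_by_label[[label]], locus)
      }
      k <- reps$n_genes[ri]
      for (s in seq_len(k)) {
        base <- plan$slots[[ri]]$seq[s]
        dmatch <- which(plan$diverged$ri == ri & plan$diverged$slot == s)
        seqv <- if (length(dmatch)) {
          mutate_protein(base, plan$diverged$target[dmatch[1]],
                         seed = derive_seed(cfg$seed, paste(g, ri, s)))
        } else base
        emit(plan$slots[[ri]]$label[s], seqv, "hypothetical protein")
        ev <- plan$events[[g]][[ri]][[as.character(s)]]
        if (!is.null(ev)) for (j in seq_len(nrow(ev))) {
          emit(ev$label[j], ev$seq[j], ev$product[j])
        }
      }
    }
    write_lines_det(lines, file.path(out_dir, "gff", paste0(g, ".gff3")))
  }

  names(all_seqs) <- all_ids
  write_fasta(all_seqs, file.path(out_dir, "proteins.faa"))

  tmpl <- c("genome_id\tcontig_id\tlabel",
            sprintf("%s\t%s_r%d\t%s", genomes[1], genomes[1],
                    seq_len(nrow(reps)), reps$label))
  write_lines_det(tmpl, file.path(out_dir, "templates.tsv"))

  circ <- c("genome_id\tcontig_id")
  for (ri in which(reps$circular)) {
    circ <- c(circ, sprintf("%s\t%s_r%d", genomes, genomes, ri))
  }
  write_lines_det(circ, file.path(out_dir, "circular_contigs.tsv"))

  half1 <- plan$half1; half2 <- setdiff(genomes, half1)
  clades <- c("clade_id\tgenome_id",
              sprintf("clade_1\t%s", half1), sprintf("clade_2\t%s", half2))
  write_lines_det(clades, file.path(out_dir, "clades.tsv"))
  cg <- c("clade_id\tlocus_id")
  for (k in seq_len(cfg$n_variant_pairs)) {
    cg <- c(cg,
            sprintf("clade_1\t%s", loci_by_label[[sprintf("var%d_a", k)]]),
            sprintf("clade_2\t%s", loci_by_label[[sprintf("var%d_b", k)]]))
  }
  write_lines_det(cg, file.path(out_dir, "clade_genes_loci.tsv"))

  manifest <- build_manifest(plan, cfg, loci_by_label)
  man_lines <- c(paste(names(manifest), collapse = "\t"),
                 vapply(seq_len(nrow(manifest)), function(i) {
                   paste(vapply(manifest[i, ], as.character, ""), collapse = "\t")
                 }, ""))
  write_lines_det(man_lines, file.path(out_dir, "manifest.tsv"))

  list(dir = out_dir,
       paths = list(gff_dir = file.path(out_dir, "gff"),
                    proteins = file.path(out_dir, "proteins.faa"),
                    templates = file.path(out_dir, "templates.tsv"),
                    circular = file.path(out_dir, "circular_contigs.tsv"),
                    clades = file.path(out_dir, "clades.tsv"),
                    clade_genes = file.path(out_dir, "clade_genes_loci.tsv"),
                    manifest = file.path(out_dir, "manifest.tsv")),
       config = cfg, manifest = manifest, genome_ids = genomes)
}

build_manifest <- function(plan, cfg, loci_by_label) {
  reps <- cfg$replicons
  rows <- lapply(plan$manifest_notes, function(nt) {
    loci <- join_set(unlist(loci_by_label[split_set(nt$label)]))
    data.frame(structure_id = nt$structure_id, type = nt$type, role = nt$role,
               label = nt$label, loci = loci, carriers = nt$carriers,
               expected_partition = nt$expected_partition,
               expected_pattern = nt$expected_pattern %||% "none",
               expected_chromosome = chromo_expect(nt, plan, cfg),
               expected_subclusters = nt$expected_subclusters %||% 1L,
               loop_length = nt$loop_length %||% NA_integer_,
               stringsAsFactors = FALSE)
  })
  bb <- lapply(seq_len(nrow(reps)), function(ri) {
    labs <- plan$slots[[ri]]$label
    data.frame(structure_id = "backbone", type = "backbone", role = labs,
               label = labs,
               loci = vapply(labs, function(l) join_set(loci_by_label[[l]]), ""),
               carriers = join_set(plan$genomes),
               expected_partition = "hard_core", expected_pattern = "none",
               expected_chromosome = reps$label[ri],
               expected_subclusters = 1L, loop_length = NA_integer_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, bb))
  rownames(out) <- NULL
  out
}

# Expected replicon class: structures carried by the template genome (the
# first genome) inherit the replicon of their planting site; structures it
# does not carry are "unknown"; the cassette is planted on both replicons.
chromo_expect <- function(nt, plan, cfg) {
  if (!is.null(nt$expected_chromosome) && !is.na(nt$expected_chromosome)) {
    return(nt$expected_chromosome)
  }
  tpl <- plan$genomes[1]
  carr <- split_set(nt$carriers)
  if (!(tpl %in% carr)) return("unknown")
  cfg$replicons$label[1]
}
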