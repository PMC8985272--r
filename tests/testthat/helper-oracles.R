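# Independent oracles, deliberately implemented apart from the package code
# paths they check.

blosum62_matrix <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

# Exhaustive affine-gap global aligner (Gotoh): returns the optimal score
# and the maximum number of identical aligned residues over all co-optimal
# alignments (forward/backward DP over the three-state alignment DAG).
# Convention: a gap of length L costs open + L * ext.
nw_oracle <- function(a, b, open = 10, ext = 1) {
  S <- blosum62_matrix()
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  # forward scores; states: 1 = diagonal (match/mismatch), 2 = gap in b
  # (a-residue vs gap), 3 = gap in a
  F <- array(NEG, c(n + 1, m + 1, 3))
  F[1, 1, 1] <- 0
  for (i in seq_len(n)) F[i + 1, 1, 2] <- -(open + i * ext)
  for (j in seq_len(m)) F[1, j + 1, 3] <- -(open + j * ext)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    sub <- S[av[i], bv[j]]
    F[i + 1, j + 1, 1] <- sub + max(F[i, j, ])
    F[i + 1, j + 1, 2] <- max(F[i, j + 1, 1] - open - ext,
                              F[i, j + 1, 2] - ext,
                              F[i, j + 1, 3] - open - ext)
    F[i + 1, j + 1, 3] <- max(F[i + 1, j, 1] - open - ext,
                              F[i + 1, j, 2] - open - ext,
                              F[i + 1, j, 3] - ext)
  }
  best <- max(F[n + 1, m + 1, ])
  # backward: best suffix score B and, over score-optimal suffixes, the
  # maximum match count Tmx
  B <- array(NEG, c(n + 1, m + 1, 3)); Tmx <- array(0, c(n + 1, m + 1, 3))
  B[n + 1, m + 1, ] <- 0
  for (i in (n + 1):1) for (j in (m + 1):1) {
    if (i == n + 1 && j == m + 1) next
    for (s in 1:3) {
      cand_s <- NEG; cand_t <- 0
      if (i <= n && j <= m) {
        w <- S[av[i], bv[j]]
        v <- w + B[i + 1, j + 1, 1]
        t <- (av[i] == bv[j]) + Tmx[i + 1, j + 1, 1]
        if (v > cand_s || (v == cand_s && t > cand_t)) { cand_s <- v; cand_t <- t }
      }
      if (i <= n) {
        w <- if (s == 2) -ext else -(open + ext)
        v <- w + B[i + 1, j, 2]; t <- Tmx[i + 1, j, 2]
        if (v > cand_s || (v == cand_s && t > cand_t)) { cand_s <- v; cand_t <- t }
      }
      if (j <= m) {
        w <- if (s == 3) -ext else -(open + ext)
        v <- w + B[i, j + 1, 3]; t <- Tmx[i, j + 1, 3]
        if (v > cand_s || (v == cand_s && t > cand_t)) { cand_s <- v; cand_t <- t }
      }
      B[i, j, s] <- cand_s; Tmx[i, j, s] <- cand_t
    }
  }
  list(score = best, max_matches = Tmx[1, 1, 1],
       max_identity = Tmx[1, 1, 1] / min(n, m))
}

# Biostrings alignment score for the same parameters, for exact score
# comparison against the oracle.
biostrings_score <- function(a, b) {
  Biostrings::pairwiseAlignment(a, b, substitutionMatrix = "BLOSUM62",
                                gapOpening = 10, gapExtension = 1,
                                type = "global", scoreOnly = TRUE)
}

# Brute-force pangenome edge-weight recount straight from gene-record
# tables: iterate every genome's consecutive locus pairs, map to labels,
# count supporting genomes per unordered pair.
brute_edge_weights <- function(records_list, label_of, circular = character(0)) {
  acc <- list()
  for (rec in records_list) {
    gpairs <- character(0)
    for (ctg in unique(rec$contig_id)) {
      loci <- rec$locus_id[rec$contig_id == ctg][
        order(rec$ordinal[rec$contig_id == ctg])]
      k <- length(loci)
      if (k < 2) next
      pairs <- cbind(loci[-k], loci[-1])
      if (ctg %in% circular && k >= 3) pairs <- rbind(pairs, c(loci[k], loci[1]))
      la <- unname(label_of[pairs[, 1]]); lb <- unname(label_of[pairs[, 2]])
      gpairs <- c(gpairs, paste(pmin(la, lb), pmax(la, lb), sep = "|"))
    }
    for (p in unique(gpairs)) acc[[p]] <- (acc[[p]] %||% 0L) + 1L
  }
  unlist(acc) %||% setNames(integer(0), character(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Edge weights of a pangenome graph in the oracle's "a|b" keyed form.
graph_edge_weights <- function(pg) {
  if (igraph::ecount(pg) == 0) return(setNames(integer(0), character(0)))
  el <- igraph::as_edgelist(pg)
  setNames(igraph::E(pg)$weight,
           paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "|"))
}

# Reference greedy clustering, recomputing every decision with the
# exhaustive aligner (max-match identity is an upper bound on any single
# optimal alignment's identity, so thresholds must use clear margins).
reference_greedy_members <- function(proteins, t) {
  ids <- names(proteins)
  o <- order(-nchar(proteins), ids)
  ids <- ids[o]; seqs <- unname(proteins[o])
  reps <- character(0); members <- list()
  for (k in seq_along(seqs)) {
    placed <- FALSE
    for (ci in seq_along(reps)) {
      idv <- if (seqs[k] == reps[ci]) 1 else nw_oracle(seqs[k], reps[ci])$max_identity
      if (idv >= t) {
        members[[ci]] <- c(members[[ci]], ids[k]); placed <- TRUE; break
      }
    }
    if (!placed) {
      reps <- c(reps, seqs[k])
      members[[length(members) + 1L]] <- ids[k]
    }
  }
  lapply(members, sort)
}

# Independent per-cluster tally from raw gene records.
tally_oracle <- function(records_list, label_of) {
  all <- do.call(rbind, records_list)
  all$label <- unname(label_of[all$locus_id])
  out <- lapply(split(all, all$label), function(d) {
    data.frame(label = d$label[1], n_strains = length(unique(d$genome_id)),
               max_paralogs = max(table(d$genome_id)),
               protein_count = nrow(d), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

random_aa_seq <- function(len) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  paste(sample(aa, len, replace = TRUE), collapse = "")
}
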