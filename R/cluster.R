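#' Configuration for the iterative clustering cascade
#'
#' The cascade clusters all proteins at a descending series of identity
#' thresholds (default 90\%, then 80\%, 75\%, 70\%). At each threshold,
#' clusters that reach the retention rule are frozen; the remaining proteins
#' are re-clustered at the next lower threshold, and at the final threshold
#' everything left is kept.
#'
#' The retention rule reads "clusters which include at least the number of
#' input genomes": \code{protein_count} (default) counts members, so paralogs
#' count towards retention; \code{genome_count} counts distinct genomes of
#' the members instead (requires a locus-to-genome mapping at clustering
#' time). Both readings of the rule are offered because the phrase is
#' ambiguous for paralogous families.
#'
#' @param n_genomes number of input strains (full genomes)
#' @param thresholds strictly decreasing identity fractions in (0, 1]
#' @param retention \code{"protein_count"} or \code{"genome_count"}
#' @param seed integer seed for the random-representative operation
#' @return a \code{cascade_config} list
#' @export
cascade_config <- function(n_genomes,
                           thresholds = c(0.90, 0.80, 0.75, 0.70),
                           retention = c("protein_count", "genome_count"),
                           seed = 42L) {
  retention <- match.arg(retention)
  if (length(n_genomes) != 1 || is.na(n_genomes) || n_genomes < 1) {
    stop_pg("n_genomes must be a positive integer")
  }
  if (!length(thresholds) || any(thresholds <= 0) || any(thresholds > 1)) {
    stop_pg("thresholds must lie in (0, 1]")
  }
  if (length(thresholds) > 1 && any(diff(thresholds) >= 0)) {
    stop_pg("thresholds must be strictly decreasing")
  }
  structure(list(n_genomes = as.integer(n_genomes), thresholds = thresholds,
                 retention = retention, seed = as.integer(seed)),
            class = "cascade_config")
}

#' Greedy incremental clustering at a single identity threshold
#'
#' Sequences are processed in decreasing length order (ties broken
#' lexicographically by locus ID, which makes the result deterministic where
#' greedy clustering tools are input-order-dependent). Each sequence joins
#' the first existing cluster whose representative it matches at identity >=
#' \code{t}; otherwise it founds a new cluster with itself as representative.
#' Identical sequences are grouped before alignment, which is exactly
#' faithful to the sequential scheme because duplicates always take the same
#' first-match decision.
#'
#' @param proteins named character vector locus_id -> sequence
#' @param t identity threshold in (0, 1]
#' @param seed kept for interface compatibility with the cascade (greedy
#'   clustering itself is deterministic)
#' @return a \code{cluster_set} (see [iterative_cluster()]), all tiers = t
#' @export
greedy_cluster <- function(proteins, t, seed = 42L) {
  if (t <= 0 || t > 1) stop_pg("threshold must be in (0, 1]")
  if (!length(proteins)) return(new_cluster_set(list(), numeric(0), character(0)))
  ids <- names(proteins)
  o <- order(-nchar(proteins), ids)
  ids <- ids[o]; seqs <- unname(proteins[o])
  # deduplicate identical sequences, keeping first-processed member as anchor
  first_idx <- !duplicated(seqs)
  uniq_seqs <- seqs[first_idx]
  grp_of <- match(seqs, uniq_seqs)
  members_by_grp <- split(ids, grp_of)
  rep_ids <- character(0)   # founder locus of each cluster, founding order
  rep_seqs <- character(0)
  assign_grp <- integer(length(uniq_seqs))
  for (k in seq_along(uniq_seqs)) {
    idv <- identity_to_many(uniq_seqs[k], rep_seqs)
    hit <- which(idv >= t)
    if (length(hit)) {
      assign_grp[k] <- hit[1]
    } else {
      rep_seqs <- c(rep_seqs, uniq_seqs[k])
      rep_ids <- c(rep_ids, members_by_grp[[as.character(k)]][1])
      assign_grp[k] <- length(rep_seqs)
    }
  }
  members <- vector("list", length(rep_ids))
  for (k in seq_along(uniq_seqs)) {
    cl <- assign_grp[k]
    members[[cl]] <- c(members[[cl]], members_by_grp[[as.character(k)]])
  }
  new_cluster_set(members, rep(t, length(members)), rep_ids)
}

new_cluster_set <- function(members, tiers, reps, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("c%05d", seq_along(members))
  names(members) <- ids
  tab <- data.frame(cluster_id = ids, tier = tiers, representative = reps,
                    size = lengths(members), stringsAsFactors = FALSE)
  cluster_of <- setNames(rep(ids, lengths(members)),
                         unlist(members, use.names = FALSE))
  structure(list(clusters = tab, members = members, cluster_of = cluster_of),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d clusters over %d proteins (tiers %s)\n",
              nrow(x$clusters), length(x$cluster_of),
              paste(sort(unique(x$clusters$tier), decreasing = TRUE),
                    collapse = "/")))
  invisible(x)
}

#' Iterative descending-identity clustering cascade
#'
#' Runs [greedy_cluster()] at each threshold of the cascade in order. After
#' each round except the last, clusters meeting the retention rule are frozen
#' at that tier and their proteins leave the pool; everything else is
#' re-clustered from scratch at the next lower threshold. At the final
#' threshold all remaining clusters are kept regardless of size. Frozen
#' clusters' members are excluded entirely from later rounds.
#'
#' Every member of a cluster has identity >= its tier to the cluster's
#' representative (the greedy founder). The paper-style random choice of a
#' representative is available separately via [choose_representative()]; the
#' founder is kept as the working representative because it is the only
#' member that carries the identity guarantee.
#'
#' @param proteins named character vector locus_id -> sequence
#' @param cfg a [cascade_config()]
#' @param genome_of named character vector locus_id -> genome_id; required
#'   for \code{retention = "genome_count"}
#' @return a \code{cluster_set}: list with \code{clusters} (data.frame of
#'   cluster_id, tier, representative, size), \code{members} (named list of
#'   locus vectors) and \code{cluster_of} (named locus -> cluster_id vector).
#'   Cluster IDs are assigned in freezing order.
#' @export
iterative_cluster <- function(proteins, cfg, genome_of = NULL) {
  stopifnot(inherits(cfg, "cascade_config"))
  if (cfg$retention == "genome_count" && is.null(genome_of)) {
    stop_pg("retention = 'genome_count' requires a genome_of mapping")
  }
  pool <- proteins
  frozen_members <- list(); frozen_tiers <- numeric(0); frozen_reps <- character(0)
  nt <- length(cfg$thresholds)
  for (i in seq_len(nt)) {
    t <- cfg$thresholds[i]
    if (!length(pool)) break
    cs <- greedy_cluster(pool, t)
    if (i == nt) {
      keep <- rep(TRUE, nrow(cs$clusters))
    } else if (cfg$retention == "protein_count") {
      keep <- cs$clusters$size >= cfg$n_genomes
    } else {
      keep <- vapply(cs$members, function(m)
        length(unique(genome_of[m])) >= cfg$n_genomes, logical(1))
    }
    frozen_members <- c(frozen_members, unname(cs$members[keep]))
    frozen_tiers <- c(frozen_tiers, rep(t, sum(keep)))
    frozen_reps <- c(frozen_reps, cs$clusters$representative[keep])
    kept_loci <- unlist(cs$members[keep], use.names = FALSE)
    pool <- pool[setdiff(names(pool), kept_loci)]
  }
  new_cluster_set(frozen_members, frozen_tiers, frozen_reps)
}

#' Choose a random cluster representative, reproducibly
#'
#' One member is drawn uniformly from a seeded generator keyed by
#' \code{(seed, cluster_id)}: the same seed always yields the same
#' representative, and different clusters draw independently.
#'
#' @param members non-empty character vector of the cluster's locus IDs
#' @param cluster_id cluster identifier (keys the random stream)
#' @param seed integer seed
#' @return one locus ID
#' @export
choose_representative <- function(members, cluster_id, seed = 42L) {
  if (!length(members)) stop_pg("cannot choose a representative of an empty cluster")
  members <- sort(members)
  if (length(members) == 1) return(members)
  with_seed(derive_seed(seed, cluster_id),
            members[sample.int(length(members), 1)])
}
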