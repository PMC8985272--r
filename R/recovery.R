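#' Map truth-manifest rows to pangenome graph nodes
#'
#' The generator identifies each planted cluster by its member loci; after a
#' pipeline run those loci carry (sub)cluster labels in the strain graphs.
#' This resolves every manifest row to the set of graph nodes its loci fall
#' into.
#'
#' @param manifest truth manifest data.frame (see [generate_cohort()])
#' @param strain_graphs the pipeline's (subcluster-labelled) strain graphs
#' @return list of character vectors of node IDs, one per manifest row
#' @export
manifest_node_map <- function(manifest, strain_graphs) {
  occ <- occurrence_table(strain_graphs)
  sub_of <- setNames(occ$subcluster, occ$locus)
  lapply(manifest$loci, function(l) {
    sort(unique(unname(sub_of[split_set(l)])))
  })
}

#' Score planted-structure recovery of a pipeline run
#'
#' Compares a pattern report (and optionally partition labels and replicon
#' assignments) against the generator's truth manifest: per pattern class,
#' the recall of planted structures and the number of detections outside
#' them; the fraction of manifest rows whose nodes carry the expected
#' partition; the fraction with the expected replicon class; and whether
#' each paralogous family split into the expected number of subclusters.
#'
#' InDel cycles are compared as node sets: a planted loop (or an insertion
#' of three or more genes, which forms a cycle with its direct anchor edge)
#' counts as recovered when some reported cycle equals its anchor-plus-path
#' node set.
#'
#' @param manifest truth manifest data.frame
#' @param pg pangenome graph (partitions assigned)
#' @param strain_graphs subcluster-labelled strain graphs
#' @param report a \code{pattern_report} from [detect_patterns()]
#' @param chromosomes optional named vector from [assign_chromosomes()]
#' @return list with \code{classes} (per-class expected/detected/matched
#'   counts, recall, false positives), \code{partition_ok} /
#'   \code{partition_total}, \code{chromosome_ok} / \code{chromosome_total},
#'   \code{subcluster_ok} / \code{subcluster_total}
#' @export
evaluate_recovery <- function(manifest, pg, strain_graphs, report,
                              chromosomes = NULL) {
  nodes_of <- manifest_node_map(manifest, strain_graphs)
  has_pat <- function(row_pat, cls) cls %in% split_set(gsub(";", ";", row_pat))
  expected_nodes <- function(cls) {
    sel <- vapply(manifest$expected_pattern, has_pat, logical(1), cls = cls)
    sort(unique(unlist(nodes_of[sel])))
  }

  cls_tab <- list()
  add_cls <- function(class, expected, detected) {
    cls_tab[[length(cls_tab) + 1L]] <<- data.frame(
      class = class, n_expected = length(expected),
      n_detected = length(detected),
      n_matched = length(intersect(expected, detected)),
      recall = if (length(expected)) length(intersect(expected, detected)) /
        length(expected) else 1,
      false_positives = length(setdiff(detected, expected)),
      stringsAsFactors = FALSE)
  }

  add_cls("orphan", expected_nodes("orphan"), report$orphans)
  add_cls("unique", expected_nodes("unique"), report$uniques)
  add_cls("variant", expected_nodes("variant"),
          sort(unique(unlist(lapply(report$variants, `[[`, "members")))))
  add_cls("insertion", expected_nodes("insertion"),
          sort(unique(report$insertions$node)))

  # indel cycles compared as node sets (anchors + path/insert nodes)
  expected_cycles <- list()
  for (sid in unique(manifest$structure_id)) {
    rows <- manifest[manifest$structure_id == sid, , drop = FALSE]
    idx <- which(manifest$structure_id == sid)
    if (any(vapply(rows$expected_pattern, has_pat, logical(1), cls = "indel"))) {
      expected_cycles[[sid]] <-
        sort(unique(unlist(nodes_of[idx])))
    }
  }
  detected_cycles <- lapply(report$indels, function(cy) sort(unique(cy)))
  exp_keys <- vapply(expected_cycles, paste, "", collapse = "\t")
  det_keys <- vapply(detected_cycles, paste, "", collapse = "\t")
  cls_tab[[length(cls_tab) + 1L]] <- data.frame(
    class = "indel", n_expected = length(exp_keys),
    n_detected = length(det_keys),
    n_matched = sum(exp_keys %in% det_keys),
    recall = if (length(exp_keys)) mean(exp_keys %in% det_keys) else 1,
    false_positives = sum(!(det_keys %in% exp_keys)),
    stringsAsFactors = FALSE)

  part_of_node <- setNames(igraph::V(pg)$partition, igraph::V(pg)$name)
  part_ok <- vapply(seq_len(nrow(manifest)), function(i) {
    all(part_of_node[nodes_of[[i]]] == manifest$expected_partition[i])
  }, logical(1))

  chr_idx <- which(!is.na(manifest$expected_chromosome) &
                     manifest$expected_chromosome != "NA")
  chr_ok <- NULL
  if (!is.null(chromosomes) && length(chr_idx)) {
    chr_ok <- vapply(chr_idx, function(i) {
      all(chromosomes[nodes_of[[i]]] == manifest$expected_chromosome[i])
    }, logical(1))
  }

  sub_tab <- manifest[manifest$type %in% c("paralog", "cassette"), , drop = FALSE]
  sub_ok <- sub_total <- 0L
  if (nrow(sub_tab)) {
    for (sid in unique(sub_tab$structure_id)) {
      idx <- which(manifest$structure_id == sid &
                     manifest$type %in% c("paralog", "cassette"))
      got <- length(unique(unlist(nodes_of[idx])))
      # per-gene expectation: a repeated gene's contexts split into
      # expected_subclusters nodes; cassette genes stay single
      gene_of <- sub("_ctx[0-9]+$", "", manifest$label[idx])
      want <- sum(tapply(manifest$expected_subclusters[idx], gene_of, max))
      sub_total <- sub_total + 1L
      if (got == want) sub_ok <- sub_ok + 1L
    }
  }

  list(classes = do.call(rbind, cls_tab),
       partition_ok = sum(part_ok), partition_total = length(part_ok),
       chromosome_ok = if (is.null(chr_ok)) NA_integer_ else sum(chr_ok),
       chromosome_total = if (is.null(chr_ok)) NA_integer_ else length(chr_ok),
       subcluster_ok = sub_ok, subcluster_total = sub_total)
}
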