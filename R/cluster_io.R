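#' Write and read the cluster file
#'
#' One cluster per line, sorted by cluster ID:
#' \code{cluster_id TAB tier TAB representative TAB member1;member2;...}
#' (members sorted). \code{read_cluster_file()} is the exact inverse.
#'
#' @param cs a \code{cluster_set}
#' @param path output path
#' @return the path, invisibly
#' @export
write_cluster_file <- function(cs, path) {
  tab <- cs$clusters[order(cs$clusters$cluster_id), , drop = FALSE]
  lines <- vapply(seq_len(nrow(tab)), function(i) {
    paste(tab$cluster_id[i], fmt_num(tab$tier[i]), tab$representative[i],
          join_set(cs$members[[tab$cluster_id[i]]]), sep = "\t")
  }, "")
  write_lines_det(lines, path)
}

#' @rdname write_cluster_file
#' @export
read_cluster_file <- function(path) {
  if (!file.exists(path)) stop_pg("cluster file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(new_cluster_set(list(), numeric(0), character(0)))
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 4L)) {
    stop_pg("malformed cluster file line %d in %s", which(lengths(f) != 4L)[1], path)
  }
  m <- do.call(rbind, f)
  members <- lapply(m[, 4], split_set)
  new_cluster_set(members, as.numeric(m[, 2]), m[, 3], ids = m[, 1])
}

#' Write the representative sequences FASTA
#'
#' One record per cluster, headers carrying the cluster ID, the
#' representative locus and (when available) its product annotation:
#' \code{>cluster_id representative=locus product=...}.
#'
#' @param cs a \code{cluster_set}
#' @param proteins named character vector locus_id -> sequence
#' @param path output path
#' @param products optional named character vector locus_id -> product text
#' @return the path, invisibly
#' @export
write_representative_fasta <- function(cs, proteins, path, products = NULL) {
  tab <- cs$clusters[order(cs$clusters$cluster_id), , drop = FALSE]
  if (!nrow(tab)) return(write_lines_det(character(0), path))
  missing <- setdiff(tab$representative, names(proteins))
  if (length(missing)) {
    stop_pg("representative sequence missing for locus '%s'", missing[1])
  }
  headers <- vapply(seq_len(nrow(tab)), function(i) {
    h <- sprintf("%s representative=%s", tab$cluster_id[i], tab$representative[i])
    p <- if (!is.null(products)) products[tab$representative[i]] else NA
    if (!is.na(p) && nzchar(p)) h <- paste0(h, " product=", p)
    h
  }, "")
  write_fasta(unname(proteins[tab$representative]), path, headers)
}
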