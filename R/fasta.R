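#' Read the multi-FASTA of predicted protein sequences
#'
#' Reads the single protein FASTA covering all input genomes. Record IDs (the
#' first whitespace-delimited token of each header) must match the locus IDs
#' of the GFF3 CDS features. Sequences are uppercased and a trailing stop
#' symbol (\code{*}) is stripped.
#'
#' @param path path to a protein FASTA file
#' @return a named character vector of amino-acid sequences keyed by locus ID
#'   (a "protein set"); empty file gives an empty vector
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop_pg("FASTA file not found: %s", path)
  if (file.size(path) == 0) return(setNames(character(0), character(0)))
  aas <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aas), "\\s+"), `[`, "", 1)
  if (anyDuplicated(ids)) {
    stop_pg("duplicate FASTA record ID '%s' in %s", ids[anyDuplicated(ids)], path)
  }
  seqs <- toupper(as.character(aas))
  seqs <- sub("\\*$", "", seqs)
  if (any(!nzchar(seqs))) {
    stop_pg("empty sequence for FASTA record '%s' in %s",
            ids[which(!nzchar(seqs))[1]], path)
  }
  setNames(unname(seqs), ids)
}

#' Map protein locus IDs to their genome of origin
#'
#' @param records_list list of gene-record data.frames (one per genome), as
#'   from [read_gff3_dir()]
#' @return named character vector locus_id -> genome_id
#' @export
protein_genomes <- function(records_list) {
  all <- do.call(rbind, records_list)
  setNames(all$genome_id, all$locus_id)
}

# Deterministic FASTA writer (60-column wrap, "\n" endings).
write_fasta <- function(seqs, path, headers = names(seqs)) {
  lines <- character(0)
  for (i in seq_along(seqs)) {
    body <- gsub("(.{60})", "\\1\n", seqs[[i]])
    body <- sub("\n$", "", body)
    lines <- c(lines, paste0(">", headers[i]), strsplit(body, "\n")[[1]])
  }
  write_lines_det(lines, path)
}
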