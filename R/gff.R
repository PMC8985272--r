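#' Read CDS features from a GFF3 annotation file
#'
#' Parses one bacterial genome annotation in GFF3 format and returns its
#' protein-coding genes as ordered gene records. Only features of type
#' \code{CDS} are ingested; parent gene/mRNA features and non-coding features
#' are ignored, since the pangenome is built over predicted proteins.
#'
#' Records are sorted per contig by start coordinate (ties broken by end), and
#' each CDS receives a 0-based \code{ordinal} giving its rank among the CDS of
#' its contig. Gene neighbourhood ("direct successors or predecessors on the
#' annotated sequence") is defined purely by these ordinals downstream; strand
#' is stored but plays no role in adjacency. Coordinates stay 1-based
#' inclusive as in GFF3.
#'
#' An embedded \code{##FASTA} section (as written by Prokka) terminates
#' parsing. A feature line with a column count other than 9 is a parse error
#' naming the line number; a CDS without the ID attribute is an error naming
#' the feature. A file with zero CDS features yields an empty record table
#' with a warning.
#'
#' @param path path to a GFF3 file
#' @param genome_id identifier for the genome (strain) this file represents
#' @param id_attribute attribute used as the locus identifier; \code{"ID"}
#'   (default) or e.g. \code{"locus_tag"}, since annotation tools differ
#' @return a data.frame with columns \code{genome_id}, \code{contig_id},
#'   \code{ordinal}, \code{start}, \code{end}, \code{strand},
#'   \code{locus_id}, \code{product}
#' @export
read_gff3 <- function(path, genome_id, id_attribute = "ID") {
  if (!file.exists(path)) stop_pg("GFF3 file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  fasta_at <- which(lines == "##FASTA")
  if (length(fasta_at)) lines <- head(lines, fasta_at[1] - 1L)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    warning(sprintf("no CDS features in %s", path), call. = FALSE)
    return(empty_gene_records())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- which(nf != 9L)[1]
    stop_pg("malformed GFF3 line %d in %s: expected 9 tab-separated columns, got %d",
            lineno[bad], path, nf[bad])
  }
  m <- do.call(rbind, fields)
  is_cds <- m[, 3] == "CDS"
  if (!any(is_cds)) {
    warning(sprintf("no CDS features in %s", path), call. = FALSE)
    return(empty_gene_records())
  }
  m <- m[is_cds, , drop = FALSE]
  cds_lineno <- lineno[is_cds]
  ids <- gff3_attr(m[, 9], id_attribute)
  if (anyNA(ids)) {
    bad <- which(is.na(ids))[1]
    stop_pg("CDS without %s attribute at line %d in %s (%s:%s-%s)",
            id_attribute, cds_lineno[bad], path, m[bad, 1], m[bad, 4], m[bad, 5])
  }
  if (anyDuplicated(ids)) {
    stop_pg("duplicate locus ID '%s' in %s (locus IDs must be unique within a genome)",
            ids[anyDuplicated(ids)], path)
  }
  prod <- gff3_attr(m[, 9], "product")
  prod[is.na(prod)] <- ""
  rec <- data.frame(
    genome_id = genome_id,
    contig_id = m[, 1],
    ordinal = NA_integer_,
    start = as.integer(m[, 4]),
    end = as.integer(m[, 5]),
    strand = m[, 7],
    locus_id = ids,
    product = prod,
    stringsAsFactors = FALSE
  )
  if (any(rec$start > rec$end)) {
    bad <- which(rec$start > rec$end)[1]
    stop_pg("CDS %s has start > end (%d > %d) in %s",
            rec$locus_id[bad], rec$start[bad], rec$end[bad], path)
  }
  # sort within contig by start then end; contigs keep file order of first
  # appearance so replicon order is preserved
  contig_rank <- match(rec$contig_id, unique(rec$contig_id))
  o <- order(contig_rank, rec$start, rec$end)
  rec <- rec[o, , drop = FALSE]
  rec$ordinal <- as.integer(stats::ave(seq_len(nrow(rec)), rec$contig_id,
                                       FUN = seq_along)) - 1L
  rownames(rec) <- NULL
  rec
}

empty_gene_records <- function() {
  data.frame(genome_id = character(0), contig_id = character(0),
             ordinal = integer(0), start = integer(0), end = integer(0),
             strand = character(0), locus_id = character(0),
             product = character(0), stringsAsFactors = FALSE)
}

# Extract one attribute value from GFF3 column-9 strings (NA when absent),
# with percent-decoding of the encoded characters the format reserves.
gff3_attr <- function(attrs, key) {
  pat <- paste0("(?:^|;)\\s*", key, "=([^;]*)")
  m <- regmatches(attrs, regexpr(pat, attrs, perl = TRUE))
  out <- rep(NA_character_, length(attrs))
  hit <- grepl(pat, attrs, perl = TRUE)
  out[hit] <- sub(pat, "\\1", m, perl = TRUE)
  needs_dec <- !is.na(out) & grepl("%", out, fixed = TRUE)
  out[needs_dec] <- vapply(out[needs_dec], URLdecode, "")
  out
}

#' Read all genome annotations from a directory of GFF3 files
#'
#' Each \code{.gff3}/\code{.gff} file is treated as one input genome (strain),
#' with the file name (without extension) as its genome identifier.
#'
#' @param dir directory containing one GFF3 file per genome
#' @inheritParams read_gff3
#' @return named list of gene-record data.frames, one per genome
#' @export
read_gff3_dir <- function(dir, id_attribute = "ID") {
  files <- sort(list.files(dir, pattern = "\\.gff3?$", full.names = TRUE))
  if (!length(files)) stop_pg("no GFF3 files found in %s", dir)
  ids <- sub("\\.gff3?$", "", basename(files))
  setNames(lapply(seq_along(files), function(i) read_gff3(files[i], ids[i],
                                                          id_attribute)), ids)
}
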