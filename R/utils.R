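#' @keywords internal
"_PACKAGE"

#' @importFrom utils URLdecode head tail write.table read.delim
#' @importFrom stats setNames
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Join a character set into the canonical semicolon-delimited attribute string
#'
#' Set-valued node attributes (strain sets) are carried through GraphML as
#' sorted, semicolon-joined strings so that any viewer can read them and so
#' that file output is deterministic.
#'
#' @param x character vector (a set; duplicates are removed)
#' @return a single string, elements sorted and joined by ";" ("" for empty)
#' @export
join_set <- function(x) paste(sort(unique(as.character(x))), collapse = ";")

#' Split a semicolon-delimited attribute string back into a character vector
#'
#' @param s a single string as produced by [join_set()]
#' @return character vector (empty for "")
#' @export
split_set <- function(s) {
  if (length(s) == 0 || is.na(s) || !nzchar(s)) return(character(0))
  strsplit(s, ";", fixed = TRUE)[[1]]
}

# Run code with a temporarily-seeded RNG, restoring the caller's RNG state.
# Keeps every seeded component (representative choice, cohort generation)
# independent of the global random stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a bounded integer sub-seed from a base seed and a string key, so
# per-cluster / per-genome draws are reproducible and mutually independent.
derive_seed <- function(seed, key) {
  h <- sum(utf8ToInt(as.character(key)) * seq_along(utf8ToInt(as.character(key))))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587L) + 1L
}

stop_pg <- function(...) stop(sprintf(...), call. = FALSE)

# Write lines with "\n" endings and no trailing-newline surprises; all text
# writers in the package funnel through here so output is byte-deterministic.
write_lines_det <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

# Format a numeric for text output without scientific notation drift.
fmt_num <- function(x) {
  ifelse(x == round(x), format(as.integer(round(x))),
         sub("0+$", "", format(x, scientific = FALSE, digits = 10)))
}
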