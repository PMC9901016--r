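#' Read and write per-population mitochondrial allele counts
#'
#' The allele-count table is the long-format exchange dialect of the
#' simulator and of any upstream mito-capture variant counter: one row per
#' `(population, position, alt allele, strand)` with the alt read `count`
#' and total strand `depth` at that position.
#'
#' @param path TSV file with columns `population`, `position` (1-based),
#'   `ref`, `alt`, `strand` (`+`/`-`), `count`, `depth`.
#' @param genome_length Optional upper bound on `position` for validation.
#' @return A tibble of class `basecount_tbl`.
#' @export
read_basecounts <- function(path, genome_length = NULL) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    population = readr::col_character(),
    position = readr::col_integer(),
    ref = readr::col_character(),
    alt = readr::col_character(),
    strand = readr::col_character(),
    count = readr::col_integer(),
    depth = readr::col_integer()
  ))
  validate_basecounts(x, genome_length = genome_length)
}

#' @rdname read_basecounts
#' @param x A data frame of allele counts.
#' @export
validate_basecounts <- function(x, genome_length = NULL) {
  need <- c("population", "position", "ref", "alt", "strand", "count", "depth")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    abort(paste0("allele-count table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  x <- tibble::as_tibble(x)[need]
  bad <- which(!x$strand %in% c("+", "-"))
  if (length(bad)) {
    abort(sprintf("invalid strand '%s' in row %d (must be '+' or '-')",
                  x$strand[bad[1]], bad[1]))
  }
  bad <- is.na(x$position) | x$position < 1
  if (!is.null(genome_length)) bad <- bad | x$position > genome_length
  if (any(bad)) {
    abort(sprintf("position out of range in row %d", which(bad)[1]))
  }
  bad <- which(is.na(x$depth) | x$depth < 0 | is.na(x$count) | x$count < 0 |
                 x$count > x$depth)
  if (length(bad)) {
    abort(sprintf("invalid count/depth in row %d (need 0 <= count <= depth)",
                  bad[1]))
  }
  key <- paste(x$population, x$position, x$alt, x$strand, sep = "\r")
  if (anyDuplicated(key)) {
    abort(sprintf("duplicated (population, position, alt, strand) in row %d",
                  which(duplicated(key))[1]))
  }
  if (!inherits(x, "basecount_tbl")) class(x) <- c("basecount_tbl", class(x))
  x
}

#' @rdname read_basecounts
#' @export
write_basecounts <- function(x, path) {
  readr::write_tsv(as.data.frame(x), path)
  invisible(path)
}
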