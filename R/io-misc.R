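# FASTA and duplication-pair table IO.

#' Read a FASTA file as a named character vector
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()]; sequences are
#' uppercased on read (soft-masking case is not used by this package).
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a named character vector to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 80L)
  invisible(path)
}

#' Read a segmental-duplication pair table
#'
#' Reads a BEDPE-like tab-separated table of duplication pairs with columns
#' `chrA, startA, endA, chrB, startB, endB, length, divergence` (header
#' optional; detected from the first line). Divergence may be given as a
#' fraction or percentage; values greater than 1 are divided by 100.
#'
#' @param path Path to the table.
#' @return A tibble of duplication pairs with divergence as a fraction.
#' @export
read_dup_pairs <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  has_header <- grepl("startA", first, fixed = TRUE)
  cols <- c("chrA", "startA", "endA", "chrB", "startB", "endB",
            "length", "divergence")
  df <- readr::read_tsv(
    path,
    col_names = if (has_header) TRUE else cols,
    col_types = readr::cols(
      chrA = readr::col_character(), chrB = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  df <- as_tibble(df)[, cols]
  df$divergence <- ifelse(df$divergence > 1, df$divergence / 100, df$divergence)
  df
}

#' @rdname read_dup_pairs
#' @param pairs Tibble of duplication pairs.
#' @export
write_dup_pairs <- function(pairs, path) {
  readr::write_tsv(pairs, path, progress = FALSE)
  invisible(path)
}
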