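#' Read a RepeatMasker .out annotation table
#'
#' Parses the standard RepeatMasker `.out` layout (three header lines,
#' whitespace-separated columns). Query coordinates are converted from
#' 1-based inclusive to the package's 0-based half-open convention, and
#' complement strand `"C"` is stored as `"-"`. The trailing ID column joins
#' fragments of one interrupted element.
#'
#' @param path Path to a `.out` file.
#' @return A `canisv_annotations` tibble with columns `seq_id`, `start`,
#'   `end`, `repeat_name`, `repeat_class`, `strand`, `element_id`,
#'   `cons_start`, `cons_end` (consensus match coordinates, 1-based
#'   inclusive as printed by RepeatMasker).
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readr::read_lines(path)
  # Standard layout: two column-header lines and one blank line.
  data_lines <- lines[-(1:3)]
  keep <- which(nzchar(trimws(data_lines)))
  data_lines <- data_lines[keep]
  if (length(data_lines) == 0L) return(empty_annotation_set())
  fields <- strsplit(trimws(data_lines), "\\s+")
  nf <- lengths(fields)
  bad <- which(nf < 14)
  if (length(bad) > 0) {
    abort(paste0("unparsable RepeatMasker row at line ", keep[bad[1]] + 3L))
  }
  f <- function(k) vapply(fields, `[[`, character(1), k)
  strip_paren <- function(x) as.integer(gsub("[()]", "", x))
  strand_raw <- f(9)
  strand <- ifelse(strand_raw == "C", "-", "+")
  qbegin <- as.integer(f(6))
  qend <- as.integer(f(7))
  if (any(qend < qbegin)) {
    abort(paste0("coordinate end < begin at line ",
                 keep[which(qend < qbegin)[1]] + 3L))
  }
  # Repeat (consensus) coordinates: "+" rows print begin end (left);
  # "C" rows print (left) end begin.
  c12 <- f(12); c13 <- f(13); c14 <- f(14)
  cons_start <- ifelse(strand == "+", strip_paren(c12), strip_paren(c14))
  cons_end <- strip_paren(c13)
  element_id <- if (all(nf >= 15)) {
    id <- suppressWarnings(as.integer(f(15)))
    ifelse(is.na(id), seq_along(fields), id)
  } else {
    seq_along(fields)
  }
  new_annotation_set(tibble(
    seq_id = f(5),
    start = qbegin - 1L,
    end = qend,
    repeat_name = f(10),
    repeat_class = f(11),
    strand = strand,
    element_id = as.integer(element_id),
    cons_start = as.integer(cons_start),
    cons_end = as.integer(cons_end)
  ))
}

#' Write annotations in RepeatMasker .out format
#'
#' Inverse of [read_repeatmasker_out()]; internal 0-based half-open
#' coordinates are converted back to 1-based inclusive and `"-"` strand to
#' `"C"`. Used by the synthetic-cohort emitter to produce truth annotations
#' in the standard format.
#'
#' @param annots A `canisv_annotations` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repeatmasker_out <- function(annots, path) {
  hdr <- c(
    "   SW  perc perc perc  query      position in query           matching       repeat              position in  repeat",
    "score  div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)     ID",
    ""
  )
  rows <- vapply(seq_len(nrow(annots)), function(i) {
    a <- annots[i, ]
    minus <- identical(a$strand, "-")
    cons_cols <- if (minus) {
      c("(0)", a$cons_end, a$cons_start)
    } else {
      c(a$cons_start, a$cons_end, "(0)")
    }
    paste(c("1000", "0.0", "0.0", "0.0", a$seq_id, a$start + 1L, a$end, "(0)",
            if (minus) "C" else "+", a$repeat_name, a$repeat_class,
            cons_cols, a$element_id), collapse = " ")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
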