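# Internal helpers shared across modules. All coordinates inside the package are
# 0-based half-open; conversion to/from 1-based inclusive happens only in the IO
# layer (VCF POS, RepeatMasker begin/end).

DNA_BASES <- c("A", "C", "G", "T")

rand_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Merge a set of [start, end) intervals into their union, sorted.
merge_intervals <- function(start, end) {
  stopifnot(length(start) == length(end))
  if (length(start) == 0L) {
    return(tibble(start = integer(0), end = integer(0)))
  }
  o <- order(start, end)
  start <- start[o]
  end <- end[o]
  ms <- start[1]
  me <- end[1]
  out_s <- integer(0)
  out_e <- integer(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms)
      out_e <- c(out_e, me)
      ms <- start[i]
      me <- end[i]
    }
  }
  tibble(start = as.integer(c(out_s, ms)), end = as.integer(c(out_e, me)))
}

interval_union_len <- function(start, end) {
  m <- merge_intervals(start, end)
  sum(m$end - m$start)
}

# Overlap length between one interval and a merged set.
overlap_with_set <- function(start, end, set_start, set_end) {
  if (length(set_start) == 0L) return(0L)
  s <- pmax(start, set_start)
  e <- pmin(end, set_end)
  sum(pmax(0L, e - s))
}

# Translate a DNA string in frame 0; stops as "*".
translate_dna <- function(seq) {
  n <- nchar(seq) - nchar(seq) %% 3
  if (n < 3) return("")
  codons <- substring(seq, seq(1, n - 2, by = 3), seq(3, n, by = 3))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# Sample random codons avoiding stop codons (used to build open reading frames).
rand_codons <- function(n, exclude = c("TAA", "TAG", "TGA", "ATG")) {
  all_codons <- as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0), DNA_BASES, paste0))
  pool <- setdiff(all_codons, exclude)
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

is_dna_string <- function(x) {
  grepl("^[ACGTN]+$", x)
}

new_annotation_set <- function(df) {
  df <- as_tibble(df)
  needed <- c("seq_id", "start", "end", "repeat_name", "repeat_class",
              "strand", "element_id", "cons_start", "cons_end")
  for (col in setdiff(needed, names(df))) {
    df[[col]] <- if (col %in% c("start", "end", "element_id", "cons_start", "cons_end")) {
      NA_integer_
    } else NA_character_
  }
  df <- df[, needed]
  class(df) <- c("canisv_annotations", class(df))
  df
}

empty_annotation_set <- function() {
  new_annotation_set(tibble(
    seq_id = character(0), start = integer(0), end = integer(0),
    repeat_name = character(0), repeat_class = character(0),
    strand = character(0), element_id = integer(0),
    cons_start = integer(0), cons_end = integer(0)
  ))
}
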