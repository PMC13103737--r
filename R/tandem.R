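# Exact tandem repeat detection (etrf-style).

# Lexicographically smallest rotation of a motif.
canonical_rotation <- function(unit) {
  k <- nchar(unit)
  if (k == 1L) return(unit)
  doubled <- paste0(unit, unit)
  rots <- substring(doubled, 1:k, k:(2L * k - 1L))
  min(rots)
}

# TRUE if the motif has a period strictly smaller than its length
# (i.e. it is a whole-number repetition of a shorter motif).
is_periodic_unit <- function(unit) {
  k <- nchar(unit)
  if (k == 1L) return(FALSE)
  divs <- which(k %% seq_len(k - 1L) == 0L)
  for (d in divs) {
    if (strrep(substr(unit, 1L, d), k / d) == unit) return(TRUE)
  }
  FALSE
}

#' Find maximal exact tandem repeat runs
#'
#' Detects every maximal run where `seq[i] == seq[i - p]` for a period
#' `p <= max_unit`. Runs are maximal for their period and reported with the
#' primitive (non-self-periodic) motif; the motif is canonicalized to its
#' lexicographically smallest rotation so that runs match regardless of
#' phase. A partial trailing copy is included in the span, but `copies`
#' counts whole copies only. Overlapping runs of different periods are all
#' reported; consumers that need base coverage should take the union.
#'
#' @param seq A single DNA string.
#' @param max_unit Maximum motif length, or `NULL` for unrestricted
#'   (up to half the sequence length).
#' @param min_copies Minimum whole copies per run (default 2).
#' @param min_span Minimum run span in bases (default 4).
#' @return A tibble with columns `start`, `end` (0-based half-open),
#'   `unit` (canonical rotation), `unit_length` and `copies`, sorted by
#'   `start` then `unit_length`.
#' @export
find_exact_tandem_repeats <- function(seq, max_unit = 6L, min_copies = 2L,
                                      min_span = 4L) {
  stopifnot(length(seq) == 1L)
  n <- nchar(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pmax_ <- if (is.null(max_unit)) n %/% 2L else min(as.integer(max_unit), n %/% 2L)
  if (is.na(pmax_) || pmax_ < 1L || n < 2L) {
    return(tibble(start = integer(0), end = integer(0), unit = character(0),
                  unit_length = integer(0), copies = integer(0)))
  }
  out <- vector("list", pmax_)
  for (p in seq_len(pmax_)) {
    eq <- chars[(p + 1L):n] == chars[1:(n - p)]
    r <- rle(eq)
    ends_at <- cumsum(r$lengths)
    starts_at <- ends_at - r$lengths + 1L
    hit <- which(r$values)
    if (length(hit) == 0L) next
    # Equality at index a means seq[a + p] == seq[a]; a run of equalities
    # a..b covers bases [a - 1, b + p) 0-based.
    a <- starts_at[hit]
    b <- ends_at[hit]
    start0 <- a - 1L
    end0 <- b + p
    span <- end0 - start0
    copies <- span %/% p
    keep <- span >= min_span & copies >= min_copies
    if (!any(keep)) next
    start0 <- start0[keep]; end0 <- end0[keep]
    span <- span[keep]; copies <- copies[keep]
    unit <- substring(seq, start0 + 1L, start0 + p)
    prim <- !vapply(unit, is_periodic_unit, logical(1))
    if (!any(prim)) next
    out[[p]] <- tibble(
      start = start0[prim], end = end0[prim],
      unit = vapply(unit[prim], canonical_rotation, character(1),
                    USE.NAMES = FALSE),
      unit_length = p,
      copies = as.integer(copies[prim])
    )
  }
  res <- bind_rows(out)
  if (nrow(res) == 0L) {
    return(tibble(start = integer(0), end = integer(0), unit = character(0),
                  unit_length = integer(0), copies = integer(0)))
  }
  arrange(res, .data$start, .data$unit_length)
}
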