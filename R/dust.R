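#' Mask low-complexity sequence with a symmetric DUST scan
#'
#' Windowed triplet-composition masking in the style of the symmetric DUST
#' (SDUST) algorithm. For every subinterval spanning at most `window` bases,
#' the composition score \eqn{S = \sum_t c_t (c_t - 1) / 2} is computed over
#' the 64 triplet counts and normalized by \eqn{k - 1}, where \eqn{k} is the
#' number of triplets in the subinterval. A subinterval is reported as a
#' perfect interval when its normalized score exceeds `threshold / 10` and
#' no proper subinterval of it has a higher normalized score — so the mask
#' covers low-complexity cores rather than every window that happens to
#' contain one. Overlapping perfect intervals are merged. With the default
#' `window = 64`, `threshold = 20` the score cutoff is 2.0, the canonical
#' published default.
#'
#' Characters outside `A/C/G/T` break triplets: no window spans them, so an
#' `N` always splits the mask.
#'
#' @param seq A single DNA string.
#' @param window Maximum window size in bases (>= 3).
#' @param threshold Integer score threshold; the cutoff applied to the
#'   normalized score is `threshold / 10`.
#' @return A tibble of masked intervals with columns `start`, `end`
#'   (0-based half-open), sorted and non-overlapping.
#' @export
sdust_mask <- function(seq, window = 64L, threshold = 20L) {
  stopifnot(length(seq) == 1L, window >= 3L)
  n <- nchar(seq)
  if (n < 3L) return(tibble(start = integer(0), end = integer(0)))
  code <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], DNA_BASES) - 1L
  trip <- 16L * code[1:(n - 2L)] + 4L * code[2:(n - 1L)] + code[3:n]
  trip[is.na(trip)] <- -1L
  m <- sdust_scan_cpp(trip, as.integer(window) - 2L, as.integer(threshold))
  tibble(start = m[, 1], end = m[, 2])
}
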