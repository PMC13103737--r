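# Permutation-based enrichment of exact STR intervals in annotation classes.

#' STR enrichment relative to shuffled placements
#'
#' Computes the observed overlap (in bases) between a set of STR intervals
#' and each annotation class, then re-places every STR interval uniformly
#' at random on the genome `n_perm` times (length preserved, chromosome
#' chosen proportional to its length, overlaps among placed intervals
#' permitted) and reports the fold enrichment
#' `observed / mean(permuted)` per class. Deterministic under `seed`.
#'
#' @param strs Tibble `chrom`, `start`, `end` of STR intervals (take the
#'   union of [find_exact_tandem_repeats()] runs with `max_unit = 6`).
#' @param classes Named list of interval tibbles (`chrom`, `start`,
#'   `end`), one per annotation class; pre-merge fragmented annotations
#'   with [merge_repeat_annotations()] first.
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @param n_perm Number of permutations (default 100).
#' @param seed RNG seed.
#' @return A tibble of class `canisv_enrichment`: `class_name`,
#'   `observed_overlap`, `mean_permuted`, `fold`, `n_perm`, `seed`, with a
#'   `permuted` list-column of per-permutation overlaps.
#' @export
str_enrichment <- function(strs, classes, chrom_sizes, n_perm = 100L,
                           seed = 1L) {
  widths <- strs$end - strs$start
  if (any(widths > max(chrom_sizes))) {
    abort("an STR interval exceeds every chromosome length")
  }
  class_ranges <- lapply(classes, function(df) {
    split(IRanges::IRanges(df$start + 1L, df$end), df$chrom)
  })
  overlap_bp <- function(chrom, start, end) {
    ir_by_chrom <- split(IRanges::IRanges(start + 1L, end), chrom)
    vapply(class_ranges, function(cr) {
      tot <- 0
      for (ch in names(ir_by_chrom)) {
        if (is.null(cr[[ch]])) next
        ov <- IRanges::intersect(IRanges::reduce(ir_by_chrom[[ch]]),
                                 IRanges::reduce(cr[[ch]]))
        tot <- tot + sum(IRanges::width(ov))
      }
      tot
    }, numeric(1))
  }
  observed <- overlap_bp(strs$chrom, strs$start, strs$end)
  permuted <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_perm), function(p) {
      ch <- sample(names(chrom_sizes), length(widths), replace = TRUE,
                   prob = chrom_sizes)
      max_start <- chrom_sizes[ch] - widths
      st <- floor(runif(length(widths), 0, pmax(1, max_start)))
      overlap_bp(ch, st, st + widths)
    })
  })
  perm_mat <- do.call(rbind, permuted)
  out <- tibble(
    class_name = names(classes),
    observed_overlap = unname(as.numeric(observed)),
    mean_permuted = unname(colMeans(perm_mat)),
    fold = unname(as.numeric(observed) / colMeans(perm_mat)),
    n_perm = as.integer(n_perm),
    seed = as.integer(seed),
    permuted = lapply(seq_along(classes), function(k) perm_mat[, k])
  )
  class(out) <- c("canisv_enrichment", class(out))
  out
}

#' @export
tidy.canisv_enrichment <- function(x, ...) {
  as_tibble(x)[, c("class_name", "observed_overlap", "mean_permuted",
                   "fold", "n_perm")]
}

#' Genome-wide exact STR intervals
#'
#' Convenience wrapper running [find_exact_tandem_repeats()] per
#' chromosome and returning the merged union of runs as intervals.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param max_unit Maximum STR unit length (default 6).
#' @param ... Passed to [find_exact_tandem_repeats()].
#' @return Tibble `chrom`, `start`, `end`.
#' @export
genome_strs <- function(genome, max_unit = 6L, ...) {
  bind_rows(lapply(names(genome), function(ch) {
    runs <- find_exact_tandem_repeats(genome[[ch]], max_unit = max_unit, ...)
    m <- merge_intervals(runs$start, runs$end)
    if (nrow(m) == 0) return(NULL)
    tibble(chrom = ch, start = m$start, end = m$end)
  }))
}
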