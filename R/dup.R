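# Segmental-duplication pair filtering, classification and summarization.

#' Filter and classify segmental-duplication pairs
#'
#' Applies the base filter (length >= 1 kb, divergence <= 10%, optional
#' mitochondrial exclusion), then the recent-large-duplication subset
#' (length >= `min_len`, divergence <= `max_div`, both paralogs on
#' primary chromosomes when `chromosomes` is given). Retained pairs are
#' labelled `INTRA` or `INTER`; intra pairs are sub-labelled `TANDEM` when
#' the gap between the nearer ends of the paralogs is below `tandem_sep`
#' (0 when overlapping), else `DISPERSED`; inter pairs are flagged
#' centromeric when both paralog starts fall within `centromeric_window`
#' of the chromosome start.
#'
#' @param pairs Tibble from [read_dup_pairs()].
#' @param min_len Minimum pair length for the subset (default 10 kb).
#' @param max_div Maximum divergence (default 0.05).
#' @param base_min_len,base_max_div Base filter (defaults 1 kb, 0.10).
#' @param tandem_sep Tandem separation threshold (default 200,000 bp).
#' @param centromeric_window Centromeric window from the chromosome start
#'   (default 5 Mbp), tested on the interval start positions.
#' @param chromosomes Optional primary-chromosome list; pairs touching
#'   other sequences are removed.
#' @param mito Optional mitochondrial chromosome name(s) to exclude.
#' @return The retained pairs with `config` (`"INTRA"`/`"INTER"`),
#'   `subclass` (`"TANDEM"`/`"DISPERSED"` for intra, `NA` otherwise),
#'   `separation` and `centromeric` columns. Removal counts in
#'   `attr(, "filter_counts")`.
#' @export
filter_and_classify_dup_pairs <- function(pairs, min_len = 10000,
                                          max_div = 0.05,
                                          base_min_len = 1000,
                                          base_max_div = 0.10,
                                          tandem_sep = 200000,
                                          centromeric_window = 5e6,
                                          chromosomes = NULL,
                                          mito = NULL) {
  n0 <- nrow(pairs)
  bad <- with(pairs, is.na(length) | is.na(divergence) | length < 1 |
                divergence < 0 | divergence > 1 |
                endA <= startA | endB <= startB)
  if (any(bad)) {
    warn(paste0(sum(bad), " malformed duplication pair(s) skipped"))
    pairs <- pairs[!bad, ]
  }
  if (!is.null(mito)) {
    pairs <- pairs[!(pairs$chrA %in% mito | pairs$chrB %in% mito), ]
  }
  base <- pairs[pairs$length >= base_min_len &
                  pairs$divergence <= base_max_div, ]
  keep <- base$length >= min_len & base$divergence <= max_div
  if (!is.null(chromosomes)) {
    keep <- keep & base$chrA %in% chromosomes & base$chrB %in% chromosomes
  }
  out <- base[keep, ]
  out$config <- ifelse(out$chrA == out$chrB, "INTRA", "INTER")
  gap <- pmax(out$startA, out$startB) - pmin(out$endA, out$endB)
  out$separation <- ifelse(out$config == "INTRA", pmax(0, gap), NA_real_)
  out$subclass <- ifelse(out$config == "INTRA",
                         ifelse(out$separation < tandem_sep, "TANDEM",
                                "DISPERSED"),
                         NA_character_)
  out$centromeric <- out$config == "INTER" &
    out$startA < centromeric_window & out$startB < centromeric_window
  attr(out, "filter_counts") <- c(
    input = n0, malformed = sum(bad),
    base_removed = n0 - sum(bad) - nrow(base),
    subset_removed = nrow(base) - nrow(out),
    retained = nrow(out)
  )
  as_tibble(out)
}

round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Summarize classified duplication pairs
#'
#' Counts and percentages (one decimal, half-up; the centromeric share is
#' additionally reported at integer precision) for the intrachromosomal
#' share of all pairs, the tandem and dispersed shares of intrachromosomal
#' pairs, and the centromeric share of interchromosomal pairs; plus the
#' genome fraction covered by the non-redundant merged paralog intervals
#' when `genome_size` is given.
#'
#' @param pairs Output of [filter_and_classify_dup_pairs()].
#' @param genome_size Optional total genome size for the coverage fraction.
#' @return A list of class `canisv_dup_summary`.
#' @export
summarize_dup_pairs <- function(pairs, genome_size = NULL) {
  n <- nrow(pairs)
  n_intra <- sum(pairs$config == "INTRA")
  n_inter <- sum(pairs$config == "INTER")
  n_tandem <- sum(pairs$subclass == "TANDEM", na.rm = TRUE)
  n_disp <- sum(pairs$subclass == "DISPERSED", na.rm = TRUE)
  n_centro <- sum(pairs$centromeric, na.rm = TRUE)
  pct <- function(a, b) if (b > 0) round_half_up(100 * a / b, 1) else NA_real_
  nonred <- NULL
  coverage <- NA_real_
  if (n > 0) {
    iv <- bind_rows(
      tibble(chrom = pairs$chrA, start = pairs$startA, end = pairs$endA),
      tibble(chrom = pairs$chrB, start = pairs$startB, end = pairs$endB)
    )
    nonred <- iv |>
      group_by(.data$chrom) |>
      dplyr::reframe(merge_intervals(.data$start, .data$end)) |>
      ungroup()
    if (!is.null(genome_size)) {
      coverage <- sum(nonred$end - nonred$start) / genome_size
    }
  }
  structure(list(
    n_pairs = n, n_intra = n_intra, n_inter = n_inter,
    n_tandem = n_tandem, n_dispersed = n_disp, n_centromeric = n_centro,
    intra_pct = pct(n_intra, n),
    tandem_pct_of_intra = pct(n_tandem, n_intra),
    dispersed_pct_of_intra = pct(n_disp, n_intra),
    centromeric_pct_of_inter = pct(n_centro, n_inter),
    centromeric_pct_of_inter_int = if (n_inter > 0) {
      round_half_up(100 * n_centro / n_inter, 0)
    } else NA_real_,
    nonredundant = nonred,
    genome_coverage = coverage
  ), class = "canisv_dup_summary")
}

#' @export
print.canisv_dup_summary <- function(x, ...) {
  cat("<canisv_dup_summary>", x$n_pairs, "pairs\n")
  cat(sprintf("  intrachromosomal: %d (%.1f%%)\n", x$n_intra, x$intra_pct))
  cat(sprintf("    tandem: %d (%.1f%%)  dispersed: %d (%.1f%%)\n",
              x$n_tandem, x$tandem_pct_of_intra,
              x$n_dispersed, x$dispersed_pct_of_intra))
  cat(sprintf("  interchromosomal: %d, centromeric: %d (%.0f%%)\n",
              x$n_inter, x$n_centromeric, x$centromeric_pct_of_inter_int))
  invisible(x)
}

#' @export
glance.canisv_dup_summary <- function(x, ...) {
  tibble(n_pairs = x$n_pairs, n_intra = x$n_intra, n_inter = x$n_inter,
         intra_pct = x$intra_pct,
         tandem_pct_of_intra = x$tandem_pct_of_intra,
         dispersed_pct_of_intra = x$dispersed_pct_of_intra,
         centromeric_pct_of_inter = x$centromeric_pct_of_inter,
         genome_coverage = x$genome_coverage)
}
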