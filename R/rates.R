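# SNP-calibrated divergence and mobile-element insertion-rate estimation.

#' Count SNP divergence between two haplotypes
#'
#' Counts biallelic SNP sites (every allele exactly 1 bp) at which the two
#' haplotypes carry different alleles, excluding sites inside `mask`
#' intervals and, when `autosomes` is given, sites on other chromosomes.
#'
#' @param variants A `canisv_variants` tibble.
#' @param hap_a,hap_b Haplotype ids (`"<sample>.<1|2>"`).
#' @param mask Optional tibble `chrom`, `start`, `end` (0-based half-open)
#'   of excluded intervals (e.g. segmental-duplication annotations).
#' @param autosomes Optional autosomal chromosome names.
#' @return Integer count of differing SNP sites.
#' @export
count_snp_divergence <- function(variants, hap_a, hap_b, mask = NULL,
                                 autosomes = NULL) {
  probe <- variants$gt[[1]]
  if (!all(c(hap_a, hap_b) %in% names(probe))) {
    abort(paste0("haplotype missing from genotypes: ",
                 paste(setdiff(c(hap_a, hap_b), names(probe)),
                       collapse = ", ")))
  }
  is_snp <- nchar(variants$ref) == 1L &
    vapply(variants$alt, function(a) all(nchar(a) == 1L), logical(1))
  keep <- is_snp
  if (!is.null(autosomes)) keep <- keep & variants$chrom %in% autosomes
  if (!is.null(mask) && nrow(mask) > 0) {
    in_mask <- vapply(seq_len(nrow(variants)), function(i) {
      m <- mask[mask$chrom == variants$chrom[i], ]
      nrow(m) > 0 && any(m$start <= variants$pos[i] & m$end > variants$pos[i])
    }, logical(1))
    keep <- keep & !in_mask
  }
  idx <- which(keep)
  diffs <- vapply(idx, function(i) {
    g <- variants$gt[[i]]
    a <- g[[hap_a]]
    b <- g[[hap_b]]
    !is.na(a) && !is.na(b) && a != b
  }, logical(1))
  sum(diffs)
}

#' Filter LINE-1 loci to 3'-intact elements
#'
#' Removes dimorphic LINE-1 loci whose longest derived allele has a
#' LINE-1 annotation ending more than `tolerance` bases short of the 3'
#' end of the element consensus. Such alleles typically arise by deletion
#' inside an existing element rather than by a new insertion, and would
#' otherwise inflate insertion-rate estimates. The removal fraction is
#' reported overall and split by whether the locus lies inside a LINE-1
#' annotated in the reference, as a 2x2 table with an odds ratio (loci
#' inside existing elements are strongly enriched for removal).
#'
#' @param mei_loci LINE-1 loci from [identify_clean_mei_loci()], whose
#'   allele annotations carry consensus coordinates.
#' @param annots Annotations for the allele sequences (with `cons_end`).
#' @param consensus_length Length of the LINE-1 consensus.
#' @param tolerance Maximum allowed distance from the consensus 3' end
#'   (default 100 bp).
#' @param ref_annots Optional reference annotations used for the
#'   inside-existing-LINE-1 split.
#' @return The retained loci; `attr(, "removal")` holds the summary list
#'   (`n_removed`, `fraction_removed`, `table`, `odds_ratio`).
#' @export
filter_line1_3prime_intact <- function(mei_loci, annots, consensus_length,
                                       tolerance = 100L, ref_annots = NULL) {
  a <- as_tibble(annots)
  a <- a[!is.na(a$repeat_class) & startsWith(a$repeat_class, "LINE/L1"), ]
  cons_end_of <- function(locus_row) {
    vcf_idx <- attr(locus_row$alleles[[1]], "vcf_index") %||%
      (seq_along(locus_row$alleles[[1]]) - 1L)
    aid <- paste0(locus_row$locus_id, "_a",
                  vcf_idx[locus_row$longest_allele_index])
    hit <- a[a$seq_id == aid, ]
    if (nrow(hit) == 0) return(NA_integer_)
    max(hit$cons_end, na.rm = TRUE)
  }
  ce <- vapply(seq_len(nrow(mei_loci)), function(i) {
    cons_end_of(mei_loci[i, ])
  }, integer(1))
  keep <- !is.na(ce) & ce >= consensus_length - tolerance
  in_ref_l1 <- rep(FALSE, nrow(mei_loci))
  if (!is.null(ref_annots)) {
    r <- as_tibble(ref_annots)
    r <- r[!is.na(r$repeat_class) & startsWith(r$repeat_class, "LINE/L1"), ]
    in_ref_l1 <- vapply(seq_len(nrow(mei_loci)), function(i) {
      m <- r[r$seq_id == mei_loci$chrom[i], ]
      nrow(m) > 0 && any(m$start <= mei_loci$pos[i] & m$end > mei_loci$pos[i])
    }, logical(1))
  }
  tab <- table(removed = !keep, in_ref_l1 = in_ref_l1)
  or <- tryCatch({
    t22 <- tab[c("TRUE", "FALSE"), c("TRUE", "FALSE")]
    (t22[1, 1] * t22[2, 2]) / (t22[1, 2] * t22[2, 1])
  }, error = function(e) NA_real_)
  out <- mei_loci[keep, , drop = FALSE]
  attr(out, "removal") <- list(
    n_removed = sum(!keep),
    fraction_removed = if (nrow(mei_loci)) mean(!keep) else NA_real_,
    removed_frac_in_ref = if (any(in_ref_l1)) mean(!keep[in_ref_l1])
      else NA_real_,
    removed_frac_not_in_ref = if (any(!in_ref_l1)) mean(!keep[!in_ref_l1])
      else NA_real_,
    table = tab,
    odds_ratio = or
  )
  attr(out, "samples") <- attr(mei_loci, "samples")
  out
}

#' Estimate mobile-element insertion rate per generation
#'
#' For each pairwise comparison, the divergence time in generations is
#' calibrated from SNP counts as \eqn{T = D / (2 \mu L)} (both lineages
#' accumulate substitutions), and the insertion rate on one lineage as
#' \eqn{r = N / T}, where N counts insertions present in the focal genome
#' and absent in the comparator. The reported rate is the mean over the
#' comparisons, with its reciprocal expressed as "one new insertion in
#' X births".
#'
#' @param insertions_by_comparison Tibble `label`, `n` of insertion counts.
#' @param snps_by_comparison Tibble `label`, `d` of SNP difference counts.
#' @param genome_size Analysed genome size L in bp.
#' @param mu SNP mutation rate per bp per generation (default 4.5e-9).
#' @param element_type Label stored on the estimate.
#' @return An object of class `canisv_rates`; see [tidy.canisv_rates()].
#' @export
estimate_insertion_rate <- function(insertions_by_comparison,
                                    snps_by_comparison,
                                    genome_size, mu = 4.5e-9,
                                    element_type = "SINEC") {
  stopifnot(genome_size > 0)
  per <- dplyr::inner_join(
    rename(insertions_by_comparison, n = 2),
    rename(snps_by_comparison, d = 2),
    by = "label"
  )
  if (nrow(per) != nrow(insertions_by_comparison) ||
      nrow(per) != nrow(snps_by_comparison)) {
    abort("comparison labels do not match between insertion and SNP tables")
  }
  if (any(per$d == 0 & per$n > 0)) {
    abort("zero SNP divergence with nonzero insertions: divergence time undefined")
  }
  per$divergence_generations <- per$d / (2 * mu * genome_size)
  per$rate <- ifelse(per$n == 0 & per$divergence_generations == 0, 0,
                     per$n / per$divergence_generations)
  mean_rate <- mean(per$rate)
  structure(list(
    element_type = element_type,
    per_comparison = as_tibble(per[, c("label", "d",
                                       "divergence_generations", "n",
                                       "rate")]),
    mean_rate = mean_rate,
    mean_rate_reciprocal = if (mean_rate > 0) round(1 / mean_rate) else Inf,
    mu = mu,
    genome_size = genome_size
  ), class = "canisv_rates")
}

#' @export
print.canisv_rates <- function(x, ...) {
  cat("<canisv_rates>", x$element_type, "insertion rate\n")
  cat(sprintf("  mean rate: %.3g per generation (~1 in %s births)\n",
              x$mean_rate, format(x$mean_rate_reciprocal, big.mark = ",")))
  cat("  ", nrow(x$per_comparison), "comparisons, mu =", x$mu,
      ", L =", x$genome_size, "bp\n")
  invisible(x)
}

#' Tidy a rate estimate
#'
#' @param x A `canisv_rates` object.
#' @param ... Unused.
#' @return One row per comparison: `label`, `snp_count`,
#'   `divergence_generations`, `insertion_count`, `rate`.
#' @export
tidy.canisv_rates <- function(x, ...) {
  out <- x$per_comparison
  rename(out, snp_count = "d", insertion_count = "n")
}

#' @rdname tidy.canisv_rates
#' @export
glance.canisv_rates <- function(x, ...) {
  tibble(element_type = x$element_type,
         mean_rate = x$mean_rate,
         mean_rate_reciprocal = x$mean_rate_reciprocal,
         n_comparisons = nrow(x$per_comparison),
         mu = x$mu, genome_size = x$genome_size)
}
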