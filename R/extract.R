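# Structural-variant locus extraction from the pangenome variant table.

#' Extract insertion/deletion structural-variant loci
#'
#' Applies the three locus filters, in order: a locus is removed if
#' (i) any analysed haplotype has a missing genotype, (ii) it is not
#' variable among the analysed samples (all analysed haplotypes carry one
#' allele), or (iii) the maximum difference in allele size among the
#' analysed samples is less than `min_size_diff` bp. A site failing several
#' filters is attributed to the first. Alleles not carried by any analysed
#' haplotype (reference-only alleles) are dropped from the locus allele
#' list; allele indices in `hap_allele` are re-mapped accordingly.
#'
#' @param variants A `canisv_variants` tibble from [read_pangenome_vcf()].
#' @param samples Character vector of analysed samples (must exclude the
#'   reference-path sample).
#' @param min_size_diff Minimum size difference between the longest and
#'   shortest carried allele (default 50 bp).
#' @return A tibble of retained loci with columns `locus_id`, `chrom`,
#'   `pos` (0-based anchor), `alleles` (list; anchor base included, so the
#'   empty site is exactly 1 bp), `hap_allele` (list of named indices into
#'   `alleles`), `longest_allele_index` (1-based into `alleles`; ties break
#'   to the lower allele index), `max_size_diff`, `n_distinct_alleles` and
#'   `allele_count_class`. Per-filter removal counts are attached as
#'   `attr(, "filter_counts")`.
#' @export
extract_sv_loci <- function(variants, samples = attr(variants, "samples"),
                            min_size_diff = 50L) {
  if (is.null(samples) || length(samples) == 0) {
    abort("empty sample list")
  }
  hap_names <- as.vector(rbind(paste0(samples, ".1"), paste0(samples, ".2")))
  n <- nrow(variants)
  counts <- c(input = n, missing = 0L, invariant = 0L, size = 0L,
              retained = 0L)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    gt <- variants$gt[[i]][hap_names]
    if (anyNA(gt)) {
      counts["missing"] <- counts["missing"] + 1L
      next
    }
    idx <- unique(gt)
    if (length(idx) < 2L) {
      counts["invariant"] <- counts["invariant"] + 1L
      next
    }
    all_alleles <- c(variants$ref[i], variants$alt[[i]])
    carried <- sort(idx)
    lens <- nchar(all_alleles[carried + 1L])
    size_diff <- max(lens) - min(lens)
    if (size_diff < min_size_diff) {
      counts["size"] <- counts["size"] + 1L
      next
    }
    counts["retained"] <- counts["retained"] + 1L
    # Restrict alleles to those carried; re-map indices to 1..k.
    alleles <- all_alleles[carried + 1L]
    attr(alleles, "vcf_index") <- carried
    remap <- match(gt, carried)
    names(remap) <- hap_names
    longest <- which.max(nchar(alleles))  # which.max takes the first tie
    rows[[i]] <- tibble(
      locus_id = paste0(variants$chrom[i], ":", variants$pos[i] + 1L),
      chrom = variants$chrom[i],
      pos = variants$pos[i],
      vcf_id = variants$id[i],
      alleles = list(alleles),
      hap_allele = list(remap),
      longest_allele_index = as.integer(longest),
      max_size_diff = as.integer(size_diff)
    )
  }
  out <- bind_rows(rows)
  if (nrow(out) > 0) {
    out$n_distinct_alleles <- vapply(out$alleles, length, integer(1))
    out$allele_count_class <- allele_count_class(out$n_distinct_alleles)
  } else {
    out <- tibble(locus_id = character(0), chrom = character(0),
                  pos = integer(0), vcf_id = character(0),
                  alleles = list(), hap_allele = list(),
                  longest_allele_index = integer(0),
                  max_size_diff = integer(0),
                  n_distinct_alleles = integer(0),
                  allele_count_class = character(0))
  }
  attr(out, "filter_counts") <- counts
  attr(out, "samples") <- samples
  out
}

allele_count_class <- function(k) {
  dplyr::case_when(
    k == 2 ~ "biallelic",
    k == 3 ~ "triallelic",
    k > 3 ~ "multiallelic",
    TRUE ~ NA_character_
  )
}

#' Longest allele at a locus
#'
#' Returns the maximum-length allele carried by an analysed haplotype (ties
#' break to the lower allele index). With `strip_anchor = TRUE` the 1 bp
#' VCF padding base is removed, yielding the insertion body used for
#' composition analysis.
#'
#' @param locus One row of the [extract_sv_loci()] tibble.
#' @param strip_anchor Remove the leading anchor base (default `TRUE`).
#' @return A character scalar.
#' @export
longest_allele <- function(locus, strip_anchor = TRUE) {
  a <- locus$alleles[[1]][locus$longest_allele_index[1]]
  if (strip_anchor) substr(a, 2L, nchar(a)) else a
}

#' Count distinct alleles at a locus
#'
#' @param locus One row of the [extract_sv_loci()] tibble.
#' @return A list with `n` (distinct allele sequences carried by analysed
#'   haplotypes) and `class` (`biallelic`, `triallelic`, or `multiallelic`
#'   for more than three).
#' @export
count_distinct_alleles <- function(locus) {
  n <- length(unique(locus$alleles[[1]]))
  list(n = n, class = allele_count_class(n))
}
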