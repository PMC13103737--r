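# Ten-category repeat-composition classification of SV alleles.

SV_CATEGORIES <- c("SINEC", "LINE/L1", "LTR/ERV", "OtherRepeat",
                   "LowComplexity", "STR", "VNTR", "Mixed", "Partial",
                   "Unclassified")

# Repeat-type bucket for an element annotation (non simple/low-complexity).
element_type_of <- function(repeat_name, repeat_class) {
  dplyr::case_when(
    startsWith(repeat_name, "SINEC") ~ "SINEC",
    startsWith(repeat_class, "LINE/L1") ~ "LINE/L1",
    startsWith(repeat_class, "LTR") ~ "LTR/ERV",
    TRUE ~ "OtherRepeat"
  )
}

#' Classify one SV allele into the ten composition categories
#'
#' The decision procedure, applied in order to the longest allele (anchor
#' base stripped):
#'
#' (1) if merged element annotations of a single repeat type (SINEC;
#' LINE/L1; LTR/ERV; anything else pooled as OtherRepeat) cover >= 70% of
#' the allele, the locus takes that type — when several types pass, the
#' larger covered length wins, ties break SINEC > LINE/L1 > LTR/ERV >
#' OtherRepeat. (2) Else if DUST plus Simple_repeat/Low_complexity
#' annotations cover >= 70%, the locus is LowComplexity, re-labelled VNTR
#' if exact tandem runs with unit length >= 7 cover >= 70%, or STR if runs
#' with unit length <= 6 cover >= 70%. (3) Else if the union of DUST and
#' all repeat annotations covers >= 70%, Mixed. (4) Else if that union
#' covers >= 5%, Partial. (5) Else Unclassified.
#'
#' @param allele The allele body (anchor base already stripped).
#' @param annots Merged repeat annotations on the allele (coordinates on
#'   the allele, 0-based); pass the output of [merge_repeat_annotations()].
#' @param dust Optional precomputed [sdust_mask()] intervals; computed if
#'   `NULL`.
#' @param trs Optional precomputed [find_exact_tandem_repeats()] runs with
#'   unrestricted unit length; computed if `NULL`.
#' @param coverage Main composition threshold (default 0.70).
#' @param partial Minimum annotated fraction for Partial (default 0.05).
#' @param str_unit_max,vntr_unit_min Unit-length split between STR and VNTR
#'   (defaults 6 and 7).
#' @return A one-row tibble: `category`, `rm_fraction` (all repeat
#'   annotations), `dust_fraction`, `union_fraction`, `tr_fraction_str`,
#'   `tr_fraction_vntr`.
#' @export
classify_locus <- function(allele, annots = NULL, dust = NULL, trs = NULL,
                           coverage = 0.70, partial = 0.05,
                           str_unit_max = 6L, vntr_unit_min = 7L) {
  len <- nchar(allele)
  stopifnot(len > 0)
  if (is.null(annots)) annots <- empty_annotation_set()
  if (is.null(dust)) dust <- sdust_mask(allele)
  lazy_trs <- is.null(trs)  # computed only if the low-complexity clause fires

  clip <- function(df) {
    if (nrow(df) == 0) return(df)
    df$start <- pmax(df$start, 0L)
    df$end <- pmin(df$end, len)
    df[df$end > df$start, , drop = FALSE]
  }
  annots <- clip(as_tibble(annots))
  dust <- clip(dust)

  simple <- annots[is_simple_class(annots$repeat_class), , drop = FALSE]
  elems <- annots[!is_simple_class(annots$repeat_class), , drop = FALSE]

  rm_fraction <- union_coverage(annots, len)
  dust_fraction <- union_coverage(dust, len)
  lc_fraction <- union_coverage(
    tibble(start = c(dust$start, simple$start),
           end = c(dust$end, simple$end)), len)
  union_fraction <- union_coverage(
    tibble(start = c(dust$start, annots$start),
           end = c(dust$end, annots$end)), len)
  tr_fraction_str <- NA_real_
  tr_fraction_vntr <- NA_real_
  compute_tr_fractions <- function() {
    if (lazy_trs) {
      trs <<- find_exact_tandem_repeats(allele, max_unit = NULL)
      lazy_trs <<- FALSE
    }
    tr_str <- trs[trs$unit_length <= str_unit_max, , drop = FALSE]
    tr_vntr <- trs[trs$unit_length >= vntr_unit_min, , drop = FALSE]
    tr_fraction_str <<- union_coverage(tr_str, len)
    tr_fraction_vntr <<- union_coverage(tr_vntr, len)
  }

  category <- NA_character_
  if (nrow(elems) > 0) {
    types <- element_type_of(elems$repeat_name, elems$repeat_class)
    cov_by_type <- vapply(split(elems, types), union_coverage, numeric(1),
                          length = len)
    passing <- cov_by_type[cov_by_type >= coverage]
    if (length(passing) > 0) {
      pref <- c("SINEC", "LINE/L1", "LTR/ERV", "OtherRepeat")
      ord <- order(-passing, match(names(passing), pref))
      category <- names(passing)[ord[1]]
    }
  }
  if (is.na(category) && lc_fraction >= coverage) {
    category <- "LowComplexity"
    compute_tr_fractions()
    if (tr_fraction_vntr >= coverage) {
      category <- "VNTR"
    } else if (tr_fraction_str >= coverage) {
      category <- "STR"
    }
  }
  if (is.na(category)) {
    category <- if (union_fraction >= coverage) {
      "Mixed"
    } else if (union_fraction >= partial) {
      "Partial"
    } else {
      "Unclassified"
    }
  }
  tibble(category = category, rm_fraction = rm_fraction,
         dust_fraction = dust_fraction, union_fraction = union_fraction,
         tr_fraction_str = tr_fraction_str,
         tr_fraction_vntr = tr_fraction_vntr)
}

#' Classify every extracted SV locus
#'
#' Looks up each locus's longest-allele annotations by allele name
#' (`"<locus_id>_a<k>"`, `k` the 1-based index into the locus allele list
#' minus one for the reference allele, i.e. `_a0` for the reference allele
#' and `_a1`.. for ALT alleles), merges them with
#' [merge_repeat_annotations()], and applies [classify_locus()]. When a
#' locus has no annotations and `library` is supplied, the built-in
#' annotator is used instead.
#'
#' @param loci Tibble from [extract_sv_loci()].
#' @param annots A `canisv_annotations` tibble covering allele sequences.
#' @param library Optional [build_repeat_library()] fallback annotator.
#' @param ... Passed to [classify_locus()].
#' @return `loci` with the classification columns appended.
#' @export
classify_loci <- function(loci, annots = NULL, library = NULL, ...) {
  if (is.null(annots)) annots <- empty_annotation_set()
  merged <- merge_repeat_annotations(annots)
  by_seq <- split(as_tibble(merged), merged$seq_id)
  res <- vector("list", nrow(loci))
  for (i in seq_len(nrow(loci))) {
    allele <- longest_allele(loci[i, ])
    aid <- allele_name(loci$locus_id[i], loci$longest_allele_index[i],
                       loci[i, ])
    a <- by_seq[[aid]]
    if (is.null(a) && !is.null(library)) {
      a <- merge_repeat_annotations(
        annotate_with_library(allele, library, seq_id = aid))
    }
    res[[i]] <- classify_locus(allele, a, ...)
  }
  dplyr::bind_cols(loci, bind_rows(res))
}

# VCF allele index (0 = REF) for a locus-table allele slot: the allele list
# was re-mapped to carried alleles, so recover the original index from the
# stored map when available; synthetic truth names use the ALT index.
allele_name <- function(locus_id, slot, locus_row) {
  orig <- attr(locus_row$alleles[[1]], "vcf_index")
  k <- if (!is.null(orig)) orig[slot] else slot - 1L
  paste0(locus_id, "_a", k)
}

#' Summarize locus classifications
#'
#' @param loci Classified loci from [classify_loci()].
#' @param n_bins Number of log-spaced size-difference histogram bins.
#' @return A list of class `canisv_classification_summary` with `by_category`
#'   (counts split by allele-count class), `size_histogram` (log-spaced bins
#'   of the largest-minus-smallest allele size difference) and `n_loci`.
#' @export
classification_summary <- function(loci, n_bins = 30L) {
  cats <- factor(if (nrow(loci)) loci$category else character(0),
                 levels = SV_CATEGORIES)
  acc <- factor(if (nrow(loci)) loci$allele_count_class else character(0),
                levels = c("biallelic", "triallelic", "multiallelic"))
  by_category <- as_tibble(as.data.frame(table(
    category = cats, allele_count_class = acc), stringsAsFactors = FALSE))
  names(by_category)[3] <- "n"
  if (nrow(loci) > 0) {
    # Bins of equal size on a log scale over the size-difference range.
    lo <- max(1, min(loci$max_size_diff))
    hi <- max(loci$max_size_diff) + 1
    breaks <- unique(exp(seq(log(lo), log(hi), length.out = n_bins + 1)))
    bins <- cut(loci$max_size_diff, breaks = breaks, include.lowest = TRUE,
                right = FALSE)
    counts <- as.integer(table(bins))
    size_histogram <- tibble(bin_lo = breaks[-length(breaks)],
                             bin_hi = breaks[-1], n = counts)
  } else {
    size_histogram <- tibble(bin_lo = numeric(0), bin_hi = numeric(0),
                             n = integer(0))
  }
  structure(list(by_category = by_category, size_histogram = size_histogram,
                 n_loci = nrow(loci)),
            class = "canisv_classification_summary")
}

#' @export
print.canisv_classification_summary <- function(x, ...) {
  cat("<canisv_classification_summary>", x$n_loci, "loci\n")
  tot <- x$by_category |>
    group_by(.data$category) |>
    summarise(n = sum(.data$n), .groups = "drop")
  print(tot, n = Inf)
  invisible(x)
}
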