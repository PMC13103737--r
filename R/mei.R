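# Dimorphic mobile-element locus genetics: clean-locus identification,
# allelic heterogeneity, and ancestral/derived allele sharing.

#' Identify clean dimorphic SINEC or LINE-1 loci
#'
#' Retains loci where every observed allele is either the 1 bp empty site
#' (the ancestral, pre-insertion state) or an allele classified to the
#' requested element type (the derived state). Loci carrying any other
#' allele are excluded with a reason. Every allele of a candidate locus is
#' classified, not just the longest.
#'
#' @param loci Classified loci from [classify_loci()].
#' @param mei_type `"SINEC"` or `"LINE/L1"`.
#' @param annots Annotations covering all allele sequences (as passed to
#'   [classify_loci()]).
#' @param ... Passed to [classify_locus()] for the non-longest alleles.
#' @return A tibble of MEI loci: the input columns plus `mei_type`,
#'   `states` (list of named `"ANCESTRAL"`/`"DERIVED"` per haplotype),
#'   `derived_alleles` (list of distinct derived allele bodies) and
#'   `n_derived_distinct`. Excluded candidate loci (longest allele of the
#'   right type but another allele inconsistent) are reported in
#'   `attr(, "excluded")`.
#' @export
identify_clean_mei_loci <- function(loci, mei_type = c("SINEC", "LINE/L1"),
                                    annots = NULL, ...) {
  mei_type <- match.arg(mei_type)
  if (is.null(annots)) annots <- empty_annotation_set()
  merged <- merge_repeat_annotations(annots)
  by_seq <- split(as_tibble(merged), merged$seq_id)
  cand <- loci[loci$category == mei_type, , drop = FALSE]
  keep <- logical(nrow(cand))
  states <- vector("list", nrow(cand))
  derived <- vector("list", nrow(cand))
  reason <- character(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    alleles <- cand$alleles[[i]]
    vcf_idx <- attr(alleles, "vcf_index") %||% (seq_along(alleles) - 1L)
    ok <- TRUE
    st <- setNames(rep(NA_character_, length(alleles)), NULL)
    for (k in seq_along(alleles)) {
      body <- substr(alleles[k], 2L, nchar(alleles[k]))
      if (nchar(body) == 0L) {
        st[k] <- "ANCESTRAL"
        next
      }
      if (k == cand$longest_allele_index[i]) {
        st[k] <- "DERIVED"  # longest allele already classified to mei_type
        next
      }
      aid <- paste0(cand$locus_id[i], "_a", vcf_idx[k])
      cl <- classify_locus(body, by_seq[[aid]], ...)
      if (cl$category == mei_type) {
        st[k] <- "DERIVED"
      } else {
        ok <- FALSE
        reason[i] <- paste0("allele ", k, " classified ", cl$category)
        break
      }
    }
    keep[i] <- ok
    if (ok) {
      hap_states <- st[cand$hap_allele[[i]]]
      names(hap_states) <- names(cand$hap_allele[[i]])
      states[[i]] <- hap_states
      bodies <- substr(alleles, 2L, nchar(alleles))
      derived[[i]] <- unique(bodies[st == "DERIVED" & !is.na(st)])
    }
  }
  out <- cand[keep, , drop = FALSE]
  out$mei_type <- mei_type
  out$states <- states[keep]
  out$derived_alleles <- derived[keep]
  out$n_derived_distinct <- vapply(out$derived_alleles, length, integer(1))
  attr(out, "excluded") <- tibble(locus_id = cand$locus_id[!keep],
                                  reason = reason[!keep])
  attr(out, "samples") <- attr(loci, "samples")
  out
}

#' Allelic heterogeneity of a dimorphic MEI locus
#'
#' The number of distinct derived allele sequences observed at the locus —
#' a count of post-insertion mutation visible among the sampled haplotypes
#' (for SINECs, typically (CT)N-run and A-tail length changes).
#'
#' @param locus One row of the [identify_clean_mei_loci()] tibble.
#' @return Integer count (>= 1).
#' @export
allele_heterogeneity <- function(locus) {
  length(locus$derived_alleles[[1]])
}

#' Allele sharing of dimorphic MEI loci across samples
#'
#' Tabulates per-sample presence/absence of the derived (insertion) state.
#' Presence is counted at the individual level: a sample carries the
#' insertion if either haplotype is derived. Loci where no ancestral allele
#' was observed count as present in all carriers of the derived state
#' (pattern all-1 when every sample carries it), since the ancestral state
#' of an MEI locus is known a priori to be the empty site.
#'
#' @param loci Tibble from [identify_clean_mei_loci()].
#' @param samples Sample order for the report (default: stored order).
#' @param autosomes Optional character vector of autosomal chromosome
#'   names; when given, loci on other chromosomes are dropped.
#' @param given Optional sample name: also report, among loci present in
#'   `given`, the fraction shared with each other sample.
#' @return An object of class `canisv_sharing`: a list with `per_sample`
#'   (`n_present`, `n_het`, `n_hom`, `n_singleton`), `profiles` (counts per
#'   presence/absence pattern over `samples`), `conditional` (when `given`
#'   is set) and `n_loci`.
#' @export
allele_sharing <- function(loci, samples = NULL, autosomes = NULL,
                           given = NULL) {
  samples <- samples %||% attr(loci, "samples")
  if (is.null(samples)) abort("sample list required")
  if (!is.null(autosomes)) {
    loci <- loci[loci$chrom %in% autosomes, , drop = FALSE]
  }
  n <- nrow(loci)
  pres <- matrix(FALSE, nrow = n, ncol = length(samples),
                 dimnames = list(NULL, samples))
  het <- matrix(FALSE, nrow = n, ncol = length(samples),
                dimnames = list(NULL, samples))
  hom <- het
  for (i in seq_len(n)) {
    st <- loci$states[[i]]
    for (s in samples) {
      h <- st[paste0(s, ".", 1:2)]
      if (anyNA(h)) abort(paste0("sample ", s, " absent from locus states"))
      d <- sum(h == "DERIVED")
      pres[i, s] <- d > 0
      het[i, s] <- d == 1
      hom[i, s] <- d == 2
    }
  }
  n_present <- colSums(pres)
  singleton <- rowSums(pres) == 1
  per_sample <- tibble(
    sample = samples,
    n_present = as.integer(n_present),
    n_het = as.integer(colSums(het)),
    n_hom = as.integer(colSums(hom)),
    n_singleton = as.integer(colSums(pres & singleton))
  )
  pattern <- apply(pres, 1, function(x) paste(as.integer(x), collapse = ""))
  profiles <- as_tibble(as.data.frame(table(pattern = pattern),
                                      stringsAsFactors = FALSE))
  names(profiles)[2] <- "n"
  conditional <- NULL
  if (!is.null(given)) {
    if (!given %in% samples) abort(paste0("sample ", given, " not in samples"))
    in_g <- pres[, given]
    conditional <- tibble(
      sample = setdiff(samples, given),
      frac_shared = vapply(setdiff(samples, given), function(s) {
        if (sum(in_g) == 0) NA_real_ else mean(pres[in_g, s])
      }, numeric(1)),
      n_given = sum(in_g)
    )
  }
  structure(list(per_sample = per_sample, profiles = profiles,
                 conditional = conditional, n_loci = n, samples = samples),
            class = "canisv_sharing")
}

#' @export
print.canisv_sharing <- function(x, ...) {
  cat("<canisv_sharing>", x$n_loci, "loci across",
      length(x$samples), "samples\n")
  print(x$per_sample)
  invisible(x)
}
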