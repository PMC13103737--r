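# Synthetic consensus repeat library.
#
# The library emulates the canine repeat families that dominate structural
# variation: a ~200 bp SINEC (tRNA-derived SINE with an internal (CT)N
# microsatellite and an A-rich tail), a ~6 kb LINE-1 with two designed open
# reading frames (ORF1p, ORF2p) and a 3' polyadenylation signal, an LTR/ERV
# unit, a satellite unit and a DNA-transposon unit. The SINEC and LINE-1
# consensi are built codon-aligned and free of stop codons in frame 0 so
# that a SINEC inserted at a codon boundary inside ORF2 keeps the reading
# frame open (the nested-allele scenario).

#' Build a synthetic consensus repeat library
#'
#' Deterministic under `seed`: the same seed always yields the same library;
#' different seeds yield different sequences with the same structural layout.
#'
#' @param seed Integer RNG seed.
#' @return An object of class `canisv_repeat_library`: a list with elements
#'   `sinec_consensus`, `line1_consensus`, `ltr_unit`, `satellite_unit`,
#'   `other_unit`, `protein_orf1`, `protein_orf2`, ORF coordinates
#'   (`orf1_range`, `orf2_range`, 1-based on the LINE-1 consensus) and a
#'   `consensus` tibble (`name`, `class`, `seq`, `length`) used by the
#'   annotator.
#' @export
build_repeat_library <- function(seed = 1L) {
  withr::local_seed(as.integer(seed))

  # SINEC: 201 bp = head (30 codons) + (CT)x12 (8 codons) + body (19 codons)
  # + A-tail (10 codons). Guard bases prevent the (CT) run from extending.
  head <- paste0(rand_codons(29L), "GAG")
  ct_run <- strrep("CT", 12L)
  body <- paste0("AAG", rand_codons(18L))
  a_tail <- strrep("A", 30L)
  sinec <- paste0(head, ct_run, body, a_tail)
  stopifnot(nchar(sinec) == 201L, nchar(sinec) %% 3 == 0)

  # LINE-1: 5'UTR (201 bp ending in an in-frame TAA), ORF1 (ATG + 333 codons
  # + TAA = 1005 bp), a 60 bp spacer with in-frame stops, ORF2 (ATG + 1248
  # codons + TAA = 3750 bp), 3'UTR (947 bp ending AATAAA + CTGCA...).
  utr5 <- paste0(rand_codons(66L), "TAA")
  orf1 <- paste0("ATG", rand_codons(333L), "TAA")
  spacer <- paste0("TAG", strrep("GGC", 18L), "TAA")
  orf2 <- paste0("ATG", rand_codons(1248L), "TAA")
  utr3 <- paste0(rand_codons(310L), "AATAAA", "CTGCATTGC")
  line1 <- paste0(utr5, orf1, spacer, orf2, utr3)
  orf1_start <- nchar(utr5) + 1L
  orf2_start <- nchar(utr5) + nchar(orf1) + nchar(spacer) + 1L
  protein_orf1 <- sub("\\*$", "", translate_dna(orf1))
  protein_orf2 <- sub("\\*$", "", translate_dna(orf2))
  stopifnot(!grepl("\\*", protein_orf1), !grepl("\\*", protein_orf2))

  ltr <- rand_dna(420L)
  satellite <- rand_dna(147L)
  other <- rand_dna(320L)

  lib <- list(
    sinec_consensus = sinec,
    line1_consensus = line1,
    ltr_unit = ltr,
    satellite_unit = satellite,
    other_unit = other,
    protein_orf1 = protein_orf1,
    protein_orf2 = protein_orf2,
    orf1_range = c(orf1_start, orf1_start + nchar(orf1) - 1L),
    orf2_range = c(orf2_start, orf2_start + nchar(orf2) - 1L),
    consensus = tibble(
      name = c("SINEC_sim", "L1_sim", "LTR_sim", "SAT_sim", "CHARLIE_sim"),
      class = c("SINE/tRNA-Lys", "LINE/L1", "LTR/ERV", "Satellite", "DNA/hAT"),
      seq = c(sinec, line1, ltr, satellite, other)
    ),
    seed = as.integer(seed)
  )
  lib$consensus$length <- nchar(lib$consensus$seq)
  class(lib) <- "canisv_repeat_library"
  lib
}

#' @export
print.canisv_repeat_library <- function(x, ...) {
  cat("<canisv_repeat_library> seed", x$seed, "\n")
  print(x$consensus[, c("name", "class", "length")])
  invisible(x)
}
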