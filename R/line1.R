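# LINE-1 specific analyses: ORF intactness, 3' transduction extraction,
# alignment filtering, and source-element resolution.

# All ORFs (ATG..stop, >= min_codons codons) in the forward frames of seq.
scan_orfs <- function(seq, min_codons = 300L) {
  n <- nchar(seq)
  out <- list()
  chars <- strsplit(seq, "")[[1]]
  for (frame in 0:2) {
    starts <- seq(1L + frame, n - 2L, by = 3L)
    if (length(starts) == 0) next
    codons <- paste0(chars[starts], chars[starts + 1L], chars[starts + 2L])
    is_stop <- codons %in% c("TAA", "TAG", "TGA")
    is_atg <- codons == "ATG"
    # Segments between stops; ORF = first ATG .. stop.
    seg_start <- 1L
    bounds <- c(which(is_stop), length(codons) + 1L)
    for (b in bounds) {
      seg <- seg_start:(b - 1L)
      seg_start <- b + 1L
      if (length(seg) < 1 || b > length(codons)) next  # require a stop codon
      atg <- seg[is_atg[seg]]
      if (length(atg) == 0) next
      orf_codons <- b - atg[1]
      if (orf_codons < min_codons) next
      nt_start <- starts[atg[1]]
      nt_end <- starts[b] + 2L
      prot <- paste(Biostrings::GENETIC_CODE[codons[atg[1]:(b - 1L)]],
                    collapse = "")
      out[[length(out) + 1L]] <- tibble(
        start = nt_start - 1L, end = nt_end, frame = frame,
        n_codons = as.integer(orf_codons), protein = prot
      )
    }
  }
  bind_rows(out)
}

#' Scan a LINE-1 allele for intact ORF1p/ORF2p reading frames
#'
#' Alleles whose merged LINE-1 annotation spans less than `min_len` bases
#' are skipped (returned empty with `attr(, "skipped") = TRUE`). Otherwise
#' every ORF of at least 300 codons on the element strand is reported,
#' matched to the library's ORF1p/ORF2p consensus proteins by local
#' alignment, and called intact when the alignment spans at least 90% of
#' the matched consensus protein. An allele is "fully intact" when both
#' ORF1p and ORF2p have an intact call. A SINEC inserted in-frame into
#' ORF2 yields an ORF2p call whose protein is longer than the consensus;
#' the elongation is reported in `insertion_codons`.
#'
#' @param allele Allele body (anchor stripped).
#' @param annots Merged annotations on the allele (used for the LINE-1
#'   span and strand).
#' @param library A [build_repeat_library()] object.
#' @param min_len Minimum LINE-1 annotation span (default 4000 bp).
#' @param min_cons_frac Minimum consensus-protein fraction covered by the
#'   alignment for an intact call (default 0.9).
#' @return A tibble of ORF calls: `start`, `end`, `frame`, `strand`,
#'   `n_codons`, `protein`, `matches` (`"ORF1p"`/`"ORF2p"`), `intact`,
#'   `insertion_codons`. `attr(, "fully_intact")` is `TRUE` when both
#'   proteins are intact.
#' @export
find_intact_orfs <- function(allele, annots, library, min_len = 4000L,
                             min_cons_frac = 0.9) {
  l1 <- as_tibble(annots)
  l1 <- l1[!is.na(l1$repeat_class) & startsWith(l1$repeat_class, "LINE/L1"), ]
  empty <- tibble(start = integer(0), end = integer(0), frame = integer(0),
                  strand = character(0), n_codons = integer(0),
                  protein = character(0), matches = character(0),
                  intact = logical(0), insertion_codons = integer(0))
  if (nrow(l1) == 0) {
    attr(empty, "skipped") <- TRUE
    return(empty)
  }
  span <- sum(l1$end - l1$start)
  if (span < min_len) {
    attr(empty, "skipped") <- TRUE
    return(empty)
  }
  strand <- l1$strand[which.max(l1$end - l1$start)]
  seq <- if (identical(strand, "-")) revcomp(allele) else allele
  orfs <- scan_orfs(seq, min_codons = 300L)
  if (nrow(orfs) == 0) {
    attr(empty, "skipped") <- FALSE
    return(empty)
  }
  cons <- list(ORF1p = library$protein_orf1, ORF2p = library$protein_orf2)
  calls <- lapply(seq_len(nrow(orfs)), function(i) {
    prot <- orfs$protein[i]
    scores <- vapply(names(cons), function(nm) {
      al <- Biostrings::pairwiseAlignment(
        pattern = Biostrings::AAString(prot),
        subject = Biostrings::AAString(cons[[nm]]),
        type = "local", substitutionMatrix = "BLOSUM62",
        gapOpening = 10, gapExtension = 0.5
      )
      Biostrings::score(al)
    }, numeric(1))
    best <- names(cons)[which.max(scores)]
    al <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAString(prot),
      subject = Biostrings::AAString(cons[[best]]),
      type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5
    )
    cons_cov <- al@subject@range@width / nchar(cons[[best]])
    intact <- cons_cov >= min_cons_frac
    tibble(
      start = orfs$start[i], end = orfs$end[i], frame = orfs$frame[i],
      strand = strand, n_codons = orfs$n_codons[i], protein = prot,
      matches = best, intact = intact,
      insertion_codons = max(0L, nchar(prot) - nchar(cons[[best]]))
    )
  })
  out <- bind_rows(calls)
  # Keep the best call per consensus protein.
  out <- out |>
    group_by(.data$matches) |>
    arrange(dplyr::desc(.data$intact), dplyr::desc(.data$n_codons),
            .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup()
  attr(out, "skipped") <- FALSE
  attr(out, "fully_intact") <-
    all(c("ORF1p", "ORF2p") %in% out$matches[out$intact])
  out
}

#' Extract the 3' transduced segment of a LINE-1 allele
#'
#' Returns the allele sequence strictly downstream (in element orientation)
#' of the longest LINE-1 annotation, with the terminal poly(A) run trimmed
#' (the maximal 3' run of at least 5 A's allowing one non-A). `NULL` when
#' the remaining segment is shorter than `min_len`.
#'
#' @param allele Allele body (anchor stripped).
#' @param annots Merged annotations on the allele.
#' @param min_len Minimum candidate length (default 25 bp).
#' @param locus_id Carried through to the returned call.
#' @return A list of class `canisv_transduction` with `locus_id`,
#'   `transduced_seq`, `alignments` (empty tibble, to be filled by
#'   [align_to_genome()]), `status` (`"CANDIDATE"`), or `NULL`.
#' @export
extract_3prime_transduction <- function(allele, annots, min_len = 25L,
                                        locus_id = NA_character_) {
  l1 <- as_tibble(annots)
  l1 <- l1[!is.na(l1$repeat_class) & startsWith(l1$repeat_class, "LINE/L1"), ]
  if (nrow(l1) == 0) return(NULL)
  main <- l1[which.max(l1$end - l1$start), ]
  seg <- if (identical(main$strand, "-")) {
    revcomp(substr(allele, 1L, main$start))
  } else {
    substr(allele, main$end + 1L, nchar(allele))
  }
  seg <- trim_polya(seg)
  if (nchar(seg) < min_len) return(NULL)
  structure(list(
    locus_id = locus_id,
    transduced_seq = seg,
    alignments = tibble(),
    status = "CANDIDATE",
    source_locus = NA_character_
  ), class = "canisv_transduction")
}

# Trim the maximal 3' A-run of >= 5 A's, allowing one internal non-A
# interruption (the interruption must sit between A's on both sides; a
# non-A at the run boundary is not an interruption, and a sequence ending
# in a non-A has no poly(A) to trim).
trim_polya <- function(seg) {
  chars <- strsplit(seg, "")[[1]]
  n <- length(chars)
  if (n == 0 || chars[n] != "A") return(seg)
  run_back <- function(from) {
    k <- 0L
    i <- from
    while (i >= 1 && chars[i] == "A") {
      k <- k + 1L
      i <- i - 1L
    }
    k
  }
  k1 <- run_back(n)
  trim <- k1
  j <- n - k1  # position of the character before the trailing A-run
  if (j >= 2 && chars[j] != "A") {
    k2 <- run_back(j - 1L)
    if (k2 >= 2L && k1 + k2 >= 5L) trim <- k1 + 1L + k2
  }
  if (trim == k1 && k1 < 5L) return(seg)
  substr(seg, 1L, n - trim)
}

#' Align a query sequence to a genome (seed-and-extend backend)
#'
#' The alignment contract used for transduction mapping: 25 bp exact seeds
#' (stride 10) are matched against each chromosome on both strands,
#' clustered by diagonal, and each cluster is rescored by local alignment
#' of the query against the seeded window. Reported fields provide what the
#' transduction filters need: per-alignment matches, mismatches, gap opens,
#' match score (matches - mismatches - gap opens), query and target spans.
#'
#' @param query A DNA string.
#' @param genome Named character vector of chromosome sequences.
#' @param min_seed Seed length (default 25).
#' @return A tibble of alignments sorted by decreasing score.
#' @export
align_to_genome <- function(query, genome, min_seed = 25L) {
  qlen <- nchar(query)
  if (qlen < min_seed) return(empty_alignments())
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  rows <- list()
  for (chrom in names(genome)) {
    subj <- Biostrings::DNAString(genome[[chrom]])
    for (strand in c("+", "-")) {
      q <- if (strand == "-") revcomp(query) else query
      seeds <- unique(pmin(seq(1L, qlen - min_seed + 1L, by = 10L),
                           qlen - min_seed + 1L))
      hit_diag <- integer(0)
      for (s in seeds) {
        pat <- substr(q, s, s + min_seed - 1L)
        m <- Biostrings::matchPattern(pat, subj)
        if (length(m) == 0) next
        hit_diag <- c(hit_diag, BiocGenerics::start(m) - s)
      }
      if (length(hit_diag) == 0) next
      # Cluster diagonals within qlen.
      hit_diag <- sort(unique(hit_diag))
      grp <- cumsum(c(TRUE, diff(hit_diag) > qlen))
      for (g in unique(grp)) {
        d <- hit_diag[grp == g][1]
        w_start <- max(1L, d + 1L - 50L)
        w_end <- min(length(subj), d + qlen + 50L)
        al <- Biostrings::pairwiseAlignment(
          pattern = q, subject = subj[w_start:w_end],
          type = "local", substitutionMatrix = mat,
          gapOpening = 2, gapExtension = 1
        )
        nm <- Biostrings::nmatch(al)
        nmm <- Biostrings::nmismatch(al)
        qi <- Biostrings::indel(al@pattern)[[1]]
        si <- Biostrings::indel(al@subject)[[1]]
        gap_opens <- length(qi) + length(si)
        t_start <- w_start + al@subject@range@start - 2L  # 0-based
        t_width <- al@subject@range@width
        q_start0 <- al@pattern@range@start - 1L
        q_width <- al@pattern@range@width
        if (strand == "-") {
          q_start0 <- qlen - (q_start0 + q_width)
        }
        rows[[length(rows) + 1L]] <- tibble(
          target_id = chrom, target_start = t_start,
          target_end = t_start + t_width,
          query_start = q_start0, query_end = q_start0 + q_width,
          strand = strand,
          matches = nm, mismatches = nmm, gap_opens = gap_opens,
          score = nm - nmm - gap_opens
        )
      }
    }
  }
  if (length(rows) == 0) return(empty_alignments())
  out <- bind_rows(rows)
  out <- out[!duplicated(out[, c("target_id", "target_start", "strand")]), ]
  arrange(out, dplyr::desc(.data$score))
}

empty_alignments <- function() {
  tibble(target_id = character(0), target_start = integer(0),
         target_end = integer(0), query_start = integer(0),
         query_end = integer(0), strand = character(0),
         matches = integer(0), mismatches = integer(0),
         gap_opens = integer(0), score = numeric(0))
}

#' Filter candidate transduction alignments
#'
#' Applies, in order: removal of alignments to sequences outside the
#' primary-chromosome list; alignments with match score
#' (matches - mismatches - gap opens) below `min_score`; alignments
#' covering fewer than `min_unmasked` unmasked query positions (mask =
#' union of repeat annotations and DUST intervals on the query);
#' alignments within `proximal` bases (nearest edge) of the locus
#' position. A call then fails with `excess` when more than `max_hits`
#' alignments survive, or with `genomic_span` when the best alignment's
#' target span exceeds its query span by more than `span_excess` bases
#' (a fragmented alignment). Per-filter removal counts are attached as
#' `attr(, "filter_counts")`.
#'
#' @param call A `canisv_transduction` with `alignments` populated.
#' @param locus_chrom,locus_pos Locus anchor (0-based).
#' @param query_annots Repeat annotations on the transduced query
#'   (`NULL` for none).
#' @param query_dust DUST intervals on the query (computed if `NULL`).
#' @param chromosomes Primary-chromosome names.
#' @param min_score,min_unmasked,proximal,max_hits,span_excess Filter
#'   thresholds (defaults 25, 25, 7000, 5, 100).
#' @return The call with `status` set to `"PASS"` or `"FAIL(<reason>)"`
#'   and `alignments` reduced to the retained set.
#' @export
filter_transduction_alignments <- function(call, locus_chrom, locus_pos,
                                           query_annots = NULL,
                                           query_dust = NULL,
                                           chromosomes,
                                           min_score = 25, min_unmasked = 25L,
                                           proximal = 7000L, max_hits = 5L,
                                           span_excess = 100L) {
  aln <- call$alignments
  counts <- c(unplaced = 0L, score = 0L, masked = 0L, proximal = 0L,
              excess = 0L, genomic_span = 0L)
  fail <- function(reason) {
    call$status <- paste0("FAIL(", reason, ")")
    call$alignments <- aln
    attr(call, "filter_counts") <- counts
    call
  }
  if (nrow(aln) == 0) return(fail("no_alignment"))

  keep <- aln$target_id %in% chromosomes
  counts["unplaced"] <- sum(!keep)
  aln <- aln[keep, ]
  if (nrow(aln) == 0) return(fail("unplaced"))

  keep <- aln$score >= min_score
  counts["score"] <- sum(!keep)
  aln <- aln[keep, ]
  if (nrow(aln) == 0) return(fail("score"))

  if (is.null(query_dust)) query_dust <- sdust_mask(call$transduced_seq)
  qmask <- merge_intervals(
    c(if (!is.null(query_annots)) query_annots$start, query_dust$start),
    c(if (!is.null(query_annots)) query_annots$end, query_dust$end)
  )
  unmasked <- vapply(seq_len(nrow(aln)), function(i) {
    span <- aln$query_end[i] - aln$query_start[i]
    span - overlap_with_set(aln$query_start[i], aln$query_end[i],
                            qmask$start, qmask$end)
  }, numeric(1))
  keep <- unmasked >= min_unmasked
  counts["masked"] <- sum(!keep)
  aln <- aln[keep, ]
  if (nrow(aln) == 0) return(fail("masked"))

  dist <- ifelse(aln$target_id != locus_chrom, Inf,
                 pmax(0, pmax(aln$target_start, locus_pos) -
                        pmin(aln$target_end, locus_pos + 1L)))
  keep <- dist > proximal
  counts["proximal"] <- sum(!keep)
  aln <- aln[keep, ]
  if (nrow(aln) == 0) return(fail("proximal"))

  if (nrow(aln) > max_hits) {
    counts["excess"] <- nrow(aln)
    return(fail("excess"))
  }
  best <- aln[which.max(aln$score), ]
  t_span <- best$target_end - best$target_start
  q_span <- best$query_end - best$query_start
  if (t_span - q_span > span_excess) {
    counts["genomic_span"] <- 1L
    return(fail("genomic_span"))
  }
  call$status <- "PASS"
  call$alignments <- aln
  attr(call, "filter_counts") <- counts
  call
}

#' Resolve transduction source elements
#'
#' Labels each PASS call by the origin of its best alignment:
#' `REFERENCE_SOURCE` when it lies within `window` bases of the 3' end of
#' a LINE-1 annotated in the reference; `SEGREGATING_SOURCE` when it lies
#' within `window` of a dimorphic LINE-1 locus (a non-reference source
#' segregating in the cohort — the resolution of a "parentless"
#' transduction); otherwise `PARENTLESS`. Calls sharing one source are
#' grouped into families.
#'
#' @param calls List of PASS-filtered `canisv_transduction` objects.
#' @param line1_loci Tibble of dimorphic LINE-1 loci
#'   ([identify_clean_mei_loci()] output).
#' @param ref_annots Reference repeat annotations.
#' @param window Matching window in bases (default 1000).
#' @return A tibble with one row per call: `locus_id`, `source_label`,
#'   `source_id`, `family`, `family_size`, plus best-alignment target
#'   coordinates.
#' @export
resolve_parentless <- function(calls, line1_loci, ref_annots,
                               window = 1000L) {
  ref_l1 <- as_tibble(ref_annots)
  ref_l1 <- ref_l1[!is.na(ref_l1$repeat_class) &
                     startsWith(ref_l1$repeat_class, "LINE/L1"), ]
  rows <- lapply(calls, function(call) {
    if (!identical(call$status, "PASS")) return(NULL)
    best <- call$alignments[which.max(call$alignments$score), ]
    lab <- "PARENTLESS"
    src <- NA_character_
    # 3' end of a reference LINE-1 within the window of the alignment?
    if (nrow(ref_l1) > 0) {
      same <- ref_l1[ref_l1$seq_id == best$target_id, ]
      if (nrow(same) > 0) {
        ends <- ifelse(same$strand == "-", same$start, same$end)
        d <- abs(ends - best$target_start)
        d2 <- abs(ends - best$target_end)
        hit <- which(pmin(d, d2) <= window)
        if (length(hit) > 0) {
          lab <- "REFERENCE_SOURCE"
          src <- paste0("ref:", same$seq_id[hit[1]], ":", same$start[hit[1]])
        }
      }
    }
    if (lab == "PARENTLESS" && !is.null(line1_loci) && nrow(line1_loci) > 0) {
      same <- line1_loci[line1_loci$chrom == best$target_id, ]
      if (nrow(same) > 0) {
        d <- pmin(abs(same$pos - best$target_start),
                  abs(same$pos - best$target_end))
        hit <- which(d <= window)
        if (length(hit) > 0) {
          lab <- "SEGREGATING_SOURCE"
          src <- same$locus_id[hit[1]]
        }
      }
    }
    tibble(locus_id = call$locus_id, source_label = lab, source_id = src,
           target_id = best$target_id, target_start = best$target_start,
           target_end = best$target_end)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(locus_id = character(0), source_label = character(0),
                  source_id = character(0), target_id = character(0),
                  target_start = integer(0), target_end = integer(0),
                  family = character(0), family_size = integer(0)))
  }
  # Family = shared resolved source, or shared target window for
  # parentless calls.
  fam_key <- ifelse(!is.na(out$source_id), out$source_id,
                    paste0(out$target_id, ":",
                           round(out$target_start / (2 * window))))
  out$family <- fam_key
  out <- out |>
    group_by(.data$family) |>
    mutate(family_size = dplyr::n()) |>
    ungroup()
  out
}
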