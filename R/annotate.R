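# Annotation merging and the lightweight consensus-library annotator.

SIMPLE_CLASSES <- c("Simple_repeat", "Low_complexity")
SINEC_CT_NAMES <- c("(CT)n", "(AG)n", "(TC)n", "(GA)n")

is_simple_class <- function(cls) cls %in% SIMPLE_CLASSES

#' Fraction of a sequence covered by the union of intervals
#'
#' @param intervals A tibble/data.frame with `start`, `end` columns
#'   (0-based half-open), all within `[0, length)`.
#' @param length Sequence length (> 0).
#' @return The covered fraction in `[0, 1]`.
#' @export
union_coverage <- function(intervals, length) {
  if (length <= 0) abort("sequence length must be positive")
  if (is.null(intervals) || nrow(intervals) == 0L) return(0)
  interval_union_len(intervals$start, intervals$end) / length
}

#' Merge fragmented repeat annotations
#'
#' Joins fragments of one interrupted element back into a single interval:
#'
#' * fragments sharing an `element_id` whose intervening gap contains only
#'   `Simple_repeat` / `Low_complexity` annotations (or nothing) are merged
#'   into one interval spanning both, keeping the element's name and class;
#' * a `(CT)n`, `(AG)n`, `(TC)n` or `(GA)n` annotation bridging two
#'   fragments of one SINEC, or lying inside a SINEC interval, is absorbed
#'   into the SINEC (SINECs carry an internal (CT)N microsatellite of
#'   variable length);
#' * simple-repeat annotations fully inside a merged element interval are
#'   absorbed (they are counted as part of the element).
#'
#' The operation is idempotent. If fragments under one `element_id` disagree
#' on name/class, the majority-length name wins with a warning.
#'
#' @param annots A `canisv_annotations` tibble.
#' @return The merged `canisv_annotations` tibble, sorted by
#'   `(seq_id, start)`.
#' @export
merge_repeat_annotations <- function(annots) {
  if (nrow(annots) == 0L) return(annots)
  annots <- arrange(as_tibble(annots), .data$seq_id, .data$start, .data$end)
  out <- lapply(split(annots, annots$seq_id), merge_one_seq)
  new_annotation_set(arrange(bind_rows(out), .data$seq_id, .data$start))
}

merge_one_seq <- function(df) {
  simple <- df[is_simple_class(df$repeat_class), ]
  elems <- df[!is_simple_class(df$repeat_class), ]
  if (nrow(elems) == 0L) return(df)

  merged <- lapply(split(elems, elems$element_id), function(frags) {
    frags <- arrange(frags, .data$start)
    if (nrow(frags) > 1 && length(unique(frags$repeat_name)) > 1) {
      lens <- tapply(frags$end - frags$start, frags$repeat_name, sum)
      keep_name <- names(lens)[which.max(lens)]
      warn(paste0("conflicting repeat names under element_id ",
                  frags$element_id[1], "; keeping ", keep_name))
      keep <- frags$repeat_name == keep_name
      frags$repeat_name <- keep_name
      frags$repeat_class <- frags$repeat_class[keep][1]
    }
    # Merge consecutive fragments whenever the gap holds no other element.
    cur <- frags[1, ]
    acc <- list()
    for (i in seq_len(nrow(frags))[-1]) {
      gap_s <- cur$end
      gap_e <- frags$start[i]
      blockers <- elems$element_id != frags$element_id[1] &
        elems$start < gap_e & elems$end > gap_s
      if (gap_e <= gap_s || !any(blockers)) {
        cur$end <- max(cur$end, frags$end[i])
        cur$cons_end <- max(cur$cons_end, frags$cons_end[i], na.rm = TRUE)
        cur$cons_start <- min(cur$cons_start, frags$cons_start[i], na.rm = TRUE)
      } else {
        acc <- c(acc, list(cur))
        cur <- frags[i, ]
      }
    }
    bind_rows(c(acc, list(cur)))
  })
  elems_m <- bind_rows(merged)

  # Absorb simple-repeat annotations contained in a merged element interval.
  # For SINECs this implements the (CT)n/(AG)n/(TC)n/(GA)n absorption rule;
  # bridging simple repeats of any kind are covered by the merged span.
  if (nrow(simple) > 0L) {
    absorbed <- vapply(seq_len(nrow(simple)), function(i) {
      any(elems_m$start <= simple$start[i] & elems_m$end >= simple$end[i])
    }, logical(1))
    simple <- simple[!absorbed, ]
  }
  bind_rows(elems_m, simple)
}

#' Annotate a sequence against a consensus repeat library
#'
#' A lightweight annotator used when RepeatMasker output is not supplied
#' (e.g. for synthetic alleles): each library consensus is locally aligned
#' against the sequence on both strands, hits at or above `min_identity`
#' are reported as repeat annotations with consensus coordinates, and the
#' flanks of each hit are re-scanned so multiple copies are found.
#' Overlapping hits across consensi are resolved best-score-first.
#'
#' @param seq A single DNA string.
#' @param library A [build_repeat_library()] object.
#' @param min_identity Minimum alignment identity (matches / alignment
#'   columns) for a reported hit.
#' @param min_hit Minimum hit length in bases (default 30).
#' @param seq_id Sequence name recorded in the result.
#' @return A `canisv_annotations` tibble.
#' @export
annotate_with_library <- function(seq, library, min_identity = 0.8,
                                  min_hit = 30L, seq_id = "seq") {
  stopifnot(inherits(library, "canisv_repeat_library"))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1.5)
  hits <- list()
  for (k in seq_len(nrow(library$consensus))) {
    cons <- library$consensus[k, ]
    hits <- c(hits, scan_consensus(seq, cons, mat, min_identity, min_hit))
  }
  if (length(hits) == 0L) return(empty_annotation_set())
  h <- bind_rows(hits)
  h <- arrange(h, dplyr::desc(.data$score))
  keep <- rep(TRUE, nrow(h))
  for (i in seq_len(nrow(h))) {
    if (!keep[i]) next
    later <- which(keep & seq_len(nrow(h)) > i)
    if (length(later) == 0) next
    ovl <- pmin(h$end[later], h$end[i]) - pmax(h$start[later], h$start[i])
    span <- h$end[later] - h$start[later]
    keep[later[ovl > 0.5 * span]] <- FALSE
  }
  h <- h[keep, ]
  h$seq_id <- seq_id
  h$element_id <- seq_len(nrow(h))
  new_annotation_set(arrange(h, .data$start))
}

# Recursively scan one strandx consensus against [offset, offset+len) of seq.
scan_consensus <- function(seq, cons, mat, min_identity, min_hit) {
  res <- list()
  scan_segment <- function(segment, offset) {
    if (nchar(segment) < min_hit) return(invisible())
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") cons$seq else revcomp(cons$seq)
      al <- Biostrings::pairwiseAlignment(
        pattern = pat, subject = segment,
        type = "local", substitutionMatrix = mat,
        gapOpening = 4, gapExtension = 1
      )
      w <- Biostrings::nchar(al)
      if (w < min_hit) next
      pid <- Biostrings::nmatch(al) / w
      if (pid < min_identity) next
      srng <- al@subject@range
      prng <- al@pattern@range
      s0 <- offset + srng@start - 1L
      e0 <- s0 + srng@width
      cs <- prng@start
      ce <- prng@start + prng@width - 1L
      if (strand == "-") {
        cl <- nchar(cons$seq)
        tmp <- cs
        cs <- cl - ce + 1L
        ce <- cl - tmp + 1L
      }
      res[[length(res) + 1L]] <<- tibble(
        start = as.integer(s0), end = as.integer(e0),
        repeat_name = cons$name, repeat_class = cons$class,
        strand = strand,
        cons_start = as.integer(cs), cons_end = as.integer(ce),
        score = Biostrings::score(al)
      )
      # Re-scan the flanks for further copies of this consensus.
      left <- substr(segment, 1L, srng@start - 1L)
      right <- substr(segment, srng@start + srng@width, nchar(segment))
      scan_segment(left, offset)
      scan_segment(right, offset + srng@start + srng@width - 1L)
      return(invisible())
    }
    invisible()
  }
  scan_segment(seq, 0L)
  res
}
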