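# PAF alignment records with cg:Z CIGAR and NM:i tags.

parse_cigar <- function(cg) {
  if (is.na(cg) || !nzchar(cg)) {
    return(tibble(op = character(0), len = integer(0)))
  }
  toks <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
  if (sum(nchar(toks)) != nchar(cg)) {
    abort(paste0("malformed CIGAR string: ", cg))
  }
  tibble(
    op = substring(toks, nchar(toks), nchar(toks)),
    len = as.integer(substring(toks, 1, nchar(toks) - 1L))
  )
}

cigar_consumed <- function(cig) {
  q <- sum(cig$len[cig$op %in% c("M", "=", "X", "I")])
  t <- sum(cig$len[cig$op %in% c("M", "=", "X", "D", "N")])
  c(query = q, target = t)
}

#' Read pairwise alignments from PAF
#'
#' Parses minimap2-style PAF with optional `cg:Z:` (CIGAR) and `NM:i:`
#' (edit distance) tags. Records whose CIGAR does not account for the
#' stated query/target spans are rejected with a warning; the count of
#' rejected records is attached as `attr(, "n_rejected")`.
#'
#' @param path Path to a PAF file.
#' @return A tibble with one row per retained alignment: `query_id`,
#'   `query_len`, `query_start`, `query_end` (0-based half-open), `strand`,
#'   `target_id`, `target_len`, `target_start`, `target_end`, `matches`,
#'   `block_len`, `mapq`, `edit_distance` and a `cigar` list-column of
#'   `(op, len)` tibbles (empty tibble when the tag is absent).
#' @export
read_alignments_paf <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  rows <- vector("list", length(lines))
  n_rejected <- 0L
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12) abort(paste0("PAF line ", i, " has fewer than 12 fields"))
    tags <- f[-(1:12)]
    cg <- sub("^cg:Z:", "", grep("^cg:Z:", tags, value = TRUE)[1])
    nm <- sub("^NM:i:", "", grep("^NM:i:", tags, value = TRUE)[1])
    cig <- parse_cigar(if (length(cg) == 0) NA_character_ else cg)
    qs <- as.integer(f[3]); qe <- as.integer(f[4])
    ts <- as.integer(f[8]); te <- as.integer(f[9])
    if (nrow(cig) > 0) {
      cons <- cigar_consumed(cig)
      if (cons[["query"]] != qe - qs || cons[["target"]] != te - ts) {
        warn(paste0("PAF line ", i,
                    ": CIGAR does not match stated spans; record skipped"))
        n_rejected <- n_rejected + 1L
        next
      }
    }
    rows[[i]] <- tibble(
      query_id = f[1], query_len = as.integer(f[2]),
      query_start = qs, query_end = qe,
      strand = f[5],
      target_id = f[6], target_len = as.integer(f[7]),
      target_start = ts, target_end = te,
      matches = as.integer(f[10]), block_len = as.integer(f[11]),
      mapq = as.integer(f[12]),
      edit_distance = if (is.na(nm)) NA_integer_ else as.integer(nm),
      cigar = list(cig)
    )
  }
  out <- bind_rows(rows)
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Gap-excluded and gap-compressed alignment identity
#'
#' Two identity measures computed from a CIGAR: gap-excluded identity
#' ignores insertions and deletions entirely
#' (`matches / (matches + mismatches)`); gap-compressed identity counts each
#' maximal run of consecutive inserted or deleted bases as a single
#' difference (`matches / (matches + mismatches + gap_events)`).
#'
#' Mismatches are taken from `=`/`X` operations when present; for plain `M`
#' CIGARs they are derived from the `NM` edit distance
#' (`NM - inserted - deleted bases`).
#'
#' @param aln One row of the tibble returned by [read_alignments_paf()], or
#'   any list with elements `cigar` (an `(op, len)` tibble) and, when the
#'   CIGAR uses `M`, `edit_distance`.
#' @return A named numeric vector `c(gap_excluded =, gap_compressed =)`.
#' @export
alignment_identities <- function(aln) {
  cig <- if (is.data.frame(aln$cigar)) aln$cigar else aln$cigar[[1]]
  if (is.null(cig) || nrow(cig) == 0) abort("alignment has no CIGAR")
  ins <- sum(cig$len[cig$op == "I"])
  del <- sum(cig$len[cig$op %in% c("D", "N")])
  if (any(cig$op %in% c("=", "X"))) {
    matches <- sum(cig$len[cig$op == "="])
    mism <- sum(cig$len[cig$op == "X"])
  } else {
    m <- sum(cig$len[cig$op == "M"])
    nm <- aln$edit_distance
    if (is.null(nm) || is.na(nm)) {
      abort("M-only CIGAR requires edit_distance (NM) to derive mismatches")
    }
    mism <- nm - ins - del
    matches <- m - mism
  }
  is_gap <- cig$op %in% c("I", "D", "N")
  gap_events <- sum(rle(is_gap)$values)
  c(
    gap_excluded = matches / (matches + mism),
    gap_compressed = matches / (matches + mism + gap_events)
  )
}
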