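# Independent brute-force reference implementations used as oracles.

# Brute-force symmetric-DUST: per-subinterval triplet counts recomputed with
# tabulate(); an interval is masked when it qualifies (normalized score
# above threshold/10) and its normalized score is >= that of every
# subinterval (checked against a row-wise cumulative-maximum table).
oracle_sdust <- function(seq, window = 64L, threshold = 20L) {
  n <- nchar(seq)
  empty <- tibble::tibble(start = integer(0), end = integer(0))
  if (n < 3L) return(empty)
  code <- match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T")) - 1L
  trip <- 16L * code[1:(n - 2L)] + 4L * code[2:(n - 1L)] + code[3:n]
  nt <- length(trip)
  wt <- window - 2L
  dens <- matrix(NA_real_, nt, wt)
  for (i in seq_len(nt)) {
    for (d in 0:(wt - 1L)) {
      j <- i + d
      if (j > nt || anyNA(trip[i:j])) break
      cnt <- tabulate(trip[i:j] + 1L, 64L)
      s <- sum(cnt * (cnt - 1) / 2)
      dens[i, d + 1L] <- if (d == 0L) 0 else s / d
    }
  }
  rowmax <- t(apply(dens, 1, function(r) {
    r[is.na(r)] <- -Inf
    cummax(r)
  }))
  mask <- rep(FALSE, n)
  for (i in seq_len(nt)) {
    for (d in seq_len(wt - 1L)) {
      j <- i + d
      if (j > nt) break
      x <- dens[i, d + 1L]
      if (is.na(x) || 10 * x <= threshold) next
      submax <- max(vapply(i:j, function(i2) {
        rowmax[i2, min(wt, j - i2 + 1L)]
      }, numeric(1)))
      if (x >= submax) mask[i:(j + 2L)] <- TRUE
    }
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  tibble::tibble(start = as.integer(starts[keep]),
                 end = as.integer(ends[keep]))
}

# Naive exact-tandem-repeat finder: per-period position walk.
oracle_etrf <- function(seq, max_unit = 6L, min_copies = 2L, min_span = 4L) {
  n <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  rot_min <- function(u) {
    k <- nchar(u)
    if (k == 1) return(u)
    min(vapply(1:k, function(r) {
      paste(chars_u[c(r:k, seq_len(r - 1L))], collapse = "")
    }, character(1), USE.NAMES = FALSE))
  }
  out <- list()
  pmax_ <- if (is.null(max_unit)) n %/% 2L else min(max_unit, n %/% 2L)
  for (p in seq_len(max(0L, pmax_))) {
    i <- p + 1L
    while (i <= n) {
      if (chars[i] == chars[i - p]) {
        a <- i
        while (i <= n && chars[i] == chars[i - p]) i <- i + 1L
        start0 <- a - p - 1L
        end0 <- i - 1L
        span <- end0 - start0
        copies <- span %/% p
        unit <- substr(seq, start0 + 1L, start0 + p)
        # primitive?
        prim <- TRUE
        for (dd in seq_len(p - 1L)) {
          if (p %% dd == 0L &&
              strrep(substr(unit, 1, dd), p / dd) == unit) {
            prim <- FALSE
            break
          }
        }
        if (span >= min_span && copies >= min_copies && prim) {
          chars_u <- strsplit(unit, "")[[1]]
          out[[length(out) + 1L]] <- tibble::tibble(
            start = start0, end = end0, unit = rot_min(unit),
            unit_length = p, copies = as.integer(copies))
        }
      } else {
        i <- i + 1L
      }
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble::tibble(start = integer(0), end = integer(0),
                          unit = character(0), unit_length = integer(0),
                          copies = integer(0)))
  }
  dplyr::arrange(res, start, unit_length)
}

# Random test sequences: mostly uniform DNA, some with planted
# low-complexity / tandem segments, occasional Ns.
random_test_seq <- function(len) {
  base <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  kind <- sample(4, 1)
  if (kind == 2 && len >= 20) {
    at <- sample(len - 12L, 1)
    base[at:(at + 11L)] <- sample(c("A", "C", "G", "T"), 1)
  } else if (kind == 3 && len >= 30) {
    u <- strsplit(paste(sample(c("A", "C", "G", "T"),
                               sample(2:4, 1), replace = TRUE),
                        collapse = ""), "")[[1]]
    at <- sample(len - 20L, 1)
    rep_seg <- rep(u, length.out = 20L)
    base[at:(at + 19L)] <- rep_seg
  } else if (kind == 4 && len >= 10) {
    base[sample(len, 2)] <- "N"
  }
  paste(base, collapse = "")
}
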