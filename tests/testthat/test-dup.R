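# Segmental-duplication pair filtering, classification and summaries.

mk_pair <- function(chrA, startA, chrB, startB, length, divergence) {
  tibble::tibble(chrA = chrA, startA = startA, endA = startA + length,
                 chrB = chrB, startB = startB, endB = startB + length,
                 length = length, divergence = divergence)
}

test_that("pairs classify into tandem/dispersed/centromeric with filters", {
  pairs <- dplyr::bind_rows(
    mk_pair("chr1", 1e6, "chr1", 1e6 + 12000 + 150000, 12000, 0.03),  # tandem
    mk_pair("chr1", 1e6, "chr1", 1e6 + 12000 + 250000, 12000, 0.03),  # dispersed
    mk_pair("chr1", 1e6, "chr2", 1e6, 9000, 0.03),                    # < 10 kb
    mk_pair("chr1", 1e6, "chr2", 1e6, 12000, 0.08),                   # > 5% div
    mk_pair("chr1", 1e5, "chr2", 2e5, 12000, 0.02),                   # centromeric
    mk_pair("chr1", 6e6, "chr2", 1e5, 12000, 0.02),                   # inter, not centro
    mk_pair("chr1", 1e6, "chr2", 1e6, 800, 0.02),                     # base filter
    mk_pair("chrM", 1e3, "chr2", 1e6, 12000, 0.02)                    # mito
  )
  cl <- filter_and_classify_dup_pairs(pairs, mito = "chrM")
  expect_equal(nrow(cl), 4L)
  expect_equal(cl$subclass[cl$config == "INTRA"], c("TANDEM", "DISPERSED"))
  inter <- cl[cl$config == "INTER", ]
  expect_equal(inter$centromeric, c(TRUE, FALSE))
  # Partition invariants.
  expect_equal(sum(cl$config == "INTRA") + sum(cl$config == "INTER"),
               nrow(cl))
  expect_equal(sum(cl$subclass %in% c("TANDEM", "DISPERSED")),
               sum(cl$config == "INTRA"))
})

test_that("separation uses the gap between nearer ends (0 if overlapping)", {
  p <- mk_pair("chr1", 1000, "chr1", 1000 + 12000 - 500, 12000, 0.02)
  cl <- filter_and_classify_dup_pairs(p)
  expect_equal(cl$separation, 0)
  expect_equal(cl$subclass, "TANDEM")
})

test_that("malformed pairs are skipped with a warning", {
  p <- dplyr::bind_rows(
    mk_pair("chr1", 1e6, "chr1", 2e6, 12000, 0.02),
    tibble::tibble(chrA = "chr1", startA = 10, endA = 5, chrB = "chr1",
                   startB = 1, endB = 2, length = 12000, divergence = 0.02)
  )
  expect_warning(cl <- filter_and_classify_dup_pairs(p), "malformed")
  expect_equal(nrow(cl), 1L)
})

# Synthetic pair table realizing given intra/tandem/centromeric counts.
pairs_with_counts <- function(n_tandem, n_dispersed, n_centro, n_far) {
  dplyr::bind_rows(
    if (n_tandem) dplyr::bind_rows(lapply(seq_len(n_tandem), function(i) {
      mk_pair("chr1", 1e6 + i * 40000, "chr1", 1e6 + i * 40000 + 20000,
              15000, 0.02)
    })),
    if (n_dispersed) dplyr::bind_rows(lapply(seq_len(n_dispersed), function(i) {
      mk_pair("chr2", 1e6 + i * 40000, "chr2", 2e6 + i * 40000 + 250000,
              15000, 0.02)
    })),
    if (n_centro) dplyr::bind_rows(lapply(seq_len(n_centro), function(i) {
      mk_pair("chr3", 1e5 + (i %% 100) * 300, "chr4", 2e5 + (i %% 97) * 300,
              15000, 0.02)
    })),
    if (n_far) dplyr::bind_rows(lapply(seq_len(n_far), function(i) {
      mk_pair("chr5", 6e6 + (i %% 50) * 1000, "chr6", 1e5 + (i %% 50) * 1000,
              15000, 0.02)
    }))
  )
}

test_that("summary percentages reproduce the published arithmetic", {
  pairs <- pairs_with_counts(n_tandem = 414, n_dispersed = 608,
                             n_centro = 10788, n_far = 12412 - 10788)
  cl <- filter_and_classify_dup_pairs(pairs)
  s <- summarize_dup_pairs(cl)
  expect_equal(s$n_pairs, 13434L)
  expect_equal(s$n_intra, 1022L)
  expect_equal(s$intra_pct, 7.6)
  expect_equal(s$tandem_pct_of_intra, 40.5)
  expect_equal(s$dispersed_pct_of_intra, 59.5)
  expect_equal(s$centromeric_pct_of_inter, 86.9)
  expect_equal(s$centromeric_pct_of_inter_int, 87)
})

test_that("empty input yields an all-zero summary", {
  cl <- filter_and_classify_dup_pairs(mk_pair("chr1", 1, "chr1", 2, 500, 0.5)[0, ])
  s <- summarize_dup_pairs(cl)
  expect_equal(s$n_pairs, 0L)
  expect_true(is.na(s$intra_pct))
})

test_that("duplication tables round-trip through the BEDPE-like format", {
  pairs <- pairs_with_counts(2, 2, 2, 2)
  p <- tempfile(fileext = ".tsv")
  write_dup_pairs(pairs, p)
  back <- read_dup_pairs(p)
  expect_equal(as.data.frame(back), as.data.frame(pairs))
})
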