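# Annotation merging, union coverage and the library annotator.

ann <- function(...) {
  rows <- list(...)
  canisv:::new_annotation_set(dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(seq_id = r[["seq_id"]] %||% "s", start = r[["start"]],
                   end = r[["end"]], repeat_name = r[["name"]],
                   repeat_class = r[["class"]], strand = "+",
                   element_id = r[["id"]] %||% 1L,
                   cons_start = 1L, cons_end = r[["end"]] - r[["start"]])
  })))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("SINEC fragments bridged by (CT)n merge into one interval", {
  a <- ann(
    list(start = 0L, end = 120L, name = "SINEC_Cf", class = "SINE/tRNA-Lys", id = 3L),
    list(start = 120L, end = 150L, name = "(CT)n", class = "Simple_repeat", id = 99L),
    list(start = 150L, end = 200L, name = "SINEC_Cf", class = "SINE/tRNA-Lys", id = 3L)
  )
  m <- merge_repeat_annotations(a)
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 0L)
  expect_equal(m$end, 200L)
  expect_equal(m$repeat_name, "SINEC_Cf")
})

test_that("elements bridged by Simple_repeat merge; different IDs do not", {
  a <- ann(
    list(start = 0L, end = 500L, name = "L1", class = "LINE/L1", id = 9L),
    list(start = 500L, end = 520L, name = "(TA)n", class = "Simple_repeat", id = 50L),
    list(start = 520L, end = 900L, name = "L1", class = "LINE/L1", id = 9L)
  )
  m <- merge_repeat_annotations(a)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(0L, 900L))

  b <- ann(
    list(start = 0L, end = 100L, name = "SINEC_Cf", class = "SINE/tRNA-Lys", id = 3L),
    list(start = 100L, end = 200L, name = "SINEC_Cf", class = "SINE/tRNA-Lys", id = 4L)
  )
  mb <- merge_repeat_annotations(b)
  expect_equal(nrow(mb), 2L)
})

test_that("a gap occupied by another element blocks merging", {
  a <- ann(
    list(start = 0L, end = 100L, name = "L1", class = "LINE/L1", id = 1L),
    list(start = 100L, end = 300L, name = "SINEC_Cf", class = "SINE/tRNA-Lys", id = 2L),
    list(start = 300L, end = 400L, name = "L1", class = "LINE/L1", id = 1L)
  )
  m <- merge_repeat_annotations(a)
  expect_equal(nrow(m), 3L)
})

test_that("simple repeats inside an element interval are absorbed", {
  a <- ann(
    list(start = 0L, end = 200L, name = "SINEC_Cf", class = "SINE/tRNA-Lys", id = 1L),
    list(start = 90L, end = 114L, name = "(CT)n", class = "Simple_repeat", id = 2L)
  )
  m <- merge_repeat_annotations(a)
  expect_equal(nrow(m), 1L)
  expect_equal(m$repeat_name, "SINEC_Cf")
})

test_that("merging is idempotent", {
  a <- small_annots()
  m1 <- merge_repeat_annotations(a)
  m2 <- merge_repeat_annotations(m1)
  expect_equal(as.data.frame(m1), as.data.frame(m2))
})

test_that("union coverage handles overlap, empties and degenerate input", {
  iv <- tibble::tibble(start = c(0L, 40L), end = c(50L, 100L))
  expect_equal(union_coverage(iv, 200), 0.5)
  expect_equal(union_coverage(tibble::tibble(start = integer(0),
                                             end = integer(0)), 200), 0)
  expect_equal(union_coverage(tibble::tibble(start = 0L, end = 200L), 200), 1)
  expect_error(union_coverage(iv, 0), "positive")
})

test_that("the library annotator recovers planted consensi", {
  lib <- test_lib()
  a <- annotate_with_library(lib$sinec_consensus, lib)
  expect_equal(nrow(a), 1L)
  expect_equal(a$repeat_name, "SINEC_sim")
  expect_equal(c(a$start, a$end), c(0L, 201L))
  expect_equal(a$cons_end, 201L)

  # 3' half of the LINE-1: consensus coordinates reflect the truncation.
  half <- substr(lib$line1_consensus, 2981, nchar(lib$line1_consensus))
  h <- annotate_with_library(half, lib)
  h <- h[h$repeat_name == "L1_sim", ]
  expect_equal(nrow(h), 1L)
  expect_gt(h$cons_start, 2900L)
  expect_equal(h$cons_end, nchar(lib$line1_consensus))

  # Reverse-complement hit is found on the minus strand.
  rc <- annotate_with_library(canisv:::revcomp(lib$sinec_consensus), lib)
  expect_equal(rc$strand, "-")
  expect_equal(rc$repeat_name, "SINEC_sim")

  # Random sequence: no hit at or above the identity floor.
  rnd <- withr::with_seed(5, paste(sample(c("A", "C", "G", "T"), 300,
                                          replace = TRUE), collapse = ""))
  expect_equal(nrow(annotate_with_library(rnd, lib)), 0L)
})
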