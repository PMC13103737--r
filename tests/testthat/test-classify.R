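# Ten-category composition classification.

mk_annots <- function(df) canisv:::new_annotation_set(df)

test_that("a 70% merged element annotation assigns the repeat type", {
  allele <- withr::with_seed(3, paste(sample(c("A", "C", "G", "T"), 200,
                                             replace = TRUE), collapse = ""))
  a <- mk_annots(tibble::tibble(
    seq_id = "s", start = 0L, end = 150L, repeat_name = "SINEC_Cf",
    repeat_class = "SINE/tRNA-Lys", strand = "+", element_id = 1L,
    cons_start = 1L, cons_end = 150L))
  cl <- classify_locus(allele, a,
                       dust = tibble::tibble(start = integer(0),
                                             end = integer(0)))
  expect_equal(cl$category, "SINEC")
  expect_equal(cl$rm_fraction, 0.75)

  # 139/200 = 69.5% stays below the threshold.
  a2 <- mk_annots(tibble::tibble(
    seq_id = "s", start = 0L, end = 139L, repeat_name = "SINEC_Cf",
    repeat_class = "SINE/tRNA-Lys", strand = "+", element_id = 1L,
    cons_start = 1L, cons_end = 139L))
  cl2 <- classify_locus(allele, a2,
                        dust = tibble::tibble(start = integer(0),
                                              end = integer(0)))
  expect_false(cl2$category == "SINEC")
})

test_that("low-complexity alleles split into STR and VNTR by unit length", {
  str_allele <- paste0(strrep("AT", 40), withr::with_seed(4, paste(
    sample(c("G", "C"), 20, replace = TRUE), collapse = "")))
  cl <- classify_locus(str_allele)
  expect_equal(cl$category, "STR")
  expect_gte(cl$tr_fraction_str, 0.7)

  vntr_allele <- strrep("ACGGTTACCGT", 20)  # 11 bp unit
  cl2 <- classify_locus(vntr_allele)
  expect_equal(cl2$category, "VNTR")
  expect_gte(cl2$tr_fraction_vntr, 0.7)
})

test_that("the union clause yields Mixed at 70% and Partial at 5%", {
  allele <- withr::with_seed(8, paste(sample(c("A", "C", "G", "T"), 300,
                                             replace = TRUE), collapse = ""))
  a <- mk_annots(tibble::tibble(
    seq_id = "s", start = 0L, end = 120L, repeat_name = "L1",
    repeat_class = "LINE/L1", strand = "+", element_id = 1L,
    cons_start = 1L, cons_end = 120L))
  dust <- tibble::tibble(start = 100L, end = 220L)
  # union [0,220) = 220/300 ~ 0.733; element alone 0.40, dust alone 0.40.
  cl <- classify_locus(allele, a, dust = dust)
  expect_equal(cl$category, "Mixed")
  expect_equal(cl$union_fraction, 220 / 300)

  # Small annotation only: Partial (>= 5%, < 70%).
  a2 <- mk_annots(tibble::tibble(
    seq_id = "s", start = 0L, end = 30L, repeat_name = "L1",
    repeat_class = "LINE/L1", strand = "+", element_id = 1L,
    cons_start = 1L, cons_end = 30L))
  cl2 <- classify_locus(allele, a2,
                        dust = tibble::tibble(start = integer(0),
                                              end = integer(0)))
  expect_equal(cl2$category, "Partial")

  # Nothing annotated: Unclassified.
  cl3 <- classify_locus(allele, NULL,
                        dust = tibble::tibble(start = integer(0),
                                              end = integer(0)))
  expect_equal(cl3$category, "Unclassified")
})

test_that("when two repeat types pass 70%, larger covered length wins", {
  allele <- strrep("G", 100)
  a <- mk_annots(tibble::tibble(
    seq_id = "s", start = c(0L, 0L), end = c(80L, 90L),
    repeat_name = c("SINEC_Cf", "L1"),
    repeat_class = c("SINE/tRNA-Lys", "LINE/L1"),
    strand = "+", element_id = 1:2, cons_start = 1L, cons_end = c(80L, 90L)))
  cl <- classify_locus(allele, a,
                       dust = tibble::tibble(start = integer(0),
                                             end = integer(0)))
  expect_equal(cl$category, "LINE/L1")
})

test_that("adding annotation never demotes a locus out of a >=70% class", {
  allele <- withr::with_seed(10, paste(sample(c("A", "C", "G", "T"), 200,
                                              replace = TRUE), collapse = ""))
  base <- tibble::tibble(
    seq_id = "s", start = 0L, end = 150L, repeat_name = "SINEC_Cf",
    repeat_class = "SINE/tRNA-Lys", strand = "+", element_id = 1L,
    cons_start = 1L, cons_end = 150L)
  cl1 <- classify_locus(allele, mk_annots(base))
  extra <- dplyr::bind_rows(base, tibble::tibble(
    seq_id = "s", start = 150L, end = 180L, repeat_name = "L1",
    repeat_class = "LINE/L1", strand = "+", element_id = 2L,
    cons_start = 1L, cons_end = 30L))
  cl2 <- classify_locus(allele, mk_annots(extra))
  expect_false(cl2$category %in% c("Partial", "Unclassified"))
  expect_true(cl1$category %in% c("SINEC"))
})

test_that("each locus gets exactly one category and counts are conserved", {
  cl <- small_classified()
  expect_true(all(cl$category %in% canisv:::SV_CATEGORIES))
  s <- classification_summary(cl)
  expect_equal(sum(s$by_category$n), nrow(cl))
  expect_equal(sum(s$size_histogram$n), nrow(cl))
  # Empty input gives an all-zero table.
  s0 <- classification_summary(cl[0, ])
  expect_equal(sum(s0$by_category$n), 0L)
})

test_that("planted categories are recovered from truth annotations", {
  acc <- truth_classification_accuracy(small_cohort(), small_classified())
  expect_gte(acc$accuracy, 0.95)
  expect_gt(acc$n_eligible, 100)
})
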