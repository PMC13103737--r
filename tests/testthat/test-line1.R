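# LINE-1 ORF intactness, transduction extraction/filtering and source
# resolution.

l1_annot <- function(len, strand = "+", start = 0L, seq_id = "s") {
  canisv:::new_annotation_set(tibble::tibble(
    seq_id = seq_id, start = start, end = start + len,
    repeat_name = "L1_sim", repeat_class = "LINE/L1", strand = strand,
    element_id = 1L, cons_start = 1L, cons_end = len))
}

test_that("a full-length element yields two intact ORF calls", {
  lib <- test_lib()
  allele <- canisv:::build_line1_body(lib, tail_len = 12L)
  orfs <- find_intact_orfs(allele, l1_annot(nchar(lib$line1_consensus)), lib)
  expect_equal(sort(orfs$matches), c("ORF1p", "ORF2p"))
  expect_true(all(orfs$intact))
  expect_true(attr(orfs, "fully_intact"))
})

test_that("a premature stop in ORF2 breaks intactness", {
  lib <- test_lib()
  allele <- canisv:::build_line1_body(lib, tail_len = 12L, orf2_stop = TRUE)
  orfs <- find_intact_orfs(allele, l1_annot(nchar(lib$line1_consensus)), lib)
  expect_false(attr(orfs, "fully_intact"))
  orf2 <- orfs[orfs$matches == "ORF2p", ]
  expect_true(nrow(orf2) == 0 || !any(orf2$intact))
})

test_that("short LINE-1 annotations are skipped by the 4 kb rule", {
  lib <- test_lib()
  allele <- canisv:::build_line1_body(lib, trunc5 = 2500L, tail_len = 12L)
  orfs <- find_intact_orfs(allele, l1_annot(nchar(allele) - 12L), lib,
                           min_len = 4000L)
  expect_equal(nrow(orfs), 0L)
  expect_true(attr(orfs, "skipped"))
})

test_that("a nested in-frame SINEC elongates the ORF2p protein", {
  lib <- test_lib()
  nested <- list(offset = lib$orf2_range[1] + 903L,
                 sinec_body = lib$sinec_consensus, tsd_len = 12L)
  allele <- canisv:::build_line1_body(lib, tail_len = 12L, nested = nested)
  a <- l1_annot(nchar(allele))
  orfs <- find_intact_orfs(allele, a, lib)
  orf2 <- orfs[orfs$matches == "ORF2p", ]
  expect_equal(nrow(orf2), 1L)
  expect_true(orf2$intact)
  expect_equal(orf2$insertion_codons, (201L + 12L) / 3L)
})

test_that("transduced segments are the sequence 3' of the element", {
  lib <- test_lib()
  tag <- withr::with_seed(6, paste(sample(c("C", "G", "T"), 80,
                                          replace = TRUE), collapse = ""))
  l1_len <- nchar(lib$line1_consensus)
  allele <- paste0(lib$line1_consensus, tag, strrep("A", 20))
  td <- extract_3prime_transduction(allele, l1_annot(l1_len), locus_id = "x")
  expect_equal(td$transduced_seq, tag)
  # Poly(A) only downstream: nothing to transduce.
  expect_null(extract_3prime_transduction(
    paste0(lib$line1_consensus, strrep("A", 20)), l1_annot(l1_len)))
  # Minus-strand element: downstream is 5' in allele coordinates.
  allele_rc <- canisv:::revcomp(allele)
  a_rc <- l1_annot(l1_len, strand = "-",
                   start = nchar(allele_rc) - l1_len)
  td_rc <- extract_3prime_transduction(allele_rc, a_rc, locus_id = "x")
  expect_equal(td_rc$transduced_seq, tag)
})

test_that("poly(A) trimming allows one interruption and needs 5 A's", {
  expect_equal(canisv:::trim_polya("GATTACAAAAAAA"), "GATTAC")
  expect_equal(canisv:::trim_polya("GATTACAAAAGAAAA"), "GATTAC")
  # Trailing non-A: no poly(A) end, nothing trimmed.
  expect_equal(canisv:::trim_polya("GATTACAAAAAAAG"), "GATTACAAAAAAAG")
  # Fewer than 5 A's: untouched.
  expect_equal(canisv:::trim_polya("GATTACAAA"), "GATTACAAA")
})

mk_call <- function(aln, seq = strrep("G", 60)) {
  structure(list(locus_id = "L", transduced_seq = seq, alignments = aln,
                 status = "CANDIDATE", source_locus = NA_character_),
            class = "canisv_transduction")
}

aln_row <- function(chrom = "chr1", tstart = 50000L, score = 40,
                    qstart = 0L, qend = 60L, tend = tstart + (qend - qstart)) {
  tibble::tibble(target_id = chrom, target_start = tstart, target_end = tend,
                 query_start = qstart, query_end = qend, strand = "+",
                 matches = score, mismatches = 0L, gap_opens = 0L,
                 score = score)
}

test_that("transduction filters apply at their exact boundaries", {
  chroms <- c("chr1", "chr2")
  nodust <- tibble::tibble(start = integer(0), end = integer(0))
  base <- function(aln) {
    filter_transduction_alignments(mk_call(aln), "chr1", 10000L,
                                   query_dust = nodust,
                                   chromosomes = chroms)
  }
  expect_equal(base(aln_row(score = 24))$status, "FAIL(score)")
  expect_equal(base(aln_row(score = 25))$status, "PASS")
  expect_equal(base(aln_row(chrom = "scaffold_12"))$status, "FAIL(unplaced)")
  # 24 unmasked query positions fail; 25 pass.
  call <- mk_call(aln_row())
  masked24 <- tibble::tibble(start = 24L, end = 60L)
  out <- filter_transduction_alignments(call, "chr1", 10000L,
                                        query_dust = masked24,
                                        chromosomes = chroms)
  expect_equal(out$status, "FAIL(masked)")
  masked25 <- tibble::tibble(start = 25L, end = 60L)
  out2 <- filter_transduction_alignments(call, "chr1", 10000L,
                                         query_dust = masked25,
                                         chromosomes = chroms)
  expect_equal(out2$status, "PASS")
  # Proximity: nearest edge at 6,999 bp fails, 7,001 bp passes.
  prox_fail <- filter_transduction_alignments(
    mk_call(aln_row(tstart = 16940L)), "chr1", 10000L,
    query_dust = nodust, chromosomes = chroms)
  expect_equal(prox_fail$status, "FAIL(proximal)")
  prox_pass <- filter_transduction_alignments(
    mk_call(aln_row(tstart = 17002L)), "chr1", 10000L,
    query_dust = nodust, chromosomes = chroms)
  expect_equal(prox_pass$status, "PASS")
  # Excess alignments.
  many <- dplyr::bind_rows(lapply(seq(30000, 300000, by = 30000),
                                  function(s) aln_row(tstart = s)))
  expect_equal(base(many)$status, "FAIL(excess)")
  # Fragmented alignment: genomic span > query span + 100.
  frag <- aln_row(tstart = 50000L, tend = 50000L + 60L + 101L)
  expect_equal(base(frag)$status, "FAIL(genomic_span)")
  frag_ok <- aln_row(tstart = 50000L, tend = 50000L + 60L + 100L)
  expect_equal(base(frag_ok)$status, "PASS")
})

test_that("the filter chain is idempotent and counts partition candidates", {
  chroms <- c("chr1", "chr2")
  nodust <- tibble::tibble(start = integer(0), end = integer(0))
  aln <- dplyr::bind_rows(aln_row(), aln_row(score = 10, tstart = 90000L))
  out <- filter_transduction_alignments(mk_call(aln), "chr1", 10000L,
                                        query_dust = nodust,
                                        chromosomes = chroms)
  expect_equal(out$status, "PASS")
  counts <- attr(out, "filter_counts")
  expect_equal(unname(counts["score"]), 1L)
  out2 <- filter_transduction_alignments(out, "chr1", 10000L,
                                         query_dust = nodust,
                                         chromosomes = chroms)
  expect_equal(out2$status, "PASS")
  expect_equal(as.data.frame(out2$alignments), as.data.frame(out$alignments))
})

test_that("sources resolve to reference, segregating or parentless", {
  ref_annots <- l1_annot(5961L, start = 20000L, seq_id = "chr1")
  l1_loci <- tibble::tibble(locus_id = "chr2:40001", chrom = "chr2",
                            pos = 40000L)
  mk <- function(tchrom, tstart) {
    c <- mk_call(aln_row(chrom = tchrom, tstart = tstart))
    c$status <- "PASS"
    c
  }
  calls <- list(
    mk("chr1", 25961L + 200L),   # just 3' of the reference LINE-1
    mk("chr2", 40100L),          # near the dimorphic locus
    mk("chr2", 40150L),          # same source: family of 2
    mk("chr1", 500000L)          # nothing nearby
  )
  res <- resolve_parentless(calls, l1_loci, ref_annots)
  expect_equal(res$source_label,
               c("REFERENCE_SOURCE", "SEGREGATING_SOURCE",
                 "SEGREGATING_SOURCE", "PARENTLESS"))
  fam <- res[res$source_label == "SEGREGATING_SOURCE", ]
  expect_equal(unique(fam$family_size), 2L)
})

test_that("the alignment backend finds planted sequence with flank tolerance", {
  co <- small_cohort()
  chrom <- names(co$reference)[1]
  tag <- substr(co$reference[[chrom]], 150001, 150080)
  aln <- align_to_genome(tag, co$reference)
  expect_gte(nrow(aln), 1L)
  best <- aln[1, ]
  expect_equal(best$target_id, chrom)
  expect_equal(best$target_start, 150000L)
  expect_equal(best$score, 80)
})
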