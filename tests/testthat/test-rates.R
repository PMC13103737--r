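# SNP divergence counting and insertion-rate estimation.

test_that("SNP divergence counts differing biallelic sites outside masks", {
  gt4 <- function(a, b, c, d) c(S1.1 = a, S1.2 = b, S2.1 = c, S2.2 = d)
  v <- make_variants(list(
    vrow("chr1", 10L, "A", "T", gt4(1L, 0L, 0L, 0L)),
    vrow("chr1", 20L, "C", "G", gt4(1L, 0L, 0L, 0L)),
    vrow("chr1", 30L, "G", "A", gt4(1L, 0L, 0L, 0L)),
    # SV record: ignored (allele length > 1).
    vrow("chr1", 40L, "A", paste0("A", strrep("T", 60)), gt4(1L, 0L, 0L, 0L)),
    # same allele on both haplotypes: not a difference
    vrow("chr1", 50L, "T", "C", gt4(1L, 1L, 0L, 0L))
  ), samples = c("S1", "S2"))
  expect_equal(count_snp_divergence(v, "S1.1", "S1.2"), 3L)
  expect_equal(count_snp_divergence(v, "S1.1", "S1.1"), 0L)
  mask <- tibble::tibble(chrom = "chr1", start = 25L, end = 35L)
  expect_equal(count_snp_divergence(v, "S1.1", "S1.2", mask = mask), 2L)
  expect_error(count_snp_divergence(v, "S1.1", "S9.1"), "S9.1")
})

test_that("cohort SNP divergence tracks the genealogy expectation", {
  co <- small_cohort()
  paths <- small_emitted()
  v <- read_pangenome_vcf(paths$vcf)
  L <- sum(nchar(co$reference))
  mu <- co$params$snp_mu
  # ACDsim.1 vs GWsim.1 diverge 2 x 20,000 generations.
  d <- count_snp_divergence(v, "ACDsim.1", "GWsim.1")
  expected <- 2 * mu * 20000 * L
  expect_lt(abs(d - expected), 4 * sqrt(expected) + 1)
})

test_that("rate arithmetic follows T = D/(2 mu L) and r = N/T", {
  ins <- tibble::tibble(label = "a_vs_b", n = 2000)
  snps <- tibble::tibble(label = "a_vs_b", d = 9000)
  est <- estimate_insertion_rate(ins, snps, genome_size = 1e6, mu = 4.5e-9)
  expect_equal(est$per_comparison$divergence_generations, 1e6)
  expect_equal(est$per_comparison$rate, 0.002)
  expect_equal(est$mean_rate, 0.002)
  expect_equal(est$mean_rate_reciprocal, 500)
  # Zero insertions give rate 0.
  est0 <- estimate_insertion_rate(tibble::tibble(label = "x", n = 0),
                                  tibble::tibble(label = "x", d = 100),
                                  genome_size = 1e6)
  expect_equal(est0$mean_rate, 0)
  # Errors: label mismatch; undefined divergence time.
  expect_error(estimate_insertion_rate(
    tibble::tibble(label = "x", n = 1), tibble::tibble(label = "y", d = 1),
    genome_size = 1e6), "label")
  expect_error(estimate_insertion_rate(
    tibble::tibble(label = "x", n = 1), tibble::tibble(label = "x", d = 0),
    genome_size = 1e6), "divergence")
})

test_that("rate estimates are internally self-consistent", {
  est <- study_pipeline()$sinec_rates
  td <- tidy(est)
  expect_equal(td$divergence_generations,
               td$snp_count / (2 * est$mu * est$genome_size))
  expect_equal(td$rate, td$insertion_count / td$divergence_generations)
  expect_equal(est$mean_rate, mean(td$rate))
  g <- glance(est)
  expect_equal(g$mean_rate_reciprocal, round(1 / g$mean_rate))
})

test_that("the 3'-intact filter removes truncated-consensus loci", {
  lib <- test_lib()
  L <- nchar(lib$line1_consensus)
  mk_locus <- function(id, cons_end) {
    alleles <- c("A", paste0("A", strrep("G", 500)))
    attr(alleles, "vcf_index") <- c(0L, 1L)
    loci <- tibble::tibble(
      locus_id = id, chrom = "chr1", pos = 100L,
      alleles = list(alleles),
      hap_allele = list(c(S1.1 = 2L, S1.2 = 1L)),
      longest_allele_index = 2L, max_size_diff = 500L)
    annots <- canisv:::new_annotation_set(tibble::tibble(
      seq_id = paste0(id, "_a1"), start = 0L, end = 500L,
      repeat_name = "L1_sim", repeat_class = "LINE/L1", strand = "+",
      element_id = 1L, cons_start = 1L, cons_end = cons_end))
    list(loci = loci, annots = annots)
  }
  kept <- mk_locus("chr1:101", L - 50L)       # within tolerance
  removed <- mk_locus("chr1:201", L - 150L)   # ends too far from the 3' end
  loci <- dplyr::bind_rows(kept$loci, removed$loci)
  annots <- dplyr::bind_rows(kept$annots, removed$annots)
  out <- filter_line1_3prime_intact(loci, annots, consensus_length = L,
                                    tolerance = 100L)
  expect_equal(out$locus_id, "chr1:101")
  rem <- attr(out, "removal")
  expect_equal(rem$n_removed, 1L)
  expect_equal(rem$fraction_removed, 0.5)
})

test_that("planted intra-element deletion variants are filtered out", {
  res <- study_pipeline()
  co <- res$cohort
  del_ids <- paste0(co$events$chrom, ":", co$events$ip)[
    !is.na(co$events$l1_3del) & co$events$l1_3del]
  expect_gt(length(del_ids), 0)
  expect_false(any(res$l1_filtered$locus_id %in% del_ids))
  # Loci inside reference LINE-1s are enriched among removals.
  rem <- attr(res$l1_filtered, "removal")
  expect_gt(rem$removed_frac_in_ref, rem$removed_frac_not_in_ref)
})
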