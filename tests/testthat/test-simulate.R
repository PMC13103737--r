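# Repeat library and cohort simulation.

test_that("the repeat library satisfies its structural invariants", {
  lib <- test_lib()
  # Exactly two designed ORFs of >= 300 codons, with clean translations.
  orfs <- canisv:::scan_orfs(lib$line1_consensus)
  expect_equal(nrow(orfs), 2L)
  expect_false(any(grepl("\\*", c(lib$protein_orf1, lib$protein_orf2))))
  expect_equal(sort(orfs$n_codons),
               sort(c(nchar(lib$protein_orf1), nchar(lib$protein_orf2))))
  # Maximal exact (CT) run of >= 8 copies in the SINEC.
  runs <- find_exact_tandem_repeats(lib$sinec_consensus, max_unit = 2)
  ct <- runs[runs$unit == "CT", ]
  expect_gte(max(ct$copies), 8L)
  # The SINEC is stop-free in frame 0 so nested insertion keeps ORFs open.
  expect_false(grepl("\\*", canisv:::translate_dna(lib$sinec_consensus)))
})

test_that("the library is deterministic in seed and varies across seeds", {
  expect_identical(build_repeat_library(5), build_repeat_library(5))
  a <- build_repeat_library(1)
  b <- build_repeat_library(2)
  expect_false(identical(a$sinec_consensus, b$sinec_consensus))
  # Same structural layout.
  expect_equal(nchar(a$line1_consensus), nchar(b$line1_consensus))
  expect_equal(a$consensus$class, b$consensus$class)
})

test_that("a cohort has one sequence per haplotype and consistent carriers", {
  co <- small_cohort()
  expect_equal(length(co$haplotypes), 10L)
  g <- co$genealogy
  for (i in seq_len(nrow(co$events))) {
    b <- co$events$branch[i]
    expect_equal(co$events$carriers[[i]],
                 g$carriers[[match(b, g$branch)]])
  }
  # An event on a branch private to one sample is carried by at most two
  # haplotypes of that sample.
  tips <- g$branch[lengths(g$carriers) <= 2]
  priv <- co$events[co$events$branch %in% tips, ]
  expect_gt(nrow(priv), 0)
  for (i in seq_len(nrow(priv))) {
    samp <- unique(sub("\\.[12]$", "", priv$carriers[[i]]))
    expect_equal(length(samp), 1L)
  }
})

test_that("zero insertion rate plants zero rate-drawn events", {
  lib <- test_lib()
  co <- simulate_cohort(lib, cohort_params(
    seed = 9, chrom_length = 120000L, sinec_rate = 1e-4, line1_rate = 0,
    n_str = 0L, n_vntr = 0L, n_ltr = 0L, n_deletion = 0L, n_mixed = 0L,
    n_partial = 0L, n_unclassified = 0L, n_transductions = 0L,
    n_l1_3del = 0L, n_nested = 0L, n_dup_pairs = 0L,
    n_ref_line1 = 1L, n_ref_sinec = 2L))
  expect_equal(sum(co$events$type == "LINE1"), 0L)
})

test_that("planted events appear in carrier haplotypes with duplicated TSDs", {
  co <- small_cohort()
  ins <- co$events[co$events$type != "deletion" & co$events$tsd_len > 0, ]
  ins <- ins[sample.int(nrow(ins), 12), ]
  for (i in seq_len(nrow(ins))) {
    e <- ins[i, ]
    hap <- e$body_carriers[[1]][[1]][1]
    hs <- co$haplotypes[[hap]][[e$chrom]]
    body <- e$bodies[[1]][[1]]
    # TSD + body + TSD present in the carrier, absent from non-carriers.
    signature <- paste0(e$tsd_seq, body, e$tsd_seq)
    expect_true(grepl(signature, hs, fixed = TRUE))
    non <- setdiff(names(co$haplotypes), e$carriers[[1]])[1]
    expect_false(grepl(signature, co$haplotypes[[non]][[e$chrom]],
                       fixed = TRUE))
  }
})

test_that("branch SNP counts follow the mutation-rate model", {
  co <- small_cohort()
  L <- sum(nchar(co$reference))
  mu <- co$params$snp_mu
  counts <- table(co$snps$branch)
  g <- co$genealogy
  # Pooled count within 4 SD of the Poisson expectation.
  expected <- mu * sum(g$length) * L
  expect_lt(abs(nrow(co$snps) - expected), 4 * sqrt(expected) + 1)
  # Longest branch carries more SNPs than a short one.
  long_b <- g$branch[which.max(g$length)]
  expect_gt(counts[[long_b]], 0)
})

test_that("simulation and emission are byte-deterministic under a seed", {
  lib <- test_lib()
  p <- cohort_params(seed = 31, chrom_length = 80000L, sinec_rate = 5e-4,
                     line1_rate = 2e-4, n_str = 2L, n_vntr = 2L, n_ltr = 1L,
                     n_deletion = 1L, n_mixed = 1L, n_partial = 1L,
                     n_unclassified = 1L, n_transductions = 2L,
                     n_l1_3del = 1L, n_l1_3del_in_ref = 1L, n_nested = 1L,
                     n_ref_line1 = 2L, n_ref_sinec = 3L, n_dup_pairs = 1L)
  c1 <- simulate_cohort(lib, p)
  c2 <- simulate_cohort(lib, p)
  expect_identical(c1$haplotypes, c2$haplotypes)
  d1 <- tempfile(); d2 <- tempfile()
  emit_cohort(c1, d1)
  emit_cohort(c2, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("re-reading the emitted VCF recovers truth carrier sets", {
  co <- small_cohort()
  paths <- small_emitted()
  v <- read_pangenome_vcf(paths$vcf)
  key <- paste0(v$chrom, ":", v$pos + 1L)
  ins <- co$events[co$events$type %in% c("SINEC", "LINE1"), ]
  ins <- ins[sample.int(nrow(ins), 10), ]
  for (i in seq_len(nrow(ins))) {
    e <- ins[i, ]
    rec <- v[key == paste0(e$chrom, ":", e$ip), ]
    expect_equal(nrow(rec), 1L)
    g <- rec$gt[[1]]
    carriers <- names(g)[!is.na(g) & g > 0]
    expect_setequal(carriers, e$carriers[[1]])
    # Insertion ALT carries the 1 bp anchor; the empty site is exactly 1 bp.
    expect_equal(nchar(rec$ref), 1L)
    expect_equal(nchar(rec$alt[[1]][1]),
                 1L + nchar(e$bodies[[1]][[1]]) + e$tsd_len)
  }
})
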