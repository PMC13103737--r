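# Clean MEI loci, heterogeneity and allele sharing.

test_that("clean-locus identification keeps only empty/element alleles", {
  cl <- small_classified()
  annots <- small_annots()
  sinec <- identify_clean_mei_loci(cl, "SINEC", annots)
  expect_gt(nrow(sinec), 50)
  # Every state vector contains only the two states, and derived alleles
  # are non-empty.
  for (i in sample.int(nrow(sinec), 10)) {
    st <- sinec$states[[i]]
    expect_true(all(st %in% c("ANCESTRAL", "DERIVED")))
    expect_gte(sinec$n_derived_distinct[i], 1L)
  }
  # Truth: all clean SINEC loci are planted SINEC events.
  co <- small_cohort()
  truth_sinec <- paste0(co$events$chrom, ":", co$events$ip)[
    co$events$type == "SINEC"]
  expect_true(all(sinec$locus_id %in% truth_sinec))
})

test_that("loci with an inconsistent allele are excluded with a reason", {
  cl <- small_classified()
  annots <- small_annots()
  # Fabricate a locus: empty + SINEC + unclassifiable 60 bp allele.
  row <- cl[cl$category == "SINEC", ][1, ]
  junk <- withr::with_seed(20, paste(sample(c("A", "C", "G", "T"), 60,
                                            replace = TRUE), collapse = ""))
  alleles <- c(row$alleles[[1]], paste0(substr(row$alleles[[1]][1], 1, 1), junk))
  attr(alleles, "vcf_index") <- c(attr(row$alleles[[1]], "vcf_index"), 9L)
  row$alleles <- list(alleles)
  ha <- row$hap_allele[[1]]
  ha[1] <- length(alleles)
  row$hap_allele <- list(ha)
  out <- identify_clean_mei_loci(dplyr::bind_rows(row), "SINEC", annots)
  expect_equal(nrow(out), 0L)
  expect_equal(nrow(attr(out, "excluded")), 1L)
})

test_that("heterogeneity counts distinct derived alleles and matches truth", {
  co <- small_cohort()
  annots <- small_annots()
  sinec <- identify_clean_mei_loci(small_classified(), "SINEC", annots)
  truth <- co$events[co$events$type == "SINEC", ]
  truth_id <- paste0(truth$chrom, ":", truth$ip)
  n_bodies <- vapply(truth$bodies, function(b) length(unique(unlist(b))),
                     integer(1))
  m <- match(sinec$locus_id, truth_id)
  expect_equal(sinec$n_derived_distinct, n_bodies[m])
  # Multi-allelic MEI loci exist by construction.
  expect_gt(sum(sinec$n_derived_distinct > 1), 0)
  expect_equal(allele_heterogeneity(sinec[1, ]),
               sinec$n_derived_distinct[1])
})

test_that("sharing profiles satisfy their accounting invariants", {
  annots <- small_annots()
  sinec <- identify_clean_mei_loci(small_classified(), "SINEC", annots)
  samples <- cohort_params()$samples
  sh <- allele_sharing(sinec, samples = samples)
  expect_equal(sum(sh$profiles$n), sh$n_loci)
  # Singletons = profiles with exactly one sample present.
  single_profiles <- sh$profiles[vapply(strsplit(sh$profiles$pattern, ""),
                                        function(x) sum(x == "1") == 1,
                                        logical(1)), ]
  expect_equal(sum(single_profiles$n), sum(sh$per_sample$n_singleton))
  # het + 2*hom = number of derived haplotypes.
  derived_haps <- sum(vapply(sinec$states, function(st) {
    sum(st == "DERIVED")
  }, integer(1)))
  expect_equal(sum(sh$per_sample$n_het) + 2L * sum(sh$per_sample$n_hom),
               derived_haps)
  # Sharing is invariant to sample order.
  sh2 <- allele_sharing(sinec, samples = rev(samples))
  expect_equal(
    dplyr::arrange(sh$per_sample, sample),
    dplyr::arrange(sh2$per_sample, sample)
  )
})

test_that("an inbred sample shows a heterozygosity deficit", {
  annots <- small_annots()
  sinec <- identify_clean_mei_loci(small_classified(), "SINEC", annots)
  sh <- allele_sharing(sinec, samples = cohort_params()$samples)
  ngsd <- sh$per_sample[sh$per_sample$sample == "NGSDsim", ]
  others <- sh$per_sample[!sh$per_sample$sample %in% c("NGSDsim", "GWsim"), ]
  expect_lt(ngsd$n_het, min(others$n_het) + 1)
  expect_gt(ngsd$n_hom, 0)
})

test_that("loci with no ancestral allele count as present in all carriers", {
  cl <- small_classified()
  annots <- small_annots()
  sinec <- identify_clean_mei_loci(cl, "SINEC", annots)
  # Force a locus where every haplotype is derived.
  row <- sinec[1, ]
  st <- row$states[[1]]
  st[] <- "DERIVED"
  row$states <- list(st)
  sh <- allele_sharing(dplyr::bind_rows(row),
                       samples = cohort_params()$samples)
  expect_equal(sh$profiles$pattern, "11111")
  # Conditional sharing given the outgroup.
  sh2 <- allele_sharing(sinec, samples = cohort_params()$samples,
                        given = "GWsim")
  expect_true(all(sh2$conditional$frac_shared >= 0 &
                    sh2$conditional$frac_shared <= 1))
  expect_error(allele_sharing(sinec, samples = c("NOPE", "GWsim")), "NOPE")
})
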