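# End-to-end pipeline: simulate (or load) -> extract -> classify -> MEI and
# LINE-1 analyses -> rates -> STR enrichment -> duplication summary.

#' Pipeline configuration
#'
#' All numeric constants of the analysis surfaced as named keys.
#'
#' @param ... Overrides; unknown keys raise an error.
#' @return A list of class `canisv_pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    simulate = TRUE,
    seed = 1L,
    outdir = NULL,
    cohort = list(),        # overrides passed to cohort_params()
    vcf = NULL, allele_annots = NULL, reference_annots = NULL,
    reference_fasta = NULL, dup_pairs = NULL,
    min_size_diff = 50L,
    coverage = 0.70,
    partial = 0.05,
    str_unit_max = 6L, vntr_unit_min = 7L,
    orf_min_len = 4000L,
    transduction_min_len = 25L,
    transduction_min_score = 25,
    transduction_min_unmasked = 25L,
    transduction_proximal = 7000L,
    transduction_max_hits = 5L,
    transduction_span_excess = 100L,
    source_window = 1000L,
    line1_3prime_tolerance = 100L,
    mu = 4.5e-9,
    n_perm = 100L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg[names(over)] <- over
  class(cfg) <- "canisv_pipeline_config"
  cfg
}

#' Run the full structural-variant analysis pipeline
#'
#' With `simulate = TRUE` (default) a cohort is generated under
#' `config$seed`, emitted to `config$outdir` (a temporary directory when
#' `NULL`) and read back through the standard-format readers, so the whole
#' IO path is exercised; with `simulate = FALSE` the configured input files
#' are used. Stages: SV extraction, ten-category classification, clean
#' SINEC/LINE-1 locus analysis (heterogeneity, allele sharing), LINE-1 ORF
#' and 3' transduction analysis, SNP-calibrated insertion-rate estimation,
#' exact-STR enrichment and duplication-pair summarization. A
#' machine-readable report is written to `report.json` in the output
#' directory.
#'
#' @param config A [pipeline_config()] object.
#' @return A list of class `canisv_pipeline_result` with all stage outputs
#'   and the `report` list.
#' @export
run_full_pipeline <- function(config = pipeline_config()) {
  cfg <- config
  outdir <- cfg$outdir %||% tempfile("canisv_run_")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  cohort <- NULL
  if (isTRUE(cfg$simulate)) {
    lib <- build_repeat_library(cfg$seed)
    cp <- do.call(cohort_params, c(list(seed = cfg$seed), cfg$cohort))
    cohort <- simulate_cohort(lib, cp)
    paths <- emit_cohort(cohort, outdir)
    cfg$vcf <- paths$vcf
    cfg$allele_annots <- paths$alleles_out
    cfg$reference_annots <- paths$reference_out
    cfg$reference_fasta <- paths$reference
    cfg$dup_pairs <- paths$dup_pairs
    samples <- cp$samples
    outgroup <- cp$outgroup
  } else {
    for (k in c("vcf", "allele_annots", "reference_annots",
                "reference_fasta", "dup_pairs")) {
      if (is.null(cfg[[k]])) abort(paste0("missing input: ", k))
    }
    lib <- build_repeat_library(cfg$seed)
    samples <- cfg$cohort$samples %||% cohort_params()$samples
    outgroup <- cfg$cohort$outgroup %||% cohort_params()$outgroup
  }

  variants <- read_pangenome_vcf(cfg$vcf, samples = samples)
  reference <- read_fasta(cfg$reference_fasta)
  chroms <- names(reference)
  annots <- read_repeatmasker_out(cfg$allele_annots)
  ref_annots <- read_repeatmasker_out(cfg$reference_annots)
  dup_pairs <- read_dup_pairs(cfg$dup_pairs)

  loci <- extract_sv_loci(variants, samples,
                          min_size_diff = cfg$min_size_diff)
  classified <- classify_loci(loci, annots, coverage = cfg$coverage,
                              partial = cfg$partial,
                              str_unit_max = cfg$str_unit_max,
                              vntr_unit_min = cfg$vntr_unit_min)
  summary <- classification_summary(classified)

  sinec_mei <- identify_clean_mei_loci(classified, "SINEC", annots)
  l1_mei <- identify_clean_mei_loci(classified, "LINE/L1", annots)
  sharing <- allele_sharing(sinec_mei, samples = samples,
                            autosomes = chroms, given = outgroup)
  heterogeneity <- table(factor(sinec_mei$n_derived_distinct,
                                levels = 1:6))

  merged_annots <- merge_repeat_annotations(annots)
  annots_by_seq <- split(as_tibble(merged_annots), merged_annots$seq_id)
  allele_annots_of <- function(row) {
    vcf_idx <- attr(row$alleles[[1]], "vcf_index") %||%
      (seq_along(row$alleles[[1]]) - 1L)
    annots_by_seq[[paste0(row$locus_id, "_a",
                          vcf_idx[row$longest_allele_index])]]
  }

  # LINE-1 ORF scan and transduction analysis on LINE/L1 loci.
  l1_loci <- classified[classified$category == "LINE/L1", , drop = FALSE]
  orf_results <- list()
  td_calls <- list()
  for (i in seq_len(nrow(l1_loci))) {
    row <- l1_loci[i, ]
    allele <- longest_allele(row)
    a <- allele_annots_of(row)
    if (is.null(a)) next
    orfs <- find_intact_orfs(allele, a, lib, min_len = cfg$orf_min_len)
    orf_results[[row$locus_id]] <- orfs
    cand <- extract_3prime_transduction(allele, a,
                                        min_len = cfg$transduction_min_len,
                                        locus_id = row$locus_id)
    if (is.null(cand)) next
    cand$alignments <- align_to_genome(cand$transduced_seq, reference)
    q_annots <- annotate_with_library(cand$transduced_seq, lib,
                                      seq_id = "query")
    cand <- filter_transduction_alignments(
      cand, row$chrom, row$pos,
      query_annots = q_annots, chromosomes = chroms,
      min_score = cfg$transduction_min_score,
      min_unmasked = cfg$transduction_min_unmasked,
      proximal = cfg$transduction_proximal,
      max_hits = cfg$transduction_max_hits,
      span_excess = cfg$transduction_span_excess
    )
    td_calls[[row$locus_id]] <- cand
  }
  fully_intact <- vapply(orf_results, function(o) {
    isTRUE(attr(o, "fully_intact"))
  }, logical(1))
  elongated_orf2 <- vapply(orf_results, function(o) {
    any(o$matches == "ORF2p" & o$intact & o$insertion_codons > 0)
  }, logical(1))
  transductions <- resolve_parentless(td_calls, l1_mei, ref_annots,
                                      window = cfg$source_window)

  # Insertion rates: 9 haplotypes vs <outgroup>.1, plus <outgroup>.1 vs the
  # first non-outgroup haplotype (avoids double counting outgroup events).
  og1 <- paste0(outgroup, ".1")
  dogs <- setdiff(samples, outgroup)
  focal <- c(unlist(lapply(dogs, function(s) paste0(s, ".", 1:2))),
             paste0(outgroup, ".2"), og1)
  comparator <- c(rep(og1, length(focal) - 1L), paste0(dogs[1], ".1"))
  mask <- bind_rows(
    tibble(chrom = dup_pairs$chrA, start = dup_pairs$startA,
           end = dup_pairs$endA),
    tibble(chrom = dup_pairs$chrB, start = dup_pairs$startB,
           end = dup_pairs$endB)
  )
  masked_bp <- sum((mask |>
                      group_by(.data$chrom) |>
                      dplyr::reframe(merge_intervals(.data$start, .data$end)) |>
                      ungroup() |>
                      mutate(w = .data$end - .data$start))$w)
  genome_size <- sum(nchar(reference)) - masked_bp
  snp_tbl <- tibble(
    label = paste0(focal, "_vs_", comparator),
    d = vapply(seq_along(focal), function(k) {
      count_snp_divergence(variants, focal[k], comparator[k], mask = mask,
                           autosomes = chroms)
    }, numeric(1))
  )
  count_insertions <- function(mei, focal, comparator) {
    vapply(seq_along(focal), function(k) {
      sum(vapply(mei$states, function(st) {
        identical(unname(st[focal[k]]), "DERIVED") &&
          identical(unname(st[comparator[k]]), "ANCESTRAL")
      }, logical(1)))
    }, numeric(1))
  }
  sinec_ins <- tibble(label = snp_tbl$label,
                      n = count_insertions(sinec_mei, focal, comparator))
  l1_filtered <- filter_line1_3prime_intact(
    l1_mei, annots, consensus_length = nchar(lib$line1_consensus),
    tolerance = cfg$line1_3prime_tolerance, ref_annots = ref_annots)
  l1_ins <- tibble(label = snp_tbl$label,
                   n = count_insertions(l1_filtered, focal, comparator))
  sinec_rates <- estimate_insertion_rate(sinec_ins, snp_tbl, genome_size,
                                         mu = cfg$mu,
                                         element_type = "SINEC")
  l1_rates <- estimate_insertion_rate(l1_ins, snp_tbl, genome_size,
                                      mu = cfg$mu, element_type = "LINE1")

  # Exact-STR enrichment against reference annotation classes.
  strs <- genome_strs(reference, max_unit = cfg$str_unit_max)
  merged_ref <- merge_repeat_annotations(ref_annots)
  cls_tbl <- as_tibble(merged_ref)
  cls_tbl$bucket <- ifelse(
    startsWith(cls_tbl$repeat_name, "SINEC"), "SINEC",
    ifelse(startsWith(cls_tbl$repeat_class, "LINE/L1"), "LINE/L1",
           ifelse(cls_tbl$repeat_class == "Satellite", "Satellite", NA)))
  classes <- lapply(split(cls_tbl[!is.na(cls_tbl$bucket), ],
                          cls_tbl$bucket[!is.na(cls_tbl$bucket)]),
                    function(df) {
                      rename(df[, c("seq_id", "start", "end")],
                             chrom = "seq_id")
                    })
  chrom_sizes <- setNames(nchar(reference), names(reference))
  enrichment <- str_enrichment(strs, classes, chrom_sizes,
                               n_perm = cfg$n_perm, seed = cfg$seed)

  dup_class <- filter_and_classify_dup_pairs(dup_pairs,
                                             chromosomes = chroms)
  dup_summary <- summarize_dup_pairs(dup_class,
                                     genome_size = sum(nchar(reference)))

  report <- list(
    seed = cfg$seed,
    n_variant_records = nrow(variants),
    filter_counts = as.list(attr(loci, "filter_counts")),
    n_loci = nrow(classified),
    category_counts = as.list(table(factor(classified$category,
                                           levels = SV_CATEGORIES))),
    allele_count_classes = as.list(table(classified$allele_count_class)),
    n_clean_sinec = nrow(sinec_mei),
    n_clean_line1 = nrow(l1_mei),
    sinec_heterogeneity = as.list(heterogeneity),
    sharing_per_sample = sharing$per_sample,
    n_line1_fully_intact = sum(fully_intact),
    n_elongated_orf2 = sum(elongated_orf2),
    n_transduction_candidates = length(td_calls),
    n_transduction_pass = sum(transductions$source_label != "" &
                                !is.na(transductions$source_label)),
    transduction_labels = as.list(table(transductions$source_label)),
    line1_3prime_removed = attr(l1_filtered, "removal")$fraction_removed,
    genome_size_analysed = genome_size,
    sinec_rate = sinec_rates$mean_rate,
    sinec_rate_reciprocal = sinec_rates$mean_rate_reciprocal,
    line1_rate = l1_rates$mean_rate,
    line1_rate_reciprocal = l1_rates$mean_rate_reciprocal,
    enrichment = tidy(enrichment),
    dup_summary = glance(dup_summary)
  )
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  structure(list(
    config = cfg, cohort = cohort, variants = variants, loci = classified,
    summary = summary, sinec_mei = sinec_mei, l1_mei = l1_mei,
    l1_filtered = l1_filtered, sharing = sharing,
    orf_results = orf_results, transductions = transductions,
    sinec_rates = sinec_rates, l1_rates = l1_rates,
    enrichment = enrichment, dup_summary = dup_summary,
    report = report, report_path = file.path(outdir, "report.json")
  ), class = "canisv_pipeline_result")
}

#' @export
print.canisv_pipeline_result <- function(x, ...) {
  cat("<canisv_pipeline_result>\n")
  cat("  loci:", x$report$n_loci,
      " clean SINEC:", x$report$n_clean_sinec,
      " clean LINE-1:", x$report$n_clean_line1, "\n")
  cat(sprintf("  SINEC rate: %.3g (~1/%d births); LINE-1 rate: %.3g (~1/%d)\n",
              x$report$sinec_rate, x$report$sinec_rate_reciprocal,
              x$report$line1_rate, x$report$line1_rate_reciprocal))
  invisible(x)
}

# ---- truth comparison helpers ---------------------------------------------

#' Compare classifications against simulation truth
#'
#' @param cohort The simulated cohort.
#' @param classified Classified loci from [classify_loci()].
#' @return A list: `n_eligible` (planted loci whose allele composition
#'   determines the category by construction), `n_correct`, `accuracy`, and
#'   the confusion tibble.
#' @export
truth_classification_accuracy <- function(cohort, classified) {
  ev <- cohort$events
  truth <- tibble(
    locus_id = paste0(ev$chrom, ":", ev$ip),
    truth_category = ev$truth_category
  )
  truth <- truth[!is.na(truth$truth_category), ]
  j <- dplyr::inner_join(truth, classified[, c("locus_id", "category")],
                         by = "locus_id")
  conf <- j |>
    count(.data$truth_category, .data$category) |>
    arrange(dplyr::desc(.data$n))
  list(
    n_eligible = nrow(j),
    n_correct = sum(j$truth_category == j$category),
    accuracy = if (nrow(j)) mean(j$truth_category == j$category) else NA_real_,
    confusion = conf
  )
}

#' Compare resolved transductions against simulation truth
#'
#' @param cohort The simulated cohort.
#' @param transductions Output of [resolve_parentless()].
#' @return A list with per-event recovery and the overall fraction of
#'   planted transductions recovered with the correct source label.
#' @export
transduction_recovery <- function(cohort, transductions) {
  ev <- cohort$events
  td <- ev[ev$type == "LINE1_TD", ]
  truth <- tibble(
    locus_id = paste0(td$chrom, ":", td$ip),
    kind = td$td_source_kind,
    source = td$td_source
  )
  expected_label <- ifelse(truth$kind == "reference", "REFERENCE_SOURCE",
                           "SEGREGATING_SOURCE")
  j <- left_join(truth, transductions, by = "locus_id")
  correct <- !is.na(j$source_label) & j$source_label == expected_label
  list(
    n_planted = nrow(truth),
    n_recovered = sum(!is.na(j$source_label)),
    n_correct_label = sum(correct),
    fraction_correct = if (nrow(truth)) mean(correct) else NA_real_,
    detail = mutate(j, expected = expected_label, correct = correct)
  )
}
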