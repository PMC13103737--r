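# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

test_lib <- function() cached("lib", build_repeat_library(1L))

# Desk-scale cohort kept small for fast module tests.
small_params <- function(...) {
  cohort_params(
    seed = 2L, chrom_length = 200000L,
    sinec_rate = 0.0025, line1_rate = 0.00045,
    n_str = 6L, n_vntr = 6L, n_ltr = 3L, n_deletion = 3L,
    n_mixed = 2L, n_partial = 2L, n_unclassified = 2L,
    n_transductions = 6L, n_l1_3del = 4L, n_l1_3del_in_ref = 2L,
    n_nested = 1L, n_ref_line1 = 4L, n_ref_sinec = 8L, n_dup_pairs = 3L,
    ...
  )
}

small_cohort <- function() {
  cached("small_cohort", simulate_cohort(test_lib(), small_params()))
}

small_emitted <- function() {
  cached("small_emitted", {
    d <- file.path(tempdir(), "canisv_small_cohort")
    emit_cohort(small_cohort(), d)
  })
}

small_loci <- function() {
  cached("small_loci", {
    paths <- small_emitted()
    v <- read_pangenome_vcf(paths$vcf)
    extract_sv_loci(v)
  })
}

small_annots <- function() {
  cached("small_annots", read_repeatmasker_out(small_emitted()$alleles_out))
}

small_classified <- function() {
  cached("small_classified", classify_loci(small_loci(), small_annots()))
}

# Full-scale pipeline at the default study design (used by the acceptance
# checks on classification, transduction recovery and rate recovery).
study_pipeline <- function() {
  cached("study_pipeline", run_full_pipeline(pipeline_config(seed = 1L)))
}

# Minimal variant table constructor for extraction tests.
make_variants <- function(rows, samples) {
  v <- dplyr::bind_rows(rows)
  attr(v, "samples") <- samples
  class(v) <- c("canisv_variants", class(v))
  v
}

vrow <- function(chrom, pos, ref, alt, gt) {
  tibble::tibble(chrom = chrom, pos = pos, id = ".", ref = ref,
                 alt = list(alt), gt = list(gt))
}

gt_of <- function(...) {
  x <- c(...)
  stopifnot(!is.null(names(x)))
  x
}
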