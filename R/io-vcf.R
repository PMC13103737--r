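#' Read a multi-sample pangenome VCF
#'
#' Parses the variant file projected from a pangenome graph (for example the
#' output of the Minigraph-Cactus pipeline) into a tidy table of sites with
#' per-haplotype allele assignments. Multiallelic records are kept unsplit:
#' alleles are indexed `0` (REF) through `length(ALT)`. Diploid genotypes
#' `a|b` map haplotype 1 to `a` and haplotype 2 to `b`; a missing genotype
#' (`.`, `./.` or `.|.`) yields `NA` for both haplotypes. Unphased `a/b`
#' genotypes are accepted as ordered with a warning, since haplotype-resolved
#' assemblies are inherently phased.
#'
#' @param path Path to a VCF 4.x file (plain or bgzipped).
#' @param samples Character vector of sample names to analyse. Defaults to all
#'   samples in the file except `reference_sample`.
#' @param reference_sample Optional name of the reference-path sample included
#'   in the graph VCF; it is read but flagged, and excluded from `samples` by
#'   default.
#' @return A tibble of class `canisv_variants` with columns `chrom`, `pos`
#'   (0-based), `id`, `ref`, `alt` (list of character vectors) and `gt` (list
#'   of named integer vectors, names `"<sample>.1"`/`"<sample>.2"`). The
#'   analysed sample set is stored in `attr(, "samples")`.
#' @export
read_pangenome_vcf <- function(path, samples = NULL, reference_sample = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt_mat <- v@gt
  available <- setdiff(colnames(gt_mat), "FORMAT")
  if (is.null(samples)) samples <- setdiff(available, reference_sample)
  wanted <- unique(c(samples, reference_sample))
  absent <- setdiff(wanted, available)
  if (length(absent) > 0) {
    abort(paste0("sample column(s) missing from VCF: ",
                 paste(absent, collapse = ", ")))
  }
  n <- nrow(fix)
  ref <- toupper(fix[, "REF"])
  alt_raw <- fix[, "ALT"]
  alt <- lapply(alt_raw, function(a) toupper(strsplit(a, ",", fixed = TRUE)[[1]]))
  bad_allele <- which(!vapply(seq_len(n), function(i) {
    is_dna_string(ref[i]) && all(is_dna_string(alt[[i]]))
  }, logical(1)))
  if (length(bad_allele) > 0) {
    abort(paste0("non-ACGTN or symbolic allele at record ", bad_allele[1]))
  }

  unphased_seen <- FALSE
  gt_rx <- "^(\\.|[0-9]+)(([|/])(\\.|[0-9]+))?(:.*)?$"
  hap_names <- as.vector(rbind(paste0(wanted, ".1"), paste0(wanted, ".2")))

  # Parse GT per sample column, vectorized over records.
  hap1 <- matrix(NA_integer_, nrow = n, ncol = length(wanted))
  hap2 <- matrix(NA_integer_, nrow = n, ncol = length(wanted))
  for (j in seq_along(wanted)) {
    g <- gt_mat[, wanted[j]]
    g[is.na(g)] <- "."  # vcfR reads "." genotypes as NA
    ok <- grepl(gt_rx, g)
    if (!all(ok)) {
      abort(paste0("malformed GT '", g[which(!ok)[1]], "' for sample ",
                   wanted[j], " at record ", which(!ok)[1]))
    }
    a1 <- sub(gt_rx, "\\1", g)
    sep <- sub(gt_rx, "\\3", g)
    a2 <- sub(gt_rx, "\\4", g)
    if (any(sep == "/" & a1 != "." )) unphased_seen <- TRUE
    haploid <- sep == ""
    a2[haploid] <- a1[haploid]
    hap1[, j] <- suppressWarnings(as.integer(ifelse(a1 == ".", NA, a1)))
    hap2[, j] <- suppressWarnings(as.integer(ifelse(a2 == ".", NA, a2)))
  }
  if (unphased_seen) {
    warn("unphased '/' genotypes present; treated as ordered (hap1 = first allele)")
  }
  n_alleles <- lengths(alt) + 1L
  too_big <- hap1 >= n_alleles | hap2 >= n_alleles
  if (any(too_big, na.rm = TRUE)) {
    abort(paste0("allele index out of range at record ",
                 which(rowSums(too_big, na.rm = TRUE) > 0)[1]))
  }

  gt <- lapply(seq_len(n), function(i) {
    v <- as.vector(rbind(hap1[i, ], hap2[i, ]))
    names(v) <- hap_names
    v
  })
  out <- tibble(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]) - 1L,
    id = fix[, "ID"],
    ref = ref,
    alt = alt,
    gt = gt
  )
  attr(out, "samples") <- samples
  attr(out, "reference_sample") <- reference_sample
  class(out) <- c("canisv_variants", class(out))
  out
}

#' Write a variant table back to VCF 4.2
#'
#' Inverse of [read_pangenome_vcf()]: positions are converted back to 1-based
#' and genotypes written phased (`a|b`, `.` for missing haplotypes).
#'
#' @param variants A `canisv_variants` tibble.
#' @param path Output path (plain text).
#' @param contigs Optional named integer vector of contig lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_pangenome_vcf <- function(variants, path, contigs = NULL) {
  samples <- attr(variants, "samples")
  ref_sample <- attr(variants, "reference_sample")
  cols <- unique(c(ref_sample, samples))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=canisv",
    if (!is.null(contigs)) {
      paste0("##contig=<ID=", names(contigs), ",length=", contigs, ">")
    },
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cols), collapse = "\t")
  )
  fmt_gt <- function(g, sample) {
    a <- g[paste0(sample, ".1")]
    b <- g[paste0(sample, ".2")]
    paste0(ifelse(is.na(a), ".", a), "|", ifelse(is.na(b), ".", b))
  }
  body <- vapply(seq_len(nrow(variants)), function(i) {
    g <- variants$gt[[i]]
    gts <- vapply(cols, fmt_gt, character(1), g = g)
    paste(c(variants$chrom[i], variants$pos[i] + 1L, variants$id[i],
            variants$ref[i], paste(variants$alt[[i]], collapse = ","),
            ".", ".", ".", "GT", gts), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}
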