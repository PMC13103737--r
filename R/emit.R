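# Emit a simulated cohort as standard files: reference and haplotype FASTA,
# a pangenome-style VCF (anchor-base convention: the empty site is exactly
# 1 bp), RepeatMasker-format truth annotations for the reference and for
# every allele, a duplication-pair table and a truth JSON.

#' Emit a simulated cohort to disk
#'
#' @param cohort A [simulate_cohort()] object.
#' @param outdir Output directory (created if needed).
#' @param fragment_fraction Fraction of single-allele SINEC loci whose truth
#'   annotation is emitted as two SINEC fragments bridged by a `(CT)n`
#'   Simple_repeat row (exercising annotation merging), as RepeatMasker
#'   output does.
#' @return Invisibly, a named list of the file paths written.
#' @export
emit_cohort <- function(cohort, outdir, fragment_fraction = 0.3) {
  stopifnot(inherits(cohort, "canisv_cohort"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    reference = file.path(outdir, "reference.fa"),
    haplotypes = file.path(outdir, "haplotypes.fa"),
    vcf = file.path(outdir, "cohort.vcf"),
    reference_out = file.path(outdir, "reference.out"),
    alleles_out = file.path(outdir, "alleles.out"),
    alleles_fa = file.path(outdir, "alleles.fa"),
    dup_pairs = file.path(outdir, "dup_pairs.tsv"),
    truth = file.path(outdir, "truth.json")
  )
  write_fasta(cohort$reference, paths$reference)
  hap_seqs <- unlist(lapply(names(cohort$haplotypes), function(h) {
    s <- cohort$haplotypes[[h]]
    setNames(s, paste0(h, "#", names(s)))
  }))
  write_fasta(hap_seqs, paths$haplotypes)

  tab <- cohort_tables(cohort, fragment_fraction = fragment_fraction)
  contigs <- setNames(nchar(cohort$reference), names(cohort$reference))
  write_pangenome_vcf(tab$variants, paths$vcf, contigs = contigs)

  ref_annots <- cohort$ref_annots
  ref_annots$element_id <- seq_len(nrow(ref_annots))
  write_repeatmasker_out(ref_annots, paths$reference_out)
  write_repeatmasker_out(tab$allele_annots, paths$alleles_out)
  if (length(tab$allele_seqs) > 0) {
    write_fasta(tab$allele_seqs, paths$alleles_fa)
  }
  write_dup_pairs(cohort$dup_pairs, paths$dup_pairs)

  ev <- cohort$events
  truth <- list(
    params = cohort$params[!vapply(cohort$params, is.character, logical(1)) |
                             names(cohort$params) %in% c("outgroup")],
    genealogy = cohort$genealogy[, c("branch", "t_lo", "t_hi")],
    snp_per_branch = as.list(table(cohort$snps$branch)),
    events = lapply(seq_len(nrow(ev)), function(i) {
      list(
        event_id = ev$event_id[i],
        locus_id = paste0(ev$chrom[i], ":", ev$ip[i]),
        type = ev$type[i],
        chrom = ev$chrom[i],
        pos = ev$ip[i],
        tsd_len = ev$tsd_len[i],
        tsd_seq = ev$tsd_seq[i],
        branch = ev$branch[i],
        carriers = ev$carriers[[i]],
        n_distinct_bodies = length(ev$bodies[[i]]),
        truth_category = ev$truth_category[i],
        td_source = if ("td_source" %in% names(ev)) ev$td_source[i] else NULL,
        td_source_kind = if ("td_source_kind" %in% names(ev))
          ev$td_source_kind[i] else NULL
      )
    })
  )
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(paths)
}

# Build the VCF variant table, allele truth annotations and allele sequences
# for a cohort. Used by emit_cohort() and directly by the in-memory pipeline.
cohort_tables <- function(cohort, fragment_fraction = 0.3) {
  ev <- cohort$events
  lib <- cohort$library
  samples <- cohort$params$samples
  haps <- unlist(lapply(samples, function(s) paste0(s, ".", 1:2)))
  l1_len <- nchar(lib$line1_consensus)

  # Deterministic fragmentation choice (independent of the simulation RNG
  # state at call time).
  frag_pick <- withr::with_seed(cohort$params$seed + 1L, {
    runif(nrow(ev)) < fragment_fraction
  })

  var_rows <- vector("list", nrow(ev))
  annot_rows <- list()
  allele_seqs <- character(0)
  eid <- 0L
  next_eid <- function() {
    eid <<- eid + 1L
    eid
  }
  for (i in seq_len(nrow(ev))) {
    e <- ev[i, ]
    chrom <- e$chrom
    ip <- e$ip
    locus <- paste0(chrom, ":", ip)
    anchor <- substr(cohort$reference[[chrom]], ip, ip)
    if (e$type == "deletion") {
      ref_allele <- substr(cohort$reference[[chrom]], ip, ip + e$del_len)
      alts <- anchor
      gt <- setNames(rep(0L, length(haps)), paste0(haps))
      gt[haps %in% e$carriers[[1]]] <- 1L
      bodies <- character(0)
      body_annots <- list()
      del_body <- substr(ref_allele, 2L, nchar(ref_allele))
      allele_seqs[paste0(locus, "_a0")] <- del_body
    } else {
      bodies <- unlist(ev$bodies[[i]])
      bcarr <- ev$body_carriers[[i]]
      # Deduplicate identical bodies (merge carrier sets).
      if (length(bodies) > 1 && anyDuplicated(bodies)) {
        u <- !duplicated(bodies)
        for (k in which(duplicated(bodies))) {
          tgt <- match(bodies[k], bodies)
          bcarr[[tgt]] <- union(bcarr[[tgt]], bcarr[[k]])
        }
        bodies <- bodies[u]
        bcarr <- bcarr[u]
      }
      alts <- paste0(anchor, bodies, e$tsd_seq)
      gt <- setNames(rep(0L, length(haps)), paste0(haps))
      for (k in seq_along(bodies)) {
        gt[haps %in% bcarr[[k]]] <- k
      }
      for (k in seq_along(bodies)) {
        aid <- paste0(locus, "_a", k)
        allele_body <- paste0(bodies[k], e$tsd_seq)
        allele_seqs[aid] <- allele_body
        annot_rows[[length(annot_rows) + 1L]] <-
          truth_allele_annots(e, k, aid, nchar(bodies[k]), lib, l1_len,
                              fragment = frag_pick[i] && k == 1L,
                              next_eid = next_eid)
      }
    }
    gt_vec <- as.vector(rbind(gt[paste0(samples, ".1")],
                              gt[paste0(samples, ".2")]))
    names(gt_vec) <- as.vector(rbind(paste0(samples, ".1"),
                                     paste0(samples, ".2")))
    var_rows[[i]] <- tibble(
      chrom = chrom, pos = ip - 1L, id = e$event_id,
      ref = if (e$type == "deletion") {
        substr(cohort$reference[[chrom]], ip, ip + e$del_len)
      } else anchor,
      alt = list(alts), gt = list(gt_vec)
    )
  }

  # SNP records.
  sn <- cohort$snps
  carriers_of <- function(branch) {
    cohort$genealogy$carriers[[match(branch, cohort$genealogy$branch)]]
  }
  snp_rows <- lapply(seq_len(nrow(sn)), function(i) {
    carr <- carriers_of(sn$branch[i])
    gt <- setNames(rep(0L, length(haps)), haps)
    gt[haps %in% carr] <- 1L
    tibble(chrom = sn$chrom[i], pos = sn$pos[i],
           id = paste0("snp", i), ref = sn$ref[i],
           alt = list(sn$alt[i]), gt = list(gt))
  })

  variants <- bind_rows(c(var_rows, snp_rows))
  variants <- arrange(variants, .data$chrom, .data$pos)
  attr(variants, "samples") <- samples
  attr(variants, "reference_sample") <- NULL
  class(variants) <- c("canisv_variants", class(variants))

  allele_annots <- if (length(annot_rows)) {
    new_annotation_set(bind_rows(annot_rows))
  } else {
    empty_annotation_set()
  }
  list(variants = variants, allele_annots = allele_annots,
       allele_seqs = allele_seqs)
}

# Truth RepeatMasker-style annotation rows for one allele body. The allele
# sequence is body + TSD; coordinates are on the allele (anchor stripped).
truth_allele_annots <- function(e, k, aid, body_len, lib, l1_len,
                                fragment = FALSE, next_eid = NULL) {
  row <- function(start, end, name, class, id, cs, ce) {
    tibble(seq_id = aid, start = as.integer(start), end = as.integer(end),
           repeat_name = name, repeat_class = class, strand = "+",
           element_id = as.integer(id), cons_start = as.integer(cs),
           cons_end = as.integer(ce))
  }
  col <- function(name, default = NA) {
    if (name %in% names(e) && !is.na(e[[name]])) e[[name]] else default
  }
  type <- e$type
  t5 <- as.integer(col("trunc5", 0L))
  if (type == "SINEC") {
    id <- next_eid()
    if (fragment && t5 < 60L) {
      # Emit as SINEC / (CT)n / SINEC fragments sharing one element ID.
      ct_s <- 90L - t5
      ct_e <- 114L - t5
      bind_rows(
        row(0L, ct_s, "SINEC_sim", "SINE/tRNA-Lys", id, t5 + 1L, 90L),
        row(ct_s, ct_e, "(CT)n", "Simple_repeat", next_eid(), 1L, 24L),
        row(ct_e, body_len, "SINEC_sim", "SINE/tRNA-Lys", id, 115L, 201L)
      )
    } else {
      row(0L, body_len, "SINEC_sim", "SINE/tRNA-Lys", id, t5 + 1L, 201L)
    }
  } else if (type %in% c("LINE1", "LINE1_TD")) {
    del3 <- as.integer(col("l1_del3", 0L))
    cons_part <- l1_len - t5 - del3
    row(0L, cons_part, "L1_sim", "LINE/L1", next_eid(), t5 + 1L,
        l1_len - del3)
  } else if (type == "nested") {
    if (k == 1L) {
      row(0L, l1_len, "L1_sim", "LINE/L1", next_eid(), 1L, l1_len)
    } else {
      off0 <- e$nested_offset - 1L  # 0-based insertion offset in the L1
      s_len <- nchar(lib$sinec_consensus)
      id <- next_eid()
      bind_rows(
        row(0L, off0, "L1_sim", "LINE/L1", id, 1L, off0),
        row(off0, off0 + s_len, "SINEC_sim", "SINE/tRNA-Lys", next_eid(),
            1L, s_len),
        row(off0 + s_len + e$nested_tsd, l1_len + s_len + e$nested_tsd,
            "L1_sim", "LINE/L1", id, off0 + 1L, l1_len)
      )
    }
  } else if (type %in% c("STR", "VNTR")) {
    row(0L, body_len, paste0("(", e$unit, ")n"), "Simple_repeat",
        next_eid(), 1L, body_len)
  } else if (type == "LTR") {
    row(0L, body_len, "LTR_sim", "LTR/ERV", next_eid(), 1L, body_len)
  } else if (type == "mixed") {
    bind_rows(
      row(0L, 150L, "SINEC_sim", "SINE/tRNA-Lys", next_eid(), 1L, 150L),
      row(150L, 240L, "LTR_sim", "LTR/ERV", next_eid(), 1L, 90L)
    )
  } else if (type == "partial") {
    row(0L, 36L, "SINEC_sim", "SINE/tRNA-Lys", next_eid(), 1L, 36L)
  } else {
    NULL
  }
}
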