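# Synthetic cohort simulation: a small canine-like reference, five diploid
# samples related by a fixed genealogy with a wolf-like outgroup, and planted
# structural-variant events with full ground truth.

#' Parameters for the synthetic cohort generator
#'
#' Defaults describe the desk-scale study design: a 2 x 1 Mb reference,
#' five diploid samples (four dog-like, one wolf-like outgroup) on a fixed
#' genealogy totalling 47,550 branch-generations, SINEC and LINE-1 insertion
#' rates of 0.0125 and 0.00125 per generation (about 600 and 60 expected
#' events), an SNP mutation rate of 4.5e-9 per bp per generation, and
#' target-site duplications drawn uniformly from 5-20 bp.
#'
#' @param ... Named overrides of any default listed above (see
#'   [simulate_cohort()] for how each is used).
#' @return A named list of class `canisv_cohort_params`.
#' @export
cohort_params <- function(...) {
  p <- list(
    seed = 1L,
    n_chrom = 2L,
    chrom_length = 1000000L,
    samples = c("ACDsim", "CCsim", "SHsim", "NGSDsim", "GWsim"),
    outgroup = "GWsim",
    snp_mu = 4.5e-9,
    sinec_rate = 0.0125,
    line1_rate = 0.00125,
    p_full_length = 0.35,
    p_orf2_stop = 0.2,
    tsd_range = c(5L, 20L),
    het_fraction = 0.15,
    n_str = 25L, n_vntr = 25L, n_ltr = 12L, n_deletion = 12L,
    n_mixed = 6L, n_partial = 6L, n_unclassified = 6L,
    n_transductions = 20L,
    n_l1_3del = 8L, n_l1_3del_in_ref = 5L,
    n_nested = 2L,
    n_ref_line1 = 6L, n_ref_sinec = 20L, n_ref_satellite = 2L,
    n_dup_pairs = 6L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown) > 0) {
    abort(paste0("unknown cohort parameter(s): ", paste(unknown, collapse = ", ")))
  }
  p[names(over)] <- over
  class(p) <- "canisv_cohort_params"
  p
}

# Fixed five-sample genealogy (generations ago). Dog haplotypes coalesce
# recently within each sample; NGSDsim coalesces at 50 generations to
# emulate captive inbreeding; the wolf-like outgroup carries deep
# within-individual diversity (haplotypes coalescing at 10,000 generations)
# and splits from the dog clade at 20,000 generations.
default_genealogy <- function(samples, outgroup) {
  dogs <- setdiff(samples, outgroup)
  stopifnot(length(dogs) == 4L)
  hap <- function(s) paste0(s, ".", 1:2)
  coal <- setNames(rep(500L, length(samples)), samples)
  if ("NGSDsim" %in% samples) coal["NGSDsim"] <- 50L
  coal[outgroup] <- 10000L
  b <- list()
  add <- function(id, t_lo, t_hi, carriers) {
    b[[length(b) + 1L]] <<- tibble(
      branch = id, t_lo = t_lo, t_hi = t_hi,
      carriers = list(carriers)
    )
  }
  for (s in samples) {
    add(paste0(s, ".1_tip"), 0L, coal[[s]], hap(s)[1])
    add(paste0(s, ".2_tip"), 0L, coal[[s]], hap(s)[2])
  }
  # ((dog1, dog2):1500, (dog3, dog4):1000):3000 with the outgroup at 20000.
  add(paste0(dogs[1], "_stem"), coal[[dogs[1]]], 1500L, hap(dogs[1]))
  add(paste0(dogs[2], "_stem"), coal[[dogs[2]]], 1500L, hap(dogs[2]))
  add(paste0(dogs[3], "_stem"), coal[[dogs[3]]], 1000L, hap(dogs[3]))
  add(paste0(dogs[4], "_stem"), coal[[dogs[4]]], 1000L, hap(dogs[4]))
  add("cladeA", 1500L, 3000L, c(hap(dogs[1]), hap(dogs[2])))
  add("cladeB", 1000L, 3000L, c(hap(dogs[3]), hap(dogs[4])))
  add("dog_stem", 3000L, 20000L, unlist(lapply(dogs, hap)))
  add(paste0(outgroup, "_stem"), coal[[outgroup]], 20000L, hap(outgroup))
  g <- bind_rows(b)
  g$length <- g$t_hi - g$t_lo
  g
}

# ---- sequence builders -----------------------------------------------------

sinec_parts <- function(lib) {
  list(head_len = 90L, ct_start = 90L, ct_copies = 12L, body_start = 114L,
       body_end = 171L, total = nchar(lib$sinec_consensus))
}

# A SINEC copy: optional 5' truncation, (CT)-run length change, extra A-tail,
# point substitutions. Returns the element body (no TSD).
build_sinec_body <- function(lib, trunc5 = 0L, ct_delta = 0L, tail_extra = 0L,
                             n_subs = 0L) {
  p <- sinec_parts(lib)
  cons <- lib$sinec_consensus
  head <- substr(cons, 1L, p$ct_start)
  ct <- strrep("CT", p$ct_copies + ct_delta)
  rest <- substr(cons, p$body_start + 1L, p$total)
  s <- paste0(head, ct, rest, strrep("A", tail_extra))
  if (trunc5 > 0L) s <- substr(s, trunc5 + 1L, nchar(s))
  if (n_subs > 0L) {
    chars <- strsplit(s, "")[[1]]
    idx <- sample(seq_len(p$ct_start - trunc5), n_subs)
    idx <- idx[idx >= 1]
    for (i in idx) chars[i] <- sample(setdiff(DNA_BASES, chars[i]), 1)
    s <- paste(chars, collapse = "")
  }
  s
}

# A LINE-1 copy: optional 5' truncation, 3' deletion (intra-element deletion
# variant), poly(A) tail, premature ORF2 stop, nested SINEC insertion into
# ORF2 (codon-aligned, with its own TSD), and a 3' transduced tag placed
# between the element and the tail.
build_line1_body <- function(lib, trunc5 = 0L, del3 = 0L, tail_len = 12L,
                             orf2_stop = FALSE, nested = NULL, tag = NULL) {
  s <- lib$line1_consensus
  total <- nchar(s)
  if (orf2_stop) {
    # Replace a codon in the middle of ORF2 with TAA.
    mid_codon <- lib$orf2_range[1] + 1800L
    off <- (mid_codon - lib$orf2_range[1]) %% 3L
    mid_codon <- mid_codon - off
    substr(s, mid_codon, mid_codon + 2L) <- "TAA"
  }
  if (!is.null(nested)) {
    # Insert a SINEC (stop-free in frame 0) at a codon boundary inside ORF2,
    # duplicating a codon-aligned target site within the LINE-1.
    ins_at <- nested$offset  # 1-based position in consensus, codon boundary
    tsd <- substr(s, ins_at, ins_at + nested$tsd_len - 1L)
    s <- paste0(substr(s, 1L, ins_at - 1L), nested$sinec_body, tsd,
                substr(s, ins_at, total))
  }
  if (del3 > 0L) s <- substr(s, 1L, nchar(s) - del3)
  if (trunc5 > 0L) s <- substr(s, trunc5 + 1L, nchar(s))
  paste0(s, if (!is.null(tag)) tag, strrep("A", tail_len))
}

# ---- placement registry ----------------------------------------------------

new_registry <- function(chroms) {
  env <- new.env(parent = emptyenv())
  env$occ <- lapply(chroms, function(x) matrix(numeric(0), ncol = 2))
  names(env$occ) <- names(chroms)
  env$len <- chroms
  env
}

reg_free <- function(reg, chrom, start, end) {
  occ <- reg$occ[[chrom]]
  if (nrow(occ) == 0) return(TRUE)
  !any(occ[, 1] < end & occ[, 2] > start)
}

reg_add <- function(reg, chrom, start, end) {
  reg$occ[[chrom]] <- rbind(reg$occ[[chrom]], c(start, end))
  invisible(NULL)
}

# Draw a free [start, start + width) interval; chromosome chosen with
# probability proportional to its length unless fixed.
reg_place <- function(reg, width, margin = 200, chrom = NULL, min_pos = 2000,
                      max_pos = Inf, max_tries = 2000) {
  for (i in seq_len(max_tries)) {
    ch <- chrom %||% sample(names(reg$len), 1, prob = reg$len)
    hi <- min(reg$len[[ch]] - width - margin - 2000, max_pos)
    if (hi <= min_pos) next
    s <- floor(runif(1, min_pos, hi))
    if (reg_free(reg, ch, s - margin, s + width + margin)) {
      reg_add(reg, ch, s - margin, s + width + margin)
      return(list(chrom = ch, start = s))
    }
  }
  abort("genome too small to place requested events without overlap")
}

# ---- main simulator --------------------------------------------------------

#' Simulate a canine-like cohort with known structural-variant truth
#'
#' Builds a random multi-chromosome reference carrying fixed repeats
#' (satellite arrays, SINECs and full-length LINE-1s) and segmental
#' duplications, then plants dimorphic insertion/deletion events on the
#' branches of a fixed five-sample genealogy. An event is carried by exactly
#' the haplotypes below its branch. Planted event classes cover SINECs (with
#' post-insertion allelic heterogeneity on sub-branches), LINE-1s (5'
#' truncation, disrupted ORF2 copies, intra-element 3' deletion variants),
#' LINE-1s with 3' transductions traced to reference-fixed or segregating
#' source elements, nested SINEC-in-LINE-1 alleles, STR and VNTR expansions,
#' LTR insertions, mixed/partial composites and deletions. Every insertion is
#' flanked by a target-site duplication drawn from `tsd_range`. Branch SNPs
#' are planted at rate `snp_mu` per bp per generation.
#'
#' @param library A [build_repeat_library()] object.
#' @param params A [cohort_params()] object.
#' @return An object of class `canisv_cohort`: a list with `reference` and
#'   `haplotypes` (named character vectors), `genealogy`, `events`, `snps`,
#'   `ref_annots`, `dup_pairs`, `library` and `params`.
#' @export
simulate_cohort <- function(library, params = cohort_params()) {
  stopifnot(inherits(library, "canisv_repeat_library"))
  p <- params
  if (p$sinec_rate < 0 || p$line1_rate < 0) abort("rates must be >= 0")
  if (p$n_chrom < 2) abort("need at least 2 chromosomes")
  withr::local_seed(as.integer(p$seed))

  chrom_names <- paste0("chr", seq_len(p$n_chrom))
  reference <- setNames(
    vapply(chrom_names, function(x) rand_dna(p$chrom_length), character(1)),
    chrom_names
  )
  chrom_len <- setNames(rep(as.numeric(p$chrom_length), p$n_chrom), chrom_names)
  genome_len <- sum(chrom_len)
  reg <- new_registry(chrom_len)
  ref_annots <- list()
  overwrite <- function(chrom, start, seq) {
    s <- reference[[chrom]]
    substr(s, start + 1L, start + nchar(seq)) <- seq
    reference[[chrom]] <<- s
  }

  # --- fixed reference features ---
  # Satellite arrays near chromosome starts (centromere-like).
  for (i in seq_len(p$n_ref_satellite)) {
    ch <- chrom_names[((i - 1L) %% p$n_chrom) + 1L]
    arr <- strrep(library$satellite_unit, 30L)
    st <- 3000L + (i %/% p$n_chrom) * 8000L
    reg_add(reg, ch, st - 200, st + nchar(arr) + 200)
    overwrite(ch, st, arr)
    ref_annots[[length(ref_annots) + 1L]] <- tibble(
      seq_id = ch, start = st, end = st + nchar(arr),
      repeat_name = "SAT_sim", repeat_class = "Satellite", strand = "+",
      element_id = NA_integer_, cons_start = 1L,
      cons_end = nchar(library$satellite_unit)
    )
  }
  ref_sinecs <- list()
  for (i in seq_len(p$n_ref_sinec)) {
    body <- build_sinec_body(library, tail_extra = sample(0:10, 1))
    loc <- reg_place(reg, nchar(body))
    overwrite(loc$chrom, loc$start, body)
    ref_annots[[length(ref_annots) + 1L]] <- tibble(
      seq_id = loc$chrom, start = loc$start, end = loc$start + nchar(body),
      repeat_name = "SINEC_sim", repeat_class = "SINE/tRNA-Lys", strand = "+",
      element_id = NA_integer_, cons_start = 1L, cons_end = 201L
    )
    ref_sinecs[[i]] <- loc
  }
  ref_l1s <- list()
  for (i in seq_len(p$n_ref_line1)) {
    body <- build_line1_body(library, tail_len = sample(8:16, 1))
    loc <- reg_place(reg, nchar(body) + 200L)
    overwrite(loc$chrom, loc$start, body)
    end <- loc$start + nchar(body)
    ref_annots[[length(ref_annots) + 1L]] <- tibble(
      seq_id = loc$chrom, start = loc$start, end = end,
      repeat_name = "L1_sim", repeat_class = "LINE/L1", strand = "+",
      element_id = NA_integer_, cons_start = 1L,
      cons_end = nchar(library$line1_consensus)
    )
    ref_l1s[[i]] <- list(chrom = loc$chrom, start = loc$start, end = end)
  }

  # --- segmental duplications (sequence copied with divergence) ---
  dup_rows <- list()
  if (p$n_dup_pairs > 0) {
    len_cap <- max(2000L, as.integer(p$chrom_length %/% 10L))
    specs <- tibble(
      len = pmin(rep_len(c(12000L, 15000L, 11000L, 800L, 12000L, 20000L),
                         p$n_dup_pairs), len_cap),
      div = rep_len(c(0.02, 0.04, 0.01, 0.03, 0.12, 0.03), p$n_dup_pairs),
      same_chrom = rep_len(c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE),
                           p$n_dup_pairs),
      tandem = rep_len(c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE),
                       p$n_dup_pairs)
    )
    for (i in seq_len(p$n_dup_pairs)) {
      sp <- specs[i, ]
      a <- reg_place(reg, sp$len, margin = 500)
      seqA <- substr(reference[[a$chrom]], a$start + 1L, a$start + sp$len)
      b_chrom <- if (sp$same_chrom) a$chrom else
        sample(setdiff(chrom_names, a$chrom), 1)
      b <- if (sp$tandem) {
        reg_place(reg, sp$len, margin = 500, chrom = b_chrom,
                  min_pos = max(2000, a$start - 150000),
                  max_pos = a$start + 150000)
      } else {
        reg_place(reg, sp$len, margin = 500, chrom = b_chrom)
      }
      n_mut <- round(sp$div * sp$len)
      chars <- strsplit(seqA, "")[[1]]
      if (n_mut > 0) {
        at <- sample.int(sp$len, n_mut)
        for (k in at) chars[k] <- sample(setdiff(DNA_BASES, chars[k]), 1)
      }
      overwrite(b$chrom, b$start, paste(chars, collapse = ""))
      dup_rows[[i]] <- tibble(
        chrA = a$chrom, startA = a$start, endA = a$start + sp$len,
        chrB = b$chrom, startB = b$start, endB = b$start + sp$len,
        length = sp$len, divergence = sp$div
      )
    }
  }
  dup_pairs <- bind_rows(dup_rows)

  genealogy <- default_genealogy(p$samples, p$outgroup)
  haps <- unlist(lapply(p$samples, function(s) paste0(s, ".", 1:2)))
  total_gen <- sum(genealogy$length)
  draw_branches <- function(n) {
    if (n == 0L) return(character(0))
    sample(genealogy$branch, n, replace = TRUE, prob = genealogy$length)
  }
  carriers_of <- function(branch) {
    genealogy$carriers[[match(branch, genealogy$branch)]]
  }

  # --- events ---
  events <- list()
  ev_n <- 0L
  tsd_draw <- function() sample(p$tsd_range[1]:p$tsd_range[2], 1)
  add_event <- function(type, branch, body_list, carrier_list, tsd_len,
                        chrom = NULL, ip = NULL, truth_category = NA_character_,
                        margin = 200, ...) {
    ev_n <<- ev_n + 1L
    if (is.null(ip)) {
      loc <- reg_place(reg, tsd_len + 2L, margin = margin, chrom = chrom)
      chrom <- loc$chrom
      ip <- loc$start + tsd_len  # insertion point; TSD is the ref just before
    }
    tsd_seq <- if (tsd_len > 0) {
      substr(reference[[chrom]], ip - tsd_len + 1L, ip)
    } else ""
    events[[ev_n]] <<- tibble(
      event_id = sprintf("ev%04d", ev_n),
      type = type, chrom = chrom, ip = as.integer(ip),
      tsd_len = as.integer(tsd_len), tsd_seq = tsd_seq,
      branch = branch,
      carriers = list(carriers_of(branch)),
      bodies = list(body_list),
      body_carriers = list(carrier_list),
      truth_category = truth_category,
      ...
    )
    invisible(ev_n)
  }

  # SINEC events (Poisson on total branch length; branch drawn by length).
  n_sinec <- rpois(1, p$sinec_rate * total_gen)
  sinec_branches <- draw_branches(n_sinec)
  for (b in sinec_branches) {
    trunc5 <- if (runif(1) < 0.1) sample(10:50, 1) else 0L
    tail_extra <- sample(0:10, 1)
    body <- build_sinec_body(library, trunc5 = trunc5, tail_extra = tail_extra)
    carr <- carriers_of(b)
    bodies <- list(body)
    body_carr <- list(carr)
    # Post-insertion heterogeneity: a sub-branch carries a mutated copy.
    if (runif(1) < p$het_fraction) {
      subs <- genealogy$branch[vapply(genealogy$carriers, function(cs) {
        length(cs) < length(carr) && all(cs %in% carr)
      }, logical(1))]
      if (length(subs) > 0) {
        sub_carr <- carriers_of(sample(subs, 1))
        v2 <- build_sinec_body(
          library, trunc5 = trunc5,
          ct_delta = sample(c(-2L, -1L, 1L, 2L), 1),
          tail_extra = max(0L, tail_extra + sample(c(-4L, 4L, 6L), 1))
        )
        bodies <- list(body, v2)
        body_carr <- list(setdiff(carr, sub_carr), sub_carr)
        if (length(body_carr[[1]]) == 0) {
          bodies <- list(v2)
          body_carr <- list(sub_carr)
        }
      }
    }
    add_event("SINEC", b, bodies, body_carr, tsd_draw(),
              truth_category = "SINEC", trunc5 = trunc5)
  }

  # LINE-1 events.
  n_l1 <- rpois(1, p$line1_rate * total_gen)
  l1_branches <- draw_branches(n_l1)
  l1_event_ids <- character(0)
  for (b in l1_branches) {
    full <- runif(1) < p$p_full_length
    trunc5 <- if (full) 0L else sample(1000:5000, 1)
    orf2_stop <- full && runif(1) < p$p_orf2_stop
    body <- build_line1_body(library, trunc5 = trunc5,
                             tail_len = sample(8:20, 1),
                             orf2_stop = orf2_stop)
    id <- add_event("LINE1", b, list(body), list(carriers_of(b)), tsd_draw(),
                    truth_category = "LINE/L1", trunc5 = trunc5,
                    orf2_disrupted = orf2_stop, l1_3del = FALSE,
                    in_ref_l1 = FALSE)
    l1_event_ids <- c(l1_event_ids, events[[id]]$event_id)
  }

  # Intra-LINE-1 3' deletion variants; most placed inside reference LINE-1s.
  if (p$n_l1_3del > 0) {
    for (i in seq_len(p$n_l1_3del)) {
      b <- draw_branches(1)
      del3 <- sample(400:1200, 1)
      body <- build_line1_body(library, del3 = del3, tail_len = 10L)
      in_ref <- i <= p$n_l1_3del_in_ref && i <= length(ref_l1s)
      if (in_ref) {
        rl <- ref_l1s[[i]]
        ip <- rl$start + 2000L + i * 97L
        add_event("LINE1", b, list(body), list(carriers_of(b)), 10L,
                  chrom = rl$chrom, ip = ip, truth_category = "LINE/L1",
                  trunc5 = 0L, orf2_disrupted = FALSE, l1_3del = TRUE,
                  l1_del3 = del3, in_ref_l1 = TRUE)
      } else {
        add_event("LINE1", b, list(body), list(carriers_of(b)), 10L,
                  truth_category = "LINE/L1", trunc5 = 0L,
                  orf2_disrupted = FALSE, l1_3del = TRUE, l1_del3 = del3,
                  in_ref_l1 = FALSE)
      }
    }
  }

  # Nested SINEC-in-LINE-1 alleles: three structural alleles at one locus
  # (empty site, full LINE-1, LINE-1 + SINEC in ORF2, reading frame kept).
  if (p$n_nested > 0) {
    deep <- genealogy$branch[vapply(genealogy$carriers, length, integer(1)) >= 4]
    for (i in seq_len(p$n_nested)) {
      b <- sample(deep, 1)
      carr <- carriers_of(b)
      subs <- genealogy$branch[vapply(genealogy$carriers, function(cs) {
        length(cs) < length(carr) && all(cs %in% carr)
      }, logical(1))]
      sub_carr <- carriers_of(sample(subs, 1))
      ins_off <- library$orf2_range[1] + 903L  # codon boundary inside ORF2
      stopifnot((ins_off - library$orf2_range[1]) %% 3L == 0L)
      nested_spec <- list(offset = ins_off,
                          sinec_body = library$sinec_consensus,
                          tsd_len = 12L)
      plain <- build_line1_body(library, tail_len = 12L)
      nested_body <- build_line1_body(library, tail_len = 12L,
                                      nested = nested_spec)
      add_event("nested", b, list(plain, nested_body),
                list(setdiff(carr, sub_carr), sub_carr), tsd_draw(),
                truth_category = "LINE/L1", trunc5 = 0L,
                orf2_disrupted = FALSE, l1_3del = FALSE, in_ref_l1 = FALSE,
                nested_offset = ins_off, nested_tsd = 12L)
    }
  }

  # 3' transductions: tags copied from sequence downstream of a source
  # element (reference-fixed LINE-1s and segregating dimorphic LINE-1s).
  if (p$n_transductions > 0) {
    # Segregating sources: full-length LINE-1 events on deep dog-side
    # branches (absent from the outgroup).
    og_haps <- paste0(p$outgroup, ".", 1:2)
    seg_pool <- Filter(function(i) {
      e <- events[[i]]
      e$type == "LINE1" && !e$l1_3del && e$trunc5 == 0L &&
        !e$orf2_disrupted && !any(og_haps %in% e$carriers[[1]]) &&
        length(e$carriers[[1]]) >= 2
    }, seq_along(events))
    if (length(seg_pool) < 2) {
      # Guarantee at least two eligible segregating sources.
      for (k in 1:2) {
        b <- if (k == 1) "dog_stem" else "cladeA"
        body <- build_line1_body(library, tail_len = 12L)
        id <- add_event("LINE1", b, list(body), list(carriers_of(b)),
                        tsd_draw(), truth_category = "LINE/L1", trunc5 = 0L,
                        orf2_disrupted = FALSE, l1_3del = FALSE,
                        in_ref_l1 = FALSE)
        seg_pool <- c(seg_pool, id)
      }
    }
    seg_sources <- sample(seg_pool, 2)
    n_seg <- max(2L, round(0.4 * p$n_transductions))
    src_kind <- c(rep("segregating", n_seg),
                  rep("reference", p$n_transductions - n_seg))
    # One reference source is shared by several offspring (a transduction
    # family with a common transduced sequence).
    family_ref <- 1L
    for (i in seq_len(p$n_transductions)) {
      kind <- src_kind[i]
      if (kind == "segregating") {
        src_i <- seg_sources[((i - 1L) %% 2L) + 1L]
        src <- events[[src_i]]
        src_chrom <- src$chrom
        src_pos <- src$ip
        tag_len <- sample(40:120, 1)
        tag <- substr(reference[[src_chrom]], src_pos + 1L, src_pos + tag_len)
        src_id <- src$event_id
        # Offspring must lie on a branch at or below the source's branch.
        src_carr <- src$carriers[[1]]
        ok <- genealogy$branch[vapply(genealogy$carriers, function(cs) {
          all(cs %in% src_carr)
        }, logical(1))]
        b <- sample(ok, 1)
      } else {
        ref_idx <- if (i %% 3L == 0L) family_ref else
          sample(seq_along(ref_l1s), 1)
        rl <- ref_l1s[[ref_idx]]
        src_chrom <- rl$chrom
        src_pos <- rl$end
        tag_len <- sample(40:120, 1)
        tag <- substr(reference[[src_chrom]], src_pos + 1L, src_pos + tag_len)
        src_id <- paste0("refL1_", ref_idx)
        b <- draw_branches(1)
      }
      body <- build_line1_body(library, tail_len = sample(8:16, 1), tag = tag)
      # Keep the insertion > 7 kb from the source site.
      repeat {
        loc <- reg_place(reg, 22L + 2L)
        if (loc$chrom != src_chrom ||
            abs(loc$start - src_pos) > 9000) break
      }
      tsd_len <- tsd_draw()
      add_event("LINE1_TD", b, list(body), list(carriers_of(b)), tsd_len,
                chrom = loc$chrom, ip = loc$start + tsd_len,
                truth_category = "LINE/L1", trunc5 = 0L,
                orf2_disrupted = FALSE, l1_3del = FALSE, in_ref_l1 = FALSE,
                td_source = src_id, td_source_kind = kind,
                td_source_chrom = src_chrom, td_source_pos = src_pos,
                td_tag = tag)
    }
  }

  # STR / VNTR expansions (no target-site duplication).
  for (i in seq_len(p$n_str)) {
    ul <- sample(1:6, 1)
    repeat {
      unit <- rand_dna(ul)
      if (!is_periodic_unit(unit)) break
    }
    copies <- sample(ceiling(70 / ul):floor(280 / ul), 1)
    add_event("STR", draw_branches(1), list(strrep(unit, copies)),
              list(NULL), 0L, truth_category = "STR", unit = unit)
  }
  for (i in seq_len(p$n_vntr)) {
    ul <- sample(7:13, 1)
    repeat {
      unit <- rand_dna(ul)
      if (!is_periodic_unit(unit)) break
    }
    copies <- sample(ceiling(130 / ul):floor(550 / ul), 1)
    add_event("VNTR", draw_branches(1), list(strrep(unit, copies)),
              list(NULL), 0L, truth_category = "VNTR", unit = unit)
  }
  for (b in draw_branches(p$n_ltr)) {
    add_event("LTR", b, list(library$ltr_unit), list(NULL), 5L,
              truth_category = "LTR/ERV")
  }
  # Composite alleles: mixed (element + simple repeat + unique, union >= 70%
  # but no single class >= 70%), partial (5-70% annotated), unclassified.
  # Mixed: two element fragments, each < 70% of the allele, union >= 70%.
  for (b in draw_branches(p$n_mixed)) {
    body <- paste0(substr(library$sinec_consensus, 1, 150),
                   substr(library$ltr_unit, 1, 90), rand_dna(60L))
    add_event("mixed", b, list(body), list(NULL), 0L,
              truth_category = "Mixed")
  }
  for (b in draw_branches(p$n_partial)) {
    body <- paste0(substr(library$sinec_consensus, 1, 36), rand_dna(264L))
    add_event("partial", b, list(body), list(NULL), 0L,
              truth_category = "Partial")
  }
  for (b in draw_branches(p$n_unclassified)) {
    add_event("unclassified", b, list(rand_dna(sample(80:200, 1))),
              list(NULL), 0L, truth_category = "Unclassified")
  }
  # Deletions: a reference segment lost on one branch (length scaled to the
  # chromosome size so desk-scale genomes retain free placement room).
  del_max <- min(1500L, max(500L, as.integer(p$chrom_length %/% 100L)))
  for (b in draw_branches(p$n_deletion)) {
    dlen <- sample(400:del_max, 1)
    loc <- reg_place(reg, dlen + 10L, margin = 300)
    ev_n <- add_event("deletion", b, list(NULL), list(NULL), 0L,
                      chrom = loc$chrom, ip = loc$start + 1L,
                      truth_category = NA_character_, del_len = dlen)
  }

  events <- bind_rows(events)
  # Default carrier assignment: events with body_carriers == list(NULL)
  # assign all carriers to the single body.
  events$body_carriers <- lapply(seq_len(nrow(events)), function(i) {
    bc <- events$body_carriers[[i]]
    if (length(bc) == 1 && is.null(bc[[1]])) list(events$carriers[[i]])
    else bc
  })

  # --- SNPs ---
  excl <- lapply(chrom_names, function(ch) {
    ev <- events[events$chrom == ch, ]
    ins <- ev[ev$type != "deletion", ]
    del <- ev[ev$type == "deletion", ]
    rbind(
      if (nrow(ins)) cbind(ins$ip - ins$tsd_len - 2, ins$ip + 2),
      if (nrow(del)) cbind(del$ip - 2, del$ip + del$del_len + 2)
    )
  })
  names(excl) <- chrom_names
  snp_excluded <- function(ch, pos) {
    m <- excl[[ch]]
    !is.null(m) && nrow(m) > 0 && any(m[, 1] <= pos & m[, 2] > pos)
  }
  snp_rows <- list()
  used_pos <- new.env(parent = emptyenv())
  for (bi in seq_len(nrow(genealogy))) {
    br <- genealogy$branch[bi]
    n <- rpois(1, p$snp_mu * genealogy$length[bi] * genome_len)
    k <- 0L
    while (k < n) {
      ch <- sample(chrom_names, 1, prob = chrom_len)
      pos <- sample.int(chrom_len[[ch]] - 2L, 1)  # 0-based
      key <- paste0(ch, ":", pos)
      if (snp_excluded(ch, pos) || !is.null(used_pos[[key]])) next
      used_pos[[key]] <- TRUE
      ref_base <- substr(reference[[ch]], pos + 1L, pos + 1L)
      alt_base <- sample(setdiff(DNA_BASES, ref_base), 1)
      snp_rows[[length(snp_rows) + 1L]] <- tibble(
        chrom = ch, pos = as.integer(pos), ref = ref_base, alt = alt_base,
        branch = br
      )
      k <- k + 1L
    }
  }
  snps <- bind_rows(snp_rows)
  if (nrow(snps) == 0) {
    snps <- tibble(chrom = character(0), pos = integer(0), ref = character(0),
                   alt = character(0), branch = character(0))
  }

  # --- build haplotype sequences ---
  snps$carriers <- lapply(snps$branch, carriers_of)
  haplotypes <- setNames(vector("list", length(haps)), haps)
  for (h in haps) {
    parts <- character(0)
    for (ch in chrom_names) {
      chars <- strsplit(reference[[ch]], "")[[1]]
      sn <- snps[snps$chrom == ch &
                   vapply(snps$carriers, function(cs) h %in% cs, logical(1)), ]
      if (nrow(sn)) chars[sn$pos + 1L] <- sn$alt
      ev <- events[events$chrom == ch, ]
      mods <- list()
      for (i in seq_len(nrow(ev))) {
        if (ev$type[i] == "deletion") {
          if (h %in% ev$carriers[[i]]) {
            mods[[length(mods) + 1L]] <-
              list(kind = "del", at = ev$ip[i], len = ev$del_len[i])
          }
        } else {
          bc <- ev$body_carriers[[i]]
          for (k in seq_along(bc)) {
            if (h %in% bc[[k]]) {
              ins <- paste0(ev$bodies[[i]][[k]], ev$tsd_seq[i])
              mods[[length(mods) + 1L]] <-
                list(kind = "ins", at = ev$ip[i], seq = ins)
              break
            }
          }
        }
      }
      haplotypes[[h]] <- c(haplotypes[[h]],
                           setNames(apply_mods(chars, mods), ch))
    }
  }
  haplotypes <- lapply(haplotypes, function(x) x)

  structure(list(
    reference = reference,
    haplotypes = haplotypes,
    genealogy = genealogy,
    events = events,
    snps = snps[, c("chrom", "pos", "ref", "alt", "branch")],
    ref_annots = new_annotation_set(bind_rows(ref_annots)),
    dup_pairs = dup_pairs,
    library = library,
    params = p
  ), class = "canisv_cohort")
}

# Apply insertion/deletion modifications (0-based insertion points /
# deletion starts) to a character vector; returns the modified string.
apply_mods <- function(chars, mods) {
  if (length(mods) == 0) return(paste(chars, collapse = ""))
  at <- vapply(mods, `[[`, numeric(1), "at")
  o <- order(at)
  mods <- mods[o]
  at <- at[o]
  n <- length(chars)
  pieces <- character(0)
  cur <- 1L
  for (m in mods) {
    if (m$kind == "ins") {
      # insert after reference position m$at (0-based gap index m$at)
      pieces <- c(pieces, paste(chars[cur:m$at], collapse = ""), m$seq)
      cur <- m$at + 1L
    } else {
      pieces <- c(pieces, paste(chars[cur:m$at], collapse = ""))
      cur <- m$at + m$len + 1L
    }
  }
  if (cur <= n) pieces <- c(pieces, paste(chars[cur:n], collapse = ""))
  paste(pieces, collapse = "")
}

#' @export
print.canisv_cohort <- function(x, ...) {
  cat("<canisv_cohort>", length(x$reference), "chromosomes,",
      length(x$haplotypes), "haplotypes\n")
  cat("  events: ")
  print(table(x$events$type))
  cat("  SNPs:", nrow(x$snps), "\n")
  invisible(x)
}
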