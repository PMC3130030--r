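# Redundant primer panel design on bisulfite-converted target DNA:
# segmentation, constrained candidate generation with penalty scoring,
# variant/CpG masking, in-silico PCR off-target screening, coverage-driven
# greedy selection and Tm-relaxation fallback.

#' Segment target regions into overlapping design windows
#'
#' Each region is cut into windows of every requested size, advancing by
#' `spacing` while the window still fits.
#'
#' @param targets Tibble with `chrom`, `start`, `end` (0-based half-open)
#'   and optional `name`.
#' @param sizes Integer vector of window sizes (bp).
#' @param spacing Step between window starts (bp).
#' @return Tibble of segments: `chrom`, `start`, `end`, `region`,
#'   `size_class`, `seg_start` (0-based offset within region).
#' @examples
#' segment_targets(tibble::tibble(chrom = "c", start = 0, end = 210), sizes = 200)
#' @export
segment_targets <- function(targets, sizes = c(200L, 300L, 400L),
                            spacing = 5L) {
  if (!"name" %in% names(targets)) {
    targets$name <- paste0("region", seq_len(nrow(targets)))
  }
  rows <- list()
  for (i in seq_len(nrow(targets))) {
    len <- targets$end[i] - targets$start[i]
    if (len < min(sizes)) {
      warn(sprintf("region '%s' (%d bp) shorter than every segment size",
                   targets$name[i], len))
    }
    for (sz in sizes) {
      if (len < sz) next
      starts <- seq.int(0L, len - sz, by = spacing)
      rows[[length(rows) + 1L]] <- tibble(
        chrom = targets$chrom[i],
        start = targets$start[i] + starts,
        end = targets$start[i] + starts + sz,
        region = targets$name[i],
        size_class = as.integer(sz),
        seg_start = as.integer(starts)
      )
    }
  }
  if (!length(rows)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  region = character(), size_class = integer(),
                  seg_start = integer()))
  }
  bind_rows(rows)
}

# Resolve user constraint overrides against package defaults.
design_constraints <- function(...) {
  cons <- hepityper_defaults()
  ov <- list(...)
  if (length(ov) == 1L && is.list(ov[[1]]) && is.null(names(ov))) ov <- ov[[1]]
  for (nm in names(ov)) cons[[nm]] <- ov[[nm]]
  cons
}

#' Enumerate constrained primer-pair candidates for design segments
#'
#' Works on the converted design-strand sequence of each region (forward
#' strand: plus-strand conversion; reverse strand: converted minus strand
#' read 5'->3'). All primer placements satisfying the hard constraints
#' (length, Tm window, delta-Tm, GC bounds, product size within segment
#' size +/- slack) are enumerated; each pair is scored with the penalty
#' `|Tm_l - target| + |Tm_r - target| + 0.5(|len_l - opt| + |len_r - opt|)
#' + |Tm_l - Tm_r|` and the `candidates_per_segment` lowest-penalty pairs
#' per segment are kept.
#'
#' @param converted_refs Output of [convert_reference()] for the regions.
#' @param segments Output of [segment_targets()].
#' @param constraints Optional named list of overrides for
#'   `hepityper_defaults()` entries.
#' @param tm_window Half-width of the Tm acceptance window, degrees C.
#' @return Tibble of candidate pairs with sequences, Tm/GC, penalty, and
#'   genome-forward product/footprint coordinates.
#' @export
generate_candidates <- function(converted_refs, segments,
                                constraints = list(),
                                tm_window = NULL) {
  cons <- design_constraints(constraints)
  if (is.null(tm_window)) tm_window <- cons$tm_window_standard
  out <- list()
  for (r in seq_len(nrow(converted_refs))) {
    ref <- converted_refs[r, ]
    segs <- segments[segments$region == ref$name, , drop = FALSE]
    if (!nrow(segs)) next
    if (ref$has_n) next   # N-containing regions are excluded from design
    L <- nchar(ref$converted_seq)
    # design-strand 5'->3' sequence
    dseq <- if (ref$strand == "forward") ref$converted_seq
            else revcomp(ref$converted_seq)
    cands <- .candidates_for_region(dseq, segs, ref, cons, tm_window, L)
    if (!is.null(cands)) out[[length(out) + 1L]] <- cands
  }
  if (!length(out)) return(.empty_candidates())
  bind_rows(out)
}

.empty_candidates <- function() {
  tibble(region = character(), chrom = character(), strand = character(),
         size_class = integer(), seg_start = integer(),
         left_seq = character(), right_seq = character(),
         left_tm = numeric(), right_tm = numeric(),
         left_gc = numeric(), right_gc = numeric(),
         left_len = integer(), right_len = integer(),
         penalty = numeric(), product_start = integer(),
         product_end = integer(), product_len = integer(),
         fp1_start = integer(), fp1_end = integer(),
         fp2_start = integer(), fp2_end = integer())
}

# Enumerate candidates for one region (all its segments at once so the
# Tm of recurring windows is computed a single time).
.candidates_for_region <- function(dseq, segs, ref, cons, tm_window, L) {
  slack <- cons$amplicon_size_slack
  lens <- cons$primer_len_min:cons$primer_len_max
  # design-strand segment coordinates: forward strand keeps region offsets,
  # reverse strand mirrors them.
  seg_d <- segs
  if (ref$strand == "reverse") {
    seg_d$seg_start <- L - (segs$seg_start + segs$size_class)
  }
  oligos <- new.env(parent = emptyenv())
  get_oligo <- function(starts, lens_) {  # cache Tm/GC by (start,len)
    key <- paste0(starts, "_", lens_)
    miss <- !vapply(key, exists, logical(1), envir = oligos)
    if (any(miss)) {
      sq <- substr(rep(dseq, sum(miss)), starts[miss] + 1L,
                   starts[miss] + lens_[miss])
      tm <- suppressWarnings(melting_temperature(sq))
      gc <- gc_percent(sq)
      for (j in seq_along(sq)) {
        assign(key[miss][j], list(seq = sq[j], tm = tm[j], gc = gc[j]),
               envir = oligos)
      }
    }
    lapply(key, get, envir = oligos)
  }

  res <- list()
  for (i in seq_len(nrow(seg_d))) {
    sz <- seg_d$size_class[i]; s0 <- seg_d$seg_start[i]
    if (s0 < 0L || s0 + sz > L) next
    # left primers: start in [s0, s0+slack]
    lgrid <- expand.grid(a = s0 + 0:slack, la = lens)
    lgrid <- lgrid[lgrid$a + lgrid$la <= L, , drop = FALSE]
    linfo <- get_oligo(lgrid$a, lgrid$la)
    ltm <- vapply(linfo, `[[`, numeric(1), "tm")
    lgc <- vapply(linfo, `[[`, numeric(1), "gc")
    lok <- abs(ltm - cons$tm_target) <= tm_window &
           lgc >= cons$gc_min & lgc <= cons$gc_max
    if (!any(lok)) next
    # right primers: product end b in [s0+sz-slack, s0+sz]
    rgrid <- expand.grid(b = s0 + sz - slack:0, lb = lens)
    rgrid <- rgrid[rgrid$b - rgrid$lb >= 0L & rgrid$b <= L, , drop = FALSE]
    rseq_fwd <- get_oligo(rgrid$b - rgrid$lb, rgrid$lb)
    # right primer is the reverse complement of the design-strand window;
    # Tm is orientation-invariant, GC likewise.
    rtm <- vapply(rseq_fwd, `[[`, numeric(1), "tm")
    rgc <- vapply(rseq_fwd, `[[`, numeric(1), "gc")
    rok <- abs(rtm - cons$tm_target) <= tm_window &
           rgc >= cons$gc_min & rgc <= cons$gc_max
    if (!any(rok)) next
    li <- which(lok); ri <- which(rok)
    pr <- expand.grid(l = li, r = ri)
    plen <- rgrid$b[pr$r] - lgrid$a[pr$l]
    keep <- plen >= sz - slack & plen <= sz + slack &
            plen >= lgrid$la[pr$l] + rgrid$lb[pr$r] &
            abs(ltm[pr$l] - rtm[pr$r]) <= cons$tm_max_diff
    if (!any(keep)) next
    pr <- pr[keep, , drop = FALSE]; plen <- plen[keep]
    pen <- abs(ltm[pr$l] - cons$tm_target) + abs(rtm[pr$r] - cons$tm_target) +
      0.5 * (abs(lgrid$la[pr$l] - cons$primer_len_opt) +
             abs(rgrid$lb[pr$r] - cons$primer_len_opt)) +
      abs(ltm[pr$l] - rtm[pr$r])
    ord <- order(pen)[seq_len(min(cons$candidates_per_segment, length(pen)))]
    pr <- pr[ord, , drop = FALSE]; plen <- plen[ord]; pen <- pen[ord]
    a <- lgrid$a[pr$l]; la <- lgrid$la[pr$l]
    b <- rgrid$b[pr$r]; lb <- rgrid$lb[pr$r]
    lseq <- vapply(linfo[pr$l], `[[`, character(1), "seq")
    rseq <- revcomp(vapply(rseq_fwd[pr$r], `[[`, character(1), "seq"))
    # map design-strand [a, b) back to genome forward coordinates
    if (ref$strand == "forward") {
      gs <- ref$start + a; ge <- ref$start + b
      f1s <- gs; f1e <- gs + la; f2s <- ge - lb; f2e <- ge
    } else {
      gs <- ref$start + L - b; ge <- ref$start + L - a
      f1s <- gs; f1e <- gs + lb; f2s <- ge - la; f2e <- ge
    }
    res[[length(res) + 1L]] <- tibble(
      region = ref$name, chrom = ref$chrom, strand = ref$strand,
      size_class = sz, seg_start = segs$seg_start[i],
      left_seq = lseq, right_seq = rseq,
      left_tm = ltm[pr$l], right_tm = rtm[pr$r],
      left_gc = lgc[pr$l], right_gc = rgc[pr$r],
      left_len = as.integer(la), right_len = as.integer(lb),
      penalty = pen,
      product_start = as.integer(gs), product_end = as.integer(ge),
      product_len = as.integer(plen),
      fp1_start = as.integer(f1s), fp1_end = as.integer(f1e),
      fp2_start = as.integer(f2s), fp2_end = as.integer(f2e)
    )
  }
  if (!length(res)) return(NULL)
  bind_rows(res)
}

#' Remove candidate pairs whose primers cover common variants or CpG sites
#'
#' A pair is dropped when either primer footprint overlaps a variant with
#' minor allele frequency above `maf_threshold`, or covers the
#' methylation-readable base of a CpG site on its design strand (the C for
#' forward-strand designs, the G for reverse-strand designs) -- such primer
#' bases would have methylation-dependent sequence.
#'
#' @param candidates Candidate tibble from [generate_candidates()].
#' @param variants Optional tibble `chrom`, `pos` (0-based), `maf`.
#' @param cpg_registry Tibble from [build_cpg_registry()].
#' @param maf_threshold Variants at or below this MAF are tolerated.
#' @return Filtered candidate tibble.
#' @export
mask_variant_and_cpg <- function(candidates, variants = NULL,
                                 cpg_registry = NULL,
                                 maf_threshold = hepityper_defaults()$maf_threshold) {
  if (!nrow(candidates)) return(candidates)
  bad <- rep(FALSE, nrow(candidates))
  overlaps <- function(chrom, s1, e1, pos) {
    # any point in pos within [s1, e1) on the same chrom
    vapply(seq_along(s1), function(i) {
      any(pos$chrom == chrom[i] & pos$p >= s1[i] & pos$p < e1[i])
    }, logical(1))
  }
  if (!is.null(variants) && nrow(variants)) {
    vv <- variants[variants$maf > maf_threshold, , drop = FALSE]
    if (nrow(vv)) {
      pts <- tibble(chrom = vv$chrom, p = vv$pos)
      bad <- bad |
        overlaps(candidates$chrom, candidates$fp1_start, candidates$fp1_end, pts) |
        overlaps(candidates$chrom, candidates$fp2_start, candidates$fp2_end, pts)
    }
  }
  if (!is.null(cpg_registry) && nrow(cpg_registry)) {
    for (st in unique(candidates$strand)) {
      idx <- candidates$strand == st
      p <- if (st == "forward") cpg_registry$pos else cpg_registry$pos + 1L
      pts <- tibble(chrom = cpg_registry$chrom, p = p)
      bad[idx] <- bad[idx] |
        overlaps(candidates$chrom[idx], candidates$fp1_start[idx],
                 candidates$fp1_end[idx], pts) |
        overlaps(candidates$chrom[idx], candidates$fp2_start[idx],
                 candidates$fp2_end[idx], pts)
    }
  }
  candidates[!bad, , drop = FALSE]
}

# Binding sites of one primer on one template string.
# Semantics: exact match of the `word` 3'-terminal bases plus at most
# `max_mm` mismatches over the full primer length (no indels).
# Returns tibble(start, end, role) with 0-based half-open coords;
# role "fwd" = primer as given matches template, "rev" = its reverse
# complement matches (primer priming leftward).
primer_binding_sites <- function(primer, template, word = 15L, max_mm = 2L) {
  n <- nchar(template); L <- nchar(primer)
  hits <- list()
  count_mm <- function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  # forward role: 3' end is the right end of the primer
  w <- substr(primer, L - word + 1L, L)
  m <- Biostrings::matchPattern(w, Biostrings::DNAString(template))
  for (st in BiocGenerics::start(m)) {
    s0 <- st - 1L - (L - word)          # 0-based primer start
    if (s0 < 0L || s0 + L > n) next
    if (count_mm(substr(template, s0 + 1L, s0 + L), primer) <= max_mm) {
      hits[[length(hits) + 1L]] <- tibble(start = s0, end = s0 + L, role = "fwd")
    }
  }
  # reverse role: revcomp(primer) on the template, 3'-terminal bases are
  # the first `word` bases of the reverse complement
  rc <- revcomp(primer)
  w <- substr(rc, 1L, word)
  m <- Biostrings::matchPattern(w, Biostrings::DNAString(template))
  for (st in BiocGenerics::start(m)) {
    s0 <- st - 1L
    if (s0 + L > n) next
    if (count_mm(substr(template, s0 + 1L, s0 + L), rc) <= max_mm) {
      hits[[length(hits) + 1L]] <- tibble(start = s0, end = s0 + L, role = "rev")
    }
  }
  if (!length(hits)) return(tibble(start = integer(), end = integer(),
                                   role = character()))
  bind_rows(hits)
}

#' Screen candidate pairs for off-target products by in-silico PCR
#'
#' Both conversion strands of the whole supplied genome form the screening
#' background. A primer binds where its 3'-terminal `epcr_word` bases match
#' exactly and at most `epcr_max_mismatch` mismatches occur over its full
#' length; any convergent placement of the pair's primers (in either role)
#' producing a product of at most `max_product` bp anywhere other than the
#' intended target removes the pair.
#'
#' @param candidates Candidate tibble.
#' @param genome Named contig vector; converted internally on both strands.
#' @param max_product Maximum off-target product size screened (bp).
#' @param constraints Optional overrides (`epcr_word`, `epcr_max_mismatch`).
#' @return Filtered candidate tibble; attribute `"offtargets"` holds the
#'   off-target product table of the removed pairs.
#' @export
epcr_screen <- function(candidates, genome,
                        max_product = hepityper_defaults()$epcr_max_product,
                        constraints = list()) {
  if (is.null(genome)) abort("e-PCR screening background genome is missing")
  cons <- design_constraints(constraints)
  if (!nrow(candidates)) return(candidates)
  bg <- convert_genome_background(genome)
  templates <- c(setNames(bg$forward, paste0(names(bg$forward), "|forward")),
                 setNames(bg$reverse, paste0(names(bg$reverse), "|reverse")))
  primers <- unique(c(candidates$left_seq, candidates$right_seq))
  # site cache: primer -> template -> sites
  sites <- lapply(primers, function(p) {
    lapply(templates, primer_binding_sites, primer = p,
           word = cons$epcr_word, max_mm = cons$epcr_max_mismatch)
  })
  names(sites) <- primers

  offt <- list()
  bad <- rep(FALSE, nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    ca <- candidates[i, ]
    intended <- paste0(ca$chrom, "|", ca$strand)
    for (tn in names(templates)) {
      s1 <- sites[[ca$left_seq]][[tn]]
      s2 <- sites[[ca$right_seq]][[tn]]
      fw <- bind_rows(s1[s1$role == "fwd", ], s2[s2$role == "fwd", ])
      rv <- bind_rows(s1[s1$role == "rev", ], s2[s2$role == "rev", ])
      if (!nrow(fw) || !nrow(rv)) next
      for (f in seq_len(nrow(fw))) {
        plen <- rv$end - fw$start[f]
        ok <- plen > 0 & plen <= max_product & rv$start >= fw$start[f]
        if (!any(ok)) next
        for (j in which(ok)) {
          if (tn == intended && fw$start[f] == ca$product_start &&
              rv$end[j] == ca$product_end) next   # the intended product
          bad[i] <- TRUE
          offt[[length(offt) + 1L]] <- tibble(
            pair = i, template = tn, start = fw$start[f], end = rv$end[j])
        }
      }
    }
  }
  out <- candidates[!bad, , drop = FALSE]
  attr(out, "offtargets") <- if (length(offt)) bind_rows(offt) else
    tibble(pair = integer(), template = character(),
           start = integer(), end = integer())
  out
}

#' Greedy coverage-driven panel selection
#'
#' Per design size class, deduplicated candidates are walked in order of
#' increasing primer GC content (mean of the two primers; ties broken
#' lexicographically by primer sequence) and a pair is selected whenever
#' any base of its product still sits below that class's fold target.
#'
#' @param candidates Screened candidate tibble.
#' @param targets Target regions tibble.
#' @param fold_targets Named integer vector, fold target per size class.
#' @param design_mode Label recorded for selected pairs.
#' @param base_coverage Optional list of per-region coverage vectors to
#'   build upon (used by the relaxation pass).
#' @return A `panel_design` object: tibble of selected pairs with
#'   attributes `coverage` (per-region per-class matrix list),
#'   `uncovered` (intervals of zero total coverage) and `targets`.
#' @export
select_by_coverage <- function(candidates, targets,
                               fold_targets = hepityper_defaults()$fold_targets,
                               design_mode = "standard",
                               base_coverage = NULL) {
  if (!"name" %in% names(targets)) {
    targets$name <- paste0("region", seq_len(nrow(targets)))
  }
  base_classes <- if (is.null(base_coverage)) character(0) else
    unique(unlist(lapply(base_coverage, rownames)))
  classes <- sort(unique(c(candidates$size_class, as.integer(base_classes))))
  # per-region, per-class coverage vectors
  cov <- lapply(seq_len(nrow(targets)), function(i) {
    len <- targets$end[i] - targets$start[i]
    matrix(0L, nrow = length(classes), ncol = len,
           dimnames = list(as.character(classes), NULL))
  })
  names(cov) <- targets$name
  if (!is.null(base_coverage)) {
    for (nm in names(base_coverage)) {
      shared <- intersect(rownames(base_coverage[[nm]]), rownames(cov[[nm]]))
      cov[[nm]][shared, ] <- base_coverage[[nm]][shared, ]
    }
  }
  picked <- integer(0)
  if (nrow(candidates)) {
    cand <- distinct(candidates, .data$left_seq, .data$right_seq,
                     .keep_all = TRUE)
    cand$gc_pair <- (cand$left_gc + cand$right_gc) / 2
    for (cl in classes) {
      sub <- cand[cand$size_class == cl, , drop = FALSE]
      sub <- arrange(sub, .data$gc_pair, .data$left_seq, .data$right_seq)
      fold <- fold_targets[[as.character(cl)]]
      if (is.null(fold)) fold <- 1L
      for (k in seq_len(nrow(sub))) {
        reg <- sub$region[k]
        r0 <- targets$start[targets$name == reg]
        idx <- (sub$product_start[k] - r0 + 1L):(sub$product_end[k] - r0)
        idx <- idx[idx >= 1L & idx <= ncol(cov[[reg]])]
        if (!length(idx)) next
        if (any(cov[[reg]][as.character(cl), idx] < fold)) {
          cov[[reg]][as.character(cl), idx] <-
            cov[[reg]][as.character(cl), idx] + 1L
          picked <- c(picked, which(candidates$left_seq == sub$left_seq[k] &
                                    candidates$right_seq == sub$right_seq[k])[1])
        }
      }
    }
  }
  sel <- candidates[picked, , drop = FALSE]
  sel$design_mode <- if (nrow(sel)) design_mode else character(0)
  new_panel_design(sel, cov, targets)
}

new_panel_design <- function(pairs, coverage, targets) {
  pairs <- as_tibble(pairs)
  if (nrow(pairs)) {
    pairs$amplicon_id <- sprintf("amp%03d", seq_len(nrow(pairs)))
  } else {
    pairs$amplicon_id <- character(0)
  }
  structure(pairs,
            coverage = coverage,
            uncovered = uncovered_intervals(coverage, targets),
            targets = targets,
            class = c("panel_design", class(pairs)))
}

# intervals of zero total (all-class) coverage, genome coordinates
uncovered_intervals <- function(coverage, targets) {
  rows <- list()
  for (nm in names(coverage)) {
    tot <- colSums(coverage[[nm]])
    r <- rle(tot == 0)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    zi <- which(r$values)
    r0 <- targets$start[targets$name == nm]
    for (z in zi) {
      rows[[length(rows) + 1L]] <- tibble(
        chrom = targets$chrom[targets$name == nm],
        start = r0 + starts[z] - 1L, end = r0 + ends[z], region = nm)
    }
  }
  if (!length(rows)) return(tibble(chrom = character(), start = integer(),
                                   end = integer(), region = character()))
  bind_rows(rows)
}

#' Relaxed-Tm redesign of uncovered intervals
#'
#' Re-runs candidate generation, masking, off-target screening and greedy
#' selection with the Tm window widened (default 56 +/- 6) on candidates
#' whose product overlaps a currently uncovered base; selected pairs are
#' tagged `design_mode = "relaxed"`.
#'
#' @param panel A `panel_design` from the standard pass.
#' @param converted_refs,variants,cpg_registry,genome As in the standard
#'   pass ([generate_candidates()], [mask_variant_and_cpg()],
#'   [epcr_screen()]).
#' @param constraints Optional constraint overrides.
#' @return Updated `panel_design` combining both passes.
#' @export
relaxed_redesign <- function(panel, converted_refs, variants = NULL,
                             cpg_registry = NULL, genome = NULL,
                             constraints = list()) {
  cons <- design_constraints(constraints)
  unc <- attr(panel, "uncovered")
  targets <- attr(panel, "targets")
  if (!nrow(unc)) return(panel)
  segs <- segment_targets(targets[targets$name %in% unique(unc$region), ,
                                  drop = FALSE],
                          sizes = cons$segment_sizes,
                          spacing = cons$segment_spacing)
  cand <- generate_candidates(converted_refs, segs, constraints = cons,
                              tm_window = cons$tm_window_relaxed)
  if (nrow(cand)) {
    hits_gap <- vapply(seq_len(nrow(cand)), function(i) {
      any(unc$chrom == cand$chrom[i] & unc$start < cand$product_end[i] &
          unc$end > cand$product_start[i])
    }, logical(1))
    cand <- cand[hits_gap, , drop = FALSE]
  }
  cand <- mask_variant_and_cpg(cand, variants, cpg_registry,
                               maf_threshold = cons$maf_threshold)
  if (!is.null(genome) && nrow(cand)) {
    cand <- epcr_screen(cand, genome, max_product = cons$epcr_max_product,
                        constraints = cons)
  }
  add <- select_by_coverage(cand, targets, fold_targets = cons$fold_targets,
                            design_mode = "relaxed",
                            base_coverage = attr(panel, "coverage"))
  combined <- bind_rows(as_tibble(panel)[setdiff(names(panel), "amplicon_id")],
                        as_tibble(add)[setdiff(names(add), "amplicon_id")])
  new_panel_design(combined, attr(add, "coverage"), targets)
}

#' Design a full redundant primer panel on converted targets
#'
#' End-to-end design: segmentation, candidate generation at Tm 56 +/- 2,
#' variant and CpG masking, off-target screening on both conversion strands
#' of the genome, greedy coverage selection (2-fold for 300 bp, 3-fold for
#' 200 and 400 bp segments by default), then a relaxation pass at
#' 56 +/- 6 over any remaining uncovered bases.
#'
#' @inheritParams convert_reference
#' @param variants Optional variant tibble (`chrom`, `pos`, `ref`, `alt`,
#'   `maf`).
#' @param genotypes Optional genotype tibble (for the CpG registry).
#' @param strands Design strands.
#' @param constraints Named list of overrides of `hepityper_defaults()`.
#' @param screen Logical; run the off-target screen (needs `genome`).
#' @return A `panel_design` object.
#' @export
design_panel <- function(genome, targets, variants = NULL, genotypes = NULL,
                         strands = "forward", constraints = list(),
                         screen = TRUE) {
  cons <- design_constraints(constraints)
  if (!"name" %in% names(targets)) {
    targets$name <- paste0("region", seq_len(nrow(targets)))
  }
  refs <- convert_reference(genome, targets, strands = strands)
  registry <- build_cpg_registry(genome, targets, variants, genotypes)
  segs <- segment_targets(targets, sizes = cons$segment_sizes,
                          spacing = cons$segment_spacing)
  cand <- generate_candidates(refs, segs, constraints = cons,
                              tm_window = cons$tm_window_standard)
  cand <- mask_variant_and_cpg(cand, variants, registry,
                               maf_threshold = cons$maf_threshold)
  if (screen && nrow(cand)) {
    cand <- epcr_screen(cand, genome, max_product = cons$epcr_max_product,
                        constraints = cons)
  }
  panel <- select_by_coverage(cand, targets, fold_targets = cons$fold_targets)
  panel <- relaxed_redesign(panel, refs, variants, registry,
                            genome = if (screen) genome else NULL,
                            constraints = cons)
  attr(panel, "cpg_registry") <- registry
  attr(panel, "refs") <- refs
  panel
}

#' Calculated product-size peak profile of a panel
#'
#' Histogram of predicted amplicon sizes assuming equimolar representation
#' of every designed product -- the expected electrophoretic peak profile of
#' a successful library.
#'
#' @param panel A `panel_design` (or tibble with `product_len`).
#' @param bin_width Histogram bin width, bp.
#' @return Tibble `bin_start`, `bin_end`, `count`; counts sum to the number
#'   of amplicons.
#' @export
calculated_peak_profile <- function(panel, bin_width = 10L) {
  if (!nrow(panel)) {
    return(tibble(bin_start = integer(), bin_end = integer(),
                  count = integer()))
  }
  b <- (panel$product_len %/% bin_width) * bin_width
  tb <- table(b)
  tibble(bin_start = as.integer(names(tb)),
         bin_end = as.integer(names(tb)) + as.integer(bin_width),
         count = as.integer(tb))
}
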