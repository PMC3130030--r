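# Seeded simulator: synthetic reference with CpG-rich target islands,
# clonal methylation mixtures, bisulfite conversion with configurable
# efficiency, amplicon reads with substitution / homopolymer errors, and
# ground-truth tables for every downstream assertion.

#' Clonal methylation population
#'
#' @param patterns Character vector of clone patterns over C (methylated) /
#'   T (unmethylated), one character per region CpG site.
#' @param fractions Mixing fractions (sum to 1).
#' @param loss_rate Per-read, per-site probability that a methylated (C)
#'   site is read unmethylated (maintenance failure on the methylated
#'   background).
#' @param gain_rate Per-read, per-site probability that an unmethylated (T)
#'   site is read methylated (de-novo/maintenance gain).
#' @return A `clone_population` list.
#' @export
clone_population <- function(patterns, fractions, loss_rate = 0,
                             gain_rate = 0) {
  stopifnot(length(patterns) == length(fractions),
            abs(sum(fractions) - 1) < 1e-8,
            loss_rate >= 0, loss_rate <= 1, gain_rate >= 0, gain_rate <= 1,
            length(unique(nchar(patterns))) == 1L)
  structure(list(patterns = toupper(patterns), fractions = fractions,
                 loss_rate = loss_rate, gain_rate = gain_rate,
                 n_sites = nchar(patterns[1])),
            class = "clone_population")
}

#' Simulation configuration
#'
#' @param seed RNG seed.
#' @param depth Reads per amplicon.
#' @param read_length_mean,read_length_sd Read-length distribution (bp);
#'   reads are clipped to the amplicon.
#' @param conversion_efficiency Probability an unmethylated C converts.
#' @param substitution_error Per-base substitution rate.
#' @param homopolymer_indel Per-homopolymer-run indel rate (off by
#'   default so exact-identity assertions hold).
#' @param clean_primer If `TRUE` sequencing errors are never placed inside
#'   primer footprints (so primer-matching tolerance is tested separately).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, depth = 100L, read_length_mean = 204,
                       read_length_sd = 30, conversion_efficiency = 0.99,
                       substitution_error = 0, homopolymer_indel = 0,
                       clean_primer = TRUE) {
  stopifnot(conversion_efficiency >= 0, conversion_efficiency <= 1,
            substitution_error >= 0, substitution_error <= 1,
            homopolymer_indel >= 0, homopolymer_indel <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a synthetic reference with CpG-rich target islands
#'
#' Each target region is a CpG island flanked by short CpG-free primer
#' pads; regions are embedded in a random background contig. Optionally a
#' decoy contig carrying a verbatim copy of part of a region is planted
#' (for off-target / ambiguity tests). Deterministic per seed.
#'
#' @param n_regions Number of target regions.
#' @param region_length Region length (bp), pads included.
#' @param n_cpg CpGs planted per region.
#' @param seed RNG seed.
#' @param pad Length of the CpG-free pads at both region ends.
#' @param decoy_regions Indices of regions whose central part is copied
#'   into a decoy contig.
#' @param island_probs Base sampling probabilities inside islands.
#' @return List: `genome` (named character), `targets` (tibble, 0-based
#'   half-open), `cpg_positions` (list per region, 0-based genome
#'   positions of planted + incidental CpGs).
#' @export
make_reference <- function(n_regions = 2L, region_length = 600L,
                           n_cpg = 20L, seed = 1L, pad = 30L,
                           decoy_regions = integer(0),
                           island_probs = c(A = 0.18, C = 0.25, G = 0.37,
                                            T = 0.20)) {
  stopifnot(n_regions >= 1L, region_length > 2L * pad + 2L)
  core_len <- region_length - 2L * pad
  if (n_cpg * 3L > core_len) abort("requested CpG density is infeasible")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  rand_seq <- function(n, probs) {
    paste(sample(names(probs), n, replace = TRUE, prob = probs),
          collapse = "")
  }
  # CpG-free pad: no C, and never starting with G after a core C
  rand_pad <- function(n) {
    paste(sample(c("A", "G", "T"), n, replace = TRUE,
                 prob = c(0.3, 0.4, 0.3)), collapse = "")
  }
  flank <- 200L
  contig <- rand_seq(flank, c(A = .3, C = .2, G = .2, T = .3))
  targets <- list(); cpgs <- list(); cores <- character(n_regions)
  for (i in seq_len(n_regions)) {
    core <- strsplit(rand_seq(core_len, island_probs), "")[[1]]
    # strip incidental CpGs, then plant exactly n_cpg at spaced positions
    repeat {
      cg <- which(core[-length(core)] == "C" & core[-1L] == "G")
      if (!length(cg)) break
      core[cg + 1L] <- sample(c("A", "T"), length(cg), replace = TRUE)
    }
    slots <- seq(3L, core_len - 3L, by = max(3L, core_len %/% (n_cpg + 1L)))
    slots <- sort(sample(slots, min(n_cpg, length(slots))))
    core[slots] <- "C"; core[slots + 1L] <- "G"
    # planting may have re-created no other CpGs than the slots
    lpad <- rand_pad(pad)
    rpad <- paste0("A", rand_pad(pad - 1L))   # never G first: no boundary CpG
    if (substr(lpad, pad, pad) == "G") {      # pad G + core C is fine (GC)
      lpad <- lpad
    }
    region <- paste0(lpad, paste(core, collapse = ""), rpad)
    start <- nchar(contig)
    contig <- paste0(contig, region,
                     rand_seq(flank, c(A = .3, C = .2, G = .2, T = .3)))
    targets[[i]] <- tibble(chrom = "chr_sim", start = start,
                           end = start + region_length,
                           name = sprintf("region%d", i))
    cpgs[[i]] <- start + find_cpg_offsets(region)
    cores[i] <- region
  }
  genome <- c(chr_sim = contig)
  if (length(decoy_regions)) {
    dec <- paste0(
      rand_seq(100L, c(A = .3, C = .2, G = .2, T = .3)),
      paste(vapply(decoy_regions, function(i) {
        r <- targets[[i]]
        substr(genome[["chr_sim"]], r$start + pad + 1L, r$end - pad)
      }, character(1)), collapse = rand_seq(80L, c(A = .3, C = .2, G = .2,
                                                   T = .3))),
      rand_seq(100L, c(A = .3, C = .2, G = .2, T = .3)))
    genome <- c(genome, chr_decoy = dec)
  }
  list(genome = genome, targets = bind_rows(targets), cpg_positions = cpgs)
}

#' Build a panel directly from known amplicon coordinates
#'
#' Constructs a `panel_design` without running the design engine: primers
#' are the converted design-strand sequence at the two product ends. Used
#' for user-supplied panels and for simulation fixtures where the amplicon
#' layout is part of the experimental design.
#'
#' @param genome Named contig vector.
#' @param targets Target tibble.
#' @param pairs Tibble with `region`, `strand`, `product_start`,
#'   `product_end` (genome 0-based half-open) and `left_len`, `right_len`
#'   primer lengths.
#' @param variants,genotypes Passed to [build_cpg_registry()].
#' @return A `panel_design` with attached references and CpG registry.
#' @export
panel_from_pairs <- function(genome, targets, pairs, variants = NULL,
                             genotypes = NULL) {
  genome <- as_genome(genome)
  if (!"name" %in% names(targets)) {
    targets$name <- paste0("region", seq_len(nrow(targets)))
  }
  refs <- convert_reference(genome, targets,
                            strands = unique(pairs$strand))
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    ref <- refs[refs$name == p$region & refs$strand == p$strand, ]
    if (!nrow(ref)) abort(sprintf("no reference for region '%s'", p$region))
    L <- ref$end - ref$start
    dseq <- if (p$strand == "forward") ref$converted_seq
            else revcomp(ref$converted_seq)
    a <- if (p$strand == "forward") p$product_start - ref$start
         else ref$end - p$product_end
    b <- if (p$strand == "forward") p$product_end - ref$start
         else ref$end - p$product_start
    lseq <- substr(dseq, a + 1L, a + p$left_len)
    rseq <- revcomp(substr(dseq, b - p$right_len + 1L, b))
    f1 <- if (p$strand == "forward") c(p$product_start, p$product_start + p$left_len)
          else c(p$product_start, p$product_start + p$right_len)
    f2 <- if (p$strand == "forward") c(p$product_end - p$right_len, p$product_end)
          else c(p$product_end - p$left_len, p$product_end)
    rows[[i]] <- tibble(
      region = p$region, chrom = ref$chrom, strand = p$strand,
      size_class = as.integer(p$product_end - p$product_start),
      seg_start = NA_integer_,
      left_seq = lseq, right_seq = rseq,
      left_tm = suppressWarnings(tryCatch(melting_temperature(lseq),
                                          error = function(e) NA_real_)),
      right_tm = suppressWarnings(tryCatch(melting_temperature(rseq),
                                           error = function(e) NA_real_)),
      left_gc = gc_percent(lseq), right_gc = gc_percent(rseq),
      left_len = as.integer(p$left_len), right_len = as.integer(p$right_len),
      penalty = NA_real_,
      product_start = as.integer(p$product_start),
      product_end = as.integer(p$product_end),
      product_len = as.integer(p$product_end - p$product_start),
      fp1_start = as.integer(f1[1]), fp1_end = as.integer(f1[2]),
      fp2_start = as.integer(f2[1]), fp2_end = as.integer(f2[2]),
      design_mode = "manual")
  }
  sel <- bind_rows(rows)
  cov <- lapply(seq_len(nrow(targets)), function(i) {
    len <- targets$end[i] - targets$start[i]
    cls <- as.character(sort(unique(sel$size_class)))
    m <- matrix(0L, length(cls), len, dimnames = list(cls, NULL))
    for (k in which(sel$region == targets$name[i])) {
      idx <- (sel$product_start[k] - targets$start[i] + 1L):
             (sel$product_end[k] - targets$start[i])
      m[as.character(sel$size_class[k]), idx] <-
        m[as.character(sel$size_class[k]), idx] + 1L
    }
    m
  })
  names(cov) <- targets$name
  panel <- new_panel_design(sel, cov, targets)
  attr(panel, "refs") <- refs
  attr(panel, "cpg_registry") <- build_cpg_registry(genome, targets,
                                                    variants, genotypes)
  panel
}

#' Draw per-read methylation patterns from a clone population
#'
#' The pattern-level core of [draw_reads()]: samples a clone per read by
#' mixing fraction and applies per-site maintenance noise (C to T at
#' `loss_rate`, T to C at `gain_rate`). Uses the current RNG stream.
#'
#' @param population A [clone_population()].
#' @param n_reads Number of reads to draw.
#' @return List: `clone` (integer vector of clone indices), `patterns`
#'   (character matrix, reads x sites, over C/T).
#' @export
draw_patterns <- function(population, n_reads) {
  k <- sample.int(length(population$fractions), n_reads, replace = TRUE,
                  prob = population$fractions)
  pat <- do.call(rbind, strsplit(population$patterns[k], "", fixed = TRUE))
  if (is.null(pat)) pat <- matrix(character(0), 0, population$n_sites)
  if (population$loss_rate > 0) {
    flip <- pat == "C" & matrix(runif(length(pat)) < population$loss_rate,
                                nrow(pat))
    pat[flip] <- "T"
  }
  if (population$gain_rate > 0) {
    flip <- pat == "T" & matrix(runif(length(pat)) < population$gain_rate,
                                nrow(pat))
    pat[flip] <- "C"
  }
  list(clone = k, patterns = pat)
}

#' Simulate amplicon sequencing reads from a clonal mixture
#'
#' Per amplicon of the panel and per read: a clone is drawn by mixing
#' fraction, per-site maintenance noise applied, the amplicon's original
#' sequence bisulfite-converted on the amplicon's design strand
#' (unmethylated C converts with probability `conversion_efficiency`;
#' methylated CpG cytosines are protected), substitution and optional
#' homopolymer-indel errors added, the read truncated to its drawn length
#' and emitted in a random orientation.
#'
#' @param population A [clone_population()]; its patterns index the CpG
#'   sites of each amplicon's region, in genomic order.
#' @param panel A `panel_design` (e.g. [panel_from_pairs()]).
#' @param config A [sim_config()].
#' @return Tibble `read_id`, `seq`; attribute `"truth"` holds per-read
#'   ground truth (`read_id`, `amplicon_id`, `region`, `clone`, `states`,
#'   `orientation`, `length`).
#' @export
draw_reads <- function(population, panel, config = sim_config()) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  refs <- attr(panel, "refs")
  registry <- attr(panel, "cpg_registry")
  reads <- list(); truth <- list()
  for (a in seq_len(nrow(panel))) {
    am <- panel[a, ]
    ref <- refs[refs$name == am$region & refs$strand == am$strand, ][1, ]
    reg_sites <- sort(registry$pos[registry$region == am$region])
    if (length(reg_sites) != population$n_sites) {
      abort(sprintf(
        "population has %d sites but region '%s' has %d CpGs",
        population$n_sites, am$region, length(reg_sites)))
    }
    orig <- substr(ref$original_seq, am$product_start - ref$start + 1L,
                   am$product_end - ref$start)
    dp <- draw_patterns(population, config$depth)
    for (r in seq_len(config$depth)) {
      seq_r <- .one_read(orig, am, reg_sites, dp$patterns[r, ], config)
      rid <- sprintf("%s_r%05d", am$amplicon_id, r)
      reads[[length(reads) + 1L]] <- tibble(read_id = rid, seq = seq_r$seq)
      truth[[length(truth) + 1L]] <- tibble(
        read_id = rid, amplicon_id = am$amplicon_id, region = am$region,
        clone = dp$clone[r], states = paste(dp$patterns[r, ], collapse = ""),
        orientation = seq_r$orientation, length = nchar(seq_r$seq))
    }
  }
  out <- bind_rows(reads)
  attr(out, "truth") <- bind_rows(truth)
  out
}

# Build one read from an amplicon: conversion, errors, truncation,
# orientation. `states` covers the region's CpG sites in genomic order.
.one_read <- function(orig, am, reg_sites, states, config) {
  ch <- strsplit(orig, "", fixed = TRUE)[[1]]
  loc_sites <- reg_sites - am$product_start        # amplicon-local C offsets
  inside <- loc_sites >= 0L & loc_sites < length(ch)
  meth <- rep(FALSE, length(ch))                   # per-base protection
  if (am$strand == "forward") {
    meth[loc_sites[inside] + 1L] <- states[inside] == "C"
    is_c <- ch == "C"
    conv <- is_c & !meth & (runif(length(ch)) < config$conversion_efficiency)
    ch[conv] <- "T"
  } else {
    gpos <- loc_sites + 1L                         # the CpG guanine
    inside_g <- gpos >= 0L & gpos < length(ch)
    meth[gpos[inside_g] + 1L] <- states[inside_g] == "C"
    is_g <- ch == "G"
    conv <- is_g & !meth & (runif(length(ch)) < config$conversion_efficiency)
    ch[conv] <- "A"
  }
  # substitution errors (outside primer footprints in clean-primer mode)
  if (config$substitution_error > 0) {
    errable <- rep(TRUE, length(ch))
    if (isTRUE(config$clean_primer)) {
      fp <- c(seq.int(am$fp1_start, am$fp1_end - 1L),
              seq.int(am$fp2_start, am$fp2_end - 1L)) - am$product_start + 1L
      errable[fp[fp >= 1L & fp <= length(ch)]] <- FALSE
    }
    hit <- which(errable & runif(length(ch)) < config$substitution_error)
    if (length(hit)) {
      ch[hit] <- vapply(ch[hit], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1L)
      }, character(1))
    }
  }
  # optional homopolymer indels
  if (config$homopolymer_indel > 0) {
    runs <- rle(ch)
    keep <- rep(TRUE, length(ch))
    insert_after <- integer(0)
    pos0 <- cumsum(c(0L, runs$lengths[-length(runs$lengths)]))
    for (k in which(runs$lengths >= 2L)) {
      if (runif(1) < config$homopolymer_indel) {
        if (runif(1) < 0.5) keep[pos0[k] + 1L] <- FALSE
        else insert_after <- c(insert_after, pos0[k] + 1L)
      }
    }
    if (any(!keep) || length(insert_after)) {
      new_ch <- character(0)
      for (i in seq_along(ch)) {
        if (keep[i]) new_ch <- c(new_ch, ch[i])
        if (i %in% insert_after) new_ch <- c(new_ch, ch[i])
      }
      ch <- new_ch
    }
  }
  mol <- paste(ch, collapse = "")
  # design-strand 5'->3' molecule; reverse-strand amplicons are stored in
  # forward coordinates, so their design-strand read is the revcomp
  if (am$strand == "reverse") mol <- revcomp(mol)
  # sequencing starts from either amplicon end (random orientation), then
  # the read is truncated at its own 3' end
  orientation <- if (runif(1) < 0.5) "+" else "-"
  if (orientation == "-") mol <- revcomp(mol)
  L <- round(rnorm(1, config$read_length_mean, config$read_length_sd))
  L <- max(50L, min(nchar(mol), as.integer(L)))
  mol <- substr(mol, 1L, L)
  list(seq = mol, orientation = orientation)
}

#' Named simulation scenario presets
#'
#' Three scenarios mirroring the archetypal hepitype architectures:
#' `"imprinted"` (50/50 fully methylated / fully unmethylated founder
#' alleles with asymmetric maintenance failure), `"demethylating"`
#' (all-methylated ancestor losing ground to the unmethylated clone across
#' two pseudo-timepoints), `"methylating"` (the mirror image).
#'
#' @param n_sites CpG sites per region pattern.
#' @return Named list; each element has `name`, `timepoints` (named list
#'   of [clone_population()]s) and `config` (a [sim_config()]).
#' @export
scenario_presets <- function(n_sites = 8L) {
  allC <- strrep("C", n_sites); allT <- strrep("T", n_sites)
  list(
    imprinted = list(
      name = "imprinted",
      timepoints = list(
        t1 = clone_population(c(allC, allT), c(0.5, 0.5),
                              loss_rate = 0.05, gain_rate = 0.005)),
      config = sim_config(depth = 500L)),
    demethylating = list(
      name = "demethylating",
      timepoints = list(
        t1 = clone_population(c(allC, allT), c(0.8, 0.2),
                              loss_rate = 0.01, gain_rate = 0.01),
        t2 = clone_population(c(allC, allT), c(0.3, 0.7),
                              loss_rate = 0.01, gain_rate = 0.01)),
      config = sim_config(depth = 500L)),
    methylating = list(
      name = "methylating",
      timepoints = list(
        t1 = clone_population(c(allT, allC), c(0.8, 0.2),
                              loss_rate = 0.01, gain_rate = 0.01),
        t2 = clone_population(c(allT, allC), c(0.2, 0.8),
                              loss_rate = 0.01, gain_rate = 0.01)),
      config = sim_config(depth = 500L))
  )
}

#' Build the standard simulation fixture for a preset
#'
#' One CpG island region carrying `n_sites` CpGs, with a single spanning
#' amplicon per requested strand, sized so that typical reads cover the
#' whole island.
#'
#' @param n_sites CpGs in the region.
#' @param seed Reference seed.
#' @param strands Amplicon strands.
#' @param region_length Region length, bp.
#' @param pad CpG-free primer pad length.
#' @return List `genome`, `targets`, `panel`.
#' @export
simulate_fixture <- function(n_sites = 8L, seed = 1L, strands = "forward",
                             region_length = 180L, pad = 26L) {
  ref <- make_reference(n_regions = 1L, region_length = region_length,
                        n_cpg = n_sites, seed = seed, pad = pad)
  pairs <- bind_rows(lapply(strands, function(st) {
    tibble(region = "region1", strand = st,
           product_start = ref$targets$start[1],
           product_end = ref$targets$end[1],
           left_len = 22L, right_len = 22L)
  }))
  panel <- panel_from_pairs(ref$genome, ref$targets, pairs)
  list(genome = ref$genome, targets = ref$targets, panel = panel)
}
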