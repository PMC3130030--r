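test_that("segmentation enumerates all fitting windows", {
  t1 <- tibble::tibble(chrom = "c", start = 0L, end = 210L, name = "r")
  s <- segment_targets(t1, sizes = 200L, spacing = 5L)
  expect_equal(nrow(s), 3L)
  expect_equal(s$start, c(0L, 5L, 10L))

  t2 <- tibble::tibble(chrom = "c", start = 0L, end = 199L, name = "r")
  expect_warning(s2 <- segment_targets(t2, sizes = 200L), "shorter")
  expect_equal(nrow(s2), 0L)

  t3 <- tibble::tibble(chrom = "c", start = 100L, end = 1100L, name = "r")
  s3 <- segment_targets(t3, sizes = c(200L, 300L, 400L), spacing = 5L)
  expect_equal(nrow(s3), 161L + 141L + 121L)
  # brute-force window generation agrees
  brute <- 0L
  for (sz in c(200L, 300L, 400L)) {
    st <- 0L
    while (st + sz <= 1000L) { brute <- brute + 1L; st <- st + 5L }
  }
  expect_equal(nrow(s3), brute)
  expect_true(all(s3$end - s3$start == s3$size_class))
})

test_that("candidate generation matches exhaustive enumeration", {
  ref <- make_reference(n_regions = 1L, region_length = 260L, n_cpg = 5L,
                        seed = 21L)
  refs <- convert_reference(ref$genome, ref$targets, strands = "forward")
  segs <- segment_targets(ref$targets, sizes = 200L, spacing = 5L)[1, ]
  cons <- list(tm_target = 50, tm_max_diff = 3)
  got <- generate_candidates(refs, segs, constraints = cons, tm_window = 15)

  expect_lte(nrow(got), 5L)
  expect_false(is.unsorted(got$penalty))

  # independent exhaustive oracle over the same placement grid
  dseq <- refs$converted_seq[1]
  s0 <- segs$seg_start; sz <- 200L; slack <- 50L
  oligo <- function(a, l) substr(dseq, a + 1L, a + l)
  best <- data.frame()
  for (a in s0 + 0:slack) for (la in 18:25) {
    lseq <- oligo(a, la)
    ltm <- melting_temperature(lseq); lgc <- gc_percent(lseq)
    if (abs(ltm - 50) > 15 || lgc < 20 || lgc > 90) next
    for (b in (s0 + sz - slack):(s0 + sz)) for (lb in 18:25) {
      plen <- b - a
      if (plen < sz - slack || plen > sz || plen < la + lb) next
      rseq_f <- oligo(b - lb, lb)
      rtm <- melting_temperature(rseq_f); rgc <- gc_percent(rseq_f)
      if (abs(rtm - 50) > 15 || rgc < 20 || rgc > 90) next
      if (abs(ltm - rtm) > 3) next
      pen <- abs(ltm - 50) + abs(rtm - 50) +
        0.5 * (abs(la - 20) + abs(lb - 20)) + abs(ltm - rtm)
      best <- rbind(best, data.frame(lseq = lseq, rseq_f = rseq_f,
                                     pen = pen))
    }
  }
  best <- best[order(best$pen), ][seq_len(min(5, nrow(best))), ]
  expect_equal(got$penalty, best$pen, tolerance = 1e-10)
  expect_equal(got$left_seq, best$lseq)
  expect_equal(got$right_seq, oracle_revcomp_vec(best$rseq_f))
})

test_that("variant and CpG masking removes exactly the offending pairs", {
  cand <- tibble::tibble(
    region = "r", chrom = "c", strand = "forward", size_class = 200L,
    seg_start = 0L,
    left_seq = c("A", "B", "C"), right_seq = c("X", "Y", "Z"),
    left_tm = 56, right_tm = 56, left_gc = 50, right_gc = 50,
    left_len = 20L, right_len = 20L, penalty = 0,
    product_start = 0L, product_end = 200L, product_len = 200L,
    fp1_start = c(0L, 50L, 100L), fp1_end = c(20L, 70L, 120L),
    fp2_start = 180L, fp2_end = 200L)
  # SNP at 10 (MAF .25) kills pair 1; SNP at 60 (MAF .05) spares pair 2
  v <- tibble::tibble(chrom = "c", pos = c(10L, 60L), maf = c(0.25, 0.05))
  out <- mask_variant_and_cpg(cand, v, NULL)
  expect_equal(out$left_seq, c("B", "C"))
  # CpG with C at 110 kills pair 3 (forward strand masks the C position)
  reg <- tibble::tibble(chrom = "c", pos = 110L, region = "r",
                        offset = 110L, polymorphic = FALSE)
  out2 <- mask_variant_and_cpg(cand, v, reg)
  expect_equal(out2$left_seq, "B")
})

test_that("e-PCR screening removes duplicated and planted off-targets", {
  set.seed(31)
  orig <- rand_dna(300, c(A = .2, C = .3, G = .3, T = .2))
  conv <- convert_forward(orig)
  left <- substr(conv, 1, 20)
  right <- oracle_revcomp(substr(conv, 281, 300))
  flank1 <- rand_dna(400); flank2 <- rand_dna(400)
  cand <- tibble::tibble(
    region = "r", chrom = "chrA", strand = "forward", size_class = 300L,
    seg_start = 0L, left_seq = left, right_seq = right,
    left_tm = NA_real_, right_tm = NA_real_, left_gc = 50, right_gc = 50,
    left_len = 20L, right_len = 20L, penalty = 0,
    product_start = 400L, product_end = 700L, product_len = 300L,
    fp1_start = 400L, fp1_end = 420L, fp2_start = 680L, fp2_end = 700L)

  # clean genome: only the intended locus -> retained
  g0 <- c(chrA = paste0(flank1, orig, flank2))
  expect_equal(nrow(epcr_screen(cand, g0)), 1L)

  # verbatim duplicate on a decoy contig -> removed
  g1 <- c(g0, chrB = paste0(rand_dna(50), orig, rand_dna(50)))
  expect_equal(nrow(epcr_screen(cand, g1)), 0L)

  # second left-primer site 5 kb from any right site -> retained
  g2 <- c(chrA = paste0(flank1, orig, flank2, strrep("A", 4500),
                        substr(orig, 1, 40), rand_dna(100)))
  expect_equal(nrow(epcr_screen(cand, g2)), 1L)

  # planted 1.5 kb off-target product -> removed; oracle agrees
  g3 <- c(chrA = paste0(flank1, orig, flank2,
                        substr(orig, 1, 40), strrep("A", 1400),
                        substr(orig, 261, 300), rand_dna(100)))
  out3 <- epcr_screen(cand, g3)
  expect_equal(nrow(out3), 0L)
  templates <- list(
    `chrA|forward` = convert_forward(g3[["chrA"]]),
    `chrA|reverse` = convert_reverse(g3[["chrA"]]))
  orc <- oracle_offtargets(left, right, templates)
  orc <- orc[!(orc$start == 400L & orc$end == 700L &
               orc$template == "chrA|forward"), ]
  expect_gt(nrow(orc), 0L)

  expect_error(epcr_screen(cand, NULL), "missing")
})

test_that("coverage-driven selection is sound and deterministic", {
  targets <- tibble::tibble(chrom = "c", start = 0L, end = 300L, name = "r")
  one <- tibble::tibble(
    region = "r", chrom = "c", strand = "forward", size_class = 300L,
    seg_start = 0L, left_seq = "AAA", right_seq = "TTT",
    left_tm = 56, right_tm = 56, left_gc = 40, right_gc = 40,
    left_len = 20L, right_len = 20L, penalty = 0,
    product_start = 0L, product_end = 300L, product_len = 300L,
    fp1_start = 0L, fp1_end = 20L, fp2_start = 280L, fp2_end = 300L)
  pool <- dplyr::bind_rows(one, one)   # redundant duplicate
  sel <- select_by_coverage(pool, targets, fold_targets = c(`300` = 2L))
  expect_equal(nrow(sel), 1L)

  empty <- one[0, ]
  sel0 <- select_by_coverage(empty, targets)
  expect_equal(nrow(sel0), 0L)
  unc <- attr(sel0, "uncovered")
  expect_equal(unc$start, 0L)
  expect_equal(unc$end, 300L)
})

test_that("a designed panel is internally consistent and reproducible", {
  ref <- make_reference(n_regions = 1L, region_length = 600L, n_cpg = 12L,
                        seed = 17L)
  p1 <- design_panel(ref$genome, ref$targets, strands = "forward")
  p2 <- design_panel(ref$genome, ref$targets, strands = "forward")
  expect_identical(tibble::as_tibble(p1), tibble::as_tibble(p2))

  # coverage map equals brute-force recomputation from selected amplicons
  cov <- attr(p1, "coverage")[["region1"]]
  for (cl in rownames(cov)) {
    recount <- integer(ncol(cov))
    sub <- p1[p1$size_class == as.integer(cl), , drop = FALSE]
    for (k in seq_len(nrow(sub))) {
      idx <- (sub$product_start[k] - ref$targets$start[1] + 1L):
             (sub$product_end[k] - ref$targets$start[1])
      recount[idx] <- recount[idx] + 1L
    }
    expect_equal(unname(cov[cl, ]), recount)
  }

  # uncovered intervals are exactly the zero-coverage bases
  tot <- colSums(cov)
  unc <- attr(p1, "uncovered")
  zero <- which(tot == 0) - 1L + ref$targets$start[1]
  listed <- unlist(lapply(seq_len(nrow(unc)), function(i)
    seq.int(unc$start[i], unc$end[i] - 1L)))
  expect_equal(sort(zero), sort(as.integer(listed %||% integer(0))))

  # every selected pair satisfies its mode's constraints
  win <- ifelse(p1$design_mode == "relaxed", 6, 2)
  expect_true(all(abs(p1$left_tm - 56) <= win + 1e-9))
  expect_true(all(abs(p1$right_tm - 56) <= win + 1e-9))
  expect_true(all(p1$left_len >= 18 & p1$left_len <= 25))
  expect_true(all(p1$right_len >= 18 & p1$right_len <= 25))
  expect_true(all(abs(p1$left_tm - p1$right_tm) <= 2 + 1e-9))
})

test_that("relaxation only ever shrinks the uncovered set", {
  ref <- make_reference(n_regions = 1L, region_length = 600L, n_cpg = 12L,
                        seed = 23L)
  refs <- convert_reference(ref$genome, ref$targets, strands = "forward")
  registry <- build_cpg_registry(ref$genome, ref$targets)
  segs <- segment_targets(ref$targets)
  cand <- generate_candidates(refs, segs)
  cand <- mask_variant_and_cpg(cand, NULL, registry)
  std <- select_by_coverage(cand, ref$targets)
  unc_before <- attr(std, "uncovered")
  rel <- relaxed_redesign(std, refs, cpg_registry = registry)
  unc_after <- attr(rel, "uncovered")
  bases <- function(u) if (!nrow(u)) integer(0) else
    unlist(lapply(seq_len(nrow(u)), function(i) u$start[i]:(u$end[i] - 1L)))
  expect_true(all(bases(unc_after) %in% bases(unc_before)))
  expect_true(all(rel$design_mode[!rel$left_seq %in% std$left_seq |
                                  !rel$right_seq %in% std$right_seq] ==
                    "relaxed"))

  # no uncovered bases -> relaxation is a no-op
  if (!nrow(unc_after)) {
    rel2 <- relaxed_redesign(rel, refs, cpg_registry = registry)
    expect_identical(tibble::as_tibble(rel2), tibble::as_tibble(rel))
  }
})

test_that("the calculated peak profile is an exact size tally", {
  targets <- tibble::tibble(chrom = "c", start = 0L, end = 300L, name = "r")
  base <- tibble::tibble(
    region = "r", chrom = "c", strand = "forward",
    seg_start = 0L, left_tm = 56, right_tm = 56, left_gc = 40,
    right_gc = 40, left_len = 20L, right_len = 20L, penalty = 0,
    fp1_start = 0L, fp1_end = 20L, fp2_start = 280L, fp2_end = 300L)
  sizes <- c(250L, 250L, 250L, 187L, 305L)
  pan <- dplyr::bind_rows(lapply(seq_along(sizes), function(i) {
    dplyr::mutate(base, size_class = sizes[i], product_start = 0L,
                  product_end = sizes[i], product_len = sizes[i],
                  left_seq = paste0("L", i), right_seq = paste0("R", i))
  }))
  prof <- calculated_peak_profile(pan, bin_width = 10L)
  expect_equal(sum(prof$count), 5L)
  expect_equal(prof$count[prof$bin_start == 250L], 3L)
  brute <- table((sizes %/% 10L) * 10L)
  expect_equal(prof$count, as.integer(brute))
  expect_equal(nrow(calculated_peak_profile(pan[0, ])), 0L)
})
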