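hep_tbl <- function(patterns, counts = rep(1L, length(patterns))) {
  tibble::tibble(pattern = patterns, count = as.integer(counts),
                 frequency = counts / sum(counts))
}

test_that("hepitypes come only from fully spanning, cleanly read molecules", {
  fx <- tiny_fixture()
  pop <- clone_population(c(strrep("C", 8), strrep("T", 8)), c(0.5, 0.5))
  rd <- draw_reads(pop, fx$panel,
                   sim_config(seed = 7L, depth = 100L,
                              conversion_efficiency = 1,
                              read_length_sd = 0))
  m <- map_reads(rd, fx$panel)
  hep <- extract_hepitypes(m, fx$panel, "region1")
  truth <- attr(rd, "truth")
  expect_setequal(hep$pattern, unique(truth$states))
  expect_equal(sum(hep$count), 100L)
  expect_equal(sum(hep$frequency), 1)
  # generator bookkeeping agrees pattern by pattern
  for (p in hep$pattern) {
    expect_equal(hep$count[hep$pattern == p], sum(truth$states == p))
  }

  # truncated reads that miss a site are excluded
  rd2 <- draw_reads(pop, fx$panel,
                    sim_config(seed = 7L, depth = 100L,
                               conversion_efficiency = 1,
                               read_length_mean = 120, read_length_sd = 0))
  hep2 <- extract_hepitypes(map_reads(rd2, fx$panel), fx$panel, "region1")
  expect_lt(attr(hep2, "n_spanning"), 100L)

  expect_error(extract_hepitypes(m, fx$panel, "no_such_region"), "no CpG")
})

test_that("the 1% frequency filter is strict and never renormalizes", {
  h <- hep_tbl(c("A", "B", "C"), c(98L, 1L, 1L))
  expect_equal(filter_hepitypes(h)$pattern, "A")
  h2 <- hep_tbl(c("A", "B", "C"), c(97L, 2L, 1L))
  f2 <- filter_hepitypes(h2)
  expect_equal(f2$pattern, c("A", "B"))
  expect_equal(f2$frequency, c(0.97, 0.02))   # not renormalized
  expect_equal(nrow(filter_hepitypes(h[0, ])), 0L)
})

test_that("the incompatible quartet needs exactly three changes", {
  tr <- parsimony_tree(hep_tbl(c("CC", "CT", "TC", "TT")),
                       method = "exhaustive")
  expect_equal(tr$tree_length, 3L)
  # independent check on the returned topology
  expect_equal(oracle_fitch(tr$tree, tr$patterns, tr$labels), 3L)
})

test_that("degenerate inputs give degenerate trees", {
  one <- parsimony_tree(hep_tbl("CCCC"))
  expect_equal(one$tree_length, 0L)
  two <- parsimony_tree(hep_tbl(c("CCCC", "CTCC")))
  expect_equal(two$tree_length, 1L)
  expect_error(parsimony_tree(hep_tbl(c("CC", "CC"))), "duplicate")
})

test_that("heuristic search finds the exhaustive minimum on random data", {
  set.seed(61)
  for (i in 1:30) {
    n <- sample(4:6, 1); L <- sample(4:10, 1)
    pats <- unique(replicate(n, paste(sample(c("C", "T"), L, TRUE),
                                      collapse = "")))
    if (length(pats) < 4) next
    h <- hep_tbl(pats)
    ex <- parsimony_tree(h, method = "exhaustive")
    he <- parsimony_tree(h, method = "heuristic")
    expect_equal(he$tree_length, ex$tree_length)
    # the exhaustive topology is confirmed by the independent Fitch oracle
    expect_equal(oracle_fitch(ex$tree, ex$patterns, ex$labels),
                 ex$tree_length)
  }
})

test_that("tree length is bounded by variable sites, with equality iff compatible", {
  # perfect phylogeny (nested splits): length == variable sites
  nested <- hep_tbl(c("TTTT", "CTTT", "CCTT", "CCCT", "CCCC"))
  tn <- parsimony_tree(nested, method = "exhaustive")
  expect_equal(tn$tree_length, 4L)
  # incompatible splits force extra changes
  tq <- parsimony_tree(hep_tbl(c("CC", "CT", "TC", "TT")),
                       method = "exhaustive")
  expect_gt(tq$tree_length, 2L)
})

test_that("Fitch length is invariant under leaf and site permutation", {
  set.seed(67)
  pats <- c("CCTTCT", "TTCCTC", "CTCTCT", "TCTCTC", "CCCTTT")
  base_len <- parsimony_tree(hep_tbl(pats), method = "exhaustive")$tree_length
  for (i in 1:5) {
    perm <- sample(pats)                       # leaf order
    sp <- sample(nchar(pats[1]))               # site order
    permuted <- vapply(perm, function(p) {
      paste(strsplit(p, "")[[1]][sp], collapse = "")
    }, character(1), USE.NAMES = FALSE)
    expect_equal(parsimony_tree(hep_tbl(permuted),
                                method = "exhaustive")$tree_length,
                 base_len)
  }
})

test_that("bootstrap supports reflect signal compatibility and are seeded", {
  # perfect phylogeny replicated over many sites: all splits certain
  strong <- hep_tbl(vapply(
    c("TTTT", "CTTT", "CCTT", "CCCT", "CCCC"),
    function(p) strrep(p, 10), character(1), USE.NAMES = FALSE))
  b1 <- bootstrap_support(strong, replicates = 100, seed = 5,
                          method = "exhaustive")
  expect_true(all(b1$bootstrap$support >= 0.95))

  # two incompatible binary columns: no resolution can be well supported
  weak <- hep_tbl(c("CC", "CT", "TC", "TT"))
  b2 <- bootstrap_support(weak, replicates = 200, seed = 5,
                          method = "exhaustive")
  expect_true(all(b2$bootstrap$support <= 0.85))

  b3 <- bootstrap_support(weak, replicates = 200, seed = 5,
                          method = "exhaustive")
  expect_identical(b2$bootstrap, b3$bootstrap)
})

test_that("two-sided Fisher p matches the hypergeometric enumeration", {
  expect_equal(fisher_exact(matrix(c(1, 0, 0, 1), 2)), 1)
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(fisher_exact(matrix(c(0, 0, 0, 0), 2)), 1)  # zero margins
  expect_equal(fisher_exact(matrix(c(10, 0, 0, 10), 2)),
               2 / choose(20, 10), tolerance = 1e-12)
  set.seed(71)
  for (i in 1:50) {
    tab <- matrix(rpois(4, sample(1:10, 1)), 2)
    p_ref <- stats::fisher.test(tab)$p.value
    expect_equal(fisher_exact(tab), p_ref, tolerance = 1e-12)
    expect_gt(fisher_exact(tab), 0)
    expect_lte(fisher_exact(tab), 1)
  }
})

test_that("deviating-site assignment, conservation and the worked table", {
  pats <- c(rep(strrep("C", 5), 40),
            rep("CTCCC", 8),
            rep(strrep("T", 5), 50),
            rep("TTCTT", 2))
  dv <- deviation_table(pats)
  expect_equal(unname(dv$table),
               matrix(c(40L, 50L, 8L, 2L), 2))
  expect_equal(dv$n_assigned, 100L)
  expect_equal(dv$n_ties, 0L)
  expect_equal(dv$fisher_p, stats::fisher.test(dv$table)$p.value,
               tolerance = 1e-12)

  # exact-distance ties are excluded but counted
  dv2 <- deviation_table(c("CT", "CC", "TT"))
  expect_equal(dv2$n_ties, 1L)
  expect_equal(dv2$n_assigned, 2L)

  # hepitype-level counting gives the same table as expanded reads
  h <- hep_tbl(c("CCCCC", "CTCCC", "TTTTT"), c(40L, 8L, 50L))
  expect_equal(deviation_table(h)$table,
               deviation_table(rep(h$pattern, h$count))$table)
})

test_that("tidiers expose the tree and test results as tibbles", {
  tr <- parsimony_tree(hep_tbl(c("CC", "CT", "TC", "TT")))
  td <- generics::tidy(tr)
  expect_equal(nrow(td), 4L)
  g <- generics::glance(tr)
  expect_equal(g$tree_length, 3L)
  dv <- deviation_table(c("CC", "CT", "TT"))
  expect_equal(sum(generics::tidy(dv)$count), dv$n_assigned)
  expect_equal(generics::glance(dv)$fisher_p, dv$fisher_p)
})
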