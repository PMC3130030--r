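# shared fixture: one 240 bp region, single forward spanning amplicon
rp_fixture <- function(seed = 13L) {
  fx <- simulate_fixture(n_sites = 6L, seed = seed, region_length = 240L)
  amp <- hepityper:::amplicon_references(fx$panel)
  fx$ref_unmeth <- chartr("Y", "T", amp$ambig_seq[1])   # all-T product
  fx$amp <- amp
  fx
}

# inject k mismatches at non-CpG insert columns of a read
inject_mismatches <- function(seq, ambig, insert, k, seed = 1) {
  set.seed(seed)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  ac <- strsplit(ambig, "", fixed = TRUE)[[1]]
  ok <- which(ac %in% c("A", "G", "T"))
  ok <- ok[ok > insert[1] & ok <= insert[2]]
  pos <- sample(ok, k)
  for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), c(ch[p], "C"))[1]
  paste(ch, collapse = "")
}

test_that("primer matching agrees with a brute-force edit-distance oracle", {
  fx <- rp_fixture()
  lib <- primer_library(fx$panel)
  set.seed(5)
  reads <- tibble::tibble(
    read_id = paste0("r", 1:30),
    seq = c(
      # exact primer at offset 0
      paste0(lib$seq[1], rand_dna(80)),
      # primer with 1 and 3 substitutions inside the read
      vapply(1:2, function(k) {
        p <- strsplit(lib$seq[1], "")[[1]]
        idx <- sample(seq_along(p), c(1, 3)[k])
        p[idx] <- vapply(p[idx], function(b)
          setdiff(c("A", "C", "G", "T"), b)[1], character(1))
        paste0(rand_dna(40), paste(p, collapse = ""), rand_dna(40))
      }, character(1)),
      replicate(27, rand_dna(120))))
  hits <- match_primers(reads, lib)

  expect_true(any(hits$read_id == "r1" & hits$primer_id == lib$primer_id[1] &
                  hits$edit_distance == 0L))
  expect_true(any(hits$read_id == "r2" & hits$primer_id == lib$primer_id[1] &
                  hits$edit_distance == 1L))
  expect_false(any(hits$read_id == "r3" & hits$primer_id == lib$primer_id[1] &
                   hits$orientation == "asis"))

  # full cross-check of every read x primer x orientation
  for (k in seq_len(nrow(lib))) {
    for (orient in c("asis", "revcomp")) {
      pat <- if (orient == "asis") lib$seq[k] else oracle_revcomp(lib$seq[k])
      for (i in seq_len(nrow(reads))) {
        d <- oracle_infix_edit(pat, reads$seq[i])
        hit <- hits[hits$read_id == reads$read_id[i] &
                    hits$primer_id == lib$primer_id[k] &
                    hits$orientation == orient, ]
        if (d <= 2L) {
          expect_equal(nrow(hit), 1L)
          expect_equal(hit$edit_distance, d)
        } else {
          expect_equal(nrow(hit), 0L)
        }
      }
    }
  }
  expect_error(match_primers(reads, lib[0, ]), "empty")
})

test_that("methylation state never penalizes alignment identity", {
  fx <- rp_fixture()
  amb <- fx$amp$ambig_seq[1]
  full_meth <- chartr("Y", "C", amb)
  full_unmeth <- chartr("Y", "T", amb)
  m <- map_reads(tibble::tibble(read_id = c("meth", "unmeth"),
                                seq = c(full_meth, full_unmeth)),
                 fx$panel)
  expect_equal(m$identity, c(1, 1))
  expect_equal(m$status, c("mapped", "mapped"))
})

test_that("identity thresholds separate 3% from 5.5% mismatched reads", {
  fx <- rp_fixture()
  ins <- c(fx$amp$insert_start[1] - fx$amp$product_start[1],
           fx$amp$insert_end[1] - fx$amp$product_start[1])
  r6 <- inject_mismatches(fx$ref_unmeth, fx$amp$ambig_seq[1], ins, 7)
  r13 <- inject_mismatches(fx$ref_unmeth, fx$amp$ambig_seq[1], ins, 13)
  m <- map_reads(tibble::tibble(read_id = c("ok", "bad"),
                                seq = c(r6, r13)), fx$panel)
  # 240 columns: 7 mismatches = 97.1% passes, 13 = 94.6% fails
  expect_equal(m$aligned_cols, c(240L, 240L))
  expect_equal(m$matching_bases, c(233L, 227L))
  expect_equal(m$status, c("mapped", "low_identity"))

  # identity exactly at the threshold is excluded (strict inequality)
  r12 <- inject_mismatches(fx$ref_unmeth, fx$amp$ambig_seq[1], ins, 12)
  m2 <- map_reads(tibble::tibble(read_id = "edge", seq = r12), fx$panel)
  expect_equal(m2$identity, 0.95)
  expect_equal(m2$status, "low_identity")

  # short perfect read: matching bases below 50 is excluded
  short <- substr(fx$ref_unmeth, 1, 49)
  m3 <- map_reads(tibble::tibble(read_id = "s", seq = short), fx$panel)
  expect_equal(m3$matching_bases, 49L)
  expect_equal(m3$status, "low_identity")
})

test_that("reads from a duplicated region are flagged ambiguous", {
  set.seed(41)
  pad <- paste0(sample(c("A", "G", "T"), 24, TRUE), collapse = "")
  pad2 <- paste0("A", paste0(sample(c("A", "G", "T"), 23, TRUE),
                             collapse = ""))
  core <- rand_dna(100, c(A = .2, C = .3, G = .3, T = .2))
  region <- paste0(pad, core, pad2)
  genome <- c(chr = paste0(rand_dna(100), region, rand_dna(150), region,
                           rand_dna(100)))
  targets <- tibble::tibble(chrom = "chr",
                            start = c(100L, 100L + 148L + 150L),
                            end = c(100L + 148L, 100L + 2L * 148L + 150L),
                            name = c("rA", "rB"))
  pairs <- tibble::tibble(region = c("rA", "rB"), strand = "forward",
                          product_start = targets$start,
                          product_end = targets$end,
                          left_len = 22L, right_len = 22L)
  panel <- panel_from_pairs(genome, targets, pairs)
  read <- chartr("Y", "T",
                 hepityper:::amplicon_references(panel)$ambig_seq[1])
  m <- map_reads(tibble::tibble(read_id = "dup", seq = read), panel)
  expect_equal(m$status, "ambiguous")
})

test_that("primer trimming excludes footprints and their CpGs", {
  # region with a CpG planted inside the left primer footprint
  set.seed(43)
  lp <- "AGGTAGGTTAGCGTAGGTAGGT"         # CpG at offset 11
  core <- "TTAGGTACGTTAGGTTTACGTTAGGTTAGGTACGTTAGGATTAGGTTAGGTTAGG"
  rp <- "ATTAGGTTAGGATTAGGTTTGG"
  region <- paste0(lp, core, rp)
  genome <- c(chr = paste0(rand_dna(60), region, rand_dna(60)))
  reg_end <- 60L + nchar(region)
  targets <- tibble::tibble(chrom = "chr", start = 60L,
                            end = reg_end, name = "r")
  panel <- panel_from_pairs(genome, targets, tibble::tibble(
    region = "r", strand = "forward", product_start = 60L,
    product_end = reg_end, left_len = 22L, right_len = 22L))
  reg <- attr(panel, "cpg_registry")
  expect_true((60L + 11L) %in% reg$pos)    # the primer-footprint CpG

  read <- chartr("Y", "C",
                 hepityper:::amplicon_references(panel)$ambig_seq[1])
  m <- map_reads(tibble::tibble(read_id = "full", seq = read), panel)
  expect_equal(m$status, "mapped")
  expect_equal(m$trim_start, 22L)
  calls <- call_sites(m, panel)
  under_primer <- calls[calls$pos == 60L + 11L, ]
  expect_true(under_primer$no_reads)      # never scored
  inside <- calls[calls$pos != 60L + 11L, ]
  expect_true(all(inside$depth == 1L))

  # a primer-only read has an empty trimmed span and is excluded
  m2 <- map_reads(tibble::tibble(read_id = "ponly",
                                 seq = substr(read, 1, 22)), panel)
  expect_false(m2$status == "mapped")
})

test_that("read accounting balances and degrades monotonically with error", {
  fx <- tiny_fixture()
  pop <- clone_population(c(strrep("C", 8), strrep("T", 8)), c(.5, .5))
  fracs <- vapply(c(0, 0.03, 0.09), function(rate) {
    rd <- draw_reads(pop, fx$panel,
                     sim_config(seed = 19L, depth = 120L,
                                conversion_efficiency = 1,
                                substitution_error = rate))
    m <- map_reads(rd, fx$panel)
    acct <- attr(m, "accounting")
    expect_equal(sum(acct$reads), nrow(rd))
    expect_equal(sum(acct$reads), sum(table(m$status)))
    if (rate == 0) expect_true(all(m$identity == 1 & m$status == "mapped"))
    mean(m$status == "mapped")
  }, numeric(1))
  expect_true(all(diff(fracs) <= 0))
  expect_lt(fracs[3], fracs[1])
})
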