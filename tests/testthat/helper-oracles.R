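# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force scans, generic library routines,
# closed forms.

# Infix edit distance: minimum global edit distance (utils::adist, C
# implementation) between `pattern` and any substring of `text` whose
# length is within `band` of the pattern's.
oracle_infix_edit <- function(pattern, text, band = 2L) {
  m <- nchar(pattern); n <- nchar(text)
  best <- m
  for (len in max(0L, m - band):(m + band)) {
    if (len > n) next
    if (len == 0L) { best <- min(best, m); next }
    subs <- substring(text, 1:(n - len + 1L), len:n)
    best <- min(best, min(utils::adist(pattern, subs)))
  }
  best
}

oracle_revcomp <- function(s) {
  paste(rev(chartr("ACGTYR", "TGCARY",
                   strsplit(s, "", fixed = TRUE)[[1]])), collapse = "")
}

# Spearman rho with explicit average-rank computation.
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    sv <- sort(v)
    for (i in seq_along(v)) r[i] <- mean(which(sv == v[i]))
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Fitch length of a given ape tree via phangorn (independent of the
# package's own Fitch code).
oracle_fitch <- function(phy, patterns, labels) {
  m <- do.call(rbind, strsplit(patterns, "", fixed = TRUE))
  rownames(m) <- labels
  dat <- phangorn::phyDat(m, type = "USER", levels = c("C", "T"))
  phangorn::fitch(ape::unroot(phy), dat)
}

# Brute-force in-silico PCR: all binding sites of a primer on a template
# by sliding-window mismatch counting (requires exact 3'-word match and
# <= max_mm mismatches overall), then all convergent products.
oracle_binding_sites <- function(primer, template, word = 15L, max_mm = 2L) {
  L <- nchar(primer); n <- nchar(template)
  if (n < L) return(list(fwd_start = integer(0), rev_end = integer(0)))
  pc <- strsplit(primer, "", fixed = TRUE)[[1]]
  tc <- strsplit(template, "", fixed = TRUE)[[1]]
  rc <- strsplit(oracle_revcomp(primer), "", fixed = TRUE)[[1]]
  ns <- n - L + 1L                 # candidate 0-based starts 0..ns-1
  mm_f <- integer(ns); mm_r <- integer(ns)
  wf <- integer(ns); wr <- integer(ns)
  for (j in seq_len(L)) {
    col <- tc[j:(j + ns - 1L)]
    mm_f <- mm_f + (col != pc[j])
    mm_r <- mm_r + (col != rc[j])
    if (j > L - word) wf <- wf + (col != pc[j])
    if (j <= word) wr <- wr + (col != rc[j])
  }
  list(fwd_start = which(mm_f <= max_mm & wf == 0L) - 1L,
       rev_end = which(mm_r <= max_mm & wr == 0L) - 1L + L)
}

oracle_offtargets <- function(left, right, templates, max_product = 2000L,
                              word = 15L, max_mm = 2L) {
  out <- list()
  for (tn in names(templates)) {
    sl <- oracle_binding_sites(left, templates[[tn]], word, max_mm)
    sr <- oracle_binding_sites(right, templates[[tn]], word, max_mm)
    fw <- c(sl$fwd_start, sr$fwd_start)
    rv <- c(sl$rev_end, sr$rev_end)
    for (f in fw) for (r in rv) {
      if (r > f && r - f <= max_product &&
          r - f >= max(nchar(left), nchar(right))) {
        out[[length(out) + 1L]] <- data.frame(template = tn, start = f,
                                              end = r)
      }
    }
  }
  if (!length(out)) return(data.frame(template = character(),
                                      start = integer(), end = integer()))
  unique(do.call(rbind, out))
}

# Random DNA string.
rand_dna <- function(n, probs = c(A = .25, C = .25, G = .25, T = .25)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs),
        collapse = "")
}

# Standard small simulation fixture: one region, one forward amplicon.
tiny_fixture <- function(n_sites = 8L, seed = 3L, strands = "forward",
                         region_length = 180L) {
  simulate_fixture(n_sites = n_sites, seed = seed, strands = strands,
                   region_length = region_length)
}

oracle_revcomp_vec <- function(x) {
  vapply(x, oracle_revcomp, character(1), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
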