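# Read-to-amplicon assignment: approximate primer matching (edit distance
# <= 2, substitutions/insertions/deletions at unit cost), dynamic-programming
# alignment to ambiguity-coded amplicons, identity/matching-base filters and
# primer trimming.

.base_code <- c(A = 1L, C = 2L, G = 3L, T = 4L)

# Integer-code matrix (reads x max length); 0 = padding or N (never matches).
encode_reads <- function(seqs) {
  L <- max(nchar(seqs), 1L)
  m <- matrix(0L, nrow = length(seqs), ncol = L)
  sp <- strsplit(toupper(seqs), "", fixed = TRUE)
  for (i in seq_along(sp)) {
    v <- .base_code[sp[[i]]]
    v[is.na(v)] <- 0L
    if (length(v)) m[i, seq_along(v)] <- v
  }
  m
}

# Infix (substring) edit distance of one pattern against many reads at once.
# Row-wise DP over the pattern, vectorized across reads; the text start is
# free, so dist[i] = min over all end offsets. Returns list(dist, end)
# with `end` the 1-based read position of the best match end (smallest on
# ties).
edit_scan <- function(pattern, read_mat, read_len) {
  p <- .base_code[strsplit(toupper(pattern), "", fixed = TRUE)[[1]]]
  p[is.na(p)] <- -1L
  m <- length(p); n <- nrow(read_mat); L <- ncol(read_mat)
  prev <- matrix(0, n, L + 1L)           # row 0: free start
  cur <- matrix(0, n, L + 1L)
  for (i in seq_len(m)) {
    cur[, 1L] <- i
    for (j in seq_len(L)) {
      cost <- (read_mat[, j] != p[i]) | (read_mat[, j] == 0L)
      cur[, j + 1L] <- pmin(prev[, j + 1L] + 1, prev[, j] + cost,
                            cur[, j] + 1)
    }
    tmp <- prev; prev <- cur; cur <- tmp
  }
  final <- prev[, -1L, drop = FALSE]
  final[col(final) > read_len[row(final)]] <- Inf   # don't end in padding
  dist <- apply(final, 1L, min)
  end <- apply(final, 1L, which.min)
  list(dist = dist, end = end)
}

#' Build the primer search library of a panel
#'
#' One row per primer with its amplicon, end, and the orientation of a read
#' (relative to the forward-coordinate amplicon reference) implied by
#' finding the primer as-synthesized at the read start.
#'
#' @param panel A `panel_design` or compatible tibble.
#' @return Tibble `primer_id`, `amplicon_id`, `region`, `end`, `seq`,
#'   `orient_asis` (`"+"` or `"-"`).
#' @export
primer_library <- function(panel) {
  stopifnot(nrow(panel) > 0)
  bind_rows(
    tibble(primer_id = paste0(panel$amplicon_id, "_L"),
           amplicon_id = panel$amplicon_id, region = panel$region,
           end = "left", seq = panel$left_seq,
           orient_asis = ifelse(panel$strand == "forward", "+", "-")),
    tibble(primer_id = paste0(panel$amplicon_id, "_R"),
           amplicon_id = panel$amplicon_id, region = panel$region,
           end = "right", seq = panel$right_seq,
           orient_asis = ifelse(panel$strand == "forward", "-", "+"))
  )
}

#' Locate primers in reads by approximate string matching
#'
#' Every library primer is searched in every read in both orientations
#' (as-synthesized and reverse-complemented), allowing at most `max_diff`
#' unit-cost differences (substitutions, insertions, deletions).
#'
#' @param reads Tibble with `read_id`, `seq` (or a named character vector).
#' @param library Primer library from [primer_library()], or any tibble
#'   with `primer_id` and `seq`.
#' @param max_diff Maximum edit distance per primer.
#' @return Tibble of hits: `read_id`, `primer_id`, `orientation` (`"asis"`
#'   or `"revcomp"`, the form of the primer found in the read),
#'   `edit_distance`, `read_offset` (0-based end-exclusive offset of the
#'   match end).
#' @export
match_primers <- function(reads, library,
                          max_diff = hepityper_defaults()$primer_max_diff) {
  reads <- as_reads(reads)
  if (!nrow(library)) abort("primer library is empty")
  if (!nrow(reads)) {
    return(tibble(read_id = character(), primer_id = character(),
                  orientation = character(), edit_distance = integer(),
                  read_offset = integer()))
  }
  mat <- encode_reads(reads$seq)
  rl <- nchar(reads$seq)
  hits <- list()
  for (k in seq_len(nrow(library))) {
    for (orient in c("asis", "revcomp")) {
      pat <- if (orient == "asis") library$seq[k] else revcomp(library$seq[k])
      sc <- edit_scan(pat, mat, rl)
      ok <- which(sc$dist <= max_diff)
      if (length(ok)) {
        hits[[length(hits) + 1L]] <- tibble(
          read_id = reads$read_id[ok],
          primer_id = library$primer_id[k],
          orientation = orient,
          edit_distance = as.integer(sc$dist[ok]),
          read_offset = as.integer(sc$end[ok]))
      }
    }
  }
  if (!length(hits)) {
    return(tibble(read_id = character(), primer_id = character(),
                  orientation = character(), edit_distance = integer(),
                  read_offset = integer()))
  }
  bind_rows(hits)
}

as_reads <- function(reads) {
  if (is.character(reads)) {
    ids <- names(reads)
    if (is.null(ids)) ids <- paste0("read", seq_along(reads))
    reads <- tibble(read_id = ids, seq = unname(reads))
  }
  stopifnot(all(c("read_id", "seq") %in% names(reads)))
  reads
}

# Substitution matrix over {A,C,G,T,Y,R,N}: +1 for compatible, -1 otherwise.
ambiguity_submat <- function() {
  al <- c("A", "C", "G", "T", "Y", "R", "N")
  compat <- list(A = "A", C = "C", G = "G", T = "T",
                 Y = c("C", "T"), R = c("A", "G"), N = character(0))
  m <- matrix(-1, length(al), length(al), dimnames = list(al, al))
  for (a in al) for (b in al) {
    if (b %in% compat[[a]] || a %in% compat[[b]]) m[a, b] <- 1
  }
  m
}

# Column tally of one alignment: matching bases (ambiguity-compatible),
# total aligned columns (gaps included).
.aln_tally <- function(p, s) {
  pc <- strsplit(p, "", fixed = TRUE)[[1]]
  sc <- strsplit(s, "", fixed = TRUE)[[1]]
  match <- (pc == sc & pc != "-") |
    (sc == "Y" & pc %in% c("C", "T")) |
    (sc == "R" & pc %in% c("A", "G"))
  c(matching = sum(match), columns = length(pc))
}

#' Align reads to their candidate amplicons
#'
#' Reads are oriented by their best primer hits, then aligned to the
#' ambiguity-coded reference of every candidate amplicon (read-global,
#' reference-local dynamic programming; match +1, mismatch -1, gap -2, free
#' end gaps on the reference; `Y` matches C/T, `R` matches A/G). The best
#' candidate by matching bases is retained per read.
#'
#' @param reads Read tibble (`read_id`, `seq`).
#' @param panel `panel_design` providing amplicon references.
#' @param hits Primer hits from [match_primers()]; computed when `NULL`.
#' @param constraints Optional overrides.
#' @return Tibble, one row per read: assignment, alignment strings, counts,
#'   identity, statuses `mapped` / `no_primer` / `low_identity` /
#'   `ambiguous` (thresholds applied by [apply_filters()], already called).
#' @export
align_to_amplicons <- function(reads, panel, hits = NULL,
                               constraints = list()) {
  cons <- design_constraints(constraints)
  reads <- as_reads(reads)
  lib <- primer_library(panel)
  if (is.null(hits)) {
    hits <- match_primers(reads, lib, max_diff = cons$primer_max_diff)
  }
  amp <- amplicon_references(panel)

  # candidate (read, amplicon, orientation) set from primer hits
  hits <- left_join(hits, lib[, c("primer_id", "amplicon_id", "orient_asis")],
                    by = "primer_id")
  hits$read_orient <- ifelse(hits$orientation == "asis",
                             hits$orient_asis,
                             ifelse(hits$orient_asis == "+", "-", "+"))
  cand <- distinct(hits, .data$read_id, .data$amplicon_id, .data$read_orient)

  base <- tibble(read_id = reads$read_id, seq = reads$seq,
                 status = "no_primer")
  if (!nrow(cand)) return(.finish_alignment(base, NULL, cons))

  submat <- ambiguity_submat()
  aln_rows <- list()
  for (key in split(seq_len(nrow(cand)),
                    paste(cand$amplicon_id, cand$read_orient))) {
    aid <- cand$amplicon_id[key[1]]
    orient <- cand$read_orient[key[1]]
    ref <- amp$ambig_seq[amp$amplicon_id == aid]
    rid <- cand$read_id[key]
    sq <- reads$seq[match(rid, reads$read_id)]
    if (orient == "-") sq <- revcomp(sq)
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAStringSet(sq),
      subject = Biostrings::DNAString(ref),
      type = "global-local", substitutionMatrix = submat,
      gapOpening = 0, gapExtension = 2)
    # aligned() yields the same column-aligned strings as
    # alignedPattern()/alignedSubject() but without per-element S4 cost
    ap <- as.character(Biostrings::aligned(Biostrings::pattern(aln)))
    as_ <- as.character(Biostrings::aligned(Biostrings::subject(aln)))
    tal <- vapply(seq_along(ap), function(i) .aln_tally(ap[i], as_[i]),
                  numeric(2))
    aln_rows[[length(aln_rows) + 1L]] <- tibble(
      read_id = rid, amplicon_id = aid, orientation = orient,
      region = amp$region[amp$amplicon_id == aid],
      matching_bases = as.integer(tal["matching", ]),
      aligned_cols = as.integer(tal["columns", ]),
      sub_start = BiocGenerics::start(Biostrings::subject(aln)) - 1L,
      sub_end = BiocGenerics::end(Biostrings::subject(aln)),
      aligned_pattern = unname(ap), aligned_subject = unname(as_))
  }
  .finish_alignment(base, bind_rows(aln_rows), cons)
}

# Per-read best-candidate selection, thresholds and ambiguity handling.
.finish_alignment <- function(base, aln, cons) {
  if (is.null(aln) || !nrow(aln)) {
    out <- base
    out$amplicon_id <- NA_character_; out$region <- NA_character_
    out$orientation <- NA_character_
    out$matching_bases <- NA_integer_; out$aligned_cols <- NA_integer_
    out$identity <- NA_real_
    out$sub_start <- NA_integer_; out$sub_end <- NA_integer_
    out$aligned_pattern <- NA_character_; out$aligned_subject <- NA_character_
    return(out)
  }
  aln$identity <- aln$matching_bases / aln$aligned_cols
  aln$passes <- aln$matching_bases >= cons$min_matching_bases &
    aln$identity > cons$min_identity
  a <- aln[order(aln$read_id, -aln$matching_bases, aln$amplicon_id), ,
           drop = FALSE]
  stats <- a %>%
    group_by(.data$read_id) %>%
    summarise(
      n_top_regions = dplyr::n_distinct(
        .data$region[.data$matching_bases == max(.data$matching_bases)]),
      n_pass_regions = dplyr::n_distinct(.data$region[.data$passes]),
      .groups = "drop")
  pick <- a[!duplicated(a$read_id), , drop = FALSE]
  pick <- left_join(pick, stats, by = "read_id")
  pick$status <- ifelse(pick$n_top_regions > 1L | pick$n_pass_regions > 1L,
                        "ambiguous",
                        ifelse(pick$passes, "mapped", "low_identity"))
  pick$passes <- NULL; pick$n_top_regions <- NULL
  pick$n_pass_regions <- NULL
  out <- left_join(base[, c("read_id", "seq")], pick, by = "read_id")
  out$status <- dplyr::coalesce(out$status, "no_primer")
  out
}

#' Re-apply mapping thresholds to aligned reads
#'
#' Reads below `min_matching_bases` or at/below the identity threshold are
#' marked `low_identity`; reads whose passing best alignments touch more
#' than one target region are `ambiguous`. Provided separately so filter
#' settings can be changed without re-aligning.
#'
#' @param mapped Output of [align_to_amplicons()].
#' @param constraints Overrides of `min_matching_bases` / `min_identity`.
#' @return `mapped` with `status` recomputed.
#' @export
apply_filters <- function(mapped, constraints = list()) {
  cons <- design_constraints(constraints)
  st <- mapped$status
  realn <- !is.na(mapped$identity)
  pass <- realn & mapped$matching_bases >= cons$min_matching_bases &
    mapped$identity > cons$min_identity
  st[realn & !pass & st != "ambiguous"] <- "low_identity"
  st[pass & st != "ambiguous"] <- "mapped"
  mapped$status <- st
  mapped
}

#' Trim primer footprints from mapped reads
#'
#' Records for every mapped read the amplicon-local interval of its
#' alignment that lies outside both primer footprints; CpG sites under
#' primers are never scored.
#'
#' @param mapped Output of [align_to_amplicons()].
#' @param panel The `panel_design` used for mapping.
#' @return `mapped` with `trim_start`, `trim_end` (0-based half-open,
#'   amplicon-local). Reads whose alignment is entirely primer sequence get
#'   an empty span (`trim_start == trim_end`).
#' @export
trim_primers <- function(mapped, panel) {
  amp <- amplicon_references(panel)
  i <- match(mapped$amplicon_id, amp$amplicon_id)
  ins_s <- amp$insert_start[i] - amp$product_start[i]  # amplicon-local
  ins_e <- amp$insert_end[i] - amp$product_start[i]
  mapped$trim_start <- pmax(mapped$sub_start, ins_s)
  mapped$trim_end <- pmin(mapped$sub_end, ins_e)
  empty <- !is.na(mapped$trim_start) & mapped$trim_start >= mapped$trim_end
  mapped$trim_start[empty] <- mapped$trim_end[empty]
  mapped
}

# Forward-coordinate ambiguity-coded reference of each amplicon, with
# insert (primer-free) genome interval.
amplicon_references <- function(panel) {
  refs <- attr(panel, "refs")
  if (is.null(refs)) abort("panel carries no converted references; build with design_panel() or attach refs")
  out <- as_tibble(panel)[, c("amplicon_id", "region", "chrom", "strand",
                              "product_start", "product_end",
                              "fp1_start", "fp1_end", "fp2_start", "fp2_end")]
  out$insert_start <- out$fp1_end
  out$insert_end <- out$fp2_start
  out$ambig_seq <- vapply(seq_len(nrow(out)), function(i) {
    r <- refs[refs$name == out$region[i] & refs$strand == out$strand[i], ]
    if (!nrow(r)) abort(sprintf("no converted reference for region '%s' strand '%s'",
                                out$region[i], out$strand[i]))
    substr(r$ambiguous_seq[1], out$product_start[i] - r$start[1] + 1L,
           out$product_end[i] - r$start[1])
  }, character(1))
  out
}

#' Map reads to a panel end to end
#'
#' Convenience wrapper: primer matching, alignment, filtering and trimming.
#'
#' @inheritParams align_to_amplicons
#' @return Mapped-read tibble with trimming columns; attribute
#'   `"accounting"` tabulates statuses.
#' @export
map_reads <- function(reads, panel, constraints = list()) {
  mapped <- align_to_amplicons(reads, panel, constraints = constraints)
  mapped <- apply_filters(mapped, constraints)
  mapped <- trim_primers(mapped, panel)
  acct <- table(factor(mapped$status,
                       levels = c("mapped", "no_primer", "low_identity",
                                  "ambiguous")))
  attr(mapped, "accounting") <- tibble(status = names(acct),
                                       reads = as.integer(acct))
  mapped
}
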