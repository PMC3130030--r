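# Per-CpG methylation quantification from mapped, trimmed reads, with
# coverage / polymorphism flags and strand-concordance statistics.

# Read base at given amplicon-local reference offsets for one mapped read.
# Returns a character vector (NA where the read has a gap or does not
# cover the offset).
.bases_at <- function(aligned_pattern, aligned_subject, sub_start, offsets) {
  sc <- strsplit(aligned_subject, "", fixed = TRUE)[[1]]
  pc <- strsplit(aligned_pattern, "", fixed = TRUE)[[1]]
  nongap <- which(sc != "-")
  ref_off <- sub_start + seq_along(nongap) - 1L
  idx <- match(offsets, ref_off)
  out <- pc[nongap[idx]]
  out[is.na(idx)] <- NA_character_
  out[!is.na(out) & out == "-"] <- NA_character_
  out
}

#' Call per-CpG methylation from mapped reads
#'
#' For every CpG site of the registry covered by an amplicon, counts
#' methylated and unmethylated read bases in the trimmed (primer-free)
#' span: `C`/`T` on forward-strand amplicons, `G`/`A` (read at the CpG
#' guanine, mapped to C/T) on reverse-strand amplicons. Methylation is the
#' proportion `n_C / (n_C + n_T)`; other aligned bases count toward depth
#' only. Sites with no aligned reads are flagged `no_reads`; depth below
#' `low_coverage_depth` is flagged `low_coverage`.
#'
#' @param mapped Mapped-read tibble from [map_reads()].
#' @param panel The `panel_design` used for mapping.
#' @param registry CpG registry from [build_cpg_registry()] (or the one
#'   attached to the panel when `NULL`).
#' @param sample Sample label recorded in the calls.
#' @param split_strand If `TRUE`, one row per site x supporting strand;
#'   otherwise counts are summed over strands.
#' @param constraints Optional overrides (`low_coverage_depth`).
#' @return Tibble of site calls: `sample`, `region`, `chrom`, `pos`,
#'   `strand_support`, `n_C`, `n_T`, `n_other`, `depth`, `methylation`,
#'   `polymorphic`, `low_coverage`, `no_reads`, `not_a_cpg_in_sample`.
#' @export
call_sites <- function(mapped, panel, registry = NULL, sample = "sample1",
                       split_strand = FALSE, constraints = list()) {
  cons <- design_constraints(constraints)
  if (is.null(registry)) registry <- attr(panel, "cpg_registry")
  if (is.null(registry)) abort("no CpG registry supplied or attached to panel")
  amp <- amplicon_references(panel)
  ok <- mapped[!is.na(mapped$status) & mapped$status == "mapped", ,
               drop = FALSE]

  # per amplicon, the registry sites whose readable base lies in the insert
  tallies <- list()
  for (a in seq_len(nrow(amp))) {
    am <- amp[a, ]
    readable <- if (am$strand == "forward") registry$pos else registry$pos + 1L
    sites <- which(registry$chrom == am$chrom &
                   readable >= am$insert_start & readable < am$insert_end)
    if (!length(sites)) next
    rds <- ok[ok$amplicon_id == am$amplicon_id, , drop = FALSE]
    loc <- readable[sites] - am$product_start     # amplicon-local offsets
    nC <- nT <- nO <- integer(length(sites))
    if (nrow(rds)) {
      for (r in seq_len(nrow(rds))) {
        inside <- loc >= rds$trim_start[r] & loc < rds$trim_end[r]
        if (!any(inside)) next
        b <- .bases_at(rds$aligned_pattern[r], rds$aligned_subject[r],
                       rds$sub_start[r], loc[inside])
        meth <- if (am$strand == "forward") "C" else "G"
        unme <- if (am$strand == "forward") "T" else "A"
        nC[inside] <- nC[inside] + (!is.na(b) & b == meth)
        nT[inside] <- nT[inside] + (!is.na(b) & b == unme)
        nO[inside] <- nO[inside] + (!is.na(b) & b != meth & b != unme)
      }
    }
    tallies[[length(tallies) + 1L]] <- tibble(
      chrom = am$chrom, pos = registry$pos[sites],
      region = registry$region[sites],
      polymorphic = registry$polymorphic[sites],
      strand_support = am$strand, n_C = nC, n_T = nT, n_other = nO)
  }

  covered <- if (length(tallies)) bind_rows(tallies) else
    tibble(chrom = character(), pos = integer(), region = character(),
           polymorphic = logical(), strand_support = character(),
           n_C = integer(), n_T = integer(), n_other = integer())
  if (split_strand) {
    covered <- covered %>%
      group_by(across(all_of(c("chrom", "pos", "region", "polymorphic",
                               "strand_support")))) %>%
      summarise(n_C = sum(.data$n_C), n_T = sum(.data$n_T),
                n_other = sum(.data$n_other), .groups = "drop")
  } else {
    covered <- covered %>%
      group_by(across(all_of(c("chrom", "pos", "region", "polymorphic")))) %>%
      summarise(strand_support = paste_strands(.data$strand_support),
                n_C = sum(.data$n_C), n_T = sum(.data$n_T),
                n_other = sum(.data$n_other), .groups = "drop")
  }

  # registry sites not covered by any amplicon insert -> no_reads
  key <- paste(covered$chrom, covered$pos,
               if (split_strand) covered$strand_support else "")
  rkey <- paste(registry$chrom, registry$pos, "")
  missing <- if (split_strand) integer(0) else which(!(rkey %in% key))
  if (length(missing)) {
    covered <- bind_rows(covered, tibble(
      chrom = registry$chrom[missing], pos = registry$pos[missing],
      region = registry$region[missing],
      polymorphic = registry$polymorphic[missing],
      strand_support = "none", n_C = 0L, n_T = 0L, n_other = 0L))
  }
  out <- covered
  out$sample <- sample
  out$depth <- out$n_C + out$n_T + out$n_other
  out$methylation <- ifelse(out$n_C + out$n_T > 0,
                            out$n_C / (out$n_C + out$n_T), NA_real_)
  out$no_reads <- out$depth == 0L
  out$low_coverage <- out$depth > 0L & out$depth < cons$low_coverage_depth
  out$not_a_cpg_in_sample <- FALSE
  arrange(out[, c("sample", "region", "chrom", "pos", "strand_support",
                  "n_C", "n_T", "n_other", "depth", "methylation",
                  "polymorphic", "low_coverage", "no_reads",
                  "not_a_cpg_in_sample")],
          .data$chrom, .data$pos)
}

paste_strands <- function(x) {
  u <- sort(unique(x))
  if (length(u) > 1L) "both" else u
}

#' Mark calls at CpG sites absent from a sample's genotype
#'
#' Polymorphic sites whose CpG does not exist on either allele of the
#' sample (per the registry's per-sample presence) get
#' `not_a_cpg_in_sample = TRUE` and `methylation = NA`. Without presence
#' information this is a no-op.
#'
#' @param calls Output of [call_sites()].
#' @param registry CpG registry with `presence` list-column.
#' @return Annotated calls.
#' @export
annotate_sample_cpg_presence <- function(calls, registry) {
  if (!"presence" %in% names(registry)) return(calls)
  for (i in seq_len(nrow(registry))) {
    pres <- registry$presence[[i]]
    if (is.null(pres)) next
    hit <- calls$chrom == registry$chrom[i] & calls$pos == registry$pos[i]
    for (s in names(pres)) {
      j <- hit & calls$sample == s
      if (!pres[[s]] && any(j)) {
        calls$not_a_cpg_in_sample[j] <- TRUE
        calls$methylation[j] <- NA_real_
      }
    }
  }
  calls
}

#' Cross-strand (or cross-method) concordance of methylation calls
#'
#' Spearman rank correlation (average ranks for ties) between two call
#' sets over the sites where both define a methylation value.
#'
#' @param calls_a,calls_b Call tibbles with `chrom`, `pos`, `methylation`
#'   (e.g. the two strata of `call_sites(..., split_strand = TRUE)`), or
#'   any tibbles with a shared `chrom`/`pos` key.
#' @return Tibble `spearman_rho`, `n_sites`; `rho` is `NA` when fewer than
#'   3 shared sites are defined.
#' @export
strand_concordance <- function(calls_a, calls_b) {
  m <- dplyr::inner_join(
    calls_a[, c("chrom", "pos", "methylation")],
    calls_b[, c("chrom", "pos", "methylation")],
    by = c("chrom", "pos"), suffix = c("_a", "_b"))
  m <- m[complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3L) {
    return(tibble(spearman_rho = NA_real_, n_sites = nrow(m)))
  }
  tibble(spearman_rho = cor(m$methylation_a, m$methylation_b,
                            method = "spearman"),
         n_sites = nrow(m))
}

#' Export a site-by-sample percent-methylation table
#'
#' Wide table, one row per site and one percent-methylation column per
#' sample: `"-"` when the sample has no reads at the site, `"NA"` when the
#' site is not a CpG in that sample; a companion `<sample>_flag` column
#' carries `low_coverage` markup.
#'
#' @param calls Call tibble (possibly several samples, long form).
#' @param file Optional path; when given the table is written as TSV.
#' @return The wide tibble (invisibly when `file` is given). Positions are
#'   reported 1-based.
#' @export
export_methylation_table <- function(calls, file = NULL) {
  fmt <- ifelse(calls$no_reads, "-",
         ifelse(calls$not_a_cpg_in_sample, "NA",
                sprintf("%.2f", 100 * calls$methylation)))
  flg <- ifelse(calls$low_coverage, "low_coverage", "")
  long <- tibble(region = calls$region, chrom = calls$chrom,
                 pos = calls$pos + 1L, polymorphic = calls$polymorphic,
                 sample = calls$sample, value = fmt, flag = flg)
  wide <- tidyr::pivot_wider(long, names_from = "sample",
                             values_from = c("value", "flag"),
                             names_glue = "{sample}{ifelse(.value=='flag','_flag','')}")
  wide <- arrange(wide, .data$chrom, .data$pos)
  if (!is.null(file)) {
    readr::write_tsv(wide, file)
    return(invisible(wide))
  }
  wide
}

#' Read back an exported methylation table
#'
#' @param file Path written by [export_methylation_table()].
#' @return Tibble as written (positions 1-based, values as characters).
#' @export
read_methylation_table <- function(file) {
  readr::read_tsv(file, show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_character(),
                                          pos = readr::col_integer(),
                                          polymorphic = readr::col_logical()))
}
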