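# In-silico bisulfite conversion of reference DNA, CpG enumeration and
# ambiguity-coded amplicon construction.

# Validate a vector of DNA strings; returns uppercased strings.
# `allow` is a regex character class body.
check_dna <- function(seq, allow = "ACGTN", arg = "seq") {
  if (!is.character(seq)) abort(sprintf("`%s` must be a character vector", arg))
  seq <- toupper(seq)
  bad <- regexpr(sprintf("[^%s]", allow), seq)
  hit <- which(bad > 0L)
  if (length(hit)) {
    abort(sprintf(
      "`%s`[%d] contains invalid character '%s' at position %d",
      arg, hit[1], substr(seq[hit[1]], bad[hit[1]], bad[hit[1]]), bad[hit[1]]
    ))
  }
  seq
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Bisulfite-convert the forward strand in silico
#'
#' Full conversion of the plus strand: every cytosine is deaminated and read
#' as thymine after PCR, so `C -> T`; all other bases are untouched. This is
#' the fully *unmethylated* conversion product; see [ambiguous_amplicon()]
#' for the methylation-agnostic (ambiguity-coded) form.
#'
#' @param seq Character vector of DNA strings over `A,C,G,T,N`.
#' @return Character vector of converted sequences, same lengths.
#' @examples
#' convert_forward("ACGTCG")  # "ATGTTG"
#' @export
convert_forward <- function(seq) {
  chartr("C", "T", check_dna(seq))
}

#' Bisulfite-convert the reverse strand, reported in forward coordinates
#'
#' Converting the minus strand (its cytosines pair with plus-strand
#' guanines) and re-expressing the product on forward coordinates turns
#' every `G` into `A`. Equivalently
#' `revcomp(convert_forward(revcomp(seq)))`.
#'
#' @inheritParams convert_forward
#' @return Character vector of converted sequences, same lengths.
#' @export
convert_reverse <- function(seq) {
  chartr("G", "A", check_dna(seq))
}

# 0-based offsets of CpG cytosines in a single sequence.
find_cpg_offsets <- function(seq) {
  hits <- gregexpr("CG", seq, fixed = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits) - 1L
}

#' Enumerate CpG sites in a sequence, including SNP-created sites
#'
#' Scans `seq` for CpG dinucleotides and, when a variant table is supplied,
#' adds sites where an alternate allele creates a CpG (flagged
#' `polymorphic`). Sites where an alternate allele destroys a reference CpG
#' are also flagged polymorphic. With a genotype table, per-sample presence
#' of each polymorphic site is computed: a site is present in a sample if at
#' least one of its two alleles yields the CpG.
#'
#' @param seq A single DNA string.
#' @param variants Optional tibble with columns `pos` (0-based offset into
#'   `seq`), `ref`, `alt` (single bases), `maf`.
#' @param genotypes Optional tibble with columns `sample`, `pos`,
#'   `allele1`, `allele2`.
#' @return Tibble with columns `offset` (0-based position of the C),
#'   `polymorphic` (logical), and `presence` (list-column of named logical
#'   vectors per sample; `NULL` when no genotypes given).
#' @export
enumerate_cpgs <- function(seq, variants = NULL, genotypes = NULL) {
  seq <- check_dna(seq)
  stopifnot(length(seq) == 1L)
  n <- nchar(seq)
  ref_sites <- find_cpg_offsets(seq)
  out <- tibble(offset = ref_sites, polymorphic = FALSE)

  if (!is.null(variants) && nrow(variants)) {
    if (any(variants$pos < 0L | variants$pos >= n)) {
      abort("variant position outside sequence")
    }
    base_at <- function(i) substr(seq, i + 1L, i + 1L)
    created <- integer(0)
    affected <- integer(0)   # reference sites destroyed by an alt allele
    for (k in seq_len(nrow(variants))) {
      p <- variants$pos[k]; alt <- toupper(variants$alt[k])
      ref <- toupper(variants$ref[k])
      # creation: alt C followed by G, or alt G preceded by C
      if (alt == "C" && p + 1L < n && base_at(p + 1L) == "G" &&
          !(p %in% ref_sites)) {
        created <- c(created, p)
      }
      if (alt == "G" && p >= 1L && base_at(p - 1L) == "C" &&
          !((p - 1L) %in% ref_sites)) {
        created <- c(created, p - 1L)
      }
      # destruction: variant hits the C or the G of an existing CpG
      if (ref == "C" && p %in% ref_sites && alt != "C") {
        affected <- c(affected, p)
      }
      if (ref == "G" && (p - 1L) %in% ref_sites && alt != "G") {
        affected <- c(affected, p - 1L)
      }
    }
    out$polymorphic[out$offset %in% affected] <- TRUE
    if (length(created)) {
      out <- bind_rows(out, tibble(offset = unique(created), polymorphic = TRUE))
    }
    out <- arrange(out, .data$offset)
  }

  out$presence <- vector("list", nrow(out))
  if (!is.null(genotypes) && nrow(out)) {
    samples <- unique(genotypes$sample)
    for (i in seq_len(nrow(out))) {
      if (!out$polymorphic[i]) next
      off <- out$offset[i]
      # which variant rows touch this site (the C or the G position)?
      vk <- which(variants$pos %in% c(off, off + 1L))
      pres <- setNames(rep(TRUE, length(samples)), samples)
      for (k in vk) {
        p <- variants$pos[k]
        g <- genotypes[genotypes$pos == p, , drop = FALSE]
        need <- if (p == off) "C" else "G"   # allele that yields the CpG
        for (s in samples) {
          gs <- g[g$sample == s, , drop = FALSE]
          al <- if (nrow(gs)) toupper(c(gs$allele1[1], gs$allele2[1]))
                else toupper(c(variants$ref[k], variants$ref[k]))
          pres[s] <- pres[s] && any(al == need)
        }
      }
      out$presence[[i]] <- pres
    }
  }
  out
}

#' Ambiguity-coded converted amplicon sequence
#'
#' Builds the conversion product that is agnostic to methylation state:
#' CpG-context cytosines read as `C` (methylated, protected) or `T`
#' (unmethylated, converted), coded `Y`; all other cytosines are fully
#' converted to `T`. On the reverse strand (in forward coordinates) the
#' readable base is the CpG guanine: `G`/`A`, coded `R`; other guanines
#' become `A`. CpG context is determined on the original sequence.
#'
#' @param original_seq A single unconverted DNA string.
#' @param strand `"forward"` or `"reverse"`.
#' @return A single string over `A,C,G,T,Y,R,N`.
#' @examples
#' ambiguous_amplicon("ACCGT", "forward")  # "ATYGT"
#' @export
ambiguous_amplicon <- function(original_seq, strand = c("forward", "reverse")) {
  strand <- match.arg(strand)
  seq <- check_dna(original_seq)
  stopifnot(length(seq) == 1L)
  cpg <- find_cpg_offsets(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (strand == "forward") {
    ch[ch == "C"] <- "T"
    ch[cpg + 1L] <- "Y"
  } else {
    ch[ch == "G"] <- "A"
    ch[cpg + 2L] <- "R"   # the G of each CpG
  }
  paste(ch, collapse = "")
}

#' Build strand-specific converted references for target regions
#'
#' For each target interval and each requested strand, extracts the original
#' sequence, its fully converted form, its ambiguity-coded form, and the CpG
#' offsets. Coordinates are 0-based half-open internally.
#'
#' @param genome Named character vector (or `DNAStringSet`) of contigs.
#' @param targets Tibble with columns `chrom`, `start`, `end`, `name`
#'   (0-based half-open).
#' @param strands Character subset of `c("forward", "reverse")`.
#' @param variants Optional variant tibble with genome coordinates
#'   (`chrom`, `pos` 0-based, `ref`, `alt`, `maf`).
#' @return Tibble with one row per region x strand: `chrom`, `start`,
#'   `end`, `name`, `strand`, `original_seq`, `converted_seq`,
#'   `ambiguous_seq`, `cpg_offsets` (list-column, 0-based region offsets),
#'   `has_n` (logical).
#' @export
convert_reference <- function(genome, targets,
                              strands = c("forward", "reverse"),
                              variants = NULL) {
  genome <- as_genome(genome)
  strands <- match.arg(strands, several.ok = TRUE)
  stopifnot(all(c("chrom", "start", "end") %in% names(targets)))
  if (!"name" %in% names(targets)) {
    targets$name <- paste0("region", seq_len(nrow(targets)))
  }
  if (any(targets$start >= targets$end)) abort("targets must have start < end")
  rows <- list()
  for (i in seq_len(nrow(targets))) {
    chrom <- targets$chrom[i]
    if (!chrom %in% names(genome)) abort(sprintf("contig '%s' not in genome", chrom))
    s0 <- targets$start[i]; e0 <- targets$end[i]
    if (e0 > nchar(genome[[chrom]])) abort("target extends beyond contig end")
    orig <- substr(genome[[chrom]], s0 + 1L, e0)
    for (st in strands) {
      conv <- if (st == "forward") convert_forward(orig) else convert_reverse(orig)
      rows[[length(rows) + 1L]] <- tibble(
        chrom = chrom, start = s0, end = e0, name = targets$name[i],
        strand = st,
        original_seq = orig,
        converted_seq = conv,
        ambiguous_seq = ambiguous_amplicon(orig, st),
        cpg_offsets = list(find_cpg_offsets(orig)),
        has_n = grepl("N", orig, fixed = TRUE)
      )
    }
  }
  bind_rows(rows)
}

#' Build a genome-wide CpG registry for a set of target regions
#'
#' @inheritParams convert_reference
#' @param genotypes Optional genotype tibble (`sample`, `chrom`, `pos`,
#'   `allele1`, `allele2`).
#' @return Tibble: `chrom`, `pos` (0-based genome position of the CpG
#'   cytosine), `region`, `offset` (0-based within region), `polymorphic`,
#'   `presence` (list-column, per-sample logical or `NULL`).
#' @export
build_cpg_registry <- function(genome, targets, variants = NULL,
                               genotypes = NULL) {
  genome <- as_genome(genome)
  if (!"name" %in% names(targets)) {
    targets$name <- paste0("region", seq_len(nrow(targets)))
  }
  rows <- list()
  for (i in seq_len(nrow(targets))) {
    chrom <- targets$chrom[i]; s0 <- targets$start[i]; e0 <- targets$end[i]
    orig <- substr(genome[[chrom]], s0 + 1L, e0)
    vloc <- NULL
    if (!is.null(variants)) {
      v <- variants[variants$chrom == chrom &
                    variants$pos >= s0 & variants$pos < e0, , drop = FALSE]
      if (nrow(v)) { vloc <- v; vloc$pos <- vloc$pos - s0 }
    }
    gloc <- NULL
    if (!is.null(genotypes) && !is.null(vloc)) {
      g <- genotypes[genotypes$chrom == chrom, , drop = FALSE]
      if (nrow(g)) { gloc <- g; gloc$pos <- gloc$pos - s0 }
    }
    cp <- enumerate_cpgs(orig, variants = vloc, genotypes = gloc)
    if (nrow(cp)) {
      rows[[length(rows) + 1L]] <- tibble(
        chrom = chrom, pos = s0 + cp$offset, region = targets$name[i],
        offset = cp$offset, polymorphic = cp$polymorphic,
        presence = cp$presence
      )
    }
  }
  if (!length(rows)) {
    return(tibble(chrom = character(), pos = integer(), region = character(),
                  offset = integer(), polymorphic = logical(),
                  presence = list()))
  }
  bind_rows(rows)
}

# Coerce genome input to a named character vector of contigs.
as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  if (is.null(names(genome)) || any(!nzchar(names(genome)))) {
    abort("genome contigs must be named")
  }
  check_dna(genome, arg = "genome")
}

# Both full-genome conversion strands, for off-target screening.
convert_genome_background <- function(genome) {
  genome <- as_genome(genome)
  list(forward = vapply(genome, convert_forward, character(1)),
       reverse = vapply(genome, convert_reverse, character(1)))
}
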