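# Orchestration and external formats: FASTA/FASTQ/BED/TSV/Newick readers
# and writers, run manifests with accounting, and the end-to-end pipeline
# driver.

#' Read / write FASTA
#'
#' @param file Path.
#' @return `read_fasta()`: named character vector.
#' @export
read_fasta <- function(file) {
  x <- Biostrings::readDNAStringSet(file)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, file) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), file)
  invisible(file)
}

#' Read / write FASTQ (qualities are not used downstream)
#'
#' @param file Path.
#' @return `read_fastq()`: tibble `read_id`, `seq`.
#' @export
read_fastq <- function(file) {
  x <- Biostrings::readDNAStringSet(file, format = "fastq")
  tibble(read_id = sub("\\s.*$", "", names(x)),
         seq = unname(as.character(x)))
}

#' @rdname read_fastq
#' @param reads Tibble `read_id`, `seq`.
#' @export
write_fastq <- function(reads, file) {
  reads <- as_reads(reads)
  con <- file(file, "w"); on.exit(close(con))
  writeLines(paste0("@", reads$read_id, "\n", reads$seq, "\n+\n",
                    strrep("I", nchar(reads$seq))), con)
  invisible(file)
}

#' Read / write BED target intervals (0-based half-open)
#'
#' @param file Path.
#' @return `read_bed()`: tibble `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(file) {
  x <- readr::read_tsv(file, col_names = FALSE, show_col_types = FALSE,
                       comment = "#")
  out <- tibble(chrom = as.character(x[[1]]), start = as.integer(x[[2]]),
                end = as.integer(x[[3]]))
  out$name <- if (ncol(x) >= 4) as.character(x[[4]]) else
    paste0("region", seq_len(nrow(out)))
  out
}

#' @rdname read_bed
#' @param targets Target tibble.
#' @export
write_bed <- function(targets, file) {
  readr::write_tsv(targets[, c("chrom", "start", "end", "name")], file,
                   col_names = FALSE)
  invisible(file)
}

#' Write / read a primer panel as TSV
#'
#' The table mirrors a primer supplementary-table layout: primer
#' sequences, target region and coordinates (1-based in the file),
#' Tm/GC/penalty and design mode.
#'
#' @param panel A `panel_design`.
#' @param file Path.
#' @export
write_panel <- function(panel, file) {
  tb <- as_tibble(panel)
  tb$product_start <- tb$product_start + 1L   # 1-based inclusive in reports
  readr::write_tsv(tb, file)
  invisible(file)
}

#' @rdname write_panel
#' @param genome,targets Needed to reattach converted references.
#' @return `read_panel()`: a `panel_design`.
#' @export
read_panel <- function(file, genome, targets) {
  tb <- readr::read_tsv(file, show_col_types = FALSE)
  tb$product_start <- tb$product_start - 1L
  pairs <- tibble(region = tb$region, strand = tb$strand,
                  product_start = tb$product_start,
                  product_end = tb$product_end,
                  left_len = tb$left_len, right_len = tb$right_len)
  panel <- panel_from_pairs(genome, targets, pairs)
  stopifnot(identical(panel$left_seq, tb$left_seq),
            identical(panel$right_seq, tb$right_seq))
  panel
}

#' Per-sample run summary and per-amplicon normalized yield
#'
#' Per sample: raw reads, total sequence (bp), mapped reads, and mapped bp
#' excluding primer footprints; per amplicon: raw read count and the count
#' normalized to 100,000 reads per library.
#'
#' @param reads Input read tibble.
#' @param mapped Mapped-read tibble from [map_reads()].
#' @param sample Sample label.
#' @return List of tibbles `samples` and `amplicons`.
#' @export
summarize_run <- function(reads, mapped, sample = "sample1") {
  reads <- as_reads(reads)
  ok <- mapped[!is.na(mapped$status) & mapped$status == "mapped", ,
               drop = FALSE]
  # aligned reference span clipped to the primer-free insert
  mapped_bp <- if (nrow(ok)) {
    sum(pmax(0L, pmin(ok$trim_end, ok$sub_end) -
                  pmax(ok$trim_start, ok$sub_start)))
  } else 0L
  n_reads <- nrow(reads)
  total_bp <- sum(nchar(reads$seq))
  samples <- tibble(
    sample = sample,
    reads = n_reads,
    total_bp = total_bp,
    mapped_reads = nrow(ok),
    mapped_bp_wo_primers = mapped_bp)
  amp <- ok %>% group_by(.data$amplicon_id) %>%
    summarise(reads = dplyr::n(), .groups = "drop")
  amp$normalized <- if (nrow(ok)) amp$reads / nrow(ok) * 1e5 else numeric(0)
  amp$sample <- sample
  list(samples = samples, amplicons = amp)
}

#' Run the pipeline end to end
#'
#' Executes the requested stages in order -- `simulate` (preset fixture and
#' reads), `map`, `call`, `hepitype` -- persisting every intermediate under
#' `outdir` and returning all in-memory results plus a run manifest with
#' per-stage read accounting and input digests. Stage inputs can also be
#' supplied directly (`genome`/`targets`/`panel`/`reads`) to skip
#' simulation.
#'
#' @param config Named list (or path to a YAML file): fields `outdir`,
#'   `stages`, `preset`, `timepoint`, `n_sites`, `seed`, `strands`,
#'   `sample`, `region`, `min_frequency`, `bootstrap`, plus optional
#'   pre-built `genome`, `targets`, `panel`, `reads`.
#' @return List with elements per executed stage (`reads`, `truth`,
#'   `mapped`, `summary`, `calls`, `hepitypes`, `tree`, `deviation`) and
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(list(
    outdir = NULL, stages = c("simulate", "map", "call", "hepitype"),
    preset = "imprinted", timepoint = "t1", n_sites = 8L, seed = 1L,
    strands = "forward", sample = "sample1", region = "region1",
    min_frequency = hepityper_defaults()$min_hepitype_freq,
    bootstrap = 0L), config)
  res <- list()
  manifest <- list(config = cfg,
                   version = as.character(utils::packageVersion("hepityper")),
                   stages = list(), digests = list())
  outdir <- cfg$outdir
  persist <- function(obj, name, writer) {
    if (is.null(outdir)) return(invisible(NULL))
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(outdir, name)
    writer(obj, path)
    manifest$digests[[name]] <<- unname(tools::md5sum(path))
    invisible(path)
  }

  genome <- cfg$genome; targets <- cfg$targets
  panel <- cfg$panel; reads <- cfg$reads

  if ("simulate" %in% cfg$stages) {
    presets <- scenario_presets(n_sites = cfg$n_sites)
    if (!cfg$preset %in% names(presets)) {
      abort(sprintf("unknown preset '%s'", cfg$preset))
    }
    pr <- presets[[cfg$preset]]
    if (!cfg$timepoint %in% names(pr$timepoints)) {
      abort(sprintf("preset '%s' has no timepoint '%s'", cfg$preset,
                    cfg$timepoint))
    }
    fx <- simulate_fixture(n_sites = cfg$n_sites, seed = cfg$seed,
                           strands = cfg$strands)
    genome <- fx$genome; targets <- fx$targets; panel <- fx$panel
    simcfg <- pr$config; simcfg$seed <- cfg$seed
    reads <- draw_reads(pr$timepoints[[cfg$timepoint]], panel, simcfg)
    res$truth <- attr(reads, "truth")
    res$reads <- reads
    persist(genome, "genome.fasta", write_fasta)
    persist(targets, "targets.bed", write_bed)
    persist(panel, "panel.tsv", write_panel)
    persist(reads, "reads.fastq", write_fastq)
    manifest$stages$simulate <- list(reads = nrow(reads),
                                     depth = simcfg$depth)
  }
  if (is.null(reads)) abort("stage input missing: reads")
  if (is.null(panel)) abort("stage input missing: panel")

  if ("map" %in% cfg$stages) {
    res$mapped <- map_reads(reads, panel)
    res$summary <- summarize_run(reads, res$mapped, sample = cfg$sample)
    acct <- attr(res$mapped, "accounting")
    manifest$stages$map <- list(accounting = acct)
    stopifnot(sum(acct$reads) == nrow(as_reads(reads)))
    persist(res$mapped[, c("read_id", "amplicon_id", "status",
                           "matching_bases", "identity")],
            "mapped.tsv", function(o, p) readr::write_tsv(o, p))
    persist(res$summary$samples, "summary.tsv",
            function(o, p) readr::write_tsv(o, p))
  }
  if ("call" %in% cfg$stages) {
    if (is.null(res$mapped)) abort("stage input missing: mapped reads")
    res$calls <- call_sites(res$mapped, panel, sample = cfg$sample)
    manifest$stages$call <- list(sites = nrow(res$calls))
    persist(res$calls, "calls.tsv",
            function(o, p) export_methylation_table(o, p))
  }
  if ("hepitype" %in% cfg$stages) {
    if (is.null(res$mapped)) abort("stage input missing: mapped reads")
    hep <- extract_hepitypes(res$mapped, panel, cfg$region)
    res$hepitypes <- filter_hepitypes(hep, cfg$min_frequency)
    res$deviation <- deviation_table(
      rep(hep$pattern, hep$count))
    if (nrow(res$hepitypes) >= 3L) {
      res$tree <- if (cfg$bootstrap > 0L) {
        bootstrap_support(res$hepitypes, replicates = cfg$bootstrap,
                          seed = cfg$seed)
      } else parsimony_tree(res$hepitypes)
      if (!is.null(outdir)) {
        ape::write.tree(res$tree$tree, file.path(outdir, "tree.nwk"))
        manifest$digests[["tree.nwk"]] <-
          unname(tools::md5sum(file.path(outdir, "tree.nwk")))
      }
    }
    manifest$stages$hepitype <- list(
      n_spanning = attr(hep, "n_spanning"),
      n_hepitypes = nrow(res$hepitypes),
      fisher_p = res$deviation$fisher_p)
    persist(res$hepitypes, "hepitypes.tsv",
            function(o, p) readr::write_tsv(o, p))
  }
  res$manifest <- manifest
  res
}
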