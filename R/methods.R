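# broom-style tidiers and ggplot2 visualisations for the result classes.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a primer panel
#'
#' @param x A `panel_design`.
#' @param ... Unused.
#' @return Tibble of selected primer pairs (coordinates 1-based inclusive,
#'   the genome-browser convention used in all user-facing reports).
#' @export
tidy.panel_design <- function(x, ...) {
  tb <- as_tibble(x)
  if (nrow(tb)) tb$product_start <- tb$product_start + 1L
  tb
}

#' @rdname tidy.panel_design
#' @export
glance.panel_design <- function(x, ...) {
  cov <- attr(x, "coverage")
  tot <- unlist(lapply(cov, colSums))
  unc <- attr(x, "uncovered")
  tibble(
    n_pairs = nrow(x),
    n_relaxed = sum(x$design_mode == "relaxed"),
    target_bp = length(tot),
    covered_bp = sum(tot > 0),
    coverage_pct = if (length(tot)) 100 * mean(tot > 0) else NA_real_,
    mean_fold = if (length(tot)) mean(tot) else NA_real_,
    uncovered_intervals = nrow(unc))
}

#' @export
print.panel_design <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "Primer panel: %d pairs (%d relaxed), %.1f%% of %d target bp covered\n",
    g$n_pairs, g$n_relaxed, g$coverage_pct, g$target_bp))
  NextMethod()
}

#' Coverage map of a primer panel
#'
#' Per-base amplicon coverage over each target region, with the fold
#' targets of each size class stacked.
#'
#' @param object A `panel_design`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.panel_design <- function(object, ...) {
  cov <- attr(object, "coverage")
  df <- bind_rows(lapply(names(cov), function(nm) {
    tibble(region = nm, pos = seq_len(ncol(cov[[nm]])),
           coverage = colSums(cov[[nm]]))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$coverage)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~region, scales = "free_x") +
    ggplot2::labs(x = "position in region (bp)",
                  y = "amplicon coverage (fold)") +
    ggplot2::theme_minimal()
}

#' Expected product-size profile plot
#'
#' @param panel A `panel_design`.
#' @param bin_width Histogram bin width (bp).
#' @return A ggplot of the calculated peak profile.
#' @export
plot_peak_profile <- function(panel, bin_width = 10L) {
  prof <- calculated_peak_profile(panel, bin_width)
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$bin_start + bin_width / 2,
                                     y = .data$count)) +
    ggplot2::geom_col(width = bin_width * 0.9) +
    ggplot2::labs(x = "product size (bp)", y = "amplicons") +
    ggplot2::theme_minimal()
}

#' Methylation profile plot
#'
#' Percent methylation along the genome, one panel per region, one colour
#' per sample.
#'
#' @param calls Call tibble from [call_sites()].
#' @return A ggplot.
#' @export
plot_methylation <- function(calls) {
  df <- calls[!is.na(calls$methylation), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos + 1L,
                                   y = 100 * .data$methylation,
                                   colour = .data$sample)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$low_coverage)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::facet_wrap(~region, scales = "free_x") +
    ggplot2::labs(x = "genomic position (1-based)", y = "% methylation") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Tidy a parsimony result
#'
#' @param x A `parsimony_result`.
#' @param ... Unused.
#' @return Tibble `label`, `pattern`, `frequency`.
#' @export
tidy.parsimony_result <- function(x, ...) {
  tibble(label = x$labels, pattern = x$patterns, frequency = x$frequencies)
}

#' @rdname tidy.parsimony_result
#' @export
glance.parsimony_result <- function(x, ...) {
  tibble(n_hepitypes = length(x$labels), tree_length = x$tree_length,
         method = x$method,
         min_bootstrap = if (is.null(x$bootstrap) || !nrow(x$bootstrap))
           NA_real_ else min(x$bootstrap$support))
}

#' @export
plot.parsimony_result <- function(x, ...) {
  phy <- x$tree
  ape::plot.phylo(phy, type = "unrooted",
                  cex = 0.8 + 2 * sqrt(x$frequencies), ...)
  invisible(x)
}

#' Hepitype frequency spectrum plot
#'
#' @param hepitypes Tibble from [extract_hepitypes()].
#' @return A ggplot bar chart, one bar per hepitype.
#' @export
plot_hepitype_spectrum <- function(hepitypes) {
  df <- as_tibble(hepitypes)
  df$pattern <- factor(df$pattern, levels = df$pattern)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pattern,
                                   y = 100 * .data$frequency)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "hepitype (C = methylated, T = unmethylated)",
                  y = "% of spanning reads") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Tidy a deviating-site test
#'
#' @param x A `deviation_test`.
#' @param ... Unused.
#' @return Tibble of the four cells (`background`, `deviation`, `count`).
#' @export
tidy.deviation_test <- function(x, ...) {
  tibble(background = rep(rownames(x$table), 2),
         deviation = rep(colnames(x$table), each = 2),
         count = as.vector(x$table))
}

#' @rdname tidy.deviation_test
#' @export
glance.deviation_test <- function(x, ...) {
  tibble(fisher_p = x$fisher_p, n_assigned = x$n_assigned,
         n_ties = x$n_ties)
}
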