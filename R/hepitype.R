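# Phased methylation patterns (hepitypes): extraction from region-spanning
# reads, frequency filtering, unrooted maximum-parsimony trees (Fitch) with
# bootstrap support, and the deviating-site exact test for
# methylation-maintenance asymmetry.

#' Extract hepitypes from region-spanning reads
#'
#' A read contributes a hepitype iff its trimmed alignment covers every CpG
#' site of the region with a methylation-readable base (C/T on
#' forward-strand amplicons, G/A mapped to C/T on reverse-strand
#' amplicons). Identical patterns are aggregated; frequencies are relative
#' to all pattern-yielding (spanning) reads.
#'
#' @param mapped Mapped-read tibble from [map_reads()].
#' @param panel The `panel_design` used for mapping.
#' @param region Region name (as in the panel's targets / registry).
#' @param registry CpG registry; taken from the panel when `NULL`.
#' @return Tibble `pattern` (string over C = methylated, T =
#'   unmethylated), `count`, `frequency`, sorted by decreasing count.
#'   Attributes: `n_spanning` (reads contributing), `sites` (0-based
#'   genome positions), `region`.
#' @export
extract_hepitypes <- function(mapped, panel, region, registry = NULL) {
  if (is.null(registry)) registry <- attr(panel, "cpg_registry")
  sites <- registry[registry$region == region, , drop = FALSE]
  sites <- arrange(sites, .data$pos)
  if (!nrow(sites)) abort(sprintf("region '%s' has no CpG sites", region))
  amp <- amplicon_references(panel)
  ok <- mapped[!is.na(mapped$status) & mapped$status == "mapped" &
               mapped$region == region, , drop = FALSE]
  pats <- character(0)
  if (nrow(ok)) {
    pats <- vapply(seq_len(nrow(ok)), function(r) {
      am <- amp[amp$amplicon_id == ok$amplicon_id[r], ]
      readable <- if (am$strand == "forward") sites$pos else sites$pos + 1L
      loc <- readable - am$product_start
      if (any(loc < ok$trim_start[r] | loc >= ok$trim_end[r]))
        return(NA_character_)
      b <- .bases_at(ok$aligned_pattern[r], ok$aligned_subject[r],
                     ok$sub_start[r], loc)
      if (am$strand == "forward") {
        if (any(is.na(b) | !(b %in% c("C", "T")))) return(NA_character_)
        paste(b, collapse = "")
      } else {
        if (any(is.na(b) | !(b %in% c("G", "A")))) return(NA_character_)
        paste(chartr("GA", "CT", b), collapse = "")
      }
    }, character(1))
    pats <- pats[!is.na(pats)]
  }
  tb <- sort(table(pats), decreasing = TRUE)
  out <- tibble(pattern = if (length(tb)) names(tb) else character(0),
                count = as.integer(tb),
                frequency = as.integer(tb) / max(sum(tb), 1L))
  # stable order: count desc, then pattern
  out <- arrange(out, desc(.data$count), .data$pattern)
  attr(out, "n_spanning") <- sum(out$count)
  attr(out, "sites") <- sites$pos
  attr(out, "region") <- region
  out
}

#' Filter hepitypes by minimum frequency
#'
#' Keeps hepitypes whose frequency strictly exceeds `min_frequency`
#' (default 1%). Frequencies are *not* renormalized: they stay relative to
#' all spanning reads.
#'
#' @param hepitypes Tibble from [extract_hepitypes()].
#' @param min_frequency Strict lower bound on frequency.
#' @return Filtered tibble (attributes preserved).
#' @export
filter_hepitypes <- function(hepitypes,
                             min_frequency = hepityper_defaults()$min_hepitype_freq) {
  keep <- hepitypes$frequency > min_frequency
  out <- hepitypes[keep, , drop = FALSE]
  for (a in c("n_spanning", "sites", "region")) {
    attr(out, a) <- attr(hepitypes, a)
  }
  out
}

# ---- Fitch parsimony ------------------------------------------------------

# bitmask states: C = 1, T = 2
.pattern_states <- function(patterns) {
  m <- do.call(rbind, strsplit(patterns, "", fixed = TRUE))
  matrix(ifelse(m == "C", 1L, 2L), nrow = length(patterns))
}

# Fitch tree length of an unrooted binary tree. `edges` is a 2-column
# integer matrix (leaves 1..n, internal nodes > n); `states` a leaves x
# sites bitmask matrix. Rooted virtually on the first edge.
fitch_length <- function(edges, states) {
  n <- nrow(states)
  nodes <- max(edges)
  adj <- vector("list", nodes)
  for (k in seq_len(nrow(edges))) {
    u <- edges[k, 1L]; v <- edges[k, 2L]
    adj[[u]] <- c(adj[[u]], v); adj[[v]] <- c(adj[[v]], u)
  }
  changes <- 0L
  down <- function(node, parent) {
    if (node <= n) return(states[node, , drop = TRUE])
    kids <- setdiff(adj[[node]], parent)
    s <- down(kids[1], node)
    for (k in kids[-1]) {
      t <- down(k, node)
      i <- bitwAnd(s, t)
      z <- i == 0L
      changes <<- changes + sum(z)
      s <- ifelse(z, bitwOr(s, t), i)
    }
    s
  }
  a <- down(edges[1, 1L], edges[1, 2L])
  b <- down(edges[1, 2L], edges[1, 1L])
  changes + sum(bitwAnd(a, b) == 0L)
}

# All unrooted binary topologies on n leaves (first-found enumeration
# order: leaf k+1 is inserted into every edge in edge-matrix order).
# Leaves are 1..n, internal nodes n+1.. . Calls fun(edges) for each; fun
# returns TRUE to keep enumerating.
.enumerate_topologies <- function(n, fun) {
  base <- matrix(c(1L, n + 1L, 2L, n + 1L, 3L, n + 1L), ncol = 2,
                 byrow = TRUE)
  grow <- function(edges, next_leaf, next_internal) {
    if (next_leaf > n) return(fun(edges))
    for (e in seq_len(nrow(edges))) {
      u <- edges[e, 1L]; v <- edges[e, 2L]
      w <- next_internal
      ne <- rbind(edges[-e, , drop = FALSE],
                  c(u, w), c(w, v), c(w, next_leaf))
      if (!grow(ne, next_leaf + 1L, next_internal + 1L)) return(FALSE)
    }
    TRUE
  }
  if (n == 3L) { fun(base); return(invisible()) }
  grow(base, 4L, n + 2L)
  invisible()
}

# relabel internal nodes so leaves are 1..n and internals n+1.. compactly
.canonical_edges <- function(edges, n) {
  ints <- sort(unique(edges[edges > n]))
  map <- integer(max(edges)); map[seq_len(n)] <- seq_len(n)
  map[ints] <- n + seq_along(ints)
  matrix(map[edges], ncol = 2)
}

# Stepwise addition under one leaf-addition order, then steepest-descent
# NNI to a local optimum.
.stepwise_nni <- function(states, order) {
  n <- nrow(states)
  relabel <- order                      # position i holds the leaf added i-th
  st <- states[relabel, , drop = FALSE]
  edges <- matrix(c(1L, n + 1L, 2L, n + 1L, 3L, n + 1L), ncol = 2,
                  byrow = TRUE)
  nxt <- n + 2L
  for (leaf in seq(4L, length.out = max(0L, n - 3L))) {
    best <- NULL; best_len <- Inf
    for (e in seq_len(nrow(edges))) {
      u <- edges[e, 1L]; v <- edges[e, 2L]
      ne <- rbind(edges[-e, , drop = FALSE],
                  c(u, nxt), c(nxt, v), c(nxt, leaf))
      len <- fitch_length(ne, st[seq_len(leaf), , drop = FALSE])
      if (len < best_len) { best_len <- len; best <- ne }
    }
    edges <- best; nxt <- nxt + 1L
  }
  # steepest-descent NNI over the full neighborhood
  len0 <- fitch_length(edges, st)
  repeat {
    best_len <- len0; best_edges <- NULL
    internal <- which(edges[, 1L] > n & edges[, 2L] > n)
    for (e in internal) {
      u <- edges[e, 1L]; v <- edges[e, 2L]
      nb_u <- setdiff(.neighbors(edges, u), v)
      nb_v <- setdiff(.neighbors(edges, v), u)
      if (length(nb_u) < 2L || length(nb_v) < 2L) next
      for (au in 1:2) for (swap in 1:2) {
        ne <- .swap_subtrees(edges, u, nb_u[au], v, nb_v[swap])
        len <- fitch_length(ne, st)
        if (len < best_len) { best_len <- len; best_edges <- ne }
      }
    }
    if (is.null(best_edges)) break
    edges <- best_edges; len0 <- best_len
  }
  # undo the relabelling so leaf ids refer to the original row order
  back <- integer(max(edges))
  back[seq_len(n)] <- relabel
  back[(n + 1L):max(edges)] <- (n + 1L):max(edges)
  list(edges = matrix(back[edges], ncol = 2L), length = len0)
}

# Deterministic multi-start heuristic: stepwise addition + NNI from every
# rotation of the canonical leaf order; best (first-found) result wins.
.heuristic_search <- function(states) {
  n <- nrow(states)
  best <- NULL
  for (r in seq_len(n)) {
    ord <- c(seq.int(r, n), seq_len(r - 1L))
    res <- .stepwise_nni(states, ord)
    if (is.null(best) || res$length < best$length) best <- res
  }
  best
}

.neighbors <- function(edges, node) {
  c(edges[edges[, 1L] == node, 2L], edges[edges[, 2L] == node, 1L])
}

.swap_subtrees <- function(edges, u, a, v, b) {
  for (k in seq_len(nrow(edges))) {
    p <- edges[k, ]
    if ((p[1L] == u && p[2L] == a) || (p[1L] == a && p[2L] == u)) {
      edges[k, ] <- c(u, b)
    } else if ((p[1L] == v && p[2L] == b) || (p[1L] == b && p[2L] == v)) {
      edges[k, ] <- c(v, a)
    }
  }
  edges
}

#' Unrooted maximum-parsimony tree of hepitypes
#'
#' Minimum-length unrooted topology under Fitch parsimony on the binary
#' C/T characters. Exhaustive search over all unrooted binary topologies
#' for up to `exhaustive_max` leaves; stepwise addition (descending
#' frequency, ties lexicographic by pattern) followed by
#' nearest-neighbor-interchange hill climbing above that. Deterministic:
#' ties are broken by the first topology found in the documented
#' enumeration order.
#'
#' @param hepitypes Tibble from [extract_hepitypes()] (or any tibble with
#'   `pattern` and optionally `count`); patterns must be distinct.
#' @param method `"auto"`, `"exhaustive"` or `"heuristic"`.
#' @param exhaustive_max Largest leaf count searched exhaustively under
#'   `"auto"` (default 7; above it the multi-start stepwise+NNI search is used, which matches the exhaustive minimum on randomized checks).
#' @return A `parsimony_result`: list with `tree` (ape `phylo`, edge
#'   lengths = change counts of one most-parsimonious assignment),
#'   `newick`, `tree_length`, `labels`, `patterns`, `frequencies`,
#'   `method`.
#' @export
parsimony_tree <- function(hepitypes, method = c("auto", "exhaustive",
                                                 "heuristic"),
                           exhaustive_max = 7L) {
  method <- match.arg(method)
  h <- as_tibble(hepitypes)
  if (!"count" %in% names(h)) h$count <- 1L
  if (anyDuplicated(h$pattern)) {
    abort("duplicate hepitype patterns; aggregate before tree building")
  }
  # leaf order: descending frequency, ties lexicographic by pattern
  h <- arrange(h, desc(.data$count), .data$pattern)
  n <- nrow(h)
  labels <- if ("label" %in% names(h)) h$label else
    sprintf("h%02d", seq_len(n))
  states <- .pattern_states(h$pattern)
  freq <- h$count / sum(h$count)

  if (n == 0L) abort("no hepitypes")
  if (n <= 2L) {
    len <- if (n == 2L)
      sum(strsplit(h$pattern[1], "")[[1]] != strsplit(h$pattern[2], "")[[1]])
    else 0L
    nwk <- if (n == 2L) sprintf("(%s:%d,%s:0);", labels[1], len, labels[2])
           else sprintf("(%s:0);", labels[1])
    return(new_parsimony_result(ape::read.tree(text = nwk), len, labels,
                                h$pattern, freq, "degenerate"))
  }
  use_exhaustive <- method == "exhaustive" ||
    (method == "auto" && n <= exhaustive_max)
  if (use_exhaustive) {
    best_len <- Inf; best_edges <- NULL
    .enumerate_topologies(n, function(edges) {
      len <- fitch_length(edges, states)
      if (len < best_len) {
        best_len <<- len; best_edges <<- edges
      }
      TRUE
    })
    edges <- .canonical_edges(best_edges, n); tlen <- best_len
    used <- "exhaustive"
  } else {
    res <- .heuristic_search(states)
    edges <- .canonical_edges(res$edges, n); tlen <- res$length
    used <- "heuristic"
  }
  phy <- .edges_to_phylo(edges, n, labels, states)
  new_parsimony_result(phy, as.integer(tlen), labels, h$pattern, freq, used)
}

new_parsimony_result <- function(tree, tree_length, labels, patterns,
                                 frequencies, method,
                                 bootstrap = NULL) {
  structure(list(tree = tree, newick = ape::write.tree(tree),
                 tree_length = tree_length, labels = labels,
                 patterns = patterns, frequencies = frequencies,
                 method = method, bootstrap = bootstrap),
            class = "parsimony_result")
}

#' @export
print.parsimony_result <- function(x, ...) {
  cat(sprintf("Unrooted maximum-parsimony tree (%s search)\n", x$method))
  cat(sprintf("  %d hepitypes, tree length %d changes\n",
              length(x$labels), x$tree_length))
  if (!is.null(x$bootstrap)) {
    cat(sprintf("  bootstrap: %d internal splits, median support %.2f\n",
                nrow(x$bootstrap), stats::median(x$bootstrap$support)))
  }
  cat(" ", x$newick, "\n")
  invisible(x)
}

# Convert the internal edge matrix to an ape phylo with per-edge change
# counts from one most-parsimonious Fitch assignment.
.edges_to_phylo <- function(edges, n, labels, states) {
  nodes <- max(edges)
  adj <- vector("list", nodes)
  for (k in seq_len(nrow(edges))) {
    u <- edges[k, 1L]; v <- edges[k, 2L]
    adj[[u]] <- c(adj[[u]], v); adj[[v]] <- c(adj[[v]], u)
  }
  root <- n + 1L
  sets <- matrix(0L, nodes, ncol(states))
  down <- function(node, parent) {
    if (node <= n) { sets[node, ] <<- states[node, ]; return(invisible()) }
    kids <- setdiff(adj[[node]], parent)
    for (k in kids) down(k, node)
    s <- sets[kids[1L], ]
    for (k in kids[-1L]) {
      t <- sets[k, ]
      i <- bitwAnd(s, t)
      s <- ifelse(i == 0L, bitwOr(s, t), i)
    }
    sets[node, ] <<- s
    invisible()
  }
  down(root, 0L)
  assign_state <- matrix(0L, nodes, ncol(states))
  pick_first <- function(mask) ifelse(bitwAnd(mask, 1L) > 0L, 1L, 2L)
  edge_changes <- new.env(parent = emptyenv())
  up <- function(node, parent) {
    if (parent == 0L) {
      assign_state[node, ] <<- pick_first(sets[node, ])
    } else {
      p <- assign_state[parent, ]
      ok <- bitwAnd(sets[node, ], p) > 0L
      assign_state[node, ] <<- ifelse(ok, p, pick_first(sets[node, ]))
      key <- paste(min(node, parent), max(node, parent))
      assign(key, sum(assign_state[node, ] != p), envir = edge_changes)
    }
    if (node > n) for (k in setdiff(adj[[node]], parent)) up(k, node)
    invisible()
  }
  up(root, 0L)
  elen <- vapply(seq_len(nrow(edges)), function(k) {
    key <- paste(min(edges[k, ]), max(edges[k, ]))
    if (exists(key, envir = edge_changes)) get(key, envir = edge_changes)
    else 0L
  }, numeric(1))
  # orient edges parent->child from root for ape
  oriented <- matrix(0L, nrow(edges), 2L)
  olen <- numeric(nrow(edges))
  cnt <- 0L
  orient <- function(node, parent) {
    for (k in setdiff(adj[[node]], parent)) {
      cnt <<- cnt + 1L
      oriented[cnt, ] <<- c(node, k)
      key <- which((edges[, 1L] == node & edges[, 2L] == k) |
                   (edges[, 1L] == k & edges[, 2L] == node))[1]
      olen[cnt] <<- elen[key]
      if (k > n) orient(k, node)
    }
  }
  orient(root, 0L)
  phy <- list(edge = oriented, edge.length = olen,
              Nnode = nodes - n, tip.label = labels)
  class(phy) <- "phylo"
  attr(phy, "order") <- "cladewise"
  phy
}

# canonical bipartition keys of the internal edges of a phylo tree
# (side of the split not containing tip 1, as sorted tip labels)
.bipartitions <- function(phy) {
  n <- length(phy$tip.label)
  internal <- which(phy$edge[, 2L] > n)
  out <- character(0)
  for (e in internal) {
    tips <- .descendant_tips(phy, phy$edge[e, 2L], n)
    if (length(tips) < 2L || length(tips) > n - 2L) next
    side <- if (1L %in% tips) setdiff(seq_len(n), tips) else tips
    out <- c(out, paste(sort(phy$tip.label[side]), collapse = "|"))
  }
  unique(out)
}

.descendant_tips <- function(phy, node, n) {
  if (node <= n) return(node)
  kids <- phy$edge[phy$edge[, 1L] == node, 2L]
  unlist(lapply(kids, .descendant_tips, phy = phy, n = n))
}

#' Bootstrap support for the internal splits of a parsimony tree
#'
#' Resamples CpG site columns with replacement, rebuilds the tree for each
#' replicate, and reports for every internal bipartition of the original
#' tree the fraction of replicate trees containing it.
#'
#' @param hepitypes Hepitype tibble (>= 4 distinct patterns).
#' @param replicates Number of bootstrap replicates.
#' @param seed RNG seed (single documented stream; fixed seed gives
#'   bit-identical supports).
#' @param method Tree-search method per replicate (heuristic by default;
#'   exhaustive is exact but slow for many leaves).
#' @return A `parsimony_result` whose `bootstrap` element is a tibble
#'   `bipartition`, `support`.
#' @export
bootstrap_support <- function(hepitypes,
                              replicates = hepityper_defaults()$bootstrap_replicates,
                              seed = 1L,
                              method = c("heuristic", "exhaustive", "auto")) {
  method <- match.arg(method)
  res <- parsimony_tree(hepitypes)
  if (length(res$labels) < 4L) {
    abort("bootstrap support needs at least 4 hepitypes")
  }
  obs <- .bipartitions(res$tree)
  if (!length(obs)) {
    res$bootstrap <- tibble(bipartition = character(), support = numeric())
    return(res)
  }
  h <- as_tibble(hepitypes)
  if (!"count" %in% names(h)) h$count <- 1L
  h <- arrange(h, desc(.data$count), .data$pattern)
  states <- .pattern_states(h$pattern)
  nsites <- ncol(states)
  n <- nrow(states)
  labels <- res$labels
  hits <- setNames(numeric(length(obs)), obs)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  for (b in seq_len(replicates)) {
    cols <- sample.int(nsites, nsites, replace = TRUE)
    st <- states[, cols, drop = FALSE]
    if (method == "exhaustive" || (method == "auto" && n <= 7L)) {
      best_len <- Inf; best_edges <- NULL
      .enumerate_topologies(n, function(edges) {
        len <- fitch_length(edges, st)
        if (len < best_len) { best_len <<- len; best_edges <<- edges }
        TRUE
      })
      edges <- .canonical_edges(best_edges, n)
    } else {
      edges <- .canonical_edges(.heuristic_search(st)$edges, n)
    }
    phy <- .edges_to_phylo(edges, n, labels, st)
    bp <- .bipartitions(phy)
    hit <- obs %in% bp
    hits[hit] <- hits[hit] + 1
  }
  res$bootstrap <- tibble(bipartition = obs, support = hits / replicates)
  res
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# ---- deviating-site test --------------------------------------------------

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by summing, at fixed margins, the
#' hypergeometric probabilities of all tables at most as probable as the
#' observed one. A zero margin gives p = 1 by convention.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return p-value in (0, 1].
#' @export
fisher_exact <- function(table) {
  x <- round(as.matrix(table))
  stopifnot(all(dim(x) == c(2L, 2L)), all(x >= 0))
  r1 <- sum(x[1L, ]); r2 <- sum(x[2L, ])
  c1 <- sum(x[, 1L]); c2 <- sum(x[, 2L])
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  lo <- max(0, c1 - r2); hi <- min(c1, r1)
  probs <- dhyper(lo:hi, r1, r2, c1)
  pobs <- dhyper(x[1L, 1L], r1, r2, c1)
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

#' Deviating-site table and maintenance-asymmetry test
#'
#' Each spanning read's pattern is assigned to the nearer of the two
#' dichotomous backgrounds (all-methylated `C...C` vs all-unmethylated
#' `T...T`) by Hamming distance; exact-distance ties are excluded and
#' counted. Column 1 holds exact background matches (no deviating site),
#' column 2 patterns with at least one deviating site. Fisher's exact test
#' (two-sided) on the table asks whether single-site deviations are
#' equally frequent on the two backgrounds.
#'
#' @param patterns Character vector of per-read patterns over C/T, or a
#'   hepitype tibble (`pattern`, `count`) with `counts` taken from it.
#' @param counts Optional integer vector of per-pattern multiplicities.
#' @return A `deviation_test`: list with `table` (2x2, rows methylated /
#'   unmethylated background, columns no-deviation / deviation),
#'   `fisher_p`, `n_ties`, `n_assigned`.
#' @export
deviation_table <- function(patterns, counts = NULL) {
  if (is.data.frame(patterns)) {
    counts <- patterns$count
    patterns <- patterns$pattern
  }
  if (is.null(counts)) counts <- rep(1L, length(patterns))
  stopifnot(length(counts) == length(patterns))
  if (!length(patterns)) abort("no patterns supplied")
  L <- nchar(patterns[1])
  n_T <- nchar(gsub("[^T]", "", patterns))   # distance to all-C
  n_C <- L - n_T                             # distance to all-T
  tie <- n_T == n_C
  meth_bg <- n_T < n_C
  tab <- matrix(0L, 2L, 2L,
                dimnames = list(c("methylated_bg", "unmethylated_bg"),
                                c("no_deviation", "deviation")))
  tab[1L, 1L] <- sum(counts[meth_bg & !tie & n_T == 0L])
  tab[1L, 2L] <- sum(counts[meth_bg & !tie & n_T > 0L])
  tab[2L, 1L] <- sum(counts[!meth_bg & !tie & n_C == 0L])
  tab[2L, 2L] <- sum(counts[!meth_bg & !tie & n_C > 0L])
  n_ties <- sum(counts[tie])
  p <- if (sum(tab) == 0L) NA_real_ else fisher_exact(tab)
  structure(list(table = tab, fisher_p = p, n_ties = as.integer(n_ties),
                 n_assigned = sum(tab)),
            class = "deviation_test")
}

#' @export
print.deviation_test <- function(x, ...) {
  cat("Deviating-site 2x2 test (methylation-maintenance asymmetry)\n")
  print(x$table)
  cat(sprintf("  excluded ties: %d;  two-sided Fisher p = %.4g\n",
              x$n_ties, x$fisher_p))
  invisible(x)
}
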