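# Pairwise rank-overlap scan: every unordered TF pair is scored by the
# minimum hypergeometric overlap p-value over a grid of top-list cutoffs
# (L1, L2). The minimum over the grid is reported, uncorrected, as a
# similarity score between the two ranked target lists.

#' Default top-list cutoff grid: 10, 20, ..., 1000
#' @return integer vector of 100 thresholds.
#' @export
default_grid <- function() seq(10L, 1000L, by = 10L)

#' Enumerate all unordered TF pairs
#' @param tfs character vector of distinct TF ids.
#' @return data.frame with columns `tf_a`, `tf_b` (`tf_a < tf_b`), sorted;
#'   exactly `n(n-1)/2` rows.
#' @export
enumerate_pairs <- function(tfs) {
  if (anyDuplicated(tfs))
    stopf("duplicate TF ids: %s",
          paste(unique(tfs[duplicated(tfs)]), collapse = ", "))
  if (length(tfs) < 2L) stopf("need at least 2 TFs")
  s <- sort(tfs, method = "radix")
  idx <- which(lower.tri(diag(length(s))), arr.ind = TRUE)
  out <- data.frame(tf_a = s[idx[, "col"]], tf_b = s[idx[, "row"]],
                    stringsAsFactors = FALSE)
  out[order(out$tf_a, out$tf_b, method = "radix"), , drop = FALSE]
}

#' Upper-tail hypergeometric overlap p-value
#'
#' Probability of observing at least `k` shared genes between a top-`L1`
#' and a top-`L2` set drawn from a universe of `N` genes (inclusive upper
#' tail, `P(K >= k)`). Computed in log space so tails far below 1e-20 do
#' not underflow.
#'
#' @param N universe size.
#' @param L1,L2 top-list sizes, each in `[0, N]`.
#' @param k observed overlap, `max(0, L1+L2-N) <= k <= min(L1, L2)`.
#' @param log10p return log10 of the p-value instead of the p-value.
#' @return p-value in (0, 1], or its log10.
#' @export
hypergeom_overlap_p <- function(N, L1, L2, k, log10p = FALSE) {
  if (any(c(N, L1, L2, k) < 0) || L1 > N || L2 > N)
    stopf("require 0 <= L1, L2 <= N")
  if (k > min(L1, L2) || k < max(0, L1 + L2 - N))
    stopf("infeasible overlap k = %d for N = %d, L1 = %d, L2 = %d",
          k, N, L1, L2)
  lp <- phyper(k - 1, L2, N - L2, L1, lower.tail = FALSE, log.p = TRUE)
  if (log10p) lp / log(10) else exp(lp)
}

# Overlap counts at every grid cell from two gene->rank maps, by bucketed
# 2D cumulative counting: O(N + |grid|^2) instead of |grid|^2 rescans.
.grid_overlap_counts <- function(rank_a, rank_b, grid) {
  G <- length(grid)
  ba <- findInterval(rank_a, c(0, grid), left.open = TRUE)
  bb <- findInterval(rank_b, c(0, grid), left.open = TRUE)
  keep <- ba <= G & bb <= G
  M <- matrix(0L, G, G)
  if (any(keep)) {
    tab <- tabulate((ba[keep] - 1L) * G + bb[keep], nbins = G * G)
    M <- matrix(tab, G, G, byrow = TRUE)
  }
  t(apply(apply(M, 2L, cumsum), 1L, cumsum))  # C[i,j] = overlap(top grid[i], top grid[j])
}

.grid_scan_ranks <- function(rank_a, rank_b, grid, N) {
  G <- length(grid)
  K <- .grid_overlap_counts(rank_a, rank_b, grid)
  L1 <- matrix(grid, G, G)              # rows: list-a cutoff
  L2 <- matrix(grid, G, G, byrow = TRUE)
  lp <- matrix(phyper(as.vector(K) - 1, as.vector(L2),
                      N - as.vector(L2), as.vector(L1),
                      lower.tail = FALSE, log.p = TRUE) / log(10), G, G)
  best <- which(lp == min(lp), arr.ind = TRUE)
  best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE][1L, ]
  list(best_L1 = grid[best[1L]], best_L2 = grid[best[2L]],
       overlap_k = K[best[1L], best[2L]],
       min_log10_p = lp[best[1L], best[2L]], log10_p_grid = lp,
       overlap_grid = K)
}

#' Grid scan of one TF pair
#'
#' Evaluates the hypergeometric overlap p-value at every `(L1, L2)` cell of
#' `grid x grid` and returns the minimum (the pair's similarity score).
#' Equal minima are resolved to the smallest `L1`, then smallest `L2`.
#' Overlaps are counted incrementally, so the cost is
#' `O(|universe| + |grid|^2)`.
#'
#' @param ranks_a,ranks_b `ranked_targets` over the same gene universe.
#' @param grid strictly increasing positive cutoffs, all `<=` universe size.
#' @return a `pair_scan_result`: `tf_a`, `tf_b` (canonical order),
#'   `best_L1`, `best_L2`, `overlap_k`, `min_log10_p`, `universe_n`.
#' @export
grid_scan <- function(ranks_a, ranks_b, grid = default_grid()) {
  stopifnot(inherits(ranks_a, "ranked_targets"),
            inherits(ranks_b, "ranked_targets"))
  if (length(ranks_a$genes) != length(ranks_b$genes) ||
      !setequal(ranks_a$genes, ranks_b$genes))
    stopf("ranked lists are over different gene universes")
  .validate_grid(grid, length(ranks_a$genes))
  if (ranks_a$tf_id > ranks_b$tf_id) { tmp <- ranks_a; ranks_a <- ranks_b; ranks_b <- tmp }
  N <- length(ranks_a$genes)
  rank_b <- match(ranks_a$genes, ranks_b$genes)
  res <- .grid_scan_ranks(seq_len(N), rank_b, grid, N)
  structure(list(tf_a = ranks_a$tf_id, tf_b = ranks_b$tf_id,
                 best_L1 = res$best_L1, best_L2 = res$best_L2,
                 overlap_k = res$overlap_k,
                 min_log10_p = res$min_log10_p, universe_n = N),
            class = "pair_scan_result")
}

.validate_grid <- function(grid, N) {
  if (length(grid) == 0L || any(grid <= 0) || is.unsorted(grid, strictly = TRUE))
    stopf("grid must be strictly increasing positive integers")
  if (max(grid) > N)
    stopf("grid maximum (%d) exceeds universe size (%d)", max(grid), N)
  invisible(grid)
}

#' @export
print.pair_scan_result <- function(x, ...) {
  cat(sprintf("<pair_scan_result> %s:%s log10p = %.3f at (L1 = %d, L2 = %d), k = %d, N = %d\n",
              x$tf_a, x$tf_b, x$min_log10_p, x$best_L1, x$best_L2,
              x$overlap_k, x$universe_n))
  invisible(x)
}

#' Grid scan of every unordered TF pair
#'
#' @param lists named list of `ranked_targets` (one per TF) over a common
#'   universe.
#' @param grid cutoff grid, as in [grid_scan()].
#' @param verbose progress messages.
#' @return data.frame with one row per pair, columns `tf_a`, `tf_b`,
#'   `best_L1`, `best_L2`, `overlap_k`, `min_log10_p`, `universe_n`,
#'   ordered by `(tf_a, tf_b)`.
#' @export
scan_all_pairs <- function(lists, grid = default_grid(), verbose = FALSE) {
  pairs <- enumerate_pairs(names(lists))
  universe <- sort(lists[[1L]]$genes, method = "radix")
  N <- length(universe)
  .validate_grid(grid, N)
  ranks <- lapply(lists, function(l) {
    if (!identical(sort(l$genes, method = "radix"), universe))
      stopf("TF '%s' is ranked over a different gene universe", l$tf_id)
    match(universe, l$genes)
  })
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$tf_a[i]; b <- pairs$tf_b[i]
    res <- .grid_scan_ranks(ranks[[a]], ranks[[b]], grid, N)
    out[[i]] <- data.frame(tf_a = a, tf_b = b, best_L1 = res$best_L1,
                           best_L2 = res$best_L2, overlap_k = res$overlap_k,
                           min_log10_p = res$min_log10_p, universe_n = N,
                           stringsAsFactors = FALSE)
    if (verbose && i %% 500L == 0L)
      msg(sprintf("scanned %d/%d pairs", i, nrow(pairs)))
  }
  do.call(rbind, out)
}

#' Write pair-scan results as TSV, sorted by ascending log10 p
#' @param results data.frame from [scan_all_pairs()].
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_pairs_tsv <- function(results, path) {
  o <- order(results$min_log10_p, results$tf_a, results$tf_b)
  write.table(results[o, , drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read pair-scan results TSV
#' @param path TSV path written by [write_pairs_tsv()].
#' @return data.frame of pair results.
#' @export
read_pairs_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
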