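# Tissue-coupled co-targeting: 2x2x2 contingency tables over
#   X = gene in TF-a's top-L targets, Y = gene in TF-b's top-L targets,
#   Z = gene specific for the tissue,
# tested for partial independence of the composite XY from Z with the
# log-likelihood-ratio (G) statistic, chi-square with 3 df. Rejection with
# an excess of genes in the (top, top, tissue) cell signals that the two
# TFs share tissue-specific targets beyond chance.

.XY_LEVELS <- c("top", "not_top")
.Z_LEVELS <- c("tissue", "not_tissue")

#' Build a 2x2x2 table from two top target sets and a tissue gene set
#'
#' Cell `mu[x, y, z]` counts universe genes by joint membership:
#' index 1 = in the set ("top" / "tissue"), index 2 = not. Tissue genes
#' absent from the universe are dropped with a warning.
#'
#' @param top_a,top_b character vectors of top-ranked target genes (subsets
#'   of `universe`).
#' @param tissue_genes character vector of tissue-specific genes.
#' @param universe all genes under consideration (the promoter set).
#' @param labels optional character vector `c(tf_a, tf_b, tissue)`.
#' @return a `three_way_table`: fields `mu` (2x2x2 array), `n`, `labels`,
#'   `dropped_tissue_genes`.
#' @export
build_table <- function(top_a, top_b, tissue_genes, universe,
                        labels = c(tf_a = "tf_a", tf_b = "tf_b",
                                   tissue = "tissue")) {
  if (length(universe) == 0L) stopf("empty gene universe")
  if (anyDuplicated(universe)) stopf("duplicated genes in universe")
  bad_a <- setdiff(top_a, universe); bad_b <- setdiff(top_b, universe)
  if (length(bad_a) || length(bad_b))
    stopf("top target genes outside the universe: %s",
          paste(head(c(bad_a, bad_b), 5L), collapse = ", "))
  dropped <- setdiff(tissue_genes, universe)
  if (length(dropped))
    warnf("%d tissue gene(s) absent from the universe were dropped",
          length(dropped))
  x <- universe %in% top_a
  y <- universe %in% top_b
  z <- universe %in% tissue_genes
  mu <- array(0L, dim = c(2L, 2L, 2L),
              dimnames = list(X = .XY_LEVELS, Y = .XY_LEVELS, Z = .Z_LEVELS))
  for (xi in 1:2) for (yi in 1:2) for (zi in 1:2)
    mu[xi, yi, zi] <- sum((x == (xi == 1L)) & (y == (yi == 1L)) &
                          (z == (zi == 1L)))
  three_way_table(mu, labels = labels,
                  dropped_tissue_genes = length(dropped))
}

#' Construct/validate a 2x2x2 contingency table object
#' @param mu 2x2x2 array of nonnegative integer counts.
#' @param labels optional `c(tf_a, tf_b, tissue)` labels.
#' @param dropped_tissue_genes bookkeeping count of dropped ids.
#' @return a `three_way_table`.
#' @export
three_way_table <- function(mu, labels = c(tf_a = "tf_a", tf_b = "tf_b",
                                           tissue = "tissue"),
                            dropped_tissue_genes = 0L) {
  mu <- array(as.numeric(mu), dim = c(2L, 2L, 2L),
              dimnames = list(X = .XY_LEVELS, Y = .XY_LEVELS, Z = .Z_LEVELS))
  if (any(mu < 0) || any(!is.finite(mu)) || any(mu != round(mu)))
    stopf("table cells must be nonnegative integers")
  structure(list(mu = mu, n = sum(mu), labels = labels,
                 dropped_tissue_genes = dropped_tissue_genes),
            class = "three_way_table")
}

#' @export
print.three_way_table <- function(x, ...) {
  cat(sprintf("<three_way_table> %s:%s in %s, n = %d, mu_111 = %d\n",
              x$labels[[1L]], x$labels[[2L]], x$labels[[3L]], x$n,
              x$mu[1L, 1L, 1L]))
  invisible(x)
}

#' Expected cell frequencies under partial independence of XY and Z
#'
#' `mu_hat[x, y, z] = mu_ppz * mu_xyp / n`, the maximum-likelihood fit of
#' the log-linear model in which the composite (X, Y) is independent of Z.
#' Preserves the total, every xy two-way marginal and the z one-way
#' marginal exactly.
#'
#' @param t a `three_way_table`.
#' @return 2x2x2 array of expected frequencies.
#' @export
expected_partial_independence <- function(t) {
  stopifnot(inherits(t, "three_way_table"))
  if (t$n <= 0) stopf("empty table")
  mu_xy <- apply(t$mu, c(1L, 2L), sum)           # xy two-way marginal
  mu_z <- apply(t$mu, 3L, sum)                   # z one-way marginal
  out <- outer(mu_xy, mu_z) / t$n
  dimnames(out) <- dimnames(t$mu)
  out
}

#' G-test of partial independence (XY vs Z), df = 3
#'
#' Statistic `G = 2 * sum mu * log(mu / mu_hat)` with the `0 log 0 = 0`
#' convention (natural logarithm), referred to the upper tail of the
#' chi-square distribution with 3 degrees of freedom. The enrichment flag
#' records whether the (top, top, tissue) cell exceeds its expectation —
#' the direction the interaction calls require.
#'
#' @param t a `three_way_table`.
#' @return a `tissue_test_result`: `labels`, `g_stat`, `df` (3), `log10_p`,
#'   `observed_111`, `expected_111`, `enriched`.
#' @export
partial_independence_test <- function(t) {
  stopifnot(inherits(t, "three_way_table"))
  mu_hat <- expected_partial_independence(t)
  if (any(t$mu > 0 & mu_hat <= 0))
    stopf("internal consistency error: observed count with zero expectation")
  pos <- t$mu > 0
  g <- 2 * sum(t$mu[pos] * log(t$mu[pos] / mu_hat[pos]))
  g <- max(g, 0)
  structure(list(labels = t$labels, g_stat = g, df = 3L,
                 log10_p = pchisq(g, df = 3L, lower.tail = FALSE,
                                  log.p = TRUE) / log(10),
                 observed_111 = as.integer(t$mu[1L, 1L, 1L]),
                 expected_111 = mu_hat[1L, 1L, 1L],
                 enriched = t$mu[1L, 1L, 1L] > mu_hat[1L, 1L, 1L]),
            class = "tissue_test_result")
}

#' @export
print.tissue_test_result <- function(x, ...) {
  cat(sprintf(
    "<tissue_test_result> %s:%s in %s: G = %.4g (df %d), log10 p = %.3f, mu_111 = %d (exp %.2f)%s\n",
    x$labels[[1L]], x$labels[[2L]], x$labels[[3L]], x$g_stat, x$df,
    x$log10_p, x$observed_111, x$expected_111,
    if (x$enriched) ", enriched" else ""))
  invisible(x)
}

#' Companion statistics: mutual and conditional independence
#'
#' The two other classical hypotheses on a 2x2x2 table — (a) mutual
#' independence of X, Y, Z (df 4) and (b) conditional independence of X
#' and Y given Z (df 2) — provided for completeness of the test family.
#' They are not used by the interaction-calling pipeline.
#'
#' @param t a `three_way_table`.
#' @param hypothesis `"mutual"` or `"conditional"`.
#' @return list with `g_stat`, `df`, `log10_p`.
#' @export
threeway_alternative_test <- function(t, hypothesis = c("mutual",
                                                        "conditional")) {
  stopifnot(inherits(t, "three_way_table"))
  hypothesis <- match.arg(hypothesis)
  if (hypothesis == "mutual") {
    mx <- apply(t$mu, 1L, sum); my <- apply(t$mu, 2L, sum)
    mz <- apply(t$mu, 3L, sum)
    mu_hat <- outer(outer(mx, my), mz) / t$n^2
    df <- 4L
  } else {
    mz <- apply(t$mu, 3L, sum)
    mu_hat <- array(0, dim = dim(t$mu))
    for (zi in 1:2) {
      mxz <- apply(t$mu[, , zi, drop = FALSE], 1L, sum)
      myz <- apply(t$mu[, , zi, drop = FALSE], 2L, sum)
      if (mz[zi] > 0) mu_hat[, , zi] <- outer(mxz, myz) / mz[zi]
    }
    df <- 2L
  }
  pos <- t$mu > 0
  g <- max(2 * sum(t$mu[pos] * log(t$mu[pos] / mu_hat[pos])), 0)
  list(g_stat = g, df = df,
       log10_p = pchisq(g, df = df, lower.tail = FALSE, log.p = TRUE) / log(10))
}

#' Read tissue gene sets
#'
#' Accepts either a directory of per-tissue plain-text files (one gene id
#' per line; tissue name = file name without extension) or a single
#' two-column TSV `(tissue, gene)`.
#'
#' @param path directory or TSV file path.
#' @return named list of character vectors (one per tissue).
#' @export
read_tissue_sets <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, full.names = TRUE)
    if (length(files) == 0L) stopf("no tissue files in %s", path)
    out <- lapply(files, function(f) unique(trimws(readLines(f))))
    names(out) <- tools::file_path_sans_ext(basename(files))
  } else {
    df <- read.table(path, sep = "\t", header = FALSE,
                     stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stopf("tissue TSV needs (tissue, gene) columns")
    out <- lapply(split(df[[2L]], df[[1L]]), unique)
  }
  lapply(out, function(g) g[nzchar(g)])
}

#' Write tissue gene sets as a two-column (tissue, gene) TSV
#' @param tissues named list of gene id vectors.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_tissue_tsv <- function(tissues, path) {
  df <- data.frame(tissue = rep(names(tissues), lengths(tissues)),
                   gene_id = unlist(tissues, use.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Tissue-stratified partial-independence scan of all TF pairs
#'
#' For every tissue and every unordered TF pair, builds the 2x2x2 table
#' from the two top-`L` target sets and the tissue gene set, runs the
#' partial-independence G-test, and annotates motif similarity when a
#' similarity matrix is supplied.
#'
#' @param lists named list of `ranked_targets` over a common universe.
#' @param tissues named list of tissue-specific gene sets.
#' @param L top-list length (default 1000; chosen against the small size
#'   of tissue sets relative to the promoter universe).
#' @param sim optional `similarity_matrix` for annotation.
#' @param cutoff similarity cutoff for the `similar_flag` column
#'   (strict `<` keeps a pair nonsimilar).
#' @param verbose progress messages.
#' @return data.frame ordered by (tissue, tf_a, tf_b) with columns
#'   `tissue`, `tf_a`, `tf_b`, `mu_111`, `expected_111`, `g_stat`,
#'   `log10_p`, `similarity`, `similar_flag`, `enriched`.
#' @export
tissue_scan <- function(lists, tissues, L = 1000L, sim = NULL, cutoff = 4,
                        verbose = FALSE) {
  universe <- lists[[1L]]$genes
  if (L > length(universe))
    stopf("L = %d exceeds universe size %d", L, length(universe))
  pairs <- enumerate_pairs(names(lists))
  tops <- lapply(lists, function(l) l$genes[seq_len(L)])
  tissue_names <- sort(names(tissues), method = "radix")
  out <- vector("list", length(tissue_names) * nrow(pairs))
  k <- 0L
  for (tn in tissue_names) {
    tg <- intersect(tissues[[tn]], universe)
    n_dropped <- length(setdiff(tissues[[tn]], universe))
    if (n_dropped > 0L)
      msg(sprintf("tissue %s: %d gene(s) outside the universe dropped",
                  tn, n_dropped), verbose = verbose)
    zin <- universe %in% tg
    for (i in seq_len(nrow(pairs))) {
      a <- pairs$tf_a[i]; b <- pairs$tf_b[i]
      tab <- .fast_table(universe %in% tops[[a]], universe %in% tops[[b]],
                         zin, labels = c(tf_a = a, tf_b = b, tissue = tn))
      res <- partial_independence_test(tab)
      k <- k + 1L
      out[[k]] <- data.frame(tissue = tn, tf_a = a, tf_b = b,
                             mu_111 = res$observed_111,
                             expected_111 = res$expected_111,
                             g_stat = res$g_stat, log10_p = res$log10_p,
                             enriched = res$enriched,
                             stringsAsFactors = FALSE)
    }
    msg(sprintf("tissue %s: %d pairs tested", tn, nrow(pairs)),
        verbose = verbose)
  }
  res <- do.call(rbind, out)
  if (!is.null(sim)) {
    res$similarity <- pair_similarity(sim, res$tf_a, res$tf_b)
    res$similar_flag <- !(res$similarity < cutoff)
  } else {
    res$similarity <- NA_real_
    res$similar_flag <- FALSE
  }
  res[order(res$tissue, res$tf_a, res$tf_b, method = "radix"),
      c("tissue", "tf_a", "tf_b", "mu_111", "expected_111", "g_stat",
        "log10_p", "similarity", "similar_flag", "enriched")]
}

# three_way_table from logical membership vectors without set operations.
.fast_table <- function(x, y, z, labels) {
  idx <- 1L + (!x) + 2L * (!y) + 4L * (!z)
  mu <- array(tabulate(idx, nbins = 8L), dim = c(2L, 2L, 2L),
              dimnames = list(X = .XY_LEVELS, Y = .XY_LEVELS,
                              Z = .Z_LEVELS))
  three_way_table(mu, labels = labels)
}

#' Write tissue-scan results as TSV
#' @param results data.frame from [tissue_scan()].
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_tissue_results_tsv <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read tissue-scan results TSV
#' @param path TSV path written by [write_tissue_results_tsv()].
#' @return data.frame of tissue test results.
#' @export
read_tissue_results_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
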