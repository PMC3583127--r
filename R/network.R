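# Interaction calling, evidence annotation against known PPIs, network
# construction with hub reporting, and Fisher-exact PPI enrichment.

#' Default log10 p-value thresholds per context
#'
#' Global (untissued) calls use 1e-20; tissue contexts 1e-6; homogeneous
#' cell-line contexts 1e-11 (their larger specific-gene sets produce more
#' significant pairs at a given error level).
#' @return named numeric vector of log10 thresholds.
#' @export
default_thresholds <- function() {
  c(global = -20, tissue = -6, cell_line = -11)
}

#' Threshold scan results into interaction calls
#'
#' Keeps rows with `log10 p <= threshold`; tissue-scan rows additionally
#' require `enriched = TRUE` (the observed (top, top, tissue) count must
#' exceed its expectation — the omnibus G-test alone is directionless).
#'
#' @param results data.frame from [scan_all_pairs()] (column
#'   `min_log10_p`) or [tissue_scan()] (columns `log10_p`, `enriched`,
#'   `tissue`).
#' @param threshold_log10_p log10 p-value cutoff; `NULL` picks the
#'   context default from [default_thresholds()].
#' @param context `"global"`, `"tissue"` or `"cell_line"`; contexts other
#'   than global take the per-row `tissue` column as the call context.
#' @return data.frame of calls with columns `tf_a`, `tf_b`, `context`,
#'   `log10_p`, `similarity`, `similar_flag`.
#' @export
call_interactions <- function(results, threshold_log10_p = NULL,
                              context = c("global", "tissue",
                                          "cell_line")) {
  context <- match.arg(context)
  thr <- threshold_log10_p %||% unname(default_thresholds()[context])
  if (thr > 0) stopf("threshold must be given as log10 p <= 0")
  is_tissue <- "tissue" %in% names(results)
  lp <- if (is_tissue) results$log10_p else results$min_log10_p
  keep <- lp <= thr
  if (is_tissue) keep <- keep & results$enriched
  out <- data.frame(
    tf_a = results$tf_a[keep], tf_b = results$tf_b[keep],
    context = if (is_tissue) results$tissue[keep] else "global",
    log10_p = lp[keep],
    similarity = if ("similarity" %in% names(results))
      results$similarity[keep] else NA_real_,
    similar_flag = if ("similar_flag" %in% names(results))
      results$similar_flag[keep] else FALSE,
    stringsAsFactors = FALSE)
  out[order(out$context, out$log10_p, out$tf_a, out$tf_b), , drop = FALSE]
}

#' Read a known-PPI edge list from TSV
#' @param path two-column TSV (tf_a, tf_b), no header; extra columns
#'   ignored.
#' @return data.frame of canonically ordered unique edges.
#' @export
read_ppi_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stopf("PPI TSV needs two columns")
  canon <- as.data.frame(canonical_pair(df[[1L]], df[[2L]]),
                         stringsAsFactors = FALSE)
  unique(canon[canon$tf_a != canon$tf_b, , drop = FALSE])
}

#' Annotate calls with known-PPI and trio evidence
#'
#' A call is `known_ppi` when the pair itself is a known PPI edge, and
#' `trio` when both TFs share at least one known interaction partner other
#' than themselves (a common co-factor); all such partners are listed.
#'
#' @param calls data.frame with `tf_a`, `tf_b`.
#' @param ppi_edges data.frame of known PPI edges (see [read_ppi_tsv()]).
#' @return `calls` with added columns `known_ppi`, `trio` (logical),
#'   `shared_cofactors` (comma-separated ids, `""` when none) and
#'   `evidence` (comma-separated evidence kinds).
#' @export
annotate_evidence <- function(calls, ppi_edges) {
  edges <- as.data.frame(canonical_pair(ppi_edges$tf_a, ppi_edges$tf_b),
                         stringsAsFactors = FALSE)
  keys <- pair_key(edges$tf_a, edges$tf_b)
  partners <- function(tf)
    unique(c(edges$tf_b[edges$tf_a == tf], edges$tf_a[edges$tf_b == tf]))
  calls$known_ppi <- pair_key(calls$tf_a, calls$tf_b) %in% keys
  cof <- character(nrow(calls)); trio <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    shared <- setdiff(intersect(partners(calls$tf_a[i]),
                                partners(calls$tf_b[i])),
                      c(calls$tf_a[i], calls$tf_b[i]))
    shared <- sort(shared, method = "radix")
    trio[i] <- length(shared) > 0L
    cof[i] <- paste(shared, collapse = ",")
  }
  calls$trio <- trio
  calls$shared_cofactors <- cof
  calls$evidence <- vapply(seq_len(nrow(calls)), function(i)
    paste(c("known_ppi", "trio")[c(calls$known_ppi[i], calls$trio[i])],
          collapse = ","), character(1L))
  calls
}

#' Enrichment of known PPIs among called pairs
#'
#' Cross-tabulates (called vs not) x (known PPI vs not) over all tested
#' pairs; fold change is the PPI fraction among calls over the PPI
#' fraction among all tested pairs, and significance is the one-sided
#' (upper tail) Fisher exact test.
#'
#' @param calls data.frame with `tf_a`, `tf_b` (subset of
#'   `all_tested_pairs`).
#' @param all_tested_pairs data.frame with `tf_a`, `tf_b`: the universe of
#'   tested pairs.
#' @param ppi_edges data.frame of known PPI edges.
#' @return list with `fold` (NA when the universe holds no PPI pair),
#'   `fisher_p`, `counts` (2x2 matrix), `ppi_fraction_called`,
#'   `ppi_fraction_universe`.
#' @export
ppi_enrichment <- function(calls, all_tested_pairs, ppi_edges) {
  ukeys <- unique(pair_key(all_tested_pairs$tf_a, all_tested_pairs$tf_b))
  ckeys <- unique(pair_key(calls$tf_a, calls$tf_b))
  if (!all(ckeys %in% ukeys))
    stopf("calls contain pairs outside the tested universe")
  pkeys <- pair_key(ppi_edges$tf_a, ppi_edges$tf_b)
  called <- ukeys %in% ckeys
  ppi <- ukeys %in% pkeys
  counts <- matrix(c(sum(called & ppi), sum(called & !ppi),
                     sum(!called & ppi), sum(!called & !ppi)),
                   nrow = 2L, byrow = TRUE,
                   dimnames = list(called = c("yes", "no"),
                                   ppi = c("yes", "no")))
  frac_all <- sum(ppi) / length(ukeys)
  frac_called <- if (sum(called) > 0L) sum(called & ppi) / sum(called) else NA
  fold <- if (frac_all > 0) frac_called / frac_all else NA_real_
  fp <- fisher.test(counts, alternative = "greater")$p.value
  list(fold = fold, fisher_p = fp, counts = counts,
       ppi_fraction_called = frac_called, ppi_fraction_universe = frac_all)
}

#' Build an interaction network from calls
#'
#' @param calls data.frame of interaction calls (one context).
#' @param context context label stored on the network.
#' @return an `interaction_network`: `nodes` (data.frame tf_id, degree),
#'   `edges` (the calls), `context`, plus an `igraph` graph in `$graph`.
#' @export
build_network <- function(calls, context = "global") {
  if (nrow(calls) == 0L) {
    g <- igraph::make_empty_graph(directed = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(calls[, c("tf_a", "tf_b")],
                                       directed = FALSE)
  }
  deg <- igraph::degree(g)
  nodes <- data.frame(tf_id = names(deg), degree = as.integer(deg),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(-nodes$degree, nodes$tf_id, method = "radix"), ,
                 drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = calls, context = context,
                 graph = g),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network> %s: %d TFs, %d interactions\n",
              x$context, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Hub TFs of an interaction network
#'
#' Central regulators: nodes whose degree is at least
#' `min_degree_fraction` of the maximum degree, ordered by decreasing
#' degree then id. The fraction rule (default 0.5) operationalizes the
#' "one or two central regulators" observation and is configurable.
#'
#' @param net an `interaction_network`.
#' @param min_degree_fraction fraction of the maximum degree in (0, 1].
#' @return character vector of hub TF ids.
#' @export
find_hubs <- function(net, min_degree_fraction = 0.5) {
  stopifnot(inherits(net, "interaction_network"))
  if (nrow(net$nodes) == 0L) stopf("empty network")
  if (min_degree_fraction <= 0 || min_degree_fraction > 1)
    stopf("min_degree_fraction must be in (0, 1]")
  cut <- min_degree_fraction * max(net$nodes$degree)
  net$nodes$tf_id[net$nodes$degree >= cut]
}

#' Write a network edge list as TSV
#' @param net an `interaction_network`.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(net, path) {
  stopifnot(inherits(net, "interaction_network"))
  write.table(net$edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Export a network as GraphML with degree and hub node attributes
#' @param net an `interaction_network`.
#' @param path GraphML path.
#' @param min_degree_fraction hub rule passed to [find_hubs()].
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path, min_degree_fraction = 0.5) {
  stopifnot(inherits(net, "interaction_network"))
  g <- net$graph
  if (igraph::vcount(g) > 0L) {
    hubs <- find_hubs(net, min_degree_fraction)
    ids <- igraph::V(g)$name
    g <- igraph::set_vertex_attr(g, "degree",
                                 value = as.integer(igraph::degree(g)))
    g <- igraph::set_vertex_attr(g, "hub", value = ids %in% hubs)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
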