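make_tissue_results <- function() {
  data.frame(
    tissue = "liver",
    tf_a = c("A", "A", "B", "C"), tf_b = c("B", "C", "C", "D"),
    mu_111 = c(40, 5, 30, 2), expected_111 = c(10, 6, 8, 5),
    g_stat = c(80, 30, 60, 28),
    log10_p = c(-16, -6.5, -12, -6.2),
    similarity = c(1, 5, 2, 1), similar_flag = c(FALSE, TRUE, FALSE, FALSE),
    enriched = c(TRUE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)
}

test_that("interaction calling thresholds and requires enrichment", {
  res <- make_tissue_results()
  calls <- call_interactions(res, context = "tissue")  # default -6
  # A:C is depleted, C:D is depleted: excluded despite p <= 1e-6
  expect_setequal(paste(calls$tf_a, calls$tf_b), c("A B", "B C"))
  expect_equal(call_interactions(res[0, ], context = "tissue"),
               call_interactions(res[0, ], context = "tissue"))
  expect_equal(nrow(call_interactions(res[0, ], context = "tissue")), 0L)

  # monotone nesting in the threshold
  c6 <- call_interactions(res, -6, context = "tissue")
  c7 <- call_interactions(res, -7, context = "tissue")
  expect_true(all(paste(c7$tf_a, c7$tf_b) %in% paste(c6$tf_a, c6$tf_b)))
  expect_error(call_interactions(res, 3), "log10")

  # defaults are the documented per-context thresholds
  expect_equal(default_thresholds(),
               c(global = -20, tissue = -6, cell_line = -11))
})

test_that("global calling uses the pair-scan minimum p", {
  res <- data.frame(tf_a = c("A", "A"), tf_b = c("B", "C"),
                    min_log10_p = c(-25, -4), universe_n = 5000,
                    stringsAsFactors = FALSE)
  calls <- call_interactions(res, context = "global")
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$context, "global")
  expect_equal(calls$log10_p, -25)
})

test_that("evidence annotation distinguishes PPIs, trios and neither", {
  ppi <- data.frame(tf_a = c("A", "B", "A", "X"),
                    tf_b = c("C", "C", "B", "Y"),
                    stringsAsFactors = FALSE)
  calls <- data.frame(tf_a = c("A", "A", "X"), tf_b = c("B", "C", "C"),
                      stringsAsFactors = FALSE)
  ann <- annotate_evidence(calls, ppi)
  # (A,B): direct PPI and both interact with C -> trio too
  expect_true(ann$known_ppi[1]); expect_true(ann$trio[1])
  expect_equal(ann$shared_cofactors[1], "C")
  # (A,C): direct PPI, and B is a shared partner of both -> trio too
  expect_true(ann$known_ppi[2]); expect_true(ann$trio[2])
  expect_equal(ann$shared_cofactors[2], "B")
  # (X,C): neither
  expect_false(ann$known_ppi[3]); expect_false(ann$trio[3])
  expect_equal(ann$evidence[3], "")

  # pure trio without direct edge: A-D, B-D only
  ppi2 <- data.frame(tf_a = c("A", "B"), tf_b = c("D", "D"))
  ann2 <- annotate_evidence(data.frame(tf_a = "A", tf_b = "B"), ppi2)
  expect_false(ann2$known_ppi); expect_true(ann2$trio)
  expect_equal(ann2$shared_cofactors, "D")
})

test_that("PPI enrichment reproduces the exact Fisher tail", {
  # universe of 10 pairs, 4 called, 4 PPI, 3 in the intersection
  universe <- data.frame(tf_a = rep("A", 10), tf_b = paste0("B", 1:10))
  calls <- universe[1:4, ]
  ppi <- universe[c(1, 2, 3, 5), ]
  enr <- ppi_enrichment(calls, universe, ppi)
  expect_equal(unname(enr$counts[1, ]), c(3, 1))
  expect_equal(enr$fisher_p, 25 / 210, tolerance = 1e-9)
  expect_equal(enr$fold, (3 / 4) / (4 / 10))

  # zero overlap -> fold 0; calls = universe -> fold 1
  enr0 <- ppi_enrichment(universe[9:10, ], universe, ppi)
  expect_equal(enr0$fold, 0)
  enr1 <- ppi_enrichment(universe, universe, ppi)
  expect_equal(enr1$fold, 1)
  # no PPI in the universe -> undefined fold
  enrNA <- ppi_enrichment(calls, universe,
                          data.frame(tf_a = "Z1", tf_b = "Z2"))
  expect_true(is.na(enrNA$fold))
})

test_that("Fisher p matches the enumeration oracle on small tables", {
  set.seed(71)
  for (rep in 1:25) {
    n <- sample(8:30, 1)
    n_called <- sample(1:(n - 1), 1)
    n_ppi <- sample(1:(n - 1), 1)
    universe <- data.frame(tf_a = rep("A", n), tf_b = paste0("B", 1:n))
    calls <- universe[sample(n, n_called), ]
    ppi <- universe[sample(n, n_ppi), ]
    enr <- ppi_enrichment(calls, universe, ppi)
    expect_equal(enr$fisher_p, oracle_fisher_upper(enr$counts),
                 tolerance = 1e-9)
  }
})

test_that("network construction and hub detection", {
  # star on 6 nodes
  star <- data.frame(tf_a = "HUB", tf_b = paste0("L", 1:5),
                     context = "global", log10_p = -21,
                     stringsAsFactors = FALSE)
  net <- build_network(star)
  expect_equal(nrow(net$nodes), 6L)
  expect_equal(net$nodes$degree[net$nodes$tf_id == "HUB"], 5L)
  expect_equal(find_hubs(net), "HUB")

  # complete graph on 4 nodes: all hubs
  k4 <- enumerate_pairs(c("A", "B", "C", "D"))
  k4$context <- "global"; k4$log10_p <- -21
  expect_equal(find_hubs(build_network(k4)), c("A", "B", "C", "D"))

  # random graph vs independent degree recount
  set.seed(72)
  pool <- enumerate_pairs(paste0("T", 1:12))
  edges <- pool[sample(nrow(pool), 20), ]
  net2 <- build_network(edges)
  deg <- table(c(edges$tf_a, edges$tf_b))
  for (i in seq_len(nrow(net2$nodes)))
    expect_equal(net2$nodes$degree[i],
                 unname(as.integer(deg[net2$nodes$tf_id[i]])))
  hubs <- find_hubs(net2, 0.6)
  oracle_hubs <- names(deg)[deg >= 0.6 * max(deg)]
  expect_setequal(hubs, oracle_hubs)
  expect_false(is.unsorted(-net2$nodes$degree[match(hubs, net2$nodes$tf_id)]))
})

test_that("network exports are written and parseable", {
  edges <- data.frame(tf_a = c("A", "A"), tf_b = c("B", "C"),
                      context = "global", log10_p = c(-30, -22),
                      stringsAsFactors = FALSE)
  net <- build_network(edges)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network_tsv(net, tsv)
  write_network_graphml(net, gml, min_degree_fraction = 0.8)
  back <- read.table(tsv, sep = "\t", header = TRUE)
  expect_equal(nrow(back), 2L)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 3L)
  expect_equal(sort(igraph::V(g)$degree, decreasing = TRUE)[1], 2L)
  expect_equal(sum(igraph::V(g)$hub), 1L)
})
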