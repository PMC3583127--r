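test_that("pair enumeration is canonical and complete", {
  expect_equal(nrow(enumerate_pairs(c("B", "A"))), 1L)
  expect_equal(enumerate_pairs(c("B", "A"))$tf_a, "A")
  p10 <- enumerate_pairs(sprintf("T%02d", 10:1))
  expect_equal(nrow(p10), 45L)
  expect_true(all(p10$tf_a < p10$tf_b))
  expect_false(any(duplicated(paste(p10$tf_a, p10$tf_b))))
  expect_error(enumerate_pairs(c("A", "A", "B")), "duplicate")
})

test_that("hypergeometric tail matches closed forms and handles bounds", {
  expect_equal(hypergeom_overlap_p(20, 5, 5, 3), 1126 / 15504,
               tolerance = 1e-12)
  expect_equal(hypergeom_overlap_p(20, 5, 5, 5), 1 / choose(20, 5),
               tolerance = 1e-12)
  # k at the lower feasibility bound: the whole support is in the tail
  expect_equal(hypergeom_overlap_p(10, 7, 6, 3), 1)
  expect_equal(hypergeom_overlap_p(50, 10, 20, 0), 1)
  expect_error(hypergeom_overlap_p(20, 5, 5, 6), "infeasible")
  expect_error(hypergeom_overlap_p(20, 25, 5, 2), "L1")
  # log form stays finite far below double underflow of the plain tail
  lp <- hypergeom_overlap_p(5000, 1000, 1000, 1000, log10p = TRUE)
  expect_lt(lp, -700)
  expect_true(is.finite(lp))
})

test_that("tail probability is monotone in k", {
  for (N in c(15, 40)) {
    L1 <- 7; L2 <- 9
    ks <- max(0, L1 + L2 - N):min(L1, L2)
    p <- vapply(ks, function(k) hypergeom_overlap_p(N, L1, L2, k),
                numeric(1))
    expect_true(all(diff(p) <= 1e-14))
  }
})

test_that("grid scan equals the naive per-cell rescan oracle", {
  set.seed(41)
  N <- 120
  genes <- sprintf("g%03d", 1:N)
  grid <- seq(5L, 60L, by = 5L)
  for (rep in 1:5) {
    la <- make_ranked("A", sample(genes))
    lb <- make_ranked("B", sample(genes))
    got <- grid_scan(la, lb, grid)
    want <- oracle_grid_scan(la$genes, lb$genes, grid, N)
    expect_equal(got$min_log10_p, want$min_log10_p, tolerance = 1e-12)
    expect_equal(got$overlap_k, want$overlap_k)
    expect_equal(got$best_L1, want$best_L1)
    expect_equal(got$best_L2, want$best_L2)
  }
})

test_that("grid scan is symmetric and dominated by every queried cell", {
  set.seed(42)
  N <- 200
  genes <- sprintf("g%03d", 1:N)
  grid <- seq(10L, 100L, by = 10L)
  la <- make_ranked("A", sample(genes))
  lb <- make_ranked("B", sample(genes))
  ab <- grid_scan(la, lb, grid)
  ba <- grid_scan(lb, la, grid)
  expect_equal(ab$min_log10_p, ba$min_log10_p, tolerance = 1e-12)
  expect_identical(c(ab$tf_a, ab$tf_b), c(ba$tf_a, ba$tf_b))
  for (i in 1:20) {
    L1 <- sample(grid, 1); L2 <- sample(grid, 1)
    k <- length(intersect(la$genes[1:L1], lb$genes[1:L2]))
    expect_lte(ab$min_log10_p,
               hypergeom_overlap_p(N, L1, L2, k, log10p = TRUE) + 1e-12)
  }
})

test_that("identical lists saturate the overlap at every grid point", {
  genes <- sprintf("g%03d", 1:100)
  la <- make_ranked("A", genes); lb <- make_ranked("B", genes)
  grid <- c(10L, 30L, 50L)
  res <- grid_scan(la, lb, grid)
  expect_equal(res$overlap_k, min(res$best_L1, res$best_L2))
  counts <- affipair:::.grid_overlap_counts(1:100, 1:100, grid)
  expect_equal(counts, outer(grid, grid, pmin))
})

test_that("shuffled-list minima match a fully recomputed oracle sample (KS)", {
  set.seed(43)
  N <- 250
  genes <- sprintf("g%03d", 1:N)
  grid <- seq(10L, 80L, by = 10L)
  sample_a <- replicate(200, {
    grid_scan(make_ranked("A", sample(genes)),
              make_ranked("B", sample(genes)), grid)$min_log10_p
  })
  sample_b <- replicate(200, {
    oracle_grid_scan(sample(genes), sample(genes), grid, N)$min_log10_p
  })
  ks <- suppressWarnings(stats::ks.test(sample_a, sample_b))
  expect_gt(ks$p.value, 0.01)
})

test_that("scan_all_pairs is complete, ordered and input-order invariant", {
  set.seed(44)
  genes <- sprintf("g%03d", 1:150)
  lists <- list(C = make_ranked("C", sample(genes)),
                A = make_ranked("A", sample(genes)),
                B = make_ranked("B", sample(genes)))
  grid <- seq(10L, 50L, by = 10L)
  res <- scan_all_pairs(lists, grid)
  expect_equal(nrow(res), 3L)
  expect_identical(paste(res$tf_a, res$tf_b),
                   c("A B", "A C", "B C"))
  res2 <- scan_all_pairs(lists[c("B", "C", "A")], grid)
  expect_equal(res, res2)
})

test_that("a planted overlapping pair wins the scan across seeds", {
  grid <- seq(10L, 100L, by = 10L)
  genes <- sprintf("g%04d", 1:2000)
  wins <- 0L
  for (seed in 1:10) {
    set.seed(seed)
    shared <- sample(genes, 50)
    mk_list <- function(id, planted) {
      top <- if (planted) c(shared, sample(setdiff(genes, shared), 50))
             else sample(genes, 100)
      make_ranked(id, c(sample(top), sample(setdiff(genes, top))))
    }
    lists <- list(P1 = mk_list("P1", TRUE), P2 = mk_list("P2", TRUE),
                  N1 = mk_list("N1", FALSE), N2 = mk_list("N2", FALSE),
                  N3 = mk_list("N3", FALSE))
    res <- scan_all_pairs(lists, grid)
    best <- res[which.min(res$min_log10_p), ]
    if (best$tf_a == "P1" && best$tf_b == "P2") wins <- wins + 1L
  }
  expect_equal(wins, 10L)
})

test_that("results TSV round trips sorted by p", {
  set.seed(45)
  genes <- sprintf("g%03d", 1:100)
  lists <- list(A = make_ranked("A", sample(genes)),
                B = make_ranked("B", sample(genes)),
                C = make_ranked("C", sample(genes)))
  res <- scan_all_pairs(lists, c(10L, 20L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pairs_tsv(res, path)
  back <- read_pairs_tsv(path)
  expect_false(is.unsorted(back$min_log10_p))
  expect_setequal(paste(back$tf_a, back$tf_b), paste(res$tf_a, res$tf_b))
})
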