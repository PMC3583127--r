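test_that("table construction counts joint memberships correctly", {
  universe <- sprintf("g%02d", 1:40)
  same10 <- universe[1:10]
  t1 <- build_table(same10, same10, same10, universe)
  expect_equal(t1$mu[1, 1, 1], 10)
  expect_equal(t1$mu[2, 2, 2], 30)
  expect_equal(sum(t1$mu), 40)
  expect_equal(sum(t1$mu != 0), 2L)

  t2 <- build_table(universe[1:5], universe[6:10], universe[1:8], universe)
  expect_equal(t2$mu[1, 1, ], c(tissue = 0, not_tissue = 0))  # disjoint tops

  # random sets vs per-gene 8-way classification oracle
  set.seed(61)
  for (rep in 1:5) {
    ta <- sample(universe, 12); tb <- sample(universe, 15)
    tz <- sample(universe, 9)
    tab <- build_table(ta, tb, tz, universe)
    oracle <- array(0L, dim = c(2, 2, 2))
    for (g in universe) {
      i <- if (g %in% ta) 1 else 2
      j <- if (g %in% tb) 1 else 2
      k <- if (g %in% tz) 1 else 2
      oracle[i, j, k] <- oracle[i, j, k] + 1L
    }
    expect_equal(unname(tab$mu), oracle + 0)
  }
})

test_that("tissue genes outside the universe are dropped with a warning", {
  universe <- sprintf("g%02d", 1:20)
  expect_warning(
    tab <- build_table(universe[1:5], universe[3:8],
                       c(universe[1:4], "alien1", "alien2"), universe),
    "dropped")
  expect_equal(sum(apply(tab$mu, 3, sum)[1]), 4)
  expect_equal(tab$dropped_tissue_genes, 2L)
  expect_error(build_table("g01", "g01", "g01", character(0)), "empty")
})

test_that("expected frequencies preserve the fitted marginals exactly", {
  t_sym <- three_way_table(array(5, dim = c(2, 2, 2)))
  expect_equal(unname(expected_partial_independence(t_sym)),
               array(5, dim = c(2, 2, 2)))

  t_x <- three_way_table(array(c(8, 2, 2, 8, 2, 8, 8, 2), dim = c(2, 2, 2)))
  expect_equal(unname(expected_partial_independence(t_x)),
               array(5, dim = c(2, 2, 2)))

  set.seed(62)
  for (rep in 1:20) {
    tt <- random_223_table()
    mh <- expected_partial_independence(tt)
    expect_equal(sum(mh), tt$n)
    expect_equal(apply(mh, c(1, 2), sum), apply(tt$mu, c(1, 2), sum))
    expect_equal(apply(mh, 3, sum), apply(tt$mu, 3, sum))
  }
})

test_that("partial-independence G matches direct evaluation and IPF oracle", {
  t_sym <- three_way_table(array(5, dim = c(2, 2, 2)))
  r <- partial_independence_test(t_sym)
  expect_equal(r$g_stat, 0)
  expect_equal(r$log10_p, 0)
  expect_equal(r$df, 3L)
  expect_false(r$enriched)

  t_x <- three_way_table(array(c(8, 2, 2, 8, 2, 8, 8, 2), dim = c(2, 2, 2)))
  rx <- partial_independence_test(t_x)
  expect_equal(rx$g_stat, 2 * (4 * 8 * log(1.6) + 4 * 2 * log(0.4)),
               tolerance = 1e-12)
  expect_equal(rx$g_stat, 15.4196, tolerance = 1e-4)

  set.seed(63)
  for (rep in 1:30) {
    tt <- random_223_table()
    expect_equal(partial_independence_test(tt)$g_stat,
                 oracle_g_ipf(tt$mu), tolerance = 1e-8)
  }
})

test_that("zero cells follow the 0 log 0 convention and labels commute", {
  mu <- array(c(12, 0, 3, 5, 0, 7, 4, 9), dim = c(2, 2, 2))
  tt <- three_way_table(mu)
  r <- partial_independence_test(tt)
  expect_true(is.finite(r$g_stat))
  expect_equal(r$g_stat, oracle_g_ipf(mu), tolerance = 1e-8)

  # swapping the two TFs transposes X and Y: statistic unchanged
  swapped <- three_way_table(aperm(mu, c(2, 1, 3)))
  rs <- partial_independence_test(swapped)
  expect_equal(rs$g_stat, r$g_stat, tolerance = 1e-12)
  expect_equal(rs$log10_p, r$log10_p, tolerance = 1e-12)
})

test_that("alternative hypotheses carry their conventional df", {
  tt <- random_223_table()
  m <- threeway_alternative_test(tt, "mutual")
  ci <- threeway_alternative_test(tt, "conditional")
  expect_equal(m$df, 4L)
  expect_equal(ci$df, 2L)
  expect_gte(m$g_stat, 0)
  expect_gte(ci$g_stat, 0)
  # mutual independence is the stricter model: larger or equal deviance
  expect_gte(m$g_stat + 1e-9, partial_independence_test(tt)$g_stat)
})

test_that("null tables are approximately calibrated at small scale", {
  tabs <- null_tables(300, n = 3000, seed = 64)
  p <- vapply(tabs, function(t) 10^partial_independence_test(t)$log10_p,
              numeric(1))
  frac <- mean(p <= 0.05)
  # loose 99.9% binomial band for 300 draws; the strict 2000-table
  # calibration criterion runs in test-acceptance.R
  expect_gte(frac, 0.01)
  expect_lte(frac, 0.11)
})

test_that("tissue scan tests every pair in every tissue deterministically", {
  expect_equal(formals(tissue_scan)$L, 1000L)
  set.seed(65)
  genes <- sprintf("g%03d", 1:200)
  lists <- list(A = make_ranked("A", sample(genes)),
                B = make_ranked("B", sample(genes)),
                C = make_ranked("C", sample(genes)))
  tissues <- list(liver = sample(genes, 30),
                  muscle = c(sample(genes, 20), "alien"))
  res <- tissue_scan(lists, tissues, L = 50)
  expect_equal(nrow(res), 6L)
  expect_identical(res$tissue, rep(c("liver", "muscle"), each = 3))
  expect_identical(res$tf_a, rep(c("A", "A", "B"), 2))
  res2 <- tissue_scan(lists[c("C", "A", "B")], tissues[c(2, 1)], L = 50)
  expect_equal(res, res2, ignore_attr = TRUE)
  expect_error(tissue_scan(lists, tissues, L = 500), "universe")
})

test_that("tissue scan agrees with explicit build_table + test", {
  set.seed(66)
  genes <- sprintf("g%03d", 1:300)
  lists <- list(A = make_ranked("A", sample(genes)),
                B = make_ranked("B", sample(genes)))
  tg <- sample(genes, 40)
  res <- tissue_scan(lists, list(t1 = tg), L = 100)
  direct <- partial_independence_test(build_table(
    lists$A$genes[1:100], lists$B$genes[1:100], tg, genes))
  expect_equal(res$g_stat, direct$g_stat, tolerance = 1e-12)
  expect_equal(res$mu_111, direct$observed_111)
  expect_equal(res$expected_111, direct$expected_111, tolerance = 1e-12)
  expect_equal(res$enriched, direct$enriched)
})

test_that("tissue set IO round trips both layouts", {
  tissues <- list(liver = c("g1", "g2"), muscle = c("g2", "g3", "g4"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_tissue_tsv(tissues, tsv)
  expect_equal(read_tissue_sets(tsv), tissues)

  dir <- withr::local_tempdir()
  writeLines(c("g1", "g2"), file.path(dir, "liver.txt"))
  writeLines(c("g9"), file.path(dir, "stomach.txt"))
  got <- read_tissue_sets(dir)
  expect_setequal(names(got), c("liver", "stomach"))
  expect_equal(got$liver, c("g1", "g2"))
})
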