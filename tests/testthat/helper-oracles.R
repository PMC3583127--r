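# Independent oracles and small fixture builders shared across tests.
# Oracles deliberately re-derive quantities by the most direct route
# (enumeration, brute-force rescans, closed forms) and never call the
# code paths they check.

# ---- fixture builders -------------------------------------------------

random_seq <- function(n, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

random_test_pwm <- function(id, width, sharp = 10) {
  counts <- matrix(rpois(4 * width, sharp) +
                     5 * diag(4)[sample.int(4, width, replace = TRUE), ],
                   nrow = width, ncol = 4)
  # transpose to 4 x width (JASPAR layout) to exercise the constructor
  pwm(t(counts), tf_id = id)
}

word_pwm <- function(word, id, conc = 90, other = 2) {
  idx <- match(strsplit(word, "")[[1]], c("A", "C", "G", "T"))
  counts <- t(vapply(idx, function(b) {
    v <- rep(other, 4); v[b] <- conc; v
  }, numeric(4)))
  pwm(counts, tf_id = id)
}

make_ranked <- function(tf_id, genes, affinities = rev(seq_along(genes))) {
  structure(list(tf_id = tf_id, genes = genes,
                 affinities = as.numeric(affinities)),
            class = "ranked_targets")
}

random_223_table <- function() {
  three_way_table(array(rpois(8, 20) + 1, dim = c(2, 2, 2)))
}

# ---- TRAP affinity oracle --------------------------------------------

# Direct double loop over windows and strands: the reverse strand is
# realized by scanning the reverse-complemented sequence, a different
# formulation than the package's reverse-complemented matrix.
oracle_trap_score <- function(seq, pwm, lambda = 0.7, R = 1e-4) {
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  strand_score <- function(s) {
    ch <- strsplit(s, "")[[1]]
    w <- pwm$width
    if (length(ch) < w) return(0)
    tot <- 0
    for (i in 1:(length(ch) - w + 1)) {
      win <- ch[i:(i + w - 1)]
      if (any(!win %in% bases)) next
      llr <- sum(log(pwm$probs[cbind(1:w, match(win, bases))] /
                       pwm$background[match(win, bases)]))
      K <- exp(llr / lambda)
      tot <- tot + R * K / (1 + R * K)
    }
    tot
  }
  rc <- paste(rev(unname(comp[strsplit(seq, "")[[1]]])), collapse = "")
  strand_score(seq) + strand_score(rc)
}

# ---- hypergeometric tail oracle --------------------------------------

oracle_hyper_tail <- function(N, L1, L2, k) {
  hi <- min(L1, L2)
  if (k > hi) return(0)
  i <- k:hi
  sum(exp(lchoose(L2, i) + lchoose(N - L2, L1 - i) - lchoose(N, L1)))
}

# ---- naive grid-scan oracle ------------------------------------------

oracle_grid_scan <- function(genes_a, genes_b, grid, N) {
  best <- c(Inf, NA, NA, NA)
  for (L1 in grid) for (L2 in grid) {
    k <- length(intersect(genes_a[seq_len(L1)], genes_b[seq_len(L2)]))
    lp <- phyper(k - 1, L2, N - L2, L1, lower.tail = FALSE,
                 log.p = TRUE) / log(10)
    if (lp < best[1]) best <- c(lp, L1, L2, k)
  }
  list(min_log10_p = best[1], best_L1 = best[2], best_L2 = best[3],
       overlap_k = best[4])
}

# ---- iterative proportional fitting oracle for the G statistic -------

oracle_g_ipf <- function(mu, n_iter = 200, tol = 1e-12) {
  safe_ratio <- function(num, den) ifelse(num == 0, 0, num / den)
  m <- array(1, dim = c(2, 2, 2))
  for (it in seq_len(n_iter)) {
    prev <- m
    txy <- safe_ratio(apply(mu, c(1, 2), sum), apply(m, c(1, 2), sum))
    m <- m * array(rep(txy, 2), dim = c(2, 2, 2))
    tz <- safe_ratio(apply(mu, 3, sum), apply(m, 3, sum))
    m <- m * array(rep(tz, each = 4), dim = c(2, 2, 2))
    if (max(abs(m - prev)) < tol) break
  }
  pos <- mu > 0
  2 * sum(mu[pos] * log(mu[pos] / m[pos]))
}

# ---- Fisher one-sided enumeration oracle -----------------------------

oracle_fisher_upper <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  i <- a:min(r1, c1)
  sum(exp(lchoose(c1, i) + lchoose(n - c1, r1 - i) - lchoose(n, r1)))
}

# ---- exhaustive joint-hit oracle for motif similarity ----------------

# Enumerates every sequence of the union window of motif a (variant
# weights Wa, integer threshold ta) at offset 0 and motif b at `delta`,
# using the same integer weight matrices as the implementation, and sums
# background probabilities of sequences on which both motifs hit.
oracle_joint_hit <- function(Wa, ta, Wb, tb, delta, background) {
  wa <- nrow(Wa); wb <- nrow(Wb)
  lo <- min(0, delta); hi <- max(wa, delta + wb)
  L <- hi - lo
  combos <- as.matrix(expand.grid(rep(list(1:4), L),
                                  KEEP.OUT.ATTRS = FALSE))
  a_cols <- (0:(wa - 1)) - lo + 1
  b_cols <- (delta:(delta + wb - 1)) - lo + 1
  sa <- rowSums(sapply(seq_len(wa), function(j) Wa[j, combos[, a_cols[j]]]))
  sb <- rowSums(sapply(seq_len(wb), function(j) Wb[j, combos[, b_cols[j]]]))
  bgp <- exp(rowSums(log(matrix(background[combos], nrow(combos), L))))
  sum(bgp[sa >= ta & sb >= tb])
}
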