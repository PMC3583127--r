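# Motif-motif similarity: a log-odds-of-overlap statistic in the spirit of
# S^max. Each motif receives a log-odds score threshold so that the expected
# number of hit events per sequence position (counting both strands) equals
# `hit_p` under the background. For every relative offset delta of the two
# motifs' start positions within half the combined width, the joint
# probability that both motifs hit is compared with the independence product;
# the statistic is the maximum over offsets of the log ratio. Near-identical
# motifs peak strongly above 0 at the aligning offset; unrelated motifs stay
# near 0 (offsets with no shared bases give exactly the independence
# product).
#
# Exact route: score distributions are convolved on an integer grid
# (discretized log-odds); joint probabilities enumerate only the 4^o shared
# bases of the overlap region and convolve the remaining positions
# independently, so motifs up to the spec'd "exhaustive" regime
# (width_a + width_b <= 16) are exact up to grid resolution. Wider motifs
# fall back to a seeded Monte Carlo scan of a long background sequence.

# Integer log-odds weights for one motif variant. `u` is the shared
# discretization unit of the motif (same for forward and reverse
# complement, whose per-position value sets are mirror images).
.int_weights <- function(probs, background, nbins) {
  W <- log(probs) - matrix(log(background), nrow(probs), 4L, byrow = TRUE)
  span <- sum(apply(W, 1L, max) - apply(W, 1L, min))
  u <- if (span > 0) span / (nbins - 1) else 1
  list(fwd = round(W / u),
       rc = round(W / u)[rev(seq_len(nrow(W))), 4:1, drop = FALSE],
       unit = u)
}

# Exact distribution of the integer score sum over `positions` (independent
# background draws). Returns offset `min` and a probability vector `p` with
# p[i] = P(sum == min + i - 1).
.score_dist <- function(Wint, background, positions) {
  dmin <- 0L; p <- 1
  for (j in positions) {
    vals <- as.integer(Wint[j, ])
    v0 <- min(vals)
    width <- max(vals) - v0
    np <- numeric(length(p) + width)
    for (b in 1:4)
      np[seq_along(p) + (vals[b] - v0)] <-
        np[seq_along(p) + (vals[b] - v0)] + p * background[b]
    p <- np
    dmin <- dmin + v0
  }
  list(min = dmin, p = p)
}

# Tail function P(sum >= v) from a .score_dist result, vectorized over v.
.tail_fun <- function(dist) {
  tails <- rev(cumsum(rev(dist$p)))
  dmin <- dist$min; n <- length(tails)
  function(v) {
    i <- pmax(1, ceiling(v) - dmin + 1)
    out <- ifelse(i > n, 0, tails[pmin(i, n)])
    out[v <= dmin] <- 1
    as.numeric(out)
  }
}

# Threshold achieving per-position both-strand hit probability <= hit_p,
# plus the attained forward/reverse tail probabilities.
.motif_threshold <- function(iw, background, hit_p) {
  distF <- .score_dist(iw$fwd, background, seq_len(nrow(iw$fwd)))
  distR <- .score_dist(iw$rc, background, seq_len(nrow(iw$rc)))
  tF <- .tail_fun(distF); tR <- .tail_fun(distR)
  lo <- min(distF$min, distR$min)
  hi <- max(distF$min + length(distF$p), distR$min + length(distR$p)) - 1L
  cand <- lo:hi
  tot <- tF(cand) + tR(cand)
  ok <- which(tot <= hit_p & tot > 0)
  t <- if (length(ok)) cand[ok[1L]] else hi
  list(threshold = t, qF = tF(t), qR = tR(t))
}

# All base combinations over o positions as a 4^o x o integer matrix.
.base_combos <- function(o) {
  if (o == 0L) return(matrix(integer(0), 1L, 0L))
  m <- as.matrix(expand.grid(rep(list(1:4), o), KEEP.OUT.ATTRS = FALSE))
  storage.mode(m) <- "integer"
  colnames(m) <- NULL
  m
}

# Joint probability that variant-a hits at 0 and variant-b hits at delta,
# via enumeration of the shared bases and exact convolution of the rest.
.joint_prob <- function(Wa, ta, Wb, tb, delta, background) {
  wa <- nrow(Wa); wb <- nrow(Wb)
  p0 <- max(0L, delta); p1 <- min(wa, delta + wb)
  if (p0 >= p1) {  # disjoint windows: exact independence
    qa <- .tail_fun(.score_dist(Wa, background, seq_len(wa)))(ta)
    qb <- .tail_fun(.score_dist(Wb, background, seq_len(wb)))(tb)
    return(qa * qb)
  }
  posA <- (p0:(p1 - 1L)) + 1L
  posB <- (p0:(p1 - 1L)) - delta + 1L
  restA <- setdiff(seq_len(wa), posA)
  restB <- setdiff(seq_len(wb), posB)
  tailA <- .tail_fun(.score_dist(Wa, background, restA))
  tailB <- .tail_fun(.score_dist(Wb, background, restB))
  combos <- .base_combos(length(posA))
  sa <- integer(nrow(combos)); sb <- integer(nrow(combos))
  lbg <- numeric(nrow(combos))
  for (j in seq_along(posA)) {
    sa <- sa + Wa[posA[j], combos[, j]]
    sb <- sb + Wb[posB[j], combos[, j]]
    lbg <- lbg + log(background[combos[, j]])
  }
  sum(exp(lbg) * tailA(ta - sa) * tailB(tb - sb))
}

#' Log-odds-of-overlap similarity of two motifs
#'
#' Maximum over start-position offsets of the log ratio between the joint
#' probability that both motifs hit (both strands, thresholds calibrated to
#' `hit_p` expected hit events per position) and the product of their
#' marginal hit probabilities. 0 means hits co-occur as if independent;
#' large positive values flag near-identical motifs. Symmetric in its
#' arguments and invariant to reverse-complementing either motif.
#'
#' @param a,b `pwm` objects.
#' @param background length-4 background distribution (default uniform).
#' @param hit_p target per-position hit probability in (0, 0.5);
#'   default 0.01.
#' @param method `"exact"` (overlap-base enumeration, feasible for
#'   `width_a + width_b <= 16`), `"mc"` (seeded Monte Carlo scan), or
#'   `"auto"` (exact when feasible).
#' @param nbins integer score-grid resolution of the exact route.
#' @param n_mc Monte Carlo sequence length (bp).
#' @param seed integer seed for the Monte Carlo route.
#' @return similarity value (natural log scale); for `method = "mc"` the
#'   result carries an `mc_se` attribute with a rough standard error.
#' @export
smax_similarity <- function(a, b, background = rep(0.25, 4), hit_p = 0.01,
                            method = c("auto", "exact", "mc"),
                            nbins = 2048L, n_mc = 2e5, seed = NULL) {
  stopifnot(inherits(a, "pwm"), inherits(b, "pwm"))
  method <- match.arg(method)
  if (hit_p <= 0 || hit_p >= 0.5) stopf("hit_p must be in (0, 0.5)")
  for (m in list(a, b))
    if (any(m$probs >= 1 - 1e-12))
      warnf("degenerate PWM '%s': a position is (near-)deterministic",
            m$tf_id)
  if (method == "auto")
    method <- if (a$width + b$width <= 16L) "exact" else "mc"
  iwa <- .int_weights(a$probs, background, nbins)
  iwb <- .int_weights(b$probs, background, nbins)
  tha <- .motif_threshold(iwa, background, hit_p)
  thb <- .motif_threshold(iwb, background, hit_p)
  qa <- tha$qF + tha$qR
  qb <- thb$qF + thb$qR
  if (qa <= 0 || qb <= 0) stopf("motif hit probability is zero; lower hit_p")
  D <- (a$width + b$width) %/% 2L
  deltas <- -D:D
  if (method == "exact") {
    per_delta <- vapply(deltas, function(d) {
      .joint_prob(iwa$fwd, tha$threshold, iwb$fwd, thb$threshold, d, background) +
      .joint_prob(iwa$fwd, tha$threshold, iwb$rc,  thb$threshold, d, background) +
      .joint_prob(iwa$rc,  tha$threshold, iwb$fwd, thb$threshold, d, background) +
      .joint_prob(iwa$rc,  tha$threshold, iwb$rc,  thb$threshold, d, background)
    }, numeric(1L))
    return(max(log(per_delta / (qa * qb))))
  }
  .smax_mc(iwa, tha, iwb, thb, deltas, background, n_mc, seed)
}

# Score all start positions of an integer-coded sequence with one variant.
.scan_int <- function(code, Wint) {
  w <- nrow(Wint)
  n <- length(code) - w + 1L
  s <- numeric(n)
  for (j in seq_len(w)) s <- s + Wint[j, code[seq_len(n) + j - 1L]]
  s
}

.smax_mc <- function(iwa, tha, iwb, thb, deltas, background, n_mc, seed) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  code <- sample.int(4L, n_mc, replace = TRUE, prob = background)
  hitsA <- .scan_int(code, iwa$fwd) >= tha$threshold |
           .scan_int(code, iwa$rc)  >= tha$threshold
  hitsB <- .scan_int(code, iwb$fwd) >= thb$threshold |
           .scan_int(code, iwb$rc)  >= thb$threshold
  n <- min(length(hitsA), length(hitsB)) - max(abs(deltas))
  ia <- which(hitsA[seq_len(n)])
  qa <- length(ia) / n
  qb <- sum(hitsB[seq_len(n)]) / n
  if (qa <= 0 || qb <= 0)
    stopf("no Monte Carlo hits; increase n_mc or hit_p")
  counts <- vapply(deltas, function(d) {
    j <- ia + d
    j <- j[j >= 1L & j <= length(hitsB)]
    sum(hitsB[j])
  }, numeric(1L))
  s_delta <- log(counts / n / (qa * qb))
  best <- which.max(s_delta)
  se <- sqrt(1 / max(counts[best], 1) + 1 / length(ia) + 1 / max(sum(hitsB[seq_len(n)]), 1))
  structure(s_delta[best], mc_se = se)
}

#' Pairwise similarity matrix for a motif collection
#'
#' @param pwms list of `pwm` objects.
#' @inheritParams smax_similarity
#' @param verbose progress messages.
#' @return a `similarity_matrix`: list with `tfs` and the symmetric
#'   `values` matrix.
#' @export
build_similarity_matrix <- function(pwms, background = rep(0.25, 4),
                                    hit_p = 0.01,
                                    method = c("auto", "exact", "mc"),
                                    nbins = 2048L, n_mc = 2e5, seed = NULL,
                                    verbose = FALSE) {
  method <- match.arg(method)
  ids <- vapply(pwms, `[[`, character(1L), "tf_id")
  if (anyDuplicated(ids)) stopf("duplicate TF ids")
  n <- length(pwms)
  vals <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in i:n) {
      s <- as.numeric(smax_similarity(pwms[[i]], pwms[[j]],
                                      background = background,
                                      hit_p = hit_p, method = method,
                                      nbins = nbins, n_mc = n_mc,
                                      seed = if (is.null(seed)) NULL else seed + i * n + j))
      vals[i, j] <- s; vals[j, i] <- s
    }
    msg(sprintf("similarity row %d/%d", i, n), verbose = verbose)
  }
  similarity_matrix(vals)
}

#' Construct/validate a similarity matrix
#' @param values symmetric numeric matrix with identical row/col TF names.
#' @return a `similarity_matrix` object.
#' @export
similarity_matrix <- function(values) {
  if (!is.matrix(values) || is.null(rownames(values)) ||
      !identical(rownames(values), colnames(values)))
    stopf("similarity matrix needs identical row and column TF names")
  if (max(abs(values - t(values))) > 1e-9)
    stopf("similarity matrix must be symmetric")
  structure(list(tfs = rownames(values), values = values),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  v <- x$values[upper.tri(x$values)]
  cat(sprintf("<similarity_matrix> %d TFs, off-diagonal range [%.3g, %.3g]\n",
              length(x$tfs), min(v), max(v)))
  invisible(x)
}

#' Look up the similarity of a TF pair
#' @param sim a `similarity_matrix`.
#' @param tf_a,tf_b TF ids (vectorized).
#' @return numeric vector of similarities.
#' @export
pair_similarity <- function(sim, tf_a, tf_b) {
  stopifnot(inherits(sim, "similarity_matrix"))
  missing <- setdiff(unique(c(tf_a, tf_b)), sim$tfs)
  if (length(missing))
    stopf("TF(s) absent from similarity matrix: %s",
          paste(missing, collapse = ", "))
  sim$values[cbind(match(tf_a, sim$tfs), match(tf_b, sim$tfs))]
}

#' Split predicted pairs into motif-nonsimilar (kept) and similar (flagged)
#'
#' Pairs with similarity strictly below `cutoff` are kept; the rest are
#' flagged (annotated, never dropped): near-identical motifs produce
#' rank-list overlap on their own, so such pairs are unreliable interaction
#' candidates.
#'
#' @param pairs data.frame with `tf_a`, `tf_b` columns (pair-scan results
#'   or interaction calls).
#' @param sim a `similarity_matrix` covering all TFs in `pairs`.
#' @param cutoff strict upper bound on similarity for kept pairs
#'   (default 4, the conventional 90%-quantile-scale cutoff).
#' @return list with data.frames `kept` and `flagged`; both carry
#'   `similarity` and `similar_motif` columns.
#' @export
filter_by_similarity <- function(pairs, sim, cutoff = 4) {
  stopifnot(is.data.frame(pairs))
  if (nrow(pairs) == 0L) {
    pairs$similarity <- numeric(0); pairs$similar_motif <- logical(0)
    return(list(kept = pairs, flagged = pairs))
  }
  pairs$similarity <- pair_similarity(sim, pairs$tf_a, pairs$tf_b)
  pairs$similar_motif <- !(pairs$similarity < cutoff)
  list(kept = pairs[!pairs$similar_motif, , drop = FALSE],
       flagged = pairs[pairs$similar_motif, , drop = FALSE])
}

#' Empirical quantile cutoff from a similarity matrix
#'
#' Quantile (linear interpolation between order statistics) of the strict
#' upper-triangle similarities, self-similarities excluded.
#'
#' @param sim a `similarity_matrix` with at least 2 TFs.
#' @param q probability in (0, 1); 0.9 mirrors the conventional
#'   90%-quantile rule.
#' @return the cutoff value.
#' @export
quantile_cutoff <- function(sim, q = 0.9) {
  stopifnot(inherits(sim, "similarity_matrix"))
  if (length(sim$tfs) < 2L) stopf("need at least 2 TFs")
  if (q <= 0 || q >= 1) stopf("q must be inside (0, 1)")
  unname(quantile(sim$values[upper.tri(sim$values)], probs = q, type = 7))
}

#' Write / read a similarity matrix as square TSV
#' @param sim a `similarity_matrix`.
#' @param path TSV path (header row and first column are TF ids).
#' @return `path` / a `similarity_matrix`.
#' @export
write_similarity_tsv <- function(sim, path) {
  stopifnot(inherits(sim, "similarity_matrix"))
  df <- data.frame(tf_id = sim$tfs, sim$values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_similarity_tsv
#' @export
read_similarity_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  similarity_matrix(m)
}
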