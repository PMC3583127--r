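# Biophysical (TRAP-like) promoter affinity scoring and per-TF ranked
# target lists.
#
# Each width-w window on each strand contributes an occupancy
#   p_w = R K_w / (1 + R K_w),  K_w = exp( (1/lambda) * sum_j log p_j(b_j)/bg(b_j) ),
# and a promoter's affinity for a TF is the sum of p_w over all windows on
# both strands. lambda flattens the energy landscape (mismatch tolerance);
# R sets the TF concentration / reference binding constant.

#' Affinity scoring parameters
#'
#' @param lambda positive mismatch-tolerance scale applied to the window
#'   log-likelihood ratio (default 0.7).
#' @param R0 reference binding constant. The default `1e-4` keeps scoring
#'   in the dilute regime, where the per-TF ranking is essentially the
#'   rank of the total Boltzmann weight and independent of the exact
#'   constant; `"trap"` derives it from the motif width as
#'   `exp(0.584 * width - 5.66)` (the original TRAP calibration, which on
#'   short promoters saturates occupancy at 2-3 mismatch windows and lets
#'   chance sites dominate single planted sites); a positive number fixes
#'   it for all motifs.
#' @return an `affinity_params` object.
#' @export
affinity_params <- function(lambda = 0.7, R0 = 1e-4) {
  if (lambda <= 0) stopf("lambda must be positive")
  if (!(identical(R0, "trap") || (is.numeric(R0) && R0 > 0)))
    stopf("R0 must be a positive number or \"trap\"")
  structure(list(lambda = lambda, R0 = R0), class = "affinity_params")
}

.affinity_R0 <- function(params, width) {
  if (identical(params$R0, "trap")) exp(0.584 * width - 5.66) else params$R0
}

# width x 4 log(p/bg) matrix scaled by 1/lambda, plus its reverse complement
.scaled_lodds <- function(pwm, lambda) {
  lo <- log(pwm$probs) -
    matrix(log(pwm$background), pwm$width, 4L, byrow = TRUE)
  lo <- lo / lambda
  lo_rc <- lo[rev(seq_len(pwm$width)), 4:1, drop = FALSE]
  colnames(lo_rc) <- DNA_BASES
  list(fwd = lo, rc = lo_rc)
}

#' Score every promoter with one PWM (TRAP-style occupancy)
#'
#' Sums per-window occupancies over all windows on both strands. Windows
#' containing an ambiguous base (N) contribute 0. Promoters shorter than
#' the motif score 0 with a warning.
#'
#' @param promoters a `promoter_set`.
#' @param pwm a `pwm` object.
#' @param params an `affinity_params` object.
#' @return named numeric vector of nonnegative affinities (one per gene).
#' @export
score_affinity <- function(promoters, pwm, params = affinity_params()) {
  stopifnot(inherits(promoters, "promoter_set"), inherits(pwm, "pwm"),
            inherits(params, "affinity_params"))
  if (length(promoters) == 0L) stopf("empty promoter set")
  codes <- lapply(promoters$sequences, encode_dna)
  short <- vapply(codes, length, integer(1L)) < pwm$width
  if (any(short))
    warnf("%d promoter(s) shorter than motif '%s' score 0",
          sum(short), pwm$tf_id)
  lo <- .scaled_lodds(pwm, params$lambda)
  logR <- log(.affinity_R0(params, pwm$width))
  out <- trap_scores_cpp(codes, lo$fwd, lo$rc, logR)
  setNames(out, gene_ids(promoters))
}

#' Build the genes x TFs affinity table
#'
#' @param promoters a `promoter_set`.
#' @param pwms list of `pwm` objects.
#' @param params an `affinity_params` object.
#' @param verbose emit one progress line per TF.
#' @return an `affinity_table`: list with `genes`, `tfs` and a
#'   `|genes| x |tfs|` matrix `values`.
#' @export
build_affinity_table <- function(promoters, pwms,
                                 params = affinity_params(),
                                 verbose = FALSE) {
  ids <- vapply(pwms, `[[`, character(1L), "tf_id")
  if (anyDuplicated(ids))
    stopf("duplicate TF ids: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- matrix(NA_real_, length(promoters), length(pwms),
                 dimnames = list(gene_ids(promoters), ids))
  for (i in seq_along(pwms)) {
    vals[, i] <- score_affinity(promoters, pwms[[i]], params)
    msg(sprintf("scored %s (%d/%d)", ids[i], i, length(pwms)),
        verbose = verbose)
  }
  affinity_table(vals)
}

#' Construct/validate an affinity table from a genes x TFs matrix
#' @param values numeric matrix with gene rownames and TF colnames; all
#'   entries finite and nonnegative.
#' @return an `affinity_table` object.
#' @export
affinity_table <- function(values) {
  if (!is.matrix(values) || is.null(rownames(values)) ||
      is.null(colnames(values)))
    stopf("affinity table needs a matrix with gene and TF dimnames")
  if (anyDuplicated(rownames(values))) stopf("duplicated gene ids")
  if (anyDuplicated(colnames(values))) stopf("duplicated TF ids")
  if (any(!is.finite(values)) || any(values < 0))
    stopf("affinities must be finite and nonnegative")
  structure(list(genes = rownames(values), tfs = colnames(values),
                 values = values),
            class = "affinity_table")
}

#' @export
print.affinity_table <- function(x, ...) {
  cat(sprintf("<affinity_table> %d genes x %d TFs\n",
              length(x$genes), length(x$tfs)))
  invisible(x)
}

#' Write / read an affinity table as TSV
#'
#' Layout: header `gene_id` + TF ids, one row per gene, float cells.
#' @param table an `affinity_table`.
#' @param path TSV path.
#' @return `path` / an `affinity_table`.
#' @export
write_affinity_tsv <- function(table, path) {
  stopifnot(inherits(table, "affinity_table"))
  df <- data.frame(gene_id = table$genes, table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_affinity_tsv
#' @export
read_affinity_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  affinity_table(m)
}

#' Per-TF ranked target lists
#'
#' Orders genes by decreasing affinity; ties are broken lexicographically
#' by gene id (radix order, locale-independent), so the result is
#' deterministic and invariant to input gene order.
#'
#' @param table an `affinity_table`.
#' @return named list of `ranked_targets` objects (fields `tf_id`,
#'   `genes`, `affinities`), one per TF.
#' @export
build_ranked_lists <- function(table) {
  stopifnot(inherits(table, "affinity_table"))
  lapply(setNames(table$tfs, table$tfs), function(tf) {
    v <- table$values[, tf]
    o <- order(-v, table$genes, method = "radix")
    structure(list(tf_id = tf, genes = table$genes[o],
                   affinities = unname(v[o])),
              class = "ranked_targets")
  })
}

#' @export
print.ranked_targets <- function(x, ...) {
  cat(sprintf("<ranked_targets> %s: %d genes, top = %s (%.4g)\n",
              x$tf_id, length(x$genes), x$genes[1L], x$affinities[1L]))
  invisible(x)
}

#' Write one ranked list as a two-column TSV (gene_id, affinity)
#' @param ranked a `ranked_targets` object.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_ranked_tsv <- function(ranked, path) {
  stopifnot(inherits(ranked, "ranked_targets"))
  write.table(data.frame(gene_id = ranked$genes,
                         affinity = ranked$affinities),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
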