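# Seeded synthetic fixtures with known ground truth: random high-information
# motifs, iid background promoters with planted co-occurring sites for
# chosen TF pairs, tissue gene sets coupled to the planted shared targets,
# and a PPI list containing the planted pairs plus decoys.

#' Specification of a synthetic fixture
#'
#' Defaults are the standard desk-scale benchmark: 5000 genes, 20 TFs,
#' width-10 motifs on 500 bp promoters, one planted pair sharing 150 target
#' genes, one tissue of 250 specific genes of which a fraction 0.6 are
#' drawn from the planted shared targets.
#'
#' @param n_genes number of promoters/genes.
#' @param n_tfs number of TFs (each gets a random high-information PWM).
#' @param motif_width motif width in bp.
#' @param promoter_length promoter length in bp.
#' @param planted_pairs list of lists with fields `tf_a`, `tf_b` (TF
#'   indices), `n_shared_targets`, `site_strength` (per-position mutation
#'   probability away from consensus when planting a site).
#' @param tissues list of lists with fields `name`, `n_specific`,
#'   `coupling` (fraction of specific genes drawn from a planted pair's
#'   shared targets).
#' @param gc_content background GC fraction.
#' @param seed integer seed; identical seeds reproduce identical fixtures.
#' @return a `fixture_spec` object.
#' @export
fixture_spec <- function(n_genes = 5000L, n_tfs = 20L, motif_width = 10L,
                         promoter_length = 500L,
                         planted_pairs = list(list(tf_a = 1L, tf_b = 2L,
                                                   n_shared_targets = 150L,
                                                   site_strength = 0.05)),
                         tissues = list(list(name = "tissue_1",
                                             n_specific = 250L,
                                             coupling = 0.6)),
                         gc_content = 0.5, seed = 1L) {
  if (n_genes < 1L || n_tfs < 2L) stopf("need >= 1 gene and >= 2 TFs")
  if (gc_content <= 0 || gc_content >= 1) stopf("gc_content must be in (0,1)")
  for (p in planted_pairs) {
    if (p$n_shared_targets > n_genes)
      stopf("n_shared_targets exceeds n_genes")
    if (p$tf_a == p$tf_b || p$tf_a > n_tfs || p$tf_b > n_tfs)
      stopf("planted pair must name two distinct TF indices <= n_tfs")
    if (2L * motif_width > promoter_length)
      stopf("two non-overlapping sites cannot fit a %d bp promoter",
            promoter_length)
  }
  for (t in tissues) {
    if (t$coupling < 0 || t$coupling > 1) stopf("coupling must be in [0,1]")
    if (t$n_specific > n_genes) stopf("n_specific exceeds n_genes")
  }
  structure(list(n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
                 motif_width = as.integer(motif_width),
                 promoter_length = as.integer(promoter_length),
                 planted_pairs = planted_pairs, tissues = tissues,
                 gc_content = gc_content, seed = as.integer(seed)),
            class = "fixture_spec")
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

.random_pwm <- function(tf_id, width, conc = 0.94) {
  consensus <- sample.int(4L, width, replace = TRUE)
  counts <- t(vapply(seq_len(width), function(j) {
    p <- rep((1 - conc) / 3, 4L)
    p[consensus[j]] <- conc
    as.numeric(stats::rmultinom(1L, 100L, p))
  }, numeric(4L)))
  colnames(counts) <- DNA_BASES
  pwm(counts, tf_id = tf_id)
}

.mutate_consensus <- function(consensus_code, strength) {
  out <- consensus_code
  hit <- runif(length(out)) < strength
  if (any(hit))
    out[hit] <- vapply(out[hit], function(b)
      sample(setdiff(1:4, b), 1L), integer(1L))
  out
}

#' Generate a synthetic fixture
#'
#' Background promoters are iid with the requested GC content; every TF
#' receives a random high-information PWM; for each planted pair,
#' `n_shared_targets` genes receive one near-consensus site of both motifs
#' at random non-overlapping positions; each tissue set mixes
#' `coupling * n_specific` genes drawn from the planted shared targets
#' with random other genes; the PPI table holds the planted pairs plus
#' random decoy pairs.
#'
#' @param spec a `fixture_spec`.
#' @return a `fixture`: list with `promoters` (`promoter_set`), `pwms`,
#'   `tissues` (named list of gene sets), `ppi` (data.frame), `manifest`
#'   (ground truth: planted pairs, their targets, tissue couplings).
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  .with_seed(spec$seed, {
    genes <- sprintf("g%05d", seq_len(spec$n_genes))
    tf_ids <- sprintf("TF%02d", seq_len(spec$n_tfs))
    bgp <- c((1 - spec$gc_content) / 2, spec$gc_content / 2,
             spec$gc_content / 2, (1 - spec$gc_content) / 2)
    codes <- lapply(seq_len(spec$n_genes), function(i)
      sample.int(4L, spec$promoter_length, replace = TRUE, prob = bgp))
    names(codes) <- genes
    pwms <- lapply(tf_ids, .random_pwm, width = spec$motif_width)
    names(pwms) <- tf_ids

    planted <- list()
    w <- spec$motif_width
    for (p in spec$planted_pairs) {
      a <- tf_ids[p$tf_a]; b <- tf_ids[p$tf_b]
      targets <- sample(genes, p$n_shared_targets)
      cons_a <- encode_dna(pwm_consensus(pwms[[a]]))
      cons_b <- encode_dna(pwm_consensus(pwms[[b]]))
      for (g in targets) {
        len <- spec$promoter_length
        placed <- FALSE
        for (try in seq_len(200L)) {
          p1 <- sample.int(len - w + 1L, 1L)
          p2 <- sample.int(len - w + 1L, 1L)
          if (abs(p1 - p2) >= w) { placed <- TRUE; break }
        }
        if (!placed) stopf("could not place non-overlapping sites")
        codes[[g]][p1:(p1 + w - 1L)] <-
          .mutate_consensus(cons_a, p$site_strength)
        codes[[g]][p2:(p2 + w - 1L)] <-
          .mutate_consensus(cons_b, p$site_strength)
      }
      planted[[length(planted) + 1L]] <-
        list(tf_a = a, tf_b = b, targets = sort(targets),
             site_strength = p$site_strength)
    }
    shared_pool <- unique(unlist(lapply(planted, `[[`, "targets")))

    tissues <- list(); tissue_truth <- list()
    for (t in spec$tissues) {
      n_coupled <- min(round(t$coupling * t$n_specific),
                       length(shared_pool))
      coupled <- if (n_coupled > 0L) sample(shared_pool, n_coupled)
                 else character(0)
      rest <- sample(setdiff(genes, coupled), t$n_specific - n_coupled)
      tissues[[t$name]] <- sort(c(coupled, rest))
      tissue_truth[[t$name]] <- list(n_specific = t$n_specific,
                                     coupling = t$coupling,
                                     coupled_genes = sort(coupled))
    }

    planted_keys <- vapply(planted, function(p)
      pair_key(p$tf_a, p$tf_b), character(1L))
    all_pairs <- enumerate_pairs(tf_ids)
    decoy_pool <- all_pairs[!pair_key(all_pairs$tf_a, all_pairs$tf_b) %in%
                              planted_keys, , drop = FALSE]
    n_decoys <- min(2L * max(length(planted), 1L), nrow(decoy_pool))
    decoys <- decoy_pool[sample.int(nrow(decoy_pool), n_decoys), ,
                         drop = FALSE]
    ppi <- rbind(
      data.frame(tf_a = vapply(planted, `[[`, character(1L), "tf_a"),
                 tf_b = vapply(planted, `[[`, character(1L), "tf_b"),
                 stringsAsFactors = FALSE),
      decoys)
    ppi <- as.data.frame(canonical_pair(ppi$tf_a, ppi$tf_b),
                         stringsAsFactors = FALSE)
    ppi <- unique(ppi[order(ppi$tf_a, ppi$tf_b), , drop = FALSE])
    rownames(ppi) <- NULL

    seqs <- vapply(codes, decode_dna, character(1L))
    structure(list(
      promoters = promoter_set(seqs),
      pwms = pwms,
      tissues = tissues,
      ppi = ppi,
      manifest = list(seed = spec$seed, n_genes = spec$n_genes,
                      n_tfs = spec$n_tfs,
                      motif_width = spec$motif_width,
                      promoter_length = spec$promoter_length,
                      gc_content = spec$gc_content,
                      planted_pairs = planted,
                      tissues = tissue_truth)),
      class = "fixture")
  })
}

#' @export
print.fixture <- function(x, ...) {
  cat(sprintf("<fixture> %d genes, %d TFs, %d planted pair(s), %d tissue(s)\n",
              length(x$promoters), length(x$pwms),
              length(x$manifest$planted_pairs), length(x$tissues)))
  invisible(x)
}

#' Write a fixture to disk in the pipeline's input formats
#'
#' Emits `promoters.fa`, `motifs.pfm`, `tissues.tsv` (two-column
#' tissue/gene), `ppi.tsv` and `manifest.json`.
#'
#' @param fixture a `fixture`.
#' @param dir output directory (created if missing).
#' @return named list of written paths, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    promoters = file.path(dir, "promoters.fa"),
    motifs = file.path(dir, "motifs.pfm"),
    tissues = file.path(dir, "tissues.tsv"),
    ppi = file.path(dir, "ppi.tsv"),
    manifest = file.path(dir, "manifest.json"))
  write_promoters(fixture$promoters, paths$promoters)
  write_jaspar(fixture$pwms, paths$motifs)
  write_tissue_tsv(fixture$tissues, paths$tissues)
  write.table(fixture$ppi, paths$ppi, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(fixture$manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}

#' Simulate 2x2x2 tables under the partial-independence null
#'
#' (X, Y) joint membership has fixed nonuniform cell probabilities and Z is
#' drawn independently, so the partial-independence hypothesis holds by
#' construction; used for type-I-error calibration of the G-test.
#'
#' @param n_tables number of tables.
#' @param n total count per table (>= 8).
#' @param seed integer seed.
#' @param p_xy length-4 probabilities of the (X, Y) cells
#'   (order: 11, 21, 12, 22).
#' @param p_z probability of Z = 1.
#' @return list of `three_way_table` objects.
#' @export
null_tables <- function(n_tables, n, seed = 1L,
                        p_xy = c(0.10, 0.20, 0.25, 0.45), p_z = 0.3) {
  if (n < 8) stopf("n must be >= 8")
  if (abs(sum(p_xy) - 1) > 1e-9 || any(p_xy <= 0))
    stopf("p_xy must be positive and sum to 1")
  .with_seed(seed, {
    cellp <- as.numeric(outer(p_xy, c(p_z, 1 - p_z)))
    lapply(seq_len(n_tables), function(i) {
      counts <- as.numeric(stats::rmultinom(1L, n, cellp))
      three_way_table(array(counts, dim = c(2L, 2L, 2L)),
                      labels = c(tf_a = "null_a", tf_b = "null_b",
                                 tissue = sprintf("null_%d", i)))
    })
  })
}
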