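# Pipeline orchestration: a JSON config file, staged execution with
# plain-text TSV artifacts (inspectable and resumable), and a CLI wrapper
# (inst/cli/affipair.R).

#' Build a pipeline configuration
#'
#' @param inputs named list of input paths: `promoters_fasta` (or
#'   `genome_fasta` + `tss_bed`), `motifs_pfm`, `tissues` (file or
#'   directory), optional `ppi_tsv`, optional `affinity_tsv` /
#'   `similarity_tsv` to bypass internal scoring.
#' @param output_dir artifact directory.
#' @param affinity list: `lambda`, `R0`, `pseudocount`, `background`,
#'   `upstream`, `downstream`.
#' @param grid cutoff grid (vector), strictly increasing positive.
#' @param similarity list: `cutoff`, `hit_p`.
#' @param tissue list: `L` (top-list length).
#' @param thresholds named log10 p thresholds (all `<= 0`), see
#'   [default_thresholds()].
#' @param context `"tissue"`, `"cell_line"` or `"global"`.
#' @param seed integer seed for all stochastic steps.
#' @param verbose logical.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(inputs = list(), output_dir = "affipair_out",
                            affinity = list(), grid = default_grid(),
                            similarity = list(), tissue = list(),
                            thresholds = default_thresholds(),
                            context = "tissue", seed = 1L,
                            verbose = TRUE) {
  affinity <- modifyList(list(lambda = 0.7, R0 = 1e-4, pseudocount = 1,
                              background = rep(0.25, 4), upstream = 500L,
                              downstream = 0L), affinity)
  similarity <- modifyList(list(cutoff = 4, hit_p = 0.01,
                                method = "auto", n_mc = 2e5), similarity)
  tissue <- modifyList(list(L = 1000L), tissue)
  thr <- default_thresholds()
  thr[names(thresholds)] <- unlist(thresholds)
  grid <- as.integer(grid)
  if (any(grid <= 0) || is.unsorted(grid, strictly = TRUE))
    stopf("config: grid must be strictly increasing and positive")
  if (any(thr > 0))
    stopf("config: thresholds must be log10 p-values <= 0")
  if (!context %in% c("global", "tissue", "cell_line"))
    stopf("config: unknown context '%s'", context)
  structure(list(inputs = inputs, output_dir = output_dir,
                 affinity = affinity, grid = grid,
                 similarity = similarity, tissue = tissue,
                 thresholds = thr, context = context,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#' @param path JSON file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- raw$grid
  if (is.list(grid) && !is.null(grid$from))
    grid <- seq(grid$from, grid$to, by = grid$by)
  pipeline_config(
    inputs = as.list(raw$inputs %||% list()),
    output_dir = raw$output_dir %||% "affipair_out",
    affinity = as.list(raw$affinity %||% list()),
    grid = grid %||% default_grid(),
    similarity = as.list(raw$similarity %||% list()),
    tissue = as.list(raw$tissue %||% list()),
    thresholds = as.list(raw$thresholds %||% list()),
    context = raw$context %||% "tissue",
    seed = raw$seed %||% 1L,
    verbose = raw$verbose %||% TRUE)
}

.artifact <- function(config, name) file.path(config$output_dir, name)

.need_file <- function(path, what) {
  if (is.null(path) || !file.exists(path))
    stopf("missing input for stage '%s': %s", what,
          path %||% "(not configured)")
  path
}

.load_promoters <- function(config) {
  inp <- config$inputs
  if (!is.null(inp$promoters_fasta))
    return(read_promoters(.need_file(inp$promoters_fasta, "affinity")))
  extract_promoters(.need_file(inp$genome_fasta, "affinity"),
                    .need_file(inp$tss_bed, "affinity"),
                    upstream = config$affinity$upstream,
                    downstream = config$affinity$downstream)
}

.load_pwms <- function(config) {
  read_jaspar(.need_file(config$inputs$motifs_pfm, "motifs"),
              pseudocount = config$affinity$pseudocount,
              background = config$affinity$background)
}

.stage_log <- function(config, stage, n, extra = "") {
  msg(sprintf("[%s] %d rows%s", stage, n,
              if (nzchar(extra)) paste0(" | ", extra) else ""),
      verbose = config$verbose)
}

#' Run pipeline stages
#'
#' Stages: `affinity` (promoters x motifs -> `affinity.tsv`), `rank`
#' (-> `ranks.tsv`), `pairscan` (-> `pairs.tsv`), `similarity`
#' (-> `similarity.tsv`), `tissue` (-> `tissue_tests.tsv`), `network`
#' (-> `network.tsv`, `network.graphml`, `hubs.tsv`, and
#' `ppi_enrichment.tsv` when a PPI list is configured). Each stage
#' consumes the previous stage's TSV artifact, so stage-by-stage runs
#' reproduce a monolithic run byte for byte.
#'
#' @param config a `pipeline_config` (or path to a JSON config).
#' @param stages character subset of
#'   `c("affinity", "rank", "pairscan", "similarity", "tissue", "network")`;
#'   default runs all.
#' @return named list of written artifact paths, invisibly.
#' @export
run_pipeline <- function(config,
                         stages = c("affinity", "rank", "pairscan",
                                    "similarity", "tissue", "network")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  written <- list()

  if ("affinity" %in% stages) {
    if (!is.null(config$inputs$affinity_tsv)) {
      tab <- read_affinity_tsv(.need_file(config$inputs$affinity_tsv,
                                          "affinity"))
    } else {
      proms <- .load_promoters(config)
      pwms <- .load_pwms(config)
      tab <- build_affinity_table(
        proms, pwms,
        affinity_params(lambda = config$affinity$lambda,
                        R0 = config$affinity$R0),
        verbose = config$verbose)
    }
    written$affinity <- write_affinity_tsv(tab, .artifact(config, "affinity.tsv"))
    .stage_log(config, "affinity", length(tab$genes),
               sprintf("%d TFs, lambda = %g", length(tab$tfs),
                       config$affinity$lambda))
  }

  if ("rank" %in% stages) {
    tab <- read_affinity_tsv(.need_file(.artifact(config, "affinity.tsv"),
                                        "rank"))
    lists <- build_ranked_lists(tab)
    df <- do.call(rbind, lapply(lists, function(l)
      data.frame(tf_id = l$tf_id, rank = seq_along(l$genes),
                 gene_id = l$genes, affinity = l$affinities,
                 stringsAsFactors = FALSE)))
    written$rank <- .artifact(config, "ranks.tsv")
    write.table(df, written$rank, sep = "\t", quote = FALSE,
                row.names = FALSE)
    .stage_log(config, "rank", nrow(df))
  }

  if ("pairscan" %in% stages) {
    lists <- .read_ranks(.need_file(.artifact(config, "ranks.tsv"),
                                    "pairscan"))
    res <- scan_all_pairs(lists, grid = config$grid,
                          verbose = config$verbose)
    written$pairscan <- write_pairs_tsv(res, .artifact(config, "pairs.tsv"))
    .stage_log(config, "pairscan", nrow(res),
               sprintf("grid %d cells", length(config$grid)^2))
  }

  if ("similarity" %in% stages) {
    if (!is.null(config$inputs$similarity_tsv)) {
      sim <- read_similarity_tsv(.need_file(config$inputs$similarity_tsv,
                                            "similarity"))
    } else {
      sim <- build_similarity_matrix(.load_pwms(config),
                                     background = config$affinity$background,
                                     hit_p = config$similarity$hit_p,
                                     method = config$similarity$method,
                                     n_mc = config$similarity$n_mc,
                                     seed = config$seed,
                                     verbose = config$verbose)
    }
    written$similarity <- write_similarity_tsv(
      sim, .artifact(config, "similarity.tsv"))
    .stage_log(config, "similarity", length(sim$tfs),
               sprintf("cutoff %g", config$similarity$cutoff))
  }

  if ("tissue" %in% stages) {
    lists <- .read_ranks(.need_file(.artifact(config, "ranks.tsv"),
                                    "tissue"))
    tissues <- read_tissue_sets(.need_file(config$inputs$tissues, "tissue"))
    simpath <- .artifact(config, "similarity.tsv")
    sim <- if (file.exists(simpath)) read_similarity_tsv(simpath) else NULL
    res <- tissue_scan(lists, tissues, L = config$tissue$L, sim = sim,
                       cutoff = config$similarity$cutoff,
                       verbose = config$verbose)
    written$tissue <- write_tissue_results_tsv(
      res, .artifact(config, "tissue_tests.tsv"))
    .stage_log(config, "tissue", nrow(res),
               sprintf("L = %d", config$tissue$L))
  }

  if ("network" %in% stages) {
    if (config$context == "global") {
      res <- read_pairs_tsv(.need_file(.artifact(config, "pairs.tsv"),
                                       "network"))
    } else {
      res <- read_tissue_results_tsv(
        .need_file(.artifact(config, "tissue_tests.tsv"), "network"))
    }
    calls <- call_interactions(
      res, threshold_log10_p = unname(config$thresholds[config$context]),
      context = config$context)
    if (!is.null(config$inputs$ppi_tsv)) {
      ppi <- read_ppi_tsv(.need_file(config$inputs$ppi_tsv, "network"))
      calls <- annotate_evidence(calls, ppi)
    }
    net <- build_network(calls, context = config$context)
    written$network <- write_network_tsv(net, .artifact(config, "network.tsv"))
    written$graphml <- write_network_graphml(
      net, .artifact(config, "network.graphml"))
    hubs <- if (nrow(net$nodes) > 0L) find_hubs(net) else character(0)
    written$hubs <- .artifact(config, "hubs.tsv")
    write.table(data.frame(tf_id = hubs), written$hubs, sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(config$inputs$ppi_tsv)) {
      universe <- if (config$context == "global")
        res[, c("tf_a", "tf_b")]
      else unique(res[, c("tf_a", "tf_b")])
      enr <- ppi_enrichment(calls, universe, ppi)
      written$enrichment <- .artifact(config, "ppi_enrichment.tsv")
      write.table(
        data.frame(context = config$context, n_calls = nrow(calls),
                   n_tested = nrow(unique(universe)),
                   ppi_fraction_called = enr$ppi_fraction_called %||% NA,
                   ppi_fraction_universe = enr$ppi_fraction_universe,
                   fold = enr$fold, fisher_p = enr$fisher_p),
        written$enrichment, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    .stage_log(config, "network", nrow(calls),
               sprintf("context %s, threshold %g", config$context,
                       config$thresholds[config$context]))
  }

  invisible(written)
}

.read_ranks <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  lapply(split(df, df$tf_id), function(d) {
    d <- d[order(d$rank), , drop = FALSE]
    structure(list(tf_id = d$tf_id[1L], genes = d$gene_id,
                   affinities = d$affinity),
              class = "ranked_targets")
  })
}

#' Generate and write a synthetic fixture (the `simulate` stage)
#'
#' @param out_dir output directory for the fixture files.
#' @param seed fixture seed.
#' @param spec optional `fixture_spec`; default standard benchmark with
#'   the given seed.
#' @return named list of written paths, invisibly.
#' @export
simulate_fixture <- function(out_dir, seed = 1L, spec = NULL) {
  spec <- spec %||% fixture_spec(seed = seed)
  write_fixture(generate_fixture(spec), out_dir)
}
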