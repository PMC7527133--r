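#' Default pipeline configuration
#'
#' Bundles every tunable of the pipeline with the defaults of the
#' published analysis: rarefaction depth 1500 (time series) or 500
#' (mixed cultures); the time-series filter preset "detected in at
#' least 29 samples and total relative abundance at least 0.1% of
#' reads"; SparCC with max_iter 100, th 0.1, exiter 10 and 100 two-sided
#' bootstraps; neighborhood selection with nlambda 20,
#' lambda.min.ratio 1e-2 and 50 StARS repetitions; consensus over the
#' dataset's method trio at |coef| > 0.3 with at least 2 supporting
#' methods.
#'
#' @param dataset `"TS"` (time series) or `"MC"` (mixed cultures);
#'   selects depth, filtering strategy and method trio.
#' @param seed Integer master seed; stage seeds are derived from it.
#' @param ... Named overrides for any top-level entry.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(dataset = c("TS", "MC"), seed = 1L, ...) {
  dataset <- match.arg(dataset)
  cfg <- list(
    dataset = dataset,
    seed = as.integer(seed),
    depth = if (dataset == "TS") 1500 else 500,
    filter = if (dataset == "TS") {
      list(mode = "preset", min_samples = 29, min_total_ra_pct = 0.1,
           strict = FALSE)
    } else {
      list(mode = "singletons")
    },
    sweep = list(min_samples_grid = c(2, 5, 10, 20, 29, 46),
                 min_total_ra_grid_reads = c(1, 15, 50, 100, 150),
                 max_sparsity = 0.5, min_mean_n_eff = 10),
    methods = if (dataset == "TS") c("pearson", "sparcc", "mb") else
      c("pearson", "dice", "mb"),
    sparcc = list(max_iter = 100, th = 0.1, exiter = 10,
                  n_boot = 100, two_sided = TRUE, run_bootstrap = FALSE),
    mb = list(nlambda = 20, lambda_min_ratio = 1e-2, n_reps = 50,
              beta = 0.05),
    consensus = list(min_methods = 2, min_abs_coef = 0.3, strict = TRUE)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full co-occurrence pipeline on one OTU table
#'
#' Rarefies, filters (time series: the detection/abundance preset or
#' the sweep; mixed cultures: singleton removal), runs the configured
#' association methods, thresholds each into an edge set, votes the
#' consensus network, and (when planted truth is supplied) scores
#' recovery. The whole run is deterministic given the config seed.
#'
#' @param table An `otu_table`.
#' @param config A `pipeline_config` (defaults match the table's
#'   dataset tag when omitted).
#' @param truth Optional `truth_network` for recovery scoring.
#' @param out_dir Optional directory; when given, the filtered table,
#'   per-method edge lists, consensus edge list (TSV) and GraphML are
#'   written there.
#' @return List of class `pipeline_result`: `network`, `filtered`
#'   (the network-ready `otu_table`), `summary` (its `table_summary`),
#'   `methods` (per-method `correlation_result`s and states),
#'   `edge_sets`, `recovery` (or `NULL`), `config`.
#' @export
run_pipeline <- function(table, config = NULL, truth = NULL,
                         out_dir = NULL) {
  if (is.null(config)) {
    ds <- if (!is.null(table$sample_data) &&
              "dataset" %in% names(table$sample_data)) {
      table$sample_data$dataset[1]
    } else "TS"
    config <- pipeline_config(ds)
  }
  if (length(config$methods) < 2) {
    stop("consensus needs at least 2 methods; got: ",
         paste(config$methods, collapse = ", "))
  }
  seeds <- withr::with_seed(config$seed,
                            sample.int(.Machine$integer.max - 1, 8))
  rar <- rarefy(table, config$depth, seed = seeds[1])
  if (identical(config$filter$mode, "preset")) {
    min_total <- config$filter$min_total_ra_pct / 100 * n_samples(rar)
    filtered <- filter_table(rar, config$filter$min_samples, min_total,
                             strict = isTRUE(config$filter$strict))
    sweep_out <- NULL
  } else if (identical(config$filter$mode, "sweep")) {
    grid_ra <- config$sweep$min_total_ra_grid_reads / config$depth
    sweep_out <- filter_sweep(rar, config$sweep$min_samples_grid, grid_ra,
                              max_sparsity = config$sweep$max_sparsity,
                              min_mean_n_eff = config$sweep$min_mean_n_eff)
    filtered <- sweep_out$table
  } else {
    filtered <- drop_singletons(rar)
    sweep_out <- NULL
  }
  if (n_otus(filtered) < 4) {
    stop("stage filter: fewer than 4 OTUs survive filtering")
  }
  method_out <- list()
  for (m in config$methods) {
    method_out[[m]] <- switch(
      m,
      pearson = list(result = pearson_matrix(filtered)),
      sparcc = {
        sp <- sparcc(filtered, config$sparcc$max_iter, config$sparcc$th,
                     config$sparcc$exiter, seed = seeds[2])
        if (isTRUE(config$sparcc$run_bootstrap)) {
          pv <- sparcc_pvalues(filtered, config$sparcc$n_boot,
                               seed = seeds[3],
                               max_iter = config$sparcc$max_iter,
                               th = config$sparcc$th,
                               exiter = config$sparcc$exiter,
                               rho_obs = sp$result$coef)
          sp$result$p_raw <- pv$p_raw
          sp$result$p_adj <- pv$p_adj
        }
        sp
      },
      dice = list(result = dice_sorensen(filtered)),
      mb = mb_network(filtered, config$mb$nlambda,
                      config$mb$lambda_min_ratio, config$mb$n_reps,
                      config$mb$beta, seed = seeds[4]),
      stop("unknown method: ", m)
    )
  }
  edge_sets <- lapply(method_out, function(mo) {
    threshold_edges(mo$result, config$consensus$min_abs_coef,
                    strict = isTRUE(config$consensus$strict))
  })
  network <- build_consensus(edge_sets, config$consensus$min_methods,
                             table = filtered)
  recovery <- if (!is.null(truth)) evaluate_recovery(network, truth)
  out <- structure(list(network = network, filtered = filtered,
                        summary = summarize_table(filtered),
                        methods = method_out, edge_sets = edge_sets,
                        sweep = sweep_out, recovery = recovery,
                        config = config),
                   class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_otu_table_tsv(filtered,
                        file.path(out_dir, "filtered_otu_table.tsv"))
    for (m in names(edge_sets)) {
      utils::write.table(edge_sets[[m]],
                         file.path(out_dir, paste0("edges_", m, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_network_tsv(network, file.path(out_dir, "consensus_edges.tsv"))
    write_network_graphml(network,
                          file.path(out_dir, "consensus_network.graphml"))
  }
  out
}

#' Generate the default planted-network benchmark
#'
#' The standard validation scenario: 100 OTUs in 6 phyla, 30 planted
#' edges at strength 0.8 (a quarter negative), 200 weekly samples at
#' depth 1500.
#'
#' @param seed Integer seed.
#' @param n_otus,n_phyla,n_edges,strength,frac_negative,n_samples,depth
#'   Scenario parameters; defaults define the benchmark.
#' @return List with `taxa`, `truth`, `table`.
#' @export
synthetic_benchmark <- function(seed = 1L, n_otus = 100, n_phyla = 6,
                                n_edges = 30, strength = 0.8,
                                frac_negative = 0.25, n_samples = 200,
                                depth = 1500) {
  taxa <- make_taxonomy(n_otus, n_phyla, seed = seed)
  truth <- make_truth_network(taxa, n_edges,
                              frac_negative = frac_negative,
                              strength = strength, seed = seed + 1L)
  tab <- simulate_timeseries(taxa, truth, n_samples, depth = depth,
                             seed = seed + 2L)
  list(taxa = taxa, truth = truth, table = tab)
}

#' Run the planted-network benchmark end to end
#'
#' Generates the default benchmark for one seed, runs the time-series
#' pipeline (pearson + sparcc + mb; permissive filtering, since every
#' simulated OTU is network-eligible by construction) and scores
#' recovery against the planted truth.
#'
#' @param seed Integer seed.
#' @param ... Passed to [synthetic_benchmark()].
#' @return The `pipeline_result`, including `$recovery`.
#' @export
benchmark_recovery <- function(seed = 1L, ...) {
  bench <- synthetic_benchmark(seed = seed, ...)
  cfg <- pipeline_config("TS", seed = seed,
                         filter = list(mode = "preset", min_samples = 2,
                                       min_total_ra_pct = 0.0001,
                                       strict = FALSE))
  run_pipeline(bench$table, cfg, truth = bench$truth)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result [%s]: %d OTUs after filtering -> %d consensus edges\n",
              x$config$dataset, n_otus(x$filtered), nrow(x$network$edges)))
  if (!is.null(x$recovery)) print(x$recovery)
  invisible(x)
}
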