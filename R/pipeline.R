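.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

.config_regimes <- function(cfg) {
  lapply(cfg$calendar$regimes, function(r)
    wind_regime(r$months, r$bearing_deg, r$speed_kmh,
                r$dir_noise_deg %||% 0, r$speed_noise_kmh %||% 0))
}

#' Read a pipeline configuration file
#'
#' YAML configuration with blocks `seed`, `grid` (n_rows, n_cols, cell_km,
#' origin), `calendar` (start, end, drop_leap, regimes), and optional
#' `duration_h`, `si` (threshold, steps), `pareto` (fraction, score) and
#' `cluster` (k, method, ga parameters). See the packaged example under
#' `system.file("extdata", "toy_config.yaml", package = "airnet")`.
#'
#' @param path YAML file path.
#' @return configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

#' Run the full connectivity pipeline
#'
#' Executes, in order: trajectory synthesis, daily network construction,
#' full/seasonal/monthly aggregation, the five-metric report, cut-distance
#' clustering of the monthly networks, Pareto near-front edge selection,
#' and node-relevance plus SI indices for the full and seasonal networks.
#' All randomness is governed by `config$seed`; running the same
#' configuration twice produces byte-identical outputs.
#'
#' @param config configuration list (see [read_config()]) or a YAML path.
#' @param out_dir output directory (created if needed).
#' @return named list of written file paths, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_config(config)
  if (is.null(config$seed)) stop("config must set a 'seed'", call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(config$seed)

  grid <- .stage("grid", make_lattice_grid(
    config$grid$n_rows, config$grid$n_cols, config$grid$cell_km,
    as.numeric(unlist(config$grid$origin))))

  cal <- .stage("calendar", synth_calendar(
    config$calendar$start, config$calendar$end, .config_regimes(config)))

  ts <- .stage("synth", generate_trajectories(
    grid, cal, duration_h = config$duration_h %||% 48L, seed = seed,
    drop_leap = isTRUE(config$calendar$drop_leap)))

  dailies <- .stage("build", build_daily_networks(ts, grid))

  aggs <- .stage("aggregate", c(
    project_periods(dailies, "full"),
    project_periods(dailies, "seasonal"),
    project_periods(dailies, "monthly")))

  paths <- list()
  metrics <- .stage("metrics",
    do.call(rbind, lapply(aggs, network_metrics)))
  metrics$weight_distance_correlation <-
    vapply(aggs, function(a) suppressWarnings(weight_distance_correlation(a)), 0)
  paths$metrics <- file.path(out_dir, "metrics.csv")
  write.csv(metrics, paths$metrics, row.names = FALSE)

  monthlies <- aggs[names(aggs) %in% month.name]
  cl_cfg <- config$cluster %||% list()
  if (length(monthlies) >= 2) {
    dm <- .stage("cluster", monthly_distance_matrix(
      monthlies, method = cl_cfg$method %||% "auto", seed = seed + 1000L,
      pop_size = cl_cfg$ga$pop_size %||% 50,
      generations = cl_cfg$ga$generations %||% 200,
      mutation_rate = cl_cfg$ga$mutation_rate %||% 0.05,
      elitism = cl_cfg$ga$elitism %||% 2))
    cl <- cluster_months(dm, k = cl_cfg$k %||% 2)
    paths$distance_matrix <- file.path(out_dir, "cut_distance_matrix.csv")
    write.csv(as.data.frame(dm), paths$distance_matrix)
    paths$clusters <- file.path(out_dir, "month_clusters.csv")
    write.csv(data.frame(month = names(cl), cluster = as.integer(cl)),
              paths$clusters, row.names = FALSE)
    paths$dendrogram <- file.path(out_dir, "month_dendrogram.nwk")
    writeLines(ape::write.tree(ape::as.phylo(attr(cl, "tree"))),
               paths$dendrogram)
  }

  full <- aggs[[1]]
  pareto_cfg <- config$pareto %||% list()
  sel <- .stage("pareto", select_near_front(
    edge_cloud(full), fraction = pareto_cfg$fraction %||% 0.01,
    score = pareto_cfg$score %||% "polyline"))
  paths$pareto <- file.path(out_dir, "pareto_selected_edges.csv")
  write.csv(sel, paths$pareto, row.names = FALSE)

  si_cfg <- si_config(config$si$threshold %||% 0.1, config$si$steps %||% 6L)
  periods <- aggs[!names(aggs) %in% month.name]
  for (p in names(periods)) {
    tab <- .stage("indices", compute_indices(periods[[p]]))
    si <- .stage("si", si_indices(periods[[p]], si_cfg))
    tab$si_persistence <- si$persistence
    tab$si_frequency <- si$frequency
    f <- file.path(out_dir, sprintf("node_indices_%s.csv", p))
    write.csv(cbind(id = rownames(tab), tab), f, row.names = FALSE)
    paths[[paste0("indices_", p)]] <- f
  }

  paths$network_edges <- file.path(out_dir, "network_full_edges.csv")
  paths$network_nodes <- file.path(out_dir, "network_full_nodes.csv")
  write_agg_network(full, paths$network_edges, paths$network_nodes)

  cfg_file <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "airnet",
    version = as.character(utils::packageVersion("airnet")),
    seed = seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    n_trajectories = length(ts$arrival_node),
    n_days = length(dailies),
    n_cells = grid$N,
    outputs = lapply(paths, basename))
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}
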