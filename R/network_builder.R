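#' Cells visited by a trajectory
#'
#' Ids of all grid cells containing at least one hourly position of the
#' trajectory (the arrival cell included). Containment is tested at the
#' hourly positions only, in 2-D (altitude ignored).
#'
#' @param traj an `air_trajectory` (see [get_trajectory()]).
#' @param grid an `air_grid`.
#' @return sorted integer vector of cell ids (possibly empty).
#' @export
visited_cells <- function(traj, grid) {
  stopifnot(inherits(traj, "air_trajectory"))
  ids <- locate_points(grid, traj$positions$lon, traj$positions$lat)
  sort(unique(ids[!is.na(ids)]))
}

#' Build the daily contact network for one day
#'
#' Binary directed adjacency `E_t` with `E_t[j, i] = 1` when the trajectory
#' arriving at cell i on day t passed over cell j during the preceding
#' hours (edge direction source -> arrival). Self-loops are excluded.
#'
#' @param ts a `trajectory_set` (only trajectories of `day` are used; all
#'   trajectories must share that day if `day` is omitted).
#' @param grid an `air_grid`.
#' @param day the arrival day (defaults to the single day present in `ts`).
#' @return a `daily_network`: list with `day` and binary matrix `E`
#'   (dimnames = cell ids).
#' @export
build_daily_network <- function(ts, grid, day = NULL) {
  stopifnot(inherits(ts, "trajectory_set"), inherits(grid, "air_grid"))
  if (is.null(day)) {
    day <- unique(ts$arrival_day)
    if (length(day) != 1)
      stop("trajectory set spans several days; give 'day'", call. = FALSE)
  }
  day <- as.Date(day)
  sel <- which(ts$arrival_day == day)
  if (anyDuplicated(ts$arrival_node[sel]))
    stop("duplicate arrival nodes for day ", format(day), call. = FALSE)
  ids <- grid$cells$id
  E <- matrix(0, grid$N, grid$N, dimnames = list(ids, ids))
  idx <- match(ts$arrival_node[sel], ids)
  for (k in seq_along(sel)) {
    i <- sel[k]
    vis <- locate_points(grid, ts$lon[i, ], ts$lat[i, ])
    vis <- unique(vis[!is.na(vis)])
    src <- match(setdiff(vis, ts$arrival_node[i]), ids)
    E[src, idx[k]] <- 1
  }
  structure(list(day = day, E = E), class = "daily_network")
}

#' Build daily networks for every day of a trajectory set
#'
#' Vectorized point location over the whole set, then one binary network per
#' arrival day.
#'
#' @inheritParams build_daily_network
#' @return a named list of `daily_network` (names = ISO dates) carrying the
#'   grid's node table as attribute `"nodes"`.
#' @export
build_daily_networks <- function(ts, grid) {
  stopifnot(inherits(ts, "trajectory_set"), inherits(grid, "air_grid"))
  ids <- grid$cells$id
  n <- length(ts$arrival_node)
  cell_of <- matrix(locate_points(grid, as.vector(ts$lon), as.vector(ts$lat)),
                    nrow = n)
  days <- sort(unique(ts$arrival_day))
  arr_idx <- match(ts$arrival_node, ids)
  out <- vector("list", length(days))
  names(out) <- format(days)
  for (d in seq_along(days)) {
    sel <- which(ts$arrival_day == days[d])
    if (anyDuplicated(ts$arrival_node[sel]))
      stop("duplicate arrival nodes for day ", format(days[d]), call. = FALSE)
    E <- matrix(0, grid$N, grid$N, dimnames = list(ids, ids))
    for (i in sel) {
      vis <- unique(cell_of[i, ])
      vis <- vis[!is.na(vis) & vis != ts$arrival_node[i]]
      E[match(vis, ids), arr_idx[i]] <- 1
    }
    out[[d]] <- structure(list(day = days[d], E = E), class = "daily_network")
  }
  attr(out, "nodes") <- grid$cells
  out
}

#' Construct an aggregated (weighted) network
#'
#' Low-level constructor; see [aggregate_networks()] for the usual entry
#' point. Weights must lie in `[0, 1]` and the diagonal must be zero.
#'
#' @param E weighted adjacency matrix.
#' @param nodes optional data.frame (`id`, `lon`, `lat`) of node coordinates.
#' @param label period label (e.g. `"2011-2017"`, `"winter"`, `"January"`).
#' @param n_days number of daily networks averaged into `E`.
#' @return an `agg_network` object.
#' @export
agg_network <- function(E, nodes = NULL, label = "", n_days = NA_integer_) {
  E <- as.matrix(E)
  stopifnot(nrow(E) == ncol(E))
  if (any(E < 0) || any(E > 1)) stop("weights must lie in [0, 1]", call. = FALSE)
  if (any(diag(E) != 0)) stop("diagonal must be zero (no self-loops)", call. = FALSE)
  if (is.null(dimnames(E))) {
    ids <- if (!is.null(nodes)) nodes$id else seq_len(nrow(E))
    dimnames(E) <- list(ids, ids)
  }
  structure(list(E = E, nodes = nodes, label = label, n_days = n_days),
            class = "agg_network")
}

#' @export
print.agg_network <- function(x, ...) {
  cat(sprintf("<agg_network> '%s': %d nodes, %d non-null edges%s\n",
              x$label, nrow(x$E), sum(x$E > 0),
              if (is.na(x$n_days)) "" else sprintf(" (mean of %d days)", x$n_days)))
  invisible(x)
}

#' Aggregate daily networks over a day subset
#'
#' Elementwise mean of the selected binary daily adjacencies:
#' `E_S(i,j) = sum_{t in S} E_t(i,j) / |S|`. Each weight is therefore the
#' fraction of days of S on which the connection i -> j occurred.
#'
#' @param dailies list of `daily_network` (as from [build_daily_networks()]).
#' @param days subset S of days to average (default: all days present);
#'   every requested day must be present.
#' @param label period label for the result.
#' @param nodes node coordinate table; defaults to `attr(dailies, "nodes")`.
#' @return an `agg_network`.
#' @export
aggregate_networks <- function(dailies, days = NULL, label = "",
                               nodes = attr(dailies, "nodes")) {
  all_days <- as.Date(vapply(dailies, function(d) format(d$day), ""))
  if (is.null(days)) days <- all_days
  days <- as.Date(days)
  if (!length(days)) stop("day subset S must be non-empty", call. = FALSE)
  sel <- match(days, all_days)
  if (anyNA(sel))
    stop("day(s) not present in 'dailies': ",
         paste(format(days[is.na(sel)]), collapse = ", "), call. = FALSE)
  E <- Reduce(`+`, lapply(dailies[sel], `[[`, "E")) / length(sel)
  agg_network(E, nodes = nodes, label = label, n_days = length(sel))
}

#' Project daily networks onto standard period schemes
#'
#' Aggregates the daily networks at full, yearly, monthly or seasonal
#' cadence. The default seasonal map follows the Mediterranean two-season
#' split: summer = May-September, winter = October-April.
#'
#' @param dailies list of `daily_network`.
#' @param scheme one of `"full"`, `"yearly"`, `"monthly"`, `"seasonal"`.
#' @param season_map named integer vector mapping month number to season
#'   name, e.g. the default `c("1"="winter", ..., "5"="summer", ...)`; must
#'   cover all months present under the seasonal scheme.
#' @param nodes node table; defaults to `attr(dailies, "nodes")`.
#' @return named list of `agg_network`, one per period (months are labelled
#'   by English month name, years by calendar year).
#' @export
project_periods <- function(dailies,
                            scheme = c("full", "yearly", "monthly", "seasonal"),
                            season_map = default_season_map(),
                            nodes = attr(dailies, "nodes")) {
  scheme <- match.arg(scheme)
  days <- as.Date(vapply(dailies, function(d) format(d$day), ""))
  grp <- switch(scheme,
    full = rep(sprintf("%s-%s", format(min(days), "%Y"), format(max(days), "%Y")),
               length(days)),
    yearly = format(days, "%Y"),
    monthly = month.name[as.integer(format(days, "%m"))],
    seasonal = {
      m <- as.integer(format(days, "%m"))
      s <- season_map[as.character(m)]
      if (anyNA(s))
        stop("season map does not cover month(s): ",
             paste(unique(m[is.na(s)]), collapse = ", "), call. = FALSE)
      unname(s)
    })
  lv <- if (scheme == "monthly") month.name[month.name %in% grp] else unique(grp)
  out <- lapply(lv, function(g)
    aggregate_networks(dailies, days[grp == g], label = g, nodes = nodes))
  names(out) <- lv
  out
}

#' Default two-season month map (summer May-Sep, winter Oct-Apr)
#' @return named character vector, names "1".."12".
#' @export
default_season_map <- function() {
  setNames(ifelse(1:12 %in% 5:9, "summer", "winter"), 1:12)
}

#' Write / read an aggregated network as plain-text tables
#'
#' The edge list holds one row per non-null directed edge (`src`, `dst`,
#' `weight`); the node table holds `id`, `lon`, `lat`.
#'
#' @param net an `agg_network` (with node coordinates for `write`).
#' @param edge_file,node_file CSV paths.
#' @param label label to attach on read.
#' @param n_days day count to attach on read.
#' @return `write_agg_network` returns `net` invisibly; `read_agg_network`
#'   returns an `agg_network`.
#' @export
write_agg_network <- function(net, edge_file, node_file) {
  stopifnot(inherits(net, "agg_network"))
  idx <- which(net$E > 0, arr.ind = TRUE)
  ids <- as.integer(rownames(net$E))
  edges <- data.frame(src = ids[idx[, 1]], dst = ids[idx[, 2]],
                      weight = net$E[idx])
  edges <- edges[order(edges$src, edges$dst), ]
  write.csv(edges, edge_file, row.names = FALSE)
  if (!is.null(net$nodes))
    write.csv(net$nodes[, c("id", "lon", "lat")], node_file, row.names = FALSE)
  invisible(net)
}

#' @rdname write_agg_network
#' @export
read_agg_network <- function(edge_file, node_file, label = "",
                             n_days = NA_integer_) {
  edges <- read.csv(edge_file)
  nodes <- read.csv(node_file)
  N <- nrow(nodes)
  E <- matrix(0, N, N, dimnames = list(nodes$id, nodes$id))
  E[cbind(match(edges$src, nodes$id), match(edges$dst, nodes$id))] <- edges$weight
  agg_network(E, nodes = nodes, label = label, n_days = n_days)
}
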