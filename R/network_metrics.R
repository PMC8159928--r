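.net_matrix <- function(net) {
  if (inherits(net, "agg_network")) net$E else as.matrix(net)
}

#' Weighted network density
#'
#' Ratio between the sum of all edge weights and the number of possible
#' directed edges `N (N - 1)`.
#'
#' @param net an `agg_network` or weighted adjacency matrix.
#' @return scalar in `[0, 1]` for day-fraction weights.
#' @export
net_density <- function(net) {
  E <- .net_matrix(net)
  N <- nrow(E)
  if (N < 2) stop("density needs at least 2 nodes", call. = FALSE)
  (sum(E) - sum(diag(E))) / (N * (N - 1))
}

#' Global weighted transitivity (clustering)
#'
#' Density applied to triplets instead of pairs: on the symmetrized weight
#' matrix `W = (E + t(E)) / 2`, each connected triplet centred at a node
#' contributes the arithmetic mean of its two tie weights; the coefficient
#' is the total value of closed triplets over the total value of all
#' connected triplets. Reduces to the classical binary transitivity on
#' unweighted graphs.
#'
#' @param net an `agg_network` or adjacency matrix.
#' @return scalar in `[0, 1]`; 0 (with a warning) when the network has no
#'   connected triplet.
#' @export
net_transitivity <- function(net) {
  E <- .net_matrix(net)
  if (nrow(E) < 3) stop("transitivity needs at least 3 nodes", call. = FALSE)
  W <- (E + t(E)) / 2
  diag(W) <- 0
  A <- (W > 0) * 1
  # ordered-triplet identities: value sums telescope to strength * (degree-1)
  denom <- sum(rowSums(W) * (rowSums(A) - 1))
  if (denom <= 0) {
    warning("no connected triplets; transitivity undefined, returning 0")
    return(0)
  }
  num <- sum(W * (A %*% A))
  num / denom
}

#' In/out strength correlation
#'
#' Pearson correlation across nodes between in-strength (column sums of the
#' weighted adjacency) and out-strength (row sums). Positive values foster,
#' negative values hamper, epidemic spread.
#'
#' @param net an `agg_network` or adjacency matrix.
#' @return scalar in `[-1, 1]`; `NA` (with a warning) when either strength
#'   is constant across nodes.
#' @export
strength_correlation <- function(net) {
  E <- .net_matrix(net)
  if (nrow(E) < 3) stop("strength correlation needs at least 3 nodes", call. = FALSE)
  s_in <- colSums(E); s_out <- rowSums(E)
  if (stats::sd(s_in) == 0 || stats::sd(s_out) == 0) {
    warning("constant strengths; correlation undefined")
    return(NA_real_)
  }
  cor(s_in, s_out)
}

#' Effective distance matrix
#'
#' Row-standardizes the weighted adjacency (`P(i,j) = E(i,j) / sum_j E(i,j)`,
#' all-zero rows left at zero) and converts connection probabilities into
#' path costs: `ED(i,j) = 1 - ln P(i,j)` on positive entries, `Inf` where no
#' edge exists (including the diagonal). Finite entries are always >= 1,
#' with equality iff a node has a single out-neighbour.
#'
#' @param net an `agg_network` or adjacency matrix.
#' @return numeric matrix of effective distances.
#' @export
effective_distances <- function(net) {
  E <- .net_matrix(net)
  rs <- rowSums(E)
  P <- E / ifelse(rs > 0, rs, 1)
  ED <- matrix(Inf, nrow(E), ncol(E), dimnames = dimnames(E))
  pos <- P > 0
  ED[pos] <- 1 - log(P[pos])
  diag(ED) <- Inf
  ED
}

.ed_graph <- function(ED) {
  W <- ED
  W[!is.finite(W)] <- 0
  igraph::graph_from_adjacency_matrix(W, mode = "directed", weighted = TRUE)
}

#' Diameter and average shortest path on the effective-distance graph
#'
#' All-pairs Dijkstra shortest paths on the directed graph whose edge costs
#' are effective distances. The diameter is the longest and the average the
#' mean of the shortest paths over all reachable ordered pairs of distinct
#' nodes; unreachable pairs are excluded and counted.
#'
#' @param ED an effective-distance matrix (see [effective_distances()]), or
#'   an `agg_network` (converted internally).
#' @return list with `diameter`, `average_shortest_path`,
#'   `unreachable_pairs` and `n_pairs` (reachable ordered pairs used).
#' @export
shortest_path_stats <- function(ED) {
  if (inherits(ED, "agg_network")) ED <- effective_distances(ED)
  off <- ED[row(ED) != col(ED)]
  if (!any(is.finite(off)))
    stop("fully disconnected network: no finite effective distance", call. = FALSE)
  g <- .ed_graph(ED)
  D <- igraph::distances(g, mode = "out", algorithm = "dijkstra")
  d_off <- D[row(D) != col(D)]
  fin <- is.finite(d_off)
  list(diameter = max(d_off[fin]),
       average_shortest_path = mean(d_off[fin]),
       unreachable_pairs = sum(!fin),
       n_pairs = sum(fin))
}

#' Correlation between edge weights and geographical distances
#'
#' Pearson correlation, over non-null directed edges only, between the
#' great-circle distance separating the two centroids (haversine, 6371 km
#' sphere) and the edge weight. Negative values indicate the
#' Tobler-consistent pattern of nearby cells being more strongly connected.
#'
#' @param net an `agg_network` with node coordinates.
#' @return scalar correlation; `NA` (with a warning) when fewer than 3
#'   non-null edges exist or the weights are constant.
#' @export
weight_distance_correlation <- function(net) {
  stopifnot(inherits(net, "agg_network"))
  if (is.null(net$nodes)) stop("node coordinates required", call. = FALSE)
  cl <- edge_cloud(net)
  if (nrow(cl) < 3) {
    warning("fewer than 3 non-null edges; correlation undefined")
    return(NA_real_)
  }
  if (stats::sd(cl$weight) == 0 || stats::sd(cl$distance_km) == 0) {
    warning("zero variance in weights or distances; correlation undefined")
    return(NA_real_)
  }
  cor(cl$distance_km, cl$weight)
}

#' Full metric report for a network
#'
#' Computes the five-metric suite (diameter, density, transitivity,
#' strength correlation, average shortest path) on an aggregated network.
#'
#' @param net an `agg_network`.
#' @param label row label (defaults to the network's label).
#' @return one-row data.frame in the column order diameter, density,
#'   transitivity, strength_correlation, average_shortest_path.
#' @export
network_metrics <- function(net, label = NULL) {
  stopifnot(inherits(net, "agg_network"))
  sp <- shortest_path_stats(effective_distances(net))
  data.frame(label = label %||% net$label,
             diameter = sp$diameter,
             density = net_density(net),
             transitivity = net_transitivity(net),
             strength_correlation = strength_correlation(net),
             average_shortest_path = sp$average_shortest_path)
}
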