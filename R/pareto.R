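#' Weight-distance edge cloud
#'
#' One record per non-null directed edge of an aggregated network, pairing
#' its weight with the great-circle distance (haversine, 6371 km sphere)
#' between the source and destination centroids. This cloud is the basis of
#' the Pareto-front comparison of spatial weighted networks: the edges of
#' interest are those that jointly maximize weight and geographical
#' distance.
#'
#' @param net an `agg_network` with node coordinates.
#' @return data.frame (`src`, `dst`, `distance_km`, `weight`) with the
#'   network label as attribute `"label"`.
#' @export
edge_cloud <- function(net) {
  stopifnot(inherits(net, "agg_network"))
  if (is.null(net$nodes)) stop("node coordinates required", call. = FALSE)
  idx <- which(net$E > 0, arr.ind = TRUE)
  if (!nrow(idx)) stop("network has no non-null edge", call. = FALSE)
  ids <- as.integer(rownames(net$E))
  pos <- match(ids, net$nodes$id)
  p1 <- as.matrix(net$nodes[pos[idx[, 1]], c("lon", "lat")])
  p2 <- as.matrix(net$nodes[pos[idx[, 2]], c("lon", "lat")])
  cl <- data.frame(
    src = ids[idx[, 1]], dst = ids[idx[, 2]],
    distance_km = geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_KM * 1000) / 1000,
    weight = net$E[idx])
  cl <- cl[order(cl$src, cl$dst), ]
  rownames(cl) <- NULL
  attr(cl, "label") <- net$label
  cl
}

# indices of the non-dominated records (weak dominance: ties survive)
.front_idx <- function(d, w) {
  n <- length(d)
  ord <- order(d, decreasing = TRUE)
  ds <- d[ord]; ws <- w[ord]
  keep <- logical(n)
  best <- -Inf  # max weight among records with strictly greater distance
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && ds[j + 1] == ds[i]) j <- j + 1  # distance-tie group
    keep[i:j] <- ws[i:j] >= best
    best <- max(best, ws[i:j])
    i <- j + 1
  }
  sort(ord[keep])
}

#' Pareto front of an edge cloud
#'
#' The non-dominated records under weak dominance: a record is dropped only
#' if some other record has strictly greater distance AND strictly greater
#' weight, so ties survive. The front is unique and independent of record
#' order.
#'
#' @param cloud an edge cloud (see [edge_cloud()]), or any data.frame with
#'   `distance_km` and `weight` columns.
#' @return the subset of rows on the front, in original row order.
#' @export
pareto_front <- function(cloud) {
  if (!nrow(cloud)) stop("empty edge cloud", call. = FALSE)
  out <- cloud[.front_idx(cloud$distance_km, cloud$weight), , drop = FALSE]
  attr(out, "label") <- attr(cloud, "label")
  out
}

# Euclidean distance from points (x, y) to segment (x1,y1)-(x2,y2)
.dist_to_segment <- function(x, y, x1, y1, x2, y2) {
  vx <- x2 - x1; vy <- y2 - y1
  L2 <- vx^2 + vy^2
  t <- if (L2 == 0) rep(0, length(x)) else
    pmin(1, pmax(0, ((x - x1) * vx + (y - y1) * vy) / L2))
  sqrt((x - (x1 + t * vx))^2 + (y - (y1 + t * vy))^2)
}

#' Score edges by proximity to the Pareto front
#'
#' Min-max normalizes distance and weight to `[0, 1]` within the cloud
#' (axes have incommensurate units, km versus day-fraction) and scores
#' every record by its Euclidean distance, in the normalized plane, to the
#' Pareto front — either to the polyline joining consecutive front points
#' (default) or to the nearest front point. Front records score 0.
#'
#' @inheritParams pareto_front
#' @param score `"polyline"` or `"point"`.
#' @return numeric score vector, one per record.
#' @export
pareto_scores <- function(cloud, score = c("polyline", "point")) {
  score <- match.arg(score)
  rng <- function(x) if (diff(range(x)) == 0) rep(0.5, length(x)) else
    (x - min(x)) / diff(range(x))
  dn <- rng(cloud$distance_km); wn <- rng(cloud$weight)
  fidx <- .front_idx(cloud$distance_km, cloud$weight)
  o <- order(dn[fidx], -wn[fidx])
  fx <- dn[fidx][o]; fy <- wn[fidx][o]
  s <- numeric(nrow(cloud))
  pts <- setdiff(seq_len(nrow(cloud)), fidx)
  if (!length(pts)) return(s)
  acc <- rep(Inf, length(pts))
  if (score == "point" || length(fx) == 1) {
    for (k in seq_along(fx))
      acc <- pmin(acc, sqrt((dn[pts] - fx[k])^2 + (wn[pts] - fy[k])^2))
  } else {
    for (k in seq_len(length(fx) - 1))
      acc <- pmin(acc, .dist_to_segment(dn[pts], wn[pts], fx[k], fy[k],
                                        fx[k + 1], fy[k + 1]))
  }
  s[pts] <- acc
  s
}

#' Select the edges nearest the Pareto front
#'
#' Returns the `ceiling(fraction * n)` records with the smallest
#' [pareto_scores()] (front records, scoring 0, are always selected first).
#' Ties are broken by higher weight, then higher distance, then row order,
#' so enlarging `fraction` always yields a superset.
#'
#' @inheritParams pareto_scores
#' @param fraction fraction of records to keep, in `(0, 1]` (default 0.01,
#'   i.e. the 1\% of edges lying closest to the front).
#' @return the selected rows with an added `score` column.
#' @export
select_near_front <- function(cloud, fraction = 0.01,
                              score = c("polyline", "point")) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1)
    stop("'fraction' must lie in (0, 1]", call. = FALSE)
  n <- nrow(cloud)
  s <- pareto_scores(cloud, score = score)
  ord <- order(s, -cloud$weight, -cloud$distance_km, seq_len(n))
  sel <- sort(ord[seq_len(ceiling(fraction * n))])
  out <- cloud[sel, , drop = FALSE]
  out$score <- s[sel]
  attr(out, "label") <- attr(cloud, "label")
  out
}
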