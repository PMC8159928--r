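#' Node-relevance indices of an aggregated network
#'
#' Computes the seven standard indices for weighted directed networks:
#' \describe{
#'   \item{betweenness}{number of effective-distance shortest paths a node
#'     bridges (Dijkstra on the ED digraph).}
#'   \item{closeness}{inverse mean ED-shortest-path from the node to the
#'     nodes it can reach (out-closeness); the reachable count is reported
#'     in `closeness_n_reachable`.}
#'   \item{coreness}{k-shell index on the binarized undirected skeleton
#'     (an edge whenever weight > 0 in either direction).}
#'   \item{eigenvector}{leading left eigenvector of the weighted adjacency
#'     (incoming influence by default), nonnegative, max-normalized to 1.}
#'   \item{in_strength / out_strength}{column / row sums of the weights.}
#'   \item{strength}{in_strength + out_strength.}
#' }
#' Binary `in_degree` / `out_degree` (counts of non-null edges) are added
#' for convenience.
#'
#' @param net an `agg_network` with at least 3 nodes.
#' @param eigen_direction `"in"` (left eigenvector, receptor-oriented,
#'   default) or `"out"` (right eigenvector, source-oriented).
#' @return data.frame, one row per node (rownames = node ids), with the
#'   network label as attribute `"label"`.
#' @export
compute_indices <- function(net, eigen_direction = c("in", "out")) {
  stopifnot(inherits(net, "agg_network"))
  eigen_direction <- match.arg(eigen_direction)
  E <- net$E
  N <- nrow(E)
  if (N < 3) stop("node indices need at least 3 nodes", call. = FALSE)
  ED <- effective_distances(net)
  g <- .ed_graph(ED)
  btw <- igraph::betweenness(g, directed = TRUE)
  D <- igraph::distances(g, mode = "out", algorithm = "dijkstra")
  diag(D) <- Inf
  n_reach <- rowSums(is.finite(D))
  clo <- ifelse(n_reach > 0,
                n_reach / rowSums(ifelse(is.finite(D), D, 0)), 0)
  skel <- igraph::graph_from_adjacency_matrix((E > 0) | (t(E) > 0),
                                              mode = "undirected")
  core <- igraph::coreness(skel)
  M <- if (eigen_direction == "in") t(E) else E
  ev <- if (all(M == 0)) rep(0, N) else {
    e <- eigen(M)
    v <- Re(e$vectors[, which.max(abs(Re(e$values)))])
    if (sum(v) < 0) v <- -v
    v <- pmax(v, 0)
    v / max(v)
  }
  out <- data.frame(
    betweenness = unname(btw),
    closeness = clo,
    closeness_n_reachable = n_reach,
    coreness = unname(core),
    eigenvector = ev,
    in_strength = colSums(E),
    out_strength = rowSums(E),
    strength = colSums(E) + rowSums(E),
    in_degree = colSums(E > 0),
    out_degree = rowSums(E > 0),
    row.names = rownames(E))
  attr(out, "label") <- net$label
  out
}

#' Pairwise correlations between node indices
#'
#' Pearson correlations between every pair of node-level indices (e.g. the
#' columns of [compute_indices()], optionally augmented with the SI
#' persistence/frequency columns from [si_indices()]), with two-sided
#' t-test p-values and significance flags.
#'
#' @param table data.frame of node-level numeric indices (one row per node).
#' @param alpha significance level for the flags (default 0.05).
#' @return list with matrices `r` (correlations; `NA` for constant
#'   indices), `p` (p-values), `significant` (logical at `alpha`), and
#'   `alpha`.
#' @export
index_correlations <- function(table, alpha = 0.05) {
  X <- as.matrix(table[vapply(table, is.numeric, TRUE)])
  if (nrow(X) < 4) stop("need at least 4 nodes", call. = FALSE)
  m <- ncol(X)
  r <- p <- matrix(NA_real_, m, m, dimnames = list(colnames(X), colnames(X)))
  const <- apply(X, 2, function(x) stats::sd(x) == 0)
  if (any(const))
    warning("constant index(es), correlations undefined: ",
            paste(colnames(X)[const], collapse = ", "))
  for (i in seq_len(m)) for (j in i:m) {
    if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
    if (const[i] || const[j]) next
    ct <- suppressWarnings(cor.test(X[, i], X[, j], method = "pearson"))
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  list(r = r, p = p, significant = !is.na(p) & p < alpha, alpha = alpha)
}
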