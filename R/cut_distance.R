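.cut_pair_matrices <- function(A, B) {
  Am <- .net_matrix(A); Bm <- .net_matrix(B)
  if (!all(dim(Am) == dim(Bm)))
    stop("networks must share the same node set", call. = FALSE)
  if (!is.null(rownames(Am)) && !is.null(rownames(Bm)) &&
      !identical(rownames(Am), rownames(Bm)))
    stop("networks must share the same node set (ids differ)", call. = FALSE)
  Am - Bm
}

.cut_result <- function(value, subset_ids, method, normalized, extra = list()) {
  structure(c(list(value = value, subset = subset_ids, method = method,
                   normalized = normalized), extra),
            class = "cut_distance_result")
}

#' @export
print.cut_distance_result <- function(x, ...) {
  cat(sprintf("<cut_distance_result> value %.6g (%s%s), |Q| = %d\n",
              x$value, x$method, if (x$normalized) "" else ", unnormalized",
              length(x$subset)))
  invisible(x)
}

#' Exact cut distance between two weighted digraphs
#'
#' The cut distance between same-node-set weighted networks A and B is the
#' maximum over node bipartitions (Q, complement) of the absolute
#' cross-partition difference sum `|sum_{i in Q, j notin Q} (A_ij - B_ij)|`,
#' here normalized by `N^2` so values are comparable across grid sizes.
#' Exhaustive enumeration over all `2^N - 2` non-trivial subsets; the
#' problem is NP-hard, so this route is guarded to `N <= 20` — use
#' [cut_distance_ga()] beyond that.
#'
#' @param A,B `agg_network`s or adjacency matrices on the same node set.
#' @param normalized divide by `N^2` (default TRUE).
#' @return a `cut_distance_result` with the optimal value and an attaining
#'   subset Q (node ids).
#' @export
cut_distance_exact <- function(A, B, normalized = TRUE) {
  D <- .cut_pair_matrices(A, B)
  N <- nrow(D)
  if (N > 20)
    stop("exact enumeration refused for N > 20 (2^N bipartitions); ",
         "use cut_distance_ga()", call. = FALSE)
  ids <- rownames(D) %||% as.character(seq_len(N))
  best <- -1; best_m <- NULL
  pow2 <- 2^(0:(N - 1))
  codes <- seq_len(2^N - 2)  # non-empty proper subsets
  block <- 2^14
  for (start in seq(1, length(codes), by = block)) {
    idx <- codes[start:min(start + block - 1, length(codes))]
    M <- outer(idx, pow2, function(i, b) bitwAnd(i, b) > 0) * 1
    f <- abs(rowSums((M %*% D) * (1 - M)))
    k <- which.max(f)
    if (f[k] > best) { best <- f[k]; best_m <- M[k, ] }
  }
  value <- if (normalized) best / N^2 else best
  .cut_result(value, ids[best_m == 1], "exact", normalized)
}

#' Genetic-algorithm cut distance
#'
#' Maximizes the bipartition objective of [cut_distance_exact()] with a
#' binary-membership genetic algorithm (chromosome = membership vector of Q;
#' fitness = normalized absolute cross-partition difference sum). The GA is
#' memetic: each generation the incumbent is refined by steepest-ascent
#' single-bit local search, and two random immigrants maintain diversity.
#' The result is a lower bound on the exact cut distance. Degenerate
#' all-in/all-out chromosomes get fitness 0. Reproducible for a given seed.
#'
#' @inheritParams cut_distance_exact
#' @param pop_size population size (default 50).
#' @param generations number of generations (default 200).
#' @param mutation_rate per-gene bit-flip probability (default 0.05).
#' @param elitism number of top chromosomes copied unchanged (default 2).
#' @param seed integer seed (required).
#' @return a `cut_distance_result` with GA diagnostics
#'   (`best_per_generation`, nondecreasing under elitism).
#' @export
cut_distance_ga <- function(A, B, pop_size = 50, generations = 200,
                            mutation_rate = 0.05, elitism = 2, seed,
                            normalized = TRUE) {
  if (missing(seed)) stop("'seed' is required for reproducibility", call. = FALSE)
  D <- .cut_pair_matrices(A, B)
  N <- nrow(D)
  ids <- rownames(D) %||% as.character(seq_len(N))
  norm <- if (normalized) N^2 else 1

  fitness <- function(M) {  # M: pop x N 0/1 matrix
    f <- abs(rowSums((M %*% D) * (1 - M))) / norm
    k <- rowSums(M)
    f[k == 0 | k == N] <- 0
    f
  }

  # steepest-ascent single-bit local search (memetic refinement); each
  # iteration scores all N flips in O(N^2) via incremental delta updates of
  # the signed cross-partition sum s(Q) = sum_{i in Q, j notin Q} D_ij
  climb <- function(m) {
    s <- sum(D[m == 1, m == 0])
    repeat {
      r <- as.vector(D %*% (1 - m))   # r_k = sum_{j notin Q} D_kj
      cc <- as.vector(crossprod(D, m))  # c_k = sum_{i in Q} D_ik
      s_new <- s + (1 - 2 * m) * (r - cc)
      size_new <- sum(m) + 1 - 2 * m
      f_new <- abs(s_new)
      f_new[size_new == 0 | size_new == N] <- 0
      k <- which.max(f_new)
      f0 <- if (sum(m) == 0 || sum(m) == N) 0 else abs(s)
      if (f_new[k] <= f0 + 1e-15) return(m)
      m[k] <- 1 - m[k]
      s <- s_new[k]
    }
  }

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))

  P <- matrix(rbinom(pop_size * N, 1, 0.5), pop_size, N)
  f <- fitness(P)
  best_per_gen <- numeric(generations)
  n_imm <- min(2L, pop_size - elitism)  # random immigrants keep diversity
  for (g in seq_len(generations)) {
    ord <- order(f, decreasing = TRUE)
    elite <- P[ord[seq_len(elitism)], , drop = FALSE]
    elite[1, ] <- climb(elite[1, ])
    # binary tournament selection
    i1 <- sample.int(pop_size, pop_size, replace = TRUE)
    i2 <- sample.int(pop_size, pop_size, replace = TRUE)
    parents <- ifelse(f[i1] >= f[i2], i1, i2)
    n_off <- pop_size - elitism - n_imm
    pa <- P[parents[seq_len(n_off)], , drop = FALSE]
    pb <- P[parents[pop_size - seq_len(n_off) + 1], , drop = FALSE]
    # uniform crossover then bit-flip mutation
    mask <- matrix(runif(n_off * N) < 0.5, n_off, N)
    off <- ifelse(mask, pa, pb)
    flip <- matrix(runif(n_off * N) < mutation_rate, n_off, N)
    off[flip] <- 1 - off[flip]
    imm <- matrix(rbinom(n_imm * N, 1, 0.5), n_imm, N)
    for (r in seq_len(n_imm)) imm[r, ] <- climb(imm[r, ])
    P <- rbind(elite, off, imm)
    f <- fitness(P)
    best_per_gen[g] <- max(f)
  }
  k <- which.max(f)
  .cut_result(f[k], ids[P[k, ] == 1], "ga", normalized,
              extra = list(generations = generations,
                           best_per_generation = best_per_gen,
                           seed = as.integer(seed)))
}

#' Cut distance with automatic method choice
#'
#' Exact enumeration for `N <= 20`, genetic algorithm otherwise.
#'
#' @inheritParams cut_distance_ga
#' @param method `"auto"`, `"exact"` or `"ga"`; GA parameters are ignored
#'   when the exact route is taken.
#' @return a `cut_distance_result`.
#' @export
cut_distance <- function(A, B, method = c("auto", "exact", "ga"), seed = NULL,
                         pop_size = 50, generations = 200,
                         mutation_rate = 0.05, elitism = 2,
                         normalized = TRUE) {
  method <- match.arg(method)
  if (method == "auto")
    method <- if (nrow(.net_matrix(A)) <= 20) "exact" else "ga"
  switch(method,
         exact = cut_distance_exact(A, B, normalized = normalized),
         ga = cut_distance_ga(A, B, pop_size = pop_size,
                              generations = generations,
                              mutation_rate = mutation_rate,
                              elitism = elitism, seed = seed,
                              normalized = normalized))
}

#' Pairwise cut-distance matrix of monthly networks
#'
#' @param monthlies list of `agg_network` on a common node set (typically
#'   the 12 monthly projections).
#' @param method `"auto"`, `"exact"` or `"ga"`.
#' @param seed base seed; each pair uses a distinct seed derived from it
#'   (GA method only).
#' @param ... passed to [cut_distance()].
#' @return symmetric matrix with zero diagonal, dimnames from the network
#'   labels.
#' @export
monthly_distance_matrix <- function(monthlies, method = "auto", seed = NULL,
                                    ...) {
  n <- length(monthlies)
  labs <- vapply(monthlies, function(x) x$label, "")
  if (anyDuplicated(labs)) labs <- make.unique(labs)
  dm <- matrix(0, n, n, dimnames = list(labs, labs))
  pair <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pair <- pair + 1L
    s <- if (is.null(seed)) NULL else (as.integer(seed) + pair) %% .Machine$integer.max
    dm[i, j] <- dm[j, i] <- cut_distance(monthlies[[i]], monthlies[[j]],
                                         method = method, seed = s, ...)$value
  }
  dm
}

#' Cluster months by cut distance
#'
#' Agglomerative hierarchical clustering (average linkage by default) of a
#' cut-distance matrix, cut at `k` clusters. With k = 2 on the 12 monthly
#' networks this recovers the main seasons of the study period.
#'
#' @param distmat symmetric distance matrix (e.g. from
#'   [monthly_distance_matrix()]).
#' @param k number of clusters (default 2).
#' @param linkage `hclust` agglomeration method (default `"average"`).
#' @return named integer vector of cluster labels; the `hclust` tree is
#'   attached as attribute `"tree"`.
#' @export
cluster_months <- function(distmat, k = 2, linkage = "average") {
  if (k > nrow(distmat))
    stop("k cannot exceed the number of networks", call. = FALSE)
  tree <- hclust(as.dist(distmat), method = linkage)
  out <- cutree(tree, k = k)
  attr(out, "tree") <- tree
  out
}
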