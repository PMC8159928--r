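# Independent brute-force oracles and fixture generators used across tests.
# These deliberately avoid the package's own code paths.

# random weighted digraph as an agg_network; optional random centroids
rand_net <- function(N, p = 0.4, seed = 1, coords = FALSE, label = "rand") {
  set.seed(seed)
  E <- matrix(runif(N * N), N, N) * (matrix(runif(N * N), N, N) < p)
  diag(E) <- 0
  nodes <- if (coords)
    data.frame(id = 1:N, lon = runif(N, 0, 10), lat = runif(N, 40, 48))
  else NULL
  agg_network(E, nodes = nodes, label = label)
}

# Floyd-Warshall all-pairs shortest paths on a cost matrix (Inf = no edge)
fw_oracle <- function(ED) {
  n <- nrow(ED)
  D <- ED
  diag(D) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# exhaustive triplet enumeration for the global weighted clustering
brute_transitivity <- function(E) {
  W <- (E + t(E)) / 2
  diag(W) <- 0
  A <- W > 0
  n <- nrow(W)
  num <- den <- 0
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    if (j >= k || i == j || i == k) next
    if (A[i, j] && A[i, k]) {
      v <- (W[i, j] + W[i, k]) / 2
      den <- den + v
      if (A[j, k]) num <- num + v
    }
  }
  if (den == 0) 0 else num / den
}

# iterative-pruning k-shell decomposition on an undirected binary adjacency
brute_coreness <- function(A) {
  A <- (A | t(A)) * 1
  diag(A) <- 0
  n <- nrow(A)
  core <- rep(NA_integer_, n)
  alive <- rep(TRUE, n)
  k <- 0
  while (any(alive)) {
    repeat {
      deg <- rowSums(A[, alive, drop = FALSE])[alive]
      victims <- which(alive)[deg <= k]
      if (!length(victims)) break
      core[victims] <- k
      alive[victims] <- FALSE
    }
    k <- k + 1
  }
  core
}

# ray-casting point-in-polygon (crossing number), independent of mgcv
pip_oracle <- function(ring, px, py) {
  n <- nrow(ring) - 1
  inside <- rep(FALSE, length(px))
  for (q in seq_along(px)) {
    cross <- 0
    for (e in 1:n) {
      x1 <- ring[e, 1]; y1 <- ring[e, 2]
      x2 <- ring[e + 1, 1]; y2 <- ring[e + 1, 2]
      if ((y1 > py[q]) != (y2 > py[q])) {
        xint <- x1 + (py[q] - y1) / (y2 - y1) * (x2 - x1)
        if (px[q] < xint) cross <- cross + 1
      }
    }
    inside[q] <- cross %% 2 == 1
  }
  inside
}

# exhaustive O(2^N) cut-distance maximization
brute_cut_distance <- function(A, B, normalized = TRUE) {
  D <- A - B
  N <- nrow(D)
  best <- 0
  for (code in 1:(2^N - 2)) {
    m <- as.integer(intToBits(code))[1:N]
    v <- abs(sum(D[m == 1, m == 0, drop = FALSE]))
    if (v > best) best <- v
  }
  if (normalized) best / N^2 else best
}

# O(n^2) pairwise weak-dominance Pareto front
brute_front <- function(d, w) {
  n <- length(d)
  keep <- vapply(seq_len(n), function(r)
    !any(d > d[r] & w > w[r]), TRUE)
  which(keep)
}

# hop-limited threshold reachability SI oracle (per-seed BFS levels)
si_oracle <- function(E, threshold, steps, strict = TRUE) {
  N <- nrow(E)
  A <- if (strict) E > threshold else E >= threshold
  X <- matrix(FALSE, N, N)
  for (s in 1:N) {
    infected <- rep(FALSE, N); infected[s] <- TRUE
    for (h in seq_len(steps)) {
      frontier <- rep(FALSE, N)
      for (j in 1:N) if (!infected[j] && any(infected & A[, j]))
        frontier[j] <- TRUE
      infected <- infected | frontier
    }
    X[s, ] <- infected
  }
  list(P = 100 * rowSums(X) / N, F = 100 * colSums(X) / N)
}

# calendar/regime fixtures
uniform_regime <- function(bearing = 270, speed = 50, dn = 0, sn = 0) {
  list(wind_regime(1:12, bearing, speed, dn, sn))
}

two_season_calendar <- function(start, end, noise = 15, speed = 40) {
  synth_calendar(start, end, list(
    wind_regime(5:9, 270, speed, noise, 5),
    wind_regime(c(10:12, 1:4), 90, speed, noise, 5)))
}
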