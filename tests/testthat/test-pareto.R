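cloud_df <- function(d, w) data.frame(src = seq_along(d), dst = seq_along(d),
                                      distance_km = d, weight = w)

test_that("edge cloud holds one record per non-null edge with geodesic distances", {
  net <- rand_net(7, 0.5, seed = 31, coords = TRUE)
  cl <- edge_cloud(net)
  expect_equal(nrow(cl), sum(net$E > 0))
  expect_true(all(cl$weight > 0))
  # independent spherical-law-of-cosines distance check
  for (r in sample(nrow(cl), 5)) {
    a <- net$nodes[match(cl$src[r], net$nodes$id), ]
    b <- net$nodes[match(cl$dst[r], net$nodes$id), ]
    rad <- pi / 180
    want <- 6371 * acos(pmin(1,
      sin(a$lat * rad) * sin(b$lat * rad) +
      cos(a$lat * rad) * cos(b$lat * rad) * cos((a$lon - b$lon) * rad)))
    expect_equal(cl$distance_km[r], want, tolerance = 1e-3)
  }
  empty <- agg_network(matrix(0, 3, 3),
                       nodes = data.frame(id = 1:3, lon = 1:3, lat = 40))
  expect_error(edge_cloud(empty), "no non-null edge")
})

test_that("the Pareto front keeps exactly the non-dominated records", {
  cl <- cloud_df(c(1, 2, 1.5), c(1, 0.5, 0.4))
  fr <- pareto_front(cl)
  expect_setequal(fr$src, c(1, 2))  # (1.5, 0.4) dominated by (2, 0.5)
  one <- cloud_df(3, 0.2)
  expect_equal(nrow(pareto_front(one)), 1)
  for (s in 1:10) {
    set.seed(s)
    n <- 60
    cl <- cloud_df(round(runif(n, 0, 5), 1), round(runif(n), 2))  # force ties
    fr <- pareto_front(cl)
    expect_identical(which(rownames(cl) %in% rownames(fr)),
                     brute_front(cl$distance_km, cl$weight))
    # order invariance
    perm <- sample(n)
    fr2 <- pareto_front(cl[perm, ])
    expect_setequal(fr2$src, fr$src)
    # cloud maxima always on the front
    expect_true(cl$src[which.max(cl$distance_km)] %in% fr$src)
    expect_true(cl$src[which.max(cl$weight)] %in% fr$src)
  }
})

test_that("near-front scores match a brute-force point-to-segment oracle", {
  seg_d <- function(px, py, x1, y1, x2, y2) {
    L2 <- (x2 - x1)^2 + (y2 - y1)^2
    t <- if (L2 == 0) 0 else
      min(1, max(0, ((px - x1) * (x2 - x1) + (py - y1) * (y2 - y1)) / L2))
    sqrt((px - (x1 + t * (x2 - x1)))^2 + (py - (y1 + t * (y2 - y1)))^2)
  }
  for (s in 1:5) {
    set.seed(s)
    n <- 40
    cl <- cloud_df(runif(n, 10, 500), runif(n))
    sc <- pareto_scores(cl)
    dn <- (cl$distance_km - min(cl$distance_km)) / diff(range(cl$distance_km))
    wn <- (cl$weight - min(cl$weight)) / diff(range(cl$weight))
    fidx <- brute_front(cl$distance_km, cl$weight)
    o <- fidx[order(dn[fidx])]
    for (r in seq_len(n)) {
      if (r %in% fidx) { expect_identical(sc[r], 0); next }
      want <- Inf
      for (k in seq_len(length(o) - 1))
        want <- min(want, seg_d(dn[r], wn[r], dn[o[k]], wn[o[k]],
                                dn[o[k + 1]], wn[o[k + 1]]))
      if (length(o) == 1)
        want <- sqrt((dn[r] - dn[o])^2 + (wn[r] - wn[o])^2)
      expect_equal(sc[r], want)
    }
  }
})

test_that("near-front selection is monotone nested in the fraction", {
  set.seed(99)
  cl <- cloud_df(runif(200, 1, 1000), runif(200))
  s10 <- select_near_front(cl, 0.10)
  s25 <- select_near_front(cl, 0.25)
  all_of <- select_near_front(cl, 1)
  key <- function(x) paste(x$src, x$dst)
  expect_true(all(key(s10) %in% key(s25)))
  expect_equal(nrow(all_of), nrow(cl))
  expect_equal(nrow(s10), ceiling(0.10 * 200))
  # every front record is selected before any non-front record
  fr <- pareto_front(cl)
  smin <- select_near_front(cl, nrow(fr) / nrow(cl))
  expect_setequal(key(smin), key(fr))
  expect_error(select_near_front(cl, 0), "fraction")
  expect_error(select_near_front(cl, 1.2), "fraction")
})
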