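# helper: trajectory set from explicit lon/lat position matrices
manual_ts <- function(nodes, day, lon, lat) {
  trajectory_set(nodes, rep(as.Date(day), length(nodes)), lon, lat,
                 duration_h = ncol(lon) - 1L, source = "synthetic")
}

test_that("visited cells match the containment rule", {
  g <- make_lattice_grid(1, 5, 50, c(0, 40))
  # stationary trajectory: all positions inside cell 2
  tr <- get_trajectory(manual_ts(2, "2015-01-01",
                                 matrix(g$cells$lon[2], 1, 5),
                                 matrix(g$cells$lat[2], 1, 5)), 1)
  expect_identical(visited_cells(tr, g), 2L)
  # straight east-west pass over cells 5 <- 3 <- 1
  lon <- matrix(g$cells$lon[c(5, 4, 3, 2, 1)], 1, 5)
  tr2 <- get_trajectory(manual_ts(5, "2015-01-01", lon,
                                  matrix(40, 1, 5)), 1)
  expect_identical(visited_cells(tr2, g), c(1L, 2L, 3L, 4L, 5L))
  # trajectory entirely off-grid
  tr3 <- get_trajectory(manual_ts(1, "2015-01-02", matrix(90, 1, 5),
                                  matrix(10, 1, 5)), 1)
  expect_identical(visited_cells(tr3, g), integer(0))
})

test_that("daily networks follow the source->arrival edge rule, no self-loops", {
  g <- make_lattice_grid(1, 5, 50, c(0, 40))
  lon <- matrix(g$cells$lon[c(1, 3, 5)], 1, 3)  # arrival at 1, visits 3 and 5
  ts <- manual_ts(1, "2015-01-01", lon, matrix(40, 1, 3))
  dn <- build_daily_network(ts, g)
  E <- dn$E
  expect_equal(E["3", "1"], 1)
  expect_equal(E["5", "1"], 1)
  expect_equal(sum(E), 2)      # self-edge 1->1 dropped
  expect_true(all(diag(E) == 0))
})

test_that("daily construction equals a brute-force point-in-polygon oracle", {
  g <- make_lattice_grid(3, 3, 60, c(2, 41))
  cal <- two_season_calendar("2015-06-01", "2015-06-03", noise = 25)
  ts <- generate_trajectories(g, cal, seed = 3)
  dailies <- build_daily_networks(ts, g)
  for (d in dailies) {
    sel <- which(ts$arrival_day == d$day)
    E <- matrix(0, g$N, g$N)
    for (i in sel) {
      for (j in seq_len(g$N)) {
        hit <- pip_oracle(g$polygons[[j]], ts$lon[i, ], ts$lat[i, ])
        if (any(hit) && g$cells$id[j] != ts$arrival_node[i])
          E[j, match(ts$arrival_node[i], g$cells$id)] <- 1
      }
    }
    expect_equal(unname(d$E), E)
  }
})

test_that("aggregation is the elementwise mean over the day subset", {
  g <- make_lattice_grid(1, 3, 50, c(0, 40))
  d1 <- structure(list(day = as.Date("2015-01-01"),
                       E = matrix(c(0, 1, 0, 0, 0, 0, 1, 0, 0), 3, 3,
                                  dimnames = list(1:3, 1:3))),
                  class = "daily_network")
  d2 <- structure(list(day = as.Date("2015-01-02"),
                       E = matrix(0, 3, 3, dimnames = list(1:3, 1:3))),
                  class = "daily_network")
  agg <- aggregate_networks(list(d1, d2), label = "both")
  expect_equal(agg$E["2", "1"], 0.5)
  expect_equal(agg$E["1", "3"], 0.5)
  one <- aggregate_networks(list(d1, d2), days = as.Date("2015-01-01"))
  expect_equal(one$E, d1$E)  # |S| = 1 keeps the binary matrix
  expect_error(aggregate_networks(list(d1, d2), days = as.Date("2014-01-01")),
               "not present")
})

test_that("aggregation satisfies mixture consistency over partitions of S", {
  g <- make_lattice_grid(2, 2, 60, c(3, 41))
  cal <- two_season_calendar("2015-04-27", "2015-05-06")
  ts <- generate_trajectories(g, cal, seed = 21)
  dailies <- build_daily_networks(ts, g)
  days <- as.Date(names(dailies))
  s1 <- days[1:4]; s2 <- days[5:10]
  E1 <- aggregate_networks(dailies, s1)$E
  E2 <- aggregate_networks(dailies, s2)$E
  Eall <- aggregate_networks(dailies, days)$E
  expect_equal(Eall, (4 * E1 + 6 * E2) / 10)
  expect_true(all(Eall >= 0 & Eall <= 1))
})

test_that("period projection yields one network per period with exact means", {
  g <- make_lattice_grid(2, 2, 60, c(3, 41))
  cal <- two_season_calendar("2014-11-20", "2015-02-10")
  ts <- generate_trajectories(g, cal, seed = 8)
  dailies <- build_daily_networks(ts, g)
  monthly <- project_periods(dailies, "monthly")
  expect_setequal(names(monthly), c("January", "February", "November", "December"))
  yearly <- project_periods(dailies, "yearly")
  expect_setequal(names(yearly), c("2014", "2015"))
  full <- project_periods(dailies, "full")
  expect_length(full, 1)
  # independent accumulation-loop oracle for one monthly mean
  days <- as.Date(names(dailies))
  jan <- which(format(days, "%m") == "01")
  acc <- matrix(0, 4, 4)
  for (i in jan) acc <- acc + dailies[[i]]$E
  expect_equal(unname(monthly$January$E), unname(acc / length(jan)))
  # seasonal scheme requires complete month coverage
  expect_error(project_periods(dailies, "seasonal",
                               season_map = c("1" = "winter")),
               "cover")
  seas <- project_periods(dailies, "seasonal")
  expect_setequal(names(seas), "winter")  # Nov-Feb are all winter months
})

test_that("westerly regimes move mass west->east (6x6 lattice)", {
  g <- make_lattice_grid(6, 6, 74, c(5, 40))
  cal <- synth_calendar("2015-06-01", "2015-06-20",
                        uniform_regime(270, 40, 15, 5))
  ts <- generate_trajectories(g, cal, seed = 13)
  net <- aggregate_networks(build_daily_networks(ts, g))
  col_of <- (g$cells$id - 1) %% 6 + 1
  west_east <- sum(net$E[outer(col_of, col_of, `<`)])
  east_west <- sum(net$E[outer(col_of, col_of, `>`)])
  expect_gt(west_east, east_west)
})

test_that("edge-list serialization round-trips an aggregated network", {
  net <- rand_net(6, 0.5, seed = 4, coords = TRUE, label = "t")
  dir <- withr::local_tempdir()
  ef <- file.path(dir, "e.csv"); nf <- file.path(dir, "n.csv")
  write_agg_network(net, ef, nf)
  back <- read_agg_network(ef, nf, label = "t")
  expect_equal(back$E, net$E, tolerance = 1e-12)
  expect_equal(back$nodes$lon, net$nodes$lon)
})
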