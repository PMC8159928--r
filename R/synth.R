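#' Define a seasonal wind regime
#'
#' A wind regime gives, for a set of calendar months, the mean direction the
#' air masses come FROM (meteorological convention, degrees clockwise from
#' north), a mean advection speed, and per-hour jitter standard deviations.
#'
#' @param months integer vector of month numbers (1-12) the regime covers.
#' @param bearing_deg mean direction the air mass comes from, degrees
#'   clockwise from north (270 = westerly flow).
#' @param speed_kmh mean advection speed, km/h; must be positive.
#' @param dir_noise_deg std dev of the per-hour direction jitter (degrees).
#' @param speed_noise_kmh std dev of the per-hour speed jitter (km/h).
#' @return An object of class `wind_regime`.
#' @export
wind_regime <- function(months, bearing_deg, speed_kmh,
                        dir_noise_deg = 0, speed_noise_kmh = 0) {
  months <- as.integer(months)
  if (length(months) < 1 || any(months < 1 | months > 12))
    stop("'months' must be month numbers in 1..12", call. = FALSE)
  if (anyDuplicated(months)) stop("duplicated months in regime", call. = FALSE)
  if (!is.finite(speed_kmh) || speed_kmh <= 0)
    stop("'speed_kmh' must be positive", call. = FALSE)
  if (dir_noise_deg < 0 || speed_noise_kmh < 0)
    stop("noise standard deviations must be non-negative", call. = FALSE)
  structure(list(months = months, bearing_deg = bearing_deg,
                 speed_kmh = speed_kmh, dir_noise_deg = dir_noise_deg,
                 speed_noise_kmh = speed_noise_kmh), class = "wind_regime")
}

#' Define a synthesis calendar
#'
#' @param start_date,end_date calendar dates (anything `as.Date()` accepts);
#'   `end_date >= start_date`.
#' @param regimes list of [wind_regime()] objects; their month sets must be
#'   disjoint and together cover every month occurring in the date range.
#' @return An object of class `synth_calendar`.
#' @export
synth_calendar <- function(start_date, end_date, regimes) {
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  if (end_date < start_date) stop("'end_date' must be >= 'start_date'", call. = FALSE)
  if (!is.list(regimes) || !all(vapply(regimes, inherits, TRUE, "wind_regime")))
    stop("'regimes' must be a list of wind_regime objects", call. = FALSE)
  mo <- unlist(lapply(regimes, `[[`, "months"))
  if (anyDuplicated(mo))
    stop("regime month sets must be disjoint", call. = FALSE)
  structure(list(start_date = start_date, end_date = end_date,
                 regimes = regimes), class = "synth_calendar")
}

#' Day sequence of a calendar
#'
#' @param calendar a [synth_calendar()], or a start date when `end` is given.
#' @param end optional end date (when `calendar` is a start date).
#' @param drop_leap drop February 29 from the sequence, so that every year
#'   contributes exactly 365 days (e.g. 7 years -> 2555 daily networks).
#' @return a `Date` vector.
#' @export
calendar_days <- function(calendar, end = NULL, drop_leap = FALSE) {
  if (inherits(calendar, "synth_calendar")) {
    days <- seq(calendar$start_date, calendar$end_date, by = "day")
  } else {
    days <- seq(as.Date(calendar), as.Date(end), by = "day")
  }
  if (drop_leap) days <- days[format(days, "%m-%d") != "02-29"]
  days
}

# month -> regime index lookup, erroring on uncovered months
.regime_lookup <- function(calendar, months_present) {
  map <- rep(NA_integer_, 12)
  for (k in seq_along(calendar$regimes)) map[calendar$regimes[[k]]$months] <- k
  bad <- setdiff(months_present, which(!is.na(map)))
  if (length(bad))
    stop("no wind regime covers month(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  map
}

#' Generate synthetic backward trajectories over a grid
#'
#' Emulates daily 48-h backward air-mass trajectories arriving at every grid
#' cell centroid (one trajectory per cell and day, nominally at 12:00). The
#' hour-0 position is the arrival centroid; each earlier hourly position is
#' obtained by stepping one hour upwind on the sphere along the active
#' month's regime bearing, with Gaussian per-hour jitter on direction and
#' speed. Altitude is a constant 500 m (it plays no role downstream).
#'
#' @param grid an `air_grid`.
#' @param calendar a [synth_calendar()] whose regimes cover every month in
#'   the date range.
#' @param duration_h trajectory length in hours (default 48).
#' @param seed integer seed; identical inputs and seed give bit-identical
#'   trajectories.
#' @param drop_leap drop February 29 so every year has 365 days.
#' @return A `trajectory_set` (see [trajectory_set()]) with one trajectory
#'   per (cell, day).
#' @examples
#' g <- make_lattice_grid(2, 2, 50, c(5, 43))
#' cal <- synth_calendar("2015-01-01", "2015-01-05",
#'                       list(wind_regime(1:12, 270, 40, 10, 5)))
#' ts <- generate_trajectories(g, cal, seed = 1)
#' length(ts$arrival_node)  # 4 cells x 5 days
#' @export
generate_trajectories <- function(grid, calendar, duration_h = 48L, seed,
                                  drop_leap = FALSE) {
  stopifnot(inherits(grid, "air_grid"), inherits(calendar, "synth_calendar"))
  if (missing(seed)) stop("'seed' is required for reproducibility", call. = FALSE)
  duration_h <- as.integer(duration_h)
  days <- calendar_days(calendar, drop_leap = drop_leap)
  mon <- as.integer(format(days, "%m"))
  map <- .regime_lookup(calendar, unique(mon))

  N <- grid$N; nd <- length(days); n <- N * nd
  # day-major ordering: all cells of day 1, then day 2, ...
  arrival_node <- rep(grid$cells$id, times = nd)
  arrival_day <- rep(days, each = N)
  reg_idx <- map[rep(mon, each = N)]
  bearing0 <- vapply(calendar$regimes, `[[`, 0, "bearing_deg")[reg_idx]
  speed0 <- vapply(calendar$regimes, `[[`, 0, "speed_kmh")[reg_idx]
  dnoise <- vapply(calendar$regimes, `[[`, 0, "dir_noise_deg")[reg_idx]
  snoise <- vapply(calendar$regimes, `[[`, 0, "speed_noise_kmh")[reg_idx]

  lon <- matrix(NA_real_, n, duration_h + 1L)
  lat <- matrix(NA_real_, n, duration_h + 1L)
  lon[, 1] <- rep(grid$cells$lon, times = nd)
  lat[, 1] <- rep(grid$cells$lat, times = nd)

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  for (h in seq_len(duration_h)) {
    b <- bearing0 + rnorm(n, 0, 1) * dnoise
    s <- pmax(speed0 + rnorm(n, 0, 1) * snoise, 0)
    p <- geosphere::destPoint(cbind(lon[, h], lat[, h]), b, s * 1000,
                              r = EARTH_RADIUS_KM * 1000)
    lon[, h + 1L] <- p[, 1]
    lat[, h + 1L] <- p[, 2]
  }
  trajectory_set(arrival_node, arrival_day, lon, lat,
                 alt = matrix(500, n, duration_h + 1L),
                 duration_h = duration_h, source = "synthetic")
}
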