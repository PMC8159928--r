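#' Construct a trajectory set
#'
#' Container for hourly-resolved backward trajectories, one per
#' (arrival node, arrival day) key. Positions are stored column-wise by hour
#' offset 0, -1, ..., -duration.
#'
#' @param arrival_node integer vector of arrival cell ids.
#' @param arrival_day `Date` vector of arrival days.
#' @param lon,lat,alt numeric matrices, one row per trajectory and
#'   `duration_h + 1` columns (hour offsets 0..-duration).
#' @param duration_h trajectory duration in hours.
#' @param source `"hysplit"` or `"synthetic"`.
#' @return An object of class `trajectory_set`.
#' @export
trajectory_set <- function(arrival_node, arrival_day, lon, lat, alt = NULL,
                           duration_h = ncol(lon) - 1L, source = "hysplit") {
  n <- length(arrival_node)
  arrival_day <- as.Date(arrival_day)
  stopifnot(length(arrival_day) == n, nrow(lon) == n, nrow(lat) == n,
            ncol(lon) == duration_h + 1L, ncol(lat) == duration_h + 1L)
  if (is.null(alt)) alt <- matrix(500, n, duration_h + 1L)
  key <- paste(arrival_node, arrival_day)
  if (anyDuplicated(key))
    stop("duplicate (arrival_node, arrival_day) keys: ",
         paste(head(key[duplicated(key)], 3), collapse = "; "), call. = FALSE)
  bad <- which(abs(lon) > 180 | abs(lat) > 90, arr.ind = TRUE)
  if (nrow(bad))
    stop("out-of-range coordinates for trajectory key(s): ",
         paste(unique(head(key[bad[, 1]], 3)), collapse = "; "), call. = FALSE)
  structure(list(arrival_node = as.integer(arrival_node),
                 arrival_day = arrival_day, lon = lon, lat = lat, alt = alt,
                 duration_h = as.integer(duration_h), source = source),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("<trajectory_set> %d trajectories, %d h backward, source: %s\n",
              length(x$arrival_node), x$duration_h, x$source))
  invisible(x)
}

#' @export
length.trajectory_set <- function(x) length(x$arrival_node)

#' Extract a single trajectory
#'
#' @param ts a `trajectory_set`.
#' @param i trajectory index, or omit and give `node` and `day`.
#' @param node,day alternative key-based lookup.
#' @return An `air_trajectory`: list with `arrival_node`, `arrival_day` and a
#'   `positions` data.frame (`hour`, `lon`, `lat`, `alt`), hour offsets
#'   strictly decreasing from 0.
#' @export
get_trajectory <- function(ts, i = NULL, node = NULL, day = NULL) {
  stopifnot(inherits(ts, "trajectory_set"))
  if (is.null(i)) {
    i <- which(ts$arrival_node == node & ts$arrival_day == as.Date(day))
    if (length(i) != 1) stop("no trajectory for that (node, day) key", call. = FALSE)
  }
  structure(list(
    arrival_node = ts$arrival_node[i], arrival_day = ts$arrival_day[i],
    positions = data.frame(hour = 0:(-ts$duration_h), lon = ts$lon[i, ],
                           lat = ts$lat[i, ], alt = ts$alt[i, ])
  ), class = "air_trajectory")
}

# ---- tdump dialect -------------------------------------------------------
# One trajectory per file. Line 1: "AIRNET-TDUMP node <id> date <YYYY-MM-DD>
# duration <H>". Then one whitespace-delimited record per hour:
# hour_offset lon lat alt, offsets strictly decreasing from 0 to -duration.
# Directory layout: <node_id>/<YYYYMMDD>.tdump

#' Write a trajectory set as tdump files
#'
#' Writes one plain-text file per trajectory under
#' `dir/<node_id>/<YYYYMMDD>.tdump` (format documented in the README).
#' Coordinates are written with 6 decimal places.
#'
#' @param ts a `trajectory_set`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_tdump <- function(ts, dir) {
  stopifnot(inherits(ts, "trajectory_set"))
  for (i in seq_along(ts$arrival_node)) {
    nd <- file.path(dir, ts$arrival_node[i])
    if (!dir.exists(nd)) dir.create(nd, recursive = TRUE)
    path <- file.path(nd, paste0(format(ts$arrival_day[i], "%Y%m%d"), ".tdump"))
    hdr <- sprintf("AIRNET-TDUMP node %d date %s duration %d",
                   ts$arrival_node[i], format(ts$arrival_day[i], "%Y-%m-%d"),
                   ts$duration_h)
    rec <- sprintf("%d %.6f %.6f %.1f", 0:(-ts$duration_h),
                   ts$lon[i, ], ts$lat[i, ], ts$alt[i, ])
    writeLines(c(hdr, rec), path)
  }
  invisible(dir)
}

.read_one_tdump <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2 || !grepl("^AIRNET-TDUMP node ", lines[1]))
    stop("malformed tdump header in ", path, " (line 1)", call. = FALSE)
  hdr <- strsplit(lines[1], "\\s+")[[1]]
  node <- as.integer(hdr[3]); day <- as.Date(hdr[5])
  dur <- as.integer(hdr[7])
  rec <- strsplit(trimws(lines[-1]), "\\s+")
  nf <- lengths(rec)
  if (any(nf != 4))
    stop("malformed record(s) in ", path, " at line(s) ",
         paste(which(nf != 4) + 1, collapse = ", "), call. = FALSE)
  m <- matrix(suppressWarnings(as.numeric(unlist(rec))), ncol = 4, byrow = TRUE)
  if (anyNA(m))
    stop("non-numeric field(s) in ", path, " at line(s) ",
         paste(unique(which(is.na(m), arr.ind = TRUE)[, 1]) + 1, collapse = ", "),
         call. = FALSE)
  if (!identical(as.integer(m[, 1]), 0:(-dur)))
    stop("hour offsets not strictly decreasing 0..-", dur, " in ", path,
         call. = FALSE)
  if (any(abs(m[, 2]) > 180) || any(abs(m[, 3]) > 90))
    stop("out-of-range coordinates in ", path, " (node ", node, ", ",
         format(day), ")", call. = FALSE)
  list(node = node, day = day, dur = dur, lon = m[, 2], lat = m[, 3],
       alt = m[, 4])
}

#' Read tdump trajectory files
#'
#' Reads either a single tdump file or a `<node_id>/<YYYYMMDD>.tdump`
#' directory tree written by [write_tdump()].
#'
#' @param path a file or directory.
#' @return a `trajectory_set`; the duration is inferred from the records.
#' @export
read_tdump <- function(path) {
  if (!file.exists(path)) stop("no such file or directory: ", path, call. = FALSE)
  files <- if (dir.exists(path)) {
    list.files(path, pattern = "\\.tdump$", recursive = TRUE, full.names = TRUE)
  } else path
  if (!length(files)) stop("no .tdump files under ", path, call. = FALSE)
  parsed <- lapply(sort(files), .read_one_tdump)
  dur <- unique(vapply(parsed, `[[`, 0L, "dur"))
  if (length(dur) != 1)
    stop("mixed trajectory durations in ", path, call. = FALSE)
  trajectory_set(
    arrival_node = vapply(parsed, `[[`, 0L, "node"),
    arrival_day = as.Date(vapply(parsed, function(p) format(p$day), "")),
    lon = do.call(rbind, lapply(parsed, `[[`, "lon")),
    lat = do.call(rbind, lapply(parsed, `[[`, "lat")),
    alt = do.call(rbind, lapply(parsed, `[[`, "alt")),
    duration_h = dur, source = "hysplit")
}
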