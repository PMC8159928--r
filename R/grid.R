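#' Construct a rectangular lattice grid of cells
#'
#' Builds an `n_rows` x `n_cols` lattice of square cells whose centroids are
#' spaced `cell_km` apart along the grid axes, using a local equirectangular
#' approximation around the grid's mid-latitude. Cell ids run 1..N in
#' row-major order starting from `origin_lonlat` (the centroid of cell 1).
#'
#' @param n_rows,n_cols positive integers; `n_rows * n_cols >= 2`.
#' @param cell_km positive mesh size in kilometres (centroid spacing).
#' @param origin_lonlat numeric length-2, `c(lon, lat)` of the first cell's
#'   centroid, in decimal degrees (WGS84).
#' @return An object of class `air_grid`: a list with `cells` (data.frame
#'   `id`, `lon`, `lat`), `polygons` (list of closed lon/lat rings, one per
#'   cell), `N`, and lattice bookkeeping used for fast point location.
#' @examples
#' g <- make_lattice_grid(2, 3, 74, c(5, 43))
#' g$N
#' @export
make_lattice_grid <- function(n_rows, n_cols, cell_km, origin_lonlat) {
  if (length(n_rows) != 1L || length(n_cols) != 1L ||
      n_rows < 1 || n_cols < 1 || n_rows != round(n_rows) || n_cols != round(n_cols))
    stop("'n_rows' and 'n_cols' must be positive integers", call. = FALSE)
  if (length(cell_km) != 1L || !is.finite(cell_km) || cell_km <= 0)
    stop("'cell_km' must be a positive length in km", call. = FALSE)
  if (n_rows * n_cols < 2)
    stop("a grid needs at least 2 cells (n_rows * n_cols >= 2)", call. = FALSE)
  if (length(origin_lonlat) != 2L || any(!is.finite(origin_lonlat)))
    stop("'origin_lonlat' must be c(lon, lat)", call. = FALSE)

  lon0 <- origin_lonlat[1]; lat0 <- origin_lonlat[2]
  dlat <- cell_km / KM_PER_DEG_LAT
  lat_mid <- lat0 + (n_rows - 1) / 2 * dlat
  dlon <- cell_km / (KM_PER_DEG_LAT * cos(lat_mid * pi / 180))

  rc <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  # row-major ids: row 1 holds ids 1..n_cols
  cells <- data.frame(
    id  = seq_len(n_rows * n_cols),
    lon = lon0 + (rc$col - 1) * dlon,
    lat = lat0 + (rc$row - 1) * dlat
  )
  polygons <- lapply(seq_len(nrow(cells)), function(i) {
    cx <- cells$lon[i]; cy <- cells$lat[i]
    cbind(lon = cx + c(-1, 1, 1, -1, -1) * dlon / 2,
          lat = cy + c(-1, -1, 1, 1, -1) * dlat / 2)
  })
  structure(list(
    cells = cells, polygons = polygons, N = nrow(cells),
    lattice = list(n_rows = n_rows, n_cols = n_cols, cell_km = cell_km,
                   lon0 = lon0, lat0 = lat0, dlon = dlon, dlat = dlat)
  ), class = "air_grid")
}

#' Construct a grid from arbitrary cell polygons
#'
#' Generic alternative to [make_lattice_grid()] for non-lattice meshes.
#' Point location falls back to point-in-polygon tests.
#'
#' @param cells data.frame with columns `id`, `lon`, `lat` (centroids).
#' @param polygons list of two-column lon/lat matrices, one ring per cell,
#'   in the same order as `cells`.
#' @return An `air_grid` object.
#' @export
grid_from_cells <- function(cells, polygons) {
  stopifnot(is.data.frame(cells), all(c("id", "lon", "lat") %in% names(cells)),
            is.list(polygons), length(polygons) == nrow(cells))
  if (anyDuplicated(cells$id)) stop("cell ids must be unique", call. = FALSE)
  structure(list(cells = cells, polygons = polygons, N = nrow(cells),
                 lattice = NULL), class = "air_grid")
}

#' @export
print.air_grid <- function(x, ...) {
  kind <- if (is.null(x$lattice)) "polygonal" else
    sprintf("%d x %d lattice, %g km mesh", x$lattice$n_rows, x$lattice$n_cols,
            x$lattice$cell_km)
  cat(sprintf("<air_grid> %d cells (%s)\n", x$N, kind))
  invisible(x)
}

#' Locate points in grid cells
#'
#' Maps lon/lat points to the id of the cell containing them (`NA` when a
#' point falls in no cell). Lattice grids use exact index arithmetic;
#' polygonal grids use point-in-polygon tests (via [mgcv::in.out()]).
#'
#' @param grid an `air_grid`.
#' @param lon,lat numeric vectors of equal length, decimal degrees.
#' @return integer vector of cell ids with `NA` for points outside the grid.
#' @export
locate_points <- function(grid, lon, lat) {
  stopifnot(inherits(grid, "air_grid"), length(lon) == length(lat))
  if (!is.null(grid$lattice)) {
    L <- grid$lattice
    col <- round((lon - L$lon0) / L$dlon) + 1
    row <- round((lat - L$lat0) / L$dlat) + 1
    ok <- !is.na(col) & col >= 1 & col <= L$n_cols & row >= 1 & row <= L$n_rows
    id <- rep(NA_integer_, length(lon))
    id[ok] <- as.integer((row[ok] - 1) * L$n_cols + col[ok])
    return(id)
  }
  pts <- cbind(lon, lat)
  id <- rep(NA_integer_, length(lon))
  todo <- !is.na(lon) & !is.na(lat)
  for (i in seq_len(grid$N)) {
    if (!any(todo)) break
    ring <- grid$polygons[[i]]
    # cheap bbox pre-filter before the polygon test
    cand <- todo & lon >= min(ring[, 1]) & lon <= max(ring[, 1]) &
      lat >= min(ring[, 2]) & lat <= max(ring[, 2])
    if (!any(cand)) next
    inside <- mgcv::in.out(ring, pts[cand, , drop = FALSE])
    hit <- which(cand)[inside]
    id[hit] <- grid$cells$id[i]
    todo[hit] <- FALSE
  }
  id
}

#' Great-circle distances between cell centroids
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param nodes data.frame with `lon`, `lat` columns.
#' @return symmetric N x N matrix of distances in km.
#' @export
centroid_distances <- function(nodes) {
  n <- nrow(nodes)
  p <- as.matrix(nodes[, c("lon", "lat")])
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d[i, ] <- geosphere::distHaversine(p[i, ], p, r = EARTH_RADIUS_KM * 1000) / 1000
  }
  d
}
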