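# Regular lon/lat grid geometry shared by all modules.

#' Mean Earth radius (m) of the spherical Earth used throughout
#'
#' All metric conversions use a spherical Earth: `dx = R cos(lat) dlambda`,
#' `dy = R dphi`, matching regional-model convention.
#' @export
EARTH_RADIUS <- 6371000

.deg2rad <- function(x) x * pi / 180

#' Build a regular lon/lat grid with a coastline-derived land mask
#'
#' The grid is cell-centered (A-grid): velocities and diagnostics live on the
#' same lon/lat points. Axis spacing is uniform; the number of points along
#' each axis is `ceiling(range / spacing) + 1`, so the last point may overshoot
#' the requested range by less than one cell.
#'
#' @param lon_range length-2 numeric, degrees east, ascending.
#' @param lat_range length-2 numeric, degrees north, ascending.
#' @param spacing_deg grid spacing in degrees (> 0), shared by both axes.
#' @param z_levels depths in metres, all `<= 0` with 0 the surface, ascending
#'   toward 0. Default a single surface level.
#' @param time_axis times in seconds since the run epoch, ascending.
#' @param coastline_spec either `NULL` (all ocean), a single latitude
#'   (straight east-west coast: cells at or north of it are land), or a
#'   two-column matrix / data.frame of (lon, lat) vertices of a piecewise
#'   linear coast polyline; cells north of the interpolated coast latitude
#'   are masked as land.
#' @return an object of class `vf_grid`: list with `lon`, `lat`, `z`, `time`,
#'   `mask` (logical `nlon x nlat`, `TRUE` = ocean) and cached spacings.
#' @export
make_grid <- function(lon_range, lat_range, spacing_deg,
                      z_levels = 0, time_axis = 0, coastline_spec = NULL) {
  if (length(lon_range) != 2 || length(lat_range) != 2 ||
      diff(lon_range) <= 0 || diff(lat_range) <= 0)
    stop("lon_range and lat_range must be ascending length-2 vectors", call. = FALSE)
  if (!is.numeric(spacing_deg) || length(spacing_deg) != 1 || spacing_deg <= 0)
    stop("spacing_deg must be a single positive number", call. = FALSE)
  nlon <- as.integer(ceiling(round(diff(lon_range) / spacing_deg, 9))) + 1L
  nlat <- as.integer(ceiling(round(diff(lat_range) / spacing_deg, 9))) + 1L
  lon <- lon_range[1] + (seq_len(nlon) - 1) * spacing_deg
  lat <- lat_range[1] + (seq_len(nlat) - 1) * spacing_deg
  if (any(z_levels > 0)) stop("z_levels must be <= 0 (0 = surface)", call. = FALSE)
  z <- sort(as.numeric(z_levels))
  time <- as.numeric(time_axis)
  if (length(time) > 1 && any(diff(time) <= 0))
    stop("time_axis must be strictly ascending", call. = FALSE)

  mask <- matrix(TRUE, nlon, nlat)
  if (!is.null(coastline_spec)) {
    coast_lat <- coastline_latitude(coastline_spec, lon)
    # ocean strictly south of the coast line
    mask <- outer(seq_len(nlon), seq_len(nlat),
                  function(i, j) lat[j] < coast_lat[i])
  }
  g <- structure(list(lon = lon, lat = lat, z = z, time = time, mask = mask,
                      dlon = spacing_deg, dlat = spacing_deg),
                 class = "vf_grid")
  validate_grid(g)
  g
}

# Latitude of the coast polyline at each requested longitude.
coastline_latitude <- function(coastline_spec, lon) {
  if (is.numeric(coastline_spec) && length(coastline_spec) == 1)
    return(rep(coastline_spec, length(lon)))
  cs <- as.matrix(coastline_spec)
  if (ncol(cs) != 2 || nrow(cs) < 2)
    stop("coastline_spec must be a latitude or a >= 2 vertex (lon, lat) polyline",
         call. = FALSE)
  stats::approx(cs[, 1], cs[, 2], xout = lon, rule = 2)$y
}

#' Validate a `vf_grid`
#'
#' Checks uniform axis spacing (1e-9 relative tolerance), minimum axis sizes
#' and mask shape. Called by constructors; exported for users assembling grids
#' by hand.
#' @param g a `vf_grid`.
#' @return `g`, invisibly, or an error.
#' @export
validate_grid <- function(g) {
  stopifnot(inherits(g, "vf_grid"))
  for (ax in c("lon", "lat")) {
    v <- g[[ax]]
    if (length(v) < 2) stop("axis '", ax, "' needs at least 2 points", call. = FALSE)
    d <- diff(v)
    if (any(abs(d - d[1]) > 1e-9 * abs(d[1])))
      stop("axis '", ax, "' is not uniformly spaced", call. = FALSE)
  }
  if (!identical(dim(g$mask), c(length(g$lon), length(g$lat))))
    stop("mask shape must be (nlon, nlat)", call. = FALSE)
  if (any(g$z > 0)) stop("z must be <= 0", call. = FALSE)
  invisible(g)
}

#' @export
print.vf_grid <- function(x, ...) {
  cat(sprintf("<vf_grid> %d x %d cells, %.4g deg spacing\n",
              length(x$lon), length(x$lat), x$dlon))
  cat(sprintf("  lon [%.3f, %.3f]  lat [%.3f, %.3f]\n",
              min(x$lon), max(x$lon), min(x$lat), max(x$lat)))
  cat(sprintf("  %d z level(s), %d time(s), %.1f%% ocean\n",
              length(x$z), length(x$time), 100 * mean(x$mask)))
  invisible(x)
}

# Metric offsets (m) of lon/lat points from a reference point, using the
# reference latitude for the zonal metric so that features keep an exactly
# non-divergent streamfunction representation on the sphere.
metric_offsets <- function(lon, lat, ref_lon, ref_lat) {
  list(s = EARTH_RADIUS * cos(.deg2rad(ref_lat)) * .deg2rad(lon - ref_lon),
       n = EARTH_RADIUS * .deg2rad(lat - ref_lat))
}
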