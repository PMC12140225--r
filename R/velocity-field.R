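# The VelocityField container: gridded, time-varying (u, v, w).

#' Construct a velocity field on a grid
#'
#' Arrays are stored in R (Fortran) order `(lon, lat, z, time)`, which is the
#' CF order `(time, z, lat, lon)` as seen from C/NetCDF tooling. Land cells
#' carry `NA` fill values and are never consumed except through mask-aware
#' interpolation.
#'
#' @param grid a `vf_grid`.
#' @param u,v zonal / meridional velocity (m/s), arrays of dim
#'   `(nlon, nlat, nz, ntime)` (or matrices `(nlon, nlat)` for a single
#'   steady surface slice, which are broadcast).
#' @param w optional vertical velocity (m/s), same shape; `NULL` means
#'   all-zero.
#' @return an object of class `velocity_field`.
#' @export
velocity_field <- function(grid, u, v, w = NULL) {
  validate_grid(grid)
  dims <- c(length(grid$lon), length(grid$lat), length(grid$z), length(grid$time))
  expand <- function(a, name) {
    if (is.matrix(a)) a <- array(a, dim = c(dim(a), 1L, 1L))
    if (length(dim(a)) != 4) stop(name, " must have dims (lon, lat, z, time)", call. = FALSE)
    if (identical(dim(a), c(dims[1:2], 1L, 1L)) && (dims[3] > 1 || dims[4] > 1))
      a <- array(a, dim = dims)  # broadcast steady surface slice
    if (!identical(as.integer(dim(a)), as.integer(dims)))
      stop(name, " shape does not match grid axes", call. = FALSE)
    a[!grid$mask] <- NA_real_   # recycles over z and time
    a
  }
  u <- expand(u, "u"); v <- expand(v, "v")
  if (!is.null(w)) w <- expand(w, "w")
  ocean <- rep(grid$mask, times = dims[3] * dims[4])
  if (anyNA(u[ocean]) || anyNA(v[ocean]))
    stop("u and v must be finite on ocean cells", call. = FALSE)
  structure(list(grid = grid, u = u, v = v, w = w), class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  g <- x$grid
  sp <- abs(sqrt(x$u^2 + x$v^2))
  cat(sprintf("<velocity_field> %d x %d x %d x %d (lon, lat, z, time)\n",
              length(g$lon), length(g$lat), length(g$z), length(g$time)))
  cat(sprintf("  max speed %.3f m/s, w %s\n", max(sp, na.rm = TRUE),
              if (is.null(x$w)) "absent (treated as 0)" else "present"))
  invisible(x)
}

#' Extract a single (time, z) slice of a velocity field
#'
#' @param field a `velocity_field`.
#' @param time_index,z_index 1-based indices into the grid time and z axes.
#' @return a `velocity_slice`: list with `u`, `v` matrices `(nlon, nlat)` and
#'   the parent `grid`.
#' @export
field_slice <- function(field, time_index = 1L, z_index = 1L) {
  stopifnot(inherits(field, "velocity_field"))
  g <- field$grid
  if (time_index < 1 || time_index > length(g$time))
    stop("time_index out of range", call. = FALSE)
  if (z_index < 1 || z_index > length(g$z))
    stop("z_index out of range", call. = FALSE)
  structure(list(u = field$u[, , z_index, time_index],
                 v = field$v[, , z_index, time_index],
                 w = if (is.null(field$w)) NULL else field$w[, , z_index, time_index],
                 grid = g),
            class = "velocity_slice")
}

#' Time-mean surface slice of a velocity field
#'
#' @param field a `velocity_field`.
#' @param z_index vertical level (default surface-most stored level 1).
#' @return a `velocity_slice` with time-averaged `u`, `v`.
#' @export
time_mean_slice <- function(field, z_index = 1L) {
  g <- field$grid
  nt <- length(g$time)
  um <- matrix(0, length(g$lon), length(g$lat))
  vm <- um
  for (it in seq_len(nt)) {
    um <- um + field$u[, , z_index, it]
    vm <- vm + field$v[, , z_index, it]
  }
  structure(list(u = um / nt, v = vm / nt, w = NULL, grid = g),
            class = "velocity_slice")
}
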