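# CF-style NetCDF read/write of gridded velocity fields, so externally
# produced ocean-model output can replace the synthetic generator.

.FILL <- 1e20

#' Write a velocity field to a CF-style NetCDF file
#'
#' Dimensions `(lon, lat, z, time)` (CF order `time, z, lat, lon` seen from
#' C tooling); variables `u`, `v` (and `w` if present) in m/s with the land
#' mask stored as a byte variable `mask` (1 = ocean). Units attributes are
#' always written.
#'
#' @param field a `velocity_field`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_velocity <- function(field, path) {
  stopifnot(inherits(field, "velocity_field"))
  g <- field$grid
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", g$lon)
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", g$lat)
  dz <- ncdf4::ncdim_def("z", "m", g$z)
  dtime <- ncdf4::ncdim_def("time", "seconds since run start", g$time,
                            unlim = TRUE)
  dims4 <- list(dlon, dlat, dz, dtime)
  vu <- ncdf4::ncvar_def("u", "m s-1", dims4, .FILL, prec = "double")
  vv <- ncdf4::ncvar_def("v", "m s-1", dims4, .FILL, prec = "double")
  vars <- list(vu, vv)
  if (!is.null(field$w)) {
    vw <- ncdf4::ncvar_def("w", "m s-1", dims4, .FILL, prec = "double")
    vars <- c(vars, list(vw))
  }
  vm <- ncdf4::ncvar_def("mask", "1", list(dlon, dlat), prec = "byte")
  vars <- c(vars, list(vm))
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc))
  put <- function(var, a) { a[is.na(a)] <- .FILL; ncdf4::ncvar_put(nc, var, a) }
  put(vu, field$u); put(vv, field$v)
  if (!is.null(field$w)) put(vw, field$w)
  ncdf4::ncvar_put(nc, vm, array(as.integer(g$mask), dim(g$mask)))
  invisible(path)
}

#' Read a velocity field from a CF-style NetCDF file
#'
#' Expects `lon`, `lat`, `time` axes (a `z` axis is optional; absent means a
#' single surface level) and `u`, `v` variables (`w` optional). A `mask`
#' variable is honoured when present; otherwise cells where `u` is fill/NA at
#' the first slice are treated as land.
#'
#' @param path NetCDF file path.
#' @return a `velocity_field`.
#' @export
read_velocity <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  need_dim <- function(name) {
    if (!name %in% names(nc$dim))
      stop("velocity file is missing required axis '", name, "'", call. = FALSE)
    nc$dim[[name]]$vals
  }
  lon <- need_dim("lon"); lat <- need_dim("lat"); time <- need_dim("time")
  z <- if ("z" %in% names(nc$dim)) nc$dim[["z"]]$vals else 0
  for (vn in c("u", "v"))
    if (!vn %in% names(nc$var))
      stop("velocity file is missing required variable '", vn, "'", call. = FALSE)
  dims <- c(length(lon), length(lat), length(z), length(time))
  get4 <- function(vn) {
    a <- ncdf4::ncvar_get(nc, vn, collapse_degen = FALSE)
    array(a, dim = dims)
  }
  u <- get4("u"); v <- get4("v")
  w <- if ("w" %in% names(nc$var)) get4("w") else NULL
  mask <- if ("mask" %in% names(nc$var)) {
    matrix(ncdf4::ncvar_get(nc, "mask") != 0, dims[1], dims[2])
  } else {
    !is.na(u[, , 1, 1]) & abs(u[, , 1, 1]) < .FILL / 2
  }
  g <- structure(list(lon = as.numeric(lon), lat = as.numeric(lat),
                      z = as.numeric(z), time = as.numeric(time), mask = mask,
                      dlon = if (length(lon) > 1) diff(lon[1:2]) else 1,
                      dlat = if (length(lat) > 1) diff(lat[1:2]) else 1),
                 class = "vf_grid")
  validate_grid(g)
  velocity_field(g, u, v, w)
}
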