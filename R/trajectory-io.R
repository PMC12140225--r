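# Trajectory persistence: NetCDF with dims (particle, time), plus a long CSV
# export for small runs.

#' Write a trajectory set to NetCDF
#'
#' Dimensions `(particle, time)`; variables `lon`, `lat`, `z`, `status`
#' (byte: 0 unreleased, 1 active, 2 beached, 3 exited), `source` (integer
#' index into a `source_names` global attribute) and `release_time`.
#'
#' @param traj a `trajectory_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(traj, path) {
  n <- nrow(traj$lon)
  dpart <- ncdf4::ncdim_def("particle", "1", seq_len(max(n, 1L)))
  dtime <- ncdf4::ncdim_def("time", "seconds since run start", traj$times)
  dims <- list(dpart, dtime)
  vlon <- ncdf4::ncvar_def("lon", "degrees_east", dims, .FILL, prec = "double")
  vlat <- ncdf4::ncvar_def("lat", "degrees_north", dims, .FILL, prec = "double")
  vz <- ncdf4::ncvar_def("z", "m", dims, .FILL, prec = "double")
  vst <- ncdf4::ncvar_def("status", "1", dims, prec = "byte")
  vsrc <- ncdf4::ncvar_def("source", "1", list(dpart), prec = "integer")
  vrel <- ncdf4::ncvar_def("release_time", "seconds since run start",
                           list(dpart), prec = "double")
  nc <- ncdf4::nc_create(path, list(vlon, vlat, vz, vst, vsrc, vrel))
  on.exit(ncdf4::nc_close(nc))
  put <- function(var, m) { m[is.na(m)] <- .FILL; ncdf4::ncvar_put(nc, var, m) }
  put(vlon, traj$lon); put(vlat, traj$lat); put(vz, traj$z)
  ncdf4::ncvar_put(nc, vst, traj$status)
  src_names <- unique(traj$releases$source)
  ncdf4::ncvar_put(nc, vsrc, match(traj$releases$source, src_names))
  ncdf4::ncvar_put(nc, vrel, traj$releases$release_time)
  ncdf4::ncatt_put(nc, 0, "source_names", paste(src_names, collapse = ","))
  ncdf4::ncatt_put(nc, 0, "status_codes",
                   "0=unreleased,1=active,2=beached,3=exited")
  invisible(path)
}

#' Read a trajectory set written by [write_trajectories()]
#' @param path NetCDF file path.
#' @return a `trajectory_set`.
#' @export
read_trajectories <- function(path) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  times <- nc$dim$time$vals
  getm <- function(vn) {
    m <- ncdf4::ncvar_get(nc, vn, collapse_degen = FALSE)
    m <- matrix(m, ncol = length(times))
    m[abs(m) >= .FILL / 2] <- NA_real_
    m
  }
  lon <- getm("lon"); lat <- getm("lat"); z <- getm("z")
  status <- matrix(as.integer(ncdf4::ncvar_get(nc, "status",
                                               collapse_degen = FALSE)),
                   ncol = length(times))
  src_names <- strsplit(ncdf4::ncatt_get(nc, 0, "source_names")$value, ",")[[1]]
  src <- src_names[as.integer(ncdf4::ncvar_get(nc, "source"))]
  releases <- data.frame(id = seq_len(nrow(lon)), source = src,
                         release_time = as.numeric(ncdf4::ncvar_get(nc, "release_time")),
                         lon = NA_real_, lat = NA_real_, z = NA_real_)
  structure(list(times = as.numeric(times), lon = lon, lat = lat, z = z,
                 status = status, releases = releases),
            class = "trajectory_set")
}

#' Long-format CSV export of a trajectory set
#'
#' One row per (particle, sample); intended for small demonstration runs.
#'
#' @param traj a `trajectory_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories_csv <- function(traj, path) {
  n <- nrow(traj$lon); ns <- ncol(traj$lon)
  df <- data.frame(particle = rep(seq_len(n), times = ns),
                   source = rep(traj$releases$source, times = ns),
                   time = rep(traj$times, each = n),
                   lon = as.vector(traj$lon),
                   lat = as.vector(traj$lat),
                   z = as.vector(traj$z),
                   status = as.vector(traj$status))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
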