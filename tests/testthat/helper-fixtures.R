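# Shared fixtures: analytic velocity slices, tiny grids and hand-built
# trajectory sets. Everything is generated in code at test time.

R_E <- larvadrift::EARTH_RADIUS
d2r <- pi / 180

ocean_grid <- function(spacing = 0.02, lon_range = c(-43, -42),
                       lat_range = c(-23.5, -22.5), coast = NULL, ...) {
  make_grid(lon_range, lat_range, spacing, coastline_spec = coast, ...)
}

# metric offsets from the grid center, matrices (nlon, nlat)
grid_offsets <- function(g, ref_lon = mean(range(g$lon)),
                         ref_lat = mean(range(g$lat))) {
  s <- outer(R_E * cos(ref_lat * d2r) * (g$lon - ref_lon) * d2r,
             rep(1, length(g$lat)))
  n <- outer(rep(1, length(g$lon)), R_E * (g$lat - ref_lat) * d2r)
  list(s = s, n = n, ref_lat = ref_lat)
}

analytic_slice <- function(g, ufun, vfun) {
  off <- grid_offsets(g)
  structure(list(u = ufun(off$s, off$n), v = vfun(off$s, off$n), grid = g),
            class = "velocity_slice")
}

shear_slice <- function(g, gamma) # u = gamma * y, v = 0
  analytic_slice(g, function(s, n) gamma * n, function(s, n) 0 * s)

strain_slice <- function(g, gamma) # u = gamma * x, v = -gamma * y
  analytic_slice(g, function(s, n) gamma * s, function(s, n) -gamma * n)

solid_rotation_slice <- function(g, omega)
  analytic_slice(g, function(s, n) -omega * n, function(s, n) omega * s)

uniform_slice <- function(g, u0, v0)
  analytic_slice(g, function(s, n) u0 + 0 * s, function(s, n) v0 + 0 * s)

# steady uniform velocity_field over a time span (s)
uniform_field <- function(g, u0, v0, t_end = 30 * 86400) {
  g$time <- c(0, t_end)
  nlon <- length(g$lon); nlat <- length(g$lat)
  velocity_field(g, array(u0, c(nlon, nlat, length(g$z), 2)),
                 array(v0, c(nlon, nlat, length(g$z), 2)))
}

# planar solid-body rotation sampler about (lon0, lat0), for integrator tests
rotation_sampler <- function(omega, lon0, lat0) {
  force(omega)
  function(lon, lat, z, t) {
    s <- R_E * cos(lat0 * d2r) * (lon - lon0) * d2r
    n <- R_E * (lat - lat0) * d2r
    list(u = -omega * n, v = omega * s, w = 0)
  }
}

metric_dist <- function(lon1, lat1, lon2, lat2, ref_lat) {
  s <- R_E * cos(ref_lat * d2r) * (lon2 - lon1) * d2r
  n <- R_E * (lat2 - lat1) * d2r
  sqrt(s^2 + n^2)
}

# hand-built trajectory set: positions (n x ns) matrices, all active
manual_traj <- function(lon, lat, times = seq(0, by = 21600,
                                              length.out = ncol(lon)),
                        sources = rep("A", nrow(lon))) {
  n <- nrow(lon)
  structure(list(times = times, lon = lon, lat = lat,
                 z = matrix(0, n, ncol(lon)),
                 status = matrix(1L, n, ncol(lon)),
                 releases = data.frame(id = seq_len(n), source = sources,
                                       release_time = numeric(n),
                                       lon = lon[, 1], lat = lat[, 1],
                                       z = numeric(n))),
            class = "trajectory_set")
}

# brute-force connectivity oracle: loops over particles and samples
brute_connectivity <- function(traj, sources, destinations) {
  src <- vapply(sources, `[[`, "", "name")
  dst <- vapply(destinations, `[[`, "", "name")
  vals <- matrix(0, length(src), length(dst), dimnames = list(src, dst))
  ns <- ncol(traj$lon)
  for (is in seq_along(src)) {
    ids <- which(traj$releases$source == src[is])
    for (jd in seq_along(dst)) {
      hit <- 0L
      for (p in ids) {
        if (src[is] == dst[jd]) {
          ok <- point_in_region(traj$lon[p, ns], traj$lat[p, ns],
                                destinations[[jd]])
        } else {
          ok <- FALSE
          for (k in seq_len(ns)) {
            if (is.finite(traj$lon[p, k]) &&
                point_in_region(traj$lon[p, k], traj$lat[p, k],
                                destinations[[jd]])) {
              ok <- TRUE
              break
            }
          }
        }
        hit <- hit + ok
      }
      vals[is, jd] <- hit / length(ids)
    }
  }
  vals
}
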