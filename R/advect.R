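# RK4 advection of passive particles with a vertical random walk and
# beaching / exit bookkeeping.

#' Vertical random-walk configuration
#'
#' A naive (constant-diffusivity) random walk emulating unresolved turbulent
#' vertical transport: after each advection step a particle receives
#' `dz = sqrt(2 kappa_v dt) N(0, 1)` and is reflected at the surface and at
#' the local bottom.
#'
#' @param kappa_v vertical diffusivity, m^2/s (>= 0). Default 1e-5.
#' @param seed integer RNG seed for the walk.
#' @param dt model time step the walk is applied at, s (> 0).
#' @return object of class `random_walk_config`.
#' @export
random_walk_config <- function(kappa_v = 1e-5, seed = 1L, dt = 60) {
  if (kappa_v < 0) stop("kappa_v must be >= 0", call. = FALSE)
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  structure(list(kappa_v = kappa_v, seed = as.integer(seed), dt = dt),
            class = "random_walk_config")
}

#' Vertical random-walk displacements
#'
#' @param n number of displacements to draw.
#' @param rw a `random_walk_config`.
#' @return numeric vector of `dz` in metres (all zero when `kappa_v = 0`).
#' @export
vertical_random_walk <- function(n, rw) {
  if (rw$kappa_v == 0) return(numeric(n))
  sqrt(2 * rw$kappa_v * rw$dt) * stats::rnorm(n)
}

# Reflect depths into [zbot, 0] (surface at 0).
.reflect_z <- function(z, zbot) {
  z <- ifelse(z > 0, -z, z)
  z <- ifelse(z < zbot, 2 * zbot - z, z)
  pmin(pmax(z, zbot), 0)
}

# One vectorized classical RK4 step of (lon, lat, z) for all particles at a
# shared time t. `sampler(lon, lat, z, t)` returns velocities in m/s;
# degree <-> metre conversion uses the instantaneous particle latitude.
.rk4_step <- function(lon, lat, z, t, dt, sampler, zbot) {
  r2d <- 180 / pi
  vel2deg <- function(vel, lat_here) {
    list(dlon = vel$u / (EARTH_RADIUS * cos(.deg2rad(lat_here))) * r2d,
         dlat = vel$v / EARTH_RADIUS * r2d,
         dz = vel$w)
  }
  k1 <- vel2deg(sampler(lon, lat, z, t), lat)
  p2lat <- lat + dt / 2 * k1$dlat
  k2 <- vel2deg(sampler(lon + dt / 2 * k1$dlon, p2lat,
                        .reflect_z(z + dt / 2 * k1$dz, zbot), t + dt / 2), p2lat)
  p3lat <- lat + dt / 2 * k2$dlat
  k3 <- vel2deg(sampler(lon + dt / 2 * k2$dlon, p3lat,
                        .reflect_z(z + dt / 2 * k2$dz, zbot), t + dt / 2), p3lat)
  p4lat <- lat + dt * k3$dlat
  k4 <- vel2deg(sampler(lon + dt * k3$dlon, p4lat,
                        .reflect_z(z + dt * k3$dz, zbot), t + dt), p4lat)
  list(lon = lon + dt / 6 * (k1$dlon + 2 * k2$dlon + 2 * k3$dlon + k4$dlon),
       lat = lat + dt / 6 * (k1$dlat + 2 * k2$dlat + 2 * k3$dlat + k4$dlat),
       z = pmin(pmax(z + dt / 6 * (k1$dz + 2 * k2$dz + 2 * k3$dz + k4$dz), zbot), 0))
}

#' Single RK4 step of one or more particles
#'
#' Thin public wrapper over the vectorized integrator used by [advect()];
#' useful for integrator-order studies. The field may be a `velocity_field`
#' or a function `(lon, lat, z, t) -> list(u, v, w)` for analytic tests.
#'
#' @param particle list or data.frame with `lon`, `lat`, `z`.
#' @param field a `velocity_field` or velocity function.
#' @param dt time step, s (> 0).
#' @param t current time, s.
#' @return list with candidate `lon`, `lat`, `z`.
#' @export
step_rk4 <- function(particle, field, dt, t = 0) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  sampler <- if (is.function(field)) field else .make_sampler(field)
  zbot <- if (is.function(field)) -Inf else min(field$grid$z, -0)
  .rk4_step(particle$lon, particle$lat, particle$z, t, dt, sampler,
            if (is.finite(zbot)) min(zbot, 0) else -Inf)
}

# status codes for the trajectory arrays
STATUS_UNRELEASED <- 0L
STATUS_ACTIVE <- 1L
STATUS_BEACHED <- 2L
STATUS_EXITED <- 3L

#' Advect a release table through a velocity field
#'
#' Steps every active particle with RK4 advection plus the vertical random
#' walk, at internal time step `dt`, sampling positions at `output_cadence`.
#' A candidate position landing on a land (masked) cell beaches the particle
#' (terminal, frozen at the candidate); a candidate leaving the grid marks
#' it exited (terminal, frozen). Fully deterministic given the random-walk
#' seed.
#'
#' @param releases data.frame from [make_release()] / [combine_releases()].
#' @param field a `velocity_field` spanning the run.
#' @param duration run length in seconds (default 20 days, the competency
#'   window); must not exceed the field's time span.
#' @param dt internal step, s; must divide `output_cadence`. Default 60.
#' @param output_cadence sampling interval, s (default 6 h).
#' @param rw a `random_walk_config` (its `dt` is overridden by `dt`).
#' @param start_time epoch seconds of the run start (default 0).
#' @return object of class `trajectory_set`: list with `times` (sample
#'   times), `lon`, `lat`, `z` matrices `(particle, sample)` (`NA` before
#'   release), `status` integer matrix (0 unreleased, 1 active, 2 beached,
#'   3 exited), and the `releases` table.
#' @export
advect <- function(releases, field, duration = 20 * 86400, dt = 60,
                   output_cadence = 6 * 3600,
                   rw = random_walk_config(), start_time = 0) {
  stopifnot(inherits(field, "velocity_field"))
  if (output_cadence %% dt != 0)
    stop("dt must divide output_cadence", call. = FALSE)
  g <- field$grid
  if (start_time < min(g$time) || start_time + duration > max(g$time))
    stop("run window exceeds the field's time span", call. = FALSE)
  n <- nrow(releases)
  times <- seq(start_time, start_time + duration, by = output_cadence)
  ns <- length(times)
  lonM <- matrix(NA_real_, n, ns); latM <- lonM; zM <- lonM
  statusM <- matrix(STATUS_UNRELEASED, n, ns)
  if (n == 0)
    return(structure(list(times = times, lon = lonM, lat = latM, z = zM,
                          status = statusM, releases = releases),
                     class = "trajectory_set"))

  sampler <- .make_sampler(field)
  zbot <- min(g$z, 0)
  lon_rng <- range(g$lon); lat_rng <- range(g$lat)
  nlon <- length(g$lon)

  lon <- rep(NA_real_, n); lat <- lon; z <- lon
  status <- rep(STATUS_UNRELEASED, n)
  rw$dt <- dt
  rs <- .local_rng(rw$seed)
  on.exit(rs$restore(), add = TRUE)

  nsteps <- as.integer(round(duration / dt))
  steps_per_sample <- as.integer(output_cadence / dt)
  isample <- 1L
  for (istep in 0:nsteps) {
    t <- start_time + istep * dt
    due <- status == STATUS_UNRELEASED & releases$release_time <= t
    if (any(due)) {
      status[due] <- STATUS_ACTIVE
      lon[due] <- releases$lon[due]
      lat[due] <- releases$lat[due]
      z[due] <- pmin(pmax(releases$z[due], zbot), 0)
    }
    if (istep %% steps_per_sample == 0L) {
      lonM[, isample] <- lon; latM[, isample] <- lat; zM[, isample] <- z
      statusM[, isample] <- status
      isample <- isample + 1L
    }
    if (istep == nsteps) break
    act <- which(status == STATUS_ACTIVE)
    if (length(act)) {
      cand <- .rk4_step(lon[act], lat[act], z[act], t, dt, sampler, zbot)
      dz <- vertical_random_walk(length(act), rw)
      cz <- .reflect_z(cand$z + dz, zbot)
      oob <- cand$lon < lon_rng[1] | cand$lon > lon_rng[2] |
             cand$lat < lat_rng[1] | cand$lat > lat_rng[2]
      ix <- pmin(pmax(as.integer(round((cand$lon - g$lon[1]) / g$dlon)) + 1L, 1L), nlon)
      iy <- pmin(pmax(as.integer(round((cand$lat - g$lat[1]) / g$dlat)) + 1L, 1L),
                 length(g$lat))
      on_land <- !g$mask[cbind(ix, iy)] & !oob
      lon[act] <- cand$lon; lat[act] <- cand$lat; z[act] <- cz
      status[act[oob]] <- STATUS_EXITED
      status[act[on_land]] <- STATUS_BEACHED
    }
  }
  structure(list(times = times, lon = lonM, lat = latM, z = zM,
                 status = statusM, releases = releases),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  fin <- x$status[, ncol(x$status)]
  cat(sprintf("<trajectory_set> %d particles, %d samples (%.1f d at %.1f h)\n",
              nrow(x$lon), length(x$times),
              diff(range(x$times)) / 86400,
              if (length(x$times) > 1) diff(x$times[1:2]) / 3600 else 0))
  cat(sprintf("  final status: %d active, %d beached, %d exited, %d unreleased\n",
              sum(fin == STATUS_ACTIVE), sum(fin == STATUS_BEACHED),
              sum(fin == STATUS_EXITED), sum(fin == STATUS_UNRELEASED)))
  invisible(x)
}

#' Per-sample status accounting of a trajectory set
#'
#' @param traj a `trajectory_set`.
#' @return data.frame with one row per sample time and columns `time`,
#'   `unreleased`, `active`, `beached`, `exited`, `total`.
#' @export
status_counts <- function(traj) {
  cnt <- function(code) colSums(traj$status == code)
  data.frame(time = traj$times,
             unreleased = cnt(STATUS_UNRELEASED),
             active = cnt(STATUS_ACTIVE),
             beached = cnt(STATUS_BEACHED),
             exited = cnt(STATUS_EXITED),
             total = nrow(traj$status))
}
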