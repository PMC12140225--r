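# Analytic synthetic velocity fields: alongshore jet, cross-shelf filaments,
# Rankine eddies, and the two wind-scenario configurations.
#
# Every feature is built from a scalar streamfunction psi(lon, lat), with
# velocities u = -(1/R) dpsi/dphi, v = (1/(R cos phi)) dpsi/dlambda evaluated
# analytically. Fields are therefore exactly non-divergent in the spherical
# flux sense; discrete divergence vanishes at second order in grid spacing.
# Feature geometry uses metric offsets at the feature's own reference
# latitude, so shapes are undistorted to O(domain width x tan(lat)).

#' Scenario configuration for synthetic wind-regime velocity fields
#'
#' Two named regimes mirror the study-area phenomenology: `"northeast"`
#' (prevailing northeasterly winds driving a steady southwestward alongshore
#' jet that sheds cyclonic cross-shelf filaments) and `"cold_front"` (the
#' same jet reversing to northeastward when a cold front passes at
#' `reversal_day`). `"custom"` applies no defaults beyond what is passed.
#'
#' @param name one of `"northeast"`, `"cold_front"`, `"custom"`.
#' @param duration_days simulation length in days (> 0); default 20, the
#'   larval competency window used throughout.
#' @param cadence_hours output cadence of the generated field (default 6 h).
#' @param jet_speed peak alongshore jet speed, m/s.
#' @param jet_width_km Gaussian e-folding half-width of the jet, km.
#' @param jet_offshore_km distance of the jet core from the coast, km.
#' @param coast_lat latitude of the (straight) coast the jet follows;
#'   `NULL` means infer from the grid mask at build time.
#' @param filament_specs list of filament specs, each a list with `origin`
#'   (lon, lat on/near the coast), `length_km` (offshore extent),
#'   `width_km` (alongshore half-width), `peak_speed` (m/s) and `polarity`
#'   (`"cyclonic"` or `"anticyclonic"`).
#' @param eddy_specs list of eddy specs, each with `center` (lon, lat),
#'   `core_radius_km`, `peak_speed`, `polarity`.
#' @param reversal_day day of the alongshore-flow reversal (cold front
#'   passage); `NULL` disables it. Must lie in `[0, duration_days]`.
#' @param reversal_width_hours time scale of the smooth (tanh) sign change.
#' @param n_random_filaments number of additional cyclonic filaments placed
#'   pseudo-randomly along the coast (0 = none); controlled by `seed`.
#' @param seed integer seed for any randomized placement.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(name = c("northeast", "cold_front", "custom"),
                            duration_days = 20, cadence_hours = 6,
                            jet_speed = 0.3, jet_width_km = 20,
                            jet_offshore_km = 25, coast_lat = NULL,
                            filament_specs = NULL, eddy_specs = NULL,
                            reversal_day = NULL, reversal_width_hours = 6,
                            n_random_filaments = 0, seed = 1L) {
  name <- match.arg(name)
  if (duration_days <= 0) stop("duration_days must be > 0", call. = FALSE)
  if (jet_width_km <= 0) stop("jet_width_km must be > 0", call. = FALSE)
  if (name == "cold_front" && is.null(reversal_day)) reversal_day <- duration_days / 2
  if (!is.null(reversal_day) &&
      (reversal_day < 0 || reversal_day > duration_days))
    stop("reversal_day must lie within [0, duration_days]", call. = FALSE)
  for (fs in filament_specs)
    if (fs$width_km <= 0 || fs$length_km <= 0)
      stop("filament widths and lengths must be > 0", call. = FALSE)
  for (es in eddy_specs)
    if (es$core_radius_km <= 0)
      stop("eddy core radii must be > 0", call. = FALSE)
  structure(list(name = name, duration_days = duration_days,
                 cadence_hours = cadence_hours, jet_speed = jet_speed,
                 jet_width_km = jet_width_km, jet_offshore_km = jet_offshore_km,
                 coast_lat = coast_lat, filament_specs = filament_specs,
                 eddy_specs = eddy_specs, reversal_day = reversal_day,
                 reversal_width_hours = reversal_width_hours,
                 n_random_filaments = n_random_filaments,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> '%s': %g d at %g h cadence\n",
              x$name, x$duration_days, x$cadence_hours))
  cat(sprintf("  jet %.2f m/s (width %g km), %d filament(s), %d eddy(ies)%s\n",
              x$jet_speed, x$jet_width_km,
              length(x$filament_specs) + x$n_random_filaments,
              length(x$eddy_specs),
              if (is.null(x$reversal_day)) ""
              else sprintf(", reversal at day %g", x$reversal_day)))
  invisible(x)
}

# Coriolis-consistent signed amplitude: cyclonic means zeta/f > 0.
.polarity_sign <- function(polarity, lat) {
  f <- coriolis_f(coriolis_model(), lat)
  if (abs(f) < 1e-12)
    stop("polarity is undefined at the equator", call. = FALSE)
  s <- sign(f)
  switch(polarity,
         cyclonic = s,
         anticyclonic = -s,
         stop("polarity must be 'cyclonic' or 'anticyclonic'", call. = FALSE))
}

# Velocity contribution of one Rankine eddy at metric offsets (s, n) from
# its center; solid-body core, azimuthal speed decaying as rc/r outside.
.eddy_uv <- function(s, n, core_radius, peak_speed, rot_sign, cos_ratio) {
  r <- sqrt(s^2 + n^2)
  vtheta <- ifelse(r <= core_radius,
                   peak_speed * r / core_radius,
                   peak_speed * core_radius / pmax(r, .Machine$double.eps))
  # streamfunction derivative dpsi/dr = rot * vtheta; u = -F_n, v = F_s
  unit_s <- ifelse(r > 0, s / r, 0)
  unit_n <- ifelse(r > 0, n / r, 0)
  list(u = -rot_sign * vtheta * unit_n,
       v =  rot_sign * vtheta * unit_s * cos_ratio)
}

# Velocity contribution of one elongated Gaussian-ridge filament. The ridge
# streamfunction F = A exp(-(s/w)^2 - ((n - nc)/hl)^2) has its center half a
# length offshore of the coastal origin; peak relative vorticity is about
# -2 A / w^2, so cyclonic filaments take A with sign opposite to f.
.filament_uv <- function(s, n, width, length_off, peak_speed, pol_sign,
                         cos_ratio) {
  hl <- length_off / 2
  nc <- -hl                       # offshore (negative n) of the coastal origin
  amp <- peak_speed * width * exp(0.5) / sqrt(2)
  # sign(zeta) = sign(f) for cyclonic => sign(A) = -sign(zeta_request)
  A <- -pol_sign2zeta(pol_sign) * amp
  G <- exp(-(s / width)^2 - ((n - nc) / hl)^2)
  Fs <- A * (-2 * s / width^2) * G
  Fn <- A * (-2 * (n - nc) / hl^2) * G
  list(u = -Fn, v = Fs * cos_ratio)
}

# pol_sign is sign(zeta) wanted (= sign(f) for cyclonic); identity helper
# kept for readability at the call site.
pol_sign2zeta <- function(pol_sign) pol_sign

#' Steady Rankine eddy velocity field
#'
#' Axisymmetric vortex with solid-body rotation inside `core_radius_km` and
#' azimuthal speed decaying as `core_radius / r` outside. `"cyclonic"`
#' polarity gives `zeta / f > 0` at the eddy latitude (clockwise rotation in
#' the southern hemisphere).
#'
#' @param grid a `vf_grid`.
#' @param center length-2 (lon, lat) of the eddy center; must be an ocean
#'   point inside the grid.
#' @param core_radius_km solid-body core radius, km (> 0).
#' @param peak_speed azimuthal speed at the core edge, m/s.
#' @param polarity `"cyclonic"` or `"anticyclonic"`.
#' @return a steady `velocity_field` on the grid's time axis.
#' @export
eddy_field <- function(grid, center, core_radius_km, peak_speed,
                       polarity = "cyclonic") {
  validate_grid(grid)
  if (core_radius_km <= 0) stop("core_radius_km must be > 0", call. = FALSE)
  if (center[1] < min(grid$lon) || center[1] > max(grid$lon) ||
      center[2] < min(grid$lat) || center[2] > max(grid$lat))
    stop("eddy center lies outside the grid", call. = FALSE)
  ic <- which.min(abs(grid$lon - center[1]))
  jc <- which.min(abs(grid$lat - center[2]))
  if (!grid$mask[ic, jc]) stop("eddy center lies on a land cell", call. = FALSE)

  ll <- expand_lonlat(grid)
  off <- metric_offsets(ll$lon, ll$lat, center[1], center[2])
  cr <- cos(.deg2rad(center[2])) / cos(.deg2rad(ll$lat))
  rot <- .polarity_sign(polarity, center[2])
  uv <- .eddy_uv(off$s, off$n, core_radius_km * 1000, peak_speed, rot, cr)
  nlon <- length(grid$lon); nlat <- length(grid$lat)
  velocity_field(grid, matrix(uv$u, nlon, nlat), matrix(uv$v, nlon, nlat))
}

# (lon, lat) of every grid point, column-major over (lon, lat).
expand_lonlat <- function(grid) {
  list(lon = rep(grid$lon, times = length(grid$lat)),
       lat = rep(grid$lat, each = length(grid$lon)))
}

# Smooth alongshore direction factor: -1 (southwestward, the
# northeasterly-wind response) before the reversal, +1 after.
.jet_direction <- function(t, config) {
  if (is.null(config$reversal_day)) return(-1)
  tau <- config$reversal_width_hours * 3600
  t_rev <- config$reversal_day * 86400
  tanh((t - t_rev) / tau)
}

# Infer a straight coast latitude from the grid mask: the northernmost
# latitude that still has ocean, plus half a cell.
.infer_coast_lat <- function(grid) {
  ocean_rows <- which(colSums(grid$mask) > 0)
  if (length(ocean_rows) == 0) stop("grid has no ocean cells", call. = FALSE)
  lat <- grid$lat[max(ocean_rows)]
  min(lat + grid$dlat / 2, max(grid$lat))
}

# Materialize the full filament list (explicit specs + seeded random ones).
.resolve_filaments <- function(config, grid, coast_lat) {
  specs <- config$filament_specs
  n_extra <- config$n_random_filaments
  if (n_extra > 0) {
    rs <- .local_rng(config$seed)
    on.exit(rs$restore(), add = TRUE)
    lon_lo <- stats::quantile(grid$lon, 0.1)
    lon_hi <- stats::quantile(grid$lon, 0.9)
    for (k in seq_len(n_extra)) {
      specs[[length(specs) + 1L]] <- list(
        origin = c(stats::runif(1, lon_lo, lon_hi), coast_lat),
        length_km = stats::runif(1, 30, 60),
        width_km = stats::runif(1, 3, 6),
        peak_speed = stats::runif(1, 0.2, 0.4),
        polarity = "cyclonic")
    }
  }
  specs
}

#' Evaluate one time slice of a scenario's velocity field
#'
#' Sums the streamfunction-derived contributions of the alongshore jet (with
#' its time-dependent direction), every filament and every eddy at time `t`.
#'
#' @param grid a `vf_grid`.
#' @param config a `scenario_config`.
#' @param t time in seconds since the scenario start, within
#'   `[0, duration]`.
#' @return a `velocity_field` with a single time `t`.
#' @export
jet_with_filaments <- function(grid, config, t) {
  stopifnot(inherits(config, "scenario_config"))
  dur <- config$duration_days * 86400
  if (t < 0 || t > dur)
    stop("t must lie within [0, duration]", call. = FALSE)
  coast_lat <- if (is.null(config$coast_lat)) .infer_coast_lat(grid) else config$coast_lat
  nlon <- length(grid$lon); nlat <- length(grid$lat)
  ll <- expand_lonlat(grid)
  u <- numeric(nlon * nlat); v <- u

  if (config$jet_speed != 0) {
    dir <- .jet_direction(t, config)
    n <- EARTH_RADIUS * .deg2rad(ll$lat - coast_lat)  # negative offshore
    nc <- -config$jet_offshore_km * 1000
    u <- u + dir * config$jet_speed * exp(-((n - nc) / (config$jet_width_km * 1000))^2)
  }
  for (fs in .resolve_filaments(config, grid, coast_lat)) {
    off <- metric_offsets(ll$lon, ll$lat, fs$origin[1], fs$origin[2])
    cr <- cos(.deg2rad(fs$origin[2])) / cos(.deg2rad(ll$lat))
    pol <- .polarity_sign(fs$polarity, fs$origin[2])
    uv <- .filament_uv(off$s, off$n, fs$width_km * 1000, fs$length_km * 1000,
                       fs$peak_speed, pol, cr)
    u <- u + uv$u; v <- v + uv$v
  }
  for (es in config$eddy_specs) {
    off <- metric_offsets(ll$lon, ll$lat, es$center[1], es$center[2])
    cr <- cos(.deg2rad(es$center[2])) / cos(.deg2rad(ll$lat))
    rot <- .polarity_sign(es$polarity, es$center[2])
    uv <- .eddy_uv(off$s, off$n, es$core_radius_km * 1000, es$peak_speed, rot, cr)
    u <- u + uv$u; v <- v + uv$v
  }
  g1 <- grid; g1$time <- t
  velocity_field(g1, matrix(u, nlon, nlat), matrix(v, nlon, nlat))
}

#' Build the full time-varying velocity field of a scenario
#'
#' Samples [jet_with_filaments()] at the configured cadence over the full
#' duration (inclusive endpoints, so 20 days at 6 h gives 81 slices). The
#' result is deterministic given `(config, seed)`.
#'
#' @param config a `scenario_config`.
#' @param grid a `vf_grid` supplying the spatial axes and land mask.
#' @return a `velocity_field` whose time axis is seconds since scenario start.
#' @export
build_scenario <- function(config, grid) {
  stopifnot(inherits(config, "scenario_config"))
  validate_grid(grid)
  cadence <- config$cadence_hours * 3600
  times <- seq(0, config$duration_days * 86400, by = cadence)
  nlon <- length(grid$lon); nlat <- length(grid$lat); nz <- length(grid$z)
  u <- array(NA_real_, c(nlon, nlat, nz, length(times)))
  v <- u
  # resolve randomized filaments once so every slice sees the same set
  coast_lat <- if (is.null(config$coast_lat)) .infer_coast_lat(grid) else config$coast_lat
  config$filament_specs <- .resolve_filaments(config, grid, coast_lat)
  config$n_random_filaments <- 0L
  config$coast_lat <- coast_lat
  for (it in seq_along(times)) {
    sl <- jet_with_filaments(grid, config, times[it])
    for (iz in seq_len(nz)) {          # vertically uniform by construction
      u[, , iz, it] <- sl$u[, , 1, 1]
      v[, , iz, it] <- sl$v[, , 1, 1]
    }
  }
  g <- grid; g$time <- times
  velocity_field(g, u, v)
}

# Save/restore the global RNG around a locally seeded draw.
.local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  list(restore = function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
}
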