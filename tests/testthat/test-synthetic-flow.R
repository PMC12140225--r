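# Synthetic flow generator: Rankine profile, streamfunction non-divergence,
# scenario determinism, polarity convention and the cold-front reversal.

test_that("Rankine eddy reproduces its azimuthal speed profile", {
  g <- ocean_grid(0.005)
  ctr <- c(-42.5, -23)
  f <- eddy_field(g, ctr, core_radius_km = 8, peak_speed = 0.4,
                  polarity = "cyclonic")
  sl <- field_slice(f)
  # exact zero at the center (a grid point), peak speed at the core edge,
  # half the peak at twice the core radius, at every azimuth
  off <- grid_offsets(g, ctr[1], ctr[2])
  r <- sqrt(off$s^2 + off$n^2)
  speed <- sqrt(sl$u^2 + sl$v^2)
  profile <- ifelse(r <= 8000, 0.4 * r / 8000, 0.4 * 8000 / pmax(r, 1))
  expect_lt(speed[r == 0], 1e-12)
  rel_err <- abs(speed - profile) / 0.4
  expect_lt(max(rel_err, na.rm = TRUE), 0.01)
  edge <- abs(r - 8000) < 200
  expect_equal(mean(speed[edge]), 0.4, tolerance = 0.03)
  far <- abs(r - 16000) < 200
  expect_equal(mean(speed[far]), 0.2, tolerance = 0.03)
})

test_that("eddy polarity fixes the sign of zeta/f in both hemispheres", {
  for (hemi_lat in c(-23, 23)) {
    g <- make_grid(c(-43, -42), hemi_lat + c(-0.5, 0.5), 0.01)
    for (pol in c("cyclonic", "anticyclonic")) {
      f <- eddy_field(g, c(-42.5, hemi_lat), 8, 0.3, pol)
      dg <- diagnose_slice(field_slice(f))
      i <- which.min(abs(g$lon + 42.5)); j <- which.min(abs(g$lat - hemi_lat))
      ro <- dg$rossby[i, j]
      if (pol == "cyclonic") expect_gt(ro, 0) else expect_lt(ro, 0)
    }
  }
})

test_that("eddy center on land or off-grid is a configuration error", {
  g <- ocean_grid(0.02, coast = -22.8)
  expect_error(eddy_field(g, c(-42.5, -22.7), 5, 0.3), "land")
  expect_error(eddy_field(g, c(-50, -23), 5, 0.3), "outside")
  expect_error(eddy_field(g, c(-42.5, -23), -5, 0.3), "> 0")
})

test_that("filament slices are non-divergent with second-order convergence", {
  cfg <- scenario_config("northeast", duration_days = 1, jet_speed = 0.25,
                         coast_lat = -22.8,
                         filament_specs = list(list(
                           origin = c(-42.5, -22.8), length_km = 50,
                           width_km = 5, peak_speed = 0.3,
                           polarity = "cyclonic")))
  div_max <- vapply(c(0.02, 0.01, 0.005), function(h) {
    g <- ocean_grid(h, coast = -22.8)
    sl <- field_slice(jet_with_filaments(g, cfg, 0))
    max(abs(divergence(sl)), na.rm = TRUE)
  }, 0)
  zeta_scale <- max(abs(relative_vorticity(
    field_slice(jet_with_filaments(ocean_grid(0.01, coast = -22.8), cfg, 0)))),
    na.rm = TRUE)
  expect_lt(div_max[1], 0.05 * zeta_scale)       # small already at coarse h
  expect_gt(div_max[1] / div_max[2], 3)          # ~4x drop per halving
  expect_gt(div_max[2] / div_max[3], 3)
})

test_that("zero jet with no features gives an all-zero field", {
  g <- ocean_grid(0.05)
  cfg <- scenario_config("custom", duration_days = 1, jet_speed = 0)
  sl <- field_slice(jet_with_filaments(g, cfg, 0))
  expect_equal(max(abs(sl$u)), 0)
  expect_equal(max(abs(sl$v)), 0)
  expect_error(jet_with_filaments(g, cfg, 2 * 86400), "within")
})

test_that("scenarios are deterministic and 20 d at 6 h gives 81 slices", {
  g <- ocean_grid(0.05, coast = -22.8)
  cfg <- scenario_config("northeast", duration_days = 20,
                         n_random_filaments = 2, seed = 7)
  f1 <- build_scenario(cfg, g)
  f2 <- build_scenario(cfg, g)
  expect_identical(f1$u, f2$u)
  expect_identical(f1$v, f2$v)
  expect_equal(length(f1$grid$time), 20 * 24 / 6 + 1)
  # a different seed moves the randomized filaments
  f3 <- build_scenario(scenario_config("northeast", duration_days = 20,
                                       n_random_filaments = 2, seed = 8), g)
  expect_false(identical(f1$v, f3$v))
})

test_that("northeast scenario has time-mean southwestward alongshore flow", {
  g <- ocean_grid(0.02, lon_range = c(-44, -42), coast = -22.8)
  cfg <- scenario_config("northeast", duration_days = 5)
  f <- build_scenario(cfg, g)
  um <- time_mean_slice(f)$u
  expect_lt(mean(um[f$grid$mask]), 0)
})

test_that("cold-front alongshore flow changes sign across reversal_day", {
  g <- ocean_grid(0.05, coast = -22.8)
  cfg <- scenario_config("cold_front", duration_days = 10, reversal_day = 5)
  before <- field_slice(jet_with_filaments(g, cfg, 4.0 * 86400))
  after <- field_slice(jet_with_filaments(g, cfg, 6.0 * 86400))
  expect_lt(mean(before$u[g$mask]), 0)
  expect_gt(mean(after$u[g$mask]), 0)
  # immediately around the reversal instant the sign already flips
  eps <- 600
  just_before <- field_slice(jet_with_filaments(g, cfg, 5 * 86400 - eps))
  just_after <- field_slice(jet_with_filaments(g, cfg, 5 * 86400 + eps))
  expect_lt(mean(just_before$u[g$mask]), 0)
  expect_gt(mean(just_after$u[g$mask]), 0)
})

test_that("filament polarity controls the sign of its zeta/f extremum", {
  g <- ocean_grid(0.01, coast = -22.8)
  for (pol in c("cyclonic", "anticyclonic")) {
    cfg <- scenario_config("custom", duration_days = 1, jet_speed = 0,
                           coast_lat = -22.8,
                           filament_specs = list(list(
                             origin = c(-42.5, -22.8), length_km = 40,
                             width_km = 4, peak_speed = 0.3, polarity = pol)))
    ro <- diagnose_slice(field_slice(jet_with_filaments(g, cfg, 0)))$rossby
    ext <- ro[which.max(abs(ro))]
    if (pol == "cyclonic") expect_gt(ext, 0) else expect_lt(ext, 0)
  }
})

test_that("velocity fields round-trip through NetCDF", {
  g <- ocean_grid(0.05, coast = -22.8)
  cfg <- scenario_config("northeast", duration_days = 1)
  f <- build_scenario(cfg, g)
  path <- withr::local_tempfile(fileext = ".nc")
  write_velocity(f, path)
  f2 <- read_velocity(path)
  expect_equal(f2$grid$lon, g$lon)
  expect_equal(f2$grid$time, f$grid$time)
  expect_identical(f2$grid$mask, g$mask)            # masked cells survive
  ocean <- which(rep(g$mask, length(g$z) * length(f$grid$time)))
  expect_lt(max(abs(f2$u[ocean] - f$u[ocean])), 1e-6)
  expect_lt(max(abs(f2$v[ocean] - f$v[ocean])), 1e-6)
})

test_that("files missing required variables raise a format error naming them", {
  path <- withr::local_tempfile(fileext = ".nc")
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", c(0, 0.1))
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", c(0, 0.1))
  dtime <- ncdf4::ncdim_def("time", "s", 0)
  vu <- ncdf4::ncvar_def("u", "m s-1", list(dlon, dlat, dtime), 1e20)
  nc <- ncdf4::nc_create(path, list(vu))
  ncdf4::ncvar_put(nc, vu, array(0, c(2, 2, 1)))
  ncdf4::nc_close(nc)
  expect_error(read_velocity(path), "'v'")
  expect_error(read_velocity("does-not-exist.nc"), "no such file")
})
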