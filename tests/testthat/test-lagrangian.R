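# Release schedules, interpolation, RK4 integration, the vertical random
# walk, and advection bookkeeping.

test_that("the default schedule emits 1000/day for 5 days = 5000 particles", {
  site <- site_region("AC", "circle", center = c(-42.3, -23.2), radius_km = 4)
  rel <- make_release(release_schedule("AC"), site, seed = 1)
  expect_equal(nrow(rel), 5000)
  expect_equal(unname(table(rel$release_time)), rep(1000L, 5),
               ignore_attr = TRUE)
  expect_true(all(point_in_region(rel$lon, rel$lat, site)))
  expect_true(all(rel$z == 0))
  # empty schedule
  expect_equal(nrow(make_release(release_schedule("AC", n_days = 0), site)), 0)
  # determinism
  rel2 <- make_release(release_schedule("AC"), site, seed = 1)
  expect_identical(rel, rel2)
})

test_that("release positions are uniform over the site (quadrant balance)", {
  site <- site_region("S", "circle", center = c(-42, -23), radius_km = 10)
  rel <- make_release(release_schedule("S", 2000, 1), site, seed = 3)
  qx <- rel$lon > -42; qy <- rel$lat > -23
  counts <- table(qx, qy)
  expect_true(all(stats::chisq.test(counts)$p.value > 1e-4))
})

test_that("interpolation is exact for constant and bilinear fields", {
  g <- ocean_grid(0.05)
  f <- uniform_field(g, 0.17, -0.05)
  got <- interpolate_velocity(f, c(-42.5, -42.93), c(-23.2, -22.51), 0, 1000)
  expect_equal(got$u, c(0.17, 0.17))
  expect_equal(got$v, c(-0.05, -0.05))

  # field linear in lon and lat is reproduced exactly at random points
  a <- 0.2; b <- -0.5; cc <- 0.3
  nlon <- length(g$lon); nlat <- length(g$lat)
  lin <- outer(g$lon + 43, rep(1, nlat)) * b +
    outer(rep(1, nlon), g$lat + 23) * cc + a
  fl <- velocity_field(g, lin, lin * 0)
  set.seed(11)
  ql <- runif(100, min(g$lon), max(g$lon))
  qa <- runif(100, min(g$lat), max(g$lat))
  got <- interpolate_velocity(fl, ql, qa, 0, 0)
  expect_equal(got$u, a + b * (ql + 43) + cc * (qa + 23), tolerance = 1e-12)
})

test_that("interpolation is linear in time and errors outside the domain", {
  g <- ocean_grid(0.05)
  g$time <- c(0, 21600)
  nlon <- length(g$lon); nlat <- length(g$lat)
  u <- array(0, c(nlon, nlat, 1, 2)); u[, , , 2] <- 0.2
  f <- velocity_field(g, u, u * 0)
  expect_equal(interpolate_velocity(f, -42.5, -23, 0, 10800)$u, 0.1)
  expect_error(interpolate_velocity(f, -40, -23, 0, 0), "outside grid")
  expect_error(interpolate_velocity(f, -42.5, -23, 0, 1e6), "time span")
})

test_that("land cells contribute zero velocity with renormalized weights", {
  g <- make_grid(c(0, 0.2), c(0, 0.2), 0.1)
  g$mask[, 3] <- FALSE  # northern row is land
  nlon <- length(g$lon); nlat <- length(g$lat)
  f <- velocity_field(g, matrix(0.3, nlon, nlat), matrix(0, nlon, nlat))
  # midway between an ocean row and the land row: pure ocean value survives
  got <- interpolate_velocity(f, 0.1, 0.15, 0, 0)
  expect_equal(got$u, 0.3)
})

test_that("a uniform current displaces particles by U*t", {
  g <- ocean_grid(0.05)
  f <- uniform_field(g, 0.1, 0)
  p <- list(lon = -42.9, lat = -23.1, z = 0)
  t <- 0
  for (i in 1:24) { p <- step_rk4(p, f, dt = 3600, t = t); t <- t + 3600 }
  dist <- metric_dist(-42.9, -23.1, p$lon, p$lat, -23.1)
  expect_equal(dist, 8640, tolerance = 1e-3)
  expect_equal(p$lat, -23.1, tolerance = 1e-9)
  # zero field: no motion
  f0 <- uniform_field(g, 0, 0)
  q <- step_rk4(list(lon = -42.5, lat = -23, z = 0), f0, dt = 3600)
  expect_equal(q$lon, -42.5)
  expect_equal(q$lat, -23)
})

test_that("RK4 closes a Rankine-core orbit and converges at fourth order", {
  omega <- 1e-3  # fast rotation so truncation dominates round-off
  lon0 <- -42.5; lat0 <- -23
  sampler <- rotation_sampler(omega, lon0, lat0)
  p0 <- list(lon = lon0 + 0.02, lat = lat0, z = 0)
  r <- metric_dist(lon0, lat0, p0$lon, p0$lat, lat0)
  period <- 2 * pi / omega
  closure <- function(dt) {
    n <- ceiling(period / dt)
    p <- p0
    for (i in seq_len(n)) p <- step_rk4(p, sampler, dt = period / n, t = 0)
    metric_dist(p0$lon, p0$lat, p$lon, p$lat, lat0)
  }
  errs <- vapply(c(240, 120, 60), closure, 0)
  expect_lt(errs[3] / r, 0.01)           # < 1% closure at dt = 60 s
  expect_gt(errs[1] / errs[2], 8)        # ~ dt^4 (16x per halving)
  expect_lt(errs[1] / errs[2], 32)
  expect_gt(errs[2] / errs[3], 8)
  expect_lt(errs[2] / errs[3], 32)

  # same closure property on a gridded Rankine eddy at the default dt
  g <- make_grid(c(-43, -42), c(-23.5, -22.5), 0.005)
  f <- eddy_field(g, c(lon0, lat0), core_radius_km = 8, peak_speed = 0.4,
                  polarity = "cyclonic")
  om <- 0.4 / 8000
  per <- 2 * pi / om
  n <- ceiling(per / 60)
  p <- p0
  for (i in seq_len(n)) p <- step_rk4(p, f, dt = per / n, t = 0)
  expect_lt(metric_dist(p0$lon, p0$lat, p$lon, p$lat, lat0) / r, 0.01)
})

test_that("the vertical random walk has the diffusive variance 2*kappa*t", {
  rw <- random_walk_config(kappa_v = 1e-4, seed = 9, dt = 100)
  set.seed(9)
  z <- rep(-50, 10000)
  for (i in 1:100) z <- z + vertical_random_walk(10000, rw)
  expect_equal(stats::var(z), 2 * 1e-4 * 1e4, tolerance = 0.05)
  # kappa = 0 never moves, and equal seeds give identical draws
  expect_identical(vertical_random_walk(100, random_walk_config(0)),
                   numeric(100))
  set.seed(1); a <- vertical_random_walk(50, rw)
  set.seed(1); b <- vertical_random_walk(50, rw)
  expect_identical(a, b)
})

test_that("advection conserves particle accounting at every sample", {
  g <- ocean_grid(0.05, coast = -22.8)
  cfg <- scenario_config("northeast", duration_days = 5)
  f <- build_scenario(cfg, g)
  site <- site_region("A", "circle", center = c(-42.4, -23.1), radius_km = 3)
  rel <- make_release(release_schedule("A", 40, 5), site, seed = 2)
  traj <- advect(rel, f, duration = 5 * 86400, dt = 600,
                 rw = random_walk_config(0, seed = 5))
  sc <- status_counts(traj)
  expect_true(all(sc$unreleased + sc$active + sc$beached + sc$exited ==
                  sc$total))
  expect_equal(length(traj$times), 5 * 4 + 1)
  # staggered releases: 40 active at t0, all 200 released by day 4
  expect_equal(sc$unreleased[1], 160)
  expect_equal(sc$unreleased[4 * 4 + 1], 0)
  # no-releases edge case keeps the time axis
  empty <- advect(rel[0, ], f, duration = 5 * 86400, dt = 600)
  expect_equal(dim(empty$lon), c(0L, 21L))
})

test_that("onshore flow beaches every particle and freezes it", {
  g <- make_grid(c(-43, -42.5), c(-23.3, -22.9), 0.02, coastline_spec = -23.0)
  f <- uniform_field(g, 0, 0.2)  # northward, toward the coast
  site <- site_region("A", "circle", center = c(-42.75, -23.2), radius_km = 3)
  rel <- make_release(release_schedule("A", 50, 1), site, seed = 4)
  traj <- advect(rel, f, duration = 2 * 86400, dt = 300,
                 rw = random_walk_config(0))
  fin <- traj$status[, ncol(traj$status)]
  expect_true(all(fin == 2L))
  # beaching time consistent with U*t to the coast: ~0.2 deg / 0.2 m/s
  dist_m <- (-23.0 - rel$lat) * pi / 180 * R_E
  t_expect <- dist_m / 0.2
  t_beach <- apply(traj$status, 1, function(s) traj$times[match(2L, s)])
  expect_lt(max(abs(t_beach - t_expect)), 21600 + 2 * 300)
  # frozen: position constant after beaching
  ib <- which.max(traj$status[1, ] == 2L)
  expect_equal(traj$lat[1, ib], traj$lat[1, ncol(traj$lat)])
})

test_that("runs are bit-identical under equal seeds and differ under new ones", {
  g <- ocean_grid(0.05, z_levels = c(-40, 0))
  f <- uniform_field(g, 0.05, 0)
  site <- site_region("A", "circle", center = c(-42.6, -23.1), radius_km = 3)
  rel <- make_release(release_schedule("A", 30, 2), site, seed = 6)
  run <- function(walk_seed, kappa)
    advect(rel, f, duration = 2 * 86400, dt = 600,
           rw = random_walk_config(kappa, seed = walk_seed))
  a <- run(7, 1e-4); b <- run(7, 1e-4); c <- run(8, 1e-4)
  expect_identical(a, b)
  expect_identical(a$lon, c$lon)     # horizontal motion unaffected by walk
  expect_false(identical(a$z, c$z))  # vertical motion is
  # with kappa = 0 and a vertically uniform field, z never changes
  g2 <- ocean_grid(0.05); g2$z <- c(-40, 0)
  f2 <- uniform_field(g2, 0.05, 0)
  rel2 <- rel; rel2$z <- -10
  d <- advect(rel2, f2, duration = 2 * 86400, dt = 600,
              rw = random_walk_config(0))
  expect_true(all(d$z[d$status == 1L] == -10))
})

test_that("per-step displacement never exceeds max speed times dt", {
  g <- ocean_grid(0.02, coast = -22.8)
  cfg <- scenario_config("northeast", duration_days = 2,
                         filament_specs = list(list(
                           origin = c(-42.5, -22.8), length_km = 40,
                           width_km = 5, peak_speed = 0.4,
                           polarity = "cyclonic")))
  f <- build_scenario(cfg, g)
  site <- site_region("A", "circle", center = c(-42.5, -23.0), radius_km = 4)
  rel <- make_release(release_schedule("A", 50, 1), site, seed = 8)
  dt_out <- 3600
  traj <- advect(rel, f, duration = 2 * 86400, dt = 600,
                 output_cadence = dt_out, rw = random_walk_config(0))
  vmax <- max(sqrt(f$u^2 + f$v^2), na.rm = TRUE)
  ds <- ncol(traj$lon)
  for (k in 2:ds) {
    act <- traj$status[, k] == 1L & traj$status[, k - 1] == 1L
    if (!any(act)) next
    d <- metric_dist(traj$lon[act, k - 1], traj$lat[act, k - 1],
                     traj$lon[act, k], traj$lat[act, k], -23)
    expect_true(all(d <= vmax * dt_out * 1.01))
  }
  expect_error(advect(rel, f, duration = 86400, dt = 700), "divide")
})
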