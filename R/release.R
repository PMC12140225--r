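# Release schedules and initial particle batches.

#' Per-site larval release schedule
#'
#' The default emission plan follows the dispersal experiments this package
#' emulates: 1,000 particles per day for 5 days (5,000 per site), released
#' at the surface.
#'
#' @param site name of the source `site_region`.
#' @param particles_per_day particles emitted each release day (>= 0).
#' @param n_days number of consecutive release days (>= 0).
#' @param release_depth release depth in metres (`<= 0`; default 0, surface).
#' @param start_time epoch seconds of the first release (default 0).
#' @return object of class `release_schedule`.
#' @export
release_schedule <- function(site, particles_per_day = 1000, n_days = 5,
                             release_depth = 0, start_time = 0) {
  if (particles_per_day < 0 || n_days < 0)
    stop("particles_per_day and n_days must be >= 0", call. = FALSE)
  if (release_depth > 0) stop("release_depth must be <= 0", call. = FALSE)
  structure(list(site = site,
                 particles_per_day = as.integer(particles_per_day),
                 n_days = as.integer(n_days),
                 release_depth = release_depth,
                 start_time = start_time),
            class = "release_schedule")
}

#' Draw the initial particle batch for one schedule
#'
#' Release positions are sampled uniformly (by rejection in the bounding
#' box) within the site region at `release_depth`; release times are
#' staggered daily from `start_time`. Deterministic given `seed`.
#'
#' @param schedule a `release_schedule`.
#' @param site_geometry the `site_region` to seed (its `name` should match
#'   `schedule$site`).
#' @param seed integer RNG seed.
#' @return data.frame with columns `id`, `source`, `release_time`, `lon`,
#'   `lat`, `z` — one row per particle,
#'   `particles_per_day * n_days` rows in total.
#' @export
make_release <- function(schedule, site_geometry, seed = 1L) {
  stopifnot(inherits(schedule, "release_schedule"),
            inherits(site_geometry, "site_region"))
  total <- schedule$particles_per_day * schedule$n_days
  if (total == 0)
    return(data.frame(id = integer(), source = character(),
                      release_time = numeric(), lon = numeric(),
                      lat = numeric(), z = numeric()))
  rs <- .local_rng(seed)
  on.exit(rs$restore(), add = TRUE)
  pts <- .sample_region(site_geometry, total)
  day <- rep(seq_len(schedule$n_days) - 1L, each = schedule$particles_per_day)
  data.frame(id = seq_len(total),
             source = schedule$site,
             release_time = schedule$start_time + day * 86400,
             lon = pts$lon, lat = pts$lat,
             z = schedule$release_depth)
}

# Uniform points inside a region by rejection sampling in its bounding box.
.sample_region <- function(region, n) {
  bb <- region_bbox(region)
  if (diff(bb$lon) <= 0 && diff(bb$lat) <= 0)
    stop("site region '", region$name, "' has zero area", call. = FALSE)
  lon <- numeric(0); lat <- numeric(0)
  guard <- 0
  while (length(lon) < n) {
    m <- max(2L * (n - length(lon)), 64L)
    cl <- stats::runif(m, bb$lon[1], bb$lon[2])
    ca <- stats::runif(m, bb$lat[1], bb$lat[2])
    keep <- point_in_region(cl, ca, region)
    lon <- c(lon, cl[keep]); lat <- c(lat, ca[keep])
    guard <- guard + 1
    if (guard > 1000)
      stop("site region '", region$name, "' has zero area", call. = FALSE)
  }
  list(lon = lon[seq_len(n)], lat = lat[seq_len(n)])
}

#' Combine several per-site batches into one release table
#' @param ... data.frames from [make_release()].
#' @return a single data.frame with globally unique ids.
#' @export
combine_releases <- function(...) {
  out <- do.call(rbind, list(...))
  out$id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
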