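# End-to-end scenario driver: config -> fields -> diagnostics -> advection
# -> connectivity / density statistics -> files on disk.

.cfg_need <- function(config, field) {
  if (is.null(config[[field]]))
    stop("configuration error: missing block '", field, "'", call. = FALSE)
  config[[field]]
}

# Turn the YAML `sites` block into site_region objects.
.sites_from_config <- function(sites_cfg) {
  out <- list()
  for (s in sites_cfg) {
    if (is.null(s$name)) stop("configuration error: site without 'name'", call. = FALSE)
    kind <- s$kind %||% "circle"
    out[[s$name]] <- if (kind == "circle")
      site_region(s$name, "circle", center = c(s$lon, s$lat),
                  radius_km = s$radius_km, role = s$role %||% "both")
    else
      site_region(s$name, "polygon",
                  vertices = do.call(rbind, lapply(s$vertices, unlist)),
                  role = s$role %||% "both")
  }
  out
}

#' Load and validate a scenario configuration file
#'
#' @param config_path path to a YAML configuration (see the bundled demo
#'   configs under `system.file("extdata", package = "larvadrift")`).
#' @return the parsed configuration list.
#' @export
load_config <- function(config_path) {
  if (!file.exists(config_path))
    stop("no such config file: ", config_path, call. = FALSE)
  cfg <- yaml::read_yaml(config_path)
  for (block in c("grid", "scenario", "sites", "schedule"))
    .cfg_need(cfg, block)
  cfg
}

#' Run a full dispersal scenario from a configuration file
#'
#' Builds the synthetic velocity field (or reads one from
#' `grid$velocity_file`), computes time-mean diagnostics, releases and
#' advects particles, and writes the output bundle: velocity, diagnostics,
#' trajectory and density-plume NetCDF, connectivity CSV/JSON, and a
#' run-summary JSON recording seeds and counts.
#'
#' @param config_path path to a YAML configuration, or an already-parsed
#'   configuration list.
#' @param seed optional integer overriding every seed in the config (the
#'   release and walk seeds are derived from it).
#' @param out_dir optional output directory overriding `output$dir`.
#' @return (invisibly) list with `field`, `diagnostics`, `trajectories`,
#'   `connectivity`, `plume`, `final_population`, `summary`.
#' @export
run_scenario <- function(config_path, seed = NULL, out_dir = NULL) {
  cfg <- if (is.character(config_path)) load_config(config_path) else config_path
  for (block in c("grid", "scenario", "sites", "schedule"))
    .cfg_need(cfg, block)

  gc <- cfg$grid
  grid <- make_grid(unlist(gc$lon_range), unlist(gc$lat_range),
                    gc$spacing_deg,
                    z_levels = unlist(gc$z_levels %||% 0),
                    coastline_spec = gc$coast_lat)

  sc <- cfg$scenario
  seeds <- list(scenario = sc$seed %||% 1L,
                release = cfg$seeds$release %||% 101L,
                walk = cfg$seeds$walk %||% 202L)
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    seeds <- list(scenario = seed, release = seed + 1L, walk = seed + 2L)
  }

  field <- if (!is.null(gc$velocity_file)) {
    read_velocity(gc$velocity_file)
  } else {
    config <- scenario_config(
      name = sc$name %||% "northeast",
      duration_days = sc$duration_days %||% 20,
      cadence_hours = sc$cadence_hours %||% 6,
      jet_speed = sc$jet_speed %||% 0.3,
      jet_width_km = sc$jet_width_km %||% 20,
      jet_offshore_km = sc$jet_offshore_km %||% 25,
      coast_lat = gc$coast_lat,
      filament_specs = lapply(sc$filaments, function(f) {
        f$origin <- unlist(f$origin); f
      }),
      eddy_specs = lapply(sc$eddies, function(e) {
        e$center <- unlist(e$center); e
      }),
      reversal_day = sc$reversal_day,
      n_random_filaments = sc$n_random_filaments %||% 0,
      seed = seeds$scenario)
    build_scenario(config, grid)
  }

  sites <- .sites_from_config(cfg$sites)
  roles <- vapply(sites, `[[`, "", "role")
  sources <- sites[roles %in% c("source", "both")]
  if (length(sources) == 0)
    stop("configuration error: 'sites' defines no source region", call. = FALSE)

  sch <- cfg$schedule
  batches <- lapply(seq_along(sources), function(i) {
    make_release(release_schedule(names(sources)[i],
                                  sch$particles_per_day %||% 1000,
                                  sch$n_days %||% 5,
                                  sch$release_depth %||% 0),
                 sources[[i]], seed = seeds$release + i)
  })
  releases <- do.call(combine_releases, batches)

  phys <- cfg$physics %||% list()
  duration <- (sc$duration_days %||% 20) * 86400
  traj <- advect(releases, field,
                 duration = duration,
                 dt = phys$dt_seconds %||% 60,
                 output_cadence = (sc$cadence_hours %||% 6) * 3600,
                 rw = random_walk_config(kappa_v = phys$kappa_v %||% 1e-5,
                                         seed = seeds$walk))

  diag <- diagnose_slice(time_mean_slice(field))
  cm <- connectivity_matrix(traj, sources, sites)
  plume <- density_plume(traj, list(lon_range = range(grid$lon),
                                    lat_range = range(grid$lat),
                                    bin_deg = gc$plume_bin_deg %||% (5 * grid$dlon)))
  pops <- final_population(traj, sites)

  counts <- status_counts(traj)
  summary <- list(scenario = sc$name %||% "northeast",
                  seeds = seeds,
                  n_particles = nrow(releases),
                  n_samples = length(traj$times),
                  final_status = as.list(counts[nrow(counts),
                                                c("active", "beached", "exited")]),
                  package_version = as.character(utils::packageVersion("larvadrift")))

  out_dir <- out_dir %||% cfg$output$dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(out_dir, f)
    write_velocity(field, p("velocity.nc"))
    write_diagnostics(diag, p("diagnostics.nc"))
    write_trajectories(traj, p("trajectories.nc"))
    write_connectivity_csv(cm, p("connectivity.csv"))
    writeLines(connectivity_json(cm), p("connectivity.json"))
    write_density_nc(plume, p("density_plume.nc"))
    jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(list(field = field, diagnostics = diag, trajectories = traj,
                 connectivity = cm, plume = plume, final_population = pops,
                 summary = summary))
}
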