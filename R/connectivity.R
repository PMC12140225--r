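# Connectivity matrices, integrated density plumes and final populations.

#' Unidirectional source-to-destination connectivity matrix
#'
#' The off-diagonal entry (S, D) is the fraction of particles released at
#' source S whose sampled position lies inside destination D at any output
#' time in the window; each particle counts at most once per destination,
#' and beached or exited particles are evaluated at their frozen positions.
#' The diagonal entry (S, S) is retention: the fraction of S's particles
#' inside S at the final sample (the any-time rule would trivially be 1).
#' Connectivity is unidirectional: only emission regions appear as rows.
#'
#' @param traj a `trajectory_set`.
#' @param sources list of `site_region` objects covering every source name
#'   appearing in the trajectory release table.
#' @param destinations list of `site_region` objects to score arrivals in.
#' @return object of class `connectivity_matrix`: list with `values`
#'   (fractions, rows = sources, cols = destinations), `counts` (integer
#'   numerators) and `denominator` (particles emitted per source).
#' @export
connectivity_matrix <- function(traj, sources, destinations) {
  stopifnot(inherits(traj, "trajectory_set"))
  src_names <- vapply(sources, `[[`, "", "name")
  dst_names <- vapply(destinations, `[[`, "", "name")
  unknown <- setdiff(unique(traj$releases$source), src_names)
  if (length(unknown))
    stop("trajectory sources not among the given source regions: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  n <- nrow(traj$lon); ns <- ncol(traj$lon)
  counts <- matrix(0L, length(sources), length(destinations),
                   dimnames = list(src_names, dst_names))
  denom <- vapply(src_names, function(s) sum(traj$releases$source == s), 0L)

  # per-destination any-time membership (particle-level), and final-sample
  # membership for the retention diagonal
  lon_fin <- traj$lon[, ns]; lat_fin <- traj$lat[, ns]
  for (jd in seq_along(destinations)) {
    D <- destinations[[jd]]
    inside <- matrix(point_in_region(as.vector(traj$lon), as.vector(traj$lat), D),
                     n, ns)
    ever <- rowSums(inside) > 0
    fin <- point_in_region(lon_fin, lat_fin, D)
    for (is in seq_along(sources)) {
      sel <- traj$releases$source == src_names[is]
      counts[is, jd] <- if (src_names[is] == dst_names[jd])
        sum(fin & sel) else sum(ever & sel)
    }
  }
  values <- sweep(counts, 1, pmax(denom, 1L), "/")
  values[denom == 0, ] <- NA_real_
  structure(list(values = values, counts = counts, denominator = denom,
                 sources = src_names, destinations = dst_names),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, digits = 2, ...) {
  cat("<connectivity_matrix> fraction of emitted particles reaching each destination\n")
  cat("(diagonal entries are final-time retention)\n")
  print(round(x$values, digits))
  invisible(x)
}

#' Write a connectivity matrix to CSV
#'
#' Values are written with two decimals (matching the precision connectivity
#' tables are conventionally reported at); use [connectivity_json()] for
#' full precision.
#'
#' @param cm a `connectivity_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_connectivity_csv <- function(cm, path) {
  m <- format(round(cm$values, 2), nsmall = 2)
  df <- data.frame(source = rownames(cm$values), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Full-precision JSON form of a connectivity matrix
#' @param cm a `connectivity_matrix`.
#' @return a JSON string.
#' @export
connectivity_json <- function(cm) {
  jsonlite::toJSON(list(sources = cm$sources, destinations = cm$destinations,
                        values = cm$values, counts = cm$counts,
                        denominator = cm$denominator),
                   auto_unbox = TRUE, digits = NA)
}

#' Integrated density plume of a trajectory set
#'
#' A 2-D lon/lat histogram of particle positions accumulated over all output
#' times after release (frozen beached/exited positions keep accumulating,
#' mirroring settled larvae).
#'
#' @param traj a `trajectory_set`.
#' @param bin_spec list with `lon_breaks` and `lat_breaks` (ascending break
#'   vectors), or `lon_range`, `lat_range` and `bin_deg` (bin width in
#'   degrees).
#' @param normalize if `TRUE`, counts are divided by the total number of
#'   in-domain particle-samples.
#' @return object of class `density_plume`: list with `lon_breaks`,
#'   `lat_breaks`, `counts` matrix and `normalized` flag.
#' @export
density_plume <- function(traj, bin_spec, normalize = FALSE) {
  if (!is.null(bin_spec$lon_breaks)) {
    xb <- bin_spec$lon_breaks; yb <- bin_spec$lat_breaks
  } else {
    if (is.null(bin_spec$bin_deg) || bin_spec$bin_deg <= 0)
      stop("bin_spec needs breaks or a positive bin_deg", call. = FALSE)
    xb <- seq(bin_spec$lon_range[1], bin_spec$lon_range[2], by = bin_spec$bin_deg)
    yb <- seq(bin_spec$lat_range[1], bin_spec$lat_range[2], by = bin_spec$bin_deg)
  }
  if (any(diff(xb) <= 0) || any(diff(yb) <= 0))
    stop("bins must have positive width", call. = FALSE)
  lon <- as.vector(traj$lon); lat <- as.vector(traj$lat)
  rel <- as.vector(traj$status) != STATUS_UNRELEASED & is.finite(lon)
  lon <- lon[rel]; lat <- lat[rel]
  ix <- findInterval(lon, xb, rightmost.closed = TRUE)
  iy <- findInterval(lat, yb, rightmost.closed = TRUE)
  nx <- length(xb) - 1L; ny <- length(yb) - 1L
  ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
  counts <- matrix(tabulate((iy[ok] - 1L) * nx + ix[ok], nbins = nx * ny), nx, ny)
  if (normalize && sum(counts) > 0) counts <- counts / sum(counts)
  structure(list(lon_breaks = xb, lat_breaks = yb, counts = counts,
                 normalized = normalize),
            class = "density_plume")
}

#' @export
print.density_plume <- function(x, ...) {
  cat(sprintf("<density_plume> %d x %d bins, total %s %.6g\n",
              nrow(x$counts), ncol(x$counts),
              if (x$normalized) "mass" else "particle-samples", sum(x$counts)))
  invisible(x)
}

#' Write a density plume to NetCDF
#' @param plume a `density_plume`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_density_nc <- function(plume, path) {
  xc <- (plume$lon_breaks[-1] + utils::head(plume$lon_breaks, -1)) / 2
  yc <- (plume$lat_breaks[-1] + utils::head(plume$lat_breaks, -1)) / 2
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", xc)
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", yc)
  vc <- ncdf4::ncvar_def("density",
                         if (plume$normalized) "1" else "particle_samples",
                         list(dlon, dlat), prec = "double")
  nc <- ncdf4::nc_create(path, list(vc))
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, vc, plume$counts)
  invisible(path)
}

#' Final population per region
#'
#' Counts particles whose final sampled (or frozen terminal) position lies
#' inside each region; a particle may count in several overlapping regions.
#'
#' @param traj a `trajectory_set`.
#' @param regions list of `site_region` objects.
#' @return named integer vector of counts.
#' @export
final_population <- function(traj, regions) {
  ns <- ncol(traj$lon)
  lon <- traj$lon[, ns]; lat <- traj$lat[, ns]
  out <- vapply(regions, function(r) sum(point_in_region(lon, lat, r)), 0L)
  names(out) <- vapply(regions, `[[`, "", "name")
  out
}
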