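# Named circle / polygon site regions used as sources and destinations.

#' Define a named site region
#'
#' Circles are defined by a center and great-circle radius; polygons by a
#' vertex list in lon/lat. Regions serve as larval sources (release areas),
#' destinations (arrival areas such as offshore platform fields), or both.
#'
#' @param name unique region name (e.g. `"AC"`, `"P1"`).
#' @param kind `"circle"` or `"polygon"`.
#' @param center length-2 (lon, lat), circles only.
#' @param radius_km great-circle radius in km (> 0), circles only.
#' @param vertices two-column matrix / data.frame of (lon, lat), polygons
#'   only; at least 3 non-collinear vertices, closure optional.
#' @param role `"source"`, `"destination"` or `"both"`.
#' @return object of class `site_region`.
#' @export
site_region <- function(name, kind = c("circle", "polygon"), center = NULL,
                        radius_km = NULL, vertices = NULL,
                        role = c("both", "source", "destination")) {
  kind <- match.arg(kind)
  role <- match.arg(role)
  if (kind == "circle") {
    if (is.null(center) || length(center) != 2 || is.null(radius_km) ||
        radius_km <= 0)
      stop("circle regions need a (lon, lat) center and radius_km > 0",
           call. = FALSE)
    vertices <- NULL
  } else {
    vertices <- as.matrix(vertices)
    if (is.null(vertices) || ncol(vertices) != 2 || nrow(vertices) < 3)
      stop("polygon regions need >= 3 (lon, lat) vertices", call. = FALSE)
    # drop an explicitly closed last vertex
    if (all(vertices[1, ] == vertices[nrow(vertices), ]) && nrow(vertices) > 3)
      vertices <- vertices[-nrow(vertices), , drop = FALSE]
    a2 <- abs(sum(vertices[, 1] * c(vertices[-1, 2], vertices[1, 2])) -
              sum(vertices[, 2] * c(vertices[-1, 1], vertices[1, 1])))
    if (a2 == 0) stop("polygon vertices are collinear", call. = FALSE)
  }
  structure(list(name = name, kind = kind, center = center,
                 radius_km = radius_km, vertices = vertices, role = role),
            class = "site_region")
}

#' @export
print.site_region <- function(x, ...) {
  if (x$kind == "circle")
    cat(sprintf("<site_region> '%s': circle r=%g km at (%.3f, %.3f), role %s\n",
                x$name, x$radius_km, x$center[1], x$center[2], x$role))
  else
    cat(sprintf("<site_region> '%s': polygon with %d vertices, role %s\n",
                x$name, nrow(x$vertices), x$role))
  invisible(x)
}

#' Bounding box of a site region
#' @param region a `site_region`.
#' @return list with `lon`, `lat` length-2 ranges.
#' @export
region_bbox <- function(region) {
  if (region$kind == "circle") {
    dlat <- region$radius_km * 1000 / EARTH_RADIUS * 180 / pi
    dlon <- dlat / cos(.deg2rad(region$center[2]))
    list(lon = region$center[1] + c(-dlon, dlon),
         lat = region$center[2] + c(-dlat, dlat))
  } else {
    list(lon = range(region$vertices[, 1]), lat = range(region$vertices[, 2]))
  }
}

# Even-odd ray casting with points on an edge counted inside.
.point_in_polygon <- function(lon, lat, verts) {
  nv <- nrow(verts)
  inside <- rep(FALSE, length(lon))
  on_edge <- rep(FALSE, length(lon))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- verts[i, 1]; yi <- verts[i, 2]
    xj <- verts[j, 1]; yj <- verts[j, 2]
    # boundary: point within the segment's span and exactly on its line
    cross <- (xj - xi) * (lat - yi) - (yj - yi) * (lon - xi)
    within <- (lon >= pmin(xi, xj) - 1e-12) & (lon <= pmax(xi, xj) + 1e-12) &
              (lat >= pmin(yi, yj) - 1e-12) & (lat <= pmax(yi, yj) + 1e-12)
    on_edge <- on_edge | (abs(cross) < 1e-12 & within)
    crosses <- ((yi > lat) != (yj > lat)) &
      (lon < (xj - xi) * (lat - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Point-in-region membership test
#'
#' Circles use the haversine great-circle distance to the center; polygons
#' use even-odd ray casting in lon/lat with boundary points counted inside.
#' Vectorized over points.
#'
#' @param lon,lat query coordinates (degrees), equal length.
#' @param region a `site_region`.
#' @return logical vector.
#' @export
point_in_region <- function(lon, lat, region) {
  stopifnot(inherits(region, "site_region"))
  ok <- is.finite(lon) & is.finite(lat)
  out <- rep(FALSE, length(lon))
  if (!any(ok)) return(out)
  if (region$kind == "circle") {
    d <- geosphere::distHaversine(cbind(lon[ok], lat[ok]),
                                  region$center, r = EARTH_RADIUS)
    out[ok] <- d <= region$radius_km * 1000
  } else {
    out[ok] <- .point_in_polygon(lon[ok], lat[ok], region$vertices)
  }
  out
}

#' Read site regions from GeoJSON
#'
#' Accepts a FeatureCollection of polygons, plus a circle extension: a Point
#' feature with a `radius_km` property is read as a circle region. Feature
#' properties `name` and `role` map onto the region fields.
#'
#' @param path GeoJSON file path.
#' @return named list of `site_region` objects.
#' @export
read_sites_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection", call. = FALSE)
  out <- list()
  for (ft in gj$features) {
    props <- ft$properties
    nm <- props$name %||% stop("feature without a 'name' property", call. = FALSE)
    role <- props$role %||% "both"
    geom <- ft$geometry
    if (geom$type == "Point") {
      if (is.null(props$radius_km))
        stop("Point feature '", nm, "' needs a radius_km property", call. = FALSE)
      out[[nm]] <- site_region(nm, "circle",
                               center = as.numeric(unlist(geom$coordinates)),
                               radius_km = props$radius_km, role = role)
    } else if (geom$type == "Polygon") {
      ring <- geom$coordinates[[1]]
      verts <- do.call(rbind, lapply(ring, function(p) as.numeric(unlist(p))))
      out[[nm]] <- site_region(nm, "polygon", vertices = verts, role = role)
    } else {
      stop("unsupported geometry type '", geom$type, "' in feature '", nm, "'",
           call. = FALSE)
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
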