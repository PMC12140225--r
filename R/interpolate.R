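# Continuous, mask-aware sampling of gridded velocity fields.

# Sampler factory: returns a vectorized closure (lon, lat, z, t) -> list(u,
# v, w). Spatial interpolation is bilinear in (lon, lat) with land corners
# contributing zero velocity and weights renormalized over ocean corners
# only; linear in z when the field has more than one level; linear in time
# between slices. Time-slice vectors are cached so tight advection loops do
# not repeatedly copy array sections.
.make_sampler <- function(field) {
  g <- field$grid
  nlon <- length(g$lon); nlat <- length(g$lat); nz <- length(g$z)
  nt <- length(g$time)
  lon0 <- g$lon[1]; lat0 <- g$lat[1]
  dlon <- g$dlon; dlat <- g$dlat
  maskv <- as.vector(g$mask)
  has_w <- !is.null(field$w)
  cache <- new.env(parent = emptyenv())

  slice_vecs <- function(it) {
    key <- as.character(it)
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    sv <- list(u = as.vector(field$u[, , , it, drop = FALSE]),
               v = as.vector(field$v[, , , it, drop = FALSE]),
               w = if (has_w) as.vector(field$w[, , , it, drop = FALSE]) else NULL)
    # keep at most the two bracketing slices resident
    for (k in ls(cache)) if (abs(as.integer(k) - it) > 1) rm(list = k, envir = cache)
    cache[[key]] <- sv
    sv
  }

  # mask-aware bilinear (+ z-linear) evaluation on one time slice
  eval_slice <- function(sv, ix, iy, fx, fy, iz, fz) {
    i11 <- ix + (iy - 1L) * nlon
    i21 <- i11 + 1L
    i12 <- i11 + nlon
    i22 <- i12 + 1L
    w11 <- (1 - fx) * (1 - fy) * maskv[i11]
    w21 <- fx * (1 - fy) * maskv[i21]
    w12 <- (1 - fx) * fy * maskv[i12]
    w22 <- fx * fy * maskv[i22]
    denom <- w11 + w21 + w12 + w22
    safe <- ifelse(denom > 0, denom, 1)
    comb <- function(vec) {
      base <- (iz - 1L) * nlon * nlat
      lo <- (.z0(vec, i11 + base) * w11 + .z0(vec, i21 + base) * w21 +
             .z0(vec, i12 + base) * w12 + .z0(vec, i22 + base) * w22)
      if (nz > 1) {
        basep <- pmin(iz, nz - 1L) * nlon * nlat
        hi <- (.z0(vec, i11 + basep) * w11 + .z0(vec, i21 + basep) * w21 +
               .z0(vec, i12 + basep) * w12 + .z0(vec, i22 + basep) * w22)
        (lo * (1 - fz) + hi * fz) / safe * (denom > 0)
      } else lo / safe * (denom > 0)
    }
    list(u = comb(sv$u), v = comb(sv$v),
         w = if (has_w) comb(sv$w) else 0)
  }

  function(lon, lat, z, t) {
    # clamp for evaluation; out-of-domain policy belongs to the caller
    x <- (pmin(pmax(lon, lon0), g$lon[nlon]) - lon0) / dlon
    y <- (pmin(pmax(lat, lat0), g$lat[nlat]) - lat0) / dlat
    ix <- pmin(pmax(as.integer(floor(x)) + 1L, 1L), nlon - 1L)
    iy <- pmin(pmax(as.integer(floor(y)) + 1L, 1L), nlat - 1L)
    fx <- x - (ix - 1L); fy <- y - (iy - 1L)
    if (nz > 1) {
      zc <- pmin(pmax(z, g$z[1]), g$z[nz])
      iz <- pmin(pmax(findInterval(zc, g$z), 1L), nz - 1L)
      fz <- (zc - g$z[iz]) / (g$z[iz + 1L] - g$z[iz])
    } else { iz <- 1L; fz <- 0 }
    tt <- pmin(pmax(t, g$time[1]), g$time[nt])
    if (nt > 1) {
      it <- pmin(pmax(findInterval(tt, g$time), 1L), nt - 1L)
      it <- it[1]  # advection calls share a scalar t
      wt <- (tt - g$time[it]) / (g$time[it + 1L] - g$time[it])
      a <- eval_slice(slice_vecs(it), ix, iy, fx, fy, iz, fz)
      b <- eval_slice(slice_vecs(it + 1L), ix, iy, fx, fy, iz, fz)
      list(u = a$u * (1 - wt) + b$u * wt,
           v = a$v * (1 - wt) + b$v * wt,
           w = a$w * (1 - wt) + b$w * wt)
    } else {
      eval_slice(slice_vecs(1L), ix, iy, fx, fy, iz, fz)
    }
  }
}

.z0 <- function(vec, idx) {
  out <- vec[idx]
  out[is.na(out)] <- 0
  out
}

#' Interpolate velocity at arbitrary points and time
#'
#' Bilinear in (lon, lat) — trilinear when the field carries more than one
#' vertical level — and linear in time. Land cells contribute zero velocity
#' with interpolation weights renormalized over ocean cells only, so values
#' taper toward the coast without NaN propagation.
#'
#' @param field a `velocity_field`.
#' @param lon,lat,z query positions (vectors of equal length; degrees,
#'   degrees, metres `<= 0`).
#' @param t a single query time (seconds, within the field's time span).
#' @return list of numeric vectors `u`, `v`, `w` (m/s).
#' @export
interpolate_velocity <- function(field, lon, lat, z = 0, t = field$grid$time[1]) {
  stopifnot(inherits(field, "velocity_field"))
  g <- field$grid
  if (any(lon < min(g$lon) | lon > max(g$lon) |
          lat < min(g$lat) | lat > max(g$lat)))
    stop("query position outside grid bounds", call. = FALSE)
  if (t < min(g$time) || t > max(g$time))
    stop("query time outside the field's time span", call. = FALSE)
  n <- length(lon)
  .make_sampler(field)(lon, lat, rep_len(z, n), t)
}
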