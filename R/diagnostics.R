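# Submesoscale diagnostics: relative vorticity, Rossby number zeta/f,
# normalized strain rate alpha/|f|, and horizontal divergence, all with
# mask-aware central differences on the cell-centered grid.

#' Coriolis parameter model
#'
#' In `"varying"` mode `f(lat) = 2 omega sin(lat)`; `"f_plane"` fixes `f` at
#' `f0` everywhere (useful for analytic tests).
#'
#' @param mode `"varying"` or `"f_plane"`.
#' @param f0 plane value of f in 1/s (required for `"f_plane"`).
#' @param omega Earth rotation rate, 1/s.
#' @return object of class `coriolis_model`.
#' @export
coriolis_model <- function(mode = c("varying", "f_plane"), f0 = NULL,
                           omega = 7.2921e-5) {
  mode <- match.arg(mode)
  if (mode == "f_plane" && (is.null(f0) || f0 == 0))
    stop("f_plane mode requires a nonzero f0", call. = FALSE)
  structure(list(mode = mode, f0 = f0, omega = omega),
            class = "coriolis_model")
}

#' Coriolis parameter at given latitudes
#' @param model a `coriolis_model`.
#' @param lat latitude(s), degrees north.
#' @return f in 1/s, vectorized over `lat`.
#' @export
coriolis_f <- function(model = coriolis_model(), lat) {
  if (model$mode == "f_plane") rep(model$f0, length(lat))
  else 2 * model$omega * sin(.deg2rad(lat))
}

# Central x/y derivatives of a (nlon, nlat) matrix with spherical metric
# factors. Cells whose 4-point stencil touches land or the boundary are NA.
# Returns list(ddx, ddy) in units of field / m.
.central_derivs <- function(fld, grid) {
  nlon <- length(grid$lon); nlat <- length(grid$lat)
  if (nlon < 3 || nlat < 3)
    stop("diagnostics need at least 3 points per spatial axis", call. = FALSE)
  dlam <- .deg2rad(grid$dlon)
  dphi <- .deg2rad(grid$dlat)
  fld[!grid$mask] <- NA_real_
  ddx <- matrix(NA_real_, nlon, nlat)
  ddy <- matrix(NA_real_, nlon, nlat)
  ii <- 2:(nlon - 1); jj <- 2:(nlat - 1)
  dxm <- 2 * EARTH_RADIUS * dlam * cos(.deg2rad(grid$lat))  # per latitude
  ddx[ii, jj] <- (fld[ii + 1, jj] - fld[ii - 1, jj]) /
    rep(dxm[jj], each = length(ii))
  ddy[ii, jj] <- (fld[ii, jj + 1] - fld[ii, jj - 1]) / (2 * EARTH_RADIUS * dphi)
  list(ddx = ddx, ddy = ddy)
}

.as_slice <- function(x) {
  if (inherits(x, "velocity_field")) field_slice(x) else x
}

#' Relative vorticity of a velocity slice
#'
#' `zeta = dv/dx - du/dy` by central differences in the grid interior, with
#' metric factors `dx = R cos(lat) dlambda`, `dy = R dphi`. Cells whose
#' stencil touches land or the domain boundary are `NA` (undefined) rather
#' than one-sided-differenced, to avoid spurious coastal extrema.
#'
#' @param slice a `velocity_slice` (or a `velocity_field`, whose first
#'   time/z slice is used).
#' @return matrix `(nlon, nlat)` of zeta in 1/s.
#' @export
relative_vorticity <- function(slice) {
  slice <- .as_slice(slice)
  du <- .central_derivs(slice$u, slice$grid)
  dv <- .central_derivs(slice$v, slice$grid)
  dv$ddx - du$ddy
}

#' Rossby number zeta / f
#'
#' Pointwise normalization of relative vorticity by the planetary vorticity
#' at each cell's latitude. Sign convention is preserved: in the southern
#' hemisphere `f < 0` and cyclonic features yield `Ro > 0`.
#'
#' @param zeta matrix of relative vorticity (1/s) as returned by
#'   [relative_vorticity()].
#' @param coriolis a `coriolis_model`.
#' @param grid the `vf_grid` the vorticity lives on.
#' @return matrix of dimensionless zeta/f.
#' @export
rossby_number <- function(zeta, coriolis = coriolis_model(), grid) {
  f <- coriolis_f(coriolis, grid$lat)
  if (any(abs(f) < 1e-12))
    stop("f vanishes at an evaluated latitude; Rossby number undefined",
         call. = FALSE)
  sweep(zeta, 2, f, "/")
}

#' Horizontal strain rate and its Coriolis normalization
#'
#' `alpha = sqrt((du/dx - dv/dy)^2 + (dv/dx + du/dy)^2)`, the magnitude of
#' the horizontal deformation combining normal and shear strain; regions of
#' high strain accumulate Lagrangian material. The normalized form divides
#' by `|f|`.
#'
#' @inheritParams relative_vorticity
#' @param coriolis a `coriolis_model`.
#' @return list with `alpha` (1/s) and `alpha_norm` (dimensionless alpha/|f|),
#'   both `(nlon, nlat)` matrices.
#' @export
strain_rate <- function(slice, coriolis = coriolis_model()) {
  slice <- .as_slice(slice)
  du <- .central_derivs(slice$u, slice$grid)
  dv <- .central_derivs(slice$v, slice$grid)
  alpha <- sqrt((du$ddx - dv$ddy)^2 + (dv$ddx + du$ddy)^2)
  f <- coriolis_f(coriolis, slice$grid$lat)
  if (any(abs(f) < 1e-12))
    stop("f vanishes at an evaluated latitude; normalization undefined",
         call. = FALSE)
  list(alpha = alpha, alpha_norm = sweep(alpha, 2, abs(f), "/"))
}

#' Horizontal divergence of a velocity slice (spherical flux form)
#'
#' `div = (1/(R cos phi)) [du/dlambda + d(v cos phi)/dphi]`, central
#' differences. Streamfunction-derived synthetic fields are analytically
#' divergence-free in this form, so the discrete value converges to zero at
#' second order in grid spacing.
#'
#' @inheritParams relative_vorticity
#' @return matrix `(nlon, nlat)` of divergence in 1/s.
#' @export
divergence <- function(slice) {
  slice <- .as_slice(slice)
  g <- slice$grid
  du <- .central_derivs(slice$u, g)
  vcos <- sweep(slice$v, 2, cos(.deg2rad(g$lat)), "*")
  dvc <- .central_derivs(vcos, g)
  # d(v cos)/dy / cos = (1/(R cos)) d(v cos)/dphi
  sweep(dvc$ddy, 2, cos(.deg2rad(g$lat)), "/") + du$ddx
}

#' Full diagnostic bundle on a velocity slice
#'
#' @inheritParams strain_rate
#' @return object of class `diagnostic_field`: list with `grid`, `zeta`,
#'   `rossby`, `strain_norm` matrices.
#' @export
diagnose_slice <- function(slice, coriolis = coriolis_model()) {
  slice <- .as_slice(slice)
  zeta <- relative_vorticity(slice)
  st <- strain_rate(slice, coriolis)
  structure(list(grid = slice$grid, zeta = zeta,
                 rossby = rossby_number(zeta, coriolis, slice$grid),
                 strain_norm = st$alpha_norm),
            class = "diagnostic_field")
}

#' @export
print.diagnostic_field <- function(x, ...) {
  rng <- function(m) sprintf("[%.3g, %.3g]", min(m, na.rm = TRUE), max(m, na.rm = TRUE))
  cat("<diagnostic_field>\n")
  cat("  zeta        ", rng(x$zeta), "1/s\n")
  cat("  zeta/f      ", rng(x$rossby), "\n")
  cat("  alpha/|f|   ", rng(x$strain_norm), "\n")
  invisible(x)
}

#' Submesoscale feature mask
#'
#' Flags cells where the Rossby number magnitude reaches a threshold
#' (default 1, the conventional marker of submesoscale dynamics). Undefined
#' cells are `FALSE`.
#'
#' @param diag a `diagnostic_field` (or a bare Rossby-number matrix).
#' @param threshold positive |Ro| threshold, default 1.
#' @return logical matrix `(nlon, nlat)`.
#' @export
feature_mask <- function(diag, threshold = 1) {
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  ro <- if (inherits(diag, "diagnostic_field")) diag$rossby else diag
  m <- abs(ro) >= threshold
  m[is.na(m)] <- FALSE
  m
}

#' Write a diagnostic field to NetCDF
#'
#' Variables `zeta` (1/s), `rossby` (1) and `strain_norm` (1) on the shared
#' lon/lat axes.
#'
#' @param diag a `diagnostic_field`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_diagnostics <- function(diag, path) {
  g <- diag$grid
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", g$lon)
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", g$lat)
  fill <- 1e20
  vz <- ncdf4::ncvar_def("zeta", "s-1", list(dlon, dlat), fill, prec = "double")
  vr <- ncdf4::ncvar_def("rossby", "1", list(dlon, dlat), fill, prec = "double")
  vs <- ncdf4::ncvar_def("strain_norm", "1", list(dlon, dlat), fill, prec = "double")
  nc <- ncdf4::nc_create(path, list(vz, vr, vs))
  on.exit(ncdf4::nc_close(nc))
  put <- function(var, m) { m[is.na(m)] <- fill; ncdf4::ncvar_put(nc, var, m) }
  put(vz, diag$zeta); put(vr, diag$rossby); put(vs, diag$strain_norm)
  invisible(path)
}
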