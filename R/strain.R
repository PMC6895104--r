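# Velocity and infinitesimal strain derived from AR-DIC displacement fields.

# Central-difference gradient of grid matrix z along x (cols) or y (rows),
# one-sided at the borders. Coordinates are the grid center positions.
grid_gradient <- function(z, coords, along = c("x", "y")) {
  along <- match.arg(along)
  if (along == "y") return(t(grid_gradient(t(z), coords, "x")))
  n <- ncol(z)
  if (n < 3) stop_arg("grid too small for gradients (need >= 3 columns)")
  g <- z
  g[, 2:(n - 1)] <- (z[, 3:n] - z[, 1:(n - 2)]) /
    rep(coords[3:n] - coords[1:(n - 2)], each = nrow(z))
  g[, 1] <- (z[, 2] - z[, 1]) / (coords[2] - coords[1])
  g[, n] <- (z[, n] - z[, n - 1]) / (coords[n] - coords[n - 1])
  g
}

# Separable Gaussian smoothing on the grid (sigma in grid cells); used only
# when requested, since differentiation amplifies PIV noise.
smooth_grid <- function(z, sigma) {
  if (sigma <= 0) return(z)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_conv <- function(m) {
    n <- ncol(m)
    idx <- clamp_idx(outer(seq_len(n), (-half):half, "+"), n)
    out <- matrix(0, nrow(m), n)
    for (j in seq_along(k)) out <- out + k[j] * m[, idx[, j]]
    out
  }
  t(pad_conv(t(pad_conv(z))))
}

#' Velocity field between consecutive frames
#'
#' Backward difference of displacement: `v = (d_t - d_{t-1}) * pixel_size_um
#' / dt_s`, in um/s on the shared vector grid. When the reference frame
#' switched between the two frames, `d_{t-1}` is first re-expressed against
#' the new reference by subtracting the new reference's own displacement
#' (measured against the old reference), so the difference is taken in one
#' frame of reference. Switch frames are rest states, so this correction is
#' small by construction.
#'
#' @param field_t,field_prev displacement fields at frames t and t-1.
#' @param dt_s time between frames (s).
#' @param ref_change_field displacement field of the new reference frame
#'   measured against the old reference, required when the two fields have
#'   different `reference_index`.
#' @return list with `vx`, `vy`, `speed` (um/s matrices), `valid`, and the
#'   grid coordinates.
#' @export
velocity_field <- function(field_t, field_prev, dt_s, ref_change_field = NULL) {
  if (dt_s <= 0) stop_arg("'dt_s' must be > 0")
  if (!identical(field_t$grid_x, field_prev$grid_x) ||
      !identical(field_t$grid_y, field_prev$grid_y))
    stop_arg("fields are on different grids")
  pu <- field_prev$u; pv <- field_prev$v
  if (!identical(field_t$reference_index, field_prev$reference_index)) {
    if (is.null(ref_change_field))
      stop_arg("reference switched between frames; ref_change_field required")
    pu <- pu - ref_change_field$u
    pv <- pv - ref_change_field$v
  }
  px <- field_t$pixel_size_um
  if (!is.finite(px)) stop_arg("field has no pixel_size_um metadata")
  vx <- (field_t$u - pu) * px / dt_s
  vy <- (field_t$v - pv) * px / dt_s
  list(grid_x = field_t$grid_x, grid_y = field_t$grid_y,
       vx = vx, vy = vy, speed = sqrt(vx^2 + vy^2),
       valid = field_t$valid & field_prev$valid,
       frame_index = field_t$frame_index)
}

#' Velocity fields for every frame of an AR-DIC fit
#'
#' Applies [velocity_field()] across the fit, supplying the reference-switch
#' correction automatically from the fit's own fields.
#'
#' @param fit an [ardic()] object.
#' @return list of velocity fields (NULL for frames without a predecessor).
#' @export
velocity_fields <- function(fit) {
  stopifnot(inherits(fit, "ardic"))
  tr <- fit$trace
  dt <- 1 / fit$fps
  out <- vector("list", length(fit$fields))
  for (t in seq_along(fit$fields)) {
    ft <- fit$fields[[t]]; fp <- if (t > 1) fit$fields[[t - 1]] else NULL
    if (is.null(ft) || is.null(fp)) next
    rc <- NULL
    if (!identical(ft$reference_index, fp$reference_index))
      rc <- fit$fields[[ft$reference_index]]
    out[[t]] <- velocity_field(ft, fp, dt, rc)
  }
  out
}

#' Infinitesimal strain tensor field
#'
#' Engineering (infinitesimal) strain components from the displacement
#' gradients on the vector grid, by central differences (one-sided at the
#' borders): `exx = du/dx`, `eyy = dv/dy`, `exy = (du/dy + dv/dx) / 2`
#' (tensorial shear, i.e. half the engineering shear angle). Displacement
#' and grid coordinates are both in px, so the strains are dimensionless.
#' Positive values are tensile, negative compressive. Principal strains and
#' angle are attached via [principal_strains()].
#'
#' @param field a displacement field (>= 3x3 vectors).
#' @param smooth_sigma optional Gaussian pre-smoothing of u, v in grid cells
#'   (0 = off). Differentiation amplifies vector noise; one cell is a
#'   reasonable setting for noisy data.
#' @return Object of class `strain_field`: matrices `exx, eyy, exy, e1, e2,
#'   theta_p, valid` plus grid coordinates.
#' @export
strain_fields <- function(field, smooth_sigma = 0) {
  if (length(field$grid_x) < 3 || length(field$grid_y) < 3)
    stop_arg("grid too small for strain (need >= 3x3 vectors)")
  u <- smooth_grid(field$u, smooth_sigma)
  v <- smooth_grid(field$v, smooth_sigma)
  exx <- grid_gradient(u, field$grid_x, "x")
  eyy <- grid_gradient(v, field$grid_y, "y")
  exy <- 0.5 * (grid_gradient(u, field$grid_y, "y") +
                grid_gradient(v, field$grid_x, "x"))
  pr <- principal_strains(exx, eyy, exy)
  # a strain value is trustworthy only if its difference stencil was valid
  ok <- field$valid
  grow <- function(m) {
    ny <- nrow(m); nx <- ncol(m)
    m & m[clamp_idx(seq_len(ny) - 1, ny), ] & m[clamp_idx(seq_len(ny) + 1, ny), ] &
      m[, clamp_idx(seq_len(nx) - 1, nx)] & m[, clamp_idx(seq_len(nx) + 1, nx)]
  }
  structure(list(grid_x = field$grid_x, grid_y = field$grid_y,
                 exx = exx, eyy = eyy, exy = exy,
                 e1 = pr$e1, e2 = pr$e2, theta_p = pr$theta_p,
                 valid = grow(ok), frame_index = field$frame_index),
            class = "strain_field")
}

#' Principal strains of a 2-D strain tensor
#'
#' Closed-form eigenvalues of the symmetric tensor
#' `[[exx, exy], [exy, eyy]]`:
#' `e1,2 = (exx+eyy)/2 +- sqrt(((exx-eyy)/2)^2 + exy^2)` with `e1 >= e2`,
#' and principal angle `theta_p = atan2(2 exy, exx - eyy) / 2` (radians,
#' angle of the e1 direction from the x axis).
#'
#' @param exx,eyy,exy tensor components (scalars or equal-shape arrays).
#' @return list `e1`, `e2`, `theta_p` with the input shape.
#' @export
principal_strains <- function(exx, eyy, exy) {
  mean_ <- (exx + eyy) / 2
  rad <- sqrt(((exx - eyy) / 2)^2 + exy^2)
  list(e1 = mean_ + rad, e2 = mean_ - rad,
       theta_p = 0.5 * atan2(2 * exy, exx - eyy))
}
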