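#' Multi-pass PIV schedule
#'
#' Ordered pass parameters for windowed cross-correlation: interrogation
#' window edge, search radius, and vector grid spacing, all in px. Windows
#' must be non-increasing across passes and spacing must not exceed the
#' window. The default two-pass schedule (64/16/32 then 32/8/24) brackets a
#' final vector spacing of 24 px, the spacing used for the cardiomyocyte
#' analyses this package targets; all values are configurable.
#'
#' @param windows,searches,spacings equal-length numeric vectors, one entry
#'   per pass.
#' @return Object of class `piv_schedule` (a data.frame, one row per pass).
#' @export
piv_schedule <- function(windows = c(64, 32), searches = c(16, 8),
                         spacings = c(32, 24)) {
  n <- length(windows)
  if (n < 1) stop_arg("need at least one pass")
  if (length(searches) != n || length(spacings) != n)
    stop_arg("windows, searches, spacings must have one entry per pass")
  if (any(diff(windows) > 0)) stop_arg("window sizes must be non-increasing")
  if (any(spacings > windows)) stop_arg("spacing must not exceed the window")
  if (any(searches < 1)) stop_arg("search radius must be >= 1 px")
  structure(data.frame(window = windows, search = searches, spacing = spacings),
            class = c("piv_schedule", "data.frame"))
}

#' Vector grid for a pass
#'
#' Window centers on a regular grid such that every interrogation window lies
#' fully inside the image, with the leftover margin split evenly. For even
#' window sizes the geometric center falls on a half-integer pixel
#' coordinate; centers are reported exactly.
#'
#' @param dim_img `c(rows, cols)` image size.
#' @param window window edge (px).
#' @param spacing grid spacing (px).
#' @return `list(x =, y =)` center coordinates.
#' @export
piv_centers <- function(dim_img, window, spacing) {
  axis_centers <- function(n) {
    span <- n - window
    if (span < 0) stop_arg("window (", window, ") exceeds image size (", n, ")")
    k <- floor(span / spacing)
    off <- floor((span - k * spacing) / 2)
    (window + 1) / 2 + off + (0:k) * spacing
  }
  list(x = axis_centers(dim_img[2]), y = axis_centers(dim_img[1]))
}

# Displacement-field constructor (internal; fields come out of piv passes).
new_displacement_field <- function(grid_x, grid_y, u, v, quality, valid,
                                   frame_index = NA_integer_,
                                   reference_index = NA_integer_,
                                   spacing_px = NA_real_,
                                   pixel_size_um = NA_real_,
                                   replaced = NULL) {
  structure(list(grid_x = grid_x, grid_y = grid_y, u = u, v = v,
                 quality = quality, valid = valid,
                 replaced = replaced %||% matrix(FALSE, nrow(u), ncol(u)),
                 frame_index = frame_index, reference_index = reference_index,
                 spacing_px = spacing_px, pixel_size_um = pixel_size_um),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf("displacement_field: %d x %d vectors (spacing %g px), frame %s vs ref %s, %d valid\n",
              length(x$grid_y), length(x$grid_x), x$spacing_px,
              x$frame_index, x$reference_index, sum(x$valid)))
  invisible(x)
}

#' Displacement magnitude of a field
#'
#' @param field a displacement field.
#' @param units `"px"` or `"um"` (microns require `pixel_size_um` metadata).
#' @return Matrix of `sqrt(u^2 + v^2)` per grid point.
#' @export
field_magnitude <- function(field, units = c("px", "um")) {
  units <- match.arg(units)
  m <- sqrt(field$u^2 + field$v^2)
  if (units == "um") {
    if (!is.finite(field$pixel_size_um))
      stop_arg("field has no pixel_size_um metadata")
    m <- m * field$pixel_size_um
  }
  m
}

# Extract the window of edge w centered at (cx, cy); centers may be
# half-integer for even w. Returns NULL if out of bounds.
extract_window <- function(img, cx, cy, w) {
  x0 <- cx - (w - 1) / 2; y0 <- cy - (w - 1) / 2
  if (abs(x0 - round(x0)) > 1e-6 || abs(y0 - round(y0)) > 1e-6) return(NULL)
  x0 <- round(x0); y0 <- round(y0)
  if (x0 < 1 || y0 < 1 || x0 + w - 1 > ncol(img) || y0 + w - 1 > nrow(img))
    return(NULL)
  img[y0:(y0 + w - 1), x0:(x0 + w - 1)]
}

#' Cross-correlate one window pair
#'
#' Zero-mean normalized cross-correlation (ZNCC) of two equal-size patches:
#' the cross term comes from a zero-padded linear FFT correlation and the
#' per-lag overlap means/variances from integral images, so the correlation
#' coefficient is exact at every lag (no circular wrap-around or
#' shrinking-overlap bias). The peak search is restricted to lags within
#' `search_px`, and the peak is refined by a 3-point Gaussian fit per axis
#' (parabolic fallback when a neighbor sample is non-positive). The returned
#' `peak_ratio` is primary/secondary peak height, the secondary being the
#' highest value outside the 3x3 neighborhood of the primary.
#'
#' A (near-)constant patch yields `valid = FALSE` rather than an error, as
#' does a peak sitting on the search boundary.
#'
#' @param ref_patch,cur_patch equal-size numeric matrices.
#' @param search_px maximum lag magnitude searched per axis.
#' @return `list(du, dv, peak, peak_ratio, valid)`; `(du, dv)` is the
#'   displacement of `cur_patch` relative to `ref_patch` in px.
#' @export
correlate_window <- function(ref_patch, cur_patch, search_px = 8) {
  stopifnot(all(dim(ref_patch) == dim(cur_patch)))
  nr <- nrow(ref_patch); nc <- ncol(ref_patch)
  invalid <- list(du = NA_real_, dv = NA_real_, peak = NA_real_,
                  peak_ratio = NA_real_, valid = FALSE)
  if (stats::sd(ref_patch) < 1e-8 || stats::sd(cur_patch) < 1e-8)
    return(invalid)
  s <- min(search_px, floor(nr / 2) - 1, floor(nc / 2) - 1)
  if (s < 1) return(invalid)
  # true zero-mean NCC per lag: the raw cross term comes from a zero-padded
  # (linear) FFT correlation; per-lag means and variances over each overlap
  # rectangle come from integral images. Circular wrap-around or global
  # mean subtraction would bias sub-pixel peaks along the lag direction.
  a <- ref_patch; b <- cur_patch
  pr <- 2 * nr; pc <- 2 * nc
  pa <- matrix(0, pr, pc); pb <- matrix(0, pr, pc)
  pa[1:nr, 1:nc] <- a; pb[1:nr, 1:nc] <- b
  cc <- Re(stats::fft(Conj(stats::fft(pa)) * stats::fft(pb), inverse = TRUE)) /
    (pr * pc)
  # padded integral images: ii[r+1, c+1] = sum over rows<=r, cols<=c
  pad_ii <- function(m) {
    ii <- matrix(0, nrow(m) + 1, ncol(m) + 1)
    ii[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
    ii
  }
  ii_a <- pad_ii(a); ii_a2 <- pad_ii(a * a)
  ii_b <- pad_ii(b); ii_b2 <- pad_ii(b * b)
  lag <- seq.int(-s, s)
  # overlap rectangle in a per lag: rows r1..r2, cols c1..c2; in b the same
  # rectangle shifted by the lag. All index vectors are separable per axis.
  r1a <- pmax(1, 1 - lag); r2a <- pmin(nr, nr - lag)
  c1a <- pmax(1, 1 - lag); c2a <- pmin(nc, nc - lag)
  r1b <- r1a + lag; r2b <- r2a + lag
  c1b <- c1a + lag; c2b <- c2a + lag
  rect <- function(ii, r1, r2, c1, c2)       # [dv, du] matrix of rect sums
    ii[r2 + 1, c2 + 1] - ii[r1, c2 + 1] - ii[r2 + 1, c1] + ii[r1, c1]
  sa_ <- rect(ii_a, r1a, r2a, c1a, c2a); sa2 <- rect(ii_a2, r1a, r2a, c1a, c2a)
  sb_ <- rect(ii_b, r1b, r2b, c1b, c2b); sb2 <- rect(ii_b2, r1b, r2b, c1b, c2b)
  nov <- outer(r2a - r1a + 1, c2a - c1a + 1)
  cross <- cc[1 + (lag %% pr), 1 + (lag %% pc), drop = FALSE]
  num <- cross - sa_ * sb_ / nov
  den <- sqrt(pmax(sa2 - sa_^2 / nov, 0) * pmax(sb2 - sb_^2 / nov, 0))
  sub <- ifelse(den > 1e-12, num / den, -Inf) # rows: dv lags, cols: du lags
  pk <- arrayInd(which.max(sub), dim(sub))
  iv <- pk[1]; iu <- pk[2]
  if (iv == 1 || iv == length(lag) || iu == 1 || iu == length(lag))
    return(invalid)                         # peak on search boundary
  c0 <- sub[iv, iu]
  # secondary peak outside the 3x3 neighborhood of the primary
  excl <- sub
  excl[max(1, iv - 1):min(nrow(sub), iv + 1),
       max(1, iu - 1):min(ncol(sub), iu + 1)] <- -Inf
  second <- max(excl)
  peak_ratio <- if (is.finite(second) && second > 1e-12) c0 / second else Inf
  fit1d <- function(cm, cz, cp) {
    denom_p <- cm + cp - 2 * cz
    if (cm > 0 && cz > 0 && cp > 0) {
      lm_ <- log(cm); lz <- log(cz); lp <- log(cp)
      den <- lm_ + lp - 2 * lz
      if (abs(den) > 1e-12) return(0.5 * (lm_ - lp) / den)
    }
    if (abs(denom_p) > 1e-12) return(0.5 * (cm - cp) / denom_p)
    0
  }
  # 2-D Gaussian fit over the 3x3 peak neighborhood (log-paraboloid with a
  # cross term). Separable 3-point fits couple the axes when both sub-pixel
  # components are large; the cross term removes that bias. Falls back to
  # the separable fits when the neighborhood is not log-fittable.
  delta <- NULL
  nb <- sub[(iv - 1):(iv + 1), (iu - 1):(iu + 1)]
  if (all(is.finite(nb)) && all(nb > 0)) {
    L <- as.vector(log(nb))
    du9 <- rep(c(-1, 0, 1), each = 3); dv9 <- rep(c(-1, 0, 1), times = 3)
    X <- cbind(1, du9, dv9, du9^2, dv9^2, du9 * dv9)
    beta <- tryCatch(solve(crossprod(X), crossprod(X, L)),
                     error = function(e) NULL)
    if (!is.null(beta)) {
      H <- matrix(c(2 * beta[4], beta[6], beta[6], 2 * beta[5]), 2, 2)
      if (H[1, 1] < 0 && det(H) > 0) {
        sol <- solve(H, -c(beta[2], beta[3]))
        if (max(abs(sol)) <= 1) delta <- sol
      }
    }
  }
  if (is.null(delta)) {
    delta <- c(fit1d(sub[iv, iu - 1], c0, sub[iv, iu + 1]),
               fit1d(sub[iv - 1, iu], c0, sub[iv + 1, iu]))
  }
  ddu <- max(min(delta[1], 1), -1); ddv <- max(min(delta[2], 1), -1)
  list(du = lag[iu] + ddu, dv = lag[iv] + ddv, peak = c0,
       peak_ratio = peak_ratio, valid = TRUE)
}

# Bilinear interpolation of a grid-sampled component at query points,
# clamped at the grid hull. NAs must be filled beforehand.
interp_grid <- function(grid_x, grid_y, z, xq, yq) {
  ix <- findInterval(xq, grid_x, all.inside = TRUE)
  iy <- findInterval(yq, grid_y, all.inside = TRUE)
  x1 <- grid_x[ix]; x2 <- grid_x[ix + 1]
  y1 <- grid_y[iy]; y2 <- grid_y[iy + 1]
  tx <- pmin(pmax((xq - x1) / (x2 - x1), 0), 1)
  ty <- pmin(pmax((yq - y1) / (y2 - y1), 0), 1)
  z11 <- z[cbind(iy, ix)];     z12 <- z[cbind(iy, ix + 1)]
  z21 <- z[cbind(iy + 1, ix)]; z22 <- z[cbind(iy + 1, ix + 1)]
  (1 - ty) * ((1 - tx) * z11 + tx * z12) + ty * ((1 - tx) * z21 + tx * z22)
}

# Fill invalid vectors with the median of valid values (for seeding only).
fill_component <- function(z, valid) {
  if (all(valid)) return(z)
  med <- stats::median(z[valid])
  if (!is.finite(med)) med <- 0
  z[!valid] <- med
  z
}

#' Single PIV pass
#'
#' Correlates each interrogation window of the reference frame against the
#' window of the current frame offset by the (rounded) seed displacement;
#' output vectors are seed offset + correlation residual. Windows that would
#' leave the image, near-constant windows, and low peak-ratio correlations
#' are flagged invalid.
#'
#' @param ref,cur grayscale matrices of equal size.
#' @param window,search,spacing pass parameters in px.
#' @param seed_field optional coarser displacement field used to pre-offset
#'   the search (`NULL` behaves as a zero seed).
#' @param min_peak_ratio validity cutoff on primary/secondary peak ratio.
#' @param min_peak validity cutoff on the NCC peak height itself; pure-noise
#'   correlations peak well below this while genuine speckle matches sit far
#'   above it.
#' @return A `displacement_field` on the pass grid.
#' @export
piv_pass <- function(ref, cur, window, search, spacing, seed_field = NULL,
                     min_peak_ratio = 1.2, min_peak = 0.35) {
  ctr <- piv_centers(dim(ref), window, spacing)
  nx <- length(ctr$x); ny <- length(ctr$y)
  gx <- rep(ctr$x, each = ny); gy <- rep(ctr$y, times = nx)
  if (!is.null(seed_field)) {
    su <- fill_component(seed_field$u, seed_field$valid)
    sv <- fill_component(seed_field$v, seed_field$valid)
    if (length(seed_field$grid_x) < 2 || length(seed_field$grid_y) < 2) {
      seed_u <- rep(mean(su), length(gx)); seed_v <- rep(mean(sv), length(gx))
    } else {
      seed_u <- interp_grid(seed_field$grid_x, seed_field$grid_y, su, gx, gy)
      seed_v <- interp_grid(seed_field$grid_x, seed_field$grid_y, sv, gx, gy)
    }
  } else {
    seed_u <- numeric(length(gx)); seed_v <- numeric(length(gx))
  }
  off_u <- round(seed_u); off_v <- round(seed_v)
  u <- matrix(0, ny, nx); v <- matrix(0, ny, nx)
  quality <- matrix(NA_real_, ny, nx); valid <- matrix(FALSE, ny, nx)
  for (k in seq_along(gx)) {
    rp <- extract_window(ref, gx[k], gy[k], window)
    cp <- extract_window(cur, gx[k] + off_u[k], gy[k] + off_v[k], window)
    if (is.null(rp) || is.null(cp)) next
    res <- correlate_window(rp, cp, search_px = search)
    i <- ((k - 1) %% ny) + 1; j <- ((k - 1) %/% ny) + 1
    if (res$valid && res$peak_ratio >= min_peak_ratio && res$peak >= min_peak) {
      u[i, j] <- off_u[k] + res$du
      v[i, j] <- off_v[k] + res$dv
      quality[i, j] <- res$peak_ratio
      valid[i, j] <- TRUE
    }
  }
  new_displacement_field(ctr$x, ctr$y, u, v, quality, valid,
                         spacing_px = spacing)
}

#' Normalized-median vector validation
#'
#' Universal outlier detection on the vector grid: for each vector, the
#' residual to the median of its 3x3 valid neighbors is normalized by the
#' median absolute neighbor residual plus `eps`; vectors whose normalized
#' residual exceeds `threshold` on either component, and vectors already
#' invalid, are replaced by the median of their valid neighbors and flagged
#' `replaced`. A vector with fewer than `min_neighbors` valid neighbors is
#' left invalid (nothing is fabricated).
#'
#' @param field a `displacement_field`.
#' @param threshold normalized residual cutoff (default 2.0).
#' @param eps residual floor in px (default 0.1).
#' @param min_neighbors minimum valid neighbors required to replace.
#' @return The validated field.
#' @export
validate_vectors <- function(field, threshold = 2.0, eps = 0.1,
                             min_neighbors = 2L) {
  ny <- nrow(field$u); nx <- ncol(field$u)
  u <- field$u; v <- field$v; valid <- field$valid
  new_u <- u; new_v <- v
  new_valid <- valid; replaced <- field$replaced
  for (j in seq_len(nx)) for (i in seq_len(ny)) {
    ii <- max(1, i - 1):min(ny, i + 1)
    jj <- max(1, j - 1):min(nx, j + 1)
    nb_mask <- valid[ii, jj]
    nb_mask[match(i, ii), match(j, jj)] <- FALSE
    nu <- u[ii, jj][nb_mask]; nv <- v[ii, jj][nb_mask]
    n_nb <- length(nu)
    bad <- !valid[i, j]
    if (!bad && n_nb >= 3L) {
      mu <- stats::median(nu); mv <- stats::median(nv)
      ru <- abs(u[i, j] - mu) / (stats::median(abs(nu - mu)) + eps)
      rv <- abs(v[i, j] - mv) / (stats::median(abs(nv - mv)) + eps)
      bad <- max(ru, rv) > threshold
    }
    if (bad) {
      if (n_nb >= min_neighbors) {
        new_u[i, j] <- stats::median(nu)
        new_v[i, j] <- stats::median(nv)
        new_valid[i, j] <- TRUE
        replaced[i, j] <- TRUE
      } else {
        new_valid[i, j] <- FALSE
      }
    }
  }
  field$u <- new_u; field$v <- new_v
  field$valid <- new_valid; field$replaced <- replaced
  field
}

#' Multi-pass PIV between two frames
#'
#' Runs the pass schedule in order with feed-forward seeding: each pass's
#' validated field seeds the next (finer) pass, whose windows are offset by
#' the interpolated seed before correlation. Vector validation
#' ([validate_vectors()]) runs after every pass. A one-pass schedule reduces
#' to a direct [piv_pass()] plus validation.
#'
#' @param ref,cur grayscale matrices of equal size.
#' @param schedule a [piv_schedule()].
#' @param min_peak_ratio,min_peak correlation validity cutoffs (see
#'   [piv_pass()]).
#' @param validate logical; run the normalized-median test between passes.
#' @return A `displacement_field` on the final pass grid.
#' @export
multipass_piv <- function(ref, cur, schedule = piv_schedule(),
                          min_peak_ratio = 1.2, min_peak = 0.35,
                          validate = TRUE) {
  stopifnot(all(dim(ref) == dim(cur)))
  field <- NULL
  for (p in seq_len(nrow(schedule))) {
    field <- piv_pass(ref, cur, schedule$window[p], schedule$search[p],
                      schedule$spacing[p], seed_field = field,
                      min_peak_ratio = min_peak_ratio, min_peak = min_peak)
    if (validate) field <- validate_vectors(field)
  }
  field
}
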