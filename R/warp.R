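# Image warping by a known displacement field (fixture machinery).

# Catmull-Rom cubic convolution kernel (a = -0.5): interpolates exactly at
# integer offsets, C1 continuous, no overshoot worth speaking of on speckle.
cubic_kernel <- function(t) {
  a <- -0.5
  at <- abs(t)
  w <- numeric(length(t))
  i1 <- at <= 1
  w[i1] <- (a + 2) * at[i1]^3 - (a + 3) * at[i1]^2 + 1
  i2 <- at > 1 & at < 2
  w[i2] <- a * at[i2]^3 - 5 * a * at[i2]^2 + 8 * a * at[i2] - 4 * a
  w
}

# Vectorised bicubic sampling of img at (xq, yq) (x = column, y = row,
# 1-based pixel centers). Out-of-range taps are clamped to the border.
interp_bicubic <- function(img, xq, yq) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- floor(xq); y0 <- floor(yq)
  fx <- xq - x0; fy <- yq - y0
  out <- numeric(length(xq))
  wx <- list(); wy <- list()
  for (i in -1:2) {
    wx[[i + 2L]] <- cubic_kernel(fx - i)
    wy[[i + 2L]] <- cubic_kernel(fy - i)
  }
  for (j in -1:2) {
    rows <- clamp_idx(y0 + j, nr)
    wyj <- wy[[j + 2L]]
    for (i in -1:2) {
      cols <- clamp_idx(x0 + i, nc)
      out <- out + wyj * wx[[i + 2L]] * img[cbind(rows, cols)]
    }
  }
  out
}

#' Warp an image by a displacement field
#'
#' Produces the "deformed" image of a displacement field `d = (u, v)` using
#' inverse mapping: `output(x, y) = input(x - u(x, y), y - v(x, y))`, sampled
#' with bicubic (Catmull-Rom) interpolation. With the fields used by the
#' synthetic generators this means features of the input appear displaced by
#' approximately `+d` in the output, which is what PIV against the input as
#' reference should recover. A zero field reproduces the input exactly
#' (integer-offset interpolation is exact).
#'
#' @param image numeric matrix.
#' @param displacement either a `function(x, y)` returning `list(u=, v=)` for
#'   vectors of pixel coordinates, or a list with matrices `u`, `v` of the
#'   same dimension as `image`.
#' @return The warped matrix, same dimension, clipped to the input range.
#' @export
warp_frame <- function(image, displacement) {
  nr <- nrow(image); nc <- ncol(image)
  xs <- rep(seq_len(nc), each = nr)
  ys <- rep(seq_len(nr), times = nc)
  if (is.function(displacement)) {
    d <- displacement(xs, ys)
    u <- d$u; v <- d$v
  } else {
    if (!all(dim(displacement$u) == dim(image)) ||
        !all(dim(displacement$v) == dim(image)))
      stop_arg("displacement matrices must match the image dimension")
    u <- as.vector(displacement$u)
    v <- as.vector(displacement$v)
  }
  if (any(!is.finite(u)) || any(!is.finite(v)))
    stop_arg("displacement field contains non-finite values")
  vals <- interp_bicubic(image, xs - u, ys - v)
  matrix(pmin(pmax(vals, min(image)), max(image)), nr, nc)
}

# Spectral (trigonometric) warp for fields of the form u = u(x), v = 0:
# each row is resampled at x - u(x) by periodic sinc (Dirichlet)
# interpolation, exact for band-limited content. Used by the sinusoidal
# validation pair, where sub-pixel fidelity of the fixture itself matters.
# Content wraps periodically, so a border band of ~max|u| px is invalid.
warp_columns_spectral <- function(image, u_col) {
  nc <- ncol(image)
  stopifnot(length(u_col) == nc)
  xq <- seq_len(nc) - u_col
  s <- outer(xq, seq_len(nc), "-")          # query minus source index
  sn <- pi * s / nc
  w <- ifelse(abs(sin(sn)) < 1e-12, 1,
              sin(pi * s) / (nc * tan(sn)))  # Dirichlet kernel, even nc
  image %*% t(w)
}
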