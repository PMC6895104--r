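#' Speckle pattern specification
#'
#' Describes a random speckle texture of the kind used as a correlation
#' target in digital image correlation: additive Gaussian blobs at uniformly
#' random positions over a flat background, clipped to `[0, 1]`. The texture
#' stands in for the phase-contrast appearance of a cell monolayer; it is not
#' a photorealistic cell rendering.
#'
#' @param shape_px integer `c(rows, cols)` image size in pixels.
#' @param density particles per 100 square pixels (> 0 for a textured image;
#'   0 yields the uniform background).
#' @param radius_px Gaussian blob sigma in pixels.
#' @param noise_sd additive intensity noise, as a standard deviation in units
#'   of the `[0, 1]` dynamic range, applied per generated frame (not to the
#'   base pattern).
#' @param seed integer RNG seed; the same spec is bit-reproducible.
#' @param periodic logical; wrap blobs around the image borders so the
#'   texture is exactly periodic. Required for artifact-free spectral
#'   warping (trigonometric interpolation rings on non-periodic content).
#' @return An object of class `speckle_spec`.
#' @seealso [make_speckle()], [beating_sequence()]
#' @export
speckle_spec <- function(shape_px = c(256L, 256L), density = 3, radius_px = 1.2,
                         noise_sd = 0.02, seed = 1L, periodic = FALSE) {
  shape_px <- as.integer(shape_px)
  if (length(shape_px) != 2L || any(!is.finite(shape_px)) || any(shape_px <= 0L))
    stop_arg("'shape_px' must be two strictly positive integers (rows, cols)")
  if (!is.finite(density) || density < 0)
    stop_arg("'density' must be a non-negative number of particles per 100 px^2")
  if (!is.finite(radius_px) || radius_px <= 0)
    stop_arg("'radius_px' must be positive")
  structure(list(shape_px = shape_px, density = density, radius_px = radius_px,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 periodic = isTRUE(periodic)),
            class = "speckle_spec")
}

#' Render a speckle base image
#'
#' Deterministically renders the speckle texture described by a
#' [speckle_spec()]: `n = density * rows * cols / 100` Gaussian blobs with
#' uniformly random sub-pixel positions and amplitudes in `[0.5, 1]`, added to
#' a 0.15 background and clipped to `[0, 1]`. Per-frame intensity noise is
#' *not* applied here (see [beating_sequence()]).
#'
#' @param spec a [speckle_spec()].
#' @return A numeric matrix in `[0, 1]` with `dim = shape_px`.
#' @export
make_speckle <- function(spec) {
  stopifnot(inherits(spec, "speckle_spec"))
  nr <- spec$shape_px[1]; nc <- spec$shape_px[2]
  img <- matrix(0.15, nr, nc)
  n <- round(spec$density * nr * nc / 100)
  if (n == 0) return(img)
  with_seed(spec$seed, {
    px <- runif(n, 0.5, nc + 0.5)   # x = column
    py <- runif(n, 0.5, nr + 0.5)   # y = row
    amp <- runif(n, 0.5, 1)
    s <- spec$radius_px
    halo <- ceiling(4 * s)
    off <- seq.int(-halo, halo)
    wrap <- isTRUE(spec$periodic)
    for (k in seq_len(n)) {
      cx <- round(px[k]); cy <- round(py[k])
      xs <- cx + off; ys <- cy + off
      gx <- exp(-((xs - px[k])^2) / (2 * s^2))
      gy <- exp(-((ys - py[k])^2) / (2 * s^2))
      if (wrap) {
        xs <- ((xs - 1L) %% nc) + 1L
        ys <- ((ys - 1L) %% nr) + 1L
        okx <- rep(TRUE, length(xs)); oky <- rep(TRUE, length(ys))
      } else {
        okx <- xs >= 1L & xs <= nc; oky <- ys >= 1L & ys <= nr
        if (!any(okx) || !any(oky)) next
      }
      img[ys[oky], xs[okx]] <- img[ys[oky], xs[okx]] +
        amp[k] * (gy[oky] %o% gx[okx])
    }
  })
  pmin(pmax(img, 0), 1)
}
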