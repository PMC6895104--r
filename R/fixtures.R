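#' Synthetic beating sequence with exact ground truth
#'
#' Warps a speckle base image by the analytic displacement history of a
#' [motion_spec()] (pulse trains, drift, rest-state micro-motion), producing
#' an [image_stack()] together with the exact fields used to warp. Truth is
#' expressed relative to frame 1 (identically zero there) and is sampled
#' both on demand at full resolution and on the PIV vector grid implied by
#' `schedule`, so every downstream stage can be checked against it.
#'
#' Per-frame additive intensity noise (`speckle$noise_sd`) is drawn from a
#' stream seeded by `speckle$seed`, so identical specs give bit-identical
#' stacks.
#'
#' @param speckle a [speckle_spec()].
#' @param motion a [motion_spec()] (any kind; `pulse_train` is the beating
#'   emulation).
#' @param schedule the [piv_schedule()] whose final pass defines the truth
#'   grid.
#' @param pixel_size_um microns per pixel attached to the stack (default
#'   0.9616, the pixel pitch for which one 24 px vector block covers
#'   532.6 um^2).
#' @return `list(stack, truth)` of classes `image_stack` / `ground_truth`.
#'   `truth` holds `grid_x`, `grid_y`, arrays `u[ny, nx, nt]`, `v`,
#'   `envelope[nt, n_origins]`, `rest` (logical per frame, all-origins
#'   quiescent), the origin table, and closures `field_at(t, xs, ys)`
#'   (analytic field anywhere) and `env_fn(t_sec)` (continuous envelopes).
#' @export
beating_sequence <- function(speckle, motion, schedule = piv_schedule(),
                             pixel_size_um = 0.9616) {
  stopifnot(inherits(speckle, "speckle_spec"), inherits(motion, "motion_spec"))
  base <- make_speckle(speckle)
  nr <- nrow(base); nc <- ncol(base)
  nt <- motion$n_frames
  final <- nrow(schedule)
  ctr <- piv_centers(c(nr, nc), schedule$window[final], schedule$spacing[final])
  rest_fn <- rest_noise_states(motion$rest_noise_norm, ctr$x, ctr$y, nr, nc)

  xs <- rep(seq_len(nc), each = nr)
  ys <- rep(seq_len(nr), times = nc)
  gx <- rep(ctr$x, each = length(ctr$y))
  gy <- rep(ctr$y, times = length(ctr$x))
  ny <- length(ctr$y); nx <- length(ctr$x)

  frames <- array(0, c(nr, nc, nt))
  u_grid <- array(0, c(ny, nx, nt)); v_grid <- array(0, c(ny, nx, nt))
  n_orig <- if (motion$kind == "pulse_train") nrow(motion$origins) else 0L
  envelope <- matrix(0, nt, max(1L, n_orig))
  with_seed(speckle$seed + 7919L, {
    for (t in seq_len(nt)) {
      d <- motion_field(motion, t, xs, ys, nr, nc, rest_fn)
      frames[, , t] <- if (t == 1) base else
        warp_frame(base, list(u = matrix(d$u, nr, nc), v = matrix(d$v, nr, nc)))
      if (speckle$noise_sd > 0)
        frames[, , t] <- pmin(pmax(frames[, , t] +
          matrix(stats::rnorm(nr * nc, 0, speckle$noise_sd), nr, nc), 0), 1)
      dg <- motion_field(motion, t, gx, gy, nr, nc, rest_fn)
      u_grid[, , t] <- matrix(dg$u, ny, nx)
      v_grid[, , t] <- matrix(dg$v, ny, nx)
      if (n_orig > 0) {
        t_sec <- (t - 1) / motion$fps
        for (k in seq_len(n_orig)) {
          o <- motion$origins[k, ]
          envelope[t, k] <- o$amplitude_px *
            pulse_envelope(t_sec, o$frequency_hz, o$phase_rad, motion$duty)
        }
      }
    }
  })
  rest <- apply(envelope, 1, function(e) all(e == 0))
  truth <- structure(list(
    grid_x = ctr$x, grid_y = ctr$y, u = u_grid, v = v_grid,
    envelope = envelope, rest = rest, origins = motion$origins,
    fps = motion$fps, pixel_size_um = pixel_size_um,
    field_at = function(t, qx, qy) motion_field(motion, t, qx, qy, nr, nc, rest_fn),
    env_fn = function(t_sec) {
      if (n_orig == 0) return(matrix(0, length(t_sec), 1))
      sapply(seq_len(n_orig), function(k) {
        o <- motion$origins[k, ]
        o$amplitude_px * pulse_envelope(t_sec, o$frequency_hz, o$phase_rad, motion$duty)
      })
    },
    mask_at = function(threshold_px) sqrt(u_grid^2 + v_grid^2) > threshold_px
  ), class = "ground_truth")
  list(stack = image_stack(frames, fps = motion$fps,
                           pixel_size_um = pixel_size_um),
       truth = truth)
}

#' Reference/deformed pair with sinusoidal deformation
#'
#' Constructs a two-image displacement benchmark in the style of synthetic
#' DIC test sets: a speckle reference and a copy deformed by
#' `u(x) = A sin(phi(x))`, `v = 0`, where the local wavelength follows
#' `wavelength_schedule` across equal-width column bands (the phase is
#' integrated so bands join continuously, giving an increasing strain
#' gradient when wavelengths shrink). Bands below a resolvable wavelength
#' are deliberately allowed, as real challenge sets include unresolvable
#' content; `resolvable(window_px)` flags the columns where the wavelength
#' is at least four final interrogation windows.
#'
#' @param amplitude_px peak displacement A in px.
#' @param wavelength_schedule wavelengths (px), one per equal-width band
#'   from left to right.
#' @param speckle a [speckle_spec()] (its `noise_sd` is applied per image).
#' @param pixel_size_um metadata for downstream conversion.
#' @return list with `ref`, `def` (matrices), `truth` (`u_col`: true u per
#'   column; `lambda_col`; `resolvable(window_px)`; `u_at(x)`), and
#'   `pixel_size_um`.
#' @export
dic_challenge_pair <- function(amplitude_px, wavelength_schedule = 256,
                               speckle = speckle_spec(shape_px = c(256L, 512L),
                                                      noise_sd = 0,
                                                      periodic = TRUE),
                               pixel_size_um = 0.9616) {
  base <- make_speckle(speckle)
  nr <- nrow(base); nc <- ncol(base)
  nb <- length(wavelength_schedule)
  band <- pmin(floor((seq_len(nc) - 1) / (nc / nb)) + 1, nb)
  lambda_col <- wavelength_schedule[band]
  phase <- cumsum(2 * pi / lambda_col)
  phase <- phase - phase[1]
  u_col <- amplitude_px * sin(phase)
  def <- warp_columns_spectral(base, u_col)
  def <- pmin(pmax(def, 0), 1)
  add_noise <- function(img, seed_off) {
    if (speckle$noise_sd == 0) return(img)
    with_seed(speckle$seed + seed_off, pmin(pmax(
      img + matrix(stats::rnorm(nr * nc, 0, speckle$noise_sd), nr, nc), 0), 1))
  }
  list(ref = add_noise(base, 101L), def = add_noise(def, 202L),
       truth = list(
         u_col = u_col, lambda_col = lambda_col,
         u_at = function(x) u_col[clamp_idx(round(x), nc)],
         # resolvable: wavelength at least 4 windows AND the window clear of
         # the border band corrupted by the (periodic) warp seam
         resolvable = function(window_px) {
           border <- ceiling(window_px / 2 + max(abs(u_col)) + 1)
           cols <- seq_len(nc)
           lambda_col >= 4 * window_px & cols > border & cols <= nc - border
         }),
       pixel_size_um = pixel_size_um)
}
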