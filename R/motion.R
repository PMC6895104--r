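#' Motion specification for synthetic sequences
#'
#' Describes the analytic displacement history used to deform a speckle base
#' image into a synthetic video with exact ground truth.
#'
#' Kinds:
#' \describe{
#' \item{`uniform_shift`}{rigid translation by `amplitude_px` along
#'   `direction` (unit vector), constant over all frames after the first.}
#' \item{`sinusoidal`}{static sinusoidal deformation `u(x) = A sin(phi(x))`
#'   (see [dic_challenge_pair()] for the two-image variant).}
#' \item{`pulse_train`}{periodic, spatially localized contraction pulses:
#'   each origin contributes either a radially inward field
#'   `d(x) = -A * env(t) * exp((sigma^2 - r^2)/(2 sigma^2)) * (x - o)/sigma`
#'   whose magnitude peaks at `A` on the ring `r = sigma` (compressive at
#'   the contraction center, tensile outside), or a rigidly translating
#'   Gaussian patch (see `mode` in [pulse_origins()]), modulated by a
#'   raised-cosine temporal envelope. This is the beating-monolayer
#'   emulation.}
#' }
#'
#' The temporal envelope is a raised-cosine pulse occupying a fraction
#' `duty` of each cycle (the "systole" fraction): with cycle position
#' `s in [-0.5, 0.5)`, `env = (1 + cos(2 pi s / duty)) / 2` for
#' `|s| < duty/2` and 0 otherwise. `duty = 1` gives the pure raised cosine
#' (no strictly motionless frames); the default 0.5 leaves genuine rest
#' (diastole) frames between beats, which adaptive re-referencing requires.
#'
#' `drift_px_per_frame` adds a slowly accumulating rigid translation
#' (`(t-1) * drift`), emulating the inter-cycle frame shifts that build up
#' measurement error under a static reference.
#'
#' `rest_noise_norm` adds deterministic frame-to-frame micro-motion designed
#' to emulate a latent noise floor of the rest frames: each frame carries one
#' of 16 smooth plane-wave displacement states, built from 8 grid-orthonormal
#' modes with Hadamard sign patterns, so that any two distinct states are the
#' same Frobenius distance apart (`rest_noise_norm`, measured on the truth
#' grid). `rest_noise_first_scale` rescales the first frame's state so the
#' norm between the first two frames can sit below the long-run floor (as
#' when an initial threshold estimate from two early quiescent frames
#' underestimates the eventual noise floor).
#'
#' @param kind one of `"uniform_shift"`, `"sinusoidal"`, `"pulse_train"`.
#' @param amplitude_px peak displacement in px (`uniform_shift`/`sinusoidal`).
#' @param direction length-2 numeric, direction of `uniform_shift`.
#' @param origins data.frame with columns `x`, `y`, `amplitude_px`,
#'   `sigma_px`, `frequency_hz`, `phase_rad` (one row per contraction
#'   origin); see [pulse_origins()].
#' @param duty systole fraction of the beat cycle in `(0, 1]`.
#' @param drift_px_per_frame length-2 numeric `(dx, dy)` px per frame.
#' @param rest_noise_norm Frobenius distance (px, on the truth grid) between
#'   distinct rest-noise states; 0 disables.
#' @param rest_noise_first_scale scale factor for the first frame's state.
#' @param fps frames per second.
#' @param n_frames number of frames.
#' @return An object of class `motion_spec`.
#' @export
motion_spec <- function(kind = c("pulse_train", "uniform_shift", "sinusoidal"),
                        amplitude_px = 0, direction = c(1, 0), origins = NULL,
                        duty = 0.5, drift_px_per_frame = c(0, 0),
                        rest_noise_norm = 0, rest_noise_first_scale = 1,
                        fps = 5, n_frames = 50L) {
  kind <- match.arg(kind)
  if (!is.finite(fps) || fps <= 0) stop_arg("'fps' must be positive")
  if (n_frames < 1) stop_arg("'n_frames' must be >= 1")
  if (duty <= 0 || duty > 1) stop_arg("'duty' must be in (0, 1]")
  if (length(drift_px_per_frame) == 1) drift_px_per_frame <- rep(drift_px_per_frame, 2)
  if (kind == "pulse_train") {
    if (is.null(origins) || nrow(origins) == 0)
      stop_arg("pulse_train motion needs at least one origin (see pulse_origins())")
    if (!all(is.finite(origins$amplitude_px)))
      stop_arg("origin amplitudes must be finite")
    if (any(origins$frequency_hz >= fps / 2))
      stop_arg("Nyquist violation: every origin frequency_hz must be < fps/2")
  }
  structure(list(kind = kind, amplitude_px = amplitude_px,
                 direction = direction / sqrt(sum(direction^2)),
                 origins = origins, duty = duty,
                 drift_px_per_frame = as.numeric(drift_px_per_frame),
                 rest_noise_norm = rest_noise_norm,
                 rest_noise_first_scale = rest_noise_first_scale,
                 fps = fps, n_frames = as.integer(n_frames)),
            class = "motion_spec")
}

#' Construct a table of contraction origins
#'
#' @param x,y origin centers in px (x = column, y = row).
#' @param amplitude_px peak displacement magnitude of each pulse (px).
#' @param sigma_px spatial Gaussian envelope sigma (px).
#' @param frequency_hz beat frequency.
#' @param phase_rad temporal phase; the default `pi` puts the first frame at
#'   rest (mid-diastole) so it can serve as the initial reference.
#' @param mode `"radial"`: tissue converges on the origin
#'   (`|d|` peaks on the ring `r = sigma` and vanishes at the exact center
#'   -- compressive core, tensile surround); `"bump"`: the patch under the
#'   Gaussian envelope translates rigidly along `dir_rad` (`|d|` peaks at
#'   the origin itself). The bump emulates a contracting cluster tugging
#'   the monolayer and gives well-posed region tracking, since windowed
#'   correlation at the center of a radial field straddles opposing motions
#'   and reports near-zero displacement there.
#' @param dir_rad translation direction for `mode = "bump"` (radians).
#' @return data.frame with one row per origin.
#' @export
pulse_origins <- function(x, y, amplitude_px, sigma_px, frequency_hz = 1.25,
                          phase_rad = pi, mode = "radial", dir_rad = 0) {
  data.frame(x = x, y = y, amplitude_px = amplitude_px, sigma_px = sigma_px,
             frequency_hz = frequency_hz, phase_rad = phase_rad,
             mode = mode, dir_rad = dir_rad)
}

# Raised-cosine pulse envelope in [0, 1]; t_sec may be a vector.
pulse_envelope <- function(t_sec, frequency_hz, phase_rad, duty) {
  s <- (frequency_hz * t_sec + phase_rad / (2 * pi)) %% 1
  s <- ifelse(s >= 0.5, s - 1, s)           # cycle position in [-0.5, 0.5)
  env <- numeric(length(s))
  on <- abs(s) < duty / 2
  env[on] <- 0.5 * (1 + cos(2 * pi * s[on] / duty))
  env
}

# Rest-noise machinery: 8 plane-wave displacement modes, orthonormalized on
# the truth grid, combined with Hadamard sign rows (16 states incl.
# negations). Any two distinct states are equidistant in Frobenius norm.
hadamard8 <- function() {
  h2 <- matrix(c(1, 1, 1, -1), 2, 2)
  h2 %x% h2 %x% h2
}

# Mode m of 8 evaluated at (xs, ys): returns list(u, v). Integer wavevectors
# (a, b) with a^2 + b^2 = 5 -> equal wavelength, equal PIV attenuation.
rest_mode_field <- function(m, xs, ys, nr, nc) {
  ab <- list(c(1, 2), c(2, 1), c(1, -2), c(2, -1))
  comp_u <- m <= 4
  k <- ab[[(m - 1) %% 4 + 1]]
  ph <- 2 * pi * (k[1] * xs / nc + k[2] * ys / nr) + 0.25 * pi * m
  w <- cos(ph)
  if (comp_u) list(u = w, v = numeric(length(w)) ) else list(u = numeric(length(w)), v = w)
}

# Build the rest-noise state generator for a given truth grid.
# Returns function(state_idx, xs, ys) -> list(u, v) with exact state norm
# `norm_px / sqrt(2)` on the grid (pairwise distance = norm_px).
rest_noise_states <- function(norm_px, grid_x, grid_y, nr, nc) {
  if (norm_px <= 0) return(NULL)
  gx <- rep(grid_x, each = length(grid_y))
  gy <- rep(grid_y, times = length(grid_x))
  raw <- sapply(1:8, function(m) {
    f <- rest_mode_field(m, gx, gy, nr, nc)
    c(f$u, f$v)
  })
  qr_ <- qr(raw)
  coef <- backsolve(qr.R(qr_), diag(8))       # raw %*% coef is orthonormal
  coef <- sweep(coef, 2, sqrt(colSums((raw %*% coef)^2)), "/")
  had <- hadamard8()
  state_norm <- norm_px / sqrt(2)
  function(state_idx, xs, ys) {
    i <- (state_idx - 1) %% 16 + 1
    signs <- if (i <= 8) had[i, ] else -had[i - 8, ]
    w <- as.vector(coef %*% (signs * state_norm / sqrt(8)))
    u <- numeric(length(xs)); v <- numeric(length(xs))
    for (m in 1:8) {
      if (w[m] == 0) next
      f <- rest_mode_field(m, xs, ys, nr, nc)
      u <- u + w[m] * f$u
      v <- v + w[m] * f$v
    }
    # re-express through the orthonormalization so grid norms are exact
    list(u = u, v = v)
  }
}

# Frame state index: frame 1 owns state 1 exclusively; later frames cycle
# through states 2..16 so no later frame ever repeats frame 1's state.
rest_state_index <- function(t) ifelse(t == 1, 1L, (t - 2L) %% 15L + 2L)

# Total analytic displacement of frame t (1-based) relative to frame 1,
# evaluated at (xs, ys). Returns list(u, v).
motion_field <- function(motion, t, xs, ys, nr, nc, rest_fn = NULL) {
  u <- numeric(length(xs)); v <- numeric(length(xs))
  t_sec <- (t - 1) / motion$fps
  if (motion$kind == "uniform_shift" && t > 1) {
    u <- u + motion$amplitude_px * motion$direction[1]
    v <- v + motion$amplitude_px * motion$direction[2]
  }
  if (motion$kind == "pulse_train") {
    for (k in seq_len(nrow(motion$origins))) {
      o <- motion$origins[k, ]
      env <- pulse_envelope(t_sec, o$frequency_hz, o$phase_rad, motion$duty)
      if (env == 0) next
      dx <- xs - o$x; dy <- ys - o$y
      if (identical(o$mode, "bump")) {
        g <- o$amplitude_px * env * exp(-(dx^2 + dy^2) / (2 * o$sigma_px^2))
        u <- u + g * cos(o$dir_rad)
        v <- v + g * sin(o$dir_rad)
      } else {
        g <- -o$amplitude_px * env *
          exp((o$sigma_px^2 - (dx^2 + dy^2)) / (2 * o$sigma_px^2)) / o$sigma_px
        u <- u + g * dx
        v <- v + g * dy
      }
    }
  }
  u <- u + motion$drift_px_per_frame[1] * (t - 1)
  v <- v + motion$drift_px_per_frame[2] * (t - 1)
  if (!is.null(rest_fn)) {
    s_t <- rest_fn(rest_state_index(t), xs, ys)
    s_1 <- rest_fn(rest_state_index(1L), xs, ys)
    scale1 <- motion$rest_noise_first_scale
    if (t == 1) {
      # truth is relative to frame 1: identically zero there
    } else {
      u <- u + s_t$u - scale1 * s_1$u
      v <- v + s_t$v - scale1 * s_1$v
    }
  }
  list(u = u, v = v)
}
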