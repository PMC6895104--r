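# Shared fixtures for the test suite. Expensive PIV runs are cached in this
# environment so unit and acceptance tests can share them; everything is
# generated in code (no stored data).

.fix_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fix_cache)) assign(key, expr, envir = .fix_cache)
  get(key, envir = .fix_cache)
}

# Schedule used by the small (192 px) fixtures: final 24 px windows on a
# 12 px grid (15 x 15 vectors).
fix_schedule <- function() piv_schedule(c(48, 24), c(12, 6), c(24, 12))

# 3-pass schedule used for the sinusoidal validation pair.
validation_schedule <- function() piv_schedule(c(64, 32, 16), c(16, 8, 4),
                                               c(32, 24, 16))

# Criteria matched to the 12 px fixture grid: one block = (12 * 0.9616)^2
# um^2, region filter = 10 blocks (same rule as the 24 px default).
fix_criteria <- function() {
  blk <- (12 * 0.9616)^2
  contraction_criteria(min_region_area_um2 = 10 * blk, block_area_um2 = blk,
                       norm_area_um2 = blk)
}

# Build a displacement field directly from matrices (unit-test plumbing).
make_field <- function(u, v = u * 0, valid = NULL, grid_x = NULL,
                       grid_y = NULL, spacing = 24, pixel_size_um = 0.9616,
                       frame = 1L, reference = 1L) {
  ny <- nrow(u); nx <- ncol(u)
  if (is.null(grid_x)) grid_x <- seq(0, by = spacing, length.out = nx) + spacing
  if (is.null(grid_y)) grid_y <- seq(0, by = spacing, length.out = ny) + spacing
  if (is.null(valid)) valid <- matrix(TRUE, ny, nx)
  ardic:::new_displacement_field(grid_x, grid_y, u, v,
                                 quality = matrix(2, ny, nx), valid = valid,
                                 frame_index = frame, reference_index = reference,
                                 spacing_px = spacing,
                                 pixel_size_um = pixel_size_um)
}

# A field whose contraction mask equals `mask`: |d| = mag_um on mask, 0 off.
field_from_mask <- function(mask, mag_um = 1, pixel_size_um = 0.9616,
                            spacing = 12, frame = 1L) {
  u <- matrix(0, nrow(mask), ncol(mask))
  u[mask] <- mag_um / pixel_size_um
  make_field(u, spacing = spacing, pixel_size_um = pixel_size_um,
             frame = frame)
}

# Minimal ardic-like object wrapping a list of fields (for metric/tree tests
# that do not need a real PIV run).
fake_fit <- function(fields, fps = 5, pixel_size_um = 0.9616) {
  trace <- data.frame(
    frame = vapply(fields, function(f) f$frame_index, numeric(1)),
    reference = vapply(fields, function(f) f$reference_index, numeric(1)),
    norm = vapply(fields, frobenius_norm_safe, numeric(1)),
    switched = FALSE)
  structure(list(fields = fields, trace = trace, config = ar_config(t_adapt = 1),
                 schedule = fix_schedule(), t_adapt = 1, ar = TRUE, fps = fps,
                 pixel_size_um = pixel_size_um),
            class = "ardic")
}

frobenius_norm_safe <- function(f) {
  if (!any(f$valid)) return(NA_real_)
  frobenius_norm(f)
}

# Dense-envelope correlation helper (analytic truth signals).
env_cor <- function(truth, t_max, i, j, dt = 0.01) {
  tt <- seq(0, t_max, by = dt)
  e <- truth$env_fn(tt)
  stats::cor(e[, i], e[, j])
}

# Single-origin slow-beat fixture (multi-frame cycles; bump mode) plus its
# AR-DIC fit -- reused by tree/ASC tests and acceptance.
slow_beat_fit <- function() {
  cached("slow_beat", {
    fx <- beating_sequence(
      speckle_spec(shape_px = c(192L, 192L), seed = 7),
      motion_spec("pulse_train",
                  origins = pulse_origins(96, 96, 3, 30, frequency_hz = 0.25,
                                          mode = "bump"),
                  duty = 0.4, fps = 5, n_frames = 40L),
      schedule = fix_schedule())
    fit <- ardic(fx$stack, fix_schedule(), ar_config(t_adapt = 0.3))
    list(fx = fx, fit = fit, forest = contraction_forest(fit, fix_criteria()))
  })
}

# Three staggered origins (onsets 0, 2, 4 frames) with inter-cycle drift.
three_origin_fit <- function() {
  cached("three_origin", {
    fx <- beating_sequence(
      speckle_spec(shape_px = c(256L, 256L), seed = 2),
      motion_spec("pulse_train",
                  origins = pulse_origins(
                    x = c(70, 186, 128), y = c(70, 70, 186),
                    amplitude_px = c(3, 2.5, 2), sigma_px = 26,
                    frequency_hz = 0.25,
                    phase_rad = pi - 2 * pi * 0.25 / 5 * c(0, 2, 4),
                    mode = "bump", dir_rad = c(0, 2.1, 4.2)),
                  duty = 0.4, drift_px_per_frame = c(0.02, 0),
                  fps = 5, n_frames = 60L),
      schedule = fix_schedule())
    fit <- ardic(fx$stack, fix_schedule(), ar_config(t_adapt = 6))
    list(fx = fx, fit = fit, forest = contraction_forest(fit, fix_criteria()))
  })
}

# Fast-beat fixture at the acquisition conditions the package targets
# (1.25 Hz at 5 FPS) -- used for BPM/metrics and drift studies.
fast_beat_fixture <- function(drift_per_cycle = 0, n_frames = 44L, seed = 4L) {
  beating_sequence(
    speckle_spec(shape_px = c(192L, 192L), seed = seed),
    motion_spec("pulse_train",
                origins = pulse_origins(96, 96, 3, 30, frequency_hz = 1.25),
                duty = 0.5, drift_px_per_frame = c(drift_per_cycle / 4, 0),
                fps = 5, n_frames = n_frames),
    schedule = fix_schedule())
}
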