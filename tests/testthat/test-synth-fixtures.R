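# Synthetic speckle generator, warping, and analytic ground truth.

test_that("speckle rendering is deterministic and seed-sensitive", {
  sp <- speckle_spec(shape_px = c(96L, 96L), density = 3, seed = 1)
  img1 <- make_speckle(sp)
  img2 <- make_speckle(sp)
  expect_identical(img1, img2)
  expect_true(all(img1 >= 0 & img1 <= 1))

  img3 <- make_speckle(speckle_spec(shape_px = c(96L, 96L), density = 3, seed = 2))
  expect_gt(mean(img1 != img3), 0.01)

  flat <- make_speckle(speckle_spec(shape_px = c(32L, 32L), density = 0))
  expect_equal(max(flat) - min(flat), 0)

  expect_error(speckle_spec(shape_px = c(0L, 10L)), "positive")
})

test_that("warping is exact for the zero field and recovers known shifts", {
  img <- make_speckle(speckle_spec(shape_px = c(96L, 96L), seed = 3))
  zero <- function(x, y) list(u = numeric(length(x)), v = numeric(length(x)))
  expect_lt(max(abs(warp_frame(img, zero) - img)), 1e-9)

  # integer shift: full-frame FFT cross-correlation oracle
  shifted <- warp_frame(img, function(x, y)
    list(u = rep(3, length(x)), v = rep(2, length(x))))
  cc <- Re(stats::fft(Conj(stats::fft(img)) * stats::fft(shifted),
                      inverse = TRUE))
  pk <- arrayInd(which.max(cc), dim(cc)) - 1L
  expect_equal(pk[1], 2)  # dy
  expect_equal(pk[2], 3)  # dx

  # sub-pixel shift: evaluate the cross-correlation at fractional x lags
  half <- warp_frame(img, function(x, y)
    list(u = rep(0.5, length(x)), v = numeric(length(x))))
  C <- Conj(stats::fft(img)) * stats::fft(half)
  S <- colSums(C)                       # collapse the y frequencies
  n <- ncol(img)
  kx <- ifelse(seq_len(n) - 1 < n / 2, seq_len(n) - 1, seq_len(n) - 1 - n)
  dxs <- seq(-1, 2, by = 1 / 64)
  vals <- vapply(dxs, function(d)
    Re(sum(S * exp(2i * pi * kx * d / n))), numeric(1))
  peak_dx <- dxs[which.max(vals)]
  expect_gt(peak_dx, 0)
  expect_lt(peak_dx, 1)
  expect_lt(abs(peak_dx - 0.5), 0.1)

  expect_error(warp_frame(img, function(x, y)
    list(u = rep(NaN, length(x)), v = numeric(length(x)))), "non-finite")
})

test_that("warping approximately conserves mean intensity for periodic fields", {
  img <- make_speckle(speckle_spec(shape_px = c(128L, 128L), seed = 5))
  per <- function(x, y) list(u = 1.5 * sin(2 * pi * y / 64),
                             v = 1.5 * sin(2 * pi * x / 64))
  out <- warp_frame(img, per)
  expect_lt(abs(mean(out) - mean(img)) / mean(img), 0.01)
})

test_that("beating sequences carry exact, consistent ground truth", {
  sp <- speckle_spec(shape_px = c(96L, 96L), seed = 2, noise_sd = 0)
  still <- beating_sequence(sp, motion_spec("pulse_train",
    origins = pulse_origins(48, 48, amplitude_px = 0, sigma_px = 20),
    fps = 5, n_frames = 6L), schedule = piv_schedule(48, 12, 24))
  for (t in 2:6)
    expect_identical(still$stack$frames[, , t], still$stack$frames[, , 1])
  expect_true(all(abs(still$truth$u) == 0))

  # determinism end to end
  again <- beating_sequence(sp, motion_spec("pulse_train",
    origins = pulse_origins(48, 48, amplitude_px = 0, sigma_px = 20),
    fps = 5, n_frames = 6L), schedule = piv_schedule(48, 12, 24))
  expect_identical(still$stack$frames, again$stack$frames)

  # 1.25 Hz for 60 s -> exactly 75 envelope maxima
  m <- motion_spec("pulse_train",
                   origins = pulse_origins(48, 48, 2, 20, frequency_hz = 1.25,
                                           phase_rad = 0),
                   fps = 5, n_frames = 300L)
  tt <- seq(0, 60 - 1e-9, by = 0.005)   # [0, 60): 75 beat cycles
  env <- ardic:::pulse_envelope(tt, 1.25, 0, 0.5)
  n_max <- sum(diff(sign(diff(env))) == -2) + (env[1] > env[2])
  expect_equal(n_max, 75)

  # two origins half a cycle apart, full-duty raised cosine: anti-correlated
  m2 <- motion_spec("pulse_train",
    origins = pulse_origins(c(30, 70), c(48, 48), 2, 15,
                            frequency_hz = 0.5, phase_rad = c(0, pi)),
    duty = 1, fps = 5, n_frames = 20L)
  fx2 <- beating_sequence(sp, m2, schedule = piv_schedule(48, 12, 24))
  expect_lt(env_cor(fx2$truth, 10, 1, 2), -0.9)

  # rest frames of a clipped pulse are strictly motionless in truth
  fx3 <- beating_sequence(sp, motion_spec("pulse_train",
    origins = pulse_origins(48, 48, 2, 20, frequency_hz = 1.25),
    duty = 0.5, fps = 5, n_frames = 12L), schedule = piv_schedule(48, 12, 24))
  rest <- which(fx3$truth$rest)
  expect_gt(length(rest), 0)
  mag <- sqrt(fx3$truth$u^2 + fx3$truth$v^2)
  expect_equal(max(mag[, , rest]), 0)
  # truth mask consistency is exact by construction
  expect_identical(fx3$truth$mask_at(0.1), mag > 0.1)

  expect_error(motion_spec("pulse_train",
    origins = pulse_origins(48, 48, 2, 20, frequency_hz = 3), fps = 5,
    n_frames = 10L), "Nyquist")
})

test_that("the sinusoidal validation pair matches its stated deformation", {
  p0 <- dic_challenge_pair(0, 256, speckle_spec(shape_px = c(64L, 128L),
                                                seed = 4, noise_sd = 0))
  expect_lt(max(abs(p0$ref - p0$def)), 1e-9)

  p <- dic_challenge_pair(2, 64, speckle_spec(shape_px = c(64L, 128L),
                                              seed = 4, noise_sd = 0))
  expect_equal(max(abs(p$truth$u_col)), 2, tolerance = 1e-6)
  expect_equal(p$truth$lambda_col, rep(64, 128))
  # resolvable flags drop short wavelengths and the warp border band
  r <- p$truth$resolvable(32)
  expect_false(any(r))            # lambda = 64 < 4 * 32
  r2 <- p$truth$resolvable(8)
  expect_true(any(r2))
  expect_false(r2[1])
})
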