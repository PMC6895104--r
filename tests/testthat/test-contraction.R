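# Contraction detection, rate estimation, contraction volume, heat maps.

test_that("contraction masks follow the sarcomere-length threshold", {
  z <- make_field(matrix(0, 6, 6))
  expect_false(any(contraction_mask(z)))

  f <- make_field(matrix(0.15 / 0.9616, 6, 6))   # uniform |d| = 0.15 um
  expect_true(all(contraction_mask(f, 0.14)))
  expect_false(any(contraction_mask(f, 0.56)))

  # monotone in the threshold, and the alternate threshold is exactly 4x
  set.seed(51)
  g <- make_field(matrix(abs(rnorm(100, 0.2, 0.3)), 10, 10))
  for (th in c(0.1, 0.14, 0.3, 0.56))
    expect_true(all(contraction_mask(g, th * 2) <= contraction_mask(g, th)))
  expect_identical(4 * 0.14, 0.56)

  # invalid vectors never enter the mask
  f$valid[1, 1] <- FALSE
  expect_false(contraction_mask(f, 0.14)[1, 1])
})

test_that("beating area and coverage use block area and valid denominator", {
  m <- matrix(FALSE, 20, 20)
  expect_equal(beating_area(m, 532.6)$area_um2, 0)
  expect_equal(beating_area(m, 532.6)$coverage_pct, 0)
  m[] <- TRUE
  expect_equal(beating_area(m, 532.6)$coverage_pct, 100)

  m[] <- FALSE; m[1:10, 1:10] <- TRUE              # 100 of 400
  ba <- beating_area(m, 532.6)
  expect_equal(ba$area_um2, 53260)
  expect_equal(ba$coverage_pct, 25)

  valid <- matrix(TRUE, 20, 20); valid[, 1:2] <- FALSE
  expect_equal(beating_area(m, 532.6, valid)$coverage_pct,
               100 * 100 / 360)
})

test_that("FFT rate estimation recovers known rates and refuses flat signals", {
  tt <- seq(0, 60 - 0.2, by = 0.2)                 # 5 FPS, 60 s
  for (hz in c(0.5, 0.75, 1.0, 1.25, 2.0)) {
    est <- bpm_fft(sin(2 * pi * hz * tt) + 0.3, fps = 5)
    expect_lt(abs(est$bpm - 60 * hz), 0.5)
    expect_true(est$prominent)
  }
  flat <- bpm_fft(rep(2, 300), fps = 5)
  expect_true(is.na(flat$bpm))
  expect_false(flat$prominent)

  set.seed(61)
  noise <- bpm_fft(rnorm(300), fps = 5)
  expect_false(noise$prominent)
})

test_that("the peak counter agrees with the spectral estimate", {
  # ten clean pulses in 8 s -> 75 BPM (pulses centred inside the record)
  tt <- seq(0, 8 - 0.2, by = 0.2)
  sig <- pmax(0, cos(2 * pi * 1.25 * (tt - 0.4)))^2
  pk <- bpm_peaks(sig, fps = 5)
  expect_equal(pk$n_peaks, 10)
  expect_equal(pk$bpm, 75)

  ramp <- bpm_peaks(seq(0, 1, length.out = 50), fps = 5)
  expect_equal(ramp$n_peaks, 0)

  tt60 <- seq(0, 60 - 0.2, by = 0.2)
  sig60 <- pmax(0, cos(2 * pi * 1.25 * (tt60 - 0.4)))^2
  expect_lte(abs(bpm_peaks(sig60, 5)$bpm - bpm_fft(sig60, 5)$bpm), 5)
})

test_that("contraction volume reduces to the masked magnitude sum", {
  f <- make_field(matrix(0, 5, 5))
  expect_equal(contraction_volume(f, contraction_mask(f)), 0)

  f$u[1, 1:3] <- 1 / 0.9616                        # three vectors of 1 um
  mask <- matrix(FALSE, 5, 5); mask[1, 1:3] <- TRUE
  expect_equal(contraction_volume(f, mask, 532.6, 532.6), 3, tolerance = 1e-12)

  # non-default block/norm areas stay explicit
  expect_equal(contraction_volume(f, mask, 133.15, 532.6), 3 * 133.15 / 532.6,
               tolerance = 1e-12)

  # brute-force oracle on an arbitrary field
  set.seed(71)
  g <- make_field(matrix(rnorm(64), 8, 8), matrix(rnorm(64), 8, 8))
  mk <- contraction_mask(g, 0.5)
  acc <- 0
  for (i in 1:8) for (j in 1:8) if (mk[i, j])
    acc <- acc + sqrt(g$u[i, j]^2 + g$v[i, j]^2) * 0.9616
  expect_equal(contraction_volume(g, mk), acc, tolerance = 1e-12)
})

test_that("the high/low contraction-volume split sits one sigma below max", {
  const <- cv_split(rep(3, 10))
  expect_true(all(const == "high"))

  s <- c(0, 0, 0, 10)
  lab <- cv_split(s)
  expect_equal(attr(lab, "cutoff"), 10 - sd(s))
  expect_identical(as.character(lab), c("low", "low", "low", "high"))

  expect_identical(as.character(cv_split(s * 37.5)), as.character(lab))
})

test_that("heat maps accumulate masks and magnitudes over frames", {
  off <- field_from_mask(matrix(FALSE, 8, 8))
  on <- field_from_mask(rbind(matrix(TRUE, 4, 8), matrix(FALSE, 4, 8)))
  hm <- heatmaps(list(off, on, off, on), fix_criteria())
  expect_true(all(hm$frequency_map >= 0 & hm$frequency_map <= 1))
  expect_equal(hm$frequency_map[1, 1], 0.5)
  expect_equal(hm$frequency_map[8, 8], 0)
  expect_equal(hm$magnitude_map[1, 1], 0.5)        # 1 um in half the frames

  static <- heatmaps(list(off, off), fix_criteria())
  expect_equal(max(static$frequency_map), 0)
  expect_equal(max(static$magnitude_map), 0)

  # frame order is irrelevant (pure accumulation)
  hm2 <- heatmaps(list(on, on, off, off), fix_criteria())
  expect_identical(hm$frequency_map, hm2$frequency_map)
  expect_identical(hm$magnitude_map, hm2$magnitude_map)

  # unequal amplitude, equal duty: frequency peaks tie, magnitude peaks do not
  mA <- matrix(FALSE, 8, 8); mA[2, 2] <- TRUE
  mB <- matrix(FALSE, 8, 8); mB[6, 6] <- TRUE
  strong <- field_from_mask(mA, mag_um = 2)
  weak <- field_from_mask(mB, mag_um = 0.5)
  hm3 <- heatmaps(list(strong, weak, field_from_mask(matrix(FALSE, 8, 8))),
                  fix_criteria())
  expect_equal(hm3$frequency_map[2, 2], hm3$frequency_map[6, 6])
  expect_gt(hm3$magnitude_map[2, 2], hm3$magnitude_map[6, 6])
})

test_that("high/low CV group comparison behaves like Welch statistics", {
  mkv <- function(speed) list(speed = matrix(speed, 4, 4),
                              valid = matrix(TRUE, 4, 4))
  mks <- function(e) list(e1 = matrix(e, 4, 4), e2 = matrix(-e, 4, 4),
                          valid = matrix(TRUE, 4, 4))
  # identical distributions in both groups -> p = 1 (t statistic 0)
  vels <- lapply(rep(c(1, 2, 3), 4), mkv)
  strs <- lapply(rep(c(.01, .02, .03), 4), mks)
  labels <- factor(rep(c("high", "low"), each = 6), levels = c("high", "low"))
  same <- compare_cv_groups(vels, strs, labels)
  expect_true(all(abs(same$p_value - 1) < 1e-9))

  # planted 10x speed in the high frames -> decisive separation
  set.seed(81)
  hi <- rnorm(10, 50, 2); lo <- rnorm(10, 5, 2)
  vels2 <- lapply(c(hi, lo), mkv)
  strs2 <- lapply(c(rnorm(10, .05, .005), rnorm(10, .01, .005)), mks)
  labels2 <- factor(rep(c("high", "low"), each = 10), levels = c("high", "low"))
  sep <- compare_cv_groups(vels2, strs2, labels2)
  expect_lt(max(sep$p_value), 0.001)

  # SEM against brute force
  expect_equal(sep$sem_high[1], sd(hi) / sqrt(10), tolerance = 1e-12)
  expect_equal(sep$mean_low[1], mean(lo), tolerance = 1e-12)
})

test_that("contraction metrics on a beating fixture find the planted rate", {
  sb <- slow_beat_fit()
  m <- contraction_metrics(sb$fit, fix_criteria())
  expect_equal(nrow(m$frames), 40)
  expect_lt(abs(m$bpm_fft$bpm - 15), 1)            # 0.25 Hz planted
  expect_lte(abs(m$bpm_peaks$bpm - m$bpm_fft$bpm), 5)
  expect_true(any(m$frames$cv > 0))
  cutoff <- max(m$frames$cv) - sd(m$frames$cv)
  expect_identical(as.character(m$frames$cv_label),
                   ifelse(m$frames$cv >= cutoff, "high", "low"))
})
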