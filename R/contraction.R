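#' Physiological contraction criteria
#'
#' Thresholds defining "contracting" tissue. The default displacement cutoff
#' is 0.14 um, the average in vivo shortening of a single sarcomere, so a
#' region moving by more than one sarcomere length counts as beating; the
#' conventional alternate of four sarcomere lengths (0.56 um) is carried
#' alongside. Regions smaller than `min_region_area_um2` (default 4840 um^2,
#' i.e. ten 24 px vector blocks of 532.6 um^2) are ignored by the
#' region/tree analyses.
#'
#' @param threshold_um displacement cutoff in microns (> 0).
#' @param alt_threshold_um optional stricter cutoff reported alongside.
#' @param min_region_area_um2 region area filter for the tree analysis.
#' @param block_area_um2 area covered by one vector block.
#' @param norm_area_um2 normalization block size for contraction volume.
#' @return Object of class `contraction_criteria`.
#' @export
contraction_criteria <- function(threshold_um = 0.14, alt_threshold_um = 0.56,
                                 min_region_area_um2 = 4840,
                                 block_area_um2 = 532.6,
                                 norm_area_um2 = 532.6) {
  if (threshold_um <= 0) stop_arg("'threshold_um' must be > 0")
  if (!is.null(alt_threshold_um) && any(alt_threshold_um <= 0))
    stop_arg("'alt_threshold_um' must be > 0")
  structure(list(threshold_um = threshold_um,
                 alt_threshold_um = alt_threshold_um,
                 min_region_area_um2 = min_region_area_um2,
                 block_area_um2 = block_area_um2,
                 norm_area_um2 = norm_area_um2),
            class = "contraction_criteria")
}

#' Binary contraction mask of a displacement field
#'
#' Grid points whose displacement magnitude exceeds the sarcomere-length
#' threshold: `|d| * pixel_size_um > threshold_um`. Invalid vectors are
#' never part of the mask.
#'
#' @param field a displacement field with `pixel_size_um` metadata.
#' @param threshold_um cutoff in microns (default one sarcomere, 0.14).
#' @return logical matrix on the vector grid.
#' @export
contraction_mask <- function(field, threshold_um = 0.14) {
  field_magnitude(field, "um") > threshold_um & field$valid
}

#' Beating area and field-of-view coverage
#'
#' @param mask logical contraction mask.
#' @param block_area_um2 area of one vector block (um^2).
#' @param valid optional validity matrix; the coverage denominator is the
#'   number of valid grid points (border windows carry no measurement), or
#'   all grid points when omitted.
#' @return `list(area_um2, coverage_pct)`.
#' @export
beating_area <- function(mask, block_area_um2 = 532.6, valid = NULL) {
  n_on <- sum(mask)
  denom <- if (is.null(valid)) length(mask) else sum(valid)
  list(area_um2 = n_on * block_area_um2,
       coverage_pct = 100 * n_on / denom)
}

#' Beating rate by FFT of the displacement signal
#'
#' Mean-detrends the signal, applies a Hann window, zero-pads to at least
#' 8x the record length, and reads the dominant frequency in
#' (0.2 Hz, fps/2); BPM is 60x that frequency. The spectral prominence
#' (peak power over median band power) qualifies the estimate; a flat or
#' aperiodic signal is reported as `NA` with `prominent = FALSE`, never as
#' 0 BPM.
#'
#' @param signal numeric displacement signal (one value per frame).
#' @param fps sampling rate (frames per second).
#' @param min_hz lower edge of the physiological search band.
#' @param min_prominence prominence required to trust the peak.
#' @return `list(bpm, freq_hz, prominence, prominent)`.
#' @export
bpm_fft <- function(signal, fps, min_hz = 0.2, min_prominence = 10) {
  n <- length(signal)
  if (n < 8) stop_arg("signal too short for spectral rate estimation")
  x <- signal - mean(signal)
  if (sd(x) < 1e-12)
    return(list(bpm = NA_real_, freq_hz = NA_real_, prominence = 0,
                prominent = FALSE))
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))   # Hann
  x <- x * w
  nfft <- 2^ceiling(log2(8 * n))
  pw <- Mod(stats::fft(c(x, numeric(nfft - n))))^2
  freq <- (seq_len(nfft) - 1) * fps / nfft
  band <- which(freq > min_hz & freq < fps / 2)
  p <- pw[band]
  i <- which.max(p)
  prom <- p[i] / max(stats::median(p), 1e-300)
  list(bpm = 60 * freq[band[i]], freq_hz = freq[band[i]],
       prominence = prom, prominent = prom >= min_prominence)
}

#' Beating rate by automated peak counting
#'
#' Counts local maxima exceeding `mean + 0.5 sd` of the signal, separated by
#' at least `refractory_s` seconds (default 0.33 s, i.e. a ceiling of about
#' 180 BPM, above the ~150 BPM that 5 FPS sampling can resolve);
#' `bpm = 60 * count / duration`.
#'
#' @param signal numeric displacement signal.
#' @param fps sampling rate.
#' @param refractory_s minimum peak separation in seconds.
#' @return `list(bpm, n_peaks, peak_frames)`.
#' @export
bpm_peaks <- function(signal, fps, refractory_s = 0.33) {
  n <- length(signal)
  thr <- mean(signal) + 0.5 * stats::sd(signal)
  if (!is.finite(thr)) thr <- Inf
  # only interior maxima count: a boundary sample cannot be confirmed as a
  # beat peak (a monotone ramp has no peaks)
  is_peak <- logical(n)
  for (i in seq_len(n)[-c(1, n)]) {
    is_peak[i] <- signal[i] > thr && signal[i] >= signal[i - 1] &&
      signal[i] > signal[i + 1]
  }
  cand <- which(is_peak)
  min_gap <- refractory_s * fps
  keep <- integer(0)
  for (i in cand) {
    if (length(keep) == 0 || i - keep[length(keep)] >= min_gap)
      keep <- c(keep, i)
  }
  duration_s <- n / fps
  list(bpm = 60 * length(keep) / duration_s, n_peaks = length(keep),
       peak_frames = keep)
}

#' Contraction volume of one frame
#'
#' Combined area-and-magnitude beating metric: the displacement magnitudes
#' of masked (contracting) vectors, each weighted by its block area and
#' normalized by the reference block size:
#' `cv = sum(|d|_um * block_area_um2) / norm_area_um2`. At the default
#' grid (24 px blocks, 532.6 um^2 both) this reduces to the plain sum of
#' supra-threshold displacement magnitudes in microns.
#'
#' @param field a displacement field.
#' @param mask logical contraction mask (see [contraction_mask()]).
#' @param block_area_um2,norm_area_um2 block and normalization areas.
#' @return scalar cv.
#' @export
contraction_volume <- function(field, mask, block_area_um2 = 532.6,
                               norm_area_um2 = 532.6) {
  m <- field_magnitude(field, "um")
  sum(m[mask & field$valid]) * block_area_um2 / norm_area_um2
}

#' Split a contraction-volume series into high and low frames
#'
#' "High CV" frames lie within one standard deviation below the maximum:
#' `cv >= max(cv) - sd(cv)`; the rest are "low". Labels are invariant to
#' uniform rescaling of the series.
#'
#' @param cv numeric contraction-volume series.
#' @return factor of labels `"high"`/`"low"` with attributes `cutoff` and
#'   `sigma`.
#' @export
cv_split <- function(cv) {
  sigma <- stats::sd(cv)
  if (!is.finite(sigma)) sigma <- 0
  cutoff <- max(cv) - sigma
  lab <- factor(ifelse(cv >= cutoff, "high", "low"), levels = c("high", "low"))
  attr(lab, "cutoff") <- cutoff
  attr(lab, "sigma") <- sigma
  lab
}

#' Beating frequency and magnitude heat maps
#'
#' Pure temporal accumulations on the vector grid: the frequency map is the
#' mean of the per-frame binary contraction masks (fraction of frames each
#' point spends contracting, in [0, 1]); the magnitude map is the mean
#' displacement magnitude in um. Both are invariant to frame order.
#'
#' @param fields list of displacement fields (e.g. `fit$fields`).
#' @param criteria a [contraction_criteria()].
#' @return `list(frequency_map, magnitude_map, grid_x, grid_y, n_frames)`.
#' @export
heatmaps <- function(fields, criteria = contraction_criteria()) {
  fields <- Filter(Negate(is.null), fields)
  if (length(fields) == 0) stop_arg("no fields")
  f1 <- fields[[1]]
  freq <- matrix(0, nrow(f1$u), ncol(f1$u))
  mag <- freq
  for (f in fields) {
    freq <- freq + contraction_mask(f, criteria$threshold_um)
    m <- field_magnitude(f, "um")
    m[!f$valid] <- 0
    mag <- mag + m
  }
  list(frequency_map = freq / length(fields),
       magnitude_map = mag / length(fields),
       grid_x = f1$grid_x, grid_y = f1$grid_y, n_frames = length(fields))
}

#' Compare kinematics between high- and low-CV frames
#'
#' For each group of frames, summarizes the per-frame maxima of speed,
#' tensile principal strain (max e1) and compressive principal strain
#' (min e2) as mean +- SEM, and tests high vs low with Welch's two-sample
#' t-test.
#'
#' @param velocities list of velocity fields ([velocity_fields()]).
#' @param strains list of strain fields ([strain_fields()] per frame).
#' @param labels factor from [cv_split()], one label per frame (frames
#'   without velocity/strain are skipped).
#' @return data.frame with one row per metric: group means, SEMs, n, and
#'   Welch p-value.
#' @export
compare_cv_groups <- function(velocities, strains, labels) {
  n <- length(labels)
  speed_max <- rep(NA_real_, n); e1_max <- rep(NA_real_, n)
  e2_min <- rep(NA_real_, n)
  for (t in seq_len(n)) {
    v <- if (t <= length(velocities)) velocities[[t]] else NULL
    s <- if (t <= length(strains)) strains[[t]] else NULL
    if (!is.null(v) && any(v$valid)) speed_max[t] <- max(v$speed[v$valid])
    if (!is.null(s) && any(s$valid)) {
      e1_max[t] <- max(s$e1[s$valid])
      e2_min[t] <- min(s$e2[s$valid])
    }
  }
  one <- function(metric, values) {
    hi <- values[labels == "high" & is.finite(values)]
    lo <- values[labels == "low" & is.finite(values)]
    p <- if (length(hi) >= 2 && length(lo) >= 2 &&
             (stats::sd(hi) > 0 || stats::sd(lo) > 0))
      stats::t.test(hi, lo)$p.value else NA_real_
    data.frame(metric = metric,
               mean_high = mean(hi), sem_high = stats::sd(hi) / sqrt(length(hi)),
               n_high = length(hi),
               mean_low = mean(lo), sem_low = stats::sd(lo) / sqrt(length(lo)),
               n_low = length(lo), p_value = p)
  }
  rbind(one("max_speed_um_s", speed_max),
        one("max_tensile_e1", e1_max),
        one("max_compressive_e2", e2_min))
}

#' Per-frame contraction metrics of an AR-DIC fit
#'
#' Convenience wrapper computing, for every measured frame: beating area and
#' coverage, contraction volume with the high/low split, the BPM estimates
#' (FFT and peak counter, on the spatial-mean displacement of grid points
#' that ever exceed the threshold), and the frequency/magnitude heat maps.
#'
#' @param fit an [ardic()] object.
#' @param criteria a [contraction_criteria()].
#' @return Object of class `contraction_metrics`: `frames` (data.frame),
#'   `bpm_fft`, `bpm_peaks`, `maps`, `signal`, `criteria`.
#' @export
contraction_metrics <- function(fit, criteria = contraction_criteria()) {
  stopifnot(inherits(fit, "ardic"))
  fields <- Filter(Negate(is.null), fit$fields)
  masks <- lapply(fields, contraction_mask, threshold_um = criteria$threshold_um)
  ever <- Reduce(`|`, masks)
  sig <- vapply(fields, function(f) {
    m <- field_magnitude(f, "um")
    sel <- ever & f$valid
    if (!any(sel)) 0 else mean(m[sel])
  }, numeric(1))
  frames <- do.call(rbind, lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    ba <- beating_area(masks[[i]], criteria$block_area_um2, f$valid)
    data.frame(frame = f$frame_index, reference = f$reference_index,
               area_um2 = ba$area_um2, coverage_pct = ba$coverage_pct,
               cv = contraction_volume(f, masks[[i]], criteria$block_area_um2,
                                       criteria$norm_area_um2))
  }))
  frames$cv_label <- cv_split(frames$cv)
  bf <- bpm_fft(sig, fit$fps)
  bp <- bpm_peaks(sig, fit$fps)
  structure(list(frames = frames, bpm_fft = bf, bpm_peaks = bp,
                 maps = heatmaps(fields, criteria), signal = sig,
                 criteria = criteria, fps = fit$fps),
            class = "contraction_metrics")
}

#' @export
print.contraction_metrics <- function(x, ...) {
  f <- x$frames
  cat(sprintf("contraction_metrics: %d frames\n", nrow(f)))
  cat(sprintf("  max beating area %.4g um^2 (coverage %.1f%%)\n",
              max(f$area_um2), max(f$coverage_pct)))
  if (is.na(x$bpm_fft$bpm)) {
    cat("  BPM: not detectable (flat or aperiodic displacement signal)\n")
  } else {
    cat(sprintf("  BPM %.1f (FFT%s), %.1f (peak counter)\n", x$bpm_fft$bpm,
                if (x$bpm_fft$prominent) "" else ", low prominence",
                x$bpm_peaks$bpm))
  }
  cat(sprintf("  CV: max %.3g, %d high frames (cutoff max - 1 sigma)\n",
              max(f$cv), sum(f$cv_label == "high")))
  invisible(x)
}
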