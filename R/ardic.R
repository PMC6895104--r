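#' Frobenius norm of a displacement field
#'
#' `sqrt(sum(u^2 + v^2))` over valid vectors (invalid vectors are excluded),
#' in px of the displacement matrix. This is the scalar score that drives
#' adaptive reference selection: near-zero for a quiescent frame measured
#' against a quiescent reference, large during a contraction, and slowly
#' growing under a static reference when inter-cycle drift accumulates.
#'
#' @param field a `displacement_field`.
#' @return A non-negative scalar (px).
#' @export
frobenius_norm <- function(field) {
  if (!any(field$valid)) stop_arg("all vectors invalid: Frobenius norm undefined")
  sqrt(sum(field$u[field$valid]^2 + field$v[field$valid]^2))
}

#' Initial adaptive-reference threshold estimate
#'
#' Estimates the noise floor of quiescent frames by running PIV between two
#' caller-designated rest frames and rounding the Frobenius norm of the
#' result *up* to the next multiple of `refine_step` (never below one step).
#' A norm of 1.25 with step 0.1 yields 1.3.
#'
#' @param stack an [image_stack()].
#' @param rest_frame_a,rest_frame_b indices of two visually quiescent frames.
#' @param schedule a [piv_schedule()].
#' @param refine_step rounding step (default 0.1).
#' @return `list(t0, norm)`: the rounded threshold and the raw norm.
#' @export
estimate_tadapt <- function(stack, rest_frame_a, rest_frame_b,
                            schedule = piv_schedule(), refine_step = 0.1) {
  stopifnot(inherits(stack, "image_stack"))
  f <- multipass_piv(get_frame(stack, rest_frame_a),
                     get_frame(stack, rest_frame_b), schedule)
  nrm <- frobenius_norm(f)
  list(t0 = round_up_to_step(nrm, refine_step), norm = nrm)
}

#' Adaptive-reference configuration
#'
#' @param initial_reference_index index of the initial (quiescent) reference
#'   frame.
#' @param t_adapt Frobenius-norm threshold (px) below which the current frame
#'   is adopted as the new reference.
#' @param refine logical; iterate `t_adapt` upward until the rest-frame
#'   baseline stops drifting (see [refine_tadapt()]).
#' @param refine_step threshold increment per refinement iteration (px).
#' @param refine_max_iters refinement iteration cap.
#' @param drift_tolerance allowed baseline slope (px of Frobenius norm per
#'   cycle) for refinement to terminate.
#' @param chain_references logical; if `TRUE`, displacement of each new
#'   reference at its adoption time is accumulated into subsequent fields so
#'   they approximate displacement from the *initial* reference (for tissues
#'   with real secular drift). Default `FALSE`: each field is relative to its
#'   recorded (rest-state) reference.
#' @return Object of class `ar_config`.
#' @export
ar_config <- function(initial_reference_index = 1L, t_adapt = NULL,
                      refine = FALSE, refine_step = 0.1,
                      refine_max_iters = 10L, drift_tolerance = 0.05,
                      chain_references = FALSE) {
  if (!is.null(t_adapt) && t_adapt <= 0) stop_arg("'t_adapt' must be > 0")
  if (refine_step <= 0) stop_arg("'refine_step' must be > 0")
  structure(list(initial_reference_index = as.integer(initial_reference_index),
                 t_adapt = t_adapt, refine = refine, refine_step = refine_step,
                 refine_max_iters = as.integer(refine_max_iters),
                 drift_tolerance = drift_tolerance,
                 chain_references = chain_references),
            class = "ar_config")
}

#' Adaptive Reference DIC over an image stack
#'
#' The core estimator. Every frame after the initial reference is measured
#' by multi-pass PIV against the currently active reference frame and its
#' Frobenius norm recorded; when the norm falls below `t_adapt` the frame is
#' judged to be at rest and becomes the reference for *subsequent* frames
#' (its own displacement is still reported against the old reference).
#' Because each adopted reference is a rest state near zero absolute
#' displacement, re-referencing removes the error build-up that a static
#' reference accumulates from minor frame shifts after each contraction
#' cycle, while displacements remain absolute (not frame-to-frame relative).
#'
#' With `ar = FALSE` the initial reference is kept throughout (conventional
#' static-reference DIC), which is the comparison mode for drift studies.
#'
#' @param stack an [image_stack()].
#' @param schedule a [piv_schedule()].
#' @param config an [ar_config()]; `config$t_adapt` must be set unless
#'   `refine = TRUE` inside, or `ar = FALSE`.
#' @param ar logical; `FALSE` disables adaptive re-referencing.
#' @param min_peak_ratio correlation validity cutoff, passed to the PIV
#'   engine.
#' @param verbose log reference switches.
#' @return Object of class `ardic`: list with `fields` (one
#'   `displacement_field` per frame, the reference frame itself holding an
#'   exact zero field), `trace` (data.frame `frame, reference, norm,
#'   switched`), `config`, `schedule`, `fps`, `pixel_size_um`.
#' @export
ardic <- function(stack, schedule = piv_schedule(), config = ar_config(),
                  ar = TRUE, min_peak_ratio = 1.2, verbose = FALSE) {
  stopifnot(inherits(stack, "image_stack"))
  nt <- n_frames(stack)
  r0 <- config$initial_reference_index
  if (r0 < 1 || r0 > nt) stop_arg("initial_reference_index out of range")
  t_adapt <- config$t_adapt
  if (ar && is.null(t_adapt))
    stop_arg("config$t_adapt must be set (or use refine_tadapt())")
  if (config$refine)
    return(refine_tadapt(stack, schedule, config, min_peak_ratio = min_peak_ratio,
                         verbose = verbose)$fit)

  ref <- r0
  fields <- vector("list", nt)
  trace <- data.frame(frame = seq_len(nt), reference = NA_integer_,
                      norm = NA_real_, switched = FALSE)
  chain_u <- 0; chain_v <- 0                 # accumulated ref offset (chained mode)
  for (t in seq_len(nt)) {
    if (t == ref && t == r0) {
      f <- multipass_piv(get_frame(stack, ref), get_frame(stack, t), schedule,
                         min_peak_ratio = min_peak_ratio)
      f$u[] <- 0; f$v[] <- 0                 # self-reference: exact zero field
      f$frame_index <- t; f$reference_index <- ref
      f$pixel_size_um <- stack$pixel_size_um
      fields[[t]] <- f
      trace$reference[t] <- ref
      trace$norm[t] <- 0
      next
    }
    if (t < r0) { trace$reference[t] <- NA_integer_; next }
    f <- multipass_piv(get_frame(stack, ref), get_frame(stack, t), schedule,
                       min_peak_ratio = min_peak_ratio)
    f$frame_index <- t; f$reference_index <- ref
    f$pixel_size_um <- stack$pixel_size_um
    nrm <- frobenius_norm(f)
    raw_u <- f$u; raw_v <- f$v
    if (config$chain_references) {
      f$u <- f$u + chain_u; f$v <- f$v + chain_v
    }
    fields[[t]] <- f
    trace$reference[t] <- ref
    trace$norm[t] <- nrm
    if (ar && nrm < t_adapt) {
      trace$switched[t] <- TRUE
      if (config$chain_references) {
        chain_u <- chain_u + raw_u; chain_v <- chain_v + raw_v
      }
      if (verbose) message(sprintf("frame %d adopted as reference (norm %.3f < %.3f)",
                                   t, nrm, t_adapt))
      ref <- t
    }
  }
  if (ar && !any(trace$switched)) {
    cm <- cycle_minima(trace, stack$fps)
    if (nrow(cm) >= 3 &&
        stats::cor(cm$cycle, cm$min_norm) > 0.8 &&
        cm$min_norm[nrow(cm)] > cm$min_norm[1])
      warning("no reference switch occurred and the baseline norm grows ",
              "monotonically; t_adapt is likely too small", call. = FALSE)
  }
  structure(list(fields = fields, trace = trace, config = config,
                 schedule = schedule, t_adapt = t_adapt, ar = ar,
                 fps = stack$fps, pixel_size_um = stack$pixel_size_um),
            class = "ardic")
}

# Per-cycle baseline minima of the norm series. The dominant beat period is
# taken from the FFT of the (mean-removed) norm series; the frame axis is
# split into consecutive one-period bins and the minimum norm of each bin is
# the cycle's baseline score.
cycle_minima <- function(trace, fps) {
  ok <- is.finite(trace$norm) & trace$norm > 0
  x <- trace$norm[ok]
  n <- length(x)
  if (n < 8) return(data.frame(cycle = 1L, min_norm = min(x)))
  # linear detrend first: under a drifting baseline the record-length trend
  # would otherwise dominate the spectrum and hide the beat period
  xd <- stats::residuals(stats::lm(x ~ seq_len(n)))
  sp <- Mod(stats::fft(xd))[2:(floor(n / 2))]
  k <- which.max(sp)                         # k cycles over the record
  period <- n / k
  period <- max(2, min(period, n / 2))
  bins <- pmin(floor((seq_len(n) - 1) / period) + 1, max(1, floor(n / period)))
  mins <- tapply(x, bins, min)
  data.frame(cycle = as.integer(names(mins)), min_norm = as.numeric(mins))
}

# Least-squares slope of baseline minima vs cycle index (px per cycle).
baseline_drift <- function(trace, fps) {
  cm <- cycle_minima(trace, fps)
  if (nrow(cm) < 3) return(0)
  unname(stats::coef(stats::lm(min_norm ~ cycle, data = cm))[2])
}

#' Iterative refinement of the adaptive-reference threshold
#'
#' Runs [ardic()] at the current `t_adapt`, fits the slope of the per-cycle
#' baseline (minimum) Frobenius norms, and, while the baseline drifts more
#' than `drift_tolerance` (px/cycle), raises `t_adapt` by `refine_step` and
#' repeats. Terminates at the first threshold whose baseline is flat; errors
#' if `refine_max_iters` is exhausted, reporting the full history.
#'
#' @param stack an [image_stack()].
#' @param schedule a [piv_schedule()].
#' @param config an [ar_config()] with `t_adapt` set to the initial estimate
#'   (see [estimate_tadapt()]).
#' @param min_peak_ratio correlation validity cutoff.
#' @param verbose log iterations.
#' @return `list(t_final, fit, history)` where `history` is a data.frame
#'   `iteration, t_adapt, baseline_drift, n_switches`.
#' @export
refine_tadapt <- function(stack, schedule = piv_schedule(),
                          config = ar_config(t_adapt = 0.1),
                          min_peak_ratio = 1.2, verbose = FALSE) {
  if (is.null(config$t_adapt)) stop_arg("config$t_adapt must hold the initial estimate")
  t_cur <- config$t_adapt
  history <- data.frame(iteration = integer(), t_adapt = numeric(),
                        baseline_drift = numeric(), n_switches = integer())
  cfg <- config; cfg$refine <- FALSE
  for (it in seq_len(config$refine_max_iters)) {
    cfg$t_adapt <- t_cur
    fit <- ardic(stack, schedule, cfg, ar = TRUE,
                 min_peak_ratio = min_peak_ratio, verbose = FALSE)
    drift <- baseline_drift(fit$trace, stack$fps)
    history <- rbind(history, data.frame(iteration = it, t_adapt = t_cur,
                                         baseline_drift = drift,
                                         n_switches = sum(fit$trace$switched)))
    if (verbose) message(sprintf("refine iter %d: t_adapt %.3f, baseline drift %.4f px/cycle",
                                 it, t_cur, drift))
    if (abs(drift) <= config$drift_tolerance) {
      fit$t_adapt_history <- history
      return(list(t_final = t_cur, fit = fit, history = history))
    }
    t_cur <- t_cur + config$refine_step
  }
  stop_arg("refine_max_iters exhausted without a flat baseline; history: ",
           paste(sprintf("(%d: t=%.2f, drift=%.4f)", history$iteration,
                         history$t_adapt, history$baseline_drift),
                 collapse = " "))
}

#' @export
print.ardic <- function(x, ...) {
  tr <- x$trace
  cat(sprintf("AR-DIC fit: %d frames, %s reference\n", nrow(tr),
              if (x$ar) "adaptive" else "static"))
  if (x$ar) cat(sprintf("  t_adapt = %.3f px; %d reference switches\n",
                        x$t_adapt, sum(tr$switched)))
  ok <- is.finite(tr$norm)
  cat(sprintf("  Frobenius norm: median %.3f, max %.3f px\n",
              stats::median(tr$norm[ok]), max(tr$norm[ok])))
  invisible(x)
}

#' @export
summary.ardic <- function(object, ...) {
  tr <- object$trace
  mx <- vapply(object$fields, function(f) {
    if (is.null(f) || !any(f$valid)) return(NA_real_)
    max(field_magnitude(f)[f$valid])
  }, numeric(1))
  out <- list(n_frames = nrow(tr), ar = object$ar, t_adapt = object$t_adapt,
              n_switches = sum(tr$switched),
              max_displacement_px = max(mx, na.rm = TRUE),
              max_displacement_um = max(mx, na.rm = TRUE) * object$pixel_size_um,
              peak_frame = which.max(mx),
              norm_median = stats::median(tr$norm[is.finite(tr$norm)]),
              t_adapt_history = object$t_adapt_history)
  class(out) <- "summary.ardic"
  out
}

#' @export
print.summary.ardic <- function(x, ...) {
  cat(sprintf("AR-DIC summary: %d frames (%s reference)\n", x$n_frames,
              if (x$ar) "adaptive" else "static"))
  if (x$ar) cat(sprintf("  t_adapt %.3f px, %d switches\n", x$t_adapt, x$n_switches))
  cat(sprintf("  max displacement %.3f px (%.3f um) at frame %d\n",
              x$max_displacement_px, x$max_displacement_um, x$peak_frame))
  if (!is.null(x$t_adapt_history)) {
    cat("  t_adapt refinement: ",
        paste(sprintf("%.2f", x$t_adapt_history$t_adapt), collapse = " -> "), "\n")
  }
  invisible(x)
}

#' Plot an AR-DIC fit
#'
#' `type = "trace"` plots the Frobenius-norm time series with reference
#' switches marked and the threshold line; `type = "field"` shows the
#' displacement magnitude (um) of one frame as an image.
#'
#' @param x an `ardic` object.
#' @param type `"trace"` or `"field"`.
#' @param frame frame index for `type = "field"` (default: peak frame).
#' @param ... passed to the underlying plotting function.
#' @export
plot.ardic <- function(x, type = c("trace", "field"), frame = NULL, ...) {
  type <- match.arg(type)
  if (type == "trace") {
    tr <- x$trace
    plot(tr$frame, tr$norm, type = "l", xlab = "frame",
         ylab = "Frobenius norm (px)", ...)
    if (x$ar) {
      graphics::abline(h = x$t_adapt, lty = 2)
      graphics::points(tr$frame[tr$switched], tr$norm[tr$switched], pch = 19)
    }
  } else {
    if (is.null(frame)) frame <- summary(x)$peak_frame
    f <- x$fields[[frame]]
    m <- field_magnitude(f, "um")
    graphics::image(f$grid_x, f$grid_y, t(m), ylim = rev(range(f$grid_y)),
                    xlab = "x (px)", ylab = "y (px)",
                    main = sprintf("frame %d |d| (um)", frame), ...)
  }
  invisible(x)
}
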