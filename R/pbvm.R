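## Phase-based motion magnification without reconstruction: band-pass the
## unwrapped sub-band phase in time, amplify, and pool everything into one
## respiratory motion signal.

#' Temporal band-pass configuration
#'
#' The respiratory band is 0.3-3.0 Hz (absolute bandwidth 2.7 Hz); the filter
#' is an ideal (hard frequency-domain mask) band-pass that also removes DC.
#'
#' @param f_lo,f_hi band edges in Hz, `0 < f_lo < f_hi`.
#' @param filter_kind only `"ideal"` is implemented.
#' @return An object of class `bandpass_config`.
#' @export
bandpass_config <- function(f_lo = 0.3, f_hi = 3.0, filter_kind = "ideal") {
  if (!identical(filter_kind, "ideal"))
    rr_abort("only the ideal filter is implemented", "rr_config_error")
  if (!is.finite(f_lo) || !is.finite(f_hi) || f_lo <= 0 || f_hi <= f_lo)
    rr_abort("need 0 < f_lo < f_hi", "rr_config_error")
  structure(list(f_lo = f_lo, f_hi = f_hi, filter_kind = filter_kind,
                 bandwidth = f_hi - f_lo),
            class = "bandpass_config")
}

check_band_vs_fps <- function(cfg, fps) {
  if (cfg$f_hi >= fps / 2)
    rr_abort(sprintf("f_hi = %g Hz is at or above Nyquist (fps = %g)",
                     cfg$f_hi, fps), "rr_config_error")
  invisible(TRUE)
}

# DFT bin mask for the ideal band-pass: TRUE where |frequency| is in
# [f_lo, f_hi]. DC (and any out-of-band bin) is zeroed.
ideal_band_mask <- function(n, fps, cfg) {
  f <- (0:(n - 1L)) * fps / n
  f_abs <- pmin(f, fps - f)
  f_abs >= cfg$f_lo & f_abs <= cfg$f_hi
}

#' Ideal temporal band-pass filter
#'
#' Hard discrete-Fourier-domain mask keeping bins with absolute frequency in
#' `[f_lo, f_hi]`; DC and out-of-band bins are zeroed, so the output is real
#' and zero-mean. Linear; exact pass-through for in-band exact-bin tones.
#'
#' @param series real time series (vector) or a `T x P` matrix filtered
#'   column-wise.
#' @param fps sampling rate in Hz.
#' @param cfg a [bandpass_config()]; `f_hi` must be below Nyquist.
#' @return Filtered series, same shape as the input.
#' @export
temporal_bandpass <- function(series, fps, cfg = bandpass_config()) {
  check_band_vs_fps(cfg, fps)
  if (is.matrix(series)) {
    n <- nrow(series)
    if (n < 4L) rr_abort("series too short to filter", "rr_validation_error")
    keep <- ideal_band_mask(n, fps, cfg)
    sp <- stats::mvfft(series)
    sp[!keep, ] <- 0
    Re(stats::mvfft(sp, inverse = TRUE)) / n
  } else {
    n <- length(series)
    if (n < 4L) rr_abort("series too short to filter", "rr_validation_error")
    keep <- ideal_band_mask(n, fps, cfg)
    sp <- stats::fft(series)
    sp[!keep] <- 0
    Re(stats::fft(sp, inverse = TRUE)) / n
  }
}

#' Band-pass and amplify sub-band phase across a pyramid stack
#'
#' For every oriented sub-band and every pixel above the amplitude floor:
#' unwrap the phase in time, ideal-band-pass it to isolate the motion term
#' `B = omega * delta(t)`, and scale it so the stored series carries the
#' motion of the magnified video, `(1 + alpha) * B` (displacement gain
#' `1 + alpha`; at `alpha = 0` the series is the band-passed phase itself).
#' No magnified video is ever rendered. Per-pixel weights are the time-mean
#' squared amplitudes, which later drive the weighted pooling.
#'
#' @param stack a [build_pyramid_stack()] result (>= 4 frames).
#' @param cfg a [bandpass_config()].
#' @param alpha amplification factor (default 40).
#' @param amp_floor_rel amplitude floor relative to the input intensity
#'   maximum; pixels below it are excluded.
#' @return An object of class `phase_signal_set`: per-band zero-mean series
#'   matrices (`T x P_retained`), weights, alpha, and provenance.
#' @export
amplify_phase <- function(stack, cfg = bandpass_config(), alpha = 40,
                          amp_floor_rel = 1e-6) {
  if (alpha < 0) rr_abort("alpha must be >= 0", "rr_config_error")
  check_band_vs_fps(cfg, stack$fps)
  nt <- stack$n_frames
  floor_abs <- amp_floor_rel * stack$input_max
  series <- list(); weights <- list(); band_ids <- character(0)
  for (s in seq_len(stack$levels)) {
    for (o in seq_len(stack$orientations)) {
      cs <- stack$bands[[s]][[o]]
      cm <- matrix(cs, nt, prod(stack$dims))           # T x (H*W)
      amp <- Mod(cm)
      mean_amp <- colMeans(amp)
      keep <- mean_amp > floor_abs      # strict: all-zero input retains nothing
      if (!any(keep)) next
      phase <- unwrap_phase_mat(Arg(cm[, keep, drop = FALSE]))
      b <- temporal_bandpass(phase, stack$fps, cfg)
      id <- sprintf("s%d.o%d", s, o)
      series[[id]] <- (1 + alpha) * b
      weights[[id]] <- colMeans(amp[, keep, drop = FALSE]^2)
      band_ids <- c(band_ids, id)
    }
  }
  if (length(series) == 0L)
    rr_abort("all pixels below the amplitude floor: no signal",
             "rr_empty_signal_error")
  structure(list(series = series, weights = weights, alpha = alpha,
                 cfg = cfg, fps = stack$fps, clip_id = stack$clip_id,
                 band_ids = band_ids, n_frames = nt),
            class = "phase_signal_set")
}

#' Merge phase signal sets into one pixel pool
#'
#' Combines the per-band series and weights of several [amplify_phase()]
#' results (e.g. the thoracodorsal and tail ROIs) so [aggregate_signal()]
#' pools them jointly — the two regions share one respiratory rhythm.
#'
#' @param sets list of `phase_signal_set` objects.
#' @return A single `phase_signal_set`.
#' @export
merge_signal_sets <- function(sets) {
  sets <- Filter(Negate(is.null), sets)
  if (length(sets) == 0L)
    rr_abort("no signal sets to merge", "rr_empty_signal_error")
  out <- sets[[1L]]
  if (length(sets) > 1L) {
    for (k in 2:length(sets)) {
      nm <- paste0("roi", k, ".", names(sets[[k]]$series))
      out$series[nm] <- sets[[k]]$series
      out$weights[nm] <- sets[[k]]$weights
      out$band_ids <- c(out$band_ids, nm)
    }
  }
  out
}

#' Pool amplified phase series into one respiratory signal
#'
#' Amplitude-squared-weighted mean over all pixels, orientations and scales,
#' with per-series sign alignment: local phase sign depends on the local
#' gradient direction, so antiphase edges would cancel under naive
#' averaging. Each series is flipped if negatively correlated with the
#' highest-weight series, pooled, then re-aligned once against the pooled
#' estimate. Output is zero-mean.
#'
#' @param set a [amplify_phase()] result (optionally merged across ROIs).
#' @return An object of class `respiratory_signal` with fields `values`,
#'   `fps`, `provenance`.
#' @export
aggregate_signal <- function(set) {
  s_mat <- do.call(cbind, set$series)
  w <- unlist(set$weights, use.names = FALSE)
  if (length(w) == 0L || sum(w) <= 0)
    rr_abort("zero total weight: no signal to aggregate",
             "rr_empty_signal_error")
  align_to <- function(ref) {
    cc <- suppressWarnings(as.numeric(stats::cor(ref, s_mat)))
    sgn <- ifelse(is.na(cc) | cc >= 0, 1, -1)
    as.numeric(s_mat %*% (w * sgn)) / sum(w)
  }
  ref0 <- s_mat[, which.max(w)]
  pooled <- align_to(ref0)
  if (stats::sd(pooled) > 0) pooled <- align_to(pooled)
  respiratory_signal(pooled - mean(pooled), set$fps,
                     provenance = list(clip_id = set$clip_id,
                                       alpha = set$alpha,
                                       bands = set$band_ids))
}

#' Construct a respiratory signal
#'
#' @param values real 1-D series (amplified phase units, radians).
#' @param fps sampling rate in Hz.
#' @param provenance free-form list (clip id, window, ROI labels).
#' @return An object of class `respiratory_signal`.
#' @export
respiratory_signal <- function(values, fps, provenance = list()) {
  if (!all(is.finite(values)))
    rr_abort("signal values must be finite", "rr_validation_error")
  structure(list(values = as.numeric(values), fps = fps,
                 provenance = provenance),
            class = "respiratory_signal")
}

#' Write a respiratory signal as a two-column CSV (time_s, value)
#' @param signal a [respiratory_signal()].
#' @param path output CSV path.
#' @export
save_signal <- function(signal, path) {
  utils::write.csv(
    data.frame(time_s = (seq_along(signal$values) - 1L) / signal$fps,
               value = signal$values),
    path, row.names = FALSE)
  invisible(path)
}
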