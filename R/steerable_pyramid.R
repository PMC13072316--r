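## Complex steerable pyramid, built in the frequency domain.
##
## Dialect (declared, configurable by its own invariants rather than assumed
## to match any particular binary): non-decimated (every sub-band at full
## frame resolution), octave radial bandwidth with raised-cosine-in-log
## profiles, 8 orientation windows spanning 180 degrees, analytic (single
## half-plane) response so coefficients are complex with Arg = local spatial
## phase. The squared filters sum to 1 pointwise (tight frame), so
## reconstruction and the energy check are exact to machine precision.

fft2 <- function(m) stats::fft(m)
ifft2 <- function(m) stats::fft(m, inverse = TRUE) / length(m)

# Signed frequency grid in (-pi, pi] for an n-sample dimension.
freq_grid_1d <- function(n) {
  k <- 0:(n - 1L)
  2 * pi * ifelse(k <= n / 2, k, k - n) / n
}

# Raised-cosine-in-log2 lowpass: 1 for r <= rc/2, 0 for r >= rc.
lo_profile <- function(r, rc) {
  out <- numeric(length(r))
  out[r <= rc / 2] <- 1
  mid <- r > rc / 2 & r < rc
  out[mid] <- cos(pi / 2 * log2(2 * r[mid] / rc))
  out
}
hi_profile <- function(r, rc) sqrt(pmax(0, 1 - lo_profile(r, rc)^2))

max_pyramid_levels <- function(h, w) max(1L, floor(log2(min(h, w))) - 2L)

#' Adaptive pyramid depth for a frame size
#'
#' Depth rule: `clamp(floor(log2(min(H, W))) - 4, 1, 4)`, i.e. keep the
#' coarsest band at roughly 16 px or more, within the 1-4 level range the
#' method uses.
#'
#' @param height,width frame size in pixels, both `>= 8`.
#' @return Integer level count in 1..4.
#' @export
adaptive_levels <- function(height, width) {
  if (min(height, width) < 8L)
    rr_abort("frame smaller than 8 px cannot be decomposed", "rr_too_small_error")
  min(max(floor(log2(min(height, width))) - 4L, 1L), 4L)
}

# Filter bank for an h x w frame: radial band masks, angular windows,
# analytic half-plane doubling masks. All masks are h x w matrices.
csp_filters <- function(h, w, levels, orientations = 8L) {
  if (levels < 1L || levels > max_pyramid_levels(h, w))
    rr_abort(sprintf("%d levels too deep for a %d x %d frame", levels, h, w),
             "rr_decomposition_error")
  wx <- matrix(rep(freq_grid_1d(w), each = h), h, w)
  wy <- matrix(rep(freq_grid_1d(h), w), h, w)
  r <- sqrt(wx^2 + wy^2)
  theta <- atan2(wy, wx)
  hi0 <- matrix(hi_profile(r, pi), h, w)
  lo <- matrix(lo_profile(r, pi), h, w)
  radial <- vector("list", levels)
  for (s in seq_len(levels)) {
    rc <- pi / 2^s
    radial[[s]] <- lo * matrix(hi_profile(r, rc), h, w)
    lo <- lo * matrix(lo_profile(r, rc), h, w)
  }
  q <- orientations
  ang <- vector("list", q)
  raw <- lapply(seq_len(q), function(o)
    abs(cos(theta - (o - 1) * pi / q))^(q - 1))
  norm <- sqrt(Reduce(`+`, lapply(raw, function(g) g^2)))
  masks <- vector("list", q)
  for (o in seq_len(q)) {
    ang[[o]] <- raw[[o]] / norm
    co <- cos(theta - (o - 1) * pi / q)
    masks[[o]] <- 2 * (co > 1e-12) + 1 * (abs(co) <= 1e-12)
  }
  list(h = h, w = w, levels = levels, orientations = q,
       hi0 = hi0, lo_final = lo, radial = radial, angular = ang,
       analytic = masks, center_frequencies = pi / 2^seq_len(levels))
}

#' Decompose one frame into a complex steerable pyramid
#'
#' Frequency-domain construction with analytic (half-plane) oriented band
#' filters; linear in the input. Coefficient modulus is local amplitude,
#' coefficient argument is local spatial phase — the carrier of sub-pixel
#' motion for the whole method.
#'
#' @param frame numeric H x W matrix.
#' @param levels pyramid depth; `NULL` uses [adaptive_levels()].
#' @param orientations number of orientation bands over 180 degrees.
#' @param filters optional precomputed filter bank (internal reuse).
#' @return An object of class `steerable_pyramid`: oriented complex bands
#'   `bands[[scale]][[orientation]]`, real `high`/`low` residuals, and the
#'   nominal band center frequencies in radians/pixel.
#' @export
build_pyramid <- function(frame, levels = NULL, orientations = 8L,
                          filters = NULL) {
  h <- nrow(frame); w <- ncol(frame)
  levels <- levels %||% adaptive_levels(h, w)
  if (is.null(filters))
    filters <- csp_filters(h, w, levels, orientations)
  ff <- fft2(frame)
  bands <- vector("list", levels)
  for (s in seq_len(levels)) {
    bands[[s]] <- vector("list", orientations)
    for (o in seq_len(orientations)) {
      bf <- filters$radial[[s]] * filters$angular[[o]] * filters$analytic[[o]]
      bands[[s]][[o]] <- ifft2(ff * bf)
    }
  }
  structure(
    list(bands = bands,
         high = Re(ifft2(ff * filters$hi0)),
         low = Re(ifft2(ff * filters$lo_final)),
         levels = levels, orientations = orientations,
         center_frequencies = filters$center_frequencies,
         dims = c(h, w)),
    class = "steerable_pyramid")
}

#' Reconstruct a frame from its pyramid (self-test of the filter bank)
#'
#' The analysis filters double as synthesis filters; with squared filters
#' summing to 1 the round trip is exact to machine precision. The RR
#' pipeline itself never reconstructs — this exists to verify the
#' decomposition.
#'
#' @param pyr a `steerable_pyramid` from [build_pyramid()].
#' @return The reconstructed H x W frame.
#' @export
reconstruct <- function(pyr) {
  h <- pyr$dims[1]; w <- pyr$dims[2]
  filters <- csp_filters(h, w, pyr$levels, pyr$orientations)
  acc <- fft2(pyr$high) * filters$hi0 + fft2(pyr$low) * filters$lo_final
  for (s in seq_len(pyr$levels))
    for (o in seq_len(pyr$orientations)) {
      b <- pyr$bands[[s]][[o]]
      if (is.null(dim(b)) || !all(dim(b) == c(h, w)))
        rr_abort("sub-band shape does not match pyramid dims",
                 "rr_structure_error")
      acc <- acc + fft2(Re(b)) * (filters$radial[[s]] * filters$angular[[o]])
    }
  Re(ifft2(acc))
}

#' Decompose every frame of a clip
#'
#' @param clip a [video_clip()].
#' @param levels pyramid depth; `NULL` uses [adaptive_levels()].
#' @param orientations orientation bands per level.
#' @return An object of class `pyramid_stack`: per-band complex arrays of
#'   dimension `c(T, H, W)` in `bands[[scale]][[orientation]]`, real residual
#'   stacks, fps and provenance.
#' @export
build_pyramid_stack <- function(clip, levels = NULL, orientations = 8L) {
  h <- frame_h(clip); w <- frame_w(clip); nt <- n_frames(clip)
  levels <- levels %||% adaptive_levels(h, w)
  filters <- csp_filters(h, w, levels, orientations)
  bands <- lapply(seq_len(levels), function(s)
    lapply(seq_len(orientations), function(o)
      array(complex(real = 0), c(nt, h, w))))
  high <- array(0, c(nt, h, w)); low <- array(0, c(nt, h, w))
  for (t in seq_len(nt)) {
    pyr <- build_pyramid(get_frame(clip, t - 1L), levels, orientations, filters)
    for (s in seq_len(levels))
      for (o in seq_len(orientations))
        bands[[s]][[o]][t, , ] <- pyr$bands[[s]][[o]]
    high[t, , ] <- pyr$high; low[t, , ] <- pyr$low
  }
  structure(
    list(bands = bands, high = high, low = low, levels = levels,
         orientations = orientations,
         center_frequencies = filters$center_frequencies,
         fps = clip$fps, clip_id = clip$clip_id,
         input_max = max(abs(clip$frames)), dims = c(h, w), n_frames = nt),
    class = "pyramid_stack")
}

# Wrap successive phase differences into (-pi, pi] and re-integrate.
unwrap_phase <- function(p) {
  if (length(p) < 2L) return(p)
  d <- diff(p)
  p[1] + c(0, cumsum(atan2(sin(d), cos(d))))
}

# Column-wise temporal unwrap of a T x P phase matrix.
unwrap_phase_mat <- function(p) {
  if (nrow(p) < 2L) return(p)
  d <- p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE]
  dw <- atan2(sin(d), cos(d))
  sweep(rbind(0, col_cumsum(dw)), 2, p[1L, ], `+`)
}

#' Temporally unwrapped phase at one pyramid pixel
#'
#' Extracts `Arg(coefficient)` across frames at one (scale, orientation,
#' pixel) and unwraps it in time (adding multiples of 2*pi so successive
#' differences stay in `(-pi, pi]`); no spatial unwrapping. Pixels whose
#' time-mean amplitude is below `1e-6 *` the input intensity maximum carry
#' noise phase and are flagged via the `"low_amplitude"` attribute.
#'
#' @param stack a [build_pyramid_stack()] result.
#' @param scale level index, 1-based (1 = finest).
#' @param orientation orientation index, 1-based.
#' @param pixel `c(x, y)` 0-based pixel coordinates.
#' @return Numeric vector of unwrapped phase in radians, first sample in
#'   `(-pi, pi]`, with attribute `low_amplitude` (logical).
#' @export
phase_series <- function(stack, scale, orientation, pixel) {
  if (scale < 1L || scale > stack$levels ||
      orientation < 1L || orientation > stack$orientations)
    rr_abort("scale/orientation index out of range", "rr_bounds_error")
  x <- pixel[1]; y <- pixel[2]
  if (x < 0 || x >= stack$dims[2] || y < 0 || y >= stack$dims[1])
    rr_abort("pixel out of range", "rr_bounds_error")
  cs <- stack$bands[[scale]][[orientation]][, y + 1L, x + 1L]
  low_amp <- mean(Mod(cs)) < 1e-6 * stack$input_max
  if (low_amp)
    rr_warn("time-mean amplitude below floor: phase unreliable",
            "rr_low_amplitude")
  structure(unwrap_phase(Arg(cs)), low_amplitude = low_amp)
}
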