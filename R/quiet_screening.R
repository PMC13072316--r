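## Quiet-state screening: dense optical flow over an ROI, integrated into a
## per-window motion amplitude, thresholded at 1.5 px over 10-s windows.

# Column-wise cumulative sum without apply(): one flattened cumsum, then
# subtract each column's carried-over total.
col_cumsum <- function(m) {
  h <- nrow(m); w <- ncol(m)
  cs <- matrix(cumsum(m), h, w)
  if (w > 1L) cs <- sweep(cs, 2L, c(0, cs[h, -w]), `-`)
  cs
}

# Sliding-window sum with radius r (window (2r+1)^2), zero-padded, via
# separable cumulative sums.
box_sum <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  cs <- col_cumsum(rbind(matrix(0, r + 1L, w), m, matrix(0, r, w)))
  vert <- cs[(2L * r + 2L):(h + 2L * r + 1L), , drop = FALSE] -
          cs[1:h, , drop = FALSE]
  cs2 <- t(col_cumsum(t(cbind(matrix(0, h, r + 1L), vert, matrix(0, h, r)))))
  cs2[, (2L * r + 2L):(w + 2L * r + 1L), drop = FALSE] - cs2[, 1:w, drop = FALSE]
}

# Bilinear sampling of matrix m at continuous 1-based coordinates (xm, ym),
# clamped to the image domain.
bilinear_sample <- function(m, xm, ym) {
  h <- nrow(m); w <- ncol(m)
  xm <- pmin(pmax(xm, 1), w); ym <- pmin(pmax(ym, 1), h)
  x0 <- pmin(floor(xm), w - 1L); y0 <- pmin(floor(ym), h - 1L)
  fx <- xm - x0; fy <- ym - y0
  i00 <- (x0 - 1L) * h + y0
  v00 <- m[i00];     v10 <- m[i00 + h]
  v01 <- m[i00 + 1L]; v11 <- m[i00 + h + 1L]
  (1 - fy) * ((1 - fx) * v00 + fx * v10) + fy * ((1 - fx) * v01 + fx * v11)
}

# Iterative dense Lucas-Kanade between two frames. Returns per-pixel (u, v)
# and a validity mask from the structure-tensor minimum eigenvalue (flat
# regions carry no flow information and are excluded from the summary).
lk_pair <- function(i1, i2, win_radius = 3L, n_iter = 3L, eig_rel_floor = 0.05,
                    grids = NULL) {
  h <- nrow(i1); w <- ncol(i1)
  ix <- (cbind(i1[, -1], i1[, w]) - cbind(i1[, 1], i1[, -w])) / 2
  iy <- (rbind(i1[-1, ], i1[h, ]) - rbind(i1[1, ], i1[-h, ])) / 2
  sxx <- box_sum(ix * ix, win_radius)
  sxy <- box_sum(ix * iy, win_radius)
  syy <- box_sum(iy * iy, win_radius)
  tr <- sxx + syy
  lam2 <- (tr - sqrt((sxx - syy)^2 + 4 * sxy^2)) / 2
  det <- sxx * syy - sxy^2
  inv_det <- 1 / det
  inv_det[!(det > max(det, 0) * 1e-9 + 1e-12)] <- 0
  if (is.null(grids)) {
    xg <- matrix(rep(seq_len(w), each = h), h, w)
    yg <- matrix(rep(seq_len(h), w), h, w)
  } else { xg <- grids$xg; yg <- grids$yg }
  u <- matrix(0, h, w); v <- matrix(0, h, w)
  for (k in seq_len(n_iter)) {
    i2w <- if (k == 1L) i2 else bilinear_sample(i2, xg + u, yg + v)
    it <- i2w - i1
    sxt <- box_sum(ix * it, win_radius)
    syt <- box_sum(iy * it, win_radius)
    u <- u - (syy * sxt - sxy * syt) * inv_det
    v <- v - (sxx * syt - sxy * sxt) * inv_det
  }
  valid <- inv_det != 0 & lam2 > eig_rel_floor * max(lam2)
  # window-sum margins touch the zero padding; drop the border
  b <- win_radius + 1L
  inner <- matrix(FALSE, h, w)
  if (h > 2L * b && w > 2L * b)
    inner[(b + 1L):(h - b), (b + 1L):(w - b)] <- TRUE
  else
    inner[] <- TRUE                                   # tiny boxes: keep all
  list(u = u, v = v, valid = valid & inner)
}

#' Construct a motion trace
#'
#' Holds the per-frame-pair summary displacement of an ROI: the median flow
#' vector over gradient-valid pixels, one entry per consecutive frame pair.
#'
#' @param dx,dy signed per-frame median displacement components in pixels,
#'   length `T - 1`.
#' @param clip_id,box provenance.
#' @return An object of class `motion_trace`, with
#'   `per_frame_displacement = sqrt(dx^2 + dy^2)`.
#' @export
motion_trace <- function(dx, dy = rep(0, length(dx)), clip_id = "clip",
                         box = NULL) {
  if (length(dx) != length(dy) || length(dx) < 1L)
    rr_abort("dx and dy must be equal-length, non-empty", "rr_validation_error")
  if (!all(is.finite(dx)) || !all(is.finite(dy)))
    rr_abort("displacements must be finite", "rr_validation_error")
  structure(list(clip_id = clip_id, box = box, dx = dx, dy = dy,
                 per_frame_displacement = sqrt(dx^2 + dy^2)),
            class = "motion_trace")
}

#' Dense optical-flow motion trace of an ROI
#'
#' Estimates a dense displacement field between every consecutive frame pair
#' inside `box` (iterative Lucas-Kanade with bilinear warping, sub-pixel
#' accurate to <= 0.2 px on 1-px synthetic shifts) and summarizes each field
#' as the median flow vector over gradient-valid pixels. Deterministic.
#'
#' @param clip a [video_clip()] with `T >= 2`.
#' @param box a [bounding_box()]; must be at least 3 x 3 px.
#' @param win_radius Lucas-Kanade window radius in pixels.
#' @param n_iter warp-and-refine iterations per pair.
#' @return A [motion_trace()] of length `T - 1`.
#' @export
estimate_flow <- function(clip, box = NULL, win_radius = 3L, n_iter = 2L) {
  sub <- if (is.null(box)) clip else crop(clip, box)
  if (frame_h(sub) < 3L || frame_w(sub) < 3L)
    rr_abort("box too small for flow estimation (need >= 3 x 3 px)",
             "rr_insufficient_texture_error")
  nt <- n_frames(sub)
  dx <- numeric(nt - 1L); dy <- numeric(nt - 1L)
  h <- frame_h(sub); w <- frame_w(sub)
  grids <- list(xg = matrix(rep(seq_len(w), each = h), h, w),
                yg = matrix(rep(seq_len(h), w), h, w))
  prev <- get_frame(sub, 0L)
  for (t in seq_len(nt - 1L)) {
    cur <- get_frame(sub, t)
    fl <- lk_pair(prev, cur, win_radius = win_radius, n_iter = n_iter,
                  grids = grids)
    if (any(fl$valid)) {
      dx[t] <- stats::median(fl$u[fl$valid])
      dy[t] <- stats::median(fl$v[fl$valid])
    }
    prev <- cur
  }
  motion_trace(dx, dy, clip_id = clip$clip_id, box = box)
}

#' Classify 10-s windows as quiet or active
#'
#' For each window the trace's median flow vectors are integrated from the
#' window's first frame; the window amplitude is the maximum norm of that
#' trajectory. A window is quiet iff amplitude `<= threshold_px`. Signed
#' integration (rather than summing magnitudes) is what lets zero-mean
#' sub-pixel respiratory motion pass while drift and locomotion accumulate.
#'
#' @param trace a [motion_trace()].
#' @param fps clip sampling rate in Hz.
#' @param threshold_px quiet-state amplitude threshold in pixels (default 1.5).
#' @param window_s window length in seconds (default 10).
#' @param stride_s window stride in seconds (default 1).
#' @return A data.frame of class `quiet_windows` with columns `start_frame`,
#'   `end_frame` (half-open), `amplitude`, `is_quiet`, ordered by start.
#' @export
classify_windows <- function(trace, fps, threshold_px = 1.5, window_s = 10,
                             stride_s = 1) {
  nt <- length(trace$dx) + 1L                          # frames covered
  wlen <- max(2L, round(window_s * fps))
  stride <- max(1L, round(stride_s * fps))
  if (wlen > nt)
    rr_abort(sprintf("window of %d frames longer than trace (%d frames)",
                     wlen, nt), "rr_window_error")
  starts <- seq.int(0L, nt - wlen, by = stride)
  amp <- vapply(starts, function(s) {
    cx <- cumsum(trace$dx[(s + 1L):(s + wlen - 1L)])
    cy <- cumsum(trace$dy[(s + 1L):(s + wlen - 1L)])
    max(sqrt(cx^2 + cy^2))
  }, 0)
  structure(data.frame(start_frame = starts, end_frame = starts + wlen,
                       amplitude = amp, is_quiet = amp <= threshold_px),
            class = c("quiet_windows", "data.frame"))
}

#' Select the earliest quiet 10-s segment of a clip
#'
#' Runs [estimate_flow()] over the body box (or the union of the ROI boxes),
#' classifies windows, and returns the earliest quiet window's temporal
#' sub-clip (full spatial frame, so downstream stages can crop per-ROI).
#'
#' @param clip a [video_clip()].
#' @param spec an [roi_spec()] for the clip.
#' @param threshold_px,window_s,stride_s see [classify_windows()].
#' @return `list(clip = <sub-clip>, window = <one-row quiet_windows>)`.
#' @export
select_quiet_segment <- function(clip, spec, threshold_px = 1.5,
                                 window_s = 10, stride_s = 1) {
  body <- roi_box(spec, "body") %||% roi_union_box(spec)
  trace <- estimate_flow(clip, body)
  wins <- classify_windows(trace, clip$fps, threshold_px = threshold_px,
                           window_s = window_s, stride_s = stride_s)
  q <- wins[wins$is_quiet, , drop = FALSE]
  if (nrow(q) == 0L)
    rr_abort("no quiet window: clip rejected by motion screening",
             "rr_no_quiet_segment_error")
  first <- q[1L, , drop = FALSE]
  list(clip = slice_time(clip, first$start_frame, first$end_frame),
       window = first)
}
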