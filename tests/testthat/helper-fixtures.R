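# Fixtures are built in code at test time; nothing binary ships with the
# package.

# Smooth random texture (box-filtered white noise) around a mean level.
smooth_texture <- function(h, w, seed = 1, level = 100, contrast = 30) {
  set.seed(seed)
  big <- matrix(rnorm((h + 20) * (w + 20)), h + 20, w + 20)
  sm <- rrvideo:::box_sum(big, 3) / 49
  level + contrast * sm[11:(10 + h), 11:(10 + w)]
}

# Clip whose textured content translates rigidly by (vx, vy) px/frame,
# rendered by integer-shifted sampling of a larger texture (exact for
# integer per-frame shifts).
translating_clip <- function(n_frames, h, w, vx = 1, vy = 0, seed = 1) {
  pad <- n_frames * max(abs(vx), abs(vy)) + 2
  big <- smooth_texture(h + 2 * pad, w + 2 * pad, seed = seed)
  fr <- array(0, c(n_frames, h, w))
  for (t in seq_len(n_frames)) {
    oy <- pad + (t - 1) * vy
    ox <- pad + (t - 1) * vx
    fr[t, , ] <- big[(oy + 1):(oy + h), (ox + 1):(ox + w)]
  }
  video_clip(fr, 30, clip_id = "translating")
}

# Horizontal grating (stripes vary along x) whose displacement follows
# disp(t): f(x, t) = level + amp * cos(omega * (x - disp_t)). Analytic
# sub-pixel motion, plus a weak oblique component so the flow solver's
# structure tensor is well conditioned when needed.
grating_clip <- function(n_frames, h, w, omega = pi / 2, disp = NULL,
                         fps = 30, level = 100, amp = 50, oblique = 0) {
  disp <- disp %||% numeric(n_frames)
  x <- matrix(rep(0:(w - 1), each = h), h, w)
  y <- matrix(rep(0:(h - 1), w), h, w)
  fr <- array(0, c(n_frames, h, w))
  for (t in seq_len(n_frames))
    fr[t, , ] <- level + amp * cos(omega * (x - disp[t])) +
      oblique * cos(0.3 * (x - disp[t]) + 0.4 * y)
  video_clip(fr, fps, clip_id = "grating")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small fast simulator geometry for screening-focused tests.
small_cfg <- function(...) {
  args <- utils::modifyList(
    list(frame_hw = c(60, 80), axes = c(20, 12), duration_s = 12),
    list(...))
  do.call(synthetic_config, args)
}

expect_rr_error <- function(expr, class) {
  expect_error(expr, class = class)
}
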