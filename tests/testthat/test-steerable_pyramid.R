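test_that("adaptive depth follows the documented size rule", {
  expect_equal(adaptive_levels(480, 640), 4)   # floor(log2 480) - 4 = 4
  expect_equal(adaptive_levels(32, 32), 1)     # floor(log2 32) - 4 = 1
  expect_equal(adaptive_levels(8, 8), 1)       # clamped at the floor
  expect_equal(adaptive_levels(1024, 1024), 4) # clamped at the ceiling
  expect_rr_error(adaptive_levels(7, 64), "rr_too_small_error")
})

test_that("constant frames put everything in the lowpass residual", {
  pyr <- build_pyramid(matrix(42, 32, 32), levels = 2)
  for (s in 1:2) for (o in 1:8)
    expect_lt(max(Mod(pyr$bands[[s]][[o]])), 1e-10)
  expect_lt(max(abs(pyr$high)), 1e-10)
  expect_equal(mean(pyr$low), 42, tolerance = 1e-10)
})

test_that("grating energy concentrates in the aligned orientation band", {
  x <- matrix(rep(0:63, each = 64), 64, 64)
  g <- cos(pi / 2 * x)                  # wave vector along x -> orientation 1
  pyr <- build_pyramid(g, levels = 3)
  energy <- vapply(1:8, function(o)
    sum(vapply(1:3, function(s) sum(Mod(pyr$bands[[s]][[o]])^2), 0)), 0)
  expect_equal(which.max(energy), 1L)
  # cos^7 angular windows overlap adjacent orientations by design; the
  # aligned band dominates every band at angular distance >= 2 by >= 10x
  expect_gt(energy[1], 10 * max(energy[3:7]))
  expect_gt(energy[1], max(energy[-1]))

  # 90-degree rotation permutes the orientation profile by 4 of 8 bands
  pyr_t <- build_pyramid(t(g), levels = 3)
  energy_t <- vapply(1:8, function(o)
    sum(vapply(1:3, function(s) sum(Mod(pyr_t$bands[[s]][[o]])^2), 0)), 0)
  expect_equal(which.max(energy_t), 5L)
})

test_that("decomposition is linear and deterministic", {
  set.seed(31)
  f <- smooth_texture(32, 32, seed = 31)
  g <- smooth_texture(32, 32, seed = 32)
  pf <- build_pyramid(f, 2); pg <- build_pyramid(g, 2)
  pfg <- build_pyramid(2 * f - 3 * g, 2)
  expect_equal(pfg$bands[[2]][[3]], 2 * pf$bands[[2]][[3]] - 3 * pg$bands[[2]][[3]],
               tolerance = 1e-12)
  expect_identical(build_pyramid(f, 2)$bands[[1]][[1]], pf$bands[[1]][[1]])
})

test_that("reconstruction inverts decomposition within 1e-4", {
  for (seed in 1:3) {
    f <- smooth_texture(48, 40, seed = seed)
    pyr <- build_pyramid(f, levels = 2)
    rec <- reconstruct(pyr)
    expect_lt(sqrt(sum((rec - f)^2) / sum(f^2)), 1e-4)
  }
  # zeroed pyramid reconstructs to zero; scaling coefficients scales output
  f <- smooth_texture(32, 32, seed = 9)
  pyr <- build_pyramid(f, 2)
  z <- pyr
  z$high[] <- 0; z$low[] <- 0
  for (s in 1:2) for (o in 1:8) z$bands[[s]][[o]][] <- 0
  expect_lt(max(abs(reconstruct(z))), 1e-12)
  sc <- pyr
  sc$high <- 2 * sc$high; sc$low <- 2 * sc$low
  for (s in 1:2) for (o in 1:8) sc$bands[[s]][[o]] <- 2 * sc$bands[[s]][[o]]
  expect_equal(reconstruct(sc), 2 * f, tolerance = 1e-9)
})

test_that("sub-band energies sum to the input energy (tight frame)", {
  f <- smooth_texture(40, 48, seed = 12)
  pyr <- build_pyramid(f, 2)
  e <- sum(pyr$high^2) + sum(pyr$low^2)
  for (s in 1:2) for (o in 1:8) e <- e + sum(Re(pyr$bands[[s]][[o]])^2)
  expect_equal(e, sum(f^2), tolerance = 1e-9)
})

test_that("levels too deep for the frame are refused", {
  expect_rr_error(build_pyramid(matrix(0, 16, 16), levels = 4),
                  "rr_decomposition_error")
})

test_that("phase series obeys the shift-to-phase law", {
  omega <- pi / 2
  # static video: constant phase
  static <- grating_clip(5, 32, 32, omega = omega)
  st <- build_pyramid_stack(static, levels = 1)
  ps <- phase_series(st, 1, 1, c(16, 16))
  expect_equal(diff(range(ps)), 0, tolerance = 1e-9)

  # translation at sub-pixel velocity v: slope ~ omega * v per frame
  v <- 0.2
  mov <- grating_clip(20, 32, 32, omega = omega, disp = v * (0:19))
  stm <- build_pyramid_stack(mov, levels = 1)
  pm <- phase_series(stm, 1, 1, c(16, 16))
  slope <- stats::coef(stats::lm(pm ~ seq_along(pm)))[[2]]
  expect_equal(abs(slope), omega * v, tolerance = 0.05 * omega * v)

  # a full spatial period of travel unwraps to ~2*pi, not 0
  period <- 2 * pi / omega
  full <- grating_clip(9, 32, 32, omega = omega, disp = seq(0, period, length.out = 9))
  pf <- phase_series(build_pyramid_stack(full, levels = 1), 1, 1, c(16, 16))
  expect_equal(abs(pf[9] - pf[1]), 2 * pi, tolerance = 0.05 * 2 * pi)

  # displacement recovery within 5% for |d| <= 1 px
  for (d in c(0.25, 1)) {
    two <- grating_clip(2, 32, 32, omega = omega, disp = c(0, d))
    pp <- phase_series(build_pyramid_stack(two, levels = 1), 1, 1, c(16, 16))
    expect_equal(abs(pp[2] - pp[1]) / omega, d, tolerance = 0.05 * d)
  }
})

test_that("near-zero amplitude pixels are flagged as unreliable", {
  clip <- grating_clip(5, 32, 32, omega = pi / 2)
  st <- build_pyramid_stack(clip, levels = 1)
  # orientation 5 is orthogonal to the grating: amplitude ~ 0 there
  expect_warning(ps <- phase_series(st, 1, 5, c(16, 16)),
                 class = "rr_low_amplitude")
  expect_true(attr(ps, "low_amplitude"))
})
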