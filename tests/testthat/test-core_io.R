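test_that("domain type invariants are enforced", {
  expect_rr_error(video_clip(array(0, c(1, 4, 4)), 30), "rr_empty_clip_error")
  expect_rr_error(video_clip(array(c(NA, rep(0, 31)), c(2, 4, 4)), 30),
                  "rr_format_error")
  expect_rr_error(video_clip(array(0, c(3, 4, 4)), 0), "rr_config_error")
  expect_rr_error(bounding_box(5, 0, 5, 4), "rr_validation_error")
  expect_rr_error(bounding_box(2, 3, 1, 4), "rr_validation_error")
  expect_rr_error(bounding_box(0, 0, 2, 2, label = "wing"),
                  "rr_validation_error")
  expect_rr_error(roi_spec("c", list()), "rr_validation_error")
})

test_that("lossless round trips are bit-exact for both containers", {
  set.seed(11)
  fr <- array(sample(0:255, 5 * 16 * 20, replace = TRUE), c(5, 16, 20))
  clip <- video_clip(fr, 25, clip_id = "rt")
  for (fmt in c("pgm_dir", "tiff")) {
    path <- if (fmt == "tiff") tempfile(fileext = ".tif") else tempfile()
    save_clip(clip, path, format = fmt)
    back <- load_clip(path)
    expect_identical(back$frames, clip$frames, label = fmt)
    expect_equal(back$fps, 25)
  }
  # 16-bit path
  fr16 <- array(sample(0:65535, 3 * 8 * 8, replace = TRUE), c(3, 8, 8))
  c16 <- video_clip(fr16, 30)
  p16 <- tempfile(fileext = ".tif")
  save_clip(c16, p16, format = "tiff", bits = 16)
  expect_identical(load_clip(p16)$frames, fr16)
})

test_that("fps precedence: caller override > container metadata > error", {
  clip <- video_clip(array(rep(1:4, each = 16), c(4, 4, 4)), 30)
  d <- tempfile()
  save_clip(clip, d)
  expect_equal(load_clip(d)$fps, 30)            # metadata
  expect_equal(load_clip(d, fps = 12)$fps, 12)  # override wins
  unlink(file.path(d, "meta.json"))
  expect_rr_error(load_clip(d), "rr_config_error")
})

test_that("quantization keeps a known clip mean within 0.5 units", {
  # mean-100 frames with +-20 spread: 8-bit rounding moves each pixel by
  # at most 0.5, so the loaded mean stays within 0.5 of the true mean
  set.seed(3)
  true_mean <- 100
  fr <- array(pmin(pmax(true_mean + runif(4 * 12 * 12, -20, 20), 0), 255),
              c(4, 12, 12))
  d <- tempfile()
  save_clip(video_clip(fr, 30), d)   # save rounds to 8-bit
  expect_lt(abs(mean(load_clip(d)$frames) - mean(fr)), 0.5)
})

test_that("pseudo-colored constant frames collapse to constant scalars", {
  lut <- rrvideo:::rainbow_lut()
  rgb <- array(0L, c(10, 12, 3))
  for (k in 1:3) rgb[, , k] <- lut[137, k]
  d <- tempfile(); dir.create(d)
  # write as P3 (ascii PPM), row-major interleaved RGB
  for (t in 0:1) {
    con <- file(file.path(d, sprintf("frame_%05d.ppm", t)), "w")
    writeLines(c("P3", "12 10", "255"), con)
    writeLines(paste(as.integer(aperm(rgb, c(3, 2, 1))), collapse = " "), con)
    close(con)
  }
  clip <- load_clip(d, color_mode = "pseudo_color", fps = 30)
  expect_equal(length(unique(as.vector(clip$frames))), 1L)
  # recovered index maps back to the same palette color
  expect_equal(unname(lut[clip$frames[1, 1, 1] + 1, ]), unname(lut[137, ]))
})

test_that("crop obeys identity, single-pixel and concatenation oracles", {
  set.seed(4)
  clip <- video_clip(array(rnorm(6 * 10 * 14), c(6, 10, 14)), 30)
  expect_identical(crop(clip, bounding_box(0, 0, 14, 10))$frames, clip$frames)
  one <- crop(clip, bounding_box(0, 0, 1, 1))
  expect_equal(dim(one$frames), c(6, 1, 1))
  expect_equal(as.vector(one$frames), clip$frames[, 1, 1])
  left <- crop(clip, bounding_box(0, 0, 7, 10))
  right <- crop(clip, bounding_box(7, 0, 14, 10))
  glued <- array(0, c(6, 10, 14))
  glued[, , 1:7] <- left$frames; glued[, , 8:14] <- right$frames
  expect_identical(glued, clip$frames)
  expect_rr_error(crop(clip, bounding_box(10, 0, 15, 10)), "rr_bounds_error")
})

test_that("crop commutes with temporal slicing", {
  set.seed(5)
  clip <- video_clip(array(rnorm(8 * 9 * 9), c(8, 9, 9)), 30)
  box <- bounding_box(2, 1, 7, 6)
  a <- crop(slice_time(clip, 2, 7), box)
  b <- slice_time(crop(clip, box), 2, 7)
  expect_identical(a$frames, b$frames)
})

test_that("ROI files round-trip and malformed rows are rejected", {
  path <- tempfile(fileext = ".csv")
  rows <- data.frame(
    clip_id = rep(c("a", "b", "c"), each = 2),
    label = rep(c("thoracodorsal", "tail"), 3),
    x0 = 1, y0 = 2, x1 = 11, y1 = 12, frame_start = 0, frame_end = 99)
  utils::write.csv(rows, path, row.names = FALSE)
  specs <- load_rois(path)
  expect_length(specs, 3)
  expect_length(specs[["b"]]$boxes, 2)
  expect_equal(specs[["c"]]$frame_range, c(0, 99))

  # JSON equivalent parses to the same thing
  jpath <- tempfile(fileext = ".json")
  jsonlite::write_json(rows, jpath)
  expect_equal(length(load_rois(jpath)), 3)

  rows$x1[3] <- 1   # inverted box (x1 <= x0)
  utils::write.csv(rows, path, row.names = FALSE)
  expect_error(load_rois(path), "row 3", class = "rr_validation_error")
})

test_that("fallback detector finds the warm body and splits it anatomically", {
  out <- generate_clip(small_cfg(noise_sd = 0, seed = 9))
  det <- fallback_detect(get_frame(out$clip, 0), 0.8)
  # body box must contain the ellipse bounding rectangle (center 40,30;
  # axes 20,12)
  expect_lte(det$body$x0, 40 - 20 + 1)
  expect_gte(det$body$x1, 40 + 20 - 1)
  expect_lte(det$body$y0, 30 - 12 + 1)
  expect_gte(det$body$y1, 30 + 12 - 1)
  # thirds rule: thoracodorsal is the middle third of the major (x) axis
  expect_true(det$thoracodorsal$x0 > det$body$x0)
  expect_true(det$thoracodorsal$x1 < det$body$x1)
  expect_true(det$tail$label == "tail")
  expect_rr_error(fallback_detect(matrix(7, 20, 20)), "rr_no_detection_error")
})

test_that("fallback detector picks the larger of two blobs and is translation-equivariant", {
  frame <- matrix(0, 40, 60)
  frame[5:10, 5:10] <- 100        # 36 px blob
  frame[20:31, 30:41] <- 100      # 144 px blob (twice the linear size)
  det <- fallback_detect(frame, 0.9)
  expect_equal(c(det$body$x0, det$body$y0, det$body$x1, det$body$y1),
               c(29, 19, 41, 31))
  shifted <- matrix(0, 40, 60)
  shifted[(5:10) + 3, (5:10) + 5] <- 100
  shifted[(20:31) + 3, (30:41) + 5] <- 100
  det2 <- fallback_detect(shifted, 0.9)
  expect_equal(c(det2$body$x0, det2$body$y0, det2$body$x1, det2$body$y1),
               c(29 + 5, 19 + 3, 41 + 5, 31 + 3))
  expect_equal(det2$thoracodorsal$x0 - det$thoracodorsal$x0, 5)
  expect_equal(det2$tail$y0 - det$tail$y0, 3)
})

test_that("pure-noise frames at extreme quantiles yield no detection", {
  set.seed(6)
  frame <- matrix(rnorm(50 * 50), 50, 50)
  expect_rr_error(fallback_detect(frame, 0.999), "rr_no_detection_error")
})
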