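#' Construct a video clip
#'
#' A `video_clip` is the raw observable of the pipeline: a uniformly sampled
#' stack of scalar-intensity thermal frames. Intensities are in arbitrary
#' thermal units; the pipeline consumes relative motion, never absolute
#' temperature.
#'
#' @param frames numeric array of dimension `c(T, H, W)` (time, rows, cols),
#'   all values finite, `T >= 2`.
#' @param fps sampling rate in Hz (`> 0`).
#' @param clip_id opaque identifier string.
#' @param t0 start time in seconds of frame 0.
#' @return An object of class `video_clip`.
#' @export
video_clip <- function(frames, fps, clip_id = "clip", t0 = 0) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    rr_abort("frames must be a T x H x W array", "rr_format_error")
  if (dim(frames)[1] < 2L)
    rr_abort("a clip needs at least 2 frames", "rr_empty_clip_error")
  if (!all(is.finite(frames)))
    rr_abort("frame intensities must be finite", "rr_format_error")
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    rr_abort("fps must be a single positive number", "rr_config_error")
  structure(
    list(frames = frames, fps = fps, clip_id = as.character(clip_id), t0 = t0),
    class = "video_clip")
}

#' @export
print.video_clip <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<video_clip '%s': %d frames, %d x %d px, %.6g fps, %.1f s>\n",
              x$clip_id, d[1], d[2], d[3], x$fps, d[1] / x$fps))
  invisible(x)
}

#' @export
dim.video_clip <- function(x) dim(x$frames)

n_frames <- function(clip) dim(clip$frames)[1]
frame_h  <- function(clip) dim(clip$frames)[2]
frame_w  <- function(clip) dim(clip$frames)[3]

#' Extract one frame as an H x W matrix
#' @param clip a [video_clip()].
#' @param t 0-based frame index.
#' @return numeric matrix (rows = y, cols = x).
#' @export
get_frame <- function(clip, t) {
  if (t < 0 || t >= n_frames(clip))
    rr_abort("frame index out of range", "rr_bounds_error")
  matrix(clip$frames[t + 1L, , ], frame_h(clip), frame_w(clip))
}

#' Construct a bounding box
#'
#' Coordinates are 0-based and half-open: the box covers pixel columns
#' `[x0, x1)` and rows `[y0, y1)`. One convention is used everywhere in the
#' package (row-major `(y, x)` frames, 0-based time).
#'
#' @param x0,y0,x1,y1 pixel coordinates, `x0 < x1`, `y0 < y1`.
#' @param label one of `"thoracodorsal"`, `"tail"`, `"body"`.
#' @return An object of class `bounding_box`.
#' @export
bounding_box <- function(x0, y0, x1, y1, label = "body") {
  ok_labels <- c("thoracodorsal", "tail", "body")
  if (!label %in% ok_labels)
    rr_abort(sprintf("label must be one of %s", paste(ok_labels, collapse = ", ")),
             "rr_validation_error")
  v <- c(x0 = x0, y0 = y0, x1 = x1, y1 = y1)
  if (any(!is.finite(v)) || any(v < 0) || x1 <= x0 || y1 <= y0)
    rr_abort("invalid box: need 0 <= x0 < x1 and 0 <= y0 < y1",
             "rr_validation_error")
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 x1 = as.integer(x1), y1 = as.integer(y1), label = label),
            class = "bounding_box")
}

box_width  <- function(b) b$x1 - b$x0
box_height <- function(b) b$y1 - b$y0

check_box_in_frame <- function(box, h, w) {
  if (box$x1 > w || box$y1 > h)
    rr_abort(sprintf("box [%d,%d)x[%d,%d) exceeds %d x %d frame",
                     box$x0, box$x1, box$y0, box$y1, h, w),
             "rr_bounds_error")
  invisible(TRUE)
}

#' Construct an ROI specification
#'
#' Binds one or more labelled boxes (thoracodorsal, tail, body) to a clip and
#' a frame range of validity.
#'
#' @param clip_id clip identifier the boxes belong to.
#' @param boxes list of [bounding_box()] objects (at least one).
#' @param frame_range inclusive 0-based `c(start, end)` frame indices.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(clip_id, boxes, frame_range = c(0L, NA_integer_)) {
  if (inherits(boxes, "bounding_box")) boxes <- list(boxes)
  if (length(boxes) < 1L)
    rr_abort("roi_spec needs at least one box", "rr_validation_error")
  for (b in boxes)
    if (!inherits(b, "bounding_box"))
      rr_abort("boxes must be bounding_box objects", "rr_validation_error")
  structure(list(clip_id = as.character(clip_id), boxes = boxes,
                 frame_range = frame_range),
            class = "roi_spec")
}

roi_box <- function(spec, label) {
  for (b in spec$boxes) if (b$label == label) return(b)
  NULL
}

# Union of all boxes in a spec; used for whole-body motion screening.
roi_union_box <- function(spec) {
  x0 <- min(vapply(spec$boxes, `[[`, 1L, "x0"))
  y0 <- min(vapply(spec$boxes, `[[`, 1L, "y0"))
  x1 <- max(vapply(spec$boxes, `[[`, 1L, "x1"))
  y1 <- max(vapply(spec$boxes, `[[`, 1L, "y1"))
  bounding_box(x0, y0, x1, y1, "body")
}

#' Crop a clip to a bounding box
#'
#' @param clip a [video_clip()].
#' @param box a [bounding_box()] inside the frame bounds.
#' @return A [video_clip()] of size `(y1-y0) x (x1-x0)`, fps unchanged.
#' @export
crop <- function(clip, box) {
  check_box_in_frame(box, frame_h(clip), frame_w(clip))
  frames <- clip$frames[, (box$y0 + 1L):box$y1, (box$x0 + 1L):box$x1,
                        drop = FALSE]
  video_clip(frames, clip$fps, clip$clip_id, clip$t0)
}

#' Temporal sub-clip by 0-based half-open frame range
#' @param clip a [video_clip()].
#' @param t0,t1 frame indices, `0 <= t0 < t1 <= T`.
#' @export
slice_time <- function(clip, t0, t1) {
  if (t0 < 0 || t1 > n_frames(clip) || t1 - t0 < 2)
    rr_abort("invalid temporal slice", "rr_bounds_error")
  video_clip(clip$frames[(t0 + 1L):t1, , , drop = FALSE], clip$fps,
             clip$clip_id, clip$t0 + t0 / clip$fps)
}

## ---- frame-stack and TIFF I/O -------------------------------------------
## No image/video package ships with this R installation, so the lossless
## paths are implemented directly: PGM/PPM frame directories (with a JSON
## sidecar carrying fps) and minimal uncompressed multi-page grayscale TIFF.

read_pnm_header <- function(con) {
  tok <- character(0)
  while (length(tok) < 4L) {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) rr_abort("truncated PNM header", "rr_io_error")
    line <- sub("#.*$", "", line)
    tok <- c(tok, strsplit(trimws(line), "\\s+")[[1]])
    tok <- tok[nzchar(tok)]
  }
  list(magic = tok[1], w = as.integer(tok[2]), h = as.integer(tok[3]),
       maxval = as.integer(tok[4]))
}

read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hd <- read_pnm_header(con)
  nchan <- switch(hd$magic, P2 = 1L, P5 = 1L, P3 = 3L, P6 = 3L,
                  rr_abort(sprintf("unsupported PNM magic '%s'", hd$magic),
                           "rr_format_error"))
  n <- hd$w * hd$h * nchan
  if (hd$magic %in% c("P2", "P3")) {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE)
  } else if (hd$maxval < 256L) {
    vals <- as.integer(readBin(con, "raw", n))
  } else {
    raw <- readBin(con, "raw", 2L * n)                 # 16-bit big-endian
    vals <- as.integer(raw[c(TRUE, FALSE)]) * 256L + as.integer(raw[c(FALSE, TRUE)])
  }
  if (length(vals) < n) rr_abort("truncated PNM data", "rr_io_error")
  if (nchan == 1L) {
    matrix(vals, hd$h, hd$w, byrow = TRUE)
  } else {
    arr <- array(NA_integer_, c(hd$h, hd$w, 3L))
    for (k in 1:3)
      arr[, , k] <- matrix(vals[seq(k, n, by = 3L)], hd$h, hd$w, byrow = TRUE)
    arr
  }
}

write_pgm <- function(mat, path, maxval = 255L) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n%d\n", ncol(mat), nrow(mat), maxval), con,
            eos = NULL)
  vals <- as.integer(round(t(mat)))                    # row-major scan order
  if (any(vals < 0 | vals > maxval))
    rr_abort("pixel values out of range for PGM maxval", "rr_format_error")
  if (maxval < 256L) {
    writeBin(as.raw(vals), con)
  } else {
    raw <- raw(2L * length(vals))
    raw[c(TRUE, FALSE)] <- as.raw(vals %/% 256L)
    raw[c(FALSE, TRUE)] <- as.raw(vals %% 256L)
    writeBin(raw, con)
  }
}

u16_to_raw_le <- function(x) {
  r <- raw(2L * length(x))
  r[c(TRUE, FALSE)] <- as.raw(x %% 256L)
  r[c(FALSE, TRUE)] <- as.raw(x %/% 256L)
  r
}
u32_to_raw_le <- function(x) {
  r <- raw(4L * length(x))
  x <- as.double(x)
  r[seq(1, length(r), 4)] <- as.raw(x %% 256)
  r[seq(2, length(r), 4)] <- as.raw((x %/% 256) %% 256)
  r[seq(3, length(r), 4)] <- as.raw((x %/% 65536) %% 256)
  r[seq(4, length(r), 4)] <- as.raw(x %/% 16777216)
  r
}
raw_to_uint_le <- function(r) sum(as.integer(r) * 256^(seq_along(r) - 1))

tiff_ifd_entry <- function(tag, type, count, value_raw) {
  if (length(value_raw) < 4L) value_raw <- c(value_raw, raw(4L - length(value_raw)))
  c(u16_to_raw_le(tag), u16_to_raw_le(type), u32_to_raw_le(count), value_raw)
}

write_tiff_stack <- function(frames, path, bits = 8L) {
  stopifnot(length(dim(frames)) == 3L, bits %in% c(8L, 16L))
  nt <- dim(frames)[1]; h <- dim(frames)[2]; w <- dim(frames)[3]
  maxval <- 2^bits - 1
  if (any(frames < 0 | frames > maxval))
    rr_abort("pixel values out of range for TIFF bit depth", "rr_format_error")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(0x49), as.raw(0x49)), con)         # little-endian
  writeBin(u16_to_raw_le(42L), con)
  data_bytes <- h * w * (bits / 8L)
  ifd_bytes <- 2L + 8L * 12L + 4L
  page_bytes <- data_bytes + ifd_bytes
  first_ifd <- 8L + data_bytes
  writeBin(u32_to_raw_le(first_ifd), con)
  for (i in seq_len(nt)) {
    page0 <- 8L + (i - 1L) * page_bytes
    vals <- as.integer(round(t(matrix(frames[i, , ], h, w))))
    if (bits == 8L) writeBin(as.raw(vals), con) else writeBin(u16_to_raw_le(vals), con)
    ifd <- c(
      u16_to_raw_le(8L),
      tiff_ifd_entry(256L, 4L, 1L, u32_to_raw_le(w)),           # ImageWidth
      tiff_ifd_entry(257L, 4L, 1L, u32_to_raw_le(h)),           # ImageLength
      tiff_ifd_entry(258L, 3L, 1L, u16_to_raw_le(bits)),        # BitsPerSample
      tiff_ifd_entry(259L, 3L, 1L, u16_to_raw_le(1L)),          # no compression
      tiff_ifd_entry(262L, 3L, 1L, u16_to_raw_le(1L)),          # BlackIsZero
      tiff_ifd_entry(273L, 4L, 1L, u32_to_raw_le(page0)),       # StripOffsets
      tiff_ifd_entry(278L, 4L, 1L, u32_to_raw_le(h)),           # RowsPerStrip
      tiff_ifd_entry(279L, 4L, 1L, u32_to_raw_le(data_bytes)),  # StripByteCounts
      u32_to_raw_le(if (i < nt) 8L + i * page_bytes + data_bytes else 0L))
    writeBin(ifd, con)
  }
  invisible(path)
}

read_tiff_stack <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 8L) rr_abort("not a TIFF file", "rr_io_error")
  if (rawToChar(raw[1:2]) == "II") le <- TRUE
  else if (rawToChar(raw[1:2]) == "MM") le <- FALSE
  else rr_abort("not a TIFF file (bad byte order mark)", "rr_format_error")
  rd_u <- function(off, n) {           # 1-based offset, n bytes, unsigned
    b <- raw[off:(off + n - 1L)]
    if (!le) b <- rev(b)
    raw_to_uint_le(b)
  }
  if (rd_u(3L, 2L) != 42L) rr_abort("bad TIFF magic", "rr_format_error")
  ifd_off <- rd_u(5L, 4L)
  frames_list <- list()
  while (ifd_off != 0) {
    n_ent <- rd_u(ifd_off + 1L, 2L)
    tags <- list()
    for (e in seq_len(n_ent)) {
      ent0 <- ifd_off + 2L + (e - 1L) * 12L + 1L
      tag <- rd_u(ent0, 2L); type <- rd_u(ent0 + 2L, 2L)
      count <- rd_u(ent0 + 4L, 4L)
      tsize <- c(1L, 1L, 2L, 4L)[match(type, c(1L, 2L, 3L, 4L))]
      if (is.na(tsize)) next
      total <- tsize * count
      voff <- if (total <= 4L) ent0 + 8L else rd_u(ent0 + 8L, 4L) + 1L
      vals <- vapply(seq_len(count),
                     function(k) rd_u(voff + (k - 1L) * tsize, tsize), 0)
      tags[[as.character(tag)]] <- vals
    }
    w <- tags[["256"]][1]; h <- tags[["257"]][1]
    bits <- (tags[["258"]] %||% 8)[1]
    comp <- (tags[["259"]] %||% 1)[1]
    if (comp != 1) rr_abort("only uncompressed TIFF supported", "rr_format_error")
    if (!bits %in% c(8, 16)) rr_abort("only 8/16-bit TIFF supported", "rr_format_error")
    offs <- tags[["273"]]; cnts <- tags[["279"]]
    buf <- unlist(lapply(seq_along(offs), function(k)
      raw[(offs[k] + 1L):(offs[k] + cnts[k])]), use.names = FALSE)
    vals <- if (bits == 8) as.integer(buf)
            else if (le) as.integer(buf[c(TRUE, FALSE)]) + 256L * as.integer(buf[c(FALSE, TRUE)])
            else 256L * as.integer(buf[c(TRUE, FALSE)]) + as.integer(buf[c(FALSE, TRUE)])
    frames_list[[length(frames_list) + 1L]] <- matrix(vals, h, w, byrow = TRUE)
    ifd_off <- rd_u(ifd_off + 2L + n_ent * 12L + 1L, 4L)
  }
  frames_list
}

#' Save a clip losslessly
#'
#' Two lossless containers are supported: a directory of numbered binary PGM
#' frames with a `meta.json` sidecar carrying fps, or a single uncompressed
#' multi-page grayscale TIFF. Integer-valued frames round-trip bit-exactly.
#'
#' @param clip a [video_clip()] with integer intensities in `[0, 2^bits - 1]`.
#' @param path output directory (`format = "pgm_dir"`) or `.tif` file path.
#' @param format `"pgm_dir"` or `"tiff"`.
#' @param bits 8 or 16 bits per pixel.
#' @return `path`, invisibly.
#' @export
save_clip <- function(clip, path, format = c("pgm_dir", "tiff"), bits = 8L) {
  format <- match.arg(format)
  if (format == "tiff") {
    write_tiff_stack(clip$frames, path, bits = as.integer(bits))
    meta <- sub("\\.tiff?$", ".json", path)
    jsonlite::write_json(list(fps = clip$fps, clip_id = clip$clip_id,
                              t0 = clip$t0),
                         meta, auto_unbox = TRUE, digits = NA)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    maxval <- as.integer(2^bits - 1)
    for (t in seq_len(n_frames(clip)))
      write_pgm(get_frame(clip, t - 1L),
                file.path(path, sprintf("frame_%05d.pgm", t - 1L)), maxval)
    jsonlite::write_json(list(fps = clip$fps, clip_id = clip$clip_id,
                              t0 = clip$t0),
                         file.path(path, "meta.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

# 256-entry blue-to-red rainbow palette as an RGB matrix; the de-mapping
# proxy for pseudo-colored ("Rainbow") thermal exports.
rainbow_lut <- function() {
  cols <- grDevices::rainbow(256L, start = 2 / 3, end = 0)
  t(grDevices::col2rgb(cols))                          # 256 x 3
}

# Collapse H x W x 3 RGB to palette-index intensity via nearest-neighbour
# lookup against the rainbow LUT.
collapse_pseudo_color <- function(rgb_arr) {
  lut <- rainbow_lut()
  px <- matrix(as.numeric(rgb_arr), ncol = 3L)          # (H*W) x 3
  d2 <- outer(rowSums(px^2), rowSums(lut^2), `+`) - 2 * px %*% t(lut)
  idx <- max.col(-d2, ties.method = "first") - 1L       # palette index 0..255
  matrix(idx, dim(rgb_arr)[1], dim(rgb_arr)[2])
}

#' Load a clip from disk
#'
#' Reads a PGM/PPM frame-stack directory or a multi-page grayscale TIFF.
#' Pseudo-colored (3-channel) frames are collapsed to a scalar intensity
#' proxy by nearest-neighbour lookup against a bundled 256-entry rainbow
#' palette. fps precedence: the `fps` argument overrides container metadata;
#' with neither present loading fails (thermal exports often carry wrong
#' metadata, so the caller must be able to win).
#'
#' @param path frame-stack directory or `.tif`/`.tiff` file.
#' @param color_mode `"gray"` or `"pseudo_color"`.
#' @param fps optional sampling-rate override in Hz.
#' @return A [video_clip()].
#' @export
load_clip <- function(path, color_mode = c("gray", "pseudo_color"), fps = NULL) {
  color_mode <- match.arg(color_mode)
  if (!file.exists(path))
    rr_abort(sprintf("no such file or directory: %s", path), "rr_io_error")
  meta <- list()
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(pgm|ppm)$", full.names = TRUE))
    if (length(files) == 0L)
      rr_abort("no PGM/PPM frames found in directory", "rr_empty_clip_error")
    frames_list <- lapply(files, read_pnm)
    mp <- file.path(path, "meta.json")
    if (file.exists(mp)) meta <- jsonlite::read_json(mp)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    frames_list <- read_tiff_stack(path)
    if (length(frames_list) == 0L)
      rr_abort("TIFF contains no pages", "rr_empty_clip_error")
    mp <- sub("\\.tiff?$", ".json", path, ignore.case = TRUE)
    if (file.exists(mp)) meta <- jsonlite::read_json(mp)
  } else {
    rr_abort(sprintf("unsupported container: %s (AVI/MP4 decoding needs an external frame export)", path),
             "rr_format_error")
  }
  if (color_mode == "pseudo_color") {
    frames_list <- lapply(frames_list, function(f) {
      if (length(dim(f)) != 3L)
        rr_abort("pseudo_color expects 3-channel frames", "rr_format_error")
      collapse_pseudo_color(f)
    })
  } else {
    frames_list <- lapply(frames_list, function(f) {
      if (length(dim(f)) == 3L) matrix(rowMeans(matrix(as.numeric(f), ncol = 3L)),
                                       dim(f)[1], dim(f)[2])
      else f
    })
  }
  dims <- vapply(frames_list, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    rr_abort("frames have non-uniform sizes", "rr_format_error")
  fps_use <- fps %||% meta$fps %||%
    rr_abort("fps not in container metadata; pass fps explicitly", "rr_config_error")
  all_int <- all(vapply(frames_list, is.integer, TRUE))
  frames <- array(if (all_int) 0L else 0,
                  c(length(frames_list), dims[1, 1], dims[2, 1]))
  for (t in seq_along(frames_list)) frames[t, , ] <- frames_list[[t]]
  video_clip(frames, fps_use,
             clip_id = meta$clip_id %||% basename(path),
             t0 = meta$t0 %||% 0)
}

## ---- ROI annotation files -----------------------------------------------

roi_csv_header <- c("clip_id", "label", "x0", "y0", "x1", "y1",
                    "frame_start", "frame_end")

#' Read ROI annotations (CSV or JSON)
#'
#' CSV columns: `clip_id,label,x0,y0,x1,y1,frame_start,frame_end`; the JSON
#' equivalent is an array of objects with the same keys. Rows are grouped by
#' `clip_id` into one [roi_spec()] per clip; malformed rows are rejected with
#' their row index.
#'
#' @param path annotation file (`.csv` or `.json`).
#' @return A named list of [roi_spec()] objects, one per clip.
#' @export
load_rois <- function(path) {
  if (!file.exists(path)) rr_abort(sprintf("no such file: %s", path), "rr_io_error")
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    rows <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!is.data.frame(rows)) rows <- as.data.frame(rows)
  } else {
    rows <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  missing <- setdiff(roi_csv_header, names(rows))
  if (length(missing))
    rr_abort(sprintf("annotation file lacks columns: %s",
                     paste(missing, collapse = ", ")), "rr_parse_error")
  specs <- list()
  for (cid in unique(rows$clip_id)) {
    sub <- rows[rows$clip_id == cid, , drop = FALSE]
    boxes <- vector("list", nrow(sub))
    for (i in seq_len(nrow(sub))) {
      r <- sub[i, ]
      row_idx <- as.integer(rownames(sub)[i])
      boxes[[i]] <- tryCatch(
        bounding_box(r$x0, r$y0, r$x1, r$y1, r$label),
        error = function(e) rr_abort(
          sprintf("row %d: %s", row_idx, conditionMessage(e)),
          "rr_validation_error"))
    }
    specs[[cid]] <- roi_spec(cid, boxes,
                             frame_range = c(min(sub$frame_start), max(sub$frame_end)))
  }
  specs
}

#' Write ROI annotations as CSV
#' @param specs list of [roi_spec()] (or a single one).
#' @param path output CSV path.
#' @export
save_rois <- function(specs, path) {
  if (inherits(specs, "roi_spec")) specs <- list(specs)
  rows <- do.call(rbind, lapply(specs, function(s) {
    do.call(rbind, lapply(s$boxes, function(b)
      data.frame(clip_id = s$clip_id, label = b$label, x0 = b$x0, y0 = b$y0,
                 x1 = b$x1, y1 = b$y1, frame_start = s$frame_range[1],
                 frame_end = s$frame_range[2])))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

## ---- fallback intensity-threshold detector ------------------------------

# 4-connected component labels by iterative min-label propagation.
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[mask] <- seq_len(sum(mask))
  repeat {
    new <- lab
    h <- nrow(lab); w <- ncol(lab)
    shift_min <- function(cur, nb) ifelse(nb > 0L & cur > 0L, pmin(cur, nb), cur)
    up    <- rbind(lab[-1, , drop = FALSE], 0L)
    down  <- rbind(0L, lab[-h, , drop = FALSE])
    left  <- cbind(lab[, -1, drop = FALSE], 0L)
    right <- cbind(0L, lab[, -w, drop = FALSE])
    new <- shift_min(new, up); new <- shift_min(new, down)
    new <- shift_min(new, left); new <- shift_min(new, right)
    if (identical(new, lab)) break
    lab <- new
  }
  lab
}

#' Intensity-threshold body detector (stand-in for a learned detector)
#'
#' Thresholds the frame at an intensity quantile, keeps the largest
#' 4-connected warm component as the body, and derives thoracodorsal and tail
#' sub-boxes geometrically: the body box is split into thirds along its major
#' axis; the middle third is the thoracodorsal ROI and the third farther from
#' the brighter end (taken as the head) is the tail ROI. Deterministic for a
#' fixed frame.
#'
#' @param frame numeric H x W matrix, not constant.
#' @param intensity_quantile threshold quantile in (0, 1); default 0.8.
#' @param min_area smallest accepted component area in pixels.
#' @return A named list of [bounding_box()]: `body`, `thoracodorsal`, `tail`.
#' @export
fallback_detect <- function(frame, intensity_quantile = 0.8, min_area = 9L) {
  if (diff(range(frame)) == 0)
    rr_abort("constant frame: nothing to detect", "rr_no_detection_error")
  thr <- stats::quantile(frame, intensity_quantile, names = FALSE)
  mask <- frame > thr
  if (!any(mask))
    rr_abort("no pixels above threshold", "rr_no_detection_error")
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  best <- which.max(sizes)
  if (sizes[best] < min_area)
    rr_abort(sprintf("largest component has %d px (< %d): no detection",
                     sizes[best], min_area), "rr_no_detection_error")
  sel <- lab == best
  ys <- row(frame)[sel]; xs <- col(frame)[sel]
  x0 <- min(xs) - 1L; x1 <- max(xs); y0 <- min(ys) - 1L; y1 <- max(ys)
  body <- bounding_box(x0, y0, x1, y1, "body")
  wv <- x1 - x0; hv <- y1 - y0
  horiz <- wv >= hv                                   # major axis direction
  if (horiz) {
    c1 <- x0 + round(wv / 3); c2 <- x0 + round(2 * wv / 3)
    m_lo <- mean(frame[sel & col(frame) - 1L < c1])   # left third mean
    m_hi <- mean(frame[sel & col(frame) - 1L >= c2])  # right third mean
    head_high <- m_hi >= m_lo
    thor <- bounding_box(c1, y0, c2, y1, "thoracodorsal")
    tail <- if (head_high) bounding_box(x0, y0, c1, y1, "tail")
            else bounding_box(c2, y0, x1, y1, "tail")
  } else {
    c1 <- y0 + round(hv / 3); c2 <- y0 + round(2 * hv / 3)
    m_lo <- mean(frame[sel & row(frame) - 1L < c1])
    m_hi <- mean(frame[sel & row(frame) - 1L >= c2])
    head_high <- m_hi >= m_lo
    thor <- bounding_box(x0, c1, x1, c2, "thoracodorsal")
    tail <- if (head_high) bounding_box(x0, y0, x1, c1, "tail")
            else bounding_box(x0, c2, x1, y1, "tail")
  }
  list(body = body, thoracodorsal = thor, tail = tail)
}
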