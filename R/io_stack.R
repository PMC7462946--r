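#' Read a DSA sequence from disk
#'
#' Accepts a multi-frame DICOM file, a multi-page TIFF, or a directory of
#' equally sized single-frame PNG/TIFF files taken in lexicographic order.
#' Intensities are returned as stored integer values (not rescaled to
#' `[0, 1]`).
#'
#' The frame interval is taken from the DICOM timing tags (FrameTimeVector or
#' FrameTime) when present; for TIFF/PNG input, or DICOM files without timing
#' tags, `frame_interval` must be supplied.
#'
#' @param path file or directory path.
#' @param frame_interval optional seconds per frame, overriding/replacing
#'   container metadata.
#' @return a [frame_stack].
#' @export
read_frame_stack <- function(path, frame_interval = NULL) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) < 3L)
      stop("too few frames: directory '", path, "' holds ", length(files),
           " image files, need at least 3")
    pages <- lapply(files, read_gray_frame)
    return(assemble_stack(pages, frame_interval,
                          source = paste0("directory ", path)))
  }
  if (is_dicom(path)) {
    dcm <- read_dicom_stack(path)
    dt <- frame_interval %||% dcm$frame_interval
    if (is.null(dt))
      stop("DICOM file '", path,
           "' carries no frame timing tags; supply frame_interval")
    return(frame_stack(dcm$frames, dt, bit_depth = dcm$bit_depth))
  }
  if (grepl("\\.(tif|tiff)$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, normalize_page)
    return(assemble_stack(pages, frame_interval, source = path))
  }
  if (grepl("\\.png$", path, ignore.case = TRUE))
    stop("'", path, "' is a single PNG; pass a directory of frames instead")
  stop("unrecognized stack container: '", path, "'")
}

# read one PNG/TIFF file as an integer-valued grayscale matrix with a
# "bit_depth" attribute
read_gray_frame <- function(file) {
  if (grepl("\\.png$", file, ignore.case = TRUE)) {
    img <- png::readPNG(file, info = TRUE)
    depth <- attr(img, "info")$bit.depth %||% 8L
    m <- drop_channels(img, file)
    m <- round(m * (2^depth - 1))
    attr(m, "bit_depth") <- as.integer(depth)
    m
  } else {
    img <- tiff::readTIFF(file, as.is = TRUE, info = TRUE)
    normalize_page(img, file)
  }
}

normalize_page <- function(img, file = "") {
  depth <- attr(img, "bits.per.sample") %||% 8L
  m <- drop_channels(img, file)
  attr(m, "bit_depth") <- as.integer(depth)
  m
}

drop_channels <- function(img, file = "") {
  if (length(dim(img)) == 3L) {
    ch <- dim(img)[3L]
    first <- img[, , 1L]
    for (k in seq_len(min(ch, 3L))[-1L])
      if (any(img[, , k] != first))
        stop("frame ", file, " is not grayscale")
    img <- first
  }
  as.matrix(img)
}

assemble_stack <- function(pages, frame_interval, source) {
  dims <- vapply(pages, dim, integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    stop("frames in ", source, " have mismatched shapes")
  if (length(pages) < 3L)
    stop("too few frames in ", source, ": got ", length(pages),
         ", need at least 3")
  if (is.null(frame_interval))
    stop("no frame timing metadata in ", source, "; supply frame_interval")
  depth <- max(vapply(pages, function(p) attr(p, "bit_depth"), integer(1L)))
  depth <- if (depth > 8L) 16L else 8L
  arr <- array(0, dim = c(dims[1L, 1L], dims[2L, 1L], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  frame_stack(arr, frame_interval, bit_depth = depth)
}

#' Write a frame stack as a multi-page TIFF
#'
#' Integer intensities are preserved exactly at the stack's bit depth, so
#' `read_frame_stack(write_frame_stack(x, f), dt)` round-trips bit-identically.
#'
#' @param stack a [frame_stack].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path) {
  vmax <- 2^stack$bit_depth - 1
  pages <- lapply(seq_len(n_frames(stack)),
                  function(k) stack$frames[, , k] / vmax)
  tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth,
                  compression = "none", reduce = FALSE)
  invisible(path)
}

# Parametric map I/O -----------------------------------------------------

#' Write a perfusion parameter map
#'
#' Writes the map twice: a 32-bit float TIFF at `path` that preserves the
#' exact values (undefined pixels stored as NaN), and a colour-coded 8-bit
#' PNG rendering alongside it (same path with a `.png` extension; undefined
#' pixels rendered black). The PNG is presentation only; the TIFF is the
#' quantitative artifact.
#'
#' @param map numeric matrix; `NA` marks undefined pixels.
#' @param path output `.tif` path.
#' @param colormap_name "jet" (default) or "gray".
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path, colormap_name = "jet") {
  stopifnot(is.matrix(map))
  write_float_tiff(map, path)
  png_path <- sub("\\.tiff?$", ".png", path, ignore.case = TRUE)
  if (png_path == path) png_path <- paste0(path, ".png")
  png::writePNG(render_map(map, colormap_name), png_path)
  invisible(path)
}

#' Read a float map written by [write_map()]
#'
#' @param path a 32-bit float TIFF.
#' @return numeric matrix with `NA` at undefined pixels.
#' @export
read_map <- function(path) {
  m <- tiff::readTIFF(path)
  m <- drop_channels(m, path)
  m[is.nan(m)] <- NA_real_
  m
}

# Minimal single-image 32-bit float TIFF writer (little-endian, one strip,
# SampleFormat = IEEE float). The `tiff` package reads but cannot faithfully
# write float samples outside [0, 1], hence the dedicated write path.
write_float_tiff <- function(m, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  w <- ncol(m); h <- nrow(m)
  v <- as.numeric(t(m))            # TIFF strips are row-major
  v[is.na(v)] <- NaN
  n_entries <- 9L
  ifd_offset <- 8L
  data_offset <- ifd_offset + 2L + n_entries * 12L + 4L
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_offset, con, size = 4, endian = "little")
  writeBin(n_entries, con, size = 2, endian = "little")
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) {               # SHORT: left-justified in the value field
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  entry(256L, 4L, 1L, w)            # ImageWidth
  entry(257L, 4L, 1L, h)            # ImageLength
  entry(258L, 3L, 1L, 32L)          # BitsPerSample
  entry(259L, 3L, 1L, 1L)           # Compression: none
  entry(262L, 3L, 1L, 1L)           # Photometric: BlackIsZero
  entry(273L, 4L, 1L, data_offset)  # StripOffsets
  entry(278L, 4L, 1L, h)            # RowsPerStrip
  entry(279L, 4L, 1L, length(v) * 4L)  # StripByteCounts
  entry(339L, 3L, 1L, 3L)           # SampleFormat: IEEE float
  writeBin(0L, con, size = 4, endian = "little")  # no next IFD
  writeBin(v, con, size = 4, endian = "little")
  invisible(path)
}

# map -> h x w x 3 array in [0,1] for png::writePNG; NA -> black
render_map <- function(map, colormap_name = "jet") {
  pal <- map_palette(colormap_name)
  out <- array(0, dim = c(nrow(map), ncol(map), 3L))
  def <- !is.na(map)
  if (any(def)) {
    rng <- range(map[def])
    span <- rng[2L] - rng[1L]
    idx <- if (span > 0) 1L + floor((map[def] - rng[1L]) / span * 255.999)
           else rep(128L, sum(def))
    cols <- grDevices::col2rgb(pal[idx]) / 255
    for (k in 1:3) {
      plane <- out[, , k]
      plane[def] <- cols[k, ]
      out[, , k] <- plane
    }
  }
  out
}

map_palette <- function(name) {
  switch(name,
    jet = grDevices::colorRampPalette(
      c("#00007F", "blue", "#007FFF", "cyan", "#7FFF7F",
        "yellow", "#FF7F00", "red", "#7F0000"))(256),
    gray = grDevices::gray(seq(0, 1, length.out = 256)),
    stop("unknown colormap '", name, "'"))
}

# Comparison report CSV --------------------------------------------------

#' Write / read the ROI comparison report
#'
#' The CSV mirrors the per-ROI comparison layout: one row per
#' (metric, ROI) with the pre value, post value and percent rise, written at
#' full precision.
#'
#' @param rows a data frame with columns `metric`, `artery_label`, `roi_id`,
#'   `pre_value`, `post_value`, `percent_rise` (extra columns are dropped);
#'   typically a [build_comparison()] result.
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_report <- function(rows, path) {
  cols <- c("metric", "artery_label", "roi_id", "pre_value", "post_value",
            "percent_rise")
  if (length(rows) == 0L || nrow(rows) == 0L) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  } else {
    df <- as.data.frame(rows)[, cols]
  }
  utils::write.csv(format_full(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

format_full <- function(df) {
  for (nm in names(df))
    if (is.numeric(df[[nm]]))
      df[[nm]] <- vapply(df[[nm]], function(x)
        if (is.na(x)) "NA" else format(x, digits = 17, scientific = FALSE),
        character(1L))
  df
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
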