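# Minimal multi-frame DICOM reader for uncompressed x-ray angiography
# exports. Supports implicit and explicit VR little endian transfer
# syntaxes; anything compressed (or big endian) is rejected. Only the tags
# the pipeline needs are interpreted; everything else is skipped.

is_dicom <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 132L)
  length(hdr) == 132L && identical(hdr[129:132], charToRaw("DICM"))
}

read_dicom_stack <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 132L || !identical(raw[129:132], charToRaw("DICM")))
    stop("'", path, "' is not a DICOM part-10 file")
  u16 <- function(i) as.integer(raw[i]) + 256L * as.integer(raw[i + 1L])
  u32 <- function(i) u16(i) + 65536 * u16(i + 2L)

  pos <- 133L
  explicit <- TRUE       # file meta group is always explicit VR
  explicit_pending <- FALSE
  transfer <- NULL
  tags <- list()
  pixel_data <- NULL
  long_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

  while (pos + 7L <= length(raw)) {
    group <- u16(pos); elem <- u16(pos + 2L)
    if (!is.null(transfer) && group != 2L && explicit_pending) {
      # first dataset element: switch to the negotiated transfer syntax
      explicit <- transfer != "1.2.840.10008.1.2"
      explicit_pending <- FALSE
    }
    if (explicit || group == 2L) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% long_vrs) {
        len <- u32(pos + 8L); hdr_len <- 12L
      } else {
        len <- u16(pos + 6L); hdr_len <- 8L
      }
    } else {
      vr <- NA_character_; len <- u32(pos + 4L); hdr_len <- 8L
    }
    val_start <- pos + hdr_len
    key <- sprintf("%04x,%04x", group, elem)

    if (key == "7fe0,0010") {
      if (len == 0xFFFFFFFF)
        stop("encapsulated (compressed) PixelData is not supported")
      pixel_data <- raw[val_start:(val_start + len - 1L)]
      break
    }
    if (len == 0xFFFFFFFF || identical(vr, "SQ")) {
      pos <- skip_dicom_sequence(raw, val_start, len, u16, u32)
      next
    }
    if (key %in% c("0002,0010", "0018,1063", "0018,1065", "0028,0008",
                   "0028,0010", "0028,0011", "0028,0100", "0028,0103")) {
      val <- raw[val_start:(val_start + len - 1L)]
      tags[[key]] <- if (key %in% c("0028,0010", "0028,0011", "0028,0100",
                                    "0028,0103"))
        u16(val_start)
      else
        trimws(rawToChar(val[val != as.raw(0L)]))
      if (key == "0002,0010") {
        transfer <- tags[[key]]
        if (!transfer %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1"))
          stop("unsupported DICOM transfer syntax '", transfer,
               "' (only uncompressed little endian is handled)")
        explicit_pending <- TRUE
      }
    }
    pos <- val_start + len
  }

  rows <- tags[["0028,0010"]]; cols <- tags[["0028,0011"]]
  bits <- tags[["0028,0100"]] %||% 8L
  if (is.null(rows) || is.null(cols) || is.null(pixel_data))
    stop("DICOM file lacks Rows/Columns/PixelData")
  if (!bits %in% c(8L, 16L)) stop("unsupported BitsAllocated: ", bits)
  nf <- as.integer(tags[["0028,0008"]] %||% "1")
  if (nf < 3L) stop("too few frames in DICOM file: ", nf)
  bytes_px <- bits / 8L
  need <- rows * cols * nf * bytes_px
  if (length(pixel_data) < need) stop("PixelData truncated")
  vals <- if (bits == 8L) as.integer(pixel_data[seq_len(need)])
          else readBin(pixel_data, "integer", n = need / 2L, size = 2L,
                       signed = FALSE, endian = "little")
  # DICOM pixel order is row-major per frame
  arr <- aperm(array(vals, dim = c(cols, rows, nf)), c(2L, 1L, 3L))

  dt <- NULL
  if (!is.null(tags[["0018,1065"]])) {
    ftv <- as.numeric(strsplit(tags[["0018,1065"]], "\\\\")[[1L]])
    ftv <- ftv[ftv > 0]
    if (length(ftv)) dt <- mean(ftv) / 1000
  } else if (!is.null(tags[["0018,1063"]])) {
    ft <- as.numeric(tags[["0018,1063"]])
    if (is.finite(ft) && ft > 0) dt <- ft / 1000
  }
  list(frames = arr, frame_interval = dt, bit_depth = bits)
}

# skip an SQ element (defined or undefined length); returns next position
skip_dicom_sequence <- function(raw, val_start, len, u16, u32) {
  if (len != 0xFFFFFFFF) return(val_start + len)
  pos <- val_start
  while (pos + 7L <= length(raw)) {
    group <- u16(pos); elem <- u16(pos + 2L); ilen <- u32(pos + 4L)
    if (group == 0xFFFE && elem == 0xE0DD) return(pos + 8L)  # seq delimiter
    if (group == 0xFFFE && elem == 0xE000) {                 # item
      if (ilen == 0xFFFFFFFF) {
        pos <- pos + 8L
        repeat {                                             # to item delim
          if (u16(pos) == 0xFFFE && u16(pos + 2L) == 0xE00D) {
            pos <- pos + 8L; break
          }
          pos <- pos + 1L
        }
      } else pos <- pos + 8L + ilen
    } else pos <- pos + 8L + ilen
  }
  stop("unterminated DICOM sequence")
}
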