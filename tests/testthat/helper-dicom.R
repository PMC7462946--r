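# Synthetic multi-frame DICOM writer (explicit or implicit VR little
# endian), used only to exercise the reader; generated at test time, never
# stored in the repository.
write_test_dicom <- function(path, frames, frame_time_ms = 500,
                             explicit = TRUE, bits = 8L) {
  d <- dim(frames)
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  put_str <- function(group, elem, vr, value, meta = FALSE) {
    bytes <- charToRaw(value)
    if (length(bytes) %% 2 == 1)   # UI pads with NUL, text VRs with space
      bytes <- c(bytes, if (vr == "UI") as.raw(0L) else charToRaw(" "))
    w16(group); w16(elem)
    if (explicit || meta) { writeBin(charToRaw(vr), con); w16(length(bytes)) }
    else w32(length(bytes))
    writeBin(bytes, con)
  }
  put_us <- function(group, elem, value) {
    w16(group); w16(elem)
    if (explicit) { writeBin(charToRaw("US"), con); w16(2L) }
    else w32(2L)
    w16(value)
  }
  transfer <- if (explicit) "1.2.840.10008.1.2.1" else "1.2.840.10008.1.2"
  put_str(0x0002, 0x0010, "UI", transfer, meta = TRUE)
  put_str(0x0018, 0x1063, "DS", format(frame_time_ms))
  put_str(0x0028, 0x0008, "IS", format(d[3L]))
  put_us(0x0028, 0x0010, d[1L])
  put_us(0x0028, 0x0011, d[2L])
  put_us(0x0028, 0x0100, bits)
  put_us(0x0028, 0x0103, 0L)
  # pixel data, row-major within each frame
  n <- prod(d)
  w16(0x7FE0); w16(0x0010)
  if (explicit) {
    writeBin(charToRaw(if (bits == 8L) "OB" else "OW"), con)
    w16(0L); w32(n * bits / 8L)
  } else w32(n * bits / 8L)
  vals <- as.integer(aperm(frames, c(2L, 1L, 3L)))
  if (bits == 8L) writeBin(as.raw(vals), con)
  else writeBin(vals, con, size = 2, endian = "little")
  invisible(path)
}
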