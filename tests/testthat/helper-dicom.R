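# Build minimal synthetic DICOM slice files (explicit VR little endian)
# for import tests. Written byte by byte at test time.

dcm_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                endian = "little")

dcm_element <- function(group, elem, vr, payload) {
  if (is.character(payload)) {
    payload <- charToRaw(payload)
    if (length(payload) %% 2 == 1)
      payload <- c(payload, if (vr == "UI") as.raw(0) else charToRaw(" "))
  }
  head <- c(dcm_u16(group), dcm_u16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    len <- writeBin(length(payload), raw(), size = 4, endian = "little")
    c(head, raw(2), len, payload)
  } else {
    c(head, dcm_u16(length(payload)), payload)
  }
}

# pixels: integer matrix [row, col], stored values before rescaling.
write_test_dicom <- function(path, pixels, position = c(0, 0, 0),
                             pixel_spacing = c(1, 1), slope = 1,
                             intercept = 0, series_uid = "1.2.3.4",
                             signed = FALSE) {
  rows <- nrow(pixels); cols <- ncol(pixels)
  px_raw <- writeBin(as.integer(t(pixels)), raw(), size = 2,
                     endian = "little")
  body <- c(
    dcm_element(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"),
    dcm_element(0x0020, 0x000e, "UI", series_uid),
    dcm_element(0x0020, 0x0032, "DS",
                paste(format(position), collapse = "\\")),
    dcm_element(0x0028, 0x0010, "US", dcm_u16(rows)),
    dcm_element(0x0028, 0x0011, "US", dcm_u16(cols)),
    dcm_element(0x0028, 0x0030, "DS",
                paste(format(pixel_spacing), collapse = "\\")),
    dcm_element(0x0028, 0x0100, "US", dcm_u16(16)),
    dcm_element(0x0028, 0x0103, "US", dcm_u16(if (signed) 1 else 0)),
    dcm_element(0x0028, 0x1052, "DS", format(intercept)),
    dcm_element(0x0028, 0x1053, "DS", format(slope)),
    dcm_element(0x7fe0, 0x0010, "OW", px_raw)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(body, con)
  invisible(path)
}
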