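# Minimal DICOM series import. No R DICOM package is declared as a
# dependency, so a small reader for the common CT/PET storage case is
# implemented here: uncompressed, explicit VR little endian, one frame per
# file. Anything else (compressed transfer syntaxes, implicit VR, multiframe)
# is rejected with a clear error; NIfTI is the canonical format and DICOM is
# import-only.

DCM_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

# Read one DICOM file, returning the handful of tags the importer needs.
read_dicom_slice <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 132 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  pos <- 133L  # 1-based offset just past the DICM magic

  u16 <- function(b) as.integer(b[1]) + 256L * as.integer(b[2])
  u32 <- function(b) sum(as.numeric(b) * c(1, 256, 65536, 16777216))

  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  tags <- list()
  transfer_syntax <- NULL

  while (pos + 7L <= length(raw) + 1L) {
    group <- u16(raw[pos:(pos + 1L)])
    elem <- u16(raw[(pos + 2L):(pos + 3L)])
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("implicit VR or unsupported encoding in ", path,
           "; only explicit VR little endian is supported")
    if (vr %in% long_vrs) {
      len <- u32(raw[(pos + 8L):(pos + 11L)])
      hdr <- 12L
    } else {
      len <- u16(raw[(pos + 6L):(pos + 7L)])
      hdr <- 8L
    }
    if (len == 4294967295)
      stop("undefined-length element (", sprintf("%04x,%04x", group, elem),
           ") not supported in ", path)
    vstart <- pos + hdr
    vend <- vstart + len - 1L
    if (len > 0 && vend > length(raw))
      stop("truncated DICOM element in ", path)
    key <- sprintf("%04x,%04x", group, elem)
    wanted <- c("0002,0010", "0020,000e", "0020,0032", "0028,0010",
                "0028,0011", "0028,0030", "0028,0100", "0028,0103",
                "0028,1052", "0028,1053", "7fe0,0010")
    if (key %in% wanted) {
      val <- if (len > 0) raw[vstart:vend] else raw(0)
      tags[[key]] <- switch(vr,
        US = u16(val),
        DS = , IS = as.numeric(strsplit(trimws(rawToChar(val)), "\\\\")[[1]]),
        UI = , LO = , SH = , CS = sub("\\x00$", "", rawToChar(val)),
        val)
      if (key == "0002,0010") transfer_syntax <- trimws(tags[[key]])
    }
    pos <- vstart + len
    if (group > 2L && !is.null(transfer_syntax) &&
        transfer_syntax != DCM_EXPLICIT_LE)
      stop("unsupported transfer syntax '", transfer_syntax, "' in ", path)
  }

  need <- c("0028,0010", "0028,0011", "0020,0032", "7fe0,0010")
  miss <- setdiff(need, names(tags))
  if (length(miss) > 0)
    stop("DICOM file ", path, " lacks required tags: ",
         paste(miss, collapse = ", "))
  rows <- tags[["0028,0010"]]
  cols <- tags[["0028,0011"]]
  bits <- if (!is.null(tags[["0028,0100"]])) tags[["0028,0100"]] else 16L
  signed <- !is.null(tags[["0028,0103"]]) && tags[["0028,0103"]] == 1L
  if (bits != 16L)
    stop("only 16-bit pixel data supported (got ", bits, " bits) in ", path)
  px <- tags[["7fe0,0010"]]
  if (length(px) < 2L * rows * cols)
    stop("pixel data shorter than Rows x Columns in ", path)
  stored <- readBin(px, "integer", n = rows * cols, size = 2L,
                    signed = signed, endian = "little")
  slope <- if (!is.null(tags[["0028,1053"]])) tags[["0028,1053"]][1] else 1
  intercept <- if (!is.null(tags[["0028,1052"]])) tags[["0028,1052"]][1] else 0
  # pixel data is row-major (rows of the image are contiguous): transpose
  mat <- t(matrix(stored, nrow = cols, ncol = rows))
  list(pixels = mat * slope + intercept,
       position = tags[["0020,0032"]],
       pixel_spacing = tags[["0028,0030"]],
       series_uid = if (!is.null(tags[["0020,000e"]]))
         trimws(tags[["0020,000e"]]) else NA_character_)
}

#' Import a DICOM series directory as a volume
#'
#' Reads every file in `dir`, requires a single series, sorts slices by
#' their physical position along the slice axis, checks that the slice
#' spacing is uniform to within 1 %, and applies the rescale
#' slope/intercept (Hounsfield units for CT).
#'
#' @param dir Directory containing the slice files of one series.
#' @param modality Modality tag for the returned volume.
#' @return An [image_volume()].
#' @export
read_dicom_series <- function(dir, modality = c("CT", "PET_VENT", "PET_PERF")) {
  modality <- match.arg(modality)
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) stop("no files in DICOM directory: ", dir)
  slices <- lapply(files, read_dicom_slice)
  uids <- unique(vapply(slices, function(s) s$series_uid, ""))
  if (length(uids) > 1)
    stop("mixed DICOM series in ", dir, ": ", paste(uids, collapse = ", "))
  z <- vapply(slices, function(s) s$position[3], 0)
  ord <- order(z)
  slices <- slices[ord]
  z <- z[ord]
  dims2d <- dim(slices[[1]]$pixels)
  if (!all(vapply(slices, function(s) identical(dim(s$pixels), dims2d), TRUE)))
    stop("inconsistent slice dimensions in ", dir)
  nz <- length(slices)
  if (nz > 1) {
    dz <- diff(z)
    if (any(dz <= 0)) stop("duplicate or unsorted slice positions in ", dir)
    if ((max(dz) - min(dz)) / mean(dz) > 0.01)
      stop("non-uniform slice spacing beyond 1% tolerance in ", dir)
    slice_dz <- mean(dz)
  } else {
    slice_dz <- 1
  }
  ps <- slices[[1]]$pixel_spacing  # (row spacing, column spacing)
  dat <- array(0, dim = c(dims2d[2], dims2d[1], nz))
  for (k in seq_len(nz)) dat[, , k] <- t(slices[[k]]$pixels)
  origin <- c(slices[[1]]$position[1], slices[[1]]$position[2], z[1])
  image_volume(dat, spacing = c(ps[2], ps[1], slice_dz), origin = origin,
               modality = modality)
}
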