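#' Read a CT or PET volume
#'
#' NIfTI-1 (`.nii` / `.nii.gz`) is the canonical interchange format; a
#' directory containing a single DICOM series (uncompressed, explicit VR
#' little endian) can be imported, in which case stored values are rescaled
#' with the header slope/intercept (giving Hounsfield units for CT) and
#' slices are sorted by physical position.
#'
#' @param path Path to a NIfTI file or a directory of DICOM slices.
#' @param modality One of `"CT"`, `"PET_VENT"`, `"PET_PERF"`.
#' @return An [image_volume()].
#' @export
read_volume <- function(path, modality = c("CT", "PET_VENT", "PET_PERF")) {
  modality <- match.arg(modality)
  if (!file.exists(path))
    stop("file or directory not found: ", path)
  if (dir.exists(path))
    return(read_dicom_series(path, modality = modality))
  img <- RNifti::readNifti(path)
  dat <- array(as.numeric(img), dim = dim(img))
  if (any(!is.finite(dat))) {
    warning("non-finite voxels in ", path, "; replaced with 0")
    dat[!is.finite(dat)] <- 0
  }
  spacing <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  origin <- as.numeric(xf[1:3, 4])
  image_volume(dat, spacing = spacing, origin = origin, modality = modality)
}

#' Read a binary mask from NIfTI
#' @param path NIfTI file; any non-zero voxel is in the mask.
#' @param label Role tag for the returned mask.
#' @return A [binary_mask()].
#' @export
read_mask <- function(path, label = "mask") {
  vol <- read_volume(path, modality = "CT")
  binary_mask(vol$data != 0, spacing = vol$spacing, origin = vol$origin,
              label = label)
}

#' Write a volume or mask as NIfTI-1
#'
#' Volumes are stored as 32-bit float, masks as uint8 0/1. The lattice
#' (spacing and origin) is stored in the qform/sform so that
#' [read_volume()] round-trips it.
#'
#' @param vol An [image_volume()] or [binary_mask()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  is_mask <- inherits(vol, "binary_mask")
  dat <- vol$data
  if (is_mask) {
    dat <- array(as.integer(dat), dim = dim(dat))
  } else {
    dat <- array(as.numeric(dat), dim = dim(dat))
  }
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- vol$spacing
  mat <- diag(c(vol$spacing, 1))
  mat[1:3, 4] <- vol$origin
  RNifti::qform(img) <- structure(mat, code = 2L)
  RNifti::sform(img) <- structure(mat, code = 2L)
  RNifti::writeNifti(img, path,
                     datatype = if (is_mask) "uint8" else "float")
  invisible(path)
}

#' Read a table of pulmonary function test indices
#'
#' Expects a delimited text file with header
#' `case_id,FEV1_FVC,FEV1_pct_pred,DLCO_pct_pred,FVC_pct_pred`.
#' FEV1/FVC is a fraction; the others are percent of predicted.
#'
#' @param path CSV path.
#' @return A data.frame with one row per case.
#' @export
read_pft_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("case_id", "FEV1_FVC", "FEV1_pct_pred", "DLCO_pct_pred",
              "FVC_pct_pred")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0)
    stop("PFT table missing columns: ", paste(missing_cols, collapse = ", "))
  for (col in needed[-1]) {
    bad <- !is.na(tab[[col]]) & (!is.finite(tab[[col]]) | tab[[col]] <= 0)
    if (any(bad))
      stop("PFT column ", col, " has non-positive or non-finite values")
  }
  tab
}

#' Write a PFT table
#' @param tab Data frame as returned by [read_pft_table()].
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
write_pft_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bundle CT and PET volumes for one case
#'
#' @param case_id Case identifier.
#' @param ct CT [image_volume()].
#' @param pet_vent,pet_perf Optional PET volumes on the CT lattice.
#' @param pft Optional named list/vector of PFT indices
#'   (`FEV1_FVC`, `FEV1_pct_pred`, `DLCO_pct_pred`, `FVC_pct_pred`).
#' @return An object of class `case_record`.
#' @export
case_record <- function(case_id, ct, pet_vent = NULL, pet_perf = NULL,
                        pft = NULL) {
  stopifnot(inherits(ct, "image_volume"))
  if (!is.null(pet_vent)) assert_same_lattice(ct, pet_vent)
  if (!is.null(pet_perf)) assert_same_lattice(ct, pet_perf)
  if (!is.null(pft)) {
    pft <- as.list(pft)
    vals <- unlist(pft)
    if (any(!is.finite(vals) | vals <= 0))
      stop("PFT values must be finite and > 0")
  }
  structure(list(case_id = as.character(case_id), ct = ct,
                 pet_vent = pet_vent, pet_perf = pet_perf, pft = pft),
            class = "case_record")
}

#' @export
print.case_record <- function(x, ...) {
  cat(sprintf("<case_record '%s'> CT %s; vent PET: %s; perf PET: %s; PFT: %s\n",
              x$case_id, paste(dim(x$ct$data), collapse = "x"),
              if (is.null(x$pet_vent)) "absent" else "present",
              if (is.null(x$pet_perf)) "absent" else "present",
              if (is.null(x$pft)) "absent" else "present"))
  invisible(x)
}

#' Read a pipeline configuration file
#'
#' YAML (or flat `key: value`) file; unknown keys are rejected to catch
#' typos. Recognised keys mirror the arguments of [lungseg_params()],
#' [estimate_max()] and [threshold_sweep()].
#'
#' @param path YAML file path.
#' @return Named list of parameters merged over package defaults.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- default_config()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, cfg)
}

#' Default pipeline configuration
#' @return Named list of parameters.
#' @export
default_config <- function() {
  list(hu_threshold = -400, min_component_ml = 100, closing_radius_mm = 6,
       fill_holes = TRUE, exclude_airways = TRUE,
       airway_seed_policy = "top-slice",
       cutoffs_pct = c(5, 10, 15, 20, 25, 30, 40, 50),
       max_policy = "auto", peak_ratio = 1.5, max_hot_ml = 2.0,
       report_cutoff = 15)
}

# Structured log line; silent unless options(vqfv.verbose = TRUE).
vq_log <- function(stage, case_id = NULL, ...) {
  if (!isTRUE(getOption("vqfv.verbose", FALSE))) return(invisible(NULL))
  kv <- list(...)
  parts <- c(sprintf("stage=%s", stage),
             if (!is.null(case_id)) sprintf("case=%s", case_id),
             if (length(kv) > 0)
               paste0(names(kv), "=", vapply(kv, function(v)
                 paste(format(v, digits = 6), collapse = ","), "")))
  message("[vqfv] ", paste(parts, collapse = " "))
  invisible(NULL)
}
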