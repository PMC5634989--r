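#' 3-D image volume
#'
#' The basic container used throughout the package: a 3-D scalar array with
#' voxel spacing and physical origin. CT volumes carry Hounsfield units,
#' PET volumes carry activity in arbitrary units (interpreted as expected
#' counts per voxel when Poisson noise is simulated).
#'
#' @param data Numeric 3-D array. Must be finite everywhere.
#' @param spacing Numeric length-3, voxel size in mm per axis; all > 0.
#' @param origin Numeric length-3, physical position (mm) of voxel (1,1,1).
#' @param modality One of `"CT"`, `"PET_VENT"`, `"PET_PERF"`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         modality = c("CT", "PET_VENT", "PET_PERF")) {
  modality <- match.arg(modality)
  if (length(dim(data)) != 3L)
    stop("'data' must be a 3-D array")
  if (!all(is.finite(data)))
    stop("'data' contains non-finite values")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be three positive voxel sizes (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be three finite coordinates (mm)")
  structure(list(data = data, spacing = spacing, origin = origin,
                 modality = modality),
            class = "image_volume")
}

#' Binary mask on the lattice of a parent volume
#'
#' A voxel is wholly in or out of a mask; physical volume is voxel count
#' times voxel volume. Masks share the spacing/origin of the volume they
#' were derived from.
#'
#' @param data Logical 3-D array (numeric arrays are coerced with `!= 0`).
#' @param spacing,origin Lattice, as for [image_volume()].
#' @param label Free-text role tag, e.g. `"WL"`, `"functional"`, `"truth"`.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        label = "mask") {
  if (length(dim(data)) != 3L)
    stop("'data' must be a 3-D array")
  if (!is.logical(data)) {
    if (any(!is.finite(data))) stop("'data' contains non-finite values")
    data <- array(data != 0, dim = dim(data))
  }
  if (anyNA(data)) stop("'data' contains NA")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be three positive voxel sizes (mm)")
  structure(list(data = data, spacing = spacing, origin = origin,
                 label = as.character(label)[1]),
            class = "binary_mask")
}

#' Derive a mask from a volume on the same lattice
#' @param vol An [image_volume()].
#' @param data Logical array with the volume's dimensions.
#' @param label Role tag.
#' @return A [binary_mask()].
#' @export
mask_like <- function(vol, data, label = "mask") {
  stopifnot(identical(dim(data), dim(vol$data)))
  binary_mask(data, spacing = vol$spacing, origin = vol$origin, label = label)
}

#' Voxel volume in millilitres
#' @param x An `image_volume` or `binary_mask`.
#' @return Product of the three spacings divided by 1000 (mm^3 -> ml).
#' @export
voxel_volume_ml <- function(x) prod(x$spacing) / 1000

#' Number of voxels inside a mask
#' @param mask A `binary_mask`.
#' @return Integer count of `TRUE` voxels.
#' @export
voxel_count <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$data)
}

#' Physical mask volume in millilitres
#' @param mask A `binary_mask`.
#' @return `voxel_count(mask) * voxel_volume_ml(mask)`.
#' @export
mask_volume_ml <- function(mask) voxel_count(mask) * voxel_volume_ml(mask)

#' Check that two objects live on the same voxel lattice
#'
#' Inter-volume operations in this package never resample silently; they
#' require identical grids and raise immediately otherwise, signalling that
#' the caller must resample upstream.
#'
#' @param a,b `image_volume` or `binary_mask` objects.
#' @param tol_mm Tolerance on spacing/origin agreement, in mm.
#' @return Invisibly `TRUE`; raises an error on mismatch.
#' @export
assert_same_lattice <- function(a, b, tol_mm = 1e-3) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("lattice mismatch: shapes ", paste(dim(a$data), collapse = "x"),
         " vs ", paste(dim(b$data), collapse = "x"))
  if (max(abs(a$spacing - b$spacing)) > tol_mm)
    stop("lattice mismatch: spacings differ by more than ", tol_mm, " mm")
  if (max(abs(a$origin - b$origin)) > tol_mm)
    stop("lattice mismatch: origins differ by more than ", tol_mm, " mm")
  invisible(TRUE)
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume %s> %s voxels, spacing %s mm, origin %s mm\n",
              x$modality, paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(format(x$origin), collapse = ",")))
  cat(sprintf("  range [%.3g, %.3g], voxel volume %.4g ml\n",
              min(x$data), max(x$data), voxel_volume_ml(x)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  n <- sum(x$data)
  cat(sprintf("<binary_mask '%s'> %s voxels, %d in mask (%.1f ml)\n",
              x$label, paste(dim(x$data), collapse = "x"), n,
              n * voxel_volume_ml(x)))
  invisible(x)
}
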