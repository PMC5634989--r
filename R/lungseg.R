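#' Parameters for whole-lung CT segmentation
#'
#' @param hu_threshold Voxels below this HU are lung candidates; must be
#'   in (-1000, 0). Default -400 separates aerated lung from soft tissue.
#' @param min_component_ml Minimum connected-component volume retained, ml.
#' @param closing_radius_mm Morphological closing radius, mm.
#' @param fill_holes Fill interior cavities after closing.
#' @param exclude_airways Remove trachea/main bronchi via a stricter HU
#'   region grow seeded in the top slice.
#' @param airway_hu Stricter HU cutoff used by the airway region grow.
#' @param airway_max_ml Grown airway regions larger than this are assumed
#'   to be lung and kept.
#' @return A list of class `lungseg_params`.
#' @export
lungseg_params <- function(hu_threshold = -400, min_component_ml = 100,
                           closing_radius_mm = 6, fill_holes = TRUE,
                           exclude_airways = TRUE, airway_hu = -950,
                           airway_max_ml = 80) {
  if (hu_threshold <= -1000 || hu_threshold >= 0)
    stop("hu_threshold must be in (-1000, 0)")
  if (min_component_ml <= 0) stop("min_component_ml must be > 0")
  structure(list(hu_threshold = hu_threshold,
                 min_component_ml = min_component_ml,
                 closing_radius_mm = closing_radius_mm,
                 fill_holes = fill_holes,
                 exclude_airways = exclude_airways,
                 airway_hu = airway_hu, airway_max_ml = airway_max_ml),
            class = "lungseg_params")
}

#' Delineate the whole-lung volume on CT
#'
#' Thresholds the CT at `hu_threshold`, discards air connected to the grid
#' border (outside-body air), keeps the up-to-two largest remaining
#' components of at least `min_component_ml` (left/right lungs, possibly
#' merged at the mediastinum), applies morphological closing and hole
#' filling, and optionally removes the trachea and main bronchi.
#'
#' @param ct CT [image_volume()].
#' @param params A [lungseg_params()].
#' @return A [binary_mask()] labelled `"WL"`.
#' @export
segment_lungs <- function(ct, params = lungseg_params()) {
  stopifnot(inherits(ct, "image_volume"))
  if (ct$modality != "CT") stop("segment_lungs requires a CT volume")
  p <- params
  raw <- ct$data < p$hu_threshold
  inside <- raw & !border_connected(raw, connectivity = 6L)

  lab <- cc_label(inside, connectivity = 26L)
  sizes <- attr(lab, "component_sizes")
  vvol <- voxel_volume_ml(ct)
  keep <- which(sizes * vvol >= p$min_component_ml)
  if (length(keep) == 0)
    stop("no lung-sized component (>= ", p$min_component_ml,
         " ml) below ", p$hu_threshold, " HU; non-thoracic or corrupt CT?")
  keep <- keep[seq_len(min(2L, length(keep)))]  # components sorted by size
  mask <- array(lab %in% keep, dim = dim(lab))

  if (p$closing_radius_mm > 0)
    mask <- close_ball(mask, p$closing_radius_mm, ct$spacing)
  if (p$fill_holes)
    mask <- fill_holes3d(mask)

  if (p$exclude_airways) {
    airway <- grow_airways(ct, mask, p)
    mask <- mask & !airway
  }
  vq_log("lungseg", n_voxels = sum(mask), volume_ml = sum(mask) * vvol)
  mask_like(ct, mask, label = "WL")
}

# Trachea/main-bronchus removal: region-grow voxels below `airway_hu`
# (near-air lumen) from seeds in the top axial slice of the current mask;
# grown components exceeding `airway_max_ml` are treated as lung, not
# airway, and retained.
grow_airways <- function(ct, mask, p) {
  dims <- dim(ct$data)
  out <- array(FALSE, dim = dims)
  lumen <- mask & ct$data < p$airway_hu
  if (!any(lumen)) return(out)
  top_z <- max(which(apply(mask, 3, any)))
  seeds <- lumen[, , top_z]
  if (!any(seeds)) return(out)
  lab <- cc_label(lumen, connectivity = 26L)
  seed_labels <- unique(as.vector(lab[, , top_z][seeds]))
  seed_labels <- seed_labels[seed_labels != 0L]
  sizes <- attr(lab, "component_sizes")
  vvol <- voxel_volume_ml(ct)
  for (l in seed_labels)
    if (sizes[l] * vvol <= p$airway_max_ml)
      out <- out | (lab == l)
  out
}

#' Apply scripted spherical edits to a mask
#'
#' The expert's "visually adjusted to match normal contours" step,
#' expressed as a reproducible edit list rather than a GUI action. Edits
#' are applied in order.
#'
#' @param mask A [binary_mask()].
#' @param edits List of `list(op = "add"|"remove", center_vox =, radius_mm =)`.
#' @return The edited [binary_mask()].
#' @export
manual_adjust <- function(mask, edits = list()) {
  stopifnot(inherits(mask, "binary_mask"))
  dat <- mask$data
  dims <- dim(dat)
  for (e in edits) {
    op <- match.arg(e$op, c("add", "remove"))
    sp <- sphere_voxels(dims, mask$spacing, e$center_vox, e$radius_mm)
    if (!any(sp))
      stop("edit sphere entirely outside the grid")
    if (op == "add") dat <- dat | sp else dat <- dat & !sp
  }
  binary_mask(dat, spacing = mask$spacing, origin = mask$origin,
              label = mask$label)
}
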