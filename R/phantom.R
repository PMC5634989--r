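# Digital thoracic phantom: paired CT + V/Q PET with known ground truth.
#
# The scene is deliberately simple — two ellipsoidal lungs inside an
# elliptic-cylinder body — because the quantity under test is the
# percentage-of-maximum threshold method, not anatomical realism. The PET
# chain reproduces the degradations that matter for that method: a
# gravity-dependent anterior-posterior activity gradient, focal functional
# defects, airway-deposition hot spots (ventilation only), Gaussian
# point-spread blur, and Poisson counting noise.

.vq_cache <- new.env(parent = emptyenv())

default_lung_geometry <- function() {
  list(
    right = list(center_mm = c(-52, 0, 0), half_axes_mm = c(38, 55, 75)),
    left = list(center_mm = c(52, 0, 0), half_axes_mm = c(38, 55, 75)),
    body_half_axes_mm = c(110, 90),
    shell_mm = 6
  )
}

#' Specification of a synthetic thoracic phantom
#'
#' @param shape Grid dimensions in voxels (x = left-right,
#'   y = anterior-posterior with posterior at larger y, z = cranio-caudal).
#' @param spacing Voxel size in mm per axis.
#' @param lung_geometry Two ellipsoid parameter sets plus body ellipse; see
#'   [default_lung_geometry()]. Centers are in mm relative to grid center.
#' @param background_hu Soft-tissue CT value inside the body (HU).
#' @param lung_hu CT value inside the lungs (HU).
#' @param body_hu CT value of the thin body-surface shell (HU).
#' @param functional_fraction Target fraction of the whole lung that is
#'   functional, in (0, 1]. When below 1 and no defect radii are fixed,
#'   defect spheres are sized automatically to reach this target.
#' @param ap_gradient Fractional activity increase from the most anterior
#'   to the most posterior lung voxel; >= 0.
#' @param defects List of `list(center_vox =, radius_mm =, activity_multiplier =)`
#'   entries. `center_vox = NULL` draws a random center inside a lung;
#'   `radius_mm = NULL` marks the defect for automatic sizing.
#' @param hotspots List of `list(center_vox =, radius_mm =, intensity_multiplier =)`
#'   entries; Gaussian blobs of peak `intensity_multiplier` times the local
#'   activity, applied to the ventilation image only (airway deposition).
#' @param base_activity Expected counts per voxel in normal anterior lung.
#' @param psf_fwhm_mm Gaussian point-spread FWHM in mm (0 disables blur).
#' @param noise `"poisson"` or `"none"`.
#' @param scatter_floor Activity outside the lungs, as a fraction of
#'   `base_activity`.
#' @param seed Integer seed; (spec, seed) fully determines every array.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 48), spacing = c(4, 4, 4),
                         lung_geometry = default_lung_geometry(),
                         background_hu = 40, lung_hu = -750, body_hu = 100,
                         functional_fraction = 1, ap_gradient = 0.3,
                         defects = NULL, hotspots = NULL,
                         base_activity = 200, psf_fwhm_mm = 8,
                         noise = c("poisson", "none"),
                         scatter_floor = 0.02, seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(length(shape) == 3, all(shape >= 8),
            length(spacing) == 3, all(spacing > 0),
            base_activity > 0, ap_gradient >= 0, psf_fwhm_mm >= 0,
            functional_fraction > 0, functional_fraction <= 1)
  for (d in defects) {
    m <- d$activity_multiplier
    if (is.null(m) || m < 0 || m >= 1)
      stop("defect activity_multiplier must be in [0, 1)")
  }
  for (h in hotspots) {
    m <- h$intensity_multiplier
    if (is.null(m) || m <= 1)
      stop("hotspot intensity_multiplier must be > 1")
  }
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 lung_geometry = lung_geometry,
                 background_hu = background_hu, lung_hu = lung_hu,
                 body_hu = body_hu,
                 functional_fraction = functional_fraction,
                 ap_gradient = ap_gradient, defects = defects,
                 hotspots = hotspots, base_activity = base_activity,
                 psf_fwhm_mm = psf_fwhm_mm, noise = noise,
                 scatter_floor = scatter_floor, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Evaluate and restore the global RNG state around `expr`.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Axis coordinate grids in mm relative to the grid center.
axis_mm <- function(shape, spacing)
  lapply(1:3, function(k) (seq_len(shape[k]) - (shape[k] + 1) / 2) * spacing[k])

ellipsoid_mask <- function(shape, spacing, center_mm, half_axes_mm) {
  ax <- axis_mm(shape, spacing)
  u2 <- ((ax[[1]] - center_mm[1]) / half_axes_mm[1])^2
  v2 <- ((ax[[2]] - center_mm[2]) / half_axes_mm[2])^2
  w2 <- ((ax[[3]] - center_mm[3]) / half_axes_mm[3])^2
  array(outer(outer(u2, v2, "+"), w2, "+") <= 1, dim = shape)
}

# Static scene geometry, cached per (shape, spacing, lung_geometry).
phantom_geometry <- function(spec) {
  key <- paste(utils::capture.output(str(list(spec$shape, spec$spacing,
                                              spec$lung_geometry))),
               collapse = ";")
  if (!is.null(.vq_cache[[key]])) return(.vq_cache[[key]])
  g <- spec$lung_geometry
  lung_r <- ellipsoid_mask(spec$shape, spec$spacing,
                           g$right$center_mm, g$right$half_axes_mm)
  lung_l <- ellipsoid_mask(spec$shape, spec$spacing,
                           g$left$center_mm, g$left$half_axes_mm)
  lung <- lung_r | lung_l
  ax <- axis_mm(spec$shape, spec$spacing)
  bx <- g$body_half_axes_mm
  e2_in <- outer((ax[[1]] / bx[1])^2, (ax[[2]] / bx[2])^2, "+")
  e2_out <- outer((ax[[1]] / (bx[1] + g$shell_mm))^2,
                  (ax[[2]] / (bx[2] + g$shell_mm))^2, "+")
  body <- array(rep(e2_in <= 1, spec$shape[3]), dim = spec$shape)
  shell <- array(rep(e2_out <= 1 & e2_in > 1, spec$shape[3]),
                 dim = spec$shape)
  ys <- which(apply(lung, 2, any))
  depth <- rep(0, spec$shape[2])
  if (length(ys) > 1)
    depth[ys] <- (ys - min(ys)) / (max(ys) - min(ys))
  depth_arr <- array(rep(rep(depth, each = spec$shape[1]), spec$shape[3]),
                     dim = spec$shape)
  # per-lung-voxel bookkeeping reused by the defect-sizing search
  lung_idx <- which(lung)
  co <- arrayInd(lung_idx, spec$shape)
  lung_mm <- sweep(sweep(co, 2, (spec$shape + 1) / 2), 2, spec$spacing, "*")
  interior <- lung &
    shift_array(lung, c(2L, 0L, 0L)) & shift_array(lung, c(-2L, 0L, 0L)) &
    shift_array(lung, c(0L, 2L, 0L)) & shift_array(lung, c(0L, -2L, 0L)) &
    shift_array(lung, c(0L, 0L, 2L)) & shift_array(lung, c(0L, 0L, -2L))
  out <- list(lung = lung, lung_right = lung_r, lung_left = lung_l,
              body = body, shell = shell, depth = depth_arr,
              lung_idx = lung_idx, lung_mm = lung_mm,
              interior_idx = which(interior))
  .vq_cache[[key]] <- out
  out
}

# Fraction of lung that is functional given a defect region and multipliers.
truth_from_defects <- function(act_normal, lung, defect_region) {
  normal <- lung & !defect_region$any
  # reference mean: non-defect lung; falls back to the healthy activity map
  # over the whole lung when the defects cover it entirely
  thr <- 0.5 * mean(act_normal[if (any(normal)) normal else lung])
  act <- act_normal
  act[defect_region$any] <- act[defect_region$any] *
    defect_region$mult[defect_region$any]
  lung & (act >= thr)
}

# Rasterise the defect list at radius scale `s` (applied to auto-sized
# defects only). Returns the union and a per-voxel multiplier (min over
# overlapping defects).
defect_region <- function(spec, defects, scale = 1) {
  dims <- spec$shape
  any_mask <- array(FALSE, dim = dims)
  mult <- array(1, dim = dims)
  for (d in defects) {
    r <- if (is.null(d$radius_mm)) scale else d$radius_mm
    if (r <= 0) next
    sp <- sphere_voxels(dims, spec$spacing, d$center_vox, r)
    any_mask <- any_mask | sp
    mult[sp] <- pmin(mult[sp], d$activity_multiplier)
  }
  list(any = any_mask, mult = mult)
}

#' Generate one synthetic phantom case
#'
#' Builds the CT (air -1000 HU outside the body, `body_hu` shell,
#' `background_hu` soft tissue, `lung_hu` lungs) and the ventilation and
#' perfusion PET volumes. Pre-degradation activity is
#' `base_activity * (1 + ap_gradient * depth)` inside the lung, reduced by
#' each defect's multiplier inside defect spheres, and a small scatter
#' floor outside the lungs. Ground truth is defined on this pre-blur,
#' pre-noise map: a voxel is functional when its activity is at least 50%
#' of the normal-lung mean. Hot spots, point-spread blur and Poisson noise
#' are then applied to the PET only.
#'
#' Poisson noise uses one random substream for the hot-spot-free activity
#' and a separate substream for hot-spot-affected voxels, so two phantoms
#' generated from the same seed with and without hot spots are voxelwise
#' identical outside the hot-spot support.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_case` with elements `case`
#'   (a [case_record()]), `truth_wl`, `truth_functional_vent`,
#'   `truth_functional_perf`, `true_fraction_vent`, `true_fraction_perf`,
#'   and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  geom <- phantom_geometry(spec)
  dims <- spec$shape
  lung <- geom$lung
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 4L)

  # --- CT ---
  ct <- array(-1000, dim = dims)
  ct[geom$shell] <- spec$body_hu
  ct[geom$body] <- spec$background_hu
  ct[lung] <- spec$lung_hu

  # --- defects ---
  defects <- spec$defects
  if (is.null(defects) && spec$functional_fraction < 1)
    defects <- list(list(center_vox = NULL, radius_mm = NULL,
                         activity_multiplier = 0.1))
  defects <- lapply(defects, function(d) {
    if (is.null(d$center_vox)) {
      # sub-voxel jitter de-degenerates voxel-to-center distances so that
      # the radius search can hit the target fraction to ~1-voxel accuracy
      d$center_vox <- random_lung_center(geom, dims) +
        stats::runif(3, -0.49, 0.49)
    }
    rc <- pmin(pmax(round(d$center_vox), 1), dims)
    if (!lung[rc[1], rc[2], rc[3]])
      stop("defect centered outside the lungs")
    d
  })
  for (h in spec$hotspots) {
    if (is.null(h$center_vox))
      stop("hotspot requires a center_vox")
    rc <- pmin(pmax(round(h$center_vox), 1), dims)
    if (!lung[rc[1], rc[2], rc[3]])
      stop("hotspot centered outside the lungs")
  }

  act_normal <- array(spec$scatter_floor * spec$base_activity, dim = dims)
  act_normal[lung] <- spec$base_activity *
    (1 + spec$ap_gradient * geom$depth[lung])

  need_sizing <- any(vapply(defects, function(d) is.null(d$radius_mm), TRUE))
  if (need_sizing) {
    target <- spec$functional_fraction
    # work on vectors over lung voxels only; the full grid is only touched
    # once the common radius scale has been found
    act_lung <- act_normal[geom$lung_idx]
    ctr_mm <- lapply(defects, function(d)
      (d$center_vox - (spec$shape + 1) / 2) * spec$spacing)
    d2 <- vapply(ctr_mm, function(cm)
      (geom$lung_mm[, 1] - cm[1])^2 + (geom$lung_mm[, 2] - cm[2])^2 +
        (geom$lung_mm[, 3] - cm[3])^2, numeric(nrow(geom$lung_mm)))
    mults <- vapply(defects, `[[`, 0, "activity_multiplier")
    frac_at <- function(s) {
      r2 <- vapply(defects, function(d)
        if (is.null(d$radius_mm)) s^2 else d$radius_mm^2, 0)
      mult <- rep(1, length(act_lung))
      for (j in seq_along(defects)) {
        inside <- d2[, j] <= r2[j]
        mult[inside] <- pmin(mult[inside], mults[j])
      }
      normal <- mult == 1
      thr <- 0.5 * mean(act_lung[if (any(normal)) normal else TRUE])
      mean(act_lung * mult >= thr)
    }
    lo <- 0; hi <- max(dims * spec$spacing)
    if (frac_at(hi) > target + 0.02)
      stop("functional_fraction unreachable given defect list")
    for (i in 1:40) {
      mid <- (lo + hi) / 2
      if (frac_at(mid) > target) lo <- mid else hi <- mid
    }
    scale <- (lo + hi) / 2
  } else {
    scale <- 1
  }
  reg <- defect_region(spec, defects, scale = scale)
  truth <- truth_from_defects(act_normal, lung, reg)
  true_fraction <- sum(truth) / sum(lung)
  if (need_sizing && abs(true_fraction - spec$functional_fraction) > 0.02)
    stop("functional_fraction unreachable given defect list")

  # --- pre-blur activity with defects applied ---
  act0 <- act_normal
  act0[reg$any] <- act0[reg$any] * reg$mult[reg$any]

  # --- hot spots (ventilation only by default): truncated Gaussian blobs
  hot0 <- array(0, dim = dims)
  hot_support <- array(FALSE, dim = dims)
  for (h in spec$hotspots) {
    sigma <- h$radius_mm / 2
    supp <- sphere_voxels(dims, spec$spacing, h$center_vox, 3 * h$radius_mm)
    idx <- which(supp)
    co <- arrayInd(idx, dims)
    d2 <- ((co[, 1] - h$center_vox[1]) * spec$spacing[1])^2 +
      ((co[, 2] - h$center_vox[2]) * spec$spacing[2])^2 +
      ((co[, 3] - h$center_vox[3]) * spec$spacing[3])^2
    local <- act0[h$center_vox[1], h$center_vox[2], h$center_vox[3]]
    blob <- (h$intensity_multiplier - 1) * local * exp(-d2 / (2 * sigma^2))
    core <- d2 <= h$radius_mm^2
    hot0[idx[core]] <- hot0[idx[core]] + blob[core]
    hot_support <- hot_support | supp
  }

  # --- PSF blur; blur is linear, so base and hot-spot fields are blurred
  # separately and the hot-spot contribution is clipped to its support so
  # that phantoms with and without hot spots agree exactly elsewhere.
  act_blur <- gaussian_blur3d(act0, spec$psf_fwhm_mm, spec$spacing)
  if (any(hot0 > 0)) {
    hot_blur <- gaussian_blur3d(hot0, spec$psf_fwhm_mm, spec$spacing)
    hot_blur[!hot_support] <- 0
  } else {
    hot_blur <- hot0
  }

  lam_vent <- act_blur + hot_blur
  lam_perf <- act_blur
  vent <- apply_noise(lam_vent, act_blur, spec$noise,
                      sub_seeds[1], sub_seeds[2])
  perf <- apply_noise(lam_perf, lam_perf, spec$noise,
                      sub_seeds[3], sub_seeds[4])

  sp <- spec$spacing
  case <- case_record(
    case_id = sprintf("phantom-%08d", spec$seed),
    ct = image_volume(ct, spacing = sp, modality = "CT"),
    pet_vent = image_volume(vent, spacing = sp, modality = "PET_VENT"),
    pet_perf = image_volume(perf, spacing = sp, modality = "PET_PERF"))
  mk <- function(m, lab) binary_mask(m, spacing = sp, label = lab)
  structure(list(case = case,
                 truth_wl = mk(lung, "WL"),
                 truth_functional_vent = mk(truth, "truth"),
                 truth_functional_perf = mk(truth, "truth"),
                 true_fraction_vent = true_fraction,
                 true_fraction_perf = true_fraction,
                 spec = spec),
            class = "phantom_case")
}

# Poisson noise with a split stream: `lam_base` voxels use `seed_main`;
# voxels where lam differs from lam_base (hot-spot influence) are redrawn
# from `seed_alt`, giving common random numbers for paired phantoms.
apply_noise <- function(lam, lam_base, noise, seed_main, seed_alt) {
  if (noise == "none") return(lam)
  n <- length(lam)
  counts <- with_seed(seed_main, rpois(n, lam_base))
  diff_idx <- which(lam != lam_base)
  if (length(diff_idx) > 0)
    counts[diff_idx] <- with_seed(seed_alt,
                                  rpois(length(diff_idx), lam[diff_idx]))
  array(as.numeric(counts), dim = dim(lam))
}

# Draw a voxel center uniformly inside the interior of one lung (kept away
# from the lung surface so auto-sized defects stay lung-centered).
random_lung_center <- function(geom, dims) {
  idx <- geom$interior_idx
  arrayInd(idx[sample.int(length(idx), 1L)], dims)[1, ]
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf(paste0("<phantom_case '%s'> grid %s @ %s mm, WL %d voxels,\n",
                     "  true functional fraction %.3f (vent) / %.3f (perf)\n"),
              x$case$case_id, paste(x$spec$shape, collapse = "x"),
              paste(x$spec$spacing, collapse = "x"),
              voxel_count(x$truth_wl),
              x$true_fraction_vent, x$true_fraction_perf))
  invisible(x)
}
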