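# Core method: reference-maximum estimation (excluding airway-deposition
# hot spots) and functional volume delineation at fractional thresholds of
# that maximum.

#' Estimate the reference maximum activity inside the lungs
#'
#' The delineation thresholds are fractions of a reference maximum that
#' must not be inflated by focal airway-deposition hot spots. Three
#' policies are available:
#' \describe{
#'   \item{auto}{Compute the 99.5th percentile of in-lung activity; flag
#'     26-connected clusters of voxels above `peak_ratio` times that
#'     percentile whose volume is at most `max_hot_ml` as hot spots;
#'     dilate the flagged clusters by `exclusion_margin_mm` to cover the
#'     partial-volume penumbra; the reference maximum is the maximum over
#'     the lung minus the excluded region. If nothing is flagged the value
#'     equals the raw in-lung maximum.}
#'   \item{manual_value}{Use `manual_value` as given (the operator read
#'     the maximum off the display).}
#'   \item{manual_roi}{Maximum over the lung minus an operator-drawn
#'     exclusion region.}
#' }
#'
#' @param pet PET [image_volume()].
#' @param wl Whole-lung [binary_mask()] on the same lattice.
#' @param policy `"auto"`, `"manual_value"` or `"manual_roi"`.
#' @param manual_value Positive scalar, required for `manual_value`.
#' @param manual_roi [binary_mask()] of voxels to exclude, required for
#'   `manual_roi`.
#' @param auto_params List with `peak_ratio` (default 1.5), `max_hot_ml`
#'   (default 2.0) and `exclusion_margin_mm` (default 8).
#' @return An object of class `max_estimate` with fields `value`,
#'   `excluded_mask`, `policy` and `diagnostics`
#'   (`raw_max`, `p995`, `n_excluded_voxels`).
#' @export
estimate_max <- function(pet, wl,
                         policy = c("auto", "manual_value", "manual_roi"),
                         manual_value = NULL, manual_roi = NULL,
                         auto_params = list()) {
  policy <- match.arg(policy)
  stopifnot(inherits(pet, "image_volume"), inherits(wl, "binary_mask"))
  assert_same_lattice(pet, wl)
  if (voxel_count(wl) == 0) stop("empty whole-lung mask")
  ap <- utils::modifyList(list(peak_ratio = 1.5, max_hot_ml = 2.0,
                               exclusion_margin_mm = 8), auto_params)
  in_lung <- pet$data[wl$data]
  raw_max <- max(in_lung)
  p995 <- as.numeric(stats::quantile(in_lung, 0.995, names = FALSE))
  excluded <- array(FALSE, dim = dim(pet$data))

  if (policy == "manual_value") {
    if (is.null(manual_value) || manual_value <= 0)
      stop("manual_value policy requires a positive manual_value")
    value <- manual_value
  } else if (policy == "manual_roi") {
    if (is.null(manual_roi)) stop("manual_roi policy requires manual_roi")
    assert_same_lattice(pet, manual_roi)
    excluded <- manual_roi$data
    rest <- wl$data & !excluded
    if (!any(rest)) stop("all in-lung voxels excluded by manual ROI")
    value <- max(pet$data[rest])
  } else {
    hot_cand <- wl$data & (pet$data > ap$peak_ratio * p995)
    if (any(hot_cand)) {
      lab <- cc_label(hot_cand, connectivity = 26L)
      sizes <- attr(lab, "component_sizes")
      vvol <- voxel_volume_ml(pet)
      small <- which(sizes * vvol <= ap$max_hot_ml)
      if (length(small) > 0) {
        core <- array(lab %in% small, dim = dim(lab))
        excluded <- if (ap$exclusion_margin_mm > 0)
          dilate_ball(core, ap$exclusion_margin_mm, pet$spacing) else core
      }
    }
    rest <- wl$data & !excluded
    if (!any(rest)) stop("all in-lung voxels excluded as hot spots")
    value <- max(pet$data[rest])
  }
  if (value <= 0) stop("non-positive reference maximum")
  vq_log("estimate_max", policy = policy, value = value, raw_max = raw_max,
         n_excluded = sum(excluded & wl$data))
  structure(list(value = value,
                 excluded_mask = mask_like(pet, excluded,
                                           label = "hotspot-exclusion"),
                 policy = policy,
                 diagnostics = list(raw_max = raw_max, p995 = p995,
                                    n_excluded_voxels = sum(excluded & wl$data))),
            class = "max_estimate")
}

#' @export
print.max_estimate <- function(x, ...) {
  cat(sprintf("<max_estimate %s> value %.4g (raw max %.4g, P99.5 %.4g), %d voxels excluded\n",
              x$policy, x$value, x$diagnostics$raw_max, x$diagnostics$p995,
              x$diagnostics$n_excluded_voxels))
  invisible(x)
}

#' Delineate the functional volume at one %max cutoff
#'
#' The functional mask is the set of in-lung voxels whose activity is at
#' least `cutoff_pct`% of the reference maximum (a voxel exactly at the
#' threshold is inside). The volume is reported as a percentage of the
#' whole-lung volume.
#'
#' @param pet PET [image_volume()].
#' @param wl Whole-lung [binary_mask()].
#' @param max_est A [estimate_max()] result (or a positive scalar).
#' @param cutoff_pct Percentage of the reference maximum, in (0, 100).
#' @return A list: `mask` ([binary_mask()]), `abs_threshold`,
#'   `volume_pct_wl`, `cutoff_pct`.
#' @export
delineate_at <- function(pet, wl, max_est, cutoff_pct) {
  stopifnot(cutoff_pct > 0, cutoff_pct < 100)
  assert_same_lattice(pet, wl)
  n_wl <- voxel_count(wl)
  if (n_wl == 0) stop("empty whole-lung mask")
  value <- if (inherits(max_est, "max_estimate")) max_est$value else max_est
  stopifnot(value > 0)
  thr <- (cutoff_pct / 100) * value
  mask <- wl$data & (pet$data >= thr)
  list(mask = mask_like(pet, mask, label = "functional"),
       abs_threshold = thr,
       volume_pct_wl = 100 * sum(mask) / n_wl,
       cutoff_pct = cutoff_pct)
}

#' Delineate at a series of %max cutoffs
#'
#' Runs [delineate_at()] for each cutoff. Because every mask is a
#' superlevel set of the same activity map, masks are nested and volumes
#' non-increasing in the cutoff by construction; thresholds are fractions
#' of the maximum, so rescaling the PET by any positive factor leaves all
#' masks unchanged.
#'
#' @param pet PET [image_volume()].
#' @param wl Whole-lung [binary_mask()].
#' @param max_est A [estimate_max()] result (or positive scalar).
#' @param cutoffs_pct Strictly increasing percentages in (0, 100).
#' @return An object of class `threshold_sweep`: `cutoffs_pct`, `masks`
#'   (list), `abs_thresholds`, `volumes_pct_wl`, `max_estimate`.
#' @export
threshold_sweep <- function(pet, wl, max_est,
                            cutoffs_pct = c(5, 10, 15, 20, 25, 30, 40, 50)) {
  stopifnot(length(cutoffs_pct) >= 1)
  if (any(diff(cutoffs_pct) <= 0))
    stop("cutoffs must be strictly increasing")
  res <- lapply(cutoffs_pct, function(c) delineate_at(pet, wl, max_est, c))
  structure(list(cutoffs_pct = cutoffs_pct,
                 masks = lapply(res, `[[`, "mask"),
                 abs_thresholds = vapply(res, `[[`, 0, "abs_threshold"),
                 volumes_pct_wl = vapply(res, `[[`, 0, "volume_pct_wl"),
                 max_estimate = if (inherits(max_est, "max_estimate"))
                   max_est else NULL),
            class = "threshold_sweep")
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat("<threshold_sweep>\n")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.threshold_sweep <- function(x, ...) {
  data.frame(cutoff_pct = x$cutoffs_pct,
             abs_threshold = x$abs_thresholds,
             voxels = vapply(x$masks, voxel_count, 0),
             volume_pct_wl = x$volumes_pct_wl)
}

#' Plot functional volume against threshold
#' @param x A [threshold_sweep()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.threshold_sweep <- function(x, ...) {
  graphics::plot(x$cutoffs_pct, x$volumes_pct_wl, type = "b", pch = 19,
                 xlab = "cutoff (% of reference max)",
                 ylab = "functional volume (% of whole lung)",
                 ylim = c(0, 100), ...)
  invisible(x)
}
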