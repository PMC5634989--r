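# Internal 3-D array utilities: shifting, binary morphology with a
# millimetre-radius ball element, hole filling via complement components,
# and separable Gaussian smoothing. All operate on plain arrays; the
# public functions wrap them with lattice bookkeeping.

# Shift array by integer voxel offsets, padding with `fill`.
shift_array <- function(a, d, fill = FALSE) {
  dm <- dim(a)
  out <- array(fill, dim = dm)
  src <- dst <- vector("list", 3L)
  for (k in 1:3) {
    if (d[k] >= 0) {
      if (d[k] >= dm[k]) return(out)
      src[[k]] <- seq_len(dm[k] - d[k])
      dst[[k]] <- seq_len(dm[k] - d[k]) + d[k]
    } else {
      if (-d[k] >= dm[k]) return(out)
      src[[k]] <- seq_len(dm[k] + d[k]) - d[k]
      dst[[k]] <- seq_len(dm[k] + d[k])
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Voxel offsets within a physical ball of radius_mm on an anisotropic grid.
ball_offsets <- function(radius_mm, spacing) {
  r <- pmax(0L, floor(radius_mm / spacing))
  g <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  d2 <- (g$dx * spacing[1])^2 + (g$dy * spacing[2])^2 + (g$dz * spacing[3])^2
  as.matrix(g[d2 <= radius_mm^2, , drop = FALSE])
}

dilate_ball <- function(mask, radius_mm, spacing) {
  off <- ball_offsets(radius_mm, spacing)
  out <- array(FALSE, dim = dim(mask))
  for (i in seq_len(nrow(off)))
    out <- out | shift_array(mask, off[i, ], fill = FALSE)
  out
}

erode_ball <- function(mask, radius_mm, spacing) {
  off <- ball_offsets(radius_mm, spacing)
  out <- array(TRUE, dim = dim(mask))
  for (i in seq_len(nrow(off)))
    out <- out & shift_array(mask, off[i, ], fill = FALSE)
  out
}

# Morphological closing; extensive on interior structures by construction.
close_ball <- function(mask, radius_mm, spacing)
  erode_ball(dilate_ball(mask, radius_mm, spacing), radius_mm, spacing)

cc_label <- function(mask, connectivity = 26L) {
  stopifnot(is.array(mask), is.logical(mask))
  lab <- .cc_label_cpp(as.vector(mask), dim(mask), as.integer(connectivity))
  sizes <- attr(lab, "component_sizes")
  lab <- array(as.integer(lab), dim = dim(mask))
  attr(lab, "component_sizes") <- sizes
  lab
}

# TRUE for voxels belonging to components that touch the grid border.
border_connected <- function(mask, connectivity = 6L) {
  lab <- cc_label(mask, connectivity)
  dm <- dim(lab)
  border_labels <- unique(c(lab[c(1, dm[1]), , ], lab[, c(1, dm[2]), ],
                            lab[, , c(1, dm[3])]))
  border_labels <- border_labels[border_labels != 0L]
  if (length(border_labels) == 0L) return(array(FALSE, dim = dm))
  array(lab %in% border_labels, dim = dm)
}

# Fill interior cavities: background components not connected to the border.
fill_holes3d <- function(mask) {
  holes <- !mask & !border_connected(!mask, connectivity = 6L)
  mask | holes
}

gaussian_kernel1d <- function(sigma_vox) {
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

# Separable Gaussian blur, zero padding outside the grid.
gaussian_blur3d <- function(a, fwhm_mm, spacing) {
  if (fwhm_mm <= 0) return(a)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  out <- a
  for (axis in 1:3) {
    sig <- sigma_mm / spacing[axis]
    if (sig < 1e-6) next
    k <- gaussian_kernel1d(sig)
    r <- (length(k) - 1L) %/% 2L
    acc <- array(0, dim = dim(out))
    for (j in seq_along(k)) {
      d <- c(0L, 0L, 0L)
      d[axis] <- j - 1L - r
      acc <- acc + k[j] * shift_array(out, d, fill = 0)
    }
    out <- acc
  }
  out
}

# Rasterise a sphere given a centre in voxel indices (1-based) and a
# radius in mm; returns a logical array.
sphere_voxels <- function(dims, spacing, center_vox, radius_mm) {
  out <- array(FALSE, dim = dims)
  r_vox <- ceiling(radius_mm / spacing)
  lo <- pmax(1, floor(center_vox - r_vox))
  hi <- pmin(dims, ceiling(center_vox + r_vox))
  if (any(lo > hi)) return(out)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  dx2 <- ((xs - center_vox[1]) * spacing[1])^2
  dy2 <- ((ys - center_vox[2]) * spacing[2])^2
  dz2 <- ((zs - center_vox[3]) * spacing[3])^2
  sub <- outer(outer(dx2, dy2, "+"), dz2, "+") <= radius_mm^2
  out[xs, ys, zs] <- sub
  out
}
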