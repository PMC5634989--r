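# Independent brute-force oracles and small fixture builders.

# Dice via enumerated voxel index sets (set formula, no array logic).
brute_dice <- function(a, b) {
  ia <- which(a$data)
  ib <- which(b$data)
  if (length(ia) + length(ib) == 0) return(1.0)
  2 * length(intersect(ia, ib)) / (length(ia) + length(ib))
}

# Pearson r by direct evaluation of the covariance / sd formula.
brute_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

# Two-sided p for Pearson r via the t transform, evaluated directly.
brute_pearson_p <- function(r, n) {
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), df = n - 2)
}

# Count of voxels within radius_mm of a (possibly fractional) voxel center,
# by exhaustive looping - the oracle for rasterised spheres.
brute_sphere_count <- function(dims, spacing, center_vox, radius_mm) {
  count <- 0L
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      d2 <- ((i - center_vox[1]) * spacing[1])^2 +
        ((j - center_vox[2]) * spacing[2])^2 +
        ((k - center_vox[3]) * spacing[3])^2
      if (d2 <= radius_mm^2) count <- count + 1L
    }
  count
}

rand_mask <- function(dims = c(6, 5, 4), p = 0.4, spacing = c(1, 1, 1)) {
  binary_mask(array(stats::runif(prod(dims)) < p, dims), spacing = spacing)
}

# Coarse phantom used where geometry detail does not matter (fast).
small_spec <- function(...) {
  phantom_spec(shape = c(32, 32, 24), spacing = c(8, 8, 8), ...)
}

# Noiseless, unblurred, gradient-free phantom: two-valued PET.
clean_spec <- function(...) {
  phantom_spec(ap_gradient = 0, psf_fwhm_mm = 0, noise = "none", ...)
}
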