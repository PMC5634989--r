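test_that("degenerate phantom is two-valued with full-lung truth", {
  ph <- generate_phantom(clean_spec(seed = 5))
  pet <- ph$case$pet_vent$data
  vals <- sort(unique(as.vector(pet)))
  expect_length(vals, 2)
  expect_equal(vals, c(0.02 * 200, 200))
  expect_identical(ph$truth_functional_vent$data, ph$truth_wl$data)
  expect_equal(ph$true_fraction_vent, 1)
  # CT scene: air outside, lung HU inside the lungs
  expect_equal(ph$case$ct$data[1, 1, 1], -1000)
  expect_true(all(ph$case$ct$data[ph$truth_wl$data] == -750))
})

test_that("auto-sized defects hit the target functional fraction", {
  for (frac in c(0.45, 0.7, 0.9)) {
    ph <- generate_phantom(small_spec(functional_fraction = frac,
                                      seed = round(100 * frac)))
    expect_lte(abs(ph$true_fraction_vent - frac), 0.02)
    # reported fraction is the realised voxel ratio
    expect_equal(ph$true_fraction_vent,
                 voxel_count(ph$truth_functional_vent) /
                   voxel_count(ph$truth_wl))
    expect_true(all(ph$truth_functional_vent$data <= ph$truth_wl$data))
  }
})

test_that("(spec, seed) fully determines every array", {
  sp <- small_spec(functional_fraction = 0.6, seed = 31,
                   hotspots = list(list(center_vox = c(9, 16, 12),
                                        radius_mm = 9,
                                        intensity_multiplier = 4)))
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$case$pet_vent$data, b$case$pet_vent$data)
  expect_identical(a$case$pet_perf$data, b$case$pet_perf$data)
  expect_identical(a$case$ct$data, b$case$ct$data)
  expect_identical(a$truth_functional_vent$data, b$truth_functional_vent$data)
  sp2 <- sp; sp2$seed <- 32L
  expect_false(identical(generate_phantom(sp2)$case$pet_vent$data,
                         a$case$pet_vent$data))
})

test_that("ventilation and perfusion share geometry but not noise", {
  ph <- generate_phantom(small_spec(functional_fraction = 0.7, seed = 8))
  expect_identical(ph$truth_functional_vent$data,
                   ph$truth_functional_perf$data)
  expect_false(identical(ph$case$pet_vent$data, ph$case$pet_perf$data))
})

test_that("adding a defect never increases the true fraction", {
  base <- small_spec(seed = 21)
  defect <- list(center_vox = c(9, 16, 12), radius_mm = 40,
                 activity_multiplier = 0.1)
  for (s in 1:4) {
    a <- base; a$seed <- s
    b <- a; b$defects <- list(defect)
    expect_lte(generate_phantom(b)$true_fraction_vent,
               generate_phantom(a)$true_fraction_vent)
  }
})

test_that("the AP gradient scales activity without changing truth", {
  mk <- function(g) small_spec(ap_gradient = g, seed = 3,
                               defects = list(list(center_vox = c(9, 16, 12),
                                                   radius_mm = 35,
                                                   activity_multiplier = 0.1)))
  t0 <- generate_phantom(mk(0))$truth_functional_vent$data
  t1 <- generate_phantom(mk(0.3))$truth_functional_vent$data
  t2 <- generate_phantom(mk(0.8))$truth_functional_vent$data
  expect_identical(t0, t1)
  expect_identical(t0, t2)
})

test_that("hot spots only perturb activity within 3x their radius", {
  base <- phantom_spec(noise = "none", seed = 14,
                       functional_fraction = 0.8)
  ctr <- c(20, 40, 24); r <- 8
  hot <- base
  hot$hotspots <- list(list(center_vox = ctr, radius_mm = r,
                            intensity_multiplier = 5))
  a <- generate_phantom(base)$case$pet_vent$data
  b <- generate_phantom(hot)$case$pet_vent$data
  dims <- dim(a)
  co <- arrayInd(seq_along(a), dims)
  d <- sqrt(((co[, 1] - ctr[1]) * 4)^2 + ((co[, 2] - ctr[2]) * 4)^2 +
              ((co[, 3] - ctr[3]) * 4)^2)
  far <- d > 3 * r
  expect_identical(a[far], b[far])
  expect_gt(max(b - a), 0)  # and the hot spot is actually there
})

test_that("defects and hotspots centered outside the lungs are rejected", {
  sp <- small_spec(defects = list(list(center_vox = c(2, 2, 2),
                                       radius_mm = 10,
                                       activity_multiplier = 0)))
  expect_error(generate_phantom(sp), "outside the lungs")
  sp2 <- small_spec(hotspots = list(list(center_vox = c(2, 2, 2),
                                         radius_mm = 8,
                                         intensity_multiplier = 3)))
  expect_error(generate_phantom(sp2), "outside the lungs")
})

test_that("noiseless cohorts couple PFT indices perfectly to truth", {
  cps <- list(FEV1_FVC = pft_coupling(0.75, 0.2, 0, clip = c(0, 1)))
  co <- generate_cohort(12, base_spec = small_spec(), pft_couplings = cps,
                        seed = 5)
  r <- cor(co$pft$FEV1_FVC, co$pft$true_fraction)
  expect_equal(r, 1.0, tolerance = 1e-12)
})

test_that("noisy coupling calibrated for r = 0.8 lands in the n = 30 sampling interval", {
  co <- generate_cohort(30, base_spec = small_spec(), seed = 12)
  r <- cor(co$pft$FEV1_FVC, co$pft$true_fraction)
  # 95% interval for rho = 0.8, n = 30 via the Fisher z transform
  ci <- tanh(atanh(0.8) + c(-1, 1) * 1.96 / sqrt(27))
  expect_gt(r, ci[1])
  expect_lt(r, ci[2])
})

test_that("cohorts are reproducible and validate their ranges", {
  a <- generate_cohort(1, base_spec = small_spec(), seed = 77)
  b <- generate_cohort(1, base_spec = small_spec(), seed = 77)
  expect_identical(a$cases[[1]]$case$pet_vent$data,
                   b$cases[[1]]$case$pet_vent$data)
  expect_identical(a$pft, b$pft)
  expect_error(generate_cohort(3, base_spec = small_spec(),
                               variability = list(fraction_range = c(0.8, 0.4)),
                               seed = 1),
               "degenerate fraction_range")
  # min = max is a valid degenerate range
  c0 <- generate_cohort(2, base_spec = small_spec(),
                        variability = list(fraction_range = c(0.7, 0.7)),
                        seed = 2)
  expect_lte(max(abs(c0$pft$true_fraction - 0.7)), 0.02)
})

test_that("coupling_for_r solves the attenuation identity", {
  cp <- coupling_for_r(0.75, 0.2, 0.8, fraction_range = c(0.4, 0.9))
  sd_x <- 0.5 / sqrt(12)
  r_implied <- 0.75 * sd_x / sqrt(0.75^2 * sd_x^2 + cp$noise_sd^2)
  expect_equal(r_implied, 0.8, tolerance = 1e-12)
})
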