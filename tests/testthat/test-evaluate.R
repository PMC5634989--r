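test_that("dice matches the set formula on canonical cases", {
  dims <- c(4, 4, 4)
  a <- binary_mask(array(FALSE, dims)); a$data[1:2, 1:2, 1:2] <- TRUE
  expect_equal(dice(a, a), 1.0)
  b <- binary_mask(array(FALSE, dims)); b$data[3:4, 3:4, 3:4] <- TRUE
  expect_equal(dice(a, b), 0.0)
  # |a| = 8, |b| = 8, overlap 6 -> 0.75
  c1 <- binary_mask(array(FALSE, dims)); c1$data[1:8] <- TRUE
  c2 <- binary_mask(array(FALSE, dims)); c2$data[3:10] <- TRUE
  expect_equal(dice(c1, c2), 0.75)
  empty <- binary_mask(array(FALSE, dims))
  expect_equal(dice(empty, empty), 1.0)
  expect_error(dice(a, binary_mask(array(FALSE, c(4, 4, 3)))), "mismatch")
})

test_that("dice is symmetric, bounded and equals brute force on random masks", {
  set.seed(42)
  for (i in 1:50) {
    a <- rand_mask(p = runif(1)); b <- rand_mask(p = runif(1))
    d <- dice(a, b)
    expect_identical(d, dice(b, a))
    expect_gte(d, 0); expect_lte(d, 1)
    expect_identical(d, brute_dice(a, b))
    expect_equal(dice(a, a), if (voxel_count(a) > 0) 1.0 else 1.0)
  }
})

test_that("volume_difference is the signed difference in %WL points", {
  expect_equal(volume_difference(30, 30), 0.0)
  expect_equal(volume_difference(45, 30), 15.0)
  expect_equal(volume_difference(10, 50.4), -40.4)
  expect_error(volume_difference(-1, 50))
  expect_error(volume_difference(10, 101))
})

test_that("bland_altman reproduces the closed-form limits of agreement", {
  ba <- bland_altman(c(1, -1, 0))
  expect_equal(ba$bias, 0.0)
  expect_equal(ba$sd, 1.0)
  expect_equal(ba$loa_low, -1.96)
  expect_equal(ba$loa_high, 1.96)
  expect_equal(c(ba$diff_min, ba$diff_max), c(-1, 1))

  const <- bland_altman(c(5, 5, 5, 5))
  expect_equal(const$bias, 5); expect_equal(const$sd, 0)
  expect_equal(const$loa_low, 5); expect_equal(const$loa_high, 5)
  expect_error(bland_altman(3), "n >= 2")
})

test_that("limits of agreement bracket the spread of normal differences", {
  set.seed(7)
  d <- rnorm(10000, mean = 0, sd = 15.6)
  ba <- bland_altman(d)
  expect_lte(abs(ba$loa_low - (-1.96 * 15.6)), 0.5)
  expect_lte(abs(ba$loa_high - 1.96 * 15.6), 0.5)
  # width identity is exact, not approximate
  expect_equal(ba$loa_high - ba$loa_low, 2 * 1.96 * ba$sd)
})

test_that("pearson matches brute-force formula and t-based p-value", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson(x, 2 * x + 1)$r, 1.0)
  expect_equal(pearson(x, -x)$r, -1.0)
  y <- c(2, 1, 4, 3, 6)
  p <- pearson(x, y)
  expect_equal(p$r, brute_pearson(x, y), tolerance = 1e-14)
  expect_equal(p$p, brute_pearson_p(brute_pearson(x, y), 5),
               tolerance = 1e-12)
  expect_identical(p$significant, p$p < 0.05)
  expect_error(pearson(x, y[1:4]), "length")
  expect_error(pearson(x, rep(1, 5)), "zero variance")
  expect_error(pearson(1:2, 2:3), "n >= 3")
})

test_that("evaluate_case scores a sweep against a reference", {
  ph <- generate_phantom(small_spec(seed = 23, functional_fraction = 0.7))
  wl <- ph$truth_wl
  me <- estimate_max(ph$case$pet_vent, wl)
  sw <- threshold_sweep(ph$case$pet_vent, wl, me)

  # self-comparison at 15%: perfect agreement
  ev <- evaluate_case(sw, sw$masks[[3]], wl, case_id = "self")
  expect_equal(nrow(ev), 8)
  expect_equal(ev$dsc[ev$cutoff_pct == 15], 1.0)
  expect_equal(ev$volume_diff[ev$cutoff_pct == 15], 0.0)

  empty <- mask_like(ph$case$pet_vent, array(FALSE, dim(wl$data)))
  ev0 <- evaluate_case(sw, empty, wl)
  expect_true(all(ev0$dsc == 0))
})

test_that("noiseless recovery: truth is recovered exactly at mid cutoffs", {
  ph <- generate_phantom(clean_spec(seed = 25, functional_fraction = 0.7))
  wl <- ph$truth_wl
  me <- estimate_max(ph$case$pet_vent, wl)
  sw <- threshold_sweep(ph$case$pet_vent, wl, me,
                        cutoffs_pct = c(15, 25, 50))
  ev <- evaluate_case(sw, ph$truth_functional_vent, wl)
  expect_true(all(ev$dsc == 1.0))
  expect_true(all(ev$volume_diff == 0.0))
})

test_that("best_cutoff_per_case minimises |diff| with the stated tie-break", {
  mk <- function(cutoffs, diffs)
    data.frame(case_id = "c", cutoff_pct = cutoffs, volume_diff = diffs)
  expect_equal(best_cutoff_per_case(mk(c(5, 15, 25), c(10, -2, -8))), 15)
  # |+3| = |-3|: 10 and 20 equidistant from 15 -> lower wins
  expect_equal(best_cutoff_per_case(mk(c(10, 20), c(3, -3))), 10)
  expect_equal(best_cutoff_per_case(mk(15, 7)), 15)
  expect_error(best_cutoff_per_case(data.frame(case_id = character(0),
                                               cutoff_pct = numeric(0),
                                               volume_diff = numeric(0))),
               "no evaluations")
})

fake_evals <- function(n_cases, cutoffs, diff_fun, dsc = 0.9) {
  do.call(rbind, lapply(seq_len(n_cases), function(i) {
    ref <- 40 + i
    data.frame(case_id = sprintf("c%02d", i), cutoff_pct = cutoffs,
               volume_pct_wl_auto = ref + diff_fun(i, cutoffs),
               volume_pct_wl_ref = ref,
               volume_diff = diff_fun(i, cutoffs), dsc = dsc)
  }))
}

test_that("a cohort where auto equals reference summarises to zero error", {
  ev <- fake_evals(6, c(10, 15, 20), function(i, co) rep(0, length(co)),
                   dsc = 1)
  s <- summarize_cohort(ev, report_cutoff = 15)
  expect_true(all(s$per_cutoff$mean_diff == 0))
  expect_true(all(s$per_cutoff$median_dsc == 1))
  expect_true(all(s$per_cutoff$pearson_r == 1))
  expect_equal(s$bland_altman$bias, 0)
  expect_equal(sum(s$best_cutoff_histogram), 6)
})

test_that("cohort summary aggregates per-case differences faithfully", {
  set.seed(31)
  diffs <- rnorm(30, mean = -0.4, sd = 15.6)
  ev <- fake_evals(30, c(10, 15, 20), function(i, co)
    ifelse(co == 15, diffs[i], co - 15))
  s <- summarize_cohort(ev, report_cutoff = 15)
  row15 <- s$per_cutoff[s$per_cutoff$cutoff_pct == 15, ]
  # re-aggregation identity
  expect_equal(row15$mean_diff, mean(diffs))
  expect_equal(row15$sd_diff, sd(diffs))
  expect_equal(c(row15$min_diff, row15$max_diff), range(diffs))
  # n = 30 sampling tolerance around the generating mean (2 sd / sqrt(n))
  expect_lte(abs(row15$mean_diff - (-0.4)), 2 * 15.6 / sqrt(30))
  expect_equal(sum(s$best_cutoff_histogram), 30)
  expect_equal(s$bland_altman$loa_high - s$bland_altman$loa_low,
               2 * 1.96 * sd(diffs))
})

test_that("PFT correlations are reported for auto and reference volumes", {
  set.seed(8)
  n <- 20
  ref <- runif(n, 30, 90)
  ev <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(case_id = sprintf("c%02d", i), cutoff_pct = c(15, 25),
               volume_pct_wl_auto = ref[i] + rnorm(2, sd = 5),
               volume_pct_wl_ref = ref[i],
               volume_diff = 0, dsc = 0.9)))
  ev$volume_diff <- ev$volume_pct_wl_auto - ev$volume_pct_wl_ref
  pft <- data.frame(case_id = sprintf("c%02d", seq_len(n)),
                    FEV1_FVC = 0.2 + 0.008 * ref + rnorm(n, sd = 0.05),
                    FEV1_pct_pred = c(NA, 60 + 0.5 * ref[-1]))
  s <- summarize_cohort(ev, pft_table = pft, report_cutoff = 15)
  pc <- s$pft_correlations
  expect_setequal(pc$pft_index, c("FEV1_FVC", "FEV1_pct_pred"))
  expect_equal(pc$n[pc$pft_index == "FEV1_pct_pred"], n - 1)  # NA dropped
  e15 <- ev[ev$cutoff_pct == 15, ]
  expect_equal(pc$r_ref[pc$pft_index == "FEV1_FVC"],
               brute_pearson(ref, pft$FEV1_FVC), tolerance = 1e-12)
  expect_equal(pc$r_auto[pc$pft_index == "FEV1_FVC"],
               brute_pearson(e15$volume_pct_wl_auto, pft$FEV1_FVC),
               tolerance = 1e-12)
})

test_that("cohort report tables have the published shape and are stable", {
  set.seed(12)
  cutoffs <- c(5, 10, 15, 20, 25, 30, 40, 50)
  mk_sum <- function(shift) {
    ev <- fake_evals(10, cutoffs, function(i, co) (co - 15) / 2 + shift * i)
    pft <- data.frame(case_id = sprintf("c%02d", 1:10),
                      FEV1_FVC = runif(10, 0.4, 0.9),
                      FEV1_pct_pred = runif(10, 40, 110),
                      DLCO_pct_pred = runif(10, 40, 110),
                      FVC_pct_pred = runif(10, 40, 110))
    summarize_cohort(ev, pft_table = pft, report_cutoff = 15)
  }
  sums <- list(ventilation = mk_sum(0.3), perfusion = mk_sum(-0.2))
  d1 <- tempfile(); d2 <- tempfile()
  write_cohort_report(sums, d1)
  write_cohort_report(sums, d2)

  t1 <- read.csv(file.path(d1, "table1.csv"), check.names = FALSE)
  expect_equal(names(t1), c("statistic", paste0("pct", cutoffs)))
  expect_equal(t1$statistic,
               c("ventilation_mean", "ventilation_sd", "ventilation_min",
                 "ventilation_max", "perfusion_mean", "perfusion_sd",
                 "perfusion_min", "perfusion_max"))
  t2 <- read.csv(file.path(d1, "table2.csv"))
  expect_equal(t2$pft_index, c("FEV1_FVC", "FEV1_pct_pred",
                               "DLCO_pct_pred", "FVC_pct_pred"))
  expect_equal(names(t2), c("pft_index", "ventilation_reference",
                            "ventilation_auto", "perfusion_reference",
                            "perfusion_auto"))
  # significance flags are "r*" strings
  expect_true(all(grepl("^-?[0-9.]+\\*?$", unlist(t2[, -1]))))
  # byte-identical re-run
  for (f in c("table1.csv", "table2.csv", "bland_altman.csv"))
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
})
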