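test_that("adaptive delineation stops immediately at a matching reference", {
  ph <- generate_phantom(small_spec(seed = 41, functional_fraction = 0.7))
  wl <- ph$truth_wl
  me <- estimate_max(ph$case$pet_vent, wl)
  ref15 <- delineate_at(ph$case$pet_vent, wl, me, 15)$mask
  res <- adaptive_delineate(ph$case$pet_vent, wl, me,
                            objective = "match_reference", reference = ref15)
  expect_equal(res$chosen_cutoff, 15)
  expect_equal(res$trajectory$cutoff_pct[1], 15)
  expect_equal(nrow(res$trajectory), 1)
  expect_equal(res$trajectory$objective[1], 0)
})

test_that("adaptive delineation walks to the best-matching neighbour", {
  ph <- generate_phantom(small_spec(seed = 43, functional_fraction = 0.6))
  wl <- ph$truth_wl
  me <- estimate_max(ph$case$pet_vent, wl)
  ref25 <- delineate_at(ph$case$pet_vent, wl, me, 25)$mask
  res <- adaptive_delineate(ph$case$pet_vent, wl, me,
                            objective = "match_reference", reference = ref25)
  expect_equal(res$chosen_cutoff, 25)
  expect_equal(res$trajectory$cutoff_pct, c(15, 20, 25))
  expect_identical(res$final_mask$data, ref25$data)
})

test_that("adaptive search never does worse than the 15%max start", {
  set.seed(51)
  cands <- c(5, 10, 15, 20, 25, 30)
  for (s in 1:5) {
    ph <- generate_phantom(small_spec(seed = 50 + s,
                                      functional_fraction = runif(1, .4, .9)))
    wl <- ph$truth_wl
    me <- estimate_max(ph$case$pet_vent, wl)
    ref <- ph$truth_functional_vent
    res <- adaptive_delineate(ph$case$pet_vent, wl, me,
                              objective = "match_reference", reference = ref)
    obj15 <- res$trajectory$objective[1]
    expect_lte(res$trajectory$objective[nrow(res$trajectory)], obj15)
    # contiguous walk over the candidate list
    steps <- match(res$trajectory$cutoff_pct, cands)
    if (length(steps) > 1)
      expect_true(all(abs(diff(steps)) == 1))
  }
})

test_that("plateau objective settles on a flat part of the volume curve", {
  ph <- generate_phantom(small_spec(seed = 47, functional_fraction = 0.7))
  wl <- ph$truth_wl
  me <- estimate_max(ph$case$pet_vent, wl)
  res <- adaptive_delineate(ph$case$pet_vent, wl, me, objective = "plateau")
  expect_true(res$chosen_cutoff %in% c(5, 10, 15, 20, 25, 30))
  expect_equal(res$trajectory$cutoff_pct[1], 15)
})

test_that("adaptive candidate lists are validated", {
  ph <- generate_phantom(small_spec(seed = 48))
  wl <- ph$truth_wl
  me <- estimate_max(ph$case$pet_vent, wl)
  res <- adaptive_delineate(ph$case$pet_vent, wl, me, objective = "plateau",
                            candidate_cutoffs = 15)
  expect_equal(res$chosen_cutoff, 15)
  expect_error(adaptive_delineate(ph$case$pet_vent, wl, me,
                                  objective = "plateau",
                                  candidate_cutoffs = numeric(0)),
               "empty candidate")
  expect_error(adaptive_delineate(ph$case$pet_vent, wl, me,
                                  objective = "plateau",
                                  candidate_cutoffs = c(10, 20)),
               "15")
})

test_that("run_case drives the full pipeline and writes its bundle", {
  ph <- generate_phantom(phantom_spec(seed = 61, functional_fraction = 0.75))
  out1 <- file.path(tempfile(), "run1")
  res <- run_case(ph$case, reference_vent = ph$truth_functional_vent,
                  reference_perf = ph$truth_functional_perf,
                  out_dir = out1)
  expect_true(file.exists(file.path(out1, "wl.nii.gz")))
  for (f in c("sweep_vent.csv", "sweep_perf.csv", "eval_vent.csv",
              "eval_perf.csv"))
    expect_true(file.exists(file.path(out1, f)))
  sw <- read.csv(file.path(out1, "sweep_vent.csv"))
  expect_equal(nrow(sw), 8)
  expect_equal(sw$cutoff_pct, c(5, 10, 15, 20, 25, 30, 40, 50))
  expect_gte(dice(res$wl, ph$truth_wl), 0.98)

  # determinism: a second run is byte-identical
  out2 <- file.path(tempfile(), "run2")
  run_case(ph$case, reference_vent = ph$truth_functional_vent,
           reference_perf = ph$truth_functional_perf, out_dir = out2)
  for (f in c("sweep_vent.csv", "sweep_perf.csv", "eval_vent.csv"))
    expect_identical(readBin(file.path(out1, f), "raw", 1e6),
                     readBin(file.path(out2, f), "raw", 1e6))
})

test_that("a case without PET fails with the stage named", {
  ph <- generate_phantom(small_spec(seed = 62))
  case <- ph$case
  case$pet_vent <- NULL
  case$pet_perf <- NULL
  expect_error(run_case(case), "stage delineate")
})

test_that("run_cohort evaluates every case against its truth", {
  co <- generate_cohort(3, base_spec = small_spec(), seed = 71)
  rc <- run_cohort(co, use_truth_wl = TRUE)
  expect_equal(rc$n_ok, 3)
  expect_length(rc$failures, 0)
  expect_equal(nrow(rc$evals_vent), 3 * 8)
  expect_equal(nrow(rc$evals_perf), 3 * 8)
  expect_setequal(unique(rc$evals_vent$case_id),
                  c("case-001", "case-002", "case-003"))
})
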