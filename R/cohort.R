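# Synthetic cohorts: many phantom cases with per-case variability and
# pulmonary function test (PFT) indices linearly coupled, with noise, to
# the true functional fraction.

#' Linear coupling between a PFT index and the true functional fraction
#'
#' The generated index is
#' `intercept + slope * true_fraction + Normal(0, noise_sd)`, clipped to
#' `clip`.
#'
#' @param slope,intercept Linear coefficients.
#' @param noise_sd Gaussian noise standard deviation, same units as the
#'   index.
#' @param clip Length-2 clipping interval.
#' @return A list of class `pft_coupling`.
#' @export
pft_coupling <- function(slope, intercept, noise_sd, clip = c(-Inf, Inf)) {
  stopifnot(noise_sd >= 0, length(clip) == 2, clip[1] < clip[2])
  structure(list(slope = slope, intercept = intercept, noise_sd = noise_sd,
                 clip = clip), class = "pft_coupling")
}

#' Choose the coupling noise so the population correlation equals a target
#'
#' For functional fractions drawn uniformly from `fraction_range`, the
#' population Pearson correlation between the index and the fraction is
#' `slope * sd_x / sqrt(slope^2 sd_x^2 + noise_sd^2)` with
#' `sd_x = range width / sqrt(12)`; this solves for `noise_sd`.
#'
#' @param slope,intercept,clip As for [pft_coupling()].
#' @param target_r Desired population correlation magnitude, in (0, 1].
#' @param fraction_range Uniform sampling interval of the true fraction.
#' @return A [pft_coupling()].
#' @export
coupling_for_r <- function(slope, intercept, target_r,
                           fraction_range = c(0.4, 0.9),
                           clip = c(-Inf, Inf)) {
  stopifnot(target_r > 0, target_r <= 1)
  sd_x <- diff(fraction_range) / sqrt(12)
  noise_sd <- abs(slope) * sd_x * sqrt(1 / target_r^2 - 1)
  pft_coupling(slope, intercept, noise_sd, clip)
}

#' Default PFT couplings
#'
#' FEV1/FVC is coupled most strongly (population r ~ 0.8 for fractions
#' uniform on 0.4-0.9), FEV1 %pred moderately (~0.6), DLCO %pred weakly
#' (~0.45) and FVC %pred weakly (~0.3), mirroring the typical ordering of
#' correlations between functional lung volume and spirometric indices in
#' obstructive disease.
#'
#' @param fraction_range Uniform sampling interval of the true fraction
#'   used to calibrate the noise level per target correlation.
#' @return Named list of [pft_coupling()] objects.
#' @export
default_pft_couplings <- function(fraction_range = c(0.4, 0.9)) {
  list(
    FEV1_FVC = coupling_for_r(0.75, 0.2, 0.80, fraction_range,
                              clip = c(0.2, 0.95)),
    FEV1_pct_pred = coupling_for_r(80, 30, 0.60, fraction_range,
                                   clip = c(20, 160)),
    DLCO_pct_pred = coupling_for_r(60, 40, 0.45, fraction_range,
                                   clip = c(20, 160)),
    FVC_pct_pred = coupling_for_r(40, 65, 0.30, fraction_range,
                                  clip = c(20, 160))
  )
}

#' Generate a cohort of phantom cases
#'
#' Per case, the target functional fraction is drawn uniformly from
#' `fraction_range`, the number of (automatically sized and placed) defect
#' spheres from `defect_count_range`, defect multipliers uniformly from
#' `defect_multiplier_range`, and with probability `hotspot_probability`
#' one 1-ml airway-deposition hot spot (peak 3-6 times the local activity)
#' is added to the ventilation image. PFT indices are generated from the
#' realised true fraction through `pft_couplings`. Per-case seeds are
#' derived deterministically from `seed`.
#'
#' @param n Number of cases (>= 1).
#' @param base_spec A [phantom_spec()] giving geometry and imaging
#'   parameters shared by all cases.
#' @param variability List with `fraction_range`, `defect_count_range`,
#'   `hotspot_probability`, `defect_multiplier_range`.
#' @param pft_couplings Named list of [pft_coupling()] objects (any subset
#'   of the four standard indices), or `NULL` for no PFT generation.
#' @param seed Master integer seed.
#' @return A list of class `phantom_cohort`: elements `cases` (list of
#'   [generate_phantom()] results), `pft` (data.frame), `seed`.
#' @export
generate_cohort <- function(n, base_spec = phantom_spec(),
                            variability = list(),
                            pft_couplings = default_pft_couplings(),
                            seed = 1L) {
  stopifnot(n >= 1)
  v <- utils::modifyList(list(fraction_range = c(0.4, 0.9),
                              defect_count_range = c(1, 3),
                              hotspot_probability = 0.3,
                              defect_multiplier_range = c(0, 0.25)),
                         variability)
  fr <- v$fraction_range
  if (fr[1] > fr[2]) stop("degenerate fraction_range: min > max")
  if (fr[1] <= 0 || fr[2] > 1) stop("fraction_range must lie in (0, 1]")

  draws <- with_seed(as.integer(seed), {
    list(case_seed = sample.int(.Machine$integer.max - 1L, n),
         fraction = runif(n, fr[1], fr[2]),
         n_defect = if (v$defect_count_range[1] == v$defect_count_range[2])
           rep(v$defect_count_range[1], n)
         else sample(v$defect_count_range[1]:v$defect_count_range[2], n,
                     replace = TRUE),
         hotspot = runif(n) < v$hotspot_probability,
         hot_mult = runif(n, 3, 6),
         pft_noise = matrix(rnorm(n * 4), nrow = n))
  })

  cases <- vector("list", n)
  for (i in seq_len(n)) {
    spec_i <- base_spec
    spec_i$seed <- draws$case_seed[i]
    spec_i$functional_fraction <- draws$fraction[i]
    mults <- with_seed(draws$case_seed[i] %% 1000000L + 7L,
                       runif(draws$n_defect[i],
                             v$defect_multiplier_range[1],
                             v$defect_multiplier_range[2]))
    spec_i$defects <- lapply(seq_len(draws$n_defect[i]), function(j)
      list(center_vox = NULL, radius_mm = NULL,
           activity_multiplier = mults[j]))
    if (draws$hotspot[i]) {
      geom <- phantom_geometry(spec_i)
      ctr <- with_seed(draws$case_seed[i] %% 1000000L + 13L,
                       random_lung_center(geom, spec_i$shape))
      spec_i$hotspots <- list(list(center_vox = ctr, radius_mm = 6.2,
                                   intensity_multiplier = draws$hot_mult[i]))
    } else {
      spec_i$hotspots <- NULL
    }
    cases[[i]] <- generate_phantom(spec_i)
    if (!is.null(pft_couplings)) {
      f <- cases[[i]]$true_fraction_vent
      pft <- list()
      for (k in seq_along(pft_couplings)) {
        cp <- pft_couplings[[k]]
        val <- cp$intercept + cp$slope * f +
          cp$noise_sd * draws$pft_noise[i, ((k - 1) %% 4) + 1]
        pft[[names(pft_couplings)[k]]] <-
          min(max(val, cp$clip[1]), cp$clip[2])
      }
      cases[[i]]$case$pft <- pft
    }
    cases[[i]]$case$case_id <- sprintf("case-%03d", i)
  }

  pft_tab <- NULL
  if (!is.null(pft_couplings)) {
    pft_tab <- data.frame(case_id = vapply(cases, function(c) c$case$case_id, ""))
    for (nm in names(pft_couplings))
      pft_tab[[nm]] <- vapply(cases, function(c) c$case$pft[[nm]], 0)
    pft_tab$true_fraction <- vapply(cases, function(c) c$true_fraction_vent, 0)
  }
  structure(list(cases = cases, pft = pft_tab, seed = as.integer(seed)),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d cases, master seed %d\n",
              length(x$cases), x$seed))
  if (!is.null(x$pft))
    cat(sprintf("  true fractions %.2f-%.2f; PFT indices: %s\n",
                min(x$pft$true_fraction), max(x$pft$true_fraction),
                paste(setdiff(names(x$pft), c("case_id", "true_fraction")),
                      collapse = ", ")))
  invisible(x)
}
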