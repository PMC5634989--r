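# Agreement and correlation statistics: Dice similarity, signed volume
# difference in %WL points, Bland-Altman limits of agreement, Pearson
# correlation, and cohort-level summary tables.

#' Dice similarity coefficient between two masks
#'
#' `2|A n B| / (|A| + |B|)`. Two empty masks are defined as identical
#' (DSC 1) with a logged warning.
#'
#' @param a,b [binary_mask()] objects on the same lattice.
#' @return A fraction in \[0, 1\].
#' @export
dice <- function(a, b) {
  assert_same_lattice(a, b)
  na <- sum(a$data); nb <- sum(b$data)
  if (na + nb == 0) {
    vq_log("dice", note = "both masks empty; DSC defined as 1")
    return(1.0)
  }
  2 * sum(a$data & b$data) / (na + nb)
}

#' Signed volume difference in %WL points
#' @param auto_pct_wl,ref_pct_wl Volumes as percent of the whole lung.
#' @return `auto_pct_wl - ref_pct_wl`.
#' @export
volume_difference <- function(auto_pct_wl, ref_pct_wl) {
  stopifnot(auto_pct_wl >= 0, auto_pct_wl <= 100,
            ref_pct_wl >= 0, ref_pct_wl <= 100)
  auto_pct_wl - ref_pct_wl
}

#' Bland-Altman agreement statistics
#'
#' Bias is the mean difference, the limits of agreement are
#' `bias +/- 1.96 * sd` with the sample (n-1) standard deviation.
#'
#' @param diffs Differences (auto - reference), %WL points.
#' @param means Optional per-case means of the paired values, stored for
#'   plotting.
#' @return An object of class `agreement_stats` with `bias`, `sd`,
#'   `loa_low`, `loa_high`, `diff_min`, `diff_max`, `n`.
#' @export
bland_altman <- function(diffs, means = NULL) {
  diffs <- as.numeric(diffs)
  if (length(diffs) < 2) stop("Bland-Altman analysis needs n >= 2")
  bias <- mean(diffs)
  s <- stats::sd(diffs)
  structure(list(bias = bias, sd = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 diff_min = min(diffs), diff_max = max(diffs),
                 n = length(diffs), diffs = diffs, means = means),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf(paste0("<agreement_stats> n = %d\n",
                     "  bias %.2f, SD %.2f, limits of agreement [%.2f, %.2f]\n",
                     "  differences range [%.2f, %.2f]\n"),
              x$n, x$bias, x$sd, x$loa_low, x$loa_high,
              x$diff_min, x$diff_max))
  invisible(x)
}

#' Bland-Altman plot
#' @param x An [bland_altman()] result with `means` stored.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.agreement_stats <- function(x, ...) {
  if (is.null(x$means))
    stop("no per-case means stored; call bland_altman(diffs, means)")
  graphics::plot(x$means, x$diffs, pch = 19,
                 xlab = "mean of methods (%WL)",
                 ylab = "difference auto - reference (%WL)",
                 ylim = range(c(x$diffs, x$loa_low, x$loa_high)), ...)
  graphics::abline(h = x$bias, lty = 1)
  graphics::abline(h = c(x$loa_low, x$loa_high), lty = 2)
  invisible(x)
}

#' Pearson correlation with a two-sided t-test
#'
#' @param x,y Equal-length numeric vectors, n >= 3, non-zero variance.
#' @return List `r`, `p` (two-sided, t distribution with n-2 df),
#'   `significant` (p < 0.05), `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3) stop("Pearson correlation needs n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the inputs")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value,
       significant = ct$p.value < 0.05, n = length(x))
}

#' Evaluate one case's sweep against a reference contour
#'
#' @param sweep A [threshold_sweep()].
#' @param reference Reference [binary_mask()] (manual contour or phantom
#'   truth).
#' @param wl Whole-lung [binary_mask()]; the reference volume is expressed
#'   as %WL on the same denominator as the sweep.
#' @param case_id Identifier carried into the result rows.
#' @return Data frame with one row per cutoff: `case_id`, `cutoff_pct`,
#'   `volume_pct_wl_auto`, `volume_pct_wl_ref`, `volume_diff`, `dsc`.
#' @export
evaluate_case <- function(sweep, reference, wl, case_id = "case") {
  stopifnot(inherits(sweep, "threshold_sweep"))
  assert_same_lattice(reference, wl)
  n_wl <- voxel_count(wl)
  if (n_wl == 0) stop("empty whole-lung mask")
  ref_pct <- 100 * voxel_count(reference) / n_wl
  if (ref_pct > 100) {
    vq_log("evaluate_case", case_id = case_id,
           note = "reference larger than WL; %WL clamped to 100")
    ref_pct <- 100
  }
  rows <- lapply(seq_along(sweep$cutoffs_pct), function(i) {
    auto_pct <- sweep$volumes_pct_wl[i]
    data.frame(case_id = case_id,
               cutoff_pct = sweep$cutoffs_pct[i],
               volume_pct_wl_auto = auto_pct,
               volume_pct_wl_ref = ref_pct,
               volume_diff = volume_difference(auto_pct, ref_pct),
               dsc = dice(sweep$masks[[i]], reference))
  })
  do.call(rbind, rows)
}

#' Per-case optimal cutoff
#'
#' The cutoff minimising the absolute volume difference. Ties are broken
#' toward the cutoff nearest 15 (the protocol's starting threshold), then
#' toward the lower cutoff.
#'
#' @param evals Data frame as returned by [evaluate_case()] (one case).
#' @return The selected `cutoff_pct`.
#' @export
best_cutoff_per_case <- function(evals) {
  if (NROW(evals) == 0) stop("no evaluations")
  a <- abs(evals$volume_diff)
  cand <- evals$cutoff_pct[a == min(a)]
  d15 <- abs(cand - 15)
  cand <- cand[d15 == min(d15)]
  min(cand)
}

#' Cohort-level summary of the threshold method
#'
#' Aggregates per-case evaluations into the structures reported for a
#' clinical cohort: per-cutoff mean/SD/min/max volume difference, median
#' and IQR of the Dice coefficient, Pearson correlation between automatic
#' and reference volumes; the overall optimal cutoff (argmin of the
#' absolute mean volume difference); the per-case optimal-cutoff
#' histogram; and Pearson correlations (r, p) between each PFT index and
#' the %WL volume, both at `report_cutoff` and for the reference.
#'
#' @param all_evals Data frame: row-bound [evaluate_case()] results for
#'   all cases (>= 2 cases).
#' @param pft_table Optional data.frame with `case_id` and PFT columns
#'   (`FEV1_FVC`, `FEV1_pct_pred`, `DLCO_pct_pred`, `FVC_pct_pred`).
#'   Missing values are dropped pairwise with a logged count.
#' @param report_cutoff Cutoff (%max) at which PFT correlations are
#'   reported.
#' @return An object of class `cohort_summary`: `per_cutoff` (data frame),
#'   `best_cutoff_overall`, `best_cutoff_histogram`, `bland_altman`
#'   (at `report_cutoff`), `pft_correlations`, `report_cutoff`, `n`.
#' @export
summarize_cohort <- function(all_evals, pft_table = NULL, report_cutoff = 15) {
  ids <- unique(all_evals$case_id)
  if (length(ids) < 2) stop("cohort summary needs >= 2 cases")
  cutoffs <- sort(unique(all_evals$cutoff_pct))
  if (!report_cutoff %in% cutoffs)
    stop("report_cutoff ", report_cutoff, " not among evaluated cutoffs")

  per_cutoff <- do.call(rbind, lapply(cutoffs, function(co) {
    e <- all_evals[all_evals$cutoff_pct == co, ]
    data.frame(cutoff_pct = co,
               mean_diff = mean(e$volume_diff),
               sd_diff = stats::sd(e$volume_diff),
               min_diff = min(e$volume_diff),
               max_diff = max(e$volume_diff),
               median_dsc = stats::median(e$dsc),
               iqr_dsc_low = unname(stats::quantile(e$dsc, 0.25)),
               iqr_dsc_high = unname(stats::quantile(e$dsc, 0.75)),
               pearson_r = if (stats::sd(e$volume_pct_wl_auto) > 0 &&
                               stats::sd(e$volume_pct_wl_ref) > 0)
                 pearson(e$volume_pct_wl_auto, e$volume_pct_wl_ref)$r
               else NA_real_)
  }))

  best_overall <- per_cutoff$cutoff_pct[which.min(abs(per_cutoff$mean_diff))]
  per_case_best <- vapply(ids, function(id)
    best_cutoff_per_case(all_evals[all_evals$case_id == id, ]), 0)
  hist <- table(factor(per_case_best, levels = cutoffs))

  e_rep <- all_evals[all_evals$cutoff_pct == report_cutoff, ]
  e_rep <- e_rep[match(ids, e_rep$case_id), ]
  ba <- bland_altman(e_rep$volume_diff,
                     means = (e_rep$volume_pct_wl_auto +
                                e_rep$volume_pct_wl_ref) / 2)

  pft_cor <- NULL
  if (!is.null(pft_table)) {
    idx <- match(ids, pft_table$case_id)
    pft_cols <- intersect(c("FEV1_FVC", "FEV1_pct_pred", "DLCO_pct_pred",
                            "FVC_pct_pred"), names(pft_table))
    pft_cor <- do.call(rbind, lapply(pft_cols, function(col) {
      v <- pft_table[[col]][idx]
      ok <- !is.na(v)
      if (sum(!ok) > 0)
        vq_log("summarize_cohort", note = paste0(sum(!ok), " cases dropped",
                                                 " pairwise for ", col))
      auto <- pearson(e_rep$volume_pct_wl_auto[ok], v[ok])
      ref <- pearson(e_rep$volume_pct_wl_ref[ok], v[ok])
      data.frame(pft_index = col,
                 r_auto = auto$r, p_auto = auto$p,
                 r_ref = ref$r, p_ref = ref$p,
                 n = sum(ok))
    }))
  }

  structure(list(per_cutoff = per_cutoff,
                 best_cutoff_overall = best_overall,
                 best_cutoff_histogram = hist,
                 bland_altman = ba,
                 pft_correlations = pft_cor,
                 report_cutoff = report_cutoff,
                 n = length(ids)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> n = %d cases\n", x$n))
  cat(sprintf("  overall optimal cutoff: %g%%max; per-case optima:\n", x$best_cutoff_overall))
  print(x$best_cutoff_histogram)
  cat("  per-cutoff volume difference (auto - reference, %WL):\n")
  print(format(x$per_cutoff, digits = 3), row.names = FALSE)
  cat(sprintf("  Bland-Altman at %g%%max: ", x$report_cutoff))
  cat(sprintf("bias %.1f, LoA [%.1f, %.1f]\n", x$bland_altman$bias,
              x$bland_altman$loa_low, x$bland_altman$loa_high))
  if (!is.null(x$pft_correlations)) {
    cat("  PFT correlations (auto at report cutoff vs reference):\n")
    print(format(x$pft_correlations, digits = 2), row.names = FALSE)
  }
  invisible(x)
}

#' Write the cohort report tables
#'
#' Emits `table1.csv` (per-cutoff mean/SD/min/max volume difference, one
#' column per cutoff, separate blocks per modality), `table2.csv` (PFT
#' correlation matrix with significance flags) and `bland_altman.csv`.
#' Output is deterministic: re-running on the same summaries is
#' byte-identical.
#'
#' @param summaries Named list of [summarize_cohort()] results, e.g.
#'   `list(ventilation =, perfusion =)`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort_report <- function(summaries, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt <- function(x) sprintf("%.1f", x)

  cutoffs <- summaries[[1]]$per_cutoff$cutoff_pct
  t1 <- data.frame(statistic = character(0))
  for (nm in names(summaries)) {
    pc <- summaries[[nm]]$per_cutoff
    block <- data.frame(statistic = paste0(nm, c("_mean", "_sd", "_min",
                                                 "_max")))
    for (i in seq_along(cutoffs))
      block[[paste0("pct", cutoffs[i])]] <-
        fmt(c(pc$mean_diff[i], pc$sd_diff[i], pc$min_diff[i],
              pc$max_diff[i]))
    t1 <- rbind(t1, block)
  }
  p1 <- file.path(dir, "table1.csv")
  utils::write.csv(t1, p1, row.names = FALSE, quote = FALSE)

  flag <- function(r, p) paste0(sprintf("%.2f", r), ifelse(p < 0.05, "*", ""))
  t2 <- NULL
  for (nm in names(summaries)) {
    pc <- summaries[[nm]]$pft_correlations
    if (is.null(pc)) next
    col_ref <- paste0(nm, "_reference")
    col_auto <- paste0(nm, "_auto")
    block <- data.frame(pft_index = pc$pft_index)
    block[[col_ref]] <- flag(pc$r_ref, pc$p_ref)
    block[[col_auto]] <- flag(pc$r_auto, pc$p_auto)
    t2 <- if (is.null(t2)) block else merge(t2, block, by = "pft_index",
                                            sort = FALSE)
  }
  p2 <- file.path(dir, "table2.csv")
  if (!is.null(t2))
    utils::write.csv(t2, p2, row.names = FALSE, quote = FALSE)

  ba <- do.call(rbind, lapply(names(summaries), function(nm) {
    b <- summaries[[nm]]$bland_altman
    data.frame(modality = nm, n = b$n, bias = fmt(b$bias), sd = fmt(b$sd),
               loa_low = fmt(b$loa_low), loa_high = fmt(b$loa_high),
               diff_min = fmt(b$diff_min), diff_max = fmt(b$diff_max))
  }))
  p3 <- file.path(dir, "bland_altman.csv")
  utils::write.csv(ba, p3, row.names = FALSE, quote = FALSE)
  invisible(c(p1, if (!is.null(t2)) p2, p3))
}
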