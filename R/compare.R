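#' Configuration for cross-cohort bootstrap comparison
#'
#' The comparison procedure: per bootstrap replicate, draw
#' \code{samples_per_cohort} one-observation-per-child subsamples from each
#' cohort, fit a reference curve on every subsample, and record the mean over
#' all \code{samples_per_cohort^2} cross-cohort pairs of the pointwise curve
#' difference.  The point estimate is the mean of the replicate means and the
#' confidence band the pointwise percentile interval of the replicate means.
#'
#' @param n_boot bootstrap replicates (default 1000).
#' @param samples_per_cohort one-per-child subsamples per cohort per
#'   replicate (default 8).
#' @param seed master seed.
#' @param ci_level confidence level of the percentile band.
#' @param percentile_level which centile curve is compared (default the
#'   median, 0.5).
#' @param age_grid optional shared evaluation grid; defaults to 0.1-year
#'   steps over the overlap of the two cohorts' age ranges.
#' @param resample_children also resample children with replacement before
#'   subsampling (off by default: the procedure's resampling unit is the
#'   one-per-child subsample).
#' @param paired_seeds reuse cohort A's subsampling seeds for cohort B
#'   (degenerate self-comparison checks).
#' @param swap_seeds exchange the two cohorts' seed streams (mirrored-seed
#'   antisymmetry checks).
#' @param max_fail_frac abort when more than this fraction of fits fail.
#' @return an object of class \code{compare_config}.
#' @export
compare_config <- function(n_boot = 1000, samples_per_cohort = 8, seed = 1L,
                           ci_level = 0.95, percentile_level = 0.5,
                           age_grid = NULL, resample_children = FALSE,
                           paired_seeds = FALSE, swap_seeds = FALSE,
                           max_fail_frac = 0.1) {
  stopifnot(n_boot >= 1, samples_per_cohort >= 1,
            ci_level > 0, ci_level < 1,
            percentile_level > 0, percentile_level < 1)
  structure(list(n_boot = as.integer(n_boot),
                 samples_per_cohort = as.integer(samples_per_cohort),
                 seed = as.integer(seed), ci_level = ci_level,
                 percentile_level = percentile_level, age_grid = age_grid,
                 resample_children = resample_children,
                 paired_seeds = paired_seeds, swap_seeds = swap_seeds,
                 max_fail_frac = max_fail_frac),
            class = "compare_config")
}

# fitted centile curve of one one-per-child subsample, on a fixed grid
# (clamped at the subsample's own age boundaries)
.subsample_curve <- function(data, config, p, grid, seed) {
  sub <- sample_one_per_child(data, seed)
  fit <- tryCatch(fit_lms(sub, config), error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  pa <- .params_at(fit, grid, allow_extrapolation = TRUE)
  pmin(pmax(qbccg(p, pa$mu, pa$sigma, pa$nu) - fit$shift, 0), 100)
}

# evaluate a static reference (lms_model or centile_set) at centile p on grid
.reference_curve <- function(ref, p, grid) {
  if (inherits(ref, "centile_set")) {
    col <- paste0("p", formatC(100 * p, format = "g"))
    if (!col %in% colnames(ref$centiles))
      stop("reference centile set lacks level ", col)
    return(stats::approx(ref$age_grid, ref$centiles[, col], grid, rule = 2)$y)
  }
  pa <- .params_at(ref, grid, allow_extrapolation = TRUE)
  pmin(pmax(qbccg(p, pa$mu, pa$sigma, pa$nu) - ref$shift, 0), 100)
}

#' Bootstrap comparison of reference curves across two cohorts
#'
#' Implements the cross-cohort uncertainty evaluation: per replicate, eight
#' (by default) one-per-child reference-curve fits per cohort, all cross
#' pairs differenced and averaged pointwise; the replicate means give the
#' mean-difference curve (A minus B) and its pointwise percentile confidence
#' band.  \code{cohortB} may instead be a static reference curve table (an
#' \code{lms_model} or \code{centile_set}, e.g. read from
#' \code{\link{read_lms_table}}); in that mode only cohort A contributes
#' uncertainty, mirroring a comparison against published curves whose raw
#' data are unavailable.
#'
#' @param cohortA,cohortB cohort slices on a common age range (same stratum),
#'   or a static reference for \code{cohortB}.
#' @param config a \code{\link{fit_config}} used for every subsample fit.
#' @param compare a \code{\link{compare_config}}.
#' @return an object of class \code{cohort_comparison}: \code{age_grid},
#'   \code{mean_difference}, \code{ci_lower}, \code{ci_upper},
#'   \code{percentile_level}, \code{n_boot}, \code{n_failed},
#'   \code{replicate_means} (matrix replicate x age).
#' @export
bootstrap_compare <- function(cohortA, cohortB, config = fit_config(),
                              compare = compare_config()) {
  cc <- compare
  static_ref <- inherits(cohortB, "lms_model") || inherits(cohortB, "centile_set")
  rngA <- range(cohortA$age_years)
  rngB <- if (static_ref) range(cohortB$age_grid) else range(cohortB$age_years)
  lo <- max(rngA[1], rngB[1]); hi <- min(rngA[2], rngB[2])
  if (lo >= hi) stop("cohorts share no age range")
  grid <- if (!is.null(cc$age_grid)) cc$age_grid else seq(lo, hi, by = 0.1)
  p <- cc$percentile_level
  m <- cc$samples_per_cohort

  refB <- if (static_ref) .reference_curve(cohortB, p, grid)
  draw_ids <- function(d, seed) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
    ids <- unique(d$child_id)
    take <- sample(ids, length(ids), replace = TRUE)
    idx <- split(seq_len(nrow(d)), d$child_id)
    out <- d[unlist(idx[take], use.names = FALSE), , drop = FALSE]
    # re-key duplicated children so one-per-child sampling treats them apart
    reps <- unlist(lapply(seq_along(take), function(k)
      rep(k, length(idx[[take[k]]]))))
    out$child_id <- paste0(out$child_id, "#", reps)
    out
  }

  reps <- matrix(NA_real_, nrow = cc$n_boot, ncol = length(grid))
  n_failed <- 0L; n_fits <- 0L
  for (b in seq_len(cc$n_boot)) {
    sA <- derive_seed(cc$seed, 2L * b - 1L)
    sB <- if (cc$paired_seeds) sA else derive_seed(cc$seed, 2L * b)
    if (cc$swap_seeds) { tmp <- sA; sA <- sB; sB <- tmp }
    dA <- if (cc$resample_children) draw_ids(cohortA, derive_seed(sA, 0L)) else cohortA
    dB <- if (!static_ref && cc$resample_children)
      draw_ids(cohortB, derive_seed(sB, 0L)) else cohortB
    curvesA <- lapply(seq_len(m), function(j)
      .subsample_curve(dA, config, p, grid, derive_seed(sA, j)))
    curvesB <- if (static_ref) list(refB) else
      lapply(seq_len(m), function(j)
        .subsample_curve(dB, config, p, grid, derive_seed(sB, j)))
    okA <- !vapply(curvesA, is.null, logical(1))
    okB <- !vapply(curvesB, is.null, logical(1))
    n_fits <- n_fits + m + if (static_ref) 0L else m
    n_failed <- n_failed + sum(!okA) + sum(!okB)
    if (!any(okA) || !any(okB)) next
    mA <- colMeans(do.call(rbind, curvesA[okA]))
    mB <- colMeans(do.call(rbind, curvesB[okB]))
    # mean over all crossed pairs of (curveA - curveB) = mean(A) - mean(B)
    reps[b, ] <- mA - mB
  }
  if (n_failed / max(n_fits, 1) > cc$max_fail_frac)
    stop(n_failed, " of ", n_fits, " subsample fits failed")
  done <- stats::complete.cases(reps)
  reps <- reps[done, , drop = FALSE]
  alpha <- 1 - cc$ci_level
  est <- colMeans(reps)
  ci <- apply(reps, 2, stats::quantile, probs = c(alpha / 2, 1 - alpha / 2))
  structure(list(age_grid = grid, mean_difference = est,
                 ci_lower = ci[1, ], ci_upper = ci[2, ],
                 percentile_level = p, n_boot = cc$n_boot,
                 n_replicates_used = sum(done), n_failed = n_failed,
                 replicate_means = reps, seed = cc$seed),
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  inside <- mean(x$ci_lower <= 0 & x$ci_upper >= 0)
  cat("Bootstrap curve comparison (centile ", 100 * x$percentile_level,
      "): ", x$n_replicates_used, " replicates\n",
      "  mean difference over ages ", sprintf("%.2f", mean(x$mean_difference)),
      "; CI covers 0 at ", round(100 * inside), "% of grid ages\n", sep = "")
  invisible(x)
}

#' Serialize a comparison to a delimited table
#' @param x a \code{cohort_comparison}.
#' @param path file path.
#' @export
write_comparison_table <- function(x, path) {
  body <- data.frame(age_years = x$age_grid, mean_diff = x$mean_difference,
                     ci_lower = x$ci_lower, ci_upper = x$ci_upper)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("# percentile_level: %g", x$percentile_level),
               sprintf("# n_boot: %d", x$n_boot),
               sprintf("# n_failed: %d", x$n_failed),
               sprintf("# seed: %d", x$seed)), con)
  utils::write.csv(format(body, digits = 8, trim = TRUE), con,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Two-age median difference test
#'
#' Tests whether the fitted median differs between two ages (e.g. an apparent
#' decline from 10 to 12 years): \code{n_reps} one-per-child replicate fits
#' give \code{n_reps} median estimates at each age; the empirical
#' distribution of all \code{n_reps^2} cross-replicate differences
#' median(age1) - median(age2) is summarized by its central interval, and the
#' difference is declared significant when 0 falls outside.  A paired
#' (diagonal-only) variant is available.
#'
#' @param data a cohort slice (one stratum).
#' @param config a \code{\link{fit_config}}.
#' @param age1,age2 the two ages compared, inside the stratum's age range.
#' @param n_reps replicate fits (default 100).
#' @param seed integer seed.
#' @param ci_level level of the central interval (default 0.95).
#' @param paired use only the \code{n_reps} paired differences.
#' @return a list with \code{estimate} (mean difference), \code{interval},
#'   \code{significant}, \code{differences}, \code{medians_age1},
#'   \code{medians_age2}, \code{n_failed}.
#' @export
two_age_median_test <- function(data, config = fit_config(), age1, age2,
                                n_reps = 100, seed = 1L, ci_level = 0.95,
                                paired = FALSE) {
  rng <- range(data$age_years)
  if (age1 < rng[1] || age1 > rng[2] || age2 < rng[1] || age2 > rng[2])
    stop("both ages must lie inside the observed age range [",
         round(rng[1], 2), ", ", round(rng[2], 2), "]")
  m1 <- m2 <- rep(NA_real_, n_reps)
  for (i in seq_len(n_reps)) {
    sub <- sample_one_per_child(data, derive_seed(seed, i))
    fit <- tryCatch(fit_lms(sub, config), error = function(e) NULL)
    if (is.null(fit)) next
    pa <- .params_at(fit, c(age1, age2), allow_extrapolation = TRUE)
    m1[i] <- pa$mu[1] - fit$shift
    m2[i] <- pa$mu[2] - fit$shift
  }
  ok <- is.finite(m1) & is.finite(m2)
  n_failed <- sum(!ok)
  if (n_failed / n_reps > 0.1) stop(n_failed, " of ", n_reps, " fits failed")
  d <- if (paired) m1[ok] - m2[ok] else as.vector(outer(m1[ok], m2[ok], "-"))
  alpha <- 1 - ci_level
  interval <- stats::quantile(d, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  list(estimate = mean(d), interval = interval,
       significant = interval[1] > 0 || interval[2] < 0,
       differences = d, medians_age1 = m1[ok], medians_age2 = m2[ok],
       n_failed = n_failed)
}
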