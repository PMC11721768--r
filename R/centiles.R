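#' Resampling configuration for repeated-measures adjustment
#'
#' Longitudinal cohorts carry within-child correlation; the reference-curve
#' procedure neutralizes it by fitting many random subsamples with exactly
#' one observation per child and reporting the pointwise median of the
#' fitted curves across subsamples.
#'
#' @param n_samples number of one-per-child subsamples (default 100).
#' @param seed master seed; subsample i gets a seed derived from
#'   \code{(seed, i)}.
#' @param percentile_levels centile levels reported, strictly increasing in
#'   (0, 1); the default mirrors conventional centile charts.
#' @param min_coverage drop grid ages covered by fewer than this fraction of
#'   successful subsample fits (each fit only spans its own sampled ages).
#' @param max_fail_frac abort when more than this fraction of subsample fits
#'   fail.
#' @return an object of class \code{resample_config}.
#' @export
resample_config <- function(n_samples = 100, seed = 1L,
                            percentile_levels = c(0.05, 0.10, 0.25, 0.50,
                                                  0.75, 0.90, 0.95),
                            min_coverage = 0.8, max_fail_frac = 0.1) {
  stopifnot(n_samples >= 1, all(percentile_levels > 0),
            all(percentile_levels < 1),
            all(diff(percentile_levels) > 0),
            min_coverage > 0, min_coverage <= 1)
  structure(list(n_samples = as.integer(n_samples), seed = as.integer(seed),
                 percentile_levels = percentile_levels,
                 min_coverage = min_coverage, max_fail_frac = max_fail_frac),
            class = "resample_config")
}

# deterministic per-subsample seed stream, kept below 2^31
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) %% 100000) * 20011 + i * 7919) %% 2147483647L
}

#' One observation per child, at random
#'
#' Selects, uniformly at random, a single test per child.  Children with one
#' test keep it; the child count is conserved.  Deterministic given
#' \code{seed}.
#'
#' @param data a cohort slice.
#' @param seed integer seed.
#' @return a data.frame with one row per child.
#' @export
sample_one_per_child <- function(data, seed = 1L) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  # one uniform key per row; keep each child's smallest key
  key <- stats::runif(nrow(data))
  ord <- order(data$child_id, key)
  d <- data[ord, , drop = FALSE]
  out <- d[!duplicated(d$child_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Median-of-subsamples reference curves for one stratum
#'
#' Fits \code{n_samples} independent one-per-child subsamples of the stratum
#' and reports, for every requested centile level, the pointwise median of
#' the fitted percentile curves on a common age grid (the full stratum's
#' grid, restricted per subsample to its own age support; grid ages covered
#' by too few subsamples are dropped).  Also reports the pointwise median of
#' the fitted L, M, S parameter curves as an \code{lms_model}-like summary.
#' Subsample fits that fail are dropped and counted; more than
#' \code{max_fail_frac} failures aborts.
#'
#' @param data a cohort slice (one stratum, repeated measures allowed).
#' @param config a \code{\link{fit_config}}.
#' @param resample a \code{\link{resample_config}}.
#' @param level label for the outputs.
#' @return an object of class \code{centile_set}: \code{age_grid},
#'   \code{centiles} (matrix age x level), \code{percentile_levels},
#'   \code{model} (median-parameter \code{lms_model}), \code{n_samples},
#'   \code{n_failed}, \code{seed}.
#' @export
median_of_samples <- function(data, config = fit_config(),
                              resample = resample_config(),
                              level = NA_character_) {
  rc <- resample
  support <- range(data$age_years)
  age_grid <- seq(support[1], support[2], by = config$grid_step)
  if (age_grid[length(age_grid)] < support[2]) age_grid <- c(age_grid, support[2])
  ng <- length(age_grid)
  pl <- rc$percentile_levels

  cent <- array(NA_real_, dim = c(ng, length(pl), rc$n_samples))
  pars <- array(NA_real_, dim = c(ng, 3, rc$n_samples))
  n_failed <- 0L
  for (i in seq_len(rc$n_samples)) {
    sub <- sample_one_per_child(data, derive_seed(rc$seed, i))
    fit <- tryCatch(fit_lms(sub, config, level = level),
                    error = function(e) NULL)
    if (is.null(fit)) { n_failed <- n_failed + 1L; next }
    inside <- age_grid >= fit$age_support[1] - 1e-9 &
              age_grid <= fit$age_support[2] + 1e-9
    if (!any(inside)) { n_failed <- n_failed + 1L; next }
    pa <- .params_at(fit, age_grid[inside])
    q <- vapply(pl, function(p)
      pmin(pmax(qbccg(p, pa$mu, pa$sigma, pa$nu) - fit$shift, 0), 100),
      numeric(sum(inside)))
    cent[inside, , i] <- q
    pars[inside, , i] <- cbind(pa$mu - fit$shift, pa$sigma, pa$nu)
  }
  n_ok <- rc$n_samples - n_failed
  if (n_ok == 0 || n_failed / rc$n_samples > rc$max_fail_frac)
    stop(n_failed, " of ", rc$n_samples, " subsample fits failed")

  cover <- apply(!is.na(cent[, 1, , drop = FALSE]), 1, sum)
  keep <- cover >= rc$min_coverage * n_ok
  if (!any(keep)) stop("no grid age is covered by enough subsample fits")
  med <- function(a) apply(a[keep, , , drop = FALSE], c(1, 2), stats::median,
                           na.rm = TRUE)
  cent_med <- med(cent)
  pars_med <- med(pars)
  colnames(cent_med) <- paste0("p", formatC(100 * pl, format = "g"))

  model <- structure(list(
    level = level, age_grid = age_grid[keep],
    mu_curve = pars_med[, 1], sigma_curve = pars_med[, 2],
    nu_curve = pars_med[, 3], shift = 0,
    edf = NULL, deviance = NA_real_, gaic = NA_real_,
    n_obs = length(unique(data$child_id)),
    age_support = range(age_grid[keep]), converged = NA), class = "lms_model")

  structure(list(level = level, age_grid = age_grid[keep],
                 centiles = cent_med, percentile_levels = pl,
                 model = model, n_samples = rc$n_samples,
                 n_failed = n_failed, seed = rc$seed),
            class = "centile_set")
}

#' @export
print.centile_set <- function(x, ...) {
  cat("Centile set", if (!is.na(x$level)) paste0("(level ", x$level, ")"),
      "- median of", x$n_samples - x$n_failed, "one-per-child subsample fits\n",
      " ages", sprintf("%.2f-%.2f;", min(x$age_grid), max(x$age_grid)),
      "levels:", paste(colnames(x$centiles), collapse = " "), "\n")
  invisible(x)
}

#' Per-level motor development curves
#'
#' Applies the median-of-subsamples procedure to every GMFCS level present in
#' the cohort (and optionally to the pooled cohort), returning the median
#' development curve and centile set per stratum.
#'
#' @param cohort a validated cohort.
#' @param config a \code{\link{fit_config}}.
#' @param resample a \code{\link{resample_config}}.
#' @param include_all also fit the unstratified (all-levels) cohort.
#' @return a named list of \code{centile_set} objects ("I".."V", and "all"
#'   when requested).
#' @export
development_curves <- function(cohort, config = fit_config(),
                               resample = resample_config(),
                               include_all = FALSE) {
  validate_cohort(cohort)
  cohort$level <- .gmfcs_levels[level_index(cohort$level)]
  levels_here <- .gmfcs_levels[.gmfcs_levels %in% unique(cohort$level)]
  out <- lapply(levels_here, function(l)
    median_of_samples(cohort[cohort$level == l, , drop = FALSE],
                      config, resample, level = l))
  names(out) <- levels_here
  if (include_all)
    out$all <- median_of_samples(cohort, config, resample, level = "all")
  out
}

#' Write a centile set as a delimited table
#'
#' Commented metadata header (level, n_samples, seed) followed by a CSV body
#' with \code{age_years} and one column per centile level.
#'
#' @param x a \code{centile_set}.
#' @param path file path.
#' @export
write_centile_table <- function(x, path) {
  meta <- c(sprintf("# level: %s", x$level),
            sprintf("# n_samples: %d", x$n_samples),
            sprintf("# n_failed: %d", x$n_failed),
            sprintf("# seed: %d", x$seed))
  body <- data.frame(age_years = x$age_grid, x$centiles, check.names = FALSE)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(format(body, digits = 8, trim = TRUE), con,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
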