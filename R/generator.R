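#' Configuration for the synthetic longitudinal cohort generator
#'
#' Builds the parameter set of a registry-like synthetic cohort of children
#' with cerebral palsy followed longitudinally with an interval-scaled gross
#' motor score (0-100), stratified by the five-level GMFCS functional
#' classification.  Each child at level \eqn{g} develops along a saturating
#' mean trajectory
#' \deqn{m(t) = \mathrm{limit}_g \,\{1 - e^{-(t - \mathrm{offset}_g)_+ / \mathrm{rate}_g}\},}
#' the classical rate-and-limit parameterization of motor development curves,
#' with child-level heterogeneity on the limit (additive, sd
#' \code{between_child_sd_limit}) and on the log rate (sd
#' \code{between_child_sd_lograte}).  An observed score is a BCCG draw with
#' median equal to the child's trajectory value, scale \code{residual_sigma}
#' and Box-Cox power \code{skewness_nu}, clamped to [0, 100].
#'
#' The default stratum prevalences (52/16/9/11/12 percent for levels I-V),
#' the 0.5-17.3 year age window, the 40 percent proportion of girls and the
#' 1-14 tests per child with mean 3 mirror the published margins of the
#' Norwegian CP registry cohort this generator emulates.  The trajectory
#' parameters themselves (limits near 90/75/60/42/22 for levels I-V, plateau
#' near 7 years for levels I-IV, a level-V curve that is flat over the
#' observed ages) are NOT published values: they are synthetic choices that
#' reproduce the qualitative shape of the published curves, and are
#' documented as such.
#'
#' @param n_children number of children.
#' @param level_proportions probabilities of GMFCS levels I-V (sum to 1).
#' @param limit per-level asymptotic score (length 5, in (0, 100]).
#' @param rate_years per-level exponential time constant, years; the mean
#'   curve reaches 95 percent of its limit at about 3 rate constants.
#' @param offset_years per-level age offset before development starts.
#' @param between_child_sd_limit sd of the additive child-level limit shift.
#' @param between_child_sd_lograte sd of the child-level log-rate shift.
#' @param residual_sigma BCCG scale of within-child score noise.
#' @param skewness_nu BCCG power of the noise (>1 gives left skew, matching a
#'   bounded score with a ceiling).
#' @param tests_per_child_size,tests_per_child_mu size and mean of the
#'   negative-binomial count of extra tests; a child has
#'   \code{1 + min(NB, 13)} tests, supported on 1..14 with target mean 3.
#' @param age_range_years two ages bounding the uniform test-age window.
#' @param prop_female probability a child is female.
#' @param seed integer seed; every draw flows from it.
#'
#' @return an object of class \code{cohort_config} (a list of the above).
#' @export
cohort_config <- function(n_children = 1206,
                          level_proportions = c(0.52, 0.16, 0.09, 0.11, 0.12),
                          limit = c(90, 75, 60, 42, 22),
                          rate_years = c(2.3, 2.3, 2.3, 2.3, 0.3),
                          offset_years = c(0, 0, 0, 0, 0),
                          between_child_sd_limit = 8,
                          between_child_sd_lograte = 0.25,
                          residual_sigma = 0.10,
                          skewness_nu = 1.3,
                          tests_per_child_size = 1.4,
                          tests_per_child_mu = 2.0036,
                          age_range_years = c(0.5, 17.3),
                          prop_female = 0.40,
                          seed = 1L) {
  stopifnot(n_children >= 1, length(level_proportions) == 5,
            all(level_proportions >= 0),
            length(limit) == 5, all(limit > 0), all(limit <= 100),
            length(rate_years) == 5, all(rate_years > 0),
            length(offset_years) == 5, all(offset_years >= 0),
            between_child_sd_limit >= 0, between_child_sd_lograte >= 0,
            residual_sigma > 0, is.finite(skewness_nu),
            tests_per_child_size > 0, tests_per_child_mu > 0,
            length(age_range_years) == 2, age_range_years[1] > 0,
            age_range_years[2] > age_range_years[1],
            prop_female > 0, prop_female < 1)
  if (abs(sum(level_proportions) - 1) > 1e-6)
    stop("'level_proportions' must sum to 1")
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "cohort_config")
}

.gmfcs_levels <- c("I", "II", "III", "IV", "V")

#' Deterministic mean trajectory of the generator
#'
#' The noise-free median score of a child at GMFCS level \code{level} and age
#' \code{age_years} under \code{config}, before any child-level perturbation:
#' \code{clamp(limit * (1 - exp(-(t - offset)+ / rate)), 0, 100)}.
#'
#' @param config a \code{\link{cohort_config}}.
#' @param level GMFCS level, 1..5 or "I".."V".
#' @param age_years vector of ages in years.
#' @return vector of scores.
#' @export
mean_trajectory <- function(config, level, age_years) {
  g <- level_index(level)
  m <- config$limit[g] *
    (1 - exp(-pmax(age_years - config$offset_years[g], 0) / config$rate_years[g]))
  pmin(pmax(m, 0), 100)
}

#' @rdname mean_trajectory
#' @param perturb_limit,perturb_lograte child-level deviations applied to the
#'   limit (additive) and log rate.
#' @keywords internal
.child_trajectory <- function(config, g, age_years, perturb_limit, perturb_lograte) {
  lim <- pmin(pmax(config$limit[g] + perturb_limit, 1), 100)
  rate <- config$rate_years[g] * exp(perturb_lograte)
  m <- lim * (1 - exp(-pmax(age_years - config$offset_years[g], 0) / rate))
  pmin(pmax(m, 0), 100)
}

# map I..V / 1..5 tokens to 1..5
level_index <- function(level) {
  if (is.numeric(level)) {
    g <- as.integer(level)
  } else {
    g <- match(toupper(as.character(level)), .gmfcs_levels)
    asint <- suppressWarnings(as.integer(as.character(level)))
    num <- is.na(g) & !is.na(asint)
    g[num] <- asint[num]
  }
  if (any(is.na(g)) || any(g < 1) || any(g > 5))
    stop("GMFCS level must be I..V or 1..5")
  g
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws a full registry-like cohort under \code{config}: each child gets a
#' GMFCS level, a sex, child-level trajectory perturbations, a number of
#' tests (1-14, mean about 3) and uniformly distributed test ages; each test
#' score is a BCCG draw around the child's trajectory, clamped to [0, 100].
#' Ages are rounded to 0.01 years (the resolution the cohort files carry) and
#' kept unique within a child.  Fully reproducible from \code{config$seed}.
#'
#' @param config a \code{\link{cohort_config}}.
#' @param label free-text cohort label stored on the result.
#' @return a \code{data.frame} of class \code{cohort} with columns
#'   \code{child_id}, \code{sex}, \code{level}, \code{age_years},
#'   \code{score}.
#' @export
generate_cohort <- function(config, label = "synthetic") {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_children
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)

  g <- sample.int(5, n, replace = TRUE, prob = config$level_proportions)
  sex <- ifelse(stats::runif(n) < config$prop_female, "female", "male")
  n_tests <- 1L + pmin(stats::rnbinom(n, size = config$tests_per_child_size,
                                      mu = config$tests_per_child_mu), 13L)
  d_lim <- stats::rnorm(n, 0, config$between_child_sd_limit)
  d_lrate <- stats::rnorm(n, 0, config$between_child_sd_lograte)

  rows <- vector("list", n)
  lo <- config$age_range_years[1]; hi <- config$age_range_years[2]
  for (i in seq_len(n)) {
    k <- n_tests[i]
    ages <- round(stats::runif(k, lo, hi), 2)
    while (anyDuplicated(ages)) {
      dup <- duplicated(ages)
      ages[dup] <- round(stats::runif(sum(dup), lo, hi), 2)
    }
    m <- .child_trajectory(config, g[i], ages, d_lim[i], d_lrate[i])
    score <- rbccg(k, mu = pmax(m, 0.5), sigma = config$residual_sigma,
                   nu = config$skewness_nu)
    rows[[i]] <- data.frame(
      child_id = sprintf("c%05d", i), sex = sex[i],
      level = .gmfcs_levels[g[i]], age_years = ages,
      score = pmin(pmax(score, 0), 100))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "label") <- label
  attr(out, "config") <- config
  class(out) <- c("cohort", "data.frame")
  validate_cohort(out)
  out
}

#' Ground-truth percentile implied by the generator
#'
#' The population p-quantile of the observed (clamped) score at a given level
#' and age.  With no child-level heterogeneity the quantile is closed form
#' from the BCCG quantile function; otherwise it is estimated by seeded Monte
#' Carlo over child-level perturbations (at least 1e5 draws).
#'
#' @param config a \code{\link{cohort_config}}.
#' @param level GMFCS level.
#' @param age_years a single age inside the configured range.
#' @param p probability in (0, 1); vectorized.
#' @param n_mc Monte Carlo size when heterogeneity is present.
#' @param mc_seed seed of the Monte Carlo draw.
#' @return score quantile(s), in [0, 100].
#' @export
true_percentile <- function(config, level, age_years, p,
                            n_mc = 2e5, mc_seed = 20251001L) {
  stopifnot(inherits(config, "cohort_config"), length(age_years) == 1)
  if (any(p <= 0) || any(p >= 1)) stop("'p' must lie in (0, 1)")
  if (age_years < config$age_range_years[1] || age_years > config$age_range_years[2])
    stop("'age_years' outside the configured age range")
  g <- level_index(level)
  if (config$between_child_sd_limit == 0 && config$between_child_sd_lograte == 0) {
    m <- mean_trajectory(config, g, age_years)
    q <- qbccg(p, mu = max(m, 0.5), sigma = config$residual_sigma,
               nu = config$skewness_nu)
    return(pmin(pmax(q, 0), 100))
  }
  n_mc <- max(n_mc, 1e5)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(mc_seed)
  d_lim <- stats::rnorm(n_mc, 0, config$between_child_sd_limit)
  d_lrate <- stats::rnorm(n_mc, 0, config$between_child_sd_lograte)
  m <- .child_trajectory(config, g, age_years, d_lim, d_lrate)
  y <- rbccg(n_mc, mu = pmax(m, 0.5), sigma = config$residual_sigma,
             nu = config$skewness_nu)
  y <- pmin(pmax(y, 0), 100)
  unname(stats::quantile(y, probs = p, type = 8))
}

# preserve the caller's RNG state around seeded internals
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Read and write generator configurations
#'
#' A \code{\link{cohort_config}} serializes to a flat key-value text file
#' (\code{key: value}, vectors comma-separated), so the exact simulation
#' conditions can be stored next to the cohorts they produced.
#'
#' @param config a \code{cohort_config}.
#' @param path file path.
#' @return \code{read_cohort_config} returns a \code{cohort_config}.
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  writeLines(vapply(names(config), function(k)
    sprintf("%s: %s", k, paste(format(config[[k]], digits = 15), collapse = ",")),
    character(1)), path)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  lines <- readLines(path)
  kv <- regmatches(lines, regexpr(": ", lines), invert = TRUE)
  vals <- lapply(kv, function(x) as.numeric(strsplit(x[2], ",")[[1]]))
  names(vals) <- vapply(kv, `[[`, character(1), 1)
  do.call(cohort_config, vals)
}
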