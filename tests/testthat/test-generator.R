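test_that("generation is deterministic in the seed and distinct across seeds", {
  cfg <- cohort_config(n_children = 120, seed = 5)
  a <- generate_cohort(cfg); b <- generate_cohort(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- generate_cohort(cohort_config(n_children = 120, seed = 6))
  expect_false(identical(a$score, c2$score))
})

test_that("cohort structure matches the configured margins", {
  cfg <- cohort_config(n_children = 1206, seed = 9)
  coh <- generate_cohort(cfg)
  expect_s3_class(coh, "cohort")
  expect_equal(length(unique(coh$child_id)), 1206)
  # about 3 tests per child (3612 total in the emulated registry)
  expect_gt(nrow(coh), 1206 * 2.7)
  expect_lt(nrow(coh), 1206 * 3.3)
  expect_true(all(coh$age_years >= 0.5 & coh$age_years <= 17.3))
  expect_true(all(coh$score >= 0 & coh$score <= 100))
  tpc <- table(coh$child_id)
  expect_true(all(tpc >= 1 & tpc <= 14))
})

test_that("level proportions and tests-per-child converge to their targets", {
  cfg <- cohort_config(n_children = 10000, seed = 21)
  coh <- generate_cohort(cfg)
  kids <- coh[!duplicated(coh$child_id), ]
  obs <- table(factor(kids$level, levels = c("I", "II", "III", "IV", "V")))
  gof <- chisq.test(obs, p = cfg$level_proportions)
  expect_gt(gof$p.value, 0.01)
  expect_lt(abs(nrow(coh) / 10000 - 3), 0.1)
})

test_that("invalid configurations are refused", {
  expect_error(cohort_config(level_proportions = c(0.5, 0.2, 0.1, 0.1, 0.2)),
               "sum to 1")
  expect_error(cohort_config(residual_sigma = 0))
  expect_error(cohort_config(age_range_years = c(5, 2)))
})

test_that("noise-free cohorts sit on the deterministic mean curves, monotone in age", {
  cfg <- noise_free_config(n_children = 200, seed = 31)
  coh <- generate_cohort(cfg)
  m <- vapply(seq_len(nrow(coh)), function(i)
    mean_trajectory(cfg, coh$level[i], coh$age_years[i]), numeric(1))
  expect_lt(max(abs(coh$score - m)), 1e-3)
  # per child: non-decreasing in age (offsets are all 0)
  for (id in unique(coh$child_id)[1:50]) {
    d <- coh[coh$child_id == id, ]
    d <- d[order(d$age_years), ]
    expect_true(all(diff(d$score) >= -1e-3))
  }
})

test_that("true_percentile matches closed forms in the homogeneous case", {
  cfg <- cohort_config(between_child_sd_limit = 0, between_child_sd_lograte = 0,
                       residual_sigma = 0.05, skewness_nu = 1)
  # median = mean curve
  expect_equal(true_percentile(cfg, "II", 4, 0.5),
               mean_trajectory(cfg, "II", 4), tolerance = 1e-10)
  # at the age where the level-I mean is exactly 60, the Phi(1) quantile of
  # normal noise is mu * (1 + sigma) = 63
  t60 <- -2.3 * log(1 - 60 / 90)
  expect_equal(mean_trajectory(cfg, "I", t60), 60, tolerance = 1e-10)
  expect_equal(true_percentile(cfg, "I", t60, pnorm(1)), 63, tolerance = 1e-9)
  expect_error(true_percentile(cfg, "I", 5, 1.2), "p")
})

test_that("true_percentile under heterogeneity matches a quadrature mixture oracle", {
  cfg <- cohort_config(between_child_sd_limit = 6, between_child_sd_lograte = 0.2,
                       residual_sigma = 0.08, skewness_nu = 1.3)
  age <- 10; level <- "IV"   # far from the 0/100 clamps
  # oracle: F(q) = E over child effects of the BCCG cdf, by nested quadrature
  F <- function(q) {
    integrate(function(dl) {
      vapply(dl, function(d1) {
        integrate(function(dr)
          pbccg(q, mu = pmax(gmfmref:::.child_trajectory(cfg, 4, age, d1, dr), 0.5),
                sigma = cfg$residual_sigma, nu = cfg$skewness_nu,
                truncate = FALSE) *
            dnorm(dr, 0, cfg$between_child_sd_lograte),
          -0.8, 0.8, rel.tol = 1e-8)$value *
          dnorm(d1, 0, cfg$between_child_sd_limit)
      }, numeric(1))
    }, -24, 24, rel.tol = 1e-7)$value
  }
  for (p in c(0.25, 0.5, 0.9)) {
    q <- true_percentile(cfg, level, age, p, n_mc = 4e5)
    # Monte-Carlo standard error of the quantile, via the density at q
    expect_equal(F(q), p, tolerance = 0.005)
  }
})

test_that("generator configurations round-trip through the key-value file", {
  cfg <- cohort_config(n_children = 77, seed = 9, residual_sigma = 0.08)
  path <- withr::local_tempfile(fileext = ".cfg")
  write_cohort_config(cfg, path)
  back <- read_cohort_config(path)
  expect_equal(back[order(names(back))], cfg[order(names(cfg))],
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_identical(as.data.frame(generate_cohort(back)),
                   as.data.frame(generate_cohort(cfg)))
})
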