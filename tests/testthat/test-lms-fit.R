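test_that("constant-parameter fits agree with a direct numerical MLE", {
  set.seed(101)
  n <- 1000
  age <- runif(n, 1, 15)
  y <- rbccg(n, mu = 60, sigma = 0.1, nu = 1)
  d <- data.frame(child_id = as.character(1:n), level = "I",
                  age_years = age, score = y)
  fit <- fit_lms(d, fit_config(mu_df = 0, sigma_df = 0, nu_df = 0))
  # independent oracle: direct optimization of the same likelihood
  nll <- function(th) -sum(dbccg(y, th[1], exp(th[2]), th[3], log = TRUE))
  opt <- optim(c(mean(y), log(sd(y) / mean(y)), 1), nll, hessian = TRUE)
  se <- sqrt(diag(solve(opt$hessian)))
  expect_lt(abs(fit$mu_curve[1] - opt$par[1]), 3 * se[1])
  expect_lt(abs(log(fit$sigma_curve[1]) - opt$par[2]), 3 * se[2])
  expect_lt(abs(fit$nu_curve[1] - opt$par[3]), 3 * se[3])
  expect_equal(fit$edf, c(mu = 1, sigma = 1, nu = 1))
  # the curves really are constants
  expect_lt(diff(range(fit$mu_curve)), 1e-8)
})

test_that("deviance is non-increasing over outer iterations and GAIC is its stated arithmetic", {
  sl <- bccg_stratum(800, seed = 7)
  fit <- fit_lms(sl, fit_config())
  expect_true(all(diff(fit$deviance_trace) <= fit$config$tol_deviance))
  expect_true(fit$converged)
  expect_equal(fit$gaic, fit$deviance + 2 * sum(fit$edf))
  expect_equal(gaic(1000, 10, 2), 1020)
})

test_that("the noise-free limit recovers the generating mean curve", {
  cfg <- noise_free_config(n_children = 500, seed = 41)
  coh <- generate_cohort(cfg)
  sl <- coh[coh$level == "I", ]
  # with essentially no noise the statistically right spline is near-
  # interpolating, so the degenerate-limit check uses a generous df budget
  fit <- fit_lms(sl, fit_config(mu_df = 20, sigma_df = 0, fix_nu = 1))
  truth <- mean_trajectory(cfg, "I", fit$age_grid)
  expect_lt(max(abs(fit$mu_curve - truth)), 0.5)
})

test_that("age-varying L, M, S are recovered from a large independent sample", {
  mu_f <- function(t) 85 * (1 - exp(-t / 2.5))
  sg_f <- function(t) 0.12 - 0.003 * t
  sl <- bccg_stratum(2000, seed = 55, mu_fun = mu_f, sigma_fun = sg_f,
                     nu_fun = function(t) rep(1.5, length(t)))
  fit <- fit_lms(sl, fit_config())
  sup <- fit$age_support
  central <- fit$age_grid >= sup[1] + 0.1 * diff(sup) &
             fit$age_grid <= sup[2] - 0.1 * diff(sup)
  mae <- median(abs(fit$mu_curve - mu_f(fit$age_grid))[central])
  expect_lt(mae, 1)
  # the scale curve tracks its (gentle) trend
  expect_lt(median(abs(fit$sigma_curve - sg_f(fit$age_grid))[central]), 0.02)
})

test_that("percentile curves are the quantile transform of the fitted parameters", {
  sl <- bccg_stratum(600, seed = 19)
  fit <- fit_lms(sl, quick_fit())
  pc <- percentile_curve(fit, c(0.05, 0.5, 0.95))
  expect_equal(pc$p50, fit$mu_curve)          # median identity (no shift here)
  expect_true(all(pc$p5 < pc$p50 & pc$p50 < pc$p95))
  expect_true(all(pc$p95 <= 100 & pc$p5 >= 0))
})

test_that("percentile_of inverts percentile_curve and orders children correctly", {
  # a lower-scoring stratum, so no centile touches the 100-point ceiling
  sl <- bccg_stratum(600, seed = 23,
                     mu_fun = function(t) 65 * (1 - exp(-t / 2.3)))
  fit <- fit_lms(sl, quick_fit())
  for (p in c(0.1, 0.5, 0.9)) {
    pc <- percentile_curve(fit, p)
    at <- c(3, 8, 14)
    sc <- approx(pc$age_years, pc[[2]], at)$y
    expect_equal(percentile_of(fit, at, sc), rep(p, 3), tolerance = 1e-6)
  }
  # same score, different ages: the child at the age with the higher median
  # ranks lower
  m5 <- approx(fit$age_grid, fit$mu_curve, 5)$y
  m12 <- approx(fit$age_grid, fit$mu_curve, 12)$y
  expect_gt(m12, m5)
  expect_lt(percentile_of(fit, 12, 60), percentile_of(fit, 5, 60))
  expect_error(percentile_of(fit, 40, 60), "outside")
})

test_that("zero scores are handled by the documented +0.5 shift", {
  sl <- bccg_stratum(400, seed = 29,
                     mu_fun = function(t) pmax(30 * (1 - exp(-t / 3)), 1))
  sl$score[1] <- 0
  fit <- fit_lms(sl, quick_fit())
  expect_equal(fit$shift, 0.5)
  pc <- percentile_curve(fit, 0.5)
  expect_equal(pc$p50, pmin(pmax(fit$mu_curve - 0.5, 0), 100))
  expect_true(all(is.finite(percentile_of(fit, sl$age_years, sl$score))))
})

test_that("small strata are refused", {
  sl <- bccg_stratum(20, seed = 1)
  expect_error(fit_lms(sl, fit_config()), "at least 50")
})

test_that("fits are equivariant under a constant age shift", {
  sl <- bccg_stratum(500, seed = 61)
  f1 <- fit_lms(sl, quick_fit())
  sl2 <- sl; sl2$age_years <- sl2$age_years + 5
  f2 <- fit_lms(sl2, quick_fit())
  expect_equal(f2$age_support, f1$age_support + 5, tolerance = 1e-10)
  expect_equal(f2$mu_curve, f1$mu_curve, tolerance = 1e-6)
  expect_equal(f2$sigma_curve, f1$sigma_curve, tolerance = 1e-6)
})

test_that("with nu fixed and a constant scale, the median spline is the weighted penalized LS fit", {
  sl <- bccg_stratum(700, seed = 71)
  cfg <- fit_config(mu_df = 4, sigma_df = 0, fix_nu = 1)
  fit <- fit_lms(sl, cfg)
  # at the fixed point, one more working-response spline step reproduces mu
  ord <- order(sl$age_years)
  x <- sl$age_years[ord]; y <- sl$score[ord]
  mu <- approx(fit$age_grid, fit$mu_curve, x)$y
  sg <- approx(fit$age_grid, fit$sigma_curve, x)$y
  st <- gmfmref:::.bccg_steps(y, mu, sg, rep(1, length(y)))
  direct <- smooth.spline(x, mu + st$mu_u / st$mu_w, w = st$mu_w, df = 5,
                          cv = FALSE)
  expect_equal(predict(direct, x)$y, mu, tolerance = 1e-4)
})

test_that("residual diagnostics are calibrated when the model is true", {
  sl <- bccg_stratum(1500, seed = 83, mu_fun = function(t) 70 * (1 - exp(-t / 2)),
                     sigma_fun = function(t) rep(0.1, length(t)),
                     nu_fun = function(t) rep(1, length(t)))
  fit <- fit_lms(sl, fit_config())
  diag <- residual_zscores(fit, sl)
  expect_lt(abs(mean(diag$z)), 3 / sqrt(length(diag$z)))
  expect_gt(shapiro.test(diag$z)$p.value, 0.01)
  # smoothed residual-by-age stays near zero away from the edges
  sm <- diag$smooth
  central <- sm$age_years > quantile(sl$age_years, 0.1) &
             sm$age_years < quantile(sl$age_years, 0.9)
  expect_lt(max(abs(sm$smooth_z[central])), 0.15)
  # binned local means carry one entry per bin
  expect_equal(sum(diag$by_age$n), nrow(sl))
  # Q-Q pairs are sorted and of equal length
  expect_equal(nrow(diag$qq), length(diag$z))
  expect_true(!is.unsorted(diag$qq$theoretical))
  expect_true(!is.unsorted(diag$qq$empirical))
})
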