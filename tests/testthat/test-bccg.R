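test_that("z-score hits its closed forms at the location point, normal and lognormal cases", {
  expect_equal(zbccg(60, mu = 60, sigma = 0.13, nu = -0.7), 0)
  expect_equal(zbccg(66, mu = 60, sigma = 0.1, nu = 1), 1)
  expect_equal(zbccg(50 * exp(0.2), mu = 50, sigma = 0.2, nu = 0), 1)
  expect_error(zbccg(-1, mu = 60, sigma = 0.1, nu = 1), "positive")
  expect_error(zbccg(60, mu = -5, sigma = 0.1, nu = 1), "mu")
})

test_that("quantile hits its closed forms and inverts the z-score", {
  expect_equal(qbccg(0.5, mu = 43.7, sigma = 0.2, nu = -1.2), 43.7)
  expect_equal(qbccg(pnorm(1), mu = 60, sigma = 0.1, nu = 1), 66)
  # round trip over a parameter sweep, tol 1e-8
  set.seed(4)
  for (i in 1:25) {
    mu <- runif(1, 5, 95); sigma <- runif(1, 0.03, 0.3); nu <- runif(1, -2, 3)
    y <- qbccg(runif(1, 0.01, 0.99), mu, sigma, nu)
    expect_equal(qbccg(pnorm(zbccg(y, mu, sigma, nu)), mu, sigma, nu), y,
                 tolerance = 1e-8)
  }
})

test_that("quantile is strictly increasing in p and continuous in nu at 0", {
  p <- seq(0.01, 0.99, by = 0.01)
  q <- qbccg(p, mu = 55, sigma = 0.12, nu = -0.5)
  expect_true(all(diff(q) > 0))
  expect_lt(max(abs(qbccg(p, 50, 0.15, 1e-8) - qbccg(p, 50, 0.15, 0))), 1e-6)
})

test_that("beyond the Box-Cox support boundary the quantile truncates to 0 with a warning", {
  # nu, sigma large enough that a moderate lower tail crosses 1 + nu*sigma*z = 0
  expect_warning(q <- qbccg(1e-6, mu = 50, sigma = 0.5, nu = 2), "truncat")
  expect_identical(q, 0)
})

test_that("log-density matches the normal closed form at nu = 1", {
  y <- seq(30, 90, by = 5)
  expect_equal(dbccg(y, mu = 60, sigma = 0.1, nu = 1, log = TRUE, truncate = FALSE),
               dnorm(y, 60, 6, log = TRUE), tolerance = 1e-6)
  # with the truncation constant the difference is the (tiny) normalization
  d <- dbccg(60, 60, 0.1, 1, log = TRUE, truncate = TRUE) -
       dnorm(60, 60, 6, log = TRUE)
  expect_equal(d, -pnorm(10, log.p = TRUE), tolerance = 1e-12)
})

test_that("density integrates to 1 over its support", {
  f <- function(y) dbccg(y, mu = 60, sigma = 0.1, nu = -0.3)
  expect_equal(integrate(f, 1e-8, 2000, rel.tol = 1e-9)$value, 1,
               tolerance = 1e-6)
  # lognormal case too
  g <- function(y) dbccg(y, mu = 40, sigma = 0.2, nu = 0)
  expect_equal(integrate(g, 1e-8, 5000, rel.tol = 1e-9)$value, 1,
               tolerance = 1e-6)
})

test_that("the mode at nu = 0 equals the lognormal closed form", {
  mu <- 52; sigma <- 0.18
  opt <- optimize(function(y) dbccg(y, mu, sigma, 0, log = TRUE),
                  c(10, 100), maximum = TRUE, tol = 1e-9)
  expect_equal(opt$maximum, mu * exp(-sigma^2), tolerance = 1e-5)
})

test_that("quantile agrees with an independent quadrature oracle for skewed parameters", {
  # oracle: integrate the density from 0 to q and recover p
  mu <- 55; sigma <- 0.08; nu <- -0.5
  for (p in c(0.1, 0.5, 0.9)) {
    q <- qbccg(p, mu, sigma, nu)
    mass <- integrate(function(y) dbccg(y, mu, sigma, nu), 1e-8, q,
                      rel.tol = 1e-10)$value
    expect_equal(mass, p, tolerance = 1e-6)
  }
})

test_that("random generation is seeded, positive, and centred on mu at nu = 1", {
  set.seed(11); a <- rbccg(5, 60, 0.1, -0.5)
  set.seed(11); b <- rbccg(5, 60, 0.1, -0.5)
  expect_identical(a, b)
  set.seed(12)
  y <- rbccg(1e5, 30, 0.4, -1.5)   # heavy skew: support check under stress
  expect_true(all(y > 0))
  set.seed(13)
  y <- rbccg(2e5, 60, 0.1, 1)
  expect_lt(abs(mean(y) - 60), 3 * 6 / sqrt(2e5))
})

test_that("pbccg is the inverse of qbccg including the truncation normalization", {
  p <- c(0.05, 0.5, 0.95)
  q <- qbccg(p, 45, 0.12, 0.8)
  # untruncated: exact inverse
  expect_equal(pbccg(q, 45, 0.12, 0.8, truncate = FALSE), p, tolerance = 1e-10)
  # truncated: differs only by the (negligible here) normalization
  expect_equal(pbccg(q, 45, 0.12, 0.8, truncate = TRUE), p, tolerance = 1e-8)
})
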