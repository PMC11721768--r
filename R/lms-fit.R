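#' Fitting configuration for age-varying LMS curves
#'
#' Controls the penalized-likelihood fit of age-varying BCCG parameters
#' L(t), M(t), S(t).  Each parameter gets its own smoothness budget \code{df},
#' counted as effective degrees of freedom beyond a constant: \code{df = 0}
#' fits a constant, \code{df = 1} a straight line in age, \code{df >= 2} a
#' cubic smoothing spline with total effective df \code{df + 1}.  The degree
#' of smoothing is either fixed here or chosen by stepwise search over
#' \code{df_grid} under the generalized Akaike criterion
#' GAIC = deviance + \code{gaic_penalty} x (total edf), with penalty 2 by
#' default.
#'
#' @param mu_df,sigma_df,nu_df smoothing df for the median, scale and power
#'   curves.  Defaults (4, 2, 0) allow a flexible median, a gently varying
#'   scale and a constant Box-Cox power, the usual LMS starting point; the
#'   power is weakly identified in small strata, so it stays constant unless
#'   selection expands it.
#' @param gaic_penalty GAIC penalty per effective df (k = 2).
#' @param df_grid candidate df values for stepwise selection.
#' @param max_outer_iters cap on outer backfitting cycles.
#' @param tol_deviance convergence tolerance on the change in deviance.
#' @param age_transform \code{"identity"} or \code{"power"}; the power
#'   transform \code{age^age_power} compresses infancy, off by default since
#'   observed ages start at 0.5 years.
#' @param age_power exponent used when \code{age_transform = "power"}.
#' @param min_group_size smallest stratum the fitter accepts.
#' @param truncate_density include the BCCG truncation normalization in the
#'   likelihood (see \code{\link{dbccg}}).
#' @param fix_nu optional fixed value for the Box-Cox power; when set, the
#'   power is held there and contributes no effective df.
#' @param grid_step spacing, in years, of the age grid curves are reported on.
#' @return an object of class \code{fit_config}.
#' @export
fit_config <- function(mu_df = 4, sigma_df = 2, nu_df = 0,
                       gaic_penalty = 2, df_grid = 0:10,
                       max_outer_iters = 50, tol_deviance = 1e-4,
                       age_transform = c("identity", "power"), age_power = 0.5,
                       min_group_size = 50, truncate_density = TRUE,
                       fix_nu = NULL, grid_step = 0.05) {
  age_transform <- match.arg(age_transform)
  stopifnot(gaic_penalty > 0, length(df_grid) >= 1, all(df_grid >= 0),
            max_outer_iters >= 1, tol_deviance > 0, min_group_size >= 4,
            grid_step > 0, mu_df >= 0, sigma_df >= 0, nu_df >= 0)
  structure(as.list(environment()), class = "fit_config")
}

# weighted smoother with a fixed effective-df budget beyond a constant;
# returns fitted values at x and a predictor usable on new x
.fit_term <- function(x, e, w, df) {
  ux <- length(unique(x))
  df <- min(df, ux - 1L)
  if (df <= 0) {
    c0 <- stats::weighted.mean(e, w)
    list(fitted = rep(c0, length(x)), predict = function(newx) rep(c0, length(newx)),
         edf = 1)
  } else if (df == 1) {
    f <- stats::lm.wfit(cbind(1, x), e, w)
    b <- f$coefficients
    list(fitted = f$fitted.values,
         predict = function(newx) b[1] + b[2] * newx, edf = 2)
  } else {
    sp <- stats::smooth.spline(x, e, w = w, df = df + 1, cv = FALSE,
                               keep.data = FALSE)
    list(fitted = stats::predict(sp, x)$y,
         predict = function(newx) stats::predict(sp, newx)$y,
         edf = df + 1)
  }
}

# score and expected-information weight of the BCCG log-likelihood with
# respect to each parameter's predictor (identity link for mu and nu, log
# link for sigma); the nu score uses a series form stable as nu -> 0
.bccg_steps <- function(y, mu, sigma, nu) {
  z <- zbccg(y, mu, sigma, nu)
  u <- log(y / mu)
  mu_u <- z / (mu * sigma) + nu * (z^2 - 1) / mu
  mu_w <- (1 + 2 * sigma^2 * nu^2) / (mu^2 * sigma^2)
  sg_u <- z^2 - 1                      # d l / d log(sigma)
  sg_w <- rep(2, length(y))
  small <- abs(nu) < 1e-4
  h <- ifelse(small, (u^2 / 2 + nu * u^3 / 6) / sigma, (z - u / sigma) / nu)
  nu_u <- u + z * h - u * z^2
  nu_w <- pmax(7 * sigma^2 / 4, 1e-8)
  list(mu_u = mu_u, mu_w = mu_w, sg_u = sg_u, sg_w = sg_w,
       nu_u = nu_u, nu_w = nu_w)
}

#' Fit age-varying LMS (BCCG) curves to one stratum
#'
#' Maximizes the penalized BCCG log-likelihood over age-varying median M(t),
#' scale S(t) and Box-Cox power L(t) by iterative backfitting: an outer loop
#' cycles over the three parameters, and each inner step fits a weighted
#' cubic smoothing spline (at that parameter's effective df) to the Fisher
#' working response.  If a full cycle would increase the deviance the step is
#' halved, so the deviance trace is non-increasing up to the convergence
#' tolerance.  Deviance is \eqn{-2\,\hat\ell} and
#' GAIC = deviance + k x (total edf).
#'
#' Scores of exactly 0 fall outside the BCCG support; when any are present,
#' all scores are shifted up by 0.5 units for fitting and every reported
#' curve is shifted back down.  Observed cohorts rarely trigger this (the
#' registry minimum is 4).
#'
#' @param data a cohort slice: data.frame with \code{age_years} and
#'   \code{score} for a single stratum.
#' @param config a \code{\link{fit_config}}.
#' @param level label stored on the model (e.g. "I".."V" or "all").
#' @return an object of class \code{lms_model}: curves \code{mu_curve},
#'   \code{sigma_curve}, \code{nu_curve} on \code{age_grid}, effective dfs,
#'   \code{deviance}, \code{gaic}, \code{n_obs}, \code{age_support},
#'   convergence information.
#' @export
fit_lms <- function(data, config = fit_config(), level = NA_character_) {
  stopifnot(inherits(config, "fit_config"))
  age <- data$age_years; score <- data$score
  ok <- is.finite(age) & is.finite(score)
  age <- age[ok]; score <- score[ok]
  n <- length(age)
  if (n < config$min_group_size)
    stop("stratum has ", n, " observations; at least ", config$min_group_size,
         " are required for a stable LMS fit")
  shift <- if (any(score <= 0)) 0.5 else 0
  y <- score + shift
  x <- if (config$age_transform == "power") age^config$age_power else age
  ord <- order(x)
  x <- x[ord]; y <- y[ord]; age_s <- age[ord]

  support <- range(age_s)
  age_grid <- seq(support[1], support[2], by = config$grid_step)
  if (age_grid[length(age_grid)] < support[2]) age_grid <- c(age_grid, support[2])
  xg <- if (config$age_transform == "power") age_grid^config$age_power else age_grid

  fixed_nu <- !is.null(config$fix_nu)
  # initial values: smoothed median-scale location, constant scale and power
  t0 <- .fit_term(x, y, rep(1, n), config$mu_df)
  mu <- pmax(t0$fitted, 0.05); mu_g <- pmax(t0$predict(xg), 0.05)
  s0 <- max(stats::sd(y - mu) / mean(mu), 0.02)
  sigma <- rep(s0, n); sigma_g <- rep(s0, length(xg))
  nu0 <- if (fixed_nu) config$fix_nu else 1
  nu <- rep(nu0, n); nu_g <- rep(nu0, length(xg))

  dev <- function(mu, sigma, nu)
    -2 * sum(dbccg(y, mu, sigma, nu, log = TRUE,
                   truncate = config$truncate_density))
  d_old <- dev(mu, sigma, nu)
  trace <- d_old
  converged <- FALSE
  edf <- c(mu = NA_real_, sigma = NA_real_, nu = NA_real_)

  for (it in seq_len(config$max_outer_iters)) {
    mu0 <- mu; sg0 <- sigma; nu0v <- nu
    mu0g <- mu_g; sg0g <- sigma_g; nu0g <- nu_g

    st <- .bccg_steps(y, mu, sigma, nu)
    tm <- .fit_term(x, mu + st$mu_u / st$mu_w, st$mu_w, config$mu_df)
    mu <- pmax(tm$fitted, 0.05); mu_g <- pmax(tm$predict(xg), 0.05)
    edf["mu"] <- tm$edf

    st <- .bccg_steps(y, mu, sigma, nu)
    ts <- .fit_term(x, log(sigma) + st$sg_u / st$sg_w, st$sg_w, config$sigma_df)
    sigma <- pmin(pmax(exp(ts$fitted), 1e-3), 2)
    sigma_g <- pmin(pmax(exp(ts$predict(xg)), 1e-3), 2)
    edf["sigma"] <- ts$edf

    if (!fixed_nu) {
      st <- .bccg_steps(y, mu, sigma, nu)
      tv <- .fit_term(x, nu + st$nu_u / st$nu_w, st$nu_w, config$nu_df)
      # damped update: the power is the least-identified parameter
      nu <- pmin(pmax(nu + 0.5 * (tv$fitted - nu), -5), 5)
      nu_g <- pmin(pmax(nu_g + 0.5 * (tv$predict(xg) - nu_g), -5), 5)
      edf["nu"] <- tv$edf
    } else {
      edf["nu"] <- 0
    }

    d_new <- dev(mu, sigma, nu)
    # step-halve the whole cycle if the deviance worsened
    if (d_new > d_old + config$tol_deviance) {
      lam <- 0.5; tries <- 0
      repeat {
        mu <- pmax(mu0 + lam * (tm$fitted - mu0), 0.05)
        mu_g <- pmax(mu0g + lam * (tm$predict(xg) - mu0g), 0.05)
        sigma <- pmin(pmax(sg0 * exp(lam * (ts$fitted - log(sg0))), 1e-3), 2)
        sigma_g <- pmin(pmax(sg0g * exp(lam * (ts$predict(xg) - log(sg0g))), 1e-3), 2)
        if (!fixed_nu) {
          nu <- pmin(pmax(nu0v + lam * 0.5 * (tv$fitted - nu0v), -5), 5)
          nu_g <- pmin(pmax(nu0g + lam * 0.5 * (tv$predict(xg) - nu0g), -5), 5)
        }
        d_new <- dev(mu, sigma, nu)
        tries <- tries + 1
        if (d_new <= d_old + config$tol_deviance || tries >= 6) break
        lam <- lam / 2
      }
      if (d_new > d_old + config$tol_deviance) {
        # no improving step: restore and stop
        mu <- mu0; sigma <- sg0; nu <- nu0v
        mu_g <- mu0g; sigma_g <- sg0g; nu_g <- nu0g
        d_new <- d_old
        converged <- TRUE
      }
    }
    trace <- c(trace, d_new)
    if (abs(d_old - d_new) < config$tol_deviance) { converged <- TRUE }
    d_old <- d_new
    if (converged) break
  }
  if (!converged)
    warning("LMS backfitting did not converge in ", config$max_outer_iters,
            " iterations (last deviance change ",
            signif(abs(diff(utils::tail(trace, 2))), 3), ")")

  edf_total <- sum(edf)
  structure(list(
    level = level, age_grid = age_grid,
    mu_curve = mu_g, sigma_curve = sigma_g, nu_curve = nu_g,
    shift = shift,
    edf = edf, df = c(mu = config$mu_df, sigma = config$sigma_df,
                      nu = if (fixed_nu) NA_real_ else config$nu_df),
    deviance = d_old, gaic = gaic(d_old, edf_total, config$gaic_penalty),
    n_obs = n, age_support = support,
    converged = converged, n_iter = length(trace) - 1,
    deviance_trace = trace, config = config), class = "lms_model")
}

#' Generalized Akaike information criterion
#'
#' GAIC = deviance + k x (total effective degrees of freedom); k = 2 gives
#' the classical AIC used to pick the degree of smoothing.
#'
#' @param deviance model deviance, \eqn{-2\log\hat L}.
#' @param edf_total summed effective df of all smooth terms.
#' @param k penalty per effective df.
#' @return the criterion value.
#' @export
gaic <- function(deviance, edf_total, k = 2) deviance + k * edf_total

#' @export
print.lms_model <- function(x, ...) {
  cat("LMS (BCCG) model", if (!is.na(x$level)) paste0("for level ", x$level),
      "\n  n =", x$n_obs, " ages", sprintf("%.2f-%.2f", x$age_support[1],
      x$age_support[2]), "\n  edf (mu, sigma, nu):",
      paste(x$edf, collapse = ", "), "\n  deviance:", round(x$deviance, 2),
      " GAIC:", round(x$gaic, 2),
      if (!x$converged) "\n  WARNING: not converged" else "", "\n")
  invisible(x)
}

# interpolate the three fitted parameter curves at arbitrary ages
.params_at <- function(model, age_years, allow_extrapolation = FALSE) {
  lo <- model$age_support[1]; hi <- model$age_support[2]
  out_of <- age_years < lo - 1e-9 | age_years > hi + 1e-9
  if (any(out_of) && !allow_extrapolation)
    stop("age(s) outside the fitted support [", round(lo, 2), ", ",
         round(hi, 2), "]; extrapolation must be requested explicitly")
  a <- pmin(pmax(age_years, lo), hi)
  list(mu = stats::approx(model$age_grid, model$mu_curve, a)$y,
       sigma = stats::approx(model$age_grid, model$sigma_curve, a)$y,
       nu = stats::approx(model$age_grid, model$nu_curve, a)$y)
}

#' Percentile curves from a fitted LMS model
#'
#' Evaluates the age-conditional BCCG quantile pointwise on the model's age
#' grid: \eqn{M(t)\{1 + L(t) S(t) z_p\}^{1/L(t)}}.  Values are clipped to
#' [0, 100]; an attribute \code{"truncated"} flags clipped entries.
#'
#' @param model an \code{lms_model}.
#' @param p percentile levels in (0, 1); vectorized.
#' @return a data.frame with \code{age_years} and one column per level,
#'   named \code{p5}, \code{p50}, ...
#' @export
percentile_curve <- function(model, p) {
  if (any(p <= 0) || any(p >= 1)) stop("'p' must lie in (0, 1)")
  cols <- lapply(p, function(pp) {
    q <- qbccg(pp, model$mu_curve, model$sigma_curve, model$nu_curve) - model$shift
    q
  })
  m <- do.call(cbind, cols)
  trunc_flag <- m < 0 | m > 100
  m <- pmin(pmax(m, 0), 100)
  out <- data.frame(age_years = model$age_grid, m)
  names(out)[-1] <- paste0("p", formatC(100 * p, format = "g"))
  attr(out, "truncated") <- trunc_flag
  out
}

#' Percentile rank of a score given a fitted model
#'
#' The age-conditional percentile of an observed score:
#' \eqn{\Phi(z)} with \eqn{z} the untruncated LMS z-score at the parameters
#' interpolated linearly on the model's age grid.
#'
#' @param model an \code{lms_model}.
#' @param age_years age(s) inside the fitted support.
#' @param score observed score(s), > 0 (after any fitting shift).
#' @param allow_extrapolation evaluate outside the support (clamped) instead
#'   of erroring.
#' @return probabilities in (0, 1).
#' @export
percentile_of <- function(model, age_years, score, allow_extrapolation = FALSE) {
  pa <- .params_at(model, age_years, allow_extrapolation)
  y <- score + model$shift
  if (any(y <= 0)) stop("score must be positive")
  stats::pnorm(zbccg(y, pa$mu, pa$sigma, pa$nu))
}

#' Residual z-scores and fit diagnostics
#'
#' Per-observation LMS z-scores under a fitted model, theoretical-vs-
#' empirical normal quantile pairs for a Q-Q plot, and a binned local-mean
#' residual-by-age curve (20 equal-width age bins).  Under a well-specified
#' model the z-scores are standard normal and the by-age curve hugs zero.
#'
#' @param model an \code{lms_model}.
#' @param data the cohort slice the model was fitted to (or fresh data from
#'   the same stratum).
#' @param n_bins number of age bins for the local-mean curve.
#' @param span \code{lowess} span of the smoothed residual-by-age line.
#' @return a list with \code{z}, \code{qq} (data.frame
#'   \code{theoretical}, \code{empirical}), \code{by_age} (binned means:
#'   data.frame \code{age_mid}, \code{mean_z}, \code{n}) and \code{smooth}
#'   (data.frame \code{age_years}, \code{smooth_z}).
#' @export
residual_zscores <- function(model, data, n_bins = 20, span = 0.6) {
  age <- data$age_years
  z <- stats::qnorm(percentile_of(model, age, data$score,
                                  allow_extrapolation = TRUE))
  ord <- order(z)
  qq <- data.frame(theoretical = stats::qnorm(stats::ppoints(length(z))),
                   empirical = z[ord])
  br <- seq(min(age), max(age), length.out = n_bins + 1)
  bin <- cut(age, br, include.lowest = TRUE)
  by_age <- data.frame(
    age_mid = (br[-1] + br[-(n_bins + 1)]) / 2,
    mean_z = as.numeric(tapply(z, bin, mean)),
    n = as.integer(table(bin)))
  lw <- stats::lowess(age, z, f = span)
  list(z = z, qq = qq, by_age = by_age,
       smooth = data.frame(age_years = lw$x, smooth_z = lw$y))
}

#' Stepwise GAIC selection of smoothing degrees of freedom
#'
#' Starting from the minimal df for every parameter, alternately attempts
#' single-step df increases (forward) and decreases (backward) for the
#' median, scale and power curves in that fixed order, accepting a move only
#' if GAIC improves; equal-GAIC ties are resolved toward the smaller df
#' (parsimony).  Terminates at a local GAIC optimum, deterministically.
#'
#' @param data a cohort slice (one stratum).
#' @param config a \code{\link{fit_config}}; its \code{df_grid} and
#'   \code{gaic_penalty} drive the search.
#' @return the input config with \code{mu_df}, \code{sigma_df}, \code{nu_df}
#'   set to the selected values; the search path is attached as attribute
#'   \code{"selection"}.
#' @export
select_smoothing <- function(data, config = fit_config()) {
  grid <- sort(unique(config$df_grid))
  cur <- config
  cur$mu_df <- min(grid); cur$sigma_df <- min(grid); cur$nu_df <- min(grid)
  fit1 <- function(cfg) fit_lms(data, cfg)$gaic
  best <- fit1(cur)
  path <- data.frame(mu_df = cur$mu_df, sigma_df = cur$sigma_df,
                     nu_df = cur$nu_df, gaic = best)
  pars <- c("mu_df", "sigma_df", "nu_df")
  repeat {
    improved <- FALSE
    for (dir in c(1L, -1L)) {
      for (p in pars) {
        cand_df <- cur[[p]] + dir
        if (!cand_df %in% grid) next
        cand <- cur; cand[[p]] <- cand_df
        g <- fit1(cand)
        accept <- if (dir > 0) g < best - 1e-9 else g <= best + 1e-9
        if (accept) {
          cur <- cand; best <- g; improved <- TRUE
          path <- rbind(path, data.frame(mu_df = cur$mu_df,
                                         sigma_df = cur$sigma_df,
                                         nu_df = cur$nu_df, gaic = best))
        }
      }
    }
    if (!improved) break
  }
  attr(cur, "selection") <- path
  cur
}

#' Read and write LMS curve tables
#'
#' The exchange format for fitted reference curves: commented metadata
#' header lines (\code{# key: value}) followed by a CSV body with columns
#' \code{age_years,L,M,S}.  Tables written here can be re-read and used as a
#' static external reference in cohort comparisons.
#'
#' @param model an \code{lms_model} (or any list with \code{age_grid},
#'   \code{mu_curve}, \code{sigma_curve}, \code{nu_curve}).
#' @param path file path.
#' @return \code{read_lms_table} returns an \code{lms_model}-like object.
#' @export
write_lms_table <- function(model, path) {
  meta <- c(
    sprintf("# level: %s", model$level),
    sprintf("# n_obs: %s", model$n_obs),
    sprintf("# edf: %s", paste(model$edf, collapse = ",")),
    sprintf("# deviance: %.6g", model$deviance),
    sprintf("# gaic: %.6g", model$gaic),
    sprintf("# shift: %s", model$shift))
  body <- data.frame(age_years = model$age_grid, L = model$nu_curve,
                     M = model$mu_curve, S = model$sigma_curve)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(format(body, digits = 8, trim = TRUE), con,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_lms_table
#' @export
read_lms_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- utils::read.csv(text = lines[!grepl("^#", lines)])
  get <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (length(ln)) trimws(sub(paste0("^# ", key, ":"), "", ln[1])) else NA
  }
  structure(list(
    level = get("level"),
    age_grid = body$age_years,
    mu_curve = body$M, sigma_curve = body$S, nu_curve = body$L,
    shift = as.numeric(ifelse(is.na(get("shift")), 0, get("shift"))),
    n_obs = suppressWarnings(as.integer(get("n_obs"))),
    deviance = suppressWarnings(as.numeric(get("deviance"))),
    gaic = suppressWarnings(as.numeric(get("gaic"))),
    edf = suppressWarnings(as.numeric(strsplit(get("edf"), ",")[[1]])),
    age_support = range(body$age_years), converged = NA),
    class = "lms_model")
}
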