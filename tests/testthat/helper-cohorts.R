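# shared fixtures, all built in code

# a noise-free, homogeneous-children configuration: scores sit on the level
# mean curves exactly (up to a 1e-6-scale BCCG wiggle that keeps sigma valid)
noise_free_config <- function(n_children = 300, seed = 1L, nu = 1) {
  cohort_config(n_children = n_children,
                between_child_sd_limit = 0, between_child_sd_lograte = 0,
                residual_sigma = 1e-6, skewness_nu = nu, seed = seed)
}

# one-stratum cohort with independent observations: n children, 1 obs each,
# drawn from a known age-varying BCCG truth
bccg_stratum <- function(n, seed, age_range = c(0.5, 17),
                         mu_fun = function(t) 90 * (1 - exp(-t / 2.3)),
                         sigma_fun = function(t) rep(0.10, length(t)),
                         nu_fun = function(t) rep(1.3, length(t))) {
  set.seed(seed)
  age <- sort(runif(n, age_range[1], age_range[2]))
  y <- rbccg(n, mu = mu_fun(age), sigma = sigma_fun(age), nu = nu_fun(age))
  data.frame(child_id = sprintf("k%05d", seq_len(n)), sex = "female",
             level = "I", age_years = age, score = pmin(pmax(y, 0), 100))
}

# cheap fit settings used where the test exercises plumbing, not accuracy
quick_fit <- function(...) fit_config(mu_df = 3, sigma_df = 1, nu_df = 0, ...)
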