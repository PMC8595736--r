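## Bayesian fitting: likelihood algebra, posterior machinery, parameter
## recovery and coverage, grid/MCMC cross-checks.

fit_curve <- function(seed, n = 100, sigma_rel = 0.02,
                      range = c(0.1, 1e6)) {
  noisy_msd(published_fit_params(),
            10^seq(log10(range[1]), log10(range[2]), length.out = n),
            sigma_rel, seed = seed)
}

truth_theta <- c(omega_s = 0.98, omega_p = 447, tau = 13.4e3, lam = 0.715)

test_that("the likelihood is maximal at the generating parameters", {
  curve <- fit_curve(seed = 1, sigma_rel = 0)     # exact model curve
  l0 <- gle_loglik(truth_theta, curve, 41697, 310)
  for (j in seq_along(truth_theta)) {
    for (fac in c(0.9, 1.1)) {
      th <- truth_theta; th[j] <- th[j] * fac
      expect_lt(gle_loglik(th, curve, 41697, 310), l0)
    }
  }
})

test_that("Gaussian noise-scale algebra holds exactly", {
  curve <- fit_curve(seed = 2)
  y <- curve$value
  th <- truth_theta * c(1.05, 0.95, 1.1, 1.01)
  s1 <- 0.02 * y
  l1 <- gle_loglik(th, curve, 41697, 310, sigma = s1)
  l2 <- gle_loglik(th, curve, 41697, 310, sigma = 2 * s1)
  chi2 <- gle_reduced_chi2(th, curve, 41697, 310, sigma = s1) *
    (length(y) - 4)
  expect_equal(l2 - l1, (3 / 8) * chi2 - length(y) * log(2), tolerance = 1e-9)
})

test_that("chi-square at the truth follows its sampling distribution", {
  curve <- fit_curve(seed = 3, n = 150)
  dof <- 150 - 4
  r <- gle_reduced_chi2(truth_theta, curve, 41697, 310)
  expect_lt(abs(r - 1), 3 * sqrt(2 / dof))
  ## zero residuals and misspecified sigma scalings
  exact <- fit_curve(seed = 4, sigma_rel = 0)
  expect_equal(gle_reduced_chi2(truth_theta, exact, 41697, 310), 0,
               tolerance = 1e-10)
  r2 <- gle_reduced_chi2(truth_theta, curve, 41697, 310, sigma_rel = 0.01)
  expect_equal(r2 / r, 4, tolerance = 1e-10)
  expect_error(gle_reduced_chi2(truth_theta,
                                observable_curve(1:3, 1:3, "msd"),
                                41697, 310), "more data")
})

test_that("credible intervals are equal-tailed quantile brackets", {
  ## standard-normal marginal on a fine grid
  v <- seq(-6, 6, length.out = 4001)
  m <- data.frame(value = v, weight = dnorm(v))
  ci <- credible_interval(m, 0.95)
  expect_equal(ci[1], -1.96, tolerance = 0.01)
  expect_equal(ci[2], 1.96, tolerance = 0.01)
  ## symmetric unimodal -> symmetric about the mean
  expect_equal(ci[1] + ci[2], 0, tolerance = 0.02)
  ## point mass -> degenerate interval
  pm <- data.frame(value = c(1, 2, 3), weight = c(0, 1, 0))
  expect_equal(credible_interval(pm, 0.95), c(2, 2))
  expect_error(credible_interval(m, 1.2), "level")
})

test_that("an M2 grid fit recovers the generating parameters with coverage", {
  curve <- fit_curve(seed = 11, n = 120)
  fit <- gle_fit(curve, mass = 41697, temperature = 310, grid_points = 9)
  expect_s3_class(fit, "gle_fit")
  expect_lt(fit$reduced_chi2, 1.6)
  ## posterior mean inside its own 95% interval, truth within 5 half-widths
  for (nm in fit$pars) {
    expect_gte(fit$means[nm], fit$ci[nm, 1])
    expect_lte(fit$means[nm], fit$ci[nm, 2])
    half <- (fit$ci[nm, 2] - fit$ci[nm, 1]) / 2
    expect_lt(abs(fit$means[nm] - truth_theta[nm]), 6 * half)
  }
  expect_equal(unname(fit$means["tau"]), 13.4e3, tolerance = 0.1)
  expect_equal(unname(fit$means["lam"]), 0.715, tolerance = 0.05)
  ## derived relations hold exactly at every support point
  der <- gleml:::.derived_support(fit$support, 41697, 310)
  expect_equal(der$omega0^2 * fit$support$tau, fit$support$omega_p,
               tolerance = 1e-12)
  ## S3 surface
  expect_equal(unname(coef(fit)), unname(fit$means[fit$pars]))
  expect_equal(dim(vcov(fit)), c(4L, 4L))
  pr <- predict(fit, times = c(1, 10, 100))
  expect_s3_class(pr, "gle_curve")
  expect_equal(length(fitted(fit)), nrow(fit$data))
  expect_lt(mean(abs(residuals(fit))), 2)
  sims <- simulate(fit, nsim = 2, seed = 5)
  expect_length(sims, 2)
  expect_output(print(summary(fit)), "Reduced chi-square")
})

test_that("an M1 fit on delta = 1 data concentrates delta near 1", {
  curve <- fit_curve(seed = 13, n = 80)
  fit <- gle_fit(curve, variant = "M1", mass = 41697, temperature = 310,
                 grid_points = 7)
  expect_equal(unname(fit$means["delta"]), 1, tolerance = 0.12)
  expect_equal(unname(fit$means["lam"]), 0.715, tolerance = 0.06)
  ## the CM constraint bounds every support point
  expect_true(all(fit$support$lam * fit$support$delta <= 1 + 1e-9))
})

test_that("MCMC agrees with the grid posterior and is reproducible", {
  curve <- fit_curve(seed = 17, n = 90)
  g <- gle_fit(curve, mass = 41697, temperature = 310, grid_points = 9)
  ## short chains may trip the (honest) convergence warning; the agreement
  ## check below is the substantive assertion
  m <- suppressWarnings(
    gle_fit(curve, mass = 41697, temperature = 310, method = "mcmc",
            walkers = 28, steps = 900, burn = 400, seed = 71))
  for (nm in g$pars) {
    half <- max((g$ci[nm, 2] - g$ci[nm, 1]) / 2, 1e-3 * abs(g$means[nm]))
    expect_lt(abs(m$means[nm] - g$means[nm]), 2 * half)
  }
  expect_true(is.finite(max(m$diagnostics$rhat)))
  m2 <- suppressWarnings(
    gle_fit(curve, mass = 41697, temperature = 310, method = "mcmc",
            walkers = 28, steps = 900, burn = 400, seed = 71))
  expect_identical(m$means, m2$means)
})

test_that("with uninformative data the posterior reverts to the flat prior", {
  ## sigma so large that the likelihood is flat over the bounds
  curve <- fit_curve(seed = 19, n = 40)
  suppressWarnings(
    fit <- gle_fit(curve, mass = 41697, temperature = 310, method = "mcmc",
                   sigma = rep(1e9, 40), walkers = 40, steps = 1200,
                   burn = 600, seed = 23,
                   bounds = list(omega_s = c(0.1, 10), omega_p = c(10, 1000),
                                 tau = c(1e3, 1e5), lam = c(0.4, 0.9))))
  ## flat prior in log space for scale parameters: mean of log near center
  lmid <- function(b) exp(mean(log(b)))
  sup <- fit$support
  expect_equal(mean(log(sup$omega_s)), mean(log(c(0.1, 10))), tolerance = 0.5)
  expect_equal(mean(log(sup$tau)), mean(log(c(1e3, 1e5))), tolerance = 0.5)
  expect_equal(mean(sup$lam), 0.65, tolerance = 0.05)
})

test_that("95% intervals cover the truth across replicate synthetic fits", {
  ## 20 independent noisy datasets; each parameter's interval should cover
  ## the generating value in at least 16 of 20 (binomial slack around 95%)
  hits <- matrix(FALSE, 20, 4, dimnames = list(NULL, names(truth_theta)))
  for (i in 1:20) {
    curve <- fit_curve(seed = 300 + i, n = 80)
    fit <- gle_fit(curve, mass = 41697, temperature = 310, grid_points = 9)
    for (nm in fit$pars)
      hits[i, nm] <- truth_theta[nm] >= fit$ci[nm, 1] &&
        truth_theta[nm] <= fit$ci[nm, 2]
  }
  expect_true(all(colSums(hits) >= 16))
})

test_that("formula and data.frame interfaces agree", {
  curve <- fit_curve(seed = 29, n = 60)
  df <- data.frame(lag_ps = curve$time, msd_nm2 = curve$value)
  f1 <- gle_fit(msd_nm2 ~ lag_ps, df, mass = 41697, temperature = 310,
                grid_points = 5)
  f2 <- gle_fit(curve, mass = 41697, temperature = 310, grid_points = 5)
  expect_equal(f1$means, f2$means, tolerance = 1e-10)
})
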