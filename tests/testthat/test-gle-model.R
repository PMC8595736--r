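## The GLE model: kernel transform, relaxation functions, observables via
## ILT, asymptotic laws, derived parameters and internal consistency.

test_that("kernel transform limits and closed-form values hold", {
  p <- published_fit_params()
  xs <- p$mass * p$omega_s
  xp <- p$mass * p$omega_p
  ## viscous-only kernel is constant in s
  p0 <- gle_params(mass = p$mass, temperature = 310, omega_s = 0.98,
                   omega_p = 0, tau = p$tau, lam = 0.715)
  s <- 10^seq(-5, 3, length.out = 9)
  expect_equal(zeta_hat(s, p0), rep(xs, length(s)))
  ## Brownian constraint: total friction at s -> 0, viscous part at s -> inf
  expect_equal(zeta_hat(1e-14, p), xs + xp, tolerance = 1e-6)
  expect_equal(zeta_hat(1e12, p), xs, tolerance = 1e-6)
  ## at s = 1/tau the elastic term is exactly xi_p / 2^delta
  expect_equal(zeta_hat(1 / p$tau, p), xs + xp / 2, tolerance = 1e-14)
  ## arbitrary delta variant of the same identity
  p2 <- gle_params(mass = p$mass, temperature = 310, omega_s = 0.98,
                   omega_p = 447, tau = p$tau, lam = 0.5, delta = 1.6)
  expect_equal(zeta_hat(1 / p2$tau, p2), xs + xp / 2^1.6, tolerance = 1e-14)
})

test_that("relaxation functions obey their defining identities", {
  p <- published_fit_params()
  set.seed(3)
  s <- complex(real = 10^runif(20, -4, 2), imaginary = runif(20, -5, 5))
  h <- relaxation_hats(s, p)
  expect_equal(s * h$I_hat, h$H_hat, tolerance = 1e-13)
  expect_equal(s * h$H_hat, h$g_hat, tolerance = 1e-13)
  expect_equal(h$g_hat, 1 / (p$mass * s + zeta_hat(s, p)), tolerance = 1e-13)
  ## closed-form value at s = omega_s
  gs <- relaxation_hats(p$omega_s, p)$g_hat
  ref <- 1 / (p$mass * p$omega_s + p$mass * p$omega_s +
                p$mass * p$omega_p / (1 + (p$tau * p$omega_s)^p$lam))
  expect_equal(gs, ref, tolerance = 1e-14)
  ## pure viscous kernel: the Langevin resolvent
  p0 <- gle_params(mass = 100, temperature = 300, omega_s = 1.5, omega_p = 0,
                   tau = 10, lam = 0.7)
  expect_equal(relaxation_hats(2, p0)$g_hat, 1 / (100 * 2 + 150))
})

test_that("the Langevin limit inverts to the exponential VACF", {
  p0 <- gle_params(mass = 41697, temperature = 310, omega_s = 0.98,
                   omega_p = 0, tau = 13.4e3, lam = 0.715)
  t <- 10^seq(-2, 0.7, length.out = 25)
  cv <- gle_observable(p0, t, "vacf")$value
  ref <- 2 * 0.00831446 * 310 / 41697 * exp(-0.98 * t)
  expect_lt(max(abs(cv / ref - 1)), 1e-6)
})

test_that("a frozen elastic term produces the harmonic confinement plateau", {
  p <- published_fit_params(kernel = "harmonic")
  omega0_sq <- p$omega_p / p$tau
  plateau <- 2 * 2 * 0.00831446 * 310 / (41697 * omega0_sq)
  msd <- gle_observable(p, c(5e3, 5e4, 5e5), "msd")$value
  expect_equal(msd, rep(plateau, 3), tolerance = 1e-6)
})

test_that("MSD by the second inversion method confirms the default", {
  p <- published_fit_params()
  v1 <- gle_observable(p, 1e4, "msd", method = "talbot")$value
  v2 <- gle_observable(p, 1e4, "msd", method = "dehoog")$value
  expect_lt(abs(v1 / v2 - 1), 1e-6)
})

test_that("MSD is nonnegative, nondecreasing and thermalized at the origin", {
  p <- published_fit_params()
  t <- 10^seq(-2, 6, length.out = 50)
  msd <- gle_observable(p, t, "msd")$value
  expect_true(all(msd >= 0))
  expect_true(all(diff(msd) > 0))
  ## Cv(0+) = 2 kBT / M within 0.1% for CM parameter sets
  for (pp in list(p, fast_params(), fast_params(omega_p = 5, lam = 0.5))) {
    cv0 <- gle_observable(pp, 1e-4 / pp$omega_s, "vacf")$value
    expect_equal(cv0, 2 * 0.00831446 * pp$temperature / pp$mass,
                 tolerance = 1e-3)
  }
})

test_that("short-time expansions agree with the inverted observables", {
  p <- published_fit_params()
  t <- 0.01 / p$omega_s
  for (kind in c("vacf", "dcoef", "msd")) {
    full <- gle_observable(p, t, kind)$value
    expect_lt(abs(full / gle_short_time(p, t, kind) - 1), 0.01)
  }
  ## ballistic MSD limit: MSD / t^2 -> 2 kBT / M (d = 2)
  tt <- 1e-3
  expect_equal(gle_observable(p, tt, "msd")$value / tt^2,
               2 * 0.00831446 * 310 / 41697, tolerance = 1e-3)
  ## frozen arithmetic check of the VACF expansion at t = 0.1 ps
  expect_equal(gle_short_time(p, 0.1, "vacf"),
               2 * 0.00831446 * 310 / 41697 * (1 - 0.098))
})

test_that("long-time laws: D_inf, Brownian MSD slope, negative VACF tail", {
  p <- published_fit_params()
  ## D(t) -> D_inf
  Dinf_int <- 0.00831446 * 310 / (41697 * (0.98 + 447))
  Dt <- gle_observable(p, c(5e6, 2e7), "dcoef")$value
  expect_lt(max(abs(Dt / Dinf_int - 1)), 0.01)
  ## VACF tail: negative, exponent -1-lam, ILT/asymptote ratio -> 1
  t <- 10^seq(log10(1e4), log10(2e5), length.out = 25)
  cv <- gle_observable(p, t, "vacf", accuracy_goal = 1e-6)$value
  expect_true(all(cv < 0))
  fit <- stats::lm(log(-cv) ~ log(t))
  expect_equal(unname(-stats::coef(fit)[2] - 1), 0.715, tolerance = 0.03)
  ratio <- cv / gle_long_time(p, t, "vacf")
  expect_lt(abs(ratio[length(ratio)] - 1), 0.05)   # t ~ 15 tau
  r100 <- gle_observable(p, 100 * p$tau, "vacf", accuracy_goal = 1e-6)$value /
    gle_long_time(p, 100 * p$tau, "vacf")
  expect_lt(abs(r100 - 1), 0.05)
  ## Brownian MSD line uses the exact total friction
  msd <- gle_observable(p, 5e6, "msd")$value
  expect_equal(msd, gle_long_time(p, 5e6, "msd"), tolerance = 0.02)
  expect_error(gle_long_time(gle_params(mass = 100, temperature = 300,
                                        omega_s = 1, omega_p = 10, tau = 10,
                                        lam = 0.5, nu = 0.7), 1, "vacf"),
               "Brownian constraint")
})

test_that("d_infinity reproduces the published value and its scalings", {
  p <- published_fit_params()
  expect_equal(d_infinity(p), 0.137, tolerance = 0.01)
  p0 <- gle_params(mass = 41697, temperature = 310, omega_s = 0.98,
                   omega_p = 0, tau = 13.4e3, lam = 0.715)
  expect_equal(d_infinity(p0),
               0.00831446 * 310 / (41697 * 0.98) * 1e6, tolerance = 1e-12)
  p2 <- gle_params(mass = 2 * 41697, temperature = 310, omega_s = 0.98,
                   omega_p = 447, tau = 13.4e3, lam = 0.715)
  expect_equal(d_infinity(p2), d_infinity(p) / 2, tolerance = 1e-12)
})

test_that("derived parameters match the published best-fit table", {
  dp <- derive_parameters(published_fit_params())
  val <- function(q) dp$value[dp$quantity == q]
  expect_equal(val("omega0"), 0.183, tolerance = 0.015)
  expect_equal(val("xi_s"), 0.067e-3, tolerance = 0.015)
  expect_equal(val("xi_p"), 0.0309, tolerance = 0.015)
  expect_equal(val("D_inf"), 0.137, tolerance = 0.015)
  expect_equal(val("tau_s"), 1 / 0.98)
  expect_equal(val("phi"), 447 / 0.98)
})

test_that("kinematic and Green-Kubo consistency tie the observables together", {
  p <- fast_params()
  t <- 10^seq(-2, 3.5, length.out = 120)
  msd <- gle_observable(p, t, "msd")$value
  Dt <- gle_observable(p, t, "dcoef")$value
  ## D(t) = (1/2d) dMSD/dt on the log grid
  lt <- log(t)
  dmsd <- exp(stats::splinefun(lt, log(msd))(lt, deriv = 0)) *
    stats::splinefun(lt, log(msd))(lt, deriv = 1) / t
  i <- 10:110
  expect_lt(max(abs(dmsd[i] / 4 - Dt[i]) / Dt[i]), 0.005)
  ## Green-Kubo: int_0^t Cv/2 = D(t) (d = 2), trapezoid + ballistic head
  tg <- 10^seq(-4, 3.5, length.out = 400)
  cvg <- gle_observable(p, tg, "vacf")$value
  kT <- 0.00831446 * p$temperature
  head <- kT / p$mass * tg[1] * (1 - p$omega_s * tg[1] / 2)
  D_gk <- head + cumsum(c(0, diff(tg) * (cvg[-1] + cvg[-length(tg)]) / 4))
  for (tt in c(1, 30, 1000)) {
    j <- which.min(abs(tg - tt))
    expect_equal(D_gk[j], gle_observable(p, tg[j], "dcoef")$value,
                 tolerance = 0.01)
  }
})

test_that("the exponential-kernel variant recovers the transient-cage law", {
  pe <- gle_params(mass = 100, temperature = 300, omega_s = 2, omega_p = 20,
                   tau = 50, lam = 1, nu = 1, kernel = "exponential")
  ## long-time diffusion coefficient kBT / [M (omega_s + omega_0^2 tau)]
  Dt <- gle_observable(pe, 5e4, "dcoef")$value
  omega0_sq <- pe$omega_p / pe$tau
  expect_equal(Dt, 0.00831446 * 300 / (100 * (2 + omega0_sq * 50)),
               tolerance = 0.01)
  expect_equal(d_infinity(pe),
               0.00831446 * 300 / (100 * (2 + omega0_sq * 50)) * 1e6,
               tolerance = 1e-12)
})

test_that("Brownian dynamics is recovered only at lags of hundreds of ns", {
  ## the time-dependent diffusion coefficient overshoots D_inf after the
  ## ballistic rise and settles from above through the subdiffusive window
  p <- published_fit_params()
  Dinf <- 0.00831446 * 310 / (41697 * (0.98 + 447))
  r <- gle_observable(p, c(1e4, 4e5, 4e6), "dcoef")$value / Dinf
  expect_gt(abs(r[1] - 1), 0.1)     # 10 ns: still far from Brownian
  expect_lt(abs(r[2] - 1), 0.05)    # ~400 ns: recovered within 5%
  expect_lt(abs(r[3] - 1), 0.01)
  ## the local MSD exponent dips well below 1 and returns to 1
  t <- 10^seq(-2, 6.6, length.out = 200)
  msd <- gle_observable(p, t, "msd")
  al <- local_exponent(msd)
  i_early <- which.min(abs(al$time - 1e-1))
  i_mid <- which.min(abs(al$time - 1e3))
  i_late <- which.min(abs(al$time - 3e6))
  expect_gt(al$value[i_early], 1.7)               # near-ballistic
  expect_lt(al$value[i_mid], 0.75)                # subdiffusive dip
  expect_equal(al$value[i_late], 1, tolerance = 0.05)
})

test_that("parameter validation rejects unphysical inputs", {
  expect_error(gle_params(mass = -1, temperature = 310, omega_s = 1,
                          omega_p = 1, tau = 1, lam = 0.7), "positive")
  expect_error(gle_params(mass = 1, temperature = 310, omega_s = 1,
                          omega_p = 1, tau = 1, lam = 0.7, dim = 4), "dim")
  expect_error(observable_curve(c(1, 1), c(1, 2)), "strictly increasing")
  expect_error(observable_curve(c(1, 2), c(-1, 2), "msd"), "non-negative")
})
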