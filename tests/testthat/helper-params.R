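## Shared fixtures: the published best-fit parameter set of the M2 receptor
## in the mixed membrane (mass and temperature fixed, frequencies and kernel
## exponents from the fit), and a small fast parameter set with the same
## structure for simulation-based tests.

published_fit_params <- function(kernel = "prabhakar") {
  gle_params(mass = 41697, temperature = 310, omega_s = 0.98, omega_p = 447,
             tau = 13.4e3, lam = 0.715, delta = 1, kernel = kernel)
}

## same physics, timescales compressed so that trajectories reach the
## Brownian regime within a short simulation
fast_params <- function(omega_p = 20, tau = 50, lam = 0.715) {
  gle_params(mass = 100, temperature = 300, omega_s = 2, omega_p = omega_p,
             tau = tau, lam = lam)
}

## random draw inside the completely monotone region (away from the lam -> 1
## boundary, where the rate spectrum degenerates towards a point mass)
draw_cm <- function() {
  lam <- runif(1, 0.4, 0.95)
  delta <- runif(1, 0.3, min(1 / lam, 1.5))
  nu <- runif(1, lam * delta, 1)
  list(lam = lam, nu = nu, delta = delta, tau = 10^runif(1, -1, 4))
}

## independent small-x series for the Prabhakar function: plain term-by-term
## summation in reverse order (no log-space tricks), adequate for x <= 3
ml3_series_ref <- function(x, lam, nu, delta, kmax = 250) {
  k <- 0:kmax
  terms <- exp(lgamma(delta + k) - lgamma(delta) - lgamma(k + 1) +
                 k * log(x)) * (-1)^k / gamma(lam * k + nu)
  sum(rev(terms))
}
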