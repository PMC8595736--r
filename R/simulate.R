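## Synthetic-data generation: GLE trajectories via a Markovian embedding of
## the kernel's relaxation-rate spectrum, noisy model MSD curves, and plain
## 2D Brownian reference trajectories.

#' Exponential-mode approximation of the elastic kernel
#'
#' Discretizes the relaxation-rate spectrum \eqn{p(f)} on log-spaced nodes so
#' that \eqn{\sum_k c_k e^{-f_k t} \approx \omega_0^2\,
#' e_{\lambda,\nu}^\delta(t/\tau)} on a target time window; the weights are
#' the spectral mass of each log-bin (8-point Gauss-Legendre per bin) times
#' \eqn{\omega_0^2}.  In the completely monotone region all weights are
#' non-negative.  The approximation is verified on the window and an error is
#' raised (suggesting a larger `K`) if the 1% contract cannot be met.
#'
#' @param p a [gle_params()] object (completely monotone, `prabhakar` or
#'   `exponential` kernel).
#' @param K number of modes (>= 4).
#' @param window c(t_min, t_max) target window (ps).
#' @param tol relative accuracy contract on the window (default 0.01).
#' @return object of class `"gle_modes"`: list with rates `f` (ps^-1),
#'   weights `c` (ps^-2), `K`, `window`, `max_rel_error`.
#' @export
kernel_modes <- function(p, K = 48L, window = c(0.1, 1e7), tol = 0.01) {
  stopifnot(inherits(p, "gle_params"))
  if (K < 4L && p$kernel == "prabhakar") stop("K must be at least 4")
  omega0_sq <- p$omega_p / p$tau
  if (p$kernel == "exponential") {
    modes <- list(f = 1 / p$tau, c = omega0_sq, K = 1L, window = window,
                  max_rel_error = 0)
    class(modes) <- "gle_modes"
    return(modes)
  }
  if (!cm_region(p$lam, p$nu, p$delta))
    stop("kernel_modes requires completely monotone parameters")
  ## node range: reciprocal of the window, padded so that truncated spectral
  ## mass is negligible at both ends
  lo <- log(0.01 / window[2])
  hi <- log(35 / window[1])
  nb <- max(2L, K %/% 2L)
  edges <- seq(lo, hi, length.out = nb + 1L)
  ## 16-point Gauss-Legendre rule for the within-bin spectral moments
  gx <- c(-0.9894009349, -0.9445750231, -0.8656312024, -0.7554044084,
          -0.6178762444, -0.4580167776, -0.2816035507, -0.0950125098)
  gx <- c(gx, rev(-gx))
  gw <- c(0.0271524594, 0.0622535239, 0.0951585117, 0.1246289713,
          0.1495959888, 0.1691565194, 0.1826034150, 0.1894506105)
  gw <- c(gw, rev(gw))
  f <- numeric(0); cc <- numeric(0)
  ## per log-bin, a two-point Gaussian rule with respect to the spectral
  ## weight p(f): nodes from the centered (cancellation-free) moments
  for (k in seq_len(nb)) {
    a <- edges[k]; b <- edges[k + 1L]
    u <- (a + b) / 2 + (b - a) / 2 * gx
    w <- (b - a) / 2 * gw
    fk <- exp(u)
    pw <- rate_spectrum(fk, p$lam, p$nu, p$delta, p$tau, check_cm = FALSE) *
      fk * w                               # p(f) df mass elements
    m0 <- sum(pw)
    if (m0 <= 0) next
    ctr <- sum(pw * fk) / m0
    mu2 <- sum(pw * (fk - ctr)^2)
    mu3 <- sum(pw * (fk - ctr)^3)
    if (mu2 <= 0) { f <- c(f, ctr); cc <- c(cc, m0); next }
    B <- mu3 / mu2; C <- mu2 / m0
    rt <- sqrt(B^2 / 4 + C)
    x1 <- B / 2 - rt; x2 <- B / 2 + rt
    w1 <- m0 * x2 / (x2 - x1); w2 <- -m0 * x1 / (x2 - x1)
    f <- c(f, ctr + x1, ctr + x2)
    cc <- c(cc, w1, w2)
  }
  keep <- cc > 0 & f > 0
  f <- f[keep]; cc <- omega0_sq * cc[keep]
  ## refine the weights by non-negative least squares on the relative error
  ## over a dense log grid of the window (coordinate descent; keeps all
  ## weights >= 0, preserving the fluctuation-dissipation structure)
  tfit <- 10^seq(log10(window[1]), log10(window[2]), length.out = 240)
  gfit <- omega0_sq * ml_kernel(tfit, p$lam, p$nu, p$delta, p$tau)
  A <- exp(-outer(tfit, f)) / gfit
  b <- rep(1, length(tfit))
  nrm <- colSums(A^2)
  ## modes faster than the window barely project onto it: freeze them at
  ## their quadrature weights (they represent genuine short-time spectral
  ## mass) and refine only the identifiable columns
  adj <- which(nrm > 1e-8 * max(nrm))
  r <- b - as.numeric(A %*% cc)
  for (sw in seq_len(400L)) {
    for (k in adj) {
      ck <- max(0, cc[k] + sum(A[, k] * r) / nrm[k])
      if (ck != cc[k]) { r <- r - A[, k] * (ck - cc[k]); cc[k] <- ck }
    }
  }
  keep <- cc > 0
  f <- f[keep]; cc <- cc[keep]
  ## verify the contract on a log grid offset from the fitting grid
  tt <- 10^seq(log10(window[1]), log10(window[2]), length.out = 413)
  target <- omega0_sq * ml_kernel(tt, p$lam, p$nu, p$delta, p$tau)
  approxv <- as.numeric(exp(-outer(tt, f)) %*% cc)
  err <- max(abs(approxv / target - 1))
  if (err > tol)
    stop(sprintf(
      "mode approximation reaches %.2g > %.2g on the window; increase K",
      err, tol))
  structure(list(f = f, c = cc, K = length(f), window = window,
                 max_rel_error = err),
            class = "gle_modes")
}

#' @export
print.gle_modes <- function(x, ...) {
  cat(sprintf("<gle_modes> %d modes, rates in [%.3g, %.3g] ps^-1, max rel err %.2g\n",
              x$K, min(x$f), max(x$f), x$max_rel_error))
  invisible(x)
}

#' Simulate GLE trajectories by Markovian embedding
#'
#' Integrates the extended Markovian system equivalent (mode by mode) to the
#' GLE with kernel \eqn{\zeta(t) = \xi_s\delta(t) + M\sum_k c_k e^{-f_k t}}:
#' each exponential mode becomes an auxiliary Ornstein-Uhlenbeck force
#' variable \eqn{dz_k = -f_k z_k\,dt - M c_k v\,dt + \sqrt{2k_BT M c_k f_k}\,
#' dW_k}, and the velocity feels the instantaneous drag \eqn{\omega_s} with
#' white noise of matching strength, so the fluctuation-dissipation theorem
#' holds per mode and the stationary velocity variance is \eqn{k_BT/M} per
#' component.  The integrator alternates half-step position/force updates
#' with exact OU updates of velocity drag and auxiliary variables.
#'
#' @param p a [gle_params()] object.
#' @param modes a [kernel_modes()] result (or `NULL` for pure Langevin
#'   dynamics, \eqn{\omega_p = 0}).
#' @param dt time step (ps); must satisfy `dt * max(omega_s, f_max) <= 0.1`.
#' @param n_steps number of steps.
#' @param seed RNG seed (integer); set for reproducibility.
#' @param n_traj number of independent trajectories (integrated together,
#'   vectorized across the ensemble).
#' @param keep_velocities return velocities as well.
#' @return a list of `n_traj` [trajectory2d()] objects (velocities, if kept,
#'   in attribute `"velocities"`).
#' @export
simulate_gle <- function(p, modes = NULL, dt, n_steps, seed = NULL,
                         n_traj = 1L, keep_velocities = FALSE) {
  stopifnot(inherits(p, "gle_params"))
  if (!is.null(seed)) set.seed(seed)
  kT <- kBT(p$temperature)
  M <- p$mass
  f <- if (is.null(modes)) numeric(0) else modes$f
  cc <- if (is.null(modes)) numeric(0) else modes$c
  K <- length(f)
  if (dt * max(p$omega_s, f, 0) > 0.1)
    stop("dt too large: dt * max(omega_s, f_max) must be <= 0.1")
  nw <- 2L * n_traj                       # x and y components share the code
  ## exact OU factors
  Ev <- exp(-p$omega_s * dt)
  Sv <- sqrt(kT / M * (1 - Ev^2))
  Ez <- exp(-f * dt)
  theta <- (1 - Ez) / f                   # integrated coupling over dt
  Sz <- sqrt(kT * M * cc * (1 - Ez^2))
  v <- matrix(stats::rnorm(nw, sd = sqrt(kT / M)), 1L, nw)
  z <- matrix(stats::rnorm(K * nw, sd = sqrt(kT * M * cc)), K, nw)
  x <- matrix(0, n_steps + 1L, nw)
  vel <- if (keep_velocities) matrix(0, n_steps + 1L, nw) else NULL
  if (keep_velocities) vel[1L, ] <- v
  cs <- colSums
  for (i in seq_len(n_steps)) {
    xi <- x[i, ] + 0.5 * dt * v
    if (K) v <- v + (0.5 * dt / M) * cs(z)
    ## exact OU: velocity drag + white noise, then auxiliary variables
    v <- Ev * v + Sv * stats::rnorm(nw)
    if (K)
      z <- Ez * z - (M * cc * theta) %o% as.numeric(v) +
        Sz * matrix(stats::rnorm(K * nw), K, nw)
    if (K) v <- v + (0.5 * dt / M) * cs(z)
    x[i + 1L, ] <- xi + 0.5 * dt * v
    if (keep_velocities) vel[i + 1L, ] <- v
  }
  times <- dt * (0:n_steps)
  lapply(seq_len(n_traj), function(j) {
    tr <- trajectory2d(times, x[, 2L * j - 1L], x[, 2L * j], mass = M,
                       label = sprintf("gle sim %d", j))
    if (keep_velocities)
      attr(tr, "velocities") <- vel[, c(2L * j - 1L, 2L * j)]
    tr
  })
}

#' Noisy model MSD curves
#'
#' The analytic model MSD evaluated at the requested lags, multiplied by
#' independent \eqn{1 + \sigma_{rel} z_i} factors (standard normal
#' \eqn{z_i}), clipped positive — the synthetic input for fitting exercises.
#'
#' @param p a [gle_params()] object.
#' @param lags positive sorted lags (ps).
#' @param sigma_rel relative noise level (>= 0), e.g. 0.02.
#' @param seed RNG seed.
#' @return an MSD [observable_curve()] with attribute `sigma_rel`.
#' @export
noisy_msd <- function(p, lags, sigma_rel = 0.02, seed = NULL) {
  if (sigma_rel < 0) stop("sigma_rel must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  base <- gle_observable(p, lags, "msd")$value
  v <- base * (1 + sigma_rel * stats::rnorm(length(lags)))
  v <- pmax(v, 1e-12 * base)
  out <- observable_curve(lags, v, "msd")
  attr(out, "sigma_rel") <- sigma_rel
  out
}

#' 2D Brownian reference trajectory
#'
#' Cumulative sum of i.i.d. Gaussian steps with per-axis variance
#' \eqn{2 D_0 dt} — the Gaussian null model for the displacement-distribution
#' diagnostic.
#'
#' @param D0 diffusion coefficient (nm^2/ps).
#' @param dt time step (ps).
#' @param n_steps number of steps.
#' @param seed RNG seed.
#' @return a [trajectory2d()].
#' @export
brownian2d <- function(D0, dt, n_steps, seed = NULL) {
  if (D0 <= 0 || dt <= 0) stop("D0 and dt must be positive")
  if (!is.null(seed)) set.seed(seed)
  sd <- sqrt(2 * D0 * dt)
  x <- c(0, cumsum(stats::rnorm(n_steps, sd = sd)))
  y <- c(0, cumsum(stats::rnorm(n_steps, sd = sd)))
  trajectory2d(dt * (0:n_steps), x, y, label = "brownian2d")
}
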