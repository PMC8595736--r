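## The GLE model: memory kernel in the Laplace domain, relaxation functions,
## time-domain observables by numerical inversion, asymptotic laws, and the
## derived physical parameters in laboratory units.

#' Parameters of the membrane-protein GLE
#'
#' Bundles the physical parameters of a generalized Langevin equation whose
#' memory kernel is a Dirac-delta viscous term plus a three-parameter
#' Mittag-Leffler (Prabhakar) elastic term,
#' \deqn{\zeta(t) = M[\omega_s^2 \delta(t/\tau_s) + \omega_0^2
#'       (t/\tau)^{\nu-1} E_{\lambda,\nu}^\delta(-(t/\tau)^\lambda)],}
#' parameterized by the frequencies \eqn{\omega_s} (inverse ballistic
#' timescale) and \eqn{\omega_p = \omega_0^2\tau}, the elastic timescale
#' \eqn{\tau}, and the Prabhakar exponents.  When `nu` is omitted it is set
#' to `lam * delta`, the constraint under which the long-time dynamics is
#' Brownian with a finite diffusion coefficient.
#'
#' @param mass particle mass M (g/mol).
#' @param temperature temperature (K).
#' @param omega_s viscous (instantaneous) kernel frequency (ps^-1).
#' @param omega_p elastic friction frequency \eqn{\omega_p=\omega_0^2\tau} (ps^-1).
#' @param tau elastic relaxation timescale (ps).
#' @param lam,delta Prabhakar exponents.
#' @param nu Prabhakar exponent; defaults to `lam * delta` (Brownian constraint).
#' @param dim spatial dimension d, 1, 2 (lateral diffusion, default) or 3.
#' @param kernel elastic kernel shape: `"prabhakar"` (the model),
#'   `"exponential"` (transient harmonic confinement with escape time `tau`),
#'   or `"harmonic"` (permanent confinement, the elastic term frozen at its
#'   t=0 plateau).
#' @return an object of class `"gle_params"`.
#' @examples
#' p <- gle_params(mass = 41697, temperature = 310, omega_s = 0.98,
#'                 omega_p = 447, tau = 13.4e3, lam = 0.715)
#' d_infinity(p)   # um^2/s
#' @export
gle_params <- function(mass, temperature, omega_s, omega_p, tau, lam,
                       delta = 1, nu = lam * delta, dim = 2,
                       kernel = c("prabhakar", "exponential", "harmonic")) {
  kernel <- match.arg(kernel)
  vals <- c(mass = mass, temperature = temperature, omega_s = omega_s,
            omega_p = omega_p, tau = tau, lam = lam, delta = delta, nu = nu)
  if (any(!is.finite(vals)) || any(vals[setdiff(names(vals), "omega_p")] <= 0) ||
      omega_p < 0)
    stop("all GLE parameters must be positive (omega_p may be zero)")
  if (!dim %in% 1:3) stop("dim must be 1, 2 or 3")
  p <- list(mass = mass, temperature = temperature, omega_s = omega_s,
            omega_p = omega_p, tau = tau, lam = lam, nu = nu, delta = delta,
            dim = dim, kernel = kernel)
  class(p) <- "gle_params"
  p
}

#' @export
print.gle_params <- function(x, ...) {
  cat("GLE parameters (", x$kernel, " elastic kernel, d = ", x$dim, ")\n", sep = "")
  cat(sprintf("  M = %g g/mol, T = %g K\n", x$mass, x$temperature))
  cat(sprintf("  omega_s = %g ps^-1, omega_p = %g ps^-1, tau = %g ps\n",
              x$omega_s, x$omega_p, x$tau))
  cat(sprintf("  lam = %g, nu = %g, delta = %g (CM: %s, Brownian constraint: %s)\n",
              x$lam, x$nu, x$delta,
              cm_region(x$lam, x$nu, x$delta),
              abs(x$delta * x$lam - x$nu) < 1e-12))
  invisible(x)
}

#' Laplace transform of the memory kernel
#'
#' \deqn{\hat\zeta(s) = \xi_s + \xi_p (\tau s)^{\delta\lambda-\nu} /
#'       (1+(\tau s)^\lambda)^\delta,} with \eqn{\xi_s = M\omega_s},
#' \eqn{\xi_p = M\omega_p}, in internal units (g/mol ps^-1).  Accepts real
#' `s > 0` or complex `s` with `Re(s) > 0` (and, on the deformed inversion
#' contour, principal-branch powers off the negative real axis).
#'
#' @param s Laplace variable (ps^-1), real positive or complex.
#' @param p a [gle_params()] object.
#' @export
zeta_hat <- function(s, p) {
  xs <- p$mass * p$omega_s
  xp <- p$mass * p$omega_p
  switch(p$kernel,
    prabhakar = {
      ts <- p$tau * s
      xs + xp * ts^(p$delta * p$lam - p$nu) / (1 + ts^p$lam)^p$delta
    },
    exponential = xs + xp / (1 + p$tau * s),
    harmonic = xs + xp / (p$tau * s))
}

#' Laplace-domain relaxation functions
#'
#' Returns \eqn{\hat g(s) = 1/(M s + \hat\zeta(s))}, \eqn{\hat H = \hat g/s}
#' and \eqn{\hat I = \hat g/s^2}; the velocity autocorrelation, the
#' time-dependent diffusion coefficient and the MSD are \eqn{2k_BT g},
#' \eqn{k_BT H} and \eqn{2 d\, k_BT I} respectively.  `H_hat` and `I_hat`
#' deliberately exclude the \eqn{k_BT} factor.
#'
#' @inheritParams zeta_hat
#' @return list with complex (or numeric) components `g_hat`, `H_hat`, `I_hat`.
#' @export
relaxation_hats <- function(s, p) {
  g <- 1 / (p$mass * s + zeta_hat(s, p))
  list(g_hat = g, H_hat = g / s, I_hat = g / s^2)
}

.observable_kinds <- c(msd = "nm^2", vacf = "nm^2/ps^2", dcoef = "nm^2/ps",
                       alpha = "1")

#' Construct a sampled observable curve
#'
#' A light container for a time-domain observable: MSD (nm^2), VACF
#' (nm^2/ps^2), time-dependent diffusion coefficient (nm^2/ps) or local MSD
#' exponent (dimensionless), sampled on strictly increasing lags in ps.
#'
#' @param times strictly increasing lags (ps).
#' @param values observable samples.
#' @param kind one of `"msd"`, `"vacf"`, `"dcoef"`, `"alpha"`.
#' @return data.frame of class `"gle_curve"` with columns `time`, `value` and
#'   attributes `kind` and `units`.
#' @export
observable_curve <- function(times, values, kind = "msd") {
  kind <- match.arg(kind, names(.observable_kinds))
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (any(!is.finite(times)) || is.unsorted(times, strictly = TRUE))
    stop("times must be finite and strictly increasing")
  if (kind == "msd" && any(values < 0)) stop("MSD values must be non-negative")
  structure(data.frame(time = times, value = values),
            kind = kind, units = c(time = "ps", value = .observable_kinds[[kind]]),
            class = c("gle_curve", "data.frame"))
}

#' @export
print.gle_curve <- function(x, ...) {
  cat(sprintf("<gle_curve> %s [%s], %d lags in [%g, %g] ps\n",
              attr(x, "kind"), attr(x, "units")[["value"]], nrow(x),
              min(x$time), max(x$time)))
  invisible(x)
}

#' Model observables by numerical Laplace inversion
#'
#' Evaluates the GLE model's mean-square displacement
#' \eqn{2 d\, k_BT\, I(t)}, velocity autocorrelation \eqn{2 k_BT\, g(t)} or
#' time-dependent diffusion coefficient \eqn{k_BT\, H(t)} at the requested
#' lags by numerically inverting the corresponding Laplace-domain relaxation
#' function.
#'
#' @param p a [gle_params()] object.
#' @param times positive sorted lags (ps).
#' @param kind `"msd"`, `"vacf"` or `"dcoef"`.
#' @param method,accuracy_goal passed to [laplace_invert()].
#' @return a [observable_curve()] in internal units (nm, ps).
#' @export
gle_observable <- function(p, times, kind = c("msd", "vacf", "dcoef"),
                           method = "talbot", accuracy_goal = 1e-8) {
  kind <- match.arg(kind)
  stopifnot(inherits(p, "gle_params"))
  kT <- kBT(p$temperature)
  F <- switch(kind,
    msd  = function(s) 2 * p$dim * kT / (p$mass * s + zeta_hat(s, p)) / s^2,
    vacf = function(s) 2 * kT / (p$mass * s + zeta_hat(s, p)),
    dcoef = function(s) kT / (p$mass * s + zeta_hat(s, p)) / s)
  v <- laplace_invert(F, times, method = method, accuracy_goal = accuracy_goal)
  if (kind == "msd") v <- pmax(as.numeric(v), 0)
  observable_curve(times, as.numeric(v), kind)
}

#' Short-time (ballistic regime) expansions
#'
#' Leading behavior for \eqn{t \ll 1/\omega_s}:
#' \eqn{C_v \approx (2k_BT/M)(1-\omega_s t)},
#' \eqn{D \approx (k_BT/M)(1-\omega_s t/2)\,t},
#' \eqn{MSD \approx (d\,k_BT/M)(1-\omega_s t/3)\,t^2} (d = 2 gives the
#' conventional \eqn{2k_BT/M\,t^2} ballistic law).
#'
#' @inheritParams gle_observable
#' @param t lags (ps).
#' @return numeric vector in internal units.
#' @export
gle_short_time <- function(p, t, kind = c("msd", "vacf", "dcoef")) {
  kind <- match.arg(kind)
  kT <- kBT(p$temperature)
  w <- p$omega_s
  switch(kind,
    vacf = 2 * kT / p$mass * (1 - w * t),
    dcoef = kT / p$mass * (1 - w * t / 2) * t,
    msd  = p$dim * kT / p$mass * (1 - w * t / 3) * t^2)
}

#' Long-time (Brownian regime) asymptotics
#'
#' Under the Brownian constraint \eqn{\delta\lambda = \nu} (and
#' \eqn{\lambda \notin Z}): the VACF decays as the negative power law
#' \deqn{C_v(t) \approx \frac{2 k_BT \delta \tau^\lambda}{\Gamma(-\lambda)}
#'   \frac{\varphi/\xi_s}{(1+\varphi)^2}\, t^{-\lambda-1},\qquad
#'   \varphi = \xi_p/\xi_s,}
#' (negative since \eqn{\Gamma(-\lambda)<0} for \eqn{0<\lambda<1}); the MSD
#' approaches the exact Brownian line \eqn{2 d\, k_BT\, t/(\xi_s+\xi_p)} and
#' \eqn{D(t) \to D_\infty = k_BT/(\xi_s+\xi_p)}.  The friction-ratio and
#' frequency-ratio forms of the VACF prefactor are algebraically identical;
#' both are computed and verified to agree.
#'
#' @inheritParams gle_short_time
#' @return numeric vector in internal units.
#' @export
gle_long_time <- function(p, t, kind = c("msd", "vacf", "dcoef")) {
  kind <- match.arg(kind)
  if (abs(p$delta * p$lam - p$nu) > 1e-12)
    stop("long-time asymptotics require the Brownian constraint delta*lam == nu")
  if (abs(p$lam - round(p$lam)) < 1e-12)
    stop("the VACF tail exponent requires non-integer lam")
  kT <- kBT(p$temperature)
  xs <- p$mass * p$omega_s
  xp <- p$mass * p$omega_p
  switch(kind,
    vacf = {
      phi <- xp / xs
      pre_xi <- 2 * kT * p$delta * p$tau^p$lam / gamma(-p$lam) *
        (xp / xs^2) / (1 + phi)^2
      pre_om <- 2 * kT / p$mass * p$delta * p$tau^p$lam / gamma(-p$lam) *
        (p$omega_p / p$omega_s^2) / (1 + p$omega_p / p$omega_s)^2
      if (abs(pre_xi / pre_om - 1) > 1e-10)
        stop("internal error: VACF prefactor forms disagree")
      pre_xi * t^(-p$lam - 1)
    },
    dcoef = rep(kT / (xs + xp), length(t)),
    msd = 2 * p$dim * kT / (xs + xp) * t)
}

#' Long-time diffusion coefficient
#'
#' \eqn{D_\infty = k_BT/(\xi_s+\xi_p) = k_BT/[M(\omega_s+\omega_p)]},
#' converted to \eqn{\mu m^2/s}.
#'
#' @param p a [gle_params()] object.
#' @return diffusion coefficient (um^2/s).
#' @export
d_infinity <- function(p) {
  kBT(p$temperature) / (p$mass * (p$omega_s + p$omega_p)) * .D_to_um2_s
}

#' Derived physical parameters in laboratory units
#'
#' From the kernel parameters: confining frequency
#' \eqn{\omega_0 = \sqrt{\omega_p/\tau}} (ps^-1), ballistic timescale
#' \eqn{\tau_s = 1/\omega_s} (ps), frictions \eqn{\xi_s = M\omega_s} and
#' \eqn{\xi_p = M\omega_p} (Pa s um), their ratio \eqn{\varphi}, and
#' \eqn{D_\infty} (um^2/s).
#'
#' @param p a [gle_params()] object.
#' @return data.frame with one row per quantity (`value`, `units`).
#' @export
derive_parameters <- function(p) {
  omega0 <- sqrt(p$omega_p / p$tau)
  xi_s <- p$mass * p$omega_s * .friction_to_Pa_s_um
  xi_p <- p$mass * p$omega_p * .friction_to_Pa_s_um
  data.frame(
    quantity = c("omega0", "tau_s", "xi_s", "xi_p", "phi", "D_inf"),
    value = c(omega0, 1 / p$omega_s, xi_s, xi_p,
              p$omega_p / p$omega_s, d_infinity(p)),
    units = c("ps^-1", "ps", "Pa s um", "Pa s um", "1", "um^2/s"),
    stringsAsFactors = FALSE)
}
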