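## Three-parameter Mittag-Leffler (Prabhakar) function on the negative real
## axis, its "generalized" time-domain form, and the relaxation-rate spectrum
## whose Laplace mixture reproduces it.
##
## Evaluation strategy (cross-validated against an arbitrary-precision series
## and an independent adaptive quadrature of the spectrum integral):
##   * power series for x <= 5 (alternating, but cancellation is still benign
##     there in double precision),
##   * algebraic asymptotic expansion, optimally truncated, for x >= 40,
##   * trapezoidal quadrature of the relaxation-rate spectrum integral on a
##     log rate grid in the crossover band 5 < x < 40 (completely monotone
##     parameter region only, where the spectrum is a genuine density).

## 1/Gamma(x) with exact zeros at non-positive integers (reflection formula).
.rcp_gamma <- function(x) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- 1 / gamma(x[pos])
  if (any(!pos)) {
    xn <- x[!pos]
    s <- sinpi(xn)
    out[!pos] <- ifelse(s == 0, 0, s / pi * exp(lgamma(1 - xn)))
  }
  out
}

.ml3_series <- function(x, lam, nu, delta, kmax = 400L) {
  k <- 0:kmax
  lg <- lgamma(delta + k) - lgamma(delta) - lgamma(k + 1) + k * log(x)
  term <- (-1)^k * exp(lg) * .rcp_gamma(lam * k + nu)
  s <- sum(term)
  tail <- abs(term[kmax + 1L])
  if (!is.finite(s) || tail > 1e-15 * max(abs(s), 1e-300))
    stop("Prabhakar series failed to converge at x = ", signif(x, 4))
  s
}

## Large-argument algebraic expansion
##   E_{lam,nu}^delta(-x) ~ sum_j (-1)^j Gamma(delta+j)/(Gamma(delta) j!)
##                          * x^-(delta+j) / Gamma(nu - lam (delta+j)),
## truncated at the smallest term.  Returns value with an error estimate.
.ml3_asym <- function(x, lam, nu, delta, jmax = 120L) {
  j <- 0:jmax
  lg <- lgamma(delta + j) - lgamma(delta) - lgamma(j + 1) - (delta + j) * log(x)
  term <- (-1)^j * exp(lg) * .rcp_gamma(nu - lam * (delta + j))
  a <- abs(term)
  nz <- which(a > 0)
  if (length(nz) == 0L) return(list(value = 0, err = 0))
  ## truncate before the first growth among non-zero terms
  cut <- length(nz)
  if (length(nz) > 1L) {
    grow <- which(diff(a[nz]) > 0)
    if (length(grow)) cut <- grow[1L]
  }
  keep <- nz[seq_len(cut)]
  val <- sum(term[seq_len(max(keep))])
  err <- if (cut < length(nz)) a[nz[cut + 1L]] else a[nz[cut]] * 1e-3
  list(value = val, err = err)
}

## Crossover band: E(-x) = t^(1-nu) * int_0^inf p(f) exp(-f t) df with
## tau = 1, t = x^(1/lam).  Trapezoid on u = log f; the substituted integrand
## decays exponentially at both ends, so the rule converges geometrically.
.ml3_quad <- function(x, lam, nu, delta) {
  t <- x^(1 / lam)
  decay <- 1 + lam * delta - nu              # low-rate decay exponent in u
  u_hi <- log(50 / t)
  u_lo <- min(-log(t), 0) - 42 / decay - 5
  h <- min(0.04, (1 - lam) / 6 + 1e-3)
  u <- seq(u_lo, u_hi, by = h)
  f <- exp(u)
  g <- rate_spectrum(f, lam, nu, delta, tau = 1, check_cm = FALSE) *
    f * exp(-f * t)
  t^(1 - nu) * h * sum(g)
}

## Kummer reduction for lam == 1 (CM region requires delta <= nu there):
## E_{1,nu}^delta(-x) = exp(-x) M(nu-delta, nu, x) / Gamma(nu), summed with
## positive terms in log space.
.ml3_lam1 <- function(x, nu, delta) {
  a <- nu - delta
  if (a < 0) {                       # outside the CM region: fall back
    if (x <= 30) return(.ml3_series(x, 1, nu, delta))
    return(.ml3_asym(x, 1, nu, delta)$value)
  }
  if (x > 700) return(.ml3_asym(x, 1, nu, delta)$value)
  if (a == 0) return(exp(-x) / gamma(nu))
  kmax <- ceiling(x + 40 * sqrt(x + 1) + 60)
  k <- 0:kmax
  lg <- lgamma(a + k) - lgamma(a) - (lgamma(nu + k) - lgamma(nu)) -
    lgamma(k + 1) + k * log(x)
  m <- max(lg)
  exp(-x + m + log(sum(exp(lg - m)))) / gamma(nu)
}

.check_ml_par <- function(lam, nu, delta, tau = 1) {
  if (!is.numeric(lam) || !is.numeric(nu) || !is.numeric(delta) ||
      length(lam) != 1L || length(nu) != 1L || length(delta) != 1L ||
      !is.finite(lam) || !is.finite(nu) || !is.finite(delta) ||
      lam <= 0 || nu <= 0 || delta <= 0)
    stop("Mittag-Leffler parameters lam, nu, delta must be positive finite scalars")
  if (length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("timescale tau must be a positive finite scalar")
  invisible(TRUE)
}

#' Complete-monotonicity region of the Prabhakar kernel
#'
#' The generalized Mittag-Leffler relaxation function
#' \eqn{e_{\lambda,\nu}^\delta(t/\tau)} is completely monotone — i.e. a
#' non-negative mixture of decaying exponentials, the physical requirement for
#' a monotone energy decay and a non-negative relaxation-rate spectrum — if
#' and only if \eqn{0 < \lambda \le 1} and \eqn{0 < \lambda\delta \le \nu \le 1}.
#'
#' @param lam,nu,delta Prabhakar exponents (positive scalars).
#' @return `TRUE` if the parameters lie in the completely monotone region.
#' @examples
#' cm_region(0.715, 0.715, 1)   # TRUE
#' cm_region(0.5, 0.2, 1)       # FALSE: lambda*delta > nu
#' @export
cm_region <- function(lam, nu, delta) {
  .check_ml_par(lam, nu, delta)
  lam <= 1 && lam * delta <= nu && nu <= 1
}

#' Three-parameter Mittag-Leffler (Prabhakar) function at negative argument
#'
#' Evaluates \eqn{E_{\lambda,\nu}^\delta(-x)} for \eqn{x \ge 0}, i.e. the
#' entire function \eqn{\sum_k \Gamma(\delta+k) (-x)^k /
#' (\Gamma(\delta)\, k!\, \Gamma(\lambda k + \nu))}.  The implementation
#' switches between the power series, an optimally truncated algebraic
#' asymptotic expansion, and quadrature of the relaxation-rate spectrum in the
#' crossover band; target relative accuracy is 1e-10 throughout
#' \eqn{x \in [0, 10^6]} for completely monotone parameters.
#'
#' @param x non-negative numeric vector; the function is evaluated at `-x`.
#' @inheritParams cm_region
#' @return numeric vector of the same length as `x`.
#' @examples
#' mittag_leffler(0, 0.715, 0.715, 1)    # 1/gamma(0.715)
#' mittag_leffler(1, 1, 1, 1)            # exp(-1)
#' @export
mittag_leffler <- function(x, lam, nu, delta) {
  .check_ml_par(lam, nu, delta)
  if (any(!is.finite(x)) || any(x < 0))
    stop("x must be non-negative and finite")
  cm <- cm_region(lam, nu, delta)
  vapply(x, function(xi) {
    if (xi == 0) return(.rcp_gamma(nu))
    if (lam == 1) return(.ml3_lam1(xi, nu, delta))
    if (xi <= (if (cm) 3 else 5)) return(.ml3_series(xi, lam, nu, delta))
    if (xi >= 40) {
      as <- .ml3_asym(xi, lam, nu, delta)
      if (as$err <= 1e-10 * max(abs(as$value), 1e-300)) return(as$value)
      if (cm) return(.ml3_quad(xi, lam, nu, delta))
      stop("Prabhakar asymptotic expansion not accurate near x = ",
           signif(xi, 4), " outside the completely monotone region")
    }
    if (cm) return(.ml3_quad(xi, lam, nu, delta))
    stop("Prabhakar evaluation in the crossover band 5 < x < 40 requires ",
         "completely monotone parameters (got lam = ", lam, ", nu = ", nu,
         ", delta = ", delta, ")")
  }, numeric(1))
}

#' Generalized Mittag-Leffler relaxation function
#'
#' The time-domain elastic kernel shape
#' \eqn{e_{\lambda,\nu}^\delta(t/\tau) = (t/\tau)^{\nu-1}
#' E_{\lambda,\nu}^\delta[-(t/\tau)^\lambda]}, a completely monotone decay for
#' parameters in [cm_region()].  For \eqn{\lambda=\nu=\delta=1} it reduces to
#' \eqn{e^{-t/\tau}}.
#'
#' @param t times (ps), non-negative; `t = 0` is admitted only when
#'   \eqn{\nu \ge 1} (otherwise the power prefactor is singular).
#' @inheritParams cm_region
#' @param tau kernel timescale (ps).
#' @return numeric vector, \eqn{e_{\lambda,\nu}^\delta(t/\tau)}.
#' @export
ml_kernel <- function(t, lam, nu, delta, tau = 1) {
  .check_ml_par(lam, nu, delta, tau)
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be non-negative and finite")
  if (any(t == 0) && nu < 1)
    stop("ml_kernel is singular at t = 0 for nu < 1")
  z <- t / tau
  out <- numeric(length(t))
  zero <- z == 0
  out[zero] <- if (nu == 1) 1 else 0          # z^(nu-1) with nu > 1
  if (any(!zero))
    out[!zero] <- z[!zero]^(nu - 1) *
      mittag_leffler(z[!zero]^lam, lam, nu, delta)
  out
}

#' Relaxation-rate spectrum of the Prabhakar kernel
#'
#' Density \eqn{p_{\lambda\nu\delta,\tau}(f)} of exponential decay rates such
#' that \eqn{e_{\lambda,\nu}^\delta(t/\tau) = \int_0^\infty p(f) e^{-ft} df}.
#' The branch angle \eqn{\theta_{\lambda\tau}(f) = \arg[(-f\tau)^\lambda + 1]}
#' is taken on the principal branch,
#' \eqn{\theta = \mathrm{atan2}(\sin(\pi\lambda)(f\tau)^\lambda,
#' \cos(\pi\lambda)(f\tau)^\lambda + 1)}.  The density is non-negative for
#' completely monotone parameters; outside that region a warning is emitted
#' and the formula is evaluated unchecked.
#'
#' @param f decay rates (ps^-1), positive.
#' @inheritParams ml_kernel
#' @param check_cm warn when the parameters are outside the completely
#'   monotone region.
#' @return spectral density values (ps).
#' @export
rate_spectrum <- function(f, lam, nu, delta, tau = 1, check_cm = TRUE) {
  .check_ml_par(lam, nu, delta, tau)
  if (any(f <= 0)) stop("rates f must be positive")
  if (check_cm && !cm_region(lam, nu, delta))
    warning("parameters outside the completely monotone region; ",
            "the rate spectrum may be negative")
  ft <- f * tau
  theta <- atan2(sinpi(lam) * ft^lam, cospi(lam) * ft^lam + 1)
  tau * ft^(lam * delta - nu) * sin(pi * (nu - lam * delta) + delta * theta) /
    (pi * (ft^(2 * lam) + 2 * ft^lam * cospi(lam) + 1)^(delta / 2))
}
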