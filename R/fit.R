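## Bayesian fitting of the GLE model to MSD curves.
##
## The model MSD is evaluated in the Laplace domain (under the Brownian
## constraint nu = delta*lambda),
##   <dX^2>^(s) = (2 d kBT / M) / [ s^2 ( s + omega_s
##                 + omega_p / (1 + (tau s)^lambda)^delta ) ],
## and inverted numerically on the data lags; a fixed Talbot contour is
## precomputed per lag so that one likelihood evaluation is a single complex
## matrix operation.  The posterior over theta (flat prior inside bounds,
## restricted to the completely monotone region) is evaluated either on a
## refinable tensor grid (the reference method) or by affine-invariant
## ensemble MCMC (stretch moves).

.variant_params <- function(variant) {
  switch(variant,
         M2 = c("omega_s", "omega_p", "tau", "lam"),
         M1 = c("omega_s", "omega_p", "tau", "lam", "delta"))
}

.default_bounds <- function(variant) {
  b <- list(omega_s = c(0.05, 20), omega_p = c(10, 5000),
            tau = c(500, 2e5), lam = c(0.35, 0.99))
  if (variant == "M1") b$delta <- c(0.3, 1.4)
  b
}

.log_scaled <- c(omega_s = TRUE, omega_p = TRUE, tau = TRUE,
                 lam = FALSE, delta = FALSE)

## fast per-lag Talbot evaluator for the Laplace-domain MSD model
.msd_model_fn <- function(lags, mass, temperature, dim = 2, nodes = 24L) {
  kT <- kBT(temperature)
  pref <- 2 * dim * kT / mass
  M <- as.integer(nodes)
  th <- seq_len(M - 1L) * pi / M
  cot <- cos(th) / sin(th)
  sig <- th + (th * cot - 1) * cot
  r <- 2 * M / (5 * lags)
  S <- outer(r, th * (cot + 1i))                    # n x (M-1)
  W <- (r / M) * exp(S * lags) *
    matrix(1 + 1i * sig, length(lags), M - 1L, byrow = TRUE)
  wr <- (r / M) * 0.5 * exp(r * lags)
  function(omega_s, omega_p, tau, lam, delta = 1) {
    den <- S + omega_s + omega_p / (1 + (tau * S)^lam)^delta
    denr <- r + omega_s + omega_p / (1 + (tau * r)^lam)^delta
    pref * (rowSums(Re(W / (S^2 * den))) + wr / (r^2 * denr))
  }
}

.theta_list <- function(theta, variant) {
  th <- as.list(theta)
  if (variant == "M2") th$delta <- 1
  th
}

#' Gaussian log-likelihood of an MSD curve under the GLE model
#'
#' Residuals between the data and the model MSD (Laplace-domain expression
#' inverted numerically at the data lags) under independent Gaussian noise
#' with standard deviations `sigma` (default `sigma_rel * data`).
#'
#' @param theta named parameter vector: `omega_s`, `omega_p` (ps^-1), `tau`
#'   (ps), `lam`, and for variant `"M1"` also `delta`.
#' @param data an MSD [observable_curve()] (or data.frame with columns
#'   `time`, `value`; ps, nm^2).
#' @param mass,temperature fixed mass (g/mol) and temperature (K).
#' @param variant `"M2"` (delta = 1, nu = lam) or `"M1"` (free delta,
#'   nu = delta*lam).
#' @param sigma_rel relative noise level defining `sigma = sigma_rel * data`.
#' @param sigma optional explicit per-point standard deviations (nm^2).
#' @param dim spatial dimension (2 for lateral diffusion).
#' @return log-likelihood (scalar).
#' @export
gle_loglik <- function(theta, data, mass, temperature, variant = "M2",
                       sigma_rel = 0.02, sigma = NULL, dim = 2) {
  y <- data$value
  if (is.null(sigma)) sigma <- sigma_rel * y
  fn <- .msd_model_fn(data$time, mass, temperature, dim)
  th <- .theta_list(theta, variant)
  m <- fn(th$omega_s, th$omega_p, th$tau, th$lam, th$delta)
  -0.5 * sum(((y - m) / sigma)^2) - sum(log(sigma)) -
    0.5 * length(y) * log(2 * pi)
}

#' Reduced chi-square of an MSD fit
#'
#' \eqn{\chi^2 / (n_{data} - n_{params})} at the given parameter vector.
#'
#' @inheritParams gle_loglik
#' @return reduced chi-square (scalar).
#' @export
gle_reduced_chi2 <- function(theta, data, mass, temperature, variant = "M2",
                             sigma_rel = 0.02, sigma = NULL, dim = 2) {
  y <- data$value
  if (is.null(sigma)) sigma <- sigma_rel * y
  npar <- length(.variant_params(variant))
  dof <- length(y) - npar
  if (dof <= 0) stop("need more data points than parameters")
  fn <- .msd_model_fn(data$time, mass, temperature, dim)
  th <- .theta_list(theta, variant)
  m <- fn(th$omega_s, th$omega_p, th$tau, th$lam, th$delta)
  sum(((y - m) / sigma)^2) / dof
}

#' Equal-tailed credible interval from a weighted marginal
#'
#' @param marginal data.frame with columns `value` and `weight` (an
#'   unnormalized 1D marginal).
#' @param level credible level in (0, 1), default 0.95.
#' @return numeric c(lower, upper).
#' @export
credible_interval <- function(marginal, level = 0.95) {
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  o <- order(marginal$value)
  v <- marginal$value[o]
  w <- marginal$weight[o] / sum(marginal$weight)
  keep <- w > 0
  v <- v[keep]; w <- w[keep]
  if (length(v) == 1L) return(c(v, v))
  ## mid-cell cumulative weights with linear interpolation between support
  ## points: avoids the half-cell inward bias of snapped quantiles on a
  ## coarse grid
  cw <- cumsum(w) - w / 2
  qf <- function(q) {
    if (q <= cw[1]) return(v[1])
    if (q >= cw[length(cw)]) return(v[length(v)])
    stats::approx(cw, v, xout = q, ties = "ordered")$y
  }
  c(qf((1 - level) / 2), qf(1 - (1 - level) / 2))
}

.weighted_mean <- function(v, w) sum(v * w) / sum(w)

.marginal <- function(support, weights, name) {
  agg <- rowsum(weights, group = support[[name]])
  data.frame(value = as.numeric(rownames(agg)), weight = as.numeric(agg))
}

.derived_support <- function(support, mass, temperature) {
  data.frame(
    omega0 = sqrt(support$omega_p / support$tau),
    xi_s = mass * support$omega_s * .friction_to_Pa_s_um,
    xi_p = mass * support$omega_p * .friction_to_Pa_s_um,
    D_inf = kBT(temperature) / (mass * (support$omega_s + support$omega_p)) *
      .D_to_um2_s)
}

## posterior summaries shared by the grid and MCMC backends
.posterior_summary <- function(support, logpost, pars, mass, temperature,
                               level = 0.95) {
  w <- exp(logpost - max(logpost))
  w <- w / sum(w)
  der <- .derived_support(support, mass, temperature)
  allq <- cbind(support[pars], der)
  means <- vapply(allq, .weighted_mean, numeric(1), w = w)
  mode_i <- which.max(logpost)
  modes <- vapply(allq, function(v) v[mode_i], numeric(1))
  ci <- t(vapply(names(allq), function(nm)
    credible_interval(data.frame(value = allq[[nm]], weight = w), level),
    numeric(2)))
  colnames(ci) <- c("lower", "upper")
  list(support = support, weights = w, means = means, modes = modes, ci = ci,
       derived_names = names(der))
}

#' Fit the GLE model to an MSD curve
#'
#' The main modelling interface: fits the Laplace-domain MSD model (under
#' the Brownian constraint \eqn{\nu = \delta\lambda}) to an observed MSD
#' curve by Bayesian inference with a flat prior on `bounds` (restricted to
#' the completely monotone region), either on a refinable tensor grid
#' (`method = "grid"`, the reference) or by affine-invariant ensemble MCMC
#' (`method = "mcmc"`).  Free parameters are \eqn{(\omega_s, \omega_p, \tau,
#' \lambda)} for variant `"M2"` (\eqn{\delta = 1}) plus \eqn{\delta} for
#' `"M1"`; mass and temperature are fixed inputs.
#'
#' @param data the observed MSD: a formula `msd ~ time` with `data` a
#'   data.frame in the second argument, an [observable_curve()], or a
#'   two-column data.frame (time ps, msd nm^2).
#' @param ... when `data` is a formula, the data.frame holding the variables
#'   (first unnamed argument).
#' @param variant `"M2"` or `"M1"`.
#' @param mass,temperature fixed mass (g/mol) and temperature (K).
#' @param dim spatial dimension (default 2).
#' @param sigma_rel,sigma noise model: independent Gaussian with
#'   `sigma = sigma_rel * data` unless `sigma` is given explicitly.
#' @param bounds named list of c(lower, upper) flat-prior ranges; defaults
#'   are wide (omega_s 0.05-20 ps^-1, omega_p 10-5000 ps^-1, tau 0.5-200 ns,
#'   lam 0.35-0.99, delta 0.3-1.4).
#' @param method `"grid"` or `"mcmc"`.
#' @param grid_points grid resolution per principal axis of the posterior
#'   (the grid is laid in the eigenbasis of the local Hessian around the
#'   mode; parameters omega_s, omega_p, tau live on a log scale, lam and
#'   delta on a linear one).
#' @param refine maximum number of widening passes when posterior mass
#'   reaches the grid boundary.
#' @param fit_range optional c(tmin, tmax) restriction of the fitted lags (ps).
#' @param max_points,per_decade the fitted lags are thinned to at most
#'   `per_decade` log-spaced points per decade, capped at `max_points`, so
#'   no single regime dominates the likelihood.
#' @param walkers,steps,burn MCMC ensemble settings (stretch moves).
#' @param seed RNG seed (used by `"mcmc"`).
#' @param level credible level for reported intervals.
#' @return an object of class `"gle_fit"`; see [summary.gle_fit()],
#'   [coef.gle_fit()], [predict.gle_fit()].
#' @examples
#' \donttest{
#' p <- gle_params(mass = 41697, temperature = 310, omega_s = 0.98,
#'                 omega_p = 447, tau = 13.4e3, lam = 0.715)
#' curve <- noisy_msd(p, 10^seq(-1, 5, length.out = 120), 0.02, seed = 1)
#' fit <- gle_fit(curve, mass = 41697, temperature = 310,
#'                grid_points = 9, refine = 1)
#' summary(fit)
#' }
#' @export
gle_fit <- function(data, ..., variant = c("M2", "M1"), mass, temperature,
                    dim = 2, sigma_rel = 0.02, sigma = NULL, bounds = NULL,
                    method = c("grid", "mcmc"), grid_points = 13L,
                    refine = 1L, fit_range = NULL, max_points = 300L,
                    per_decade = 40, walkers = 32L, steps = 1500L,
                    burn = 500L, seed = NULL, level = 0.95) {
  variant <- match.arg(variant)
  method <- match.arg(method)
  cl <- match.call()
  ## -- assemble the data curve ------------------------------------------
  if (inherits(data, "formula")) {
    dots <- list(...)
    df <- if (length(dots) && is.data.frame(dots[[1]])) dots[[1]] else
      stop("with a formula, supply the data.frame as the second argument")
    mf <- stats::model.frame(data, df)
    curve <- observable_curve(mf[[2]], mf[[1]], "msd")
  } else if (inherits(data, "gle_curve") || is.data.frame(data)) {
    curve <- observable_curve(data$time, data$value, "msd")
  } else stop("data must be a formula, gle_curve, or data.frame")
  if (!is.null(sigma) && length(sigma) != nrow(curve))
    stop("sigma must match the full data curve")
  keep <- rep(TRUE, nrow(curve))
  if (!is.null(fit_range))
    keep <- curve$time >= fit_range[1] & curve$time <= fit_range[2]
  ## thin to log spacing: nearest observed lag per log-grid point
  t_all <- curve$time[keep]
  ndec <- log10(max(t_all) / min(t_all))
  ngrid <- min(max_points, max(10L, ceiling(ndec * per_decade)))
  tg <- 10^seq(log10(min(t_all)), log10(max(t_all)), length.out = ngrid)
  idx <- unique(vapply(tg, function(x) which.min(abs(log(t_all / x))),
                       integer(1)))
  sel <- which(keep)[idx]
  y <- curve$value[sel]; tl <- curve$time[sel]
  sg <- if (is.null(sigma)) sigma_rel * y else sigma[sel]
  fitdata <- observable_curve(tl, y, "msd")
  pars <- .variant_params(variant)
  if (is.null(bounds)) bounds <- .default_bounds(variant)
  if (!all(pars %in% names(bounds))) stop("bounds must cover ", toString(pars))
  fn <- .msd_model_fn(tl, mass, temperature, dim)
  ## -- unit-cube transform shared by both backends ----------------------
  nd <- length(pars)
  tounit <- function(th) vapply(seq_len(nd), function(j) {
    b <- bounds[[pars[j]]]
    if (.log_scaled[[pars[j]]]) log(th[j] / b[1]) / log(b[2] / b[1])
    else (th[j] - b[1]) / (b[2] - b[1])
  }, numeric(1))
  fromunit <- function(u) vapply(seq_len(nd), function(j) {
    b <- bounds[[pars[j]]]
    if (.log_scaled[[pars[j]]]) b[1] * (b[2] / b[1])^u[j]
    else b[1] + u[j] * (b[2] - b[1])
  }, numeric(1))
  loglik_u <- function(u) {
    if (any(u < 0) || any(u > 1)) return(-Inf)
    th <- fromunit(u)
    de <- if (variant == "M1") th[5] else 1
    if (th[4] * de > 1 + 1e-12) return(-Inf)
    m <- fn(th[1], th[2], th[3], th[4], de)
    -0.5 * sum(((y - m) / sg)^2)
  }
  ## -- posterior mode, shared by both backends --------------------------
  ## The posterior of this model is extremely narrow and correlated relative
  ## to the wide prior box, so neither a bare tensor grid nor randomly
  ## initialized walkers can resolve it: locate the mode first (coarse scan
  ## + Nelder-Mead) and take the local Hessian as the scale.
  init <- expand.grid(rep(list(seq(0.1, 0.9, length.out = 5)), nd))
  lp0 <- apply(init, 1, loglik_u)
  u0 <- as.numeric(init[which.max(lp0), ])
  opt <- stats::optim(u0, function(u) -loglik_u(u), method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  opt <- stats::optim(opt$par, function(u) -loglik_u(u),
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  umap <- opt$par
  h <- 1e-3
  H <- matrix(0, nd, nd)
  for (a in seq_len(nd)) for (b in a:nd) {
    ea <- eb <- rep(0, nd); ea[a] <- h; eb[b] <- h
    H[a, b] <- H[b, a] <-
      (loglik_u(umap + ea + eb) - loglik_u(umap + ea - eb) -
       loglik_u(umap - ea + eb) + loglik_u(umap - ea - eb)) / (4 * h^2)
  }
  Sg <- tryCatch(solve(-H), error = function(e) NULL)
  if (is.null(Sg) || any(!is.finite(Sg)) || any(diag(Sg) <= 0))
    Sg <- diag(4e-4, nd)
  sdu <- pmin(pmax(sqrt(diag(Sg)), 1e-4), 0.25)
  if (method == "grid") {
    ## The posterior is strongly correlated between parameters, so an
    ## axis-aligned tensor grid aliases the thin probability ridge.  The
    ## grid is laid in the eigenbasis of the local covariance (principal
    ## axes of the posterior), widened while mass leaks to the boundary.
    ev <- eigen(Sg, symmetric = TRUE)
    evals <- pmax(ev$values, 1e-10)
    scales <- pmin(pmax(sqrt(evals), 1e-5), 0.5)
    width <- 5
    res <- NULL; support <- NULL; lp <- NULL
    for (pass in 0:max(1L, refine)) {
      axes <- lapply(seq_len(nd), function(j)
        seq(-width * scales[j], width * scales[j],
            length.out = grid_points))
      egrid <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
      ugrid <- sweep(egrid %*% t(ev$vectors), 2, umap, `+`)
      lp <- apply(ugrid, 1, loglik_u)
      if (!any(is.finite(lp)))
        stop("posterior mass is zero everywhere on the grid: ",
             "the model cannot reach the data within the bounds")
      support <- as.data.frame(t(apply(ugrid, 1, fromunit)))
      names(support) <- pars
      ## fraction of mass on the outermost shell of the eigen-grid
      w <- exp(lp - max(lp)); w <- w / sum(w)
      edge <- rowSums(abs(abs(egrid) -
                            rep(width * scales, each = nrow(egrid))) <
                        1e-12) > 0
      if (sum(w[edge]) < 1e-3 || pass == max(1L, refine)) break
      width <- width * 2
    }
    res <- .posterior_summary(support, lp, pars, mass, temperature, level)
    diag <- list(method = "grid", grid_points = grid_points,
                 map = stats::setNames(fromunit(umap), pars), width = width)
  } else {
    if (!is.null(seed)) set.seed(seed)
    logpost_u <- loglik_u
    ## walkers start in a Hessian-scaled ball around the mode
    U <- matrix(stats::rnorm(walkers * nd, mean = rep(umap, each = walkers),
                             sd = rep(sdu, each = walkers)), walkers, nd)
    U <- pmin(pmax(U, 1e-6), 1 - 1e-6)
    lp <- apply(U, 1, logpost_u)
    for (k in which(!is.finite(lp))) {       # resample invalid starts
      for (tries in 1:100) {
        U[k, ] <- pmin(pmax(umap + sdu * stats::rnorm(nd), 1e-6), 1 - 1e-6)
        lp[k] <- logpost_u(U[k, ])
        if (is.finite(lp[k])) break
      }
    }
    chain <- array(NA_real_, c(steps, walkers, nd))
    lpchain <- matrix(NA_real_, steps, walkers)
    a <- 2
    for (it in seq_len(steps)) {
      for (k in seq_len(walkers)) {
        j <- sample(seq_len(walkers)[-k], 1L)
        zz <- ((a - 1) * stats::runif(1) + 1)^2 / a
        prop <- U[j, ] + zz * (U[k, ] - U[j, ])
        lpp <- logpost_u(prop)
        if (is.finite(lpp) &&
            log(stats::runif(1)) < (nd - 1) * log(zz) + lpp - lp[k]) {
          U[k, ] <- prop; lp[k] <- lpp
        }
      }
      chain[it, , ] <- t(apply(U, 1, fromunit))
      lpchain[it, ] <- lp
    }
    post <- chain[(burn + 1):steps, , , drop = FALSE]
    lpost <- lpchain[(burn + 1):steps, , drop = FALSE]
    ns <- dim(post)[1]
    ## split-chain convergence statistic per parameter
    rhat <- vapply(seq_len(nd), function(j) {
      half <- ns %/% 2L
      segs <- cbind(post[1:half, , j], post[(ns - half + 1):ns, , j])
      m <- colMeans(segs); v <- apply(segs, 2, stats::var)
      W <- mean(v); B <- half * stats::var(m)
      sqrt(((half - 1) / half * W + B / half) / W)
    }, numeric(1))
    support <- as.data.frame(matrix(aperm(post, c(1, 2, 3)), ncol = nd))
    names(support) <- pars
    if (variant == "M2") support$delta <- NULL
    lp_flat <- as.numeric(lpost)
    res <- .posterior_summary(support, lp_flat * 0, pars, mass, temperature,
                              level)
    ## for samples the weights are uniform; the mode is the best sample
    res$modes <- vapply(cbind(support[pars],
                              .derived_support(support, mass, temperature)),
                        function(v) v[which.max(lp_flat)], numeric(1))
    diag <- list(method = "mcmc", walkers = walkers, steps = steps,
                 burn = burn, rhat = rhat, converged = all(rhat < 1.05))
    if (!diag$converged)
      warning("MCMC split-chain statistic >= 1.05; chain may not have converged")
  }
  theta_hat <- res$means[pars]
  rchi2 <- gle_reduced_chi2(theta_hat, fitdata, mass, temperature, variant,
                            sigma = sg, dim = dim)
  out <- list(call = cl, variant = variant, mass = mass,
              temperature = temperature, dim = dim,
              data = fitdata, sigma = sg, sigma_rel = sigma_rel,
              bounds = bounds, pars = pars, support = res$support,
              weights = res$weights, means = res$means, modes = res$modes,
              ci = res$ci, derived_names = res$derived_names, level = level,
              reduced_chi2 = rchi2, diagnostics = diag, seed = seed,
              interval_type = "equal-tailed")
  class(out) <- "gle_fit"
  out
}

#' Marginal posterior of one parameter
#'
#' @param object a [gle_fit()] result.
#' @param name parameter name (free or derived, e.g. `"tau"`, `"D_inf"`).
#' @return data.frame with columns `value`, `weight`.
#' @export
marginal_posterior <- function(object, name) {
  stopifnot(inherits(object, "gle_fit"))
  sup <- cbind(object$support[object$pars],
               .derived_support(object$support, object$mass,
                                object$temperature))
  if (!name %in% names(sup)) stop("unknown parameter: ", name)
  .marginal(sup, object$weights, name)
}

#' @export
print.gle_fit <- function(x, ...) {
  cat(sprintf("GLE MSD fit, variant %s (%s posterior), %d lags\n",
              x$variant, x$diagnostics$method, nrow(x$data)))
  cat("Posterior means:\n")
  print(signif(x$means[x$pars], 4))
  cat(sprintf("Reduced chi-square: %.3g\n", x$reduced_chi2))
  invisible(x)
}

#' Summarize a GLE MSD fit
#'
#' Parameter table (posterior mean, mode and credible interval) for the free
#' parameters and the derived physical quantities \eqn{\omega_0}
#' (ps^-1), \eqn{\xi_s}, \eqn{\xi_p} (Pa s um) and \eqn{D_\infty} (um^2/s).
#'
#' @param object a [gle_fit()] result.
#' @param ... unused.
#' @export
summary.gle_fit <- function(object, ...) {
  units <- c(omega_s = "ps^-1", omega_p = "ps^-1", tau = "ps", lam = "1",
             delta = "1", omega0 = "ps^-1", xi_s = "Pa s um",
             xi_p = "Pa s um", D_inf = "um^2/s")
  nm <- names(object$means)
  tab <- data.frame(mean = object$means, mode = object$modes,
                    lower = object$ci[, "lower"], upper = object$ci[, "upper"],
                    units = units[nm], row.names = nm)
  out <- list(call = object$call, variant = object$variant, table = tab,
              reduced_chi2 = object$reduced_chi2, level = object$level,
              interval_type = object$interval_type,
              diagnostics = object$diagnostics, n = nrow(object$data))
  class(out) <- "summary.gle_fit"
  out
}

#' @export
print.summary.gle_fit <- function(x, ...) {
  cat("Bayesian GLE MSD fit (variant ", x$variant, ", flat prior, ",
      x$diagnostics$method, ")\n", sep = "")
  cat(sprintf("%d fitted lags; %.0f%% %s credible intervals\n",
              x$n, 100 * x$level, x$interval_type))
  print(cbind(signif(x$table[1:4], 4), units = x$table$units))
  cat(sprintf("Reduced chi-square at the posterior mean: %.3g\n",
              x$reduced_chi2))
  if (x$diagnostics$method == "mcmc")
    cat(sprintf("Split-chain statistic: max %.3f (converged: %s)\n",
                max(x$diagnostics$rhat), x$diagnostics$converged))
  invisible(x)
}

#' @export
coef.gle_fit <- function(object, ...) object$means[object$pars]

#' @export
vcov.gle_fit <- function(object, ...) {
  sup <- as.matrix(object$support[object$pars])
  w <- object$weights
  mu <- colSums(sup * w)
  crossprod(sqrt(w) * sweep(sup, 2, mu))
}

#' Model curves at the fitted parameters
#'
#' @param object a [gle_fit()] result.
#' @param times lags (ps); defaults to the fitted lags.
#' @param kind observable kind (`"msd"`, `"vacf"`, `"dcoef"`).
#' @param ... unused.
#' @return an [observable_curve()].
#' @export
predict.gle_fit <- function(object, times = NULL, kind = "msd", ...) {
  if (is.null(times)) times <- object$data$time
  p <- .params_from_fit(object)
  gle_observable(p, times, kind)
}

.params_from_fit <- function(object) {
  th <- as.list(object$means[object$pars])
  gle_params(mass = object$mass, temperature = object$temperature,
             omega_s = th$omega_s, omega_p = th$omega_p, tau = th$tau,
             lam = th$lam, delta = if (is.null(th$delta)) 1 else th$delta,
             dim = object$dim)
}

#' @export
fitted.gle_fit <- function(object, ...) {
  fn <- .msd_model_fn(object$data$time, object$mass, object$temperature,
                      object$dim)
  th <- .theta_list(object$means[object$pars], object$variant)
  fn(th$omega_s, th$omega_p, th$tau, th$lam, th$delta)
}

#' @export
residuals.gle_fit <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  r <- object$data$value - fitted(object)
  if (type == "pearson") r / object$sigma else r
}

#' @export
logLik.gle_fit <- function(object, ...) {
  ll <- -0.5 * sum(residuals(object, "pearson")^2) -
    sum(log(object$sigma)) - 0.5 * nrow(object$data) * log(2 * pi)
  structure(ll, df = length(object$pars), class = "logLik")
}

#' Simulate noisy MSD replicates from a fitted model
#'
#' Parametric bootstrap: the fitted model MSD with fresh multiplicative
#' Gaussian noise at the fit's `sigma_rel`.
#'
#' @param object a [gle_fit()] result.
#' @param nsim number of replicates.
#' @param seed RNG seed.
#' @param ... unused.
#' @return list of MSD [observable_curve()]s.
#' @export
simulate.gle_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- .params_from_fit(object)
  lapply(seq_len(nsim), function(i)
    noisy_msd(p, object$data$time, object$sigma_rel))
}

#' Plot a GLE MSD fit
#'
#' `which = 1`: data and fitted model on log-log axes; `which = 2`: 1D
#' marginal posteriors of the free parameters.
#'
#' @param x a [gle_fit()] result.
#' @param which plots to draw.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gle_fit <- function(x, which = 1L, ...) {
  if (1L %in% which) {
    graphics::plot(x$data$time, x$data$value, log = "xy", pch = 16, cex = 0.4,
                   col = "grey40", xlab = "lag (ps)", ylab = "MSD (nm^2)", ...)
    graphics::lines(x$data$time, fitted(x), col = "firebrick", lwd = 2)
    graphics::legend("topleft", c("data", "model"), pch = c(16, NA),
                     lty = c(NA, 1), col = c("grey40", "firebrick"), bty = "n")
  }
  if (2L %in% which) {
    np <- length(x$pars)
    op <- graphics::par(mfrow = c(ceiling(np / 2), 2), mar = c(4, 4, 1, 1))
    on.exit(graphics::par(op))
    for (nm in x$pars) {
      m <- marginal_posterior(x, nm)
      graphics::plot(m$value, m$weight / sum(m$weight), type = "h",
                     xlab = nm, ylab = "posterior mass")
      graphics::abline(v = x$means[nm], col = "firebrick")
    }
  }
  invisible(x)
}
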