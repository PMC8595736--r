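## Estimators and diagnostics for 2D single-particle trajectories and MSD
## curves: FFT-based time-averaged MSD and VACF, smoothed local exponent and
## time-dependent diffusion coefficient, cumulative displacement distribution
## (Gaussianity check), mass-weighted group averages and residence-time
## ("NEAR shell") selection.

#' Construct a 2D trajectory
#'
#' @param times uniformly spaced sampling times (ps), length N >= 2.
#' @param x,y coordinates (nm).
#' @param mass particle mass (g/mol), used by mass-weighted group averages.
#' @param label free-text label.
#' @return object of class `"gle_trajectory"`: list with `times`, `pos`
#'   (N x 2 matrix), `dt`, `mass`, `label`.
#' @export
trajectory2d <- function(times, x, y, mass = 1, label = "") {
  n <- length(times)
  if (n < 2L || length(x) != n || length(y) != n)
    stop("need at least 2 samples with matching times, x, y")
  if (any(!is.finite(times)) || any(!is.finite(x)) || any(!is.finite(y)))
    stop("trajectory contains non-finite values")
  dt <- diff(times)
  if (any(abs(dt / dt[1] - 1) > 1e-6))
    stop("sampling times must be uniformly spaced")
  structure(list(times = times, pos = cbind(x = x, y = y), dt = dt[1],
                 mass = mass, label = label),
            class = "gle_trajectory")
}

#' @export
print.gle_trajectory <- function(x, ...) {
  cat(sprintf("<gle_trajectory> %d frames, dt = %g ps, mass = %g g/mol%s\n",
              length(x$times), x$dt, x$mass,
              if (nzchar(x$label)) paste0(" (", x$label, ")") else ""))
  invisible(x)
}

## autocorrelation sum_{k} a_k a_{k+m} for m = 0..N-1 via zero-padded FFT
.acf_fft <- function(a) {
  n <- length(a)
  npad <- 2^ceiling(log2(2 * n))
  fa <- stats::fft(c(a, rep(0, npad - n)))
  Re(stats::fft(fa * Conj(fa), inverse = TRUE))[1:n] / npad
}

#' Time-averaged mean-square displacement
#'
#' MSD over sliding origins,
#' \eqn{MSD(m\,dt) = \frac{1}{N-m}\sum_{k} \|X_{k+m}-X_k\|^2},
#' computed with the FFT correlation algorithm in O(N log N).
#'
#' @param traj a [trajectory2d()], or a list of them (curves are averaged
#'   across trajectories after per-trajectory time averaging).
#' @param lags lags (ps); must be multiples of the sampling step smaller than
#'   the span.  Defaults to every available lag up to a quarter of the span.
#' @return an MSD [observable_curve()].
#' @export
msd_tavg <- function(traj, lags = NULL) {
  if (inherits(traj, "gle_trajectory")) traj <- list(traj)
  dt <- traj[[1]]$dt
  n <- length(traj[[1]]$times)
  if (is.null(lags)) lags <- dt * seq_len(max(1L, n %/% 4L))
  m <- .lag_index(lags, dt, n)
  msd <- rowMeans(vapply(traj, function(tr) .msd_single(tr$pos, m),
                         numeric(length(m))))
  observable_curve(m * dt, msd, "msd")
}

.lag_index <- function(lags, dt, n) {
  m <- round(lags / dt)
  if (any(abs(lags / dt - m) > 1e-6))
    stop("lags must be integer multiples of the sampling step")
  if (any(m < 1L) || any(m > n - 1L))
    stop("lags must lie in [dt, span)")
  as.integer(m)
}

.msd_single <- function(pos, m) {
  n <- nrow(pos)
  out <- numeric(length(m))
  for (j in 1:2) {
    a <- pos[, j]
    d <- a^2
    s2 <- .acf_fft(a)                      # sum a_k a_{k+m}
    ## ss[m] = sum_{k=0}^{N-m-1} (d_k + d_{k+m}), computed by recursion
    q <- 2 * sum(d)
    ss <- numeric(n)
    ss[1] <- q                              # m = 0
    for (mm in 2:n) ss[mm] <- ss[mm - 1] - d[mm - 1] - d[n - mm + 2]
    msd_all <- (ss - 2 * s2) / (n - 0:(n - 1))
    out <- out + msd_all[m + 1L]
  }
  out
}

#' Time-averaged velocity autocorrelation function
#'
#' Velocities are taken from the positions by central differences (second
#' order; the two end frames are dropped) unless supplied.  The zero-lag
#' value estimates \eqn{\langle U\cdot U\rangle = 2k_BT/M} for thermalized
#' input.
#'
#' @inheritParams msd_tavg
#' @param lags lags (ps) including 0; defaults to 0..span/4.
#' @param velocities optional (N x 2) velocity matrix (nm/ps).
#' @return a VACF [observable_curve()]; lag 0 is included only if requested.
#' @export
vacf_tavg <- function(traj, lags = NULL, velocities = NULL) {
  if (inherits(traj, "gle_trajectory")) traj <- list(traj)
  dt <- traj[[1]]$dt
  one <- function(tr, vel) {
    if (is.null(vel)) {
      n <- nrow(tr$pos)
      if (n < 3L) stop("need at least 3 frames to differentiate positions")
      vel <- (tr$pos[3:n, , drop = FALSE] - tr$pos[1:(n - 2), , drop = FALSE]) /
        (2 * dt)
    }
    vel
  }
  vels <- lapply(traj, one, vel = velocities)
  nv <- nrow(vels[[1]])
  if (is.null(lags)) lags <- dt * (0:max(1L, nv %/% 4L))
  m <- round(lags / dt)
  if (any(abs(lags / dt - m) > 1e-6) || any(m < 0L) || any(m > nv - 1L))
    stop("lags must be multiples of the step within the differentiated span")
  m <- as.integer(m)
  cv <- rowMeans(vapply(vels, function(v) {
    (.acf_fft(v[, 1]) + .acf_fft(v[, 2]))[m + 1L] / (nv - m)
  }, numeric(length(m))))
  observable_curve(m * dt, cv, "vacf")
}

## resample a positive curve onto log-spaced lags (geometric interpolation)
.log_resample <- function(curve, per_decade = 24) {
  t <- curve$time; v <- curve$value
  keep <- t > 0 & v > 0
  t <- t[keep]; v <- v[keep]
  if (length(t) < 4L) stop("too few positive samples to resample")
  lt <- log(t); lv <- log(v)
  grid <- seq(min(lt), max(lt),
              length.out = max(8L, ceiling(diff(range(lt)) / log(10) * per_decade)))
  list(lt = grid, lv = stats::approx(lt, lv, xout = grid, ties = "ordered")$y)
}

## derivative d lv / d lt by local quadratic least squares over a sliding
## window (default 7 points)
.loglog_slope <- function(lt, lv, window = 7L) {
  n <- length(lt)
  half <- window %/% 2L
  vapply(seq_len(n), function(i) {
    j <- max(1L, i - half):min(n, i + half)
    if (length(j) < 3L) j <- if (i <= half) 1:3 else (n - 2L):n
    x <- lt[j] - lt[i]
    fit <- stats::lm.fit(cbind(1, x, x^2), lv[j])
    fit$coefficients[2]
  }, numeric(1))
}

#' Local MSD exponent
#'
#' \eqn{\alpha(t) = d\log MSD/d\log t}, the instantaneous power-law exponent
#' of the MSD (2 ballistic, 1 Brownian, between 0 and 1 subdiffusive).  The
#' curve is resampled to log-spaced lags and differentiated by local
#' quadratic smoothing over a 7-point window.
#'
#' @param curve an MSD [observable_curve()] with positive values.
#' @param per_decade resampling density.
#' @param window smoothing window (odd, >= 3).
#' @return an `alpha` [observable_curve()].
#' @export
local_exponent <- function(curve, per_decade = 24, window = 7L) {
  if (any(curve$value <= 0)) stop("local_exponent requires positive MSD values")
  rs <- .log_resample(curve, per_decade)
  observable_curve(exp(rs$lt), .loglog_slope(rs$lt, rs$lv, window), "alpha")
}

#' Time-dependent diffusion coefficient from an MSD curve
#'
#' \eqn{D(t) = \frac{1}{2d}\,dMSD/dt}, evaluated as
#' \eqn{\alpha(t)\,MSD(t)/(2d\,t)} on the smoothed log-log derivative.
#'
#' @inheritParams local_exponent
#' @param dim spatial dimension (2 for lateral diffusion).
#' @param p optional [gle_params()]; when given, the returned curve carries a
#'   `D_inf_ratio` attribute with \eqn{D(t)/D_\infty} (internal units).
#' @return a `dcoef` [observable_curve()] (nm^2/ps).
#' @export
time_dependent_D <- function(curve, dim = 2, per_decade = 24, window = 7L,
                             p = NULL) {
  if (any(curve$value <= 0)) stop("time_dependent_D requires positive MSD values")
  rs <- .log_resample(curve, per_decade)
  alpha <- .loglog_slope(rs$lt, rs$lv, window)
  tt <- exp(rs$lt)
  D <- alpha * exp(rs$lv) / (2 * dim * tt)
  out <- observable_curve(tt, D, "dcoef")
  if (!is.null(p)) {
    Dinf <- kBT(p$temperature) / (p$mass * (p$omega_s + p$omega_p))
    attr(out, "D_inf_ratio") <- D / Dinf
  }
  out
}

#' Cumulative distribution of squared displacements
#'
#' Empirical \eqn{\Pi(r^2, \Delta)}: the fraction of (overlapping) origins
#' whose squared displacement after lag \eqn{\Delta} is at most \eqn{r^2}.
#' For 2D Gaussian diffusion \eqn{\Pi = 1 - \exp[-r^2/(4D_\alpha
#' \Delta^\alpha)]}, so \eqn{-\log(1-\Pi)} scales as \eqn{r^2}.
#'
#' @param traj a [trajectory2d()].
#' @param lag lag \eqn{\Delta} (ps), a multiple of the sampling step.
#' @param min_origins minimum number of origins for a stable empirical CDF.
#' @return object of class `"gle_cdist"`: list with sorted `r2` (nm^2), `pi`
#'   values in (0, 1], `lag`, and `origins = "overlapping"` metadata.
#' @export
displacement_cdf <- function(traj, lag, min_origins = 100L) {
  stopifnot(inherits(traj, "gle_trajectory"))
  n <- nrow(traj$pos)
  m <- .lag_index(lag, traj$dt, n)
  if (length(m) != 1L) stop("lag must be a single value")
  k <- n - m
  if (k < min_origins)
    stop("insufficient origins (", k, " < ", min_origins, ") at this lag")
  d <- traj$pos[(m + 1):n, , drop = FALSE] - traj$pos[1:k, , drop = FALSE]
  r2 <- sort(d[, 1]^2 + d[, 2]^2)
  structure(list(r2 = r2, pi = seq_len(k) / k, lag = m * traj$dt,
                 origins = "overlapping"),
            class = "gle_cdist")
}

#' @export
print.gle_cdist <- function(x, ...) {
  cat(sprintf("<gle_cdist> Pi(r^2, Delta = %g ps), %d overlapping origins\n",
              x$lag, length(x$r2)))
  invisible(x)
}

#' Gaussianity exponent of the displacement distribution
#'
#' Least-squares slope of \eqn{\log[-\log(1-\Pi)]} against \eqn{\log r} over
#' a central quantile window (default 10-90%).  Gaussian (Brownian or
#' fractional-Brownian) displacements give slope 2; heavy-tailed mixtures
#' deviate.
#'
#' @param cdist a [displacement_cdf()] result.
#' @param quantile_window central window of \eqn{\Pi} used in the regression.
#' @return slope estimate (dimensionless).
#' @export
gaussianity_exponent <- function(cdist, quantile_window = c(0.1, 0.9)) {
  stopifnot(inherits(cdist, "gle_cdist"))
  keep <- cdist$pi >= quantile_window[1] & cdist$pi <= quantile_window[2] &
    cdist$r2 > 0
  if (sum(keep) < 10L) stop("quantile window contains too few points")
  y <- log(-log(1 - cdist$pi[keep]))
  x <- 0.5 * log(cdist$r2[keep])          # log r
  unname(stats::coef(stats::lm(y ~ x))[2])
}

#' Mass-weighted group average of observable curves
#'
#' \eqn{\sum_i m_i c_i(t) / \sum_i m_i} over curves on identical lag grids —
#' the average representative curve of a group of lipids.
#'
#' @param curves list of [observable_curve()]s on one common lag grid.
#' @param masses positive weights (g/mol).
#' @return an [observable_curve()] of the same kind.
#' @export
group_average <- function(curves, masses) {
  if (length(curves) != length(masses) || any(masses <= 0))
    stop("need one positive mass per curve")
  t0 <- curves[[1]]$time
  for (cv in curves)
    if (length(cv$time) != length(t0) || any(cv$time != t0))
      stop("curves must share an identical lag grid")
  vals <- vapply(curves, function(cv) cv$value, numeric(length(t0)))
  w <- masses / sum(masses)
  observable_curve(t0, as.numeric(vals %*% w), attr(curves[[1]], "kind"))
}

#' Residence-time selection of NEAR particles
#'
#' Ranks particles by the fraction of frames spent within a threshold
#' distance of a reference (e.g. the protein center of mass) and returns the
#' `count` longest residents; ties are broken in favor of the lower particle
#' index.
#'
#' @param distances frames x particles matrix of distances (nm).
#' @param threshold shell radius (nm), e.g. 3.
#' @param count number of particles to select.
#' @return integer vector of particle indices (columns of `distances`).
#' @export
select_near <- function(distances, threshold = 3, count) {
  distances <- as.matrix(distances)
  if (threshold <= 0) stop("threshold must be positive")
  np <- ncol(distances)
  if (count > np) stop("count exceeds the number of particles")
  res <- colMeans(distances < threshold)
  ord <- order(-res, seq_len(np))
  sort(ord[seq_len(count)])
}
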