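## Third-order echo observables in the second-order cumulant approximation.
##
## Frequency fluctuations are treated as Gaussian, so all spectroscopy
## follows from the lineshape function g(t), the double time-integral of
## the unnormalized frequency-time correlation function C(t):
##   g(t) = int_0^t dt' int_0^t' dt'' C(t'')       [C in rad^2/fs^2]
## The three rephasing pathways share the Condon two-level envelope
##   R(t1,t2,t3) ~ exp[-g(t1)+g(t2)-g(t3)-g(t1+t2)-g(t2+t3)+g(t1+t2+t3)]
## and the integrated echo intensity, its short-time slope in t1 (S3PE)
## and the normalized slope are
##   I(t1,t2) = int_0^t3max |3 R|^2 dt3,
##   S(t2) = dI/dt1 at t1 = 0,   C(t2) = S(t2)/S(0).

#' Lineshape function from an unnormalized FTCF
#'
#' Converts the frequency-fluctuation correlation from cm^-2 to angular
#' units, (2 pi c)^2 rad^2/fs^2, resamples it on a fine uniform grid, and
#' integrates twice by cumulative trapezoids.  The classical
#' (high-temperature) treatment is used: the imaginary solvation part of
#' g is zero, so `g` is real with `g(0) = 0`, non-negative and
#' non-decreasing for any positive-semidefinite input correlation.
#'
#' @param ftcf A `tcf_curve` (unnormalized; `value[1]` is the variance) or
#'   data.frame with `lag_fs` and `value`, on a uniform lag grid.
#' @param units Units of `value`: `"cm2"` (default; converted) or
#'   `"rad2fs2"` (used as is).
#' @param dt_fine Quadrature step (fs, default 1).
#' @return A `lineshape_fn`: list with `t_grid` (fs), `g` (dimensionless),
#'   `delta2` (lag-0 variance in rad^2/fs^2).
#' @export
lineshape <- function(ftcf, units = c("cm2", "rad2fs2"), dt_fine = 1) {
  units <- match.arg(units)
  lag <- ftcf$lag_fs
  val <- ftcf$value
  if (length(lag) < 2) stop("FTCF needs at least 2 lags")
  steps <- diff(lag)
  if (any(abs(steps - steps[1]) > 1e-9 * steps[1]))
    stop("non-uniform lag grid")
  if (units == "cm2") val <- val * (2 * pi * C_CM_PER_FS)^2
  t_grid <- seq(0, lag[length(lag)], by = dt_fine)
  C_fine <- if (length(lag) > 3) stats::spline(lag, val, xout = t_grid)$y
            else stats::approx(lag, val, xout = t_grid)$y
  ## exact reduction of the double integral to single integrals,
  ##   g(t) = t * int_0^t C(s) ds - int_0^t s C(s) ds,
  ## each by endpoint-corrected (Euler-Maclaurin) trapezoid: the plain
  ## trapezoid is only O(dt/tau) accurate relative to g near t = 0 where
  ## g ~ t^2
  H <- cumtrapz_em(t_grid, C_fine)
  M <- cumtrapz_em(t_grid, t_grid * C_fine)
  structure(list(t_grid = t_grid, g = t_grid * H - M, delta2 = val[1]),
            class = "lineshape_fn")
}

## cumulative trapezoid with Euler-Maclaurin endpoint correction
## (4th-order for smooth integrands on a uniform grid)
cumtrapz_em <- function(x, y) {
  n <- length(y)
  h <- x[2] - x[1]
  d <- c((-3 * y[1] + 4 * y[2] - y[3]) / (2 * h),
         (y[-(1:2)] - y[1:(n - 2)]) / (2 * h),
         (3 * y[n] - 4 * y[n - 1] + y[n - 2]) / (2 * h))
  pracma::cumtrapz(x, y)[, 1] - h^2 / 12 * (d - d[1])
}

## linear interpolant of g(t); error outside the computed range
g_interp <- function(ls) {
  stats::approxfun(ls$t_grid, ls$g, rule = 1)
}

#' Integrated three-pulse echo intensity
#'
#' Evaluates `I(t1, t2) = int_0^t3max |sum_i R_i|^2 dt3` on the given
#' coherence/waiting-time grids, with the three rephasing pathways in the
#' Condon two-level cumulant form (all sharing the same envelope).  The
#' lineshape must cover `max(t1) + max(t2) + t3_max`.  The integral is a
#' trapezoid over `t3`; if for any grid point the integrand tail at
#' `t3_max` exceeds 1e-3 of its peak, a truncation warning is recorded on
#' the result (`truncation_ok = FALSE`).
#'
#' @param ls A `lineshape_fn`.
#' @param t1_grid,t2_grid Coherence and waiting times (fs).
#' @param t3_max Upper limit of the detection-time integral (fs, default
#'   2000).
#' @param dt3 Detection-time quadrature step (fs, default 2).
#' @return An `echo_surface`: list with `t1_grid`, `t2_grid`, `I` (matrix,
#'   t1 rows x t2 cols, non-negative), `t3_max`, `truncation_ok`,
#'   `max_tail_ratio`.
#' @export
echo_intensity <- function(ls, t1_grid, t2_grid, t3_max = 2000, dt3 = 2) {
  stopifnot(inherits(ls, "lineshape_fn"))
  need <- max(t1_grid) + max(t2_grid) + t3_max
  if (need > max(ls$t_grid) + 1e-9)
    stop("lineshape covers only ", max(ls$t_grid), " fs but ", need,
         " fs are required (t1_max + t2_max + t3_max)")
  g <- g_interp(ls)
  t3 <- seq(0, t3_max, by = dt3)
  I <- matrix(NA_real_, length(t1_grid), length(t2_grid))
  max_tail <- 0
  for (j in seq_along(t2_grid)) {
    t2 <- t2_grid[j]
    g2 <- g(t2)
    g23 <- g(t2 + t3)
    for (i in seq_along(t1_grid)) {
      t1 <- t1_grid[i]
      env <- exp(-g(t1) + g2 - g(t3) - g(t1 + t2) - g23 + g(t1 + t2 + t3))
      integrand <- (3 * env)^2
      I[i, j] <- pracma::trapz(t3, integrand)
      max_tail <- max(max_tail,
                      integrand[length(integrand)] / max(integrand))
    }
  }
  structure(list(t1_grid = t1_grid, t2_grid = t2_grid, I = I,
                 t3_max = t3_max, truncation_ok = max_tail <= 1e-3,
                 max_tail_ratio = max_tail),
            class = "echo_surface")
}

#' Short-time slope of the echo intensity (S3PE)
#'
#' `S(t2)` is the partial derivative of the integrated echo intensity with
#' respect to the first coherence time at `t1 = 0`, evaluated by a
#' one-sided second-order finite difference over the first three `t1` grid
#' points (which must be uniformly spaced).  The normalized curve is
#' `C(t2) = S(t2) / S(0)`.
#'
#' @param surface An `echo_surface` whose `t1_grid` starts at 0 with at
#'   least three uniformly spaced points.
#' @param fit Fit the normalized curve with [fit_biexp()] (default `TRUE`).
#' @param ... Passed to [fit_biexp()].
#' @return An `s3pe_curve`: data.frame with columns `t2_fs`, `S`, `C`
#'   (`C[1] = 1`); attribute `fit` (a `biexp_fit` or `NULL`).
#' @export
s3pe <- function(surface, fit = TRUE, ...) {
  stopifnot(inherits(surface, "echo_surface"))
  t1 <- surface$t1_grid
  if (length(t1) < 3 || abs(t1[1]) > 1e-9)
    stop("t1_grid must start at 0 with at least 3 points")
  d1 <- diff(t1[1:3])
  if (abs(d1[1] - d1[2]) > 1e-9) stop("first three t1 points must be uniform")
  dt1 <- d1[1]
  S <- (-3 * surface$I[1, ] + 4 * surface$I[2, ] - surface$I[3, ]) / (2 * dt1)
  if (S[1] == 0) stop("cannot normalize: S(0) = 0")
  out <- data.frame(t2_fs = surface$t2_grid, S = S, C = S / S[1])
  f <- NULL
  if (fit)
    f <- fit_biexp(data.frame(lag_fs = out$t2_fs, value = out$C), ...)
  structure(out, fit = f, class = c("s3pe_curve", "data.frame"))
}

#' Rescale an observable TCF to frequency units
#'
#' An observable linearly coupled to the OH frequency,
#' `y = intercept + slope * omega + noise`, has fluctuation correlation
#' `C_y(t) = slope^2 * C_omega(t)` (plus a lag-0 noise spike).  Dividing an
#' unnormalized HBCF or CTCF by `slope^2` therefore converts it to cm^-2 so
#' the cumulant echo pipeline can run on HB-strength or charge-transfer
#' fluctuations in place of frequencies.
#'
#' Because the map residual is uncorrelated between frames it contributes
#' a lag-0 nugget that would inflate the apparent dephasing amplitude;
#' [denoise_lag0()] is applied by default before rescaling.
#'
#' @param curve An unnormalized `tcf_curve` in the observable's units^2.
#' @param map The fitted `linear_map` relating the observable to frequency.
#' @param denoise Remove the lag-0 scatter nugget first (default `TRUE`).
#' @return A `tcf_curve` in cm^-2, flagged with attribute
#'   `rescaled_from = map$y_kind`.
#' @export
rescale_tcf_to_frequency <- function(curve, map, denoise = TRUE) {
  if (isTRUE(attr(curve, "normalized")))
    stop("curve must be unnormalized to carry units")
  if (!is.finite(map$slope) || map$slope == 0)
    stop("map slope must be nonzero")
  if (denoise) curve <- denoise_lag0(curve)
  out <- curve
  out$value <- curve$value / map$slope^2
  if (!is.null(out$stderr)) out$stderr <- out$stderr / map$slope^2
  attr(out, "C0") <- attr(curve, "C0") / map$slope^2
  attr(out, "rescaled_from") <- map$y_kind
  out
}

#' Full S3PE pipeline from an FTCF
#'
#' Chains [lineshape()], [echo_intensity()] and [s3pe()] with the default
#' grids: `t1 = (0, dt1, 2 dt1)`, `t2` on the FTCF lag grid subsampled to
#' at most `n_t2` points, and detection integral to `t3_max`.
#'
#' @param ftcf Unnormalized FTCF (`tcf_curve`, cm^-2) covering at least
#'   `2 dt1 + t2_max + t3_max` fs of lag.
#' @param dt1 Finite-difference step for the slope (fs, default 2).
#' @param t2_max Largest waiting time (fs); default 40% of the FTCF lag
#'   range.
#' @param n_t2 Maximum number of waiting-time points (default 100).
#' @param t3_max,dt3 Detection integral truncation and step (fs).
#' @param dt_fine Lineshape quadrature step (fs).
#' @param fit Fit the normalized S3PE with [fit_biexp()].
#' @param units_in Units of the FTCF values, as in [lineshape()].
#' @return List with `lineshape`, `surface` and `curve` (an `s3pe_curve`).
#' @export
s3pe_from_ftcf <- function(ftcf, dt1 = 2, t2_max = NULL, n_t2 = 100,
                           t3_max = 2000, dt3 = 2, dt_fine = 1, fit = TRUE,
                           units_in = "cm2") {
  lag_max <- max(ftcf$lag_fs)
  if (is.null(t2_max)) t2_max <- 0.4 * lag_max
  if (2 * dt1 + t2_max + t3_max > lag_max)
    stop("FTCF lag range (", lag_max, " fs) too short for t2_max + t3_max")
  ls <- lineshape(ftcf, units = units_in, dt_fine = dt_fine)
  lag2 <- ftcf$lag_fs[ftcf$lag_fs <= t2_max]
  stride <- max(1L, ceiling(length(lag2) / n_t2))
  t2_grid <- lag2[seq(1L, length(lag2), by = stride)]
  surface <- echo_intensity(ls, t1_grid = c(0, dt1, 2 * dt1),
                            t2_grid = t2_grid, t3_max = t3_max, dt3 = dt3)
  list(lineshape = ls, surface = surface,
       curve = s3pe(surface, fit = fit))
}

#' Write an S3PE curve as TSV
#'
#' @param curve An `s3pe_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_s3pe <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
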