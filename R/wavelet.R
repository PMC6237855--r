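## Continuous wavelet transform instantaneous frequencies.
##
## Mother wavelet (Morlet-Grossman form):
##   psi(t) = (sigma^2 * pi)^(-1/4) * exp(2*pi*i*lambda*t) * exp(-t^2 / (2*sigma^2))
## The transform of a uniformly sampled series f, at scale a (in samples)
## and analysis time b (sample index), is the discrete quadrature of
##   L_psi f(a, b) = a^(-1/2) * sum_t f(t) * Conj(psi((t - b)/a)) * dt
## truncated at |t - b| > 4*a*sigma.  A scale a maps to the wavenumber
##   nu = lambda / (a * dt * c)   [cm^-1]

#' Wavelet analysis parameters
#'
#' Builds the parameter set for the Morlet-Grossman continuous wavelet
#' transform: mother-wavelet oscillation parameter `lambda`, Gaussian
#' envelope width `sigma`, and a geometric grid of `n_scales` scales
#' spanning the admissible frequency window `window_cm`.
#'
#' @param dt Sampling interval of the series to be analysed (fs).
#' @param lambda Oscillation parameter of the mother wavelet (default 1).
#' @param sigma Envelope width (default 2).
#' @param window_cm Length-2 admissible frequency window in cm^-1
#'   (default `c(2800, 4000)`, covering the OH stretch band of liquid water).
#' @param n_scales Number of scales (default 256, sub-5-cm^-1 resolution
#'   over the default window).
#' @return A `wavelet_params` object with the strictly increasing
#'   `scale_grid` (dimensionless, in units of samples).
#' @export
wavelet_params <- function(dt, lambda = 1, sigma = 2,
                           window_cm = c(2800, 4000), n_scales = 256) {
  stopifnot(dt > 0, lambda > 0, sigma > 0, n_scales >= 2)
  if (!(is.numeric(window_cm) && length(window_cm) == 2 &&
        window_cm[1] < window_cm[2] && window_cm[1] > 0))
    stop("window_cm must be c(lo, hi) with 0 < lo < hi")
  ## high frequency <-> small scale; geometric grid, strictly increasing in a
  a_lo <- lambda / (window_cm[2] * C_CM_PER_FS * dt)
  a_hi <- lambda / (window_cm[1] * C_CM_PER_FS * dt)
  structure(
    list(lambda = lambda, sigma = sigma, window_cm = window_cm,
         scale_grid = exp(seq(log(a_lo), log(a_hi), length.out = n_scales)),
         dt = dt),
    class = "wavelet_params")
}

#' Convert a wavelet scale to a wavenumber
#'
#' The scaled wavelet oscillates at `lambda / a` cycles per sample, i.e.
#' `lambda / (a * dt)` cycles per fs; division by the speed of light gives
#' cm^-1.  Strictly decreasing and bijective in `a`.
#'
#' @param a Scale(s), dimensionless (samples), > 0.
#' @param params A `wavelet_params` object.
#' @param dt Sampling interval (fs); defaults to the one stored in `params`.
#' @return Wavenumber(s) in cm^-1.
#' @seealso [cm_to_scale()] for the inverse.
#' @export
scale_to_cm <- function(a, params, dt = params$dt) {
  if (any(a <= 0)) stop("scale a must be > 0")
  params$lambda / (a * dt * C_CM_PER_FS)
}

#' @rdname scale_to_cm
#' @param nu_cm Wavenumber(s) in cm^-1, > 0.
#' @export
cm_to_scale <- function(nu_cm, params, dt = params$dt) {
  if (any(nu_cm <= 0)) stop("wavenumber must be > 0")
  params$lambda / (nu_cm * dt * C_CM_PER_FS)
}

## mother wavelet evaluated at dimensionless argument u
morlet_grossman <- function(u, lambda, sigma) {
  (sigma^2 * pi)^(-0.25) * exp(2i * pi * lambda * u - u^2 / (2 * sigma^2))
}

#' Continuous wavelet transform of a complex series
#'
#' Computes `L_psi f(a, b)` on the full scale grid for every sample time `b`
#' (FFT-based convolution per scale; the wavelet is truncated at
#' `|t - b| > 4 a sigma`).
#'
#' @param signal Complex (or numeric) vector, sampled uniformly at `dt`.
#' @param params A `wavelet_params` object.
#' @param b Optional vector of analysis times (fs) at which to return
#'   coefficients; default all sample times.  Times outside the sampled
#'   interval are an error.
#' @return A `cwt_result`: list with `coef` (matrix, scales x times),
#'   `scales`, `t_fs` (analysis times), `edge` (logical, TRUE where the
#'   truncated wavelet support at the largest scale is clipped by the ends
#'   of the series).
#' @export
cwt <- function(signal, params, b = NULL) {
  stopifnot(inherits(params, "wavelet_params"))
  n <- length(signal)
  dt <- params$dt
  t_all <- (seq_len(n) - 1) * dt
  if (is.null(b)) b <- t_all
  if (any(b < 0 | b > t_all[n]))
    stop("analysis time b outside the sampled interval [0, ", t_all[n], "] fs")
  bi <- round(b / dt) + 1L
  scales <- params$scale_grid
  half_max <- ceiling(4 * scales[length(scales)] * params$sigma)
  nfft <- stats::nextn(n + 2L * half_max + 1L, 2)
  fs <- stats::fft(c(as.complex(signal), complex(nfft - n)))
  coef <- matrix(NA_complex_, length(scales), length(bi))
  for (k in seq_along(scales)) {
    a <- scales[k]
    half <- ceiling(4 * a * params$sigma)
    j <- seq(-half, half)
    ker <- Conj(morlet_grossman(j / a, params$lambda, params$sigma)) *
      dt / sqrt(a)
    ## circular cross-correlation: out[b] = sum_j signal[b + j] * ker[j],
    ## via out = ifft( fft(s) * Conj(fft(Conj(ker))) )
    kfull <- complex(nfft)
    kfull[1L + (j %% nfft)] <- ker
    kq <- Conj(stats::fft(Conj(kfull)))
    conv <- stats::fft(fs * kq, inverse = TRUE) / nfft
    coef[k, ] <- conv[bi]
  }
  edge <- bi - 1L < half_max | n - bi < half_max
  structure(list(coef = coef, scales = scales, t_fs = (bi - 1) * dt,
                 edge = edge, params = params),
            class = "cwt_result")
}

#' Instantaneous OH stretch frequency track from one mode
#'
#' Builds the complex phase-space signal
#' `f(t) = dr(t) - i * dp(t) / (mu * wbar)` from the mean-removed bond
#' length and momentum of an `oh_mode` (with `wbar` a fixed scaling angular
#' frequency taken at the window centre, making the two parts commensurate
#' so the signal rotates at +omega for a harmonic mode), transforms it on
#' the scale grid, and at each analysis time reports the wavenumber of the
#' scale maximizing the amplitude-normalized modulus of the transform.
#'
#' Times whose argmax falls on the boundary of the scale grid are flagged
#' (`boundary`), as are times where the wavelet support is clipped by the
#' ends of the series (`edge`); neither is silently dropped.
#'
#' @param mode An `oh_mode` (see [extract_oh_modes()]).
#' @param params A `wavelet_params` object built with the mode's `dt`.
#' @param stride Analysis stride in frames (default 1).
#' @return A `freq_track`: data.frame with columns `t_fs`, `omega_cm`,
#'   `modulus`, `boundary`, `edge`; attributes `mode_id` and `params`.
#' @export
instantaneous_frequency <- function(mode, params, stride = 1L) {
  stopifnot(inherits(mode, "oh_mode"), inherits(params, "wavelet_params"))
  if (abs(params$dt - mode$dt) > 1e-9)
    stop("params built for dt = ", params$dt, " fs but mode sampled at ",
         mode$dt, " fs")
  wbar <- cm_to_radfs(mean(params$window_cm))
  dr <- mode$bond_length - mean(mode$bond_length)
  dp <- mode$bond_momentum - mean(mode$bond_momentum)
  sig <- complex(real = dr, imaginary = -dp / (mode$mu * wbar))
  n <- length(sig)
  bi <- seq(1L, n, by = as.integer(stride))
  res <- cwt(sig, params, b = (bi - 1) * params$dt)
  ## amplitude-normalized modulus: removes the a^(1/2) bias of |L| so the
  ## pure-tone argmax sits on the true scale (see vignette)
  amp <- abs(res$coef) / sqrt(res$scales)
  k <- apply(amp, 2, which.max)
  track <- data.frame(
    t_fs = res$t_fs,
    omega_cm = scale_to_cm(res$scales[k], params),
    modulus = abs(res$coef)[cbind(k, seq_along(k))],
    boundary = k == 1L | k == length(res$scales),
    edge = res$edge)
  attr(track, "mode_id") <- mode$mode_id
  attr(track, "params") <- params
  class(track) <- c("freq_track", "data.frame")
  track
}

#' Frequency tracks for all OH modes of a trajectory
#'
#' Convenience wrapper applying [instantaneous_frequency()] to every mode
#' returned by [extract_oh_modes()].
#'
#' @inheritParams instantaneous_frequency
#' @param traj A `water_trajectory` with velocities.
#' @param params A `wavelet_params`; defaults to `wavelet_params(traj$dt)`.
#' @return List of `freq_track` objects (2 per molecule).
#' @export
frequency_tracks <- function(traj, params = wavelet_params(traj$dt),
                             stride = 1L) {
  lapply(extract_oh_modes(traj), instantaneous_frequency,
         params = params, stride = stride)
}

#' Write frequency tracks as TSV
#'
#' Columns: `time_fs`, `molecule`, `H`, `omega_cm`, `modulus`, `boundary`,
#' `edge`.
#'
#' @param tracks A `freq_track` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  if (inherits(tracks, "freq_track")) tracks <- list(tracks)
  tab <- do.call(rbind, lapply(tracks, function(tr) {
    id <- attr(tr, "mode_id")
    data.frame(time_fs = tr$t_fs, molecule = id[[1]], H = id[[2]],
               omega_cm = tr$omega_cm, modulus = tr$modulus,
               boundary = tr$boundary, edge = tr$edge)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
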