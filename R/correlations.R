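## Time-correlation engine: generic fluctuation TCFs (HBCF, CTCF, FTCF,
## LSRI-TCF), the continuous hydrogen-bond correlation S_HB, the HB-number
## correlation N_HB, bi-exponential fitting and block-averaged errors.
##
## Series are passed as a numeric matrix with one column per entity (OH
## mode or HB pair) and one row per frame; NA marks frames where the
## entity is absent (e.g. pair not hydrogen-bonded).  Absent stretches are
## never zero-filled: only contiguous present segments contribute.

as_series_matrix <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    n <- max(lengths(x))
    x <- vapply(x, function(v) c(v, rep(NA_real_, n - length(v))), numeric(n))
  }
  as.matrix(x)
}

## linear autocorrelation sums of a gap-free real segment via FFT:
## sums[k+1] = sum_t x[t] x[t+k], counts[k+1] = L - k
segment_acf_sums <- function(x, max_k) {
  L <- length(x)
  nfft <- stats::nextn(L + max_k + 1L, 2)
  S <- stats::fft(c(x, numeric(nfft - L)))
  raw <- Re(stats::fft(S * Conj(S), inverse = TRUE)) / nfft
  raw[seq_len(max_k + 1L)]
}

#' Time-correlation function of fluctuation series
#'
#' Computes `C(t) = < x(0) x(t) >` averaged over time origins and entities,
#' pooling all (entity, origin) products per lag.  Entities with gaps (`NA`)
#' contribute only their contiguous present segments.  By default the
#' per-entity mean over its present frames is removed first (fluctuation
#' correlation); set `center = FALSE` for the uncentred form.
#'
#' @param x Series: numeric matrix (frames x entities), vector, or list of
#'   vectors.  `NA` marks absence.
#' @param dt Frame spacing (fs).
#' @param max_lag Largest lag (fs); must be shorter than the series.
#' @param center Mean removal before correlating: `"ensemble"` (default;
#'   the pooled mean over all entities and present frames, matching the
#'   ensemble-average reading of `<x>` and nearly free of the finite-record
#'   bias that per-entity sample means introduce when the record is only a
#'   few tens of correlation times long), `"entity"` (per-entity sample
#'   mean), or `"none"` for the uncentred form.  `TRUE`/`FALSE` map to
#'   `"ensemble"`/`"none"`.
#' @param normalize Divide by `C(0)` (default `FALSE`).
#' @param n_blocks If not `NULL`, also estimate a per-lag standard error by
#'   splitting the frames into this many contiguous blocks.
#' @param kind Label stored on the curve (e.g. `"FTCF"`, `"HBCF"`).
#' @return A `tcf_curve`: data.frame with columns `lag_fs`, `value` (and
#'   `stderr` when `n_blocks` is given); attributes `kind`, `normalized`,
#'   `C0` (the lag-0 value before normalization) and `dt`.
#' @export
tcf <- function(x, dt, max_lag, center = "ensemble", normalize = FALSE,
                n_blocks = NULL, kind = "TCF") {
  if (is.logical(center)) center <- if (center) "ensemble" else "none"
  center <- match.arg(center, c("ensemble", "entity", "none"))
  x <- as_series_matrix(x)
  n <- nrow(x)
  max_k <- as.integer(round(max_lag / dt))
  if (max_k >= n) stop("max_lag (", max_lag, " fs) must be shorter than the ",
                       "series (", (n - 1) * dt, " fs)")
  acc <- tcf_sums(x, max_k, center)
  if (acc$counts[1] == 0) stop("no data: all entities are entirely absent")
  values <- ifelse(acc$counts > 0, acc$sums / acc$counts, NA_real_)
  C0 <- values[1]
  if (normalize) {
    if (!is.finite(C0) || C0 == 0) stop("cannot normalize: C(0) is zero")
    values <- values / C0
  }
  out <- data.frame(lag_fs = (0:max_k) * dt, value = values)
  if (!is.null(n_blocks)) {
    blocks <- block_frame_ranges(n, n_blocks)
    bvals <- vapply(blocks, function(rg) {
      a <- tcf_sums(x[rg[1]:rg[2], , drop = FALSE], max_k, center)
      v <- ifelse(a$counts > 0, a$sums / a$counts, NA_real_)
      if (normalize) v <- v / v[1]
      v
    }, numeric(max_k + 1L))
    out$stderr <- apply(bvals, 1, stats::sd) / sqrt(length(blocks))
  }
  structure(out, kind = kind, normalized = normalize, C0 = C0, dt = dt,
            class = c("tcf_curve", "data.frame"))
}

tcf_sums <- function(x, max_k, center) {
  sums <- numeric(max_k + 1L)
  counts <- numeric(max_k + 1L)
  if (center == "ensemble") x <- x - mean(x, na.rm = TRUE)
  for (e in seq_len(ncol(x))) {
    col <- x[, e]
    pres <- !is.na(col)
    if (!any(pres)) next
    if (center == "entity") col <- col - mean(col[pres])
    r <- rle(pres)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (s in which(r$values)) {
      seg <- col[starts[s]:ends[s]]
      L <- length(seg)
      k <- min(max_k, L - 1L)
      sums[1:(k + 1L)] <- sums[1:(k + 1L)] + segment_acf_sums(seg, k)
      counts[1:(k + 1L)] <- counts[1:(k + 1L)] + (L - 0:k)
    }
  }
  list(sums = sums, counts = counts)
}

block_frame_ranges <- function(n, n_blocks) {
  if (n_blocks < 2) stop("n_blocks must be >= 2")
  edges <- floor(seq(0, n, length.out = n_blocks + 1L))
  lapply(seq_len(n_blocks), function(b) c(edges[b] + 1L, edges[b + 1L]))
}

## pair indicator matrix (frames x pairs) from an HB record data.frame
hb_indicator <- function(records, n_frames = NULL) {
  if (is.null(n_frames)) n_frames <- attr(records, "n_frames")
  if (is.null(n_frames)) n_frames <- max(records$frame)
  key <- paste(records$donor_mol, records$donor_H, records$acceptor_mol,
               sep = "/")
  pairs <- unique(key)
  h <- matrix(FALSE, n_frames, length(pairs))
  h[cbind(records$frame, match(key, pairs))] <- TRUE
  colnames(h) <- pairs
  h
}

#' Continuous hydrogen-bond correlation function S_HB
#'
#' `S_HB(t)` is the probability that a pair hydrogen-bonded at a time
#' origin remains continuously bonded through every frame up to lag `t`
#' (no transient breaks allowed unless `allowance > 0` frames of
#' interruption are tolerated).  Time origins are restricted to
#' `t0 <= T - max_lag` so the curve is exactly non-increasing, bounded in
#' [0, 1], and free of end-of-record censoring.
#'
#' @param records HB record data.frame (columns `frame`, `donor_mol`,
#'   `donor_H`, `acceptor_mol`), as produced by [assign_hbonds()] or
#'   [gen_markov_hbonds()].
#' @param dt Frame spacing (fs).
#' @param max_lag Largest lag (fs).
#' @param n_frames Total number of frames (defaults to the `n_frames`
#'   attribute of `records`, else the largest frame index).
#' @param allowance Number of broken frames tolerated inside a "continuous"
#'   bond (default 0, the strictly continuous definition).
#' @return A `tcf_curve` with `kind = "S_HB"`, normalized
#'   (`S_HB(0) = 1`).
#' @export
s_hb <- function(records, dt, max_lag, n_frames = NULL, allowance = 0L) {
  h <- hb_indicator(records, n_frames)
  if (!any(h)) stop("no HBs present in the record list")
  if (allowance > 0L) h <- fill_short_breaks(h, allowance)
  n <- nrow(h)
  max_k <- as.integer(round(max_lag / dt))
  if (max_k >= n) stop("max_lag must be shorter than the record list")
  cnt <- s_hb_rem_counts(h, n - max_k, max_k)
  den <- sum(cnt)
  if (den == 0) stop("no bonded origins in the usable window")
  num <- rev(cumsum(rev(cnt)))
  structure(data.frame(lag_fs = (0:max_k) * dt, value = num / den),
            kind = "S_HB", normalized = TRUE, C0 = 1, dt = dt,
            class = c("tcf_curve", "data.frame"))
}

## counts of bonded origins (t0 <= t_max) by remaining continuous lifetime,
## capped at max_k; cnt[j+1] = #origins with min(remaining, max_k) == j
s_hb_rem_counts <- function(h, t_max, max_k) {
  cnt <- numeric(max_k + 1L)
  for (p in seq_len(ncol(h))) {
    r <- rle(h[, p])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (s in which(r$values)) {
      if (starts[s] > t_max) next
      t0 <- starts[s]:min(ends[s], t_max)
      rem <- pmin(ends[s] - t0, max_k)
      cnt <- cnt + tabulate(rem + 1L, nbins = max_k + 1L)
    }
  }
  cnt
}

fill_short_breaks <- function(h, allowance) {
  apply(h, 2, function(col) {
    r <- rle(col)
    short <- !r$values & r$lengths <= allowance
    ## interior short breaks only
    short[c(1, length(short))] <- FALSE
    r$values[short] <- TRUE
    inverse.rle(r)
  })
}

#' Hydrogen-bond number correlation function N_HB
#'
#' Per-molecule HB counts `n(t)` (bonds donated plus accepted) are formed
#' from the records; the normalized autocorrelation of the fluctuations
#' `dn = n - <n>` is returned:
#' `C(t) = <dn(t) dn(0)> / <dn^2>`, so `C(0) = 1` exactly.
#'
#' @inheritParams s_hb
#' @param n_molecules Number of molecules (defaults to the largest molecule
#'   index appearing in the records).
#' @return A `tcf_curve` with `kind = "N_HB"`, normalized.
#' @export
n_hb <- function(records, dt, max_lag, n_frames = NULL, n_molecules = NULL) {
  if (is.null(n_frames)) n_frames <- attr(records, "n_frames")
  if (is.null(n_frames)) n_frames <- max(records$frame)
  if (is.null(n_molecules))
    n_molecules <- max(records$donor_mol, records$acceptor_mol)
  counts <- matrix(0, n_frames, n_molecules)
  add <- function(mol) {
    t <- tapply(rep(1, length(mol)), list(records$frame, mol), sum)
    idx <- cbind(as.integer(rownames(t)[row(t)]),
                 as.integer(colnames(t)[col(t)]))
    ok <- !is.na(t)
    counts[idx[ok, , drop = FALSE]] <<-
      counts[idx[ok, , drop = FALSE]] + t[ok]
  }
  add(records$donor_mol)
  add(records$acceptor_mol)
  vars <- apply(counts, 2, stats::var)
  if (all(vars == 0))
    stop("zero variance: every molecule has a constant HB count")
  tcf(counts, dt = dt, max_lag = max_lag, center = TRUE, normalize = TRUE,
      kind = "N_HB")
}

#' Bi-exponential fit of a correlation decay
#'
#' Least-squares fit of `f(t) = a0 exp(-t/tau0) + (1 - a0) exp(-t/tau1)` to
#' a normalized correlation curve, by Levenberg-Marquardt
#' ([minpack.lm::nls.lm()]) with a multistart grid over
#' `tau0 in {0.02, 0.05, 0.1} ps`, `tau1 in {0.5, 1, 2} ps` and
#' `a0 in {0.3, 0.7}`, bounds `a0 in [0, 1]`, `tau > 0`.  The two time
#' constants are ordered `tau0 <= tau1` after the fit (amplitudes swapped
#' accordingly).
#'
#' @param curve A `tcf_curve` (or data.frame with `lag_fs` and `value`).
#' @param t_min,t_max Fit window (fs).  Default window is 0 to
#'   `min(4000, 0.4 * max lag)` fs, since long-lag estimates are noisy.
#' @return A `biexp_fit`: list with `a0`, `tau0_ps`, `tau1_ps`, `sse`,
#'   `covariance` (3x3, order a0/tau0/tau1, `NA` when singular),
#'   `n_points`, `window_fs`.
#' @seealso [biexp_long_time()] for the dominant long-time constant.
#' @export
fit_biexp <- function(curve, t_min = 0, t_max = NULL) {
  lag <- curve$lag_fs
  if (is.null(t_max)) t_max <- min(4000, 0.4 * max(lag))
  sel <- lag >= t_min & lag <= t_max & is.finite(curve$value)
  if (sum(sel) < 3) stop("fit window contains fewer than 3 points")
  t_ps <- lag[sel] / 1000
  y <- curve$value[sel]
  model <- function(p, t) p[1] * exp(-t / p[2]) + (1 - p[1]) * exp(-t / p[3])
  resid_fn <- function(p) y - model(p, t_ps)
  starts <- expand.grid(a0 = c(0.3, 0.7), tau0 = c(0.02, 0.05, 0.1),
                        tau1 = c(0.5, 1, 2))
  best <- NULL
  msgs <- character()
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = as.numeric(starts[i, ]), fn = resid_fn,
        lower = c(0, 1e-4, 1e-4), upper = c(1, Inf, Inf),
        control = minpack.lm::nls.lm.control(
          ftol = 1e-14, ptol = 1e-12, maxiter = 500)),
      error = function(e) e)
    if (inherits(fit, "error")) { msgs <- c(msgs, conditionMessage(fit)); next }
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse - 1e-14 * max(1, best$sse))
      best <- list(fit = fit, sse = sse)
  }
  if (is.null(best))
    stop("bi-exponential fit failed to converge from every start: ",
         paste(unique(msgs), collapse = "; "))
  p <- best$fit$par
  a0 <- p[1]; tau0 <- p[2]; tau1 <- p[3]
  if (tau0 > tau1) { tmp <- tau0; tau0 <- tau1; tau1 <- tmp; a0 <- 1 - a0 }
  covm <- tryCatch({
    dof <- max(1, length(y) - 3)
    solve(best$fit$hessian) * 2 * best$sse / dof
  }, error = function(e) matrix(NA_real_, 3, 3))
  structure(list(a0 = a0, tau0_ps = tau0, tau1_ps = tau1, sse = best$sse,
                 covariance = covm, n_points = length(y),
                 window_fs = c(t_min, t_max)),
            class = "biexp_fit")
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat(sprintf(
    "biexp_fit: a0 = %.4f, tau0 = %.4g ps, tau1 = %.4g ps  (sse %.3g, n %d)\n",
    x$a0, x$tau0_ps, x$tau1_ps, x$sse, x$n_points))
  invisible(x)
}

#' Dominant long-time constant of a bi-exponential fit
#'
#' Returns `tau1` unless its amplitude `1 - a0` is negligible (below
#' `amp_tol`), in which case the decay is effectively single-exponential
#' and the active branch `tau0` is returned instead.  On noisy curves the
#' slow branch sometimes fits a flat noise floor with a huge time constant
#' and a vanishing amplitude; the amplitude threshold filters that
#' degenerate branch out.
#'
#' A `tau1` far beyond the fit window (more than `window_factor` times its
#' span) is likewise unidentifiable -- it parameterizes a constant offset,
#' not a decay -- and the `tau0` branch is reported instead.
#'
#' @param fit A `biexp_fit`.
#' @param amp_tol Amplitude below which a branch is considered inert
#'   (default 0.05).
#' @param window_factor Multiple of the fit-window span beyond which a
#'   time constant is treated as an offset (default 5).
#' @return Time constant in ps.
#' @export
biexp_long_time <- function(fit, amp_tol = 0.05, window_factor = 5) {
  span_ps <- diff(fit$window_fs) / 1000
  tail_resolved <- is.finite(fit$tau1_ps) &&
    fit$tau1_ps <= window_factor * span_ps
  if ((1 - fit$a0) < amp_tol || (!tail_resolved && fit$a0 >= amp_tol))
    fit$tau0_ps
  else fit$tau1_ps
}

#' Remove the lag-0 nugget of a correlation curve
#'
#' Frame-uncorrelated measurement scatter (for example the Gaussian
#' residual of a linear frequency map) contributes to a fluctuation TCF
#' only at lag 0, where it adds a spike ("nugget") on top of the smooth
#' dynamical correlation.  This replaces the lag-0 value by the quadratic
#' extrapolation of the next three lags back to zero, recovering the
#' dynamical variance.
#'
#' @param curve An unnormalized `tcf_curve` with at least 4 lags.
#' @return The curve with `value[1]` replaced; the original value is kept
#'   in attribute `raw_C0` and the removed nugget in `nugget`.
#' @export
denoise_lag0 <- function(curve) {
  if (nrow(curve) < 4) stop("need at least 4 lags to extrapolate")
  t <- curve$lag_fs[2:4]
  v <- curve$value[2:4]
  c0 <- sum(solve(cbind(1, t, t^2), v) * c(1, 0, 0))
  out <- curve
  attr(out, "raw_C0") <- curve$value[1]
  attr(out, "nugget") <- curve$value[1] - c0
  out$value[1] <- c0
  attr(out, "C0") <- c0
  out
}

#' Normalize a correlation curve by its lag-0 value
#'
#' @param curve An unnormalized `tcf_curve`.
#' @return The curve divided by `value[1]`, flagged normalized.
#' @export
normalize_tcf <- function(curve) {
  c0 <- curve$value[1]
  if (!is.finite(c0) || c0 == 0) stop("cannot normalize: C(0) is zero")
  out <- curve
  out$value <- curve$value / c0
  if (!is.null(out$stderr)) out$stderr <- out$stderr / c0
  attr(out, "normalized") <- TRUE
  out
}

#' Single-exponential fit of a correlation decay
#'
#' Least-squares fit of `a * exp(-t/tau)` (amplitude bounded in [0, 1.5])
#' to a normalized correlation curve -- the appropriate model when the
#' decay is a single relaxation, e.g. the survival and number correlations
#' of independent two-state bonds, for which a bi-exponential is
#' ill-posed.
#'
#' @inheritParams fit_biexp
#' @return An `exp_fit`: list with `a`, `tau_ps`, `sse`, `n_points`,
#'   `window_fs`.
#' @export
fit_exp <- function(curve, t_min = 0, t_max = NULL) {
  lag <- curve$lag_fs
  if (is.null(t_max)) t_max <- min(4000, 0.4 * max(lag))
  sel <- lag >= t_min & lag <= t_max & is.finite(curve$value)
  if (sum(sel) < 3) stop("fit window contains fewer than 3 points")
  t_ps <- lag[sel] / 1000
  y <- curve$value[sel]
  best <- NULL
  for (tau_start in c(0.2, 0.5, 1, 2)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(1, tau_start), fn = function(p)
          y - p[1] * exp(-t_ps / p[2]),
        lower = c(0, 1e-4), upper = c(1.5, Inf),
        control = minpack.lm::nls.lm.control(ftol = 1e-14, ptol = 1e-12,
                                             maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) stop("exponential fit failed to converge")
  structure(list(a = best$fit$par[1], tau_ps = best$fit$par[2],
                 sse = best$sse, n_points = length(y),
                 window_fs = c(t_min, t_max)),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("exp_fit: a = %.4f, tau = %.4g ps  (sse %.3g, n %d)\n",
              x$a, x$tau_ps, x$sse, x$n_points))
  invisible(x)
}

#' Evaluate the bi-exponential decay model
#'
#' @param t_fs Times (fs).
#' @param a0,tau0_ps,tau1_ps Model parameters.
#' @return `a0 exp(-t/tau0) + (1-a0) exp(-t/tau1)`.
#' @export
biexp_decay <- function(t_fs, a0, tau0_ps, tau1_ps) {
  t <- t_fs / 1000
  a0 * exp(-t / tau0_ps) + (1 - a0) * exp(-t / tau1_ps)
}

#' Block-averaged standard error of an estimator
#'
#' Splits the frames of a series into `n_blocks` contiguous blocks, applies
#' the estimator to each block, and reports the block estimates together
#' with their standard error `sd / sqrt(n_blocks)`.
#'
#' @param x Input sliced per block: a matrix / data.frame of per-frame rows,
#'   a vector, or an HB record data.frame with a `frame` column (sliced by
#'   frame ranges; the `n_frames` attribute, if present, defines the grid).
#' @param estimator Function applied to each block slice, returning a
#'   numeric scalar.
#' @param n_blocks Number of contiguous blocks (default 3).
#' @return List with `estimates` (length `n_blocks`), `mean` and `stderr`.
#' @export
block_errors <- function(x, estimator, n_blocks = 3) {
  is_records <- is.data.frame(x) && "frame" %in% names(x)
  n <- if (is_records) {
    nf <- attr(x, "n_frames")
    if (is.null(nf)) max(x$frame) else nf
  } else if (is.null(dim(x))) length(x) else nrow(x)
  ranges <- block_frame_ranges(n, n_blocks)
  est <- vapply(ranges, function(rg) {
    slice <- if (is_records) {
      s <- x[x$frame >= rg[1] & x$frame <= rg[2], , drop = FALSE]
      s$frame <- s$frame - rg[1] + 1L
      attr(s, "n_frames") <- rg[2] - rg[1] + 1L
      s
    } else if (is.null(dim(x))) x[rg[1]:rg[2]]
    else x[rg[1]:rg[2], , drop = FALSE]
    estimator(slice)
  }, numeric(1))
  list(estimates = est, mean = mean(est),
       stderr = stats::sd(est) / sqrt(n_blocks))
}

#' Write a TCF curve as TSV
#'
#' @param curve A `tcf_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tcf <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
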