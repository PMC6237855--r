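## Linear maps between OH stretch frequency and per-pair observables
## (HB strength dE, charge transfer dCT, LSRI), with RMSE, plus 2-D
## probability densities of the joined samples.

#' Ordinary least-squares frequency map
#'
#' Fits `y = intercept + slope * omega` by ordinary least squares
#' (via [stats::lm()]) and records the root-mean-square residual.
#'
#' @param omega Frequencies (cm^-1); at least two distinct values.
#' @param y Observable values (kJ/mol for `dE`/`LSRI`, a.u. for `dCT`).
#' @param y_kind One of `"dE"`, `"dCT"`, `"LSRI"` (or any label).
#' @return A `linear_map`: list with `slope` (y-units per cm^-1),
#'   `intercept`, `rmse`, `n_samples`, `y_kind`.
#' @export
fit_linear <- function(omega, y, y_kind = "y") {
  ok <- is.finite(omega) & is.finite(y)
  omega <- omega[ok]; y <- y[ok]
  if (length(omega) < 2) stop("need at least 2 samples")
  if (length(unique(omega)) < 2)
    stop("degenerate fit: all omega values are equal")
  fit <- stats::lm(y ~ omega)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 rmse = sqrt(mean(stats::residuals(fit)^2)),
                 n_samples = length(omega), y_kind = y_kind),
            class = "linear_map")
}

#' @export
print.linear_map <- function(x, ...) {
  cat(sprintf("linear_map [%s]: y = %.6g %+.6g * omega  (rmse %.4g, n %d)\n",
              x$y_kind, x$intercept, x$slope, x$rmse, x$n_samples))
  invisible(x)
}

#' Predict from a linear frequency map
#'
#' @param object A `linear_map`.
#' @param omega Frequencies (cm^-1).
#' @param ... Ignored.
#' @return `intercept + slope * omega`.
#' @export
predict.linear_map <- function(object, omega, ...) {
  object$intercept + object$slope * omega
}

#' Construct a linear map from known coefficients
#'
#' @param slope,intercept Map coefficients (y-units per cm^-1, y-units).
#' @param rmse Root-mean-square residual (default `NA`).
#' @param y_kind Observable label.
#' @return A `linear_map`.
#' @export
linear_map <- function(slope, intercept, rmse = NA_real_, y_kind = "y") {
  structure(list(slope = slope, intercept = intercept, rmse = rmse,
                 n_samples = NA_integer_, y_kind = y_kind),
            class = "linear_map")
}

#' Reference frequency maps for ambient liquid water
#'
#' Linear maps relating the OH stretch wavenumber (cm^-1) to the
#' donor-to-acceptor HB stabilization energy (kJ/mol), the HB charge
#' transfer (a.u.) and the local solvent reorganization index (kJ/mol), as
#' obtained from least-squares fits over an ambient-water ab-initio
#' ensemble.  Slope/intercept placement and signs follow the inverse
#' relation between frequency and HB strength and give physical magnitudes
#' near 3400 cm^-1 (dE about -17 kJ/mol, dCT about 0.011 a.u., LSRI about
#' 12.7 kJ/mol); the scatter about each line has RMSE 7.27 kJ/mol (dE) and
#' 0.004 a.u. (dCT).  The library primarily FITS maps from data; these
#' constants serve as defaults for synthetic generation and unit
#' conversion.
#'
#' @return Named list of `linear_map` objects (`dE`, `dCT`, `LSRI`).
#' @export
water_frequency_maps <- function() {
  list(dE   = linear_map(slope = 0.0392,     intercept = -150.6,
                         rmse = 7.27,  y_kind = "dE"),
       dCT  = linear_map(slope = -0.0000221, intercept = 0.086,
                         rmse = 0.004, y_kind = "dCT"),
       LSRI = linear_map(slope = -0.01755,   intercept = 72.34,
                         rmse = NA_real_, y_kind = "LSRI"))
}

#' Normalized 2-D probability density of (frequency, observable) samples
#'
#' Histograms the samples on the given bin edges and normalizes so that
#' `sum(P * cell_area) = 1`.  Samples outside the edges are counted in
#' open boundary bins and reported via the `n_outside` attribute.
#'
#' @param omega,y Sample coordinates.
#' @param x_edges,y_edges Strictly increasing bin edges (cm^-1, y-units).
#' @return A `density2d`: list with `x_edges`, `y_edges`, `P` (matrix,
#'   x-bins rows x y-bins cols), `n_outside`.
#' @export
density2d <- function(omega, y, x_edges, y_edges) {
  ok <- is.finite(omega) & is.finite(y)
  omega <- omega[ok]; y <- y[ok]
  if (!length(omega)) stop("no samples")
  stopifnot(all(diff(x_edges) > 0), all(diff(y_edges) > 0))
  nx <- length(x_edges) - 1L
  ny <- length(y_edges) - 1L
  ix <- findInterval(omega, x_edges, rightmost.closed = TRUE)
  iy <- findInterval(y, y_edges, rightmost.closed = TRUE)
  outside <- ix < 1L | ix > nx | iy < 1L | iy > ny
  ix <- pmin(pmax(ix, 1L), nx)   # open boundary bins absorb outliers
  iy <- pmin(pmax(iy, 1L), ny)
  counts <- matrix(0, nx, ny)
  for (s in seq_along(ix)) counts[ix[s], iy[s]] <- counts[ix[s], iy[s]] + 1
  area <- outer(diff(x_edges), diff(y_edges))
  P <- counts / sum(counts) / area
  structure(list(x_edges = x_edges, y_edges = y_edges, P = P,
                 n_outside = sum(outside)),
            class = "density2d")
}

#' Write a linear map as JSON
#'
#' @param map A `linear_map`.
#' @param path Output path.
#' @param units Optional unit string stored alongside.
#' @return `path`, invisibly.
#' @export
write_linear_map <- function(map, path, units = NULL) {
  jsonlite::write_json(
    list(slope = map$slope, intercept = map$intercept, rmse = map$rmse,
         n = map$n_samples, y_kind = map$y_kind, units = units),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
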