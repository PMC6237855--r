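## Seeded synthetic generators emulating every statistical structure the
## analysis assumes: Gaussian frequency fluctuations with bi-exponential
## autocorrelation (sum of two Ornstein-Uhlenbeck processes), linearly
## coupled observables with Gaussian scatter, two-state Markov hydrogen
## bonds, and analytic oscillator trajectories.  All generators call
## set.seed(seed) so the same spec and seed reproduce byte-identical
## output.

## exact stationary OU update: x[t+1] = rho x[t] + sqrt(var (1-rho^2)) eps
gen_ou <- function(n_frames, n_modes, dt, tau_fs, var) {
  rho <- exp(-dt / tau_fs)
  innov_sd <- sqrt(var * (1 - rho^2))
  x <- matrix(0, n_frames, n_modes)
  x[1, ] <- stats::rnorm(n_modes, 0, sqrt(var))
  for (t in 2:n_frames)
    x[t, ] <- rho * x[t - 1, ] + stats::rnorm(n_modes, 0, innov_sd)
  x
}

#' Gaussian frequency process with bi-exponential autocorrelation
#'
#' Generates stationary Gaussian instantaneous-frequency tracks with
#' autocorrelation
#' `C(t) = Delta^2 [a0 exp(-t/tau0) + (1-a0) exp(-t/tau1)]`,
#' realized exactly as the sum of two independent Ornstein-Uhlenbeck
#' processes with variances `a0 Delta^2` and `(1-a0) Delta^2`.
#'
#' @param n_modes Number of independent tracks (columns).
#' @param n_frames Frames per track.
#' @param dt Frame spacing (fs).
#' @param mean_cm Mean frequency (cm^-1, default 3400).
#' @param a0 Short-time amplitude in [0, 1].
#' @param tau0_ps,tau1_ps Short and long correlation times (ps, > 0).
#' @param delta_cm Root-variance Delta (cm^-1, > 0).
#' @param seed Integer seed (passed to [set.seed()]).
#' @return Numeric matrix (`n_frames` x `n_modes`) of frequencies in
#'   cm^-1, with attributes `dt`, `mean_cm` and `spec`.
#' @export
gen_frequency_process <- function(n_modes, n_frames, dt, mean_cm = 3400,
                                  a0 = 0.6, tau0_ps = 0.1, tau1_ps = 1.01,
                                  delta_cm = 100, seed = 1) {
  stopifnot(a0 >= 0, a0 <= 1, tau0_ps > 0, tau1_ps > 0, delta_cm > 0,
            n_frames >= 2)
  set.seed(seed)
  d2 <- delta_cm^2
  x <- gen_ou(n_frames, n_modes, dt, tau0_ps * 1000, a0 * d2) +
       gen_ou(n_frames, n_modes, dt, tau1_ps * 1000, (1 - a0) * d2)
  structure(mean_cm + x, dt = dt, mean_cm = mean_cm,
            spec = list(a0 = a0, tau0_ps = tau0_ps, tau1_ps = tau1_ps,
                        delta_cm = delta_cm, seed = seed))
}

#' Observables linearly coupled to a frequency process
#'
#' Emits a valid pair table (and LSRI samples) in which each frequency
#' track drives one fictitious hydrogen-bonded pair through the linear
#' maps `y = intercept + slope * omega + N(0, sigma)`; the default maps
#' and scatter widths are the ambient-water reference values
#' ([water_frequency_maps()], RMSE 7.27 kJ/mol for `dE` and 0.004 a.u.
#' for `dCT`; 5 kJ/mol for LSRI, whose scatter is not pinned by a
#' reference value).
#'
#' @param omega Frequency matrix from [gen_frequency_process()] (frames x
#'   modes), cm^-1.
#' @param coupling Named list of lists `dE`, `dCT`, `LSRI`, each with
#'   `slope`, `intercept` and `sigma`.
#' @param seed Integer seed.
#' @return List with `pair_table` (a `pair_table`; mode i appears as
#'   donor_mol i, donor_H 1, acceptor_mol n_modes + i) and
#'   `lsri_samples` (data.frame `omega_cm`, `O_h`).
#' @export
gen_coupled_observables <- function(omega, coupling = default_coupling(),
                                    seed = 1) {
  set.seed(seed)
  dt <- attr(omega, "dt")
  n_frames <- nrow(omega)
  n_modes <- ncol(omega)
  draw <- function(cp) cp$intercept + cp$slope * as.vector(omega) +
    stats::rnorm(n_frames * n_modes, 0, cp$sigma)
  dE <- draw(coupling$dE)
  dCT <- draw(coupling$dCT)
  oh <- draw(coupling$LSRI)
  frame <- rep(seq_len(n_frames), n_modes)
  mode <- rep(seq_len(n_modes), each = n_frames)
  tab <- as_pair_table(data.frame(
    frame = frame, time_fs = (frame - 1) * dt, donor_mol = mode,
    donor_H = 1L, acceptor_mol = n_modes + mode,
    dE_kJmol = dE, dCT_au = dCT))
  list(pair_table = tab,
       lsri_samples = data.frame(omega_cm = as.vector(omega), O_h = oh))
}

#' Default coupling specification for synthetic observables
#'
#' @return Named list (`dE`, `dCT`, `LSRI`) of `slope`, `intercept`,
#'   `sigma`, built from [water_frequency_maps()].
#' @export
default_coupling <- function() {
  maps <- water_frequency_maps()
  list(dE   = list(slope = maps$dE$slope, intercept = maps$dE$intercept,
                   sigma = 7.27),
       dCT  = list(slope = maps$dCT$slope, intercept = maps$dCT$intercept,
                   sigma = 0.004),
       LSRI = list(slope = maps$LSRI$slope, intercept = maps$LSRI$intercept,
                   sigma = 5))
}

#' Two-state Markov hydrogen-bond processes
#'
#' Simulates `n_pairs` independent bonded/unbonded Markov chains with
#' per-step survival probabilities `exp(-k_break dt)` (bonded) and
#' `exp(-k_form dt)` (unbonded), started from equilibrium.  Continuously
#' bonded intervals are geometric with mean continuous lifetime
#' `1/k_break`; the bond-indicator autocorrelation relaxes with time
#' constant `1/(k_break + k_form)`; the equilibrium bonded fraction is
#' `k_form / (k_form + k_break)`.
#'
#' @param n_pairs Number of independent bonds.
#' @param n_frames Frames.
#' @param dt Frame spacing (fs).
#' @param k_break,k_form Breaking and (re)formation rates (1/ps, > 0).
#' @param seed Integer seed.
#' @return HB record data.frame (`frame`, `donor_mol`, `donor_H`,
#'   `acceptor_mol`, `r_OO`, `angle`) with pair i as donor_mol i ->
#'   acceptor_mol `n_pairs + i`; attribute `n_frames`.
#' @export
gen_markov_hbonds <- function(n_pairs, n_frames, dt, k_break, k_form,
                              seed = 1) {
  stopifnot(k_break > 0, k_form > 0, n_pairs >= 1, n_frames >= 2)
  set.seed(seed)
  dt_ps <- dt / 1000
  p_stay_b <- exp(-k_break * dt_ps)
  p_stay_u <- exp(-k_form * dt_ps)
  p_eq <- k_form / (k_form + k_break)
  h <- matrix(FALSE, n_frames, n_pairs)
  h[1, ] <- stats::runif(n_pairs) < p_eq
  for (t in 2:n_frames) {
    u <- stats::runif(n_pairs)
    h[t, ] <- ifelse(h[t - 1, ], u < p_stay_b, u >= p_stay_u)
  }
  idx <- which(h, arr.ind = TRUE)
  rec <- data.frame(frame = idx[, 1], donor_mol = idx[, 2], donor_H = 1L,
                    acceptor_mol = n_pairs + idx[, 2],
                    r_OO = 2.8, angle = 10)
  rec <- rec[order(rec$frame, rec$donor_mol), ]
  rownames(rec) <- NULL
  attr(rec, "n_frames") <- n_frames
  rec
}

#' Analytic oscillator trajectory for end-to-end wavelet tests
#'
#' Embeds a single O-H oscillator with instantaneous frequency
#' `omega_cm(t)` into a minimal one-molecule trajectory with exact
#' analytic velocities: the first O-H bond length follows
#' `r(t) = r0 + A cos(phi(t))` with `dphi/dt = 2 pi c omega(t)`; the
#' second O-H bond and the O atom are static.
#'
#' @param omega_cm Frequency series (cm^-1), one value per frame.
#' @param dt Frame spacing (fs).
#' @param r0 Equilibrium bond length (Angstrom, default 0.9584).
#' @param amplitude Oscillation amplitude (Angstrom, default 0.05).
#' @param box_edge Box edge (Angstrom, default 20).
#' @return A `water_trajectory` with one molecule and velocities; the
#'   oscillating mode is molecule 1, H 1.
#' @export
gen_oscillator_trajectory <- function(omega_cm, dt, r0 = 0.9584,
                                      amplitude = 0.05, box_edge = 20) {
  n <- length(omega_cm)
  t_fs <- (seq_len(n) - 1) * dt
  phidot <- cm_to_radfs(omega_cm)
  phi <- c(0, cumsum((phidot[-n] + phidot[-1]) / 2 * dt))
  r <- r0 + amplitude * cos(phi)
  v <- -amplitude * sin(phi) * phidot
  O <- c(5, 5, 5)
  ang <- 104.5 * pi / 180
  pos <- array(0, c(3, 3, n))
  vel <- array(0, c(3, 3, n))
  for (f in seq_len(n)) {
    pos[1, , f] <- O
    pos[2, , f] <- O + c(r[f], 0, 0)
    pos[3, , f] <- O + r0 * c(cos(ang), sin(ang), 0)
    vel[2, , f] <- c(v[f], 0, 0)
  }
  new_trajectory(c("O", "H", "H"), pos, vel, box_edge, dt)
}
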