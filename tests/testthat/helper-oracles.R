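# Independent oracles used across the suite: brute-force correlation,
# closed-form lineshapes, and small fixture builders.

# double-loop fluctuation autocorrelation, pooled over origins
brute_tcf <- function(x, max_k, center = TRUE) {
  if (center) x <- x - mean(x)
  vapply(0:max_k, function(k) {
    n <- length(x)
    sum(x[seq_len(n - k)] * x[seq_len(n - k) + k]) / (n - k)
  }, numeric(1))
}

# Kubo lineshape closed form: C(t) = d2 * exp(-t/tauc)
kubo_g <- function(t, d2, tauc) d2 * tauc^2 * (exp(-t / tauc) + t / tauc - 1)

# static (inhomogeneous) limit: C(t) = d2
static_g <- function(t, d2) d2 * t^2 / 2

# tiny two-molecule trajectory: one donor O-H pointing at an acceptor O at
# distance r_OO, optionally tilted by `tilt` degrees
dimer_trajectory <- function(r_OO = 2.8, tilt = 0, n_frames = 1,
                             box_edge = 15, with_velocities = TRUE) {
  th <- tilt * pi / 180
  O1 <- c(3, 3, 3)
  O2 <- O1 + c(r_OO, 0, 0)
  ang <- 104.5 * pi / 180
  pos1 <- rbind(O1,
                O1 + 0.96 * c(cos(th), sin(th), 0),    # donor H along O...O
                O1 + 0.96 * c(cos(ang), sin(ang), 0))
  pos2 <- rbind(O2,
                O2 + 0.96 * c(cos(ang / 2), sin(ang / 2), 0),
                O2 + 0.96 * c(cos(ang / 2), -sin(ang / 2), 0))
  pos <- array(rep(rbind(pos1, pos2), n_frames), c(6, 3, n_frames))
  vel <- if (with_velocities) array(0, c(6, 3, n_frames)) else NULL
  hbdyn:::new_trajectory(rep(c("O", "H", "H"), 2), pos, vel, box_edge, 1)
}

# pair table from explicit rows (frame, donor, H, acceptor, dE, dCT)
make_pair_table <- function(rows, dt = 5) {
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- c("frame", "donor_mol", "donor_H", "acceptor_mol",
                 "dE_kJmol", "dCT_au")
  df$time_fs <- (df$frame - 1) * dt
  as_pair_table(df[, c("frame", "time_fs", "donor_mol", "donor_H",
                       "acceptor_mol", "dE_kJmol", "dCT_au")])
}
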