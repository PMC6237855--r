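## Per-pair energy-decomposition data: donor->acceptor delocalization
## energies dE (kJ/mol, negative = stabilizing) and charge transfer dCT
## (a.u.), the local solvent reorganization index (LSRI), and matching of
## pair records to frequency tracks.
##
## A pair table is a data.frame with columns
##   frame, time_fs, donor_mol, donor_H, acceptor_mol, dE_kJmol, dCT_au
## one row per (frame, hydrogen-bonded pair).  A pair absent at a frame is
## simply absent from the table -- absence is never encoded as zero.

PAIR_TABLE_COLS <- c("frame", "time_fs", "donor_mol", "donor_H",
                     "acceptor_mol", "dE_kJmol", "dCT_au")

#' Read a per-pair energy-decomposition table
#'
#' Validates the column contract, rejects duplicate (frame, pair) rows, and
#' checks that the time grid is uniform.
#'
#' @param path Path to a TSV file with header columns `frame`, `time_fs`,
#'   `donor_mol`, `donor_H`, `acceptor_mol`, `dE_kJmol`, `dCT_au`.
#' @return A `pair_table` data.frame with attributes `dt` (fs) and `frames`
#'   (the sorted frame grid).
#' @export
read_pair_table <- function(path) {
  stopifnot(file.exists(path))
  tab <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  as_pair_table(tab)
}

#' Validate a data.frame as a pair table
#'
#' @param tab Data.frame with the pair-table columns.
#' @return A validated `pair_table`.
#' @export
as_pair_table <- function(tab) {
  missing <- setdiff(PAIR_TABLE_COLS, names(tab))
  if (length(missing))
    stop("pair table missing column(s): ", paste(missing, collapse = ", "))
  key <- paste(tab$frame, tab$donor_mol, tab$donor_H, tab$acceptor_mol)
  if (anyDuplicated(key))
    stop("duplicate (frame, pair) rows, first at table row ",
         which(duplicated(key))[1])
  grid <- unique(tab[order(tab$frame), c("frame", "time_fs")])
  if (anyDuplicated(grid$frame))
    stop("inconsistent time_fs for frame ",
         grid$frame[duplicated(grid$frame)][1])
  if (nrow(grid) > 2) {
    steps <- diff(grid$time_fs) / diff(grid$frame)
    bad <- which(abs(steps - steps[1]) > 1e-9 * max(1, abs(steps[1])))
    if (length(bad))
      stop("non-uniform time grid, first offending frame ",
           grid$frame[bad[1] + 1])
  }
  dt <- if (nrow(grid) > 1) (grid$time_fs[2] - grid$time_fs[1]) /
          (grid$frame[2] - grid$frame[1]) else NA_real_
  structure(tab, dt = dt,
            frames = seq(min(tab$frame), max(tab$frame)),
            class = c("pair_table", "data.frame"))
}

#' Write a pair table as TSV
#'
#' @param tab A `pair_table` (or conforming data.frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(tab, path) {
  utils::write.table(tab[, PAIR_TABLE_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Split a pair table into per-pair series
#'
#' Each pair's `dE` and `dCT` are laid out on the full frame grid of the
#' table, with `NA` at frames where the pair is not hydrogen-bonded
#' (explicit absence, never zero).
#'
#' @param tab A `pair_table`.
#' @return A list of `pair_series` objects with fields `donor_mol`,
#'   `donor_H`, `acceptor_mol`, `dE`, `dCT`, `t_fs` and `frames`.
#' @export
pair_series <- function(tab) {
  tab <- as_pair_table(tab)
  frames <- attr(tab, "frames")
  dt <- attr(tab, "dt")
  t0 <- tab$time_fs[which.min(tab$frame)] - min(tab$frame) * dt
  idx <- match(tab$frame, frames)
  key <- paste(tab$donor_mol, tab$donor_H, tab$acceptor_mol, sep = "/")
  lapply(split(seq_len(nrow(tab)), key), function(rows) {
    dE <- rep(NA_real_, length(frames))
    dCT <- rep(NA_real_, length(frames))
    dE[idx[rows]] <- tab$dE_kJmol[rows]
    dCT[idx[rows]] <- tab$dCT_au[rows]
    structure(list(donor_mol = tab$donor_mol[rows[1]],
                   donor_H = tab$donor_H[rows[1]],
                   acceptor_mol = tab$acceptor_mol[rows[1]],
                   dE = dE, dCT = dCT,
                   t_fs = t0 + frames * dt, frames = frames),
              class = "pair_series")
  })
}

#' Local solvent reorganization index at one frame
#'
#' For every hydrogen-bonded pair (D -> A) present at `frame`, computes the
#' energy-flux order parameter
#' `O_h = D_Acc + A_Don - D_Don - A_Acc`, where `D_Acc` sums `dE` over the
#' bonds the donor molecule accepts, `A_Don` over the bonds the acceptor
#' donates, `D_Don` over the bonds the donor donates and `A_Acc` over the
#' bonds the acceptor accepts.  Sums run over ALL bonds of the molecule in
#' that role, including the pair's own bond, unless
#' `exclude_self_bond = TRUE` (which removes the pair's own `dE` from
#' `D_Don` and `A_Acc`).  Energies enter with their signed values
#' (stabilization negative): for an isolated dimer with `dE = -20` kJ/mol
#' the index is `0 + 0 - (-20) - (-20) = 40` kJ/mol, and exchanging the
#' donor/acceptor roles of every bond flips the sign of every `O_h`.
#'
#' @param tab A `pair_table`.
#' @param frame Frame index to evaluate.
#' @param exclude_self_bond Exclude the pair's own bond from `D_Don` and
#'   `A_Acc` (default `FALSE`).
#' @return Data.frame with columns `frame`, `donor_mol`, `donor_H`,
#'   `acceptor_mol`, `O_h`, `D_Acc`, `A_Don`, `D_Don`, `A_Acc`
#'   (all energies kJ/mol).  Pairs absent at the frame are excluded.
#' @export
lsri <- function(tab, frame, exclude_self_bond = FALSE) {
  tab <- as_pair_table(tab)
  rows <- tab[tab$frame == frame, , drop = FALSE]
  if (!nrow(rows)) {
    return(data.frame(frame = integer(), donor_mol = integer(),
                      donor_H = integer(), acceptor_mol = integer(),
                      O_h = numeric(), D_Acc = numeric(), A_Don = numeric(),
                      D_Don = numeric(), A_Acc = numeric()))
  }
  ## per-molecule role sums over the frame's HB graph
  don_sum <- tapply(rows$dE_kJmol, rows$donor_mol, sum)       # donated bonds
  acc_sum <- tapply(rows$dE_kJmol, rows$acceptor_mol, sum)    # accepted bonds
  gets <- function(sums, mol) {
    v <- sums[as.character(mol)]
    ifelse(is.na(v), 0, v)
  }
  D_Acc <- gets(acc_sum, rows$donor_mol)
  A_Don <- gets(don_sum, rows$acceptor_mol)
  D_Don <- gets(don_sum, rows$donor_mol)
  A_Acc <- gets(acc_sum, rows$acceptor_mol)
  if (exclude_self_bond) {
    D_Don <- D_Don - rows$dE_kJmol
    A_Acc <- A_Acc - rows$dE_kJmol
  }
  data.frame(frame = rows$frame, donor_mol = rows$donor_mol,
             donor_H = rows$donor_H, acceptor_mol = rows$acceptor_mol,
             O_h = D_Acc + A_Don - D_Don - A_Acc,
             D_Acc = D_Acc, A_Don = A_Don, D_Don = D_Don, A_Acc = A_Acc,
             row.names = NULL)
}

#' Local solvent reorganization index over all frames
#'
#' @inheritParams lsri
#' @return Data.frame as in [lsri()], rows for every frame in the table.
#' @export
lsri_series <- function(tab, exclude_self_bond = FALSE) {
  tab <- as_pair_table(tab)
  out <- lapply(sort(unique(tab$frame)), function(f)
    lsri(tab, f, exclude_self_bond = exclude_self_bond))
  do.call(rbind, out)
}

#' Join pair records to frequency tracks
#'
#' Produces one sample per (frame, donor OH mode) where both a frequency
#' and a pair record exist: the donor OH of each pair is matched to the
#' frequency track of that same OH mode, and times are matched to the
#' nearest track sample within half the coarser grid spacing.
#'
#' @param tab A `pair_table`.
#' @param tracks List of `freq_track` objects (see
#'   [instantaneous_frequency()]).
#' @param lsri_tab Optional precomputed [lsri_series()] output; computed
#'   from `tab` when `NULL`.
#' @return Data.frame with columns `time_fs`, `donor_mol`, `donor_H`,
#'   `acceptor_mol`, `omega_cm`, `dE_kJmol`, `dCT_au`, `O_h`.  Empty (with
#'   a warning) when no times overlap.
#' @export
match_pairs_to_tracks <- function(tab, tracks, lsri_tab = NULL) {
  tab <- as_pair_table(tab)
  if (is.null(lsri_tab)) lsri_tab <- lsri_series(tab)
  key <- function(f, d, h, a) paste(f, d, h, a)
  oh <- match(key(tab$frame, tab$donor_mol, tab$donor_H, tab$acceptor_mol),
              key(lsri_tab$frame, lsri_tab$donor_mol, lsri_tab$donor_H,
                  lsri_tab$acceptor_mol))
  ids <- vapply(tracks, function(tr) {
    id <- attr(tr, "mode_id"); paste(id[[1]], id[[2]])
  }, "")
  out <- vector("list", length(tracks))
  for (i in seq_along(tracks)) {
    tr <- tracks[[i]]
    rows <- which(paste(tab$donor_mol, tab$donor_H) == ids[i])
    if (!length(rows)) next
    track_dt <- if (nrow(tr) > 1) tr$t_fs[2] - tr$t_fs[1] else Inf
    tol <- max(track_dt, attr(tab, "dt"), na.rm = TRUE) / 2
    j <- findInterval(tab$time_fs[rows], tr$t_fs +
                        c(diff(tr$t_fs) / 2, Inf))
    j <- pmin(j + 1L, nrow(tr))
    ok <- abs(tr$t_fs[j] - tab$time_fs[rows]) <= tol + 1e-9
    if (!any(ok)) next
    r <- rows[ok]
    out[[i]] <- data.frame(
      time_fs = tab$time_fs[r], donor_mol = tab$donor_mol[r],
      donor_H = tab$donor_H[r], acceptor_mol = tab$acceptor_mol[r],
      omega_cm = tr$omega_cm[j[ok]], dE_kJmol = tab$dE_kJmol[r],
      dCT_au = tab$dCT_au[r], O_h = lsri_tab$O_h[oh[r]])
  }
  res <- do.call(rbind, out)
  if (is.null(res) || !nrow(res)) {
    warning("no overlapping times between pair table and tracks")
    res <- data.frame(time_fs = numeric(), donor_mol = integer(),
                      donor_H = integer(), acceptor_mol = integer(),
                      omega_cm = numeric(), dE_kJmol = numeric(),
                      dCT_au = numeric(), O_h = numeric())
  }
  res
}
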