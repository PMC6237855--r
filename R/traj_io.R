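## Trajectory I/O and hydrogen-bond geometry.
##
## Trajectories are stored as a `water_trajectory` object:
##   elements   character vector, length n_atoms (O,H,H per molecule)
##   positions  array [n_atoms, 3, n_frames], Angstrom
##   velocities array [n_atoms, 3, n_frames] or NULL, Angstrom/fs
##   box_edge   cubic box length (Angstrom), dt frame spacing (fs)
## Molecule m occupies atom rows (3m-2, 3m-1, 3m) as O, H1, H2.

#' Read an extended-XYZ water trajectory
#'
#' Parses the extended-XYZ dialect written by common ab-initio MD codes:
#' repeated frame blocks of an atom-count line, a comment line, then one
#' `El x y z [vx vy vz]` line per atom.  Atoms must be grouped O,H,H per
#' water molecule; the grouping is validated on load.
#'
#' @param path Path to the trajectory file.
#' @param dt Frame spacing in fs (> 0).
#' @param box_edge Cubic box edge length in Angstrom (> 0).
#' @return A `water_trajectory` object.
#' @seealso [write_trajectory()], [extract_oh_modes()], [assign_hbonds()]
#' @export
read_trajectory <- function(path, dt, box_edge) {
  stopifnot(file.exists(path))
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  if (!is.numeric(box_edge) || box_edge <= 0) stop("box_edge must be > 0")
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  if (!length(lines)) stop("empty trajectory file: ", path)

  n_atoms <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n_atoms) || n_atoms <= 0)
    stop("malformed header: first line must be the atom count")
  block <- n_atoms + 2L
  if (length(lines) %% block != 0L)
    stop("truncated file: ", length(lines), " lines is not a multiple of ",
         block, " (", n_atoms, " atoms + 2 header lines per frame)")
  n_frames <- length(lines) %/% block

  elements <- character(n_atoms)
  pos <- array(NA_real_, c(n_atoms, 3L, n_frames))
  vel <- NULL
  for (f in seq_len(n_frames)) {
    off <- (f - 1L) * block
    na_f <- suppressWarnings(as.integer(trimws(lines[off + 1L])))
    if (is.na(na_f) || na_f != n_atoms)
      stop("parse error at frame ", f, ": atom count ", na_f,
           " differs from first frame (", n_atoms, ")")
    body <- lines[off + 2L + seq_len(n_atoms)]
    toks <- strsplit(trimws(body), "[[:space:]]+")
    ncol <- lengths(toks)
    if (any(ncol != ncol[1]) || !(ncol[1] %in% c(4L, 7L)))
      stop("parse error at frame ", f,
           ": atom lines must have 'El x y z' or 'El x y z vx vy vz'")
    m <- matrix(suppressWarnings(as.numeric(unlist(lapply(toks, `[`, -1L)))),
                nrow = n_atoms, byrow = TRUE)
    if (anyNA(m)) stop("parse error at frame ", f, ": non-numeric coordinate")
    el <- vapply(toks, `[`, "", 1L)
    if (f == 1L) {
      elements <- el
      if (ncol[1] == 7L) vel <- array(NA_real_, c(n_atoms, 3L, n_frames))
    } else if (!identical(el, elements)) {
      stop("parse error at frame ", f, ": atom ordering differs from frame 1")
    }
    pos[, , f] <- m[, 1:3]
    if (!is.null(vel)) {
      if (ncol[1] != 7L)
        stop("parse error at frame ", f, ": velocities present in frame 1 ",
             "but missing here")
      vel[, , f] <- m[, 4:6]
    }
  }
  new_trajectory(elements, pos, vel, box_edge, dt)
}

new_trajectory <- function(elements, positions, velocities, box_edge, dt) {
  n_atoms <- length(elements)
  if (n_atoms %% 3L != 0L)
    stop("atom count ", n_atoms, " is not a multiple of 3 (O,H,H per water)")
  n_mol <- n_atoms %/% 3L
  expected <- rep(c("O", "H", "H"), n_mol)
  if (!identical(toupper(elements), expected))
    stop("atoms must be grouped O,H,H per molecule; got: ",
         paste(utils::head(elements, 6), collapse = " "), " ...")
  structure(
    list(elements = elements, positions = positions, velocities = velocities,
         box_edge = box_edge, dt = dt, n_molecules = n_mol,
         n_frames = dim(positions)[3]),
    class = "water_trajectory")
}

#' @export
print.water_trajectory <- function(x, ...) {
  cat("water_trajectory:", x$n_molecules, "molecules,", x$n_frames,
      "frames\n  box_edge:", x$box_edge, "A  dt:", x$dt, "fs  velocities:",
      if (is.null(x$velocities)) "absent" else "present", "\n")
  invisible(x)
}

#' Write an extended-XYZ trajectory
#'
#' @param traj A `water_trajectory`.
#' @param path Output file path.
#' @param digits Number of significant digits written (default 10, ample for
#'   the 1e-6 round-trip guarantee).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, digits = 10) {
  stopifnot(inherits(traj, "water_trajectory"))
  has_vel <- !is.null(traj$velocities)
  props <- if (has_vel) "species:S:1:pos:R:3:vel:R:3" else "species:S:1:pos:R:3"
  comment <- sprintf(
    'Lattice="%g 0 0 0 %g 0 0 0 %g" Properties=%s dt_fs=%g',
    traj$box_edge, traj$box_edge, traj$box_edge, props, traj$dt)
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- paste0("%.", digits, "g")
  for (f in seq_len(traj$n_frames)) {
    writeLines(c(as.character(length(traj$elements)), comment), con)
    m <- traj$positions[, , f, drop = FALSE][, , 1]
    if (has_vel) m <- cbind(m, traj$velocities[, , f, drop = FALSE][, , 1])
    writeLines(paste(traj$elements,
                     apply(matrix(sprintf(fmt, m), nrow = nrow(m)), 1,
                           paste, collapse = " ")), con)
  }
  invisible(path)
}

## minimum-image displacement for a cubic box (componentwise)
minimum_image <- function(d, box_edge) d - box_edge * round(d / box_edge)

#' Extract O-H stretch mode series from a trajectory
#'
#' For every O-H bond, returns the instantaneous bond length r_OH(t) and the
#' momentum of the relative O-H motion projected along the instantaneous
#' bond unit vector, p(t) = mu * (v_H - v_O) . u(t), with mu the O-H reduced
#' mass.  The O-H vector uses the minimum-image convention, so the series
#' are invariant under rigid box translations.
#'
#' @param traj A `water_trajectory` with velocities.
#' @param masses Named numeric vector of atomic masses in amu
#'   (default `c(O = 15.999, H = 1.008)`).
#' @return A list of `oh_mode` objects (2 per molecule), each with fields
#'   `mode_id = c(molecule, H index)`, `bond_length` (Angstrom),
#'   `bond_momentum` (amu Angstrom/fs) and `dt` (fs).
#' @export
extract_oh_modes <- function(traj, masses = c(O = MASS_O, H = MASS_H)) {
  stopifnot(inherits(traj, "water_trajectory"))
  if (is.null(traj$velocities))
    stop("trajectory has no velocities; bond momenta cannot be computed ",
         "(re-read the trajectory from a file with velocity columns)")
  mu <- masses[["O"]] * masses[["H"]] / (masses[["O"]] + masses[["H"]])
  modes <- vector("list", 2L * traj$n_molecules)
  for (m in seq_len(traj$n_molecules)) {
    iO <- 3L * (m - 1L) + 1L
    for (h in 1:2) {
      iH <- iO + h
      dr <- traj$positions[iH, , ] - traj$positions[iO, , ]   # 3 x n_frames
      dr <- minimum_image(dr, traj$box_edge)
      r <- sqrt(colSums(dr^2))
      dv <- traj$velocities[iH, , ] - traj$velocities[iO, , ]
      p <- mu * colSums(dv * sweep(dr, 2, r, "/"))
      modes[[2L * (m - 1L) + h]] <- structure(
        list(mode_id = c(molecule = m, H = h), bond_length = r,
             bond_momentum = p, dt = traj$dt, mu = mu),
        class = "oh_mode")
    }
  }
  modes
}

#' Assign hydrogen bonds by a geometric criterion
#'
#' A donor O-H donates to an acceptor O when the O...O distance is at most
#' `r_OO_max` and the angle between the O-H bond and the O...O axis is at
#' most `angle_max`.  Each O-H donates to at most one acceptor: the nearest
#' O among candidates, ties broken by the lower molecule index.  The default
#' cutoffs are the standard liquid-water criterion of the HB-lifetime
#' literature.
#'
#' @param traj A `water_trajectory`.
#' @param criterion List with `r_OO_max` (Angstrom, default 3.5) and
#'   `angle_max` (degrees, default 30).
#' @return A data.frame with columns `frame`, `donor_mol`, `donor_H`,
#'   `acceptor_mol`, `r_OO` and `angle` (one row per hydrogen bond), plus a
#'   `n_frames` attribute.  All indices are 1-based.
#' @export
assign_hbonds <- function(traj, criterion = list(r_OO_max = 3.5, angle_max = 30)) {
  stopifnot(inherits(traj, "water_trajectory"))
  r_max <- criterion$r_OO_max
  a_max <- criterion$angle_max
  n_mol <- traj$n_molecules
  iO <- 3L * (seq_len(n_mol) - 1L) + 1L
  out <- vector("list", traj$n_frames)
  for (f in seq_len(traj$n_frames)) {
    O <- traj$positions[iO, , f, drop = FALSE][, , 1, drop = FALSE]
    dim(O) <- c(n_mol, 3L)
    recs <- list()
    for (d in seq_len(n_mol)) {
      dOO <- minimum_image(sweep(O, 2, O[d, ], "-"), traj$box_edge)
      rOO <- sqrt(rowSums(dOO^2))
      for (h in 1:2) {
        oh <- minimum_image(traj$positions[iO[d] + h, , f] - O[d, ],
                            traj$box_edge)
        oh_len <- sqrt(sum(oh^2))
        cosang <- (dOO %*% oh)[, 1] / (rOO * oh_len)
        ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
        cand <- which(rOO <= r_max & ang <= a_max & seq_len(n_mol) != d)
        if (!length(cand)) next
        best <- cand[order(rOO[cand], cand)][1L]   # nearest O, lower index ties
        recs[[length(recs) + 1L]] <- data.frame(
          frame = f, donor_mol = d, donor_H = h, acceptor_mol = best,
          r_OO = rOO[best], angle = ang[best])
      }
    }
    out[[f]] <- if (length(recs)) do.call(rbind, recs) else NULL
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(frame = integer(), donor_mol = integer(),
                      donor_H = integer(), acceptor_mol = integer(),
                      r_OO = numeric(), angle = numeric())
  attr(res, "n_frames") <- traj$n_frames
  res
}
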