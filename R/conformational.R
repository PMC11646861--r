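#' Per-frame scalar series
#'
#' @param values per-frame values.
#' @param times per-frame times, ps.
#' @param label series label.
#' @param unit unit string.
#' @return data.frame `frame`, `time`, `value` of class `"scalar_series"`.
#' @keywords internal
scalar_series <- function(values, times, label, unit) {
  stopifnot(length(values) == length(times), all(is.finite(values)))
  structure(data.frame(frame = seq_along(values), time = times,
                       value = values),
            label = label, unit = unit,
            class = c("scalar_series", "data.frame"))
}

#' RMSD time series against a reference frame
#'
#' Mass-unweighted RMSD (nm) of the selected atoms, after an optional
#' per-frame Kabsch superposition on the same selection.
#'
#' @param traj a [trajectory()].
#' @param reference frame index or `atoms x 3` full-coordinate matrix.
#' @param selection atom indices (default backbone, matching the usual
#'   deviation-from-start readout).
#' @param fit superpose each frame on the reference before measuring?
#' @return a scalar series (value in nm).
#' @export
rmsd_series <- function(traj, reference = 1,
                        selection = select_atoms(traj$top, class = "backbone"),
                        fit = TRUE) {
  if (length(selection) == 0) stop("empty selection")
  ref <- if (is.matrix(reference)) reference else frame_coords(traj, reference)
  ref <- ref[selection, , drop = FALSE]
  v <- vapply(seq_len(n_frames(traj)), function(f) {
    x <- frame_coords(traj, f)[selection, , drop = FALSE]
    if (fit) fitted_rmsd(x, ref) else rmsd_xyz(x, ref)
  }, numeric(1))
  scalar_series(v, traj$times, "RMSD", "nm")
}

#' Per-residue root-mean-square fluctuation
#'
#' RMSF of one representative atom per residue (default the alpha carbon)
#' about its time-averaged position: `sqrt(mean(|r - <r>|^2))`, nm. The
#' trajectory must already be fitted ([rms_fit()]); fluctuations are
#' otherwise inflated by global rigid-body motion.
#'
#' @param traj a fitted [trajectory()].
#' @param selection atom indices, one atom per residue (default all CAs).
#' @return data.frame `resid`, `value` of class `"residue_profile"` (nm).
#' @export
rmsf_profile <- function(traj,
                         selection = select_atoms(traj$top, class = "ca")) {
  if (n_frames(traj) < 2) stop("RMSF needs at least 2 frames")
  if (length(selection) == 0) stop("empty selection")
  resid <- traj$top$atoms$resid[selection]
  if (anyDuplicated(resid)) stop("selection must have one atom per residue")
  x <- traj$coords[, selection, , drop = FALSE]
  mu <- apply(x, c(2, 3), mean)
  dev2 <- sweep(x, c(2, 3), mu)^2
  msf <- apply(dev2, 2, mean) * 3  # mean over frames&axes * 3 axes
  structure(data.frame(resid = resid, value = sqrt(msf)),
            unit = "nm", class = c("residue_profile", "data.frame"))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Signed torsion (degrees, IUPAC: cis = 0, right-handed positive),
# range (-180, 180].
torsion_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  y <- sum(cross3(n1, n2) * b2 / sqrt(sum(b2^2)))
  ang <- atan2(y, sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

#' Side-chain dihedral time series
#'
#' Dihedral angle over four named atoms of one residue, e.g. the
#' CA-CB-CG-CD1 torsion that tracks an aromatic side chain's rotation
#' between outward- and inward-pointing states.
#'
#' @param traj a [trajectory()].
#' @param residue residue index.
#' @param atoms character 4-vector of atom names, in chain order.
#' @return a scalar series (degrees, in `(-180, 180]`).
#' @export
sidechain_dihedral <- function(traj, residue,
                               atoms = c("CA", "CB", "CG", "CD1")) {
  stopifnot(length(atoms) == 4)
  idx <- vapply(atoms, function(nm) {
    i <- select_atoms(traj$top, resid = residue, name = nm)
    if (length(i) != 1) {
      stop("residue ", residue, " is missing atom ", nm)
    }
    i
  }, numeric(1))
  v <- vapply(seq_len(n_frames(traj)), function(f) {
    x <- frame_coords(traj, f)
    torsion_deg(x[idx[1], ], x[idx[2], ], x[idx[3], ], x[idx[4], ])
  }, numeric(1))
  scalar_series(v, traj$times, paste0("dihedral(", residue, ")"), "deg")
}

#' Minimum inter-residue distance time series
#'
#' Per-frame minimum over all atom pairs between two residues (nm);
#' minimum-image convention when the trajectory carries a periodic box.
#'
#' @param traj a [trajectory()].
#' @param resA,resB distinct residue indices.
#' @param heavy_only restrict to heavy atoms (default TRUE).
#' @return a scalar series (nm).
#' @export
min_distance_series <- function(traj, resA, resB, heavy_only = TRUE) {
  if (resA == resB) stop("residues must be distinct")
  cls <- if (heavy_only) "heavy" else "all"
  ia <- select_atoms(traj$top, resid = resA, class = cls)
  ib <- select_atoms(traj$top, resid = resB, class = cls)
  if (length(ia) == 0 || length(ib) == 0) stop("residue without atoms")
  v <- vapply(seq_len(n_frames(traj)), function(f) {
    x <- frame_coords(traj, f)
    min_pair_distance(x[ia, , drop = FALSE], x[ib, , drop = FALSE],
                      if (is.null(traj$box)) NULL else traj$box[f, ])
  }, numeric(1))
  scalar_series(v, traj$times,
                sprintf("mindist(%d,%d)", resA, resB), "nm")
}

#' Distance between two residue segments over time
#'
#' Either the centre-of-geometry distance (`mode = "com"`) or the minimal
#' heavy-atom distance (`mode = "min"`) between two residue ranges, e.g.
#' the intracellular ends of two transmembrane helices.
#'
#' @param traj a [trajectory()].
#' @param segA,segB non-overlapping residue index vectors.
#' @param mode `"com"` or `"min"`.
#' @return a scalar series (nm).
#' @export
segment_distance_series <- function(traj, segA, segB,
                                    mode = c("com", "min")) {
  mode <- match.arg(mode)
  if (length(segA) == 0 || length(segB) == 0) stop("empty segment")
  if (length(intersect(segA, segB)) > 0) stop("segments must not overlap")
  ia <- select_atoms(traj$top, resid = segA, class = "heavy")
  ib <- select_atoms(traj$top, resid = segB, class = "heavy")
  v <- vapply(seq_len(n_frames(traj)), function(f) {
    x <- frame_coords(traj, f)
    a <- x[ia, , drop = FALSE]
    b <- x[ib, , drop = FALSE]
    if (mode == "com") {
      sqrt(sum((colMeans(a) - colMeans(b))^2))
    } else {
      min_pair_distance(a, b, if (is.null(traj$box)) NULL else traj$box[f, ])
    }
  }, numeric(1))
  scalar_series(v, traj$times, "segment distance", "nm")
}
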