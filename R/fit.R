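#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' two paired point sets (rows are points).
#'
#' @param from `n x 3` matrix of mobile points.
#' @param to `n x 3` matrix of reference points.
#' @return list with `rotation` (3x3, applied on the right to centred row
#'   vectors), `centre_from`, `centre_to`.
#' @export
kabsch <- function(from, to) {
  stopifnot(nrow(from) == nrow(to), ncol(from) == 3, ncol(to) == 3)
  c_from <- colMeans(from)
  c_to <- colMeans(to)
  p <- sweep(from, 2, c_from)
  q <- sweep(to, 2, c_to)
  sv <- svd(crossprod(p, q))
  d <- sign(det(sv$u) * det(sv$v))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  list(rotation = rot, centre_from = c_from, centre_to = c_to)
}

#' @rdname kabsch
#' @param x `m x 3` matrix of points to transform with a fitted superposition.
#' @param fit result of `kabsch()`.
#' @export
apply_kabsch <- function(x, fit) {
  sweep(sweep(x, 2, fit$centre_from) %*% fit$rotation, 2, fit$centre_to, `+`)
}

# plain coordinate RMSD between paired n x 3 matrices, nm
rmsd_xyz <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# RMSD after optimal superposition of a onto b
fitted_rmsd <- function(a, b) rmsd_xyz(apply_kabsch(a, kabsch(a, b)), b)

#' Least-squares fit every frame onto a reference
#'
#' Each frame is rigid-body transformed (Kabsch) so that the selected atoms
#' superpose onto the reference; the transform is applied to all atoms.
#' Analyses that compare positions across frames (RMSF, dihedral
#' distributions, correlation matrices, pocket volume) should run on a
#' fitted trajectory.
#'
#' @param traj a [trajectory()].
#' @param reference frame index into `traj`, or an `atoms x 3` coordinate
#'   matrix for the full atom set.
#' @param selection atom indices used for the fit (default: backbone).
#' @return fitted trajectory, flagged with `attr(, "fitted") = TRUE`.
#' @export
rms_fit <- function(traj, reference = 1,
                    selection = select_atoms(traj$top, class = "backbone")) {
  if (length(selection) < 3) {
    stop("underdetermined fit: selection must contain at least 3 atoms")
  }
  ref <- if (is.matrix(reference)) reference else frame_coords(traj, reference)
  if (nrow(ref) != dim(traj$coords)[2]) {
    stop("reference must cover the trajectory's full atom set")
  }
  ref_sel <- ref[selection, , drop = FALSE]
  out <- traj$coords
  for (f in seq_len(n_frames(traj))) {
    x <- frame_coords(traj, f)
    fit <- kabsch(x[selection, , drop = FALSE], ref_sel)
    out[f, , ] <- apply_kabsch(x, fit)
  }
  res <- trajectory(traj$top, out, traj$times, traj$box)
  attr(res, "fitted") <- TRUE
  attr(res, "provenance") <- attr(traj, "provenance")
  res
}
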