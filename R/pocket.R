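#' Define a maximum-englobing region (MER) for pocket-volume tracking
#'
#' The MER is a fixed sphere, conventionally centred at the mass-weighted
#' centroid of the bound ligand in a chosen defining frame and of radius
#' 1.3 nm for a GPCR orthosteric site. The definition is frozen: volume
#' evaluation expects trajectories RMS-fitted to the defining frame.
#'
#' @param top a [topology()] (or `NULL` when `centre` is given directly).
#' @param xyz defining-frame coordinates, `atoms x 3` nm.
#' @param ligand ligand atom indices; ignored when `centre` is supplied.
#' @param radius MER radius, nm.
#' @param centre optional explicit centre (length-3, nm).
#' @param excluded_residues residue indices whose atoms are ignored during
#'   occupancy testing (e.g. a mobile lid).
#' @param exclude_ligand ignore the ligand's atoms during occupancy?
#' @param spacing grid spacing, nm; must be at most `radius / 5`.
#' @return object of class `"pocket_definition"`.
#' @export
define_mer <- function(top = NULL, xyz = NULL, ligand = NULL, radius = 1.3,
                       centre = NULL, excluded_residues = NULL,
                       exclude_ligand = TRUE, spacing = 0.05) {
  stopifnot(radius > 0, spacing > 0)
  if (spacing > radius / 5) stop("grid spacing must be at most radius/5")
  if (is.null(centre)) {
    if (is.null(ligand) || length(ligand) == 0) {
      stop("empty ligand selection: cannot place the MER centre")
    }
    m <- .atomic_masses[top$atoms$elem[ligand]]
    m[is.na(m)] <- .atomic_masses["X"]
    centre <- colSums(xyz[ligand, , drop = FALSE] * m) / sum(m)
  }
  stopifnot(length(centre) == 3)
  structure(list(centre = as.numeric(centre), radius = radius,
                 excluded_residues = excluded_residues,
                 exclude_ligand = exclude_ligand, spacing = spacing),
            class = "pocket_definition")
}

# grid points (offsets from centre) inside the MER sphere; boundary points
# (distance exactly == radius) included.
mer_grid <- function(pocket) {
  s <- pocket$spacing
  r <- pocket$radius
  ax <- seq(-r, r, by = s)
  g <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  g[rowSums(g * g) <= r^2, , drop = FALSE]
}

#' Pocket volume along a trajectory
#'
#' For every frame, counts the MER grid points not covered by any
#' considered atom's exclusion sphere and multiplies by the grid cell
#' volume. An atom's exclusion radius is its per-atom `radius` from the
#' topology when present, else the Bondi van der Waals radius of its
#' element. Atoms of `excluded_residues` and (optionally) the ligand are
#' ignored.
#'
#' @param traj a [trajectory()] that has been RMS-fitted to the
#'   MER-defining configuration ([rms_fit()] flags this); pass
#'   `assume_fitted = TRUE` only for trajectories that are already in the
#'   defining frame's coordinate system by construction.
#' @param pocket a [define_mer()] definition.
#' @param assume_fitted skip the fit-flag check.
#' @return data.frame `frame`, `time`, `volume` (nm^3) of class
#'   `"volume_series"`.
#' @export
pocket_volume_series <- function(traj, pocket, assume_fitted = FALSE) {
  if (!assume_fitted && !isTRUE(attr(traj, "fitted"))) {
    stop("fit required: RMS-fit the trajectory to the MER-defining frame ",
         "first (rms_fit), or pass assume_fitted = TRUE")
  }
  a <- traj$top$atoms
  consider <- rep(TRUE, nrow(a))
  if (!is.null(pocket$excluded_residues)) {
    consider <- consider & !(a$resid %in% pocket$excluded_residues)
  }
  if (pocket$exclude_ligand && !is.null(traj$top$ligand)) {
    consider <- consider & a$resname != traj$top$ligand
  }
  radii <- if (!is.null(a$radius)) a$radius else .vdw_radii_nm[a$elem]
  radii[is.na(radii)] <- .vdw_radii_nm["X"]
  grid <- sweep(mer_grid(pocket), 2, pocket$centre, `+`)
  cellv <- pocket$spacing^3
  idx <- which(consider)
  rmax <- if (length(idx)) max(radii[idx]) else 0
  vol <- vapply(seq_len(n_frames(traj)), function(f) {
    x <- frame_coords(traj, f)
    free <- rep(TRUE, nrow(grid))
    if (length(idx)) {
      cd2 <- rowSums(sweep(x[idx, , drop = FALSE], 2, pocket$centre)^2)
      near <- idx[cd2 <= (pocket$radius + rmax)^2]
      for (at in near) {
        d2 <- (grid[, 1] - x[at, 1])^2 + (grid[, 2] - x[at, 2])^2 +
          (grid[, 3] - x[at, 3])^2
        free <- free & d2 > radii[at]^2
      }
    }
    sum(free) * cellv
  }, numeric(1))
  structure(data.frame(frame = seq_len(n_frames(traj)), time = traj$times,
                       volume = vol),
            class = c("volume_series", "data.frame"))
}

# Analytic volume of the intersection of two spheres (radii R and r,
# centre separation d); used by the pocket phantom's ground truth.
sphere_intersection_volume <- function(R, r, d) {
  if (d >= R + r) return(0)
  if (d <= abs(R - r)) return(4 / 3 * pi * min(R, r)^3)
  pi * (R + r - d)^2 *
    (d^2 + 2 * d * r - 3 * r^2 + 2 * d * R + 6 * r * R - 3 * R^2) / (12 * d)
}
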