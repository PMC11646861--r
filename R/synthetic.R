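#' Idealised multi-segment scaffold
#'
#' Builds a toy parallel-segment protein: `n_segments` straight "helices"
#' laid side by side (segment gap 0.36 nm), each a stack of residues
#' 0.38 nm apart, threaded serpentine-fashion so that chain-consecutive
#' residues are always spatial neighbours. Each residue carries backbone
#' atoms (N, CA, C, O) and a dummy CB side chain. By construction the
#' heavy-atom contact set (0.45 nm cutoff) is exactly: consecutive residues
#' within a segment, and same-height residues in adjacent segments.
#'
#' @param n_segments number of segments (>= 2).
#' @param residues_per_segment residues per segment.
#' @param spacing intra-segment residue spacing, nm.
#' @param segment_gap inter-segment axis distance, nm.
#' @return list with `traj` (single-frame [trajectory()]), `map` (a
#'   synthetic [bw_map()] labelling segments TM1..TMn with mid-segment
#'   anchors), and `contacts` (data.frame of the constructed contact
#'   pairs).
#' @export
make_scaffold <- function(n_segments = 7, residues_per_segment = 5,
                          spacing = 0.38, segment_gap = 0.36) {
  stopifnot(n_segments >= 2, residues_per_segment >= 2)
  m <- residues_per_segment
  atom_tpl <- data.frame(
    name = c("N", "CA", "C", "O", "CB"),
    elem = c("N", "C", "C", "O", "C"),
    dx = c(0, 0, 0, 0, 0),
    dy = c(0, 0, 0, 0.05, 0.15),
    dz = c(-0.02, 0, 0.02, 0.02, 0))
  rows <- list()
  resid <- 0
  for (s in seq_len(n_segments)) {
    order_in_seg <- if (s %% 2 == 1) seq_len(m) else rev(seq_len(m))
    for (p in order_in_seg) {
      resid <- resid + 1
      ca <- c((s - 1) * segment_gap, 0, (p - 1) * spacing)
      rows[[resid]] <- data.frame(
        name = atom_tpl$name, elem = atom_tpl$elem,
        resid = resid, resname = "ALA", chain = "A",
        x = ca[1] + atom_tpl$dx, y = ca[2] + atom_tpl$dy,
        z = ca[3] + atom_tpl$dz)
    }
  }
  at <- do.call(rbind, rows)
  top <- topology(at[, c("name", "elem", "resid", "resname", "chain")])
  coords <- array(as.matrix(at[, c("x", "y", "z")]),
                  dim = c(1, nrow(at), 3))
  traj <- trajectory(top, coords, times = 0)
  segs <- data.frame(
    segment = paste0("TM", seq_len(n_segments)),
    start = (seq_len(n_segments) - 1) * m + 1,
    end = seq_len(n_segments) * m,
    anchor_label = sprintf("%d.50", seq_len(n_segments)),
    anchor_residue = (seq_len(n_segments) - 1) * m + ceiling(m / 2),
    stringsAsFactors = FALSE)
  map <- bw_map(segs)
  contacts <- scaffold_contacts(n_segments, m)
  list(traj = traj, map = map, contacts = contacts)
}

# the contact pairs make_scaffold() constructs, from its serpentine layout
scaffold_contacts <- function(n_segments, m) {
  height <- integer(n_segments * m)
  seg <- integer(n_segments * m)
  r <- 0
  for (s in seq_len(n_segments)) {
    ord <- if (s %% 2 == 1) seq_len(m) else rev(seq_len(m))
    for (p in ord) {
      r <- r + 1
      height[r] <- p
      seg[r] <- s
    }
  }
  pairs <- list()
  n <- n_segments * m
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      same_seg_adjacent <- seg[i] == seg[j] && abs(height[i] - height[j]) == 1
      adj_seg_same_h <- abs(seg[i] - seg[j]) == 1 && height[i] == height[j]
      if (same_seg_adjacent || adj_seg_same_h) {
        pairs[[length(pairs) + 1]] <- data.frame(i = i, j = j)
      }
    }
  }
  do.call(rbind, pairs)
}

#' Correlated Gaussian ensemble around a reference structure
#'
#' Draws `n_frames` independent frames as the reference plus per-residue
#' rigid Gaussian displacements: for each Cartesian axis, the vector of
#' per-residue displacements is multivariate normal with covariance
#' `sigma^2 * rho` (axes independent, identical `rho`). Under this model
#' the mutual information between two residues' 3-D positions has the
#' closed form `-(3/2) log(1 - rho_ij^2)`, so the generalized correlation
#' coefficient equals `|rho_ij|` exactly — the generator is its own ground
#' truth for the correlation module.
#'
#' An optional AR(1) mode (`phi > 0`) makes successive frames temporally
#' correlated with lag-1 autocorrelation `phi`, for exercising stride
#' logic; the stationary covariance is unchanged.
#'
#' @param reference single-frame [trajectory()] (or any trajectory; frame 1
#'   is the reference).
#' @param rho residue-residue correlation matrix (symmetric, unit diagonal,
#'   positive semi-definite).
#' @param sigma per-axis fluctuation, nm.
#' @param n_frames number of frames.
#' @param dt frame spacing, ps.
#' @param seed RNG seed (frames are reproducible bit-for-bit).
#' @param phi AR(1) lag-1 autocorrelation in `[0, 1)`; 0 = independent
#'   frames.
#' @return a [trajectory()].
#' @export
gaussian_ensemble <- function(reference, rho, sigma = 0.05, n_frames = 1200,
                              dt = 1000, seed = 1, phi = 0) {
  nres <- n_residues(reference$top)
  stopifnot(nrow(rho) == nres, ncol(rho) == nres)
  if (max(abs(rho - t(rho))) > 1e-10 || any(abs(diag(rho) - 1) > 1e-10)) {
    stop("rho must be symmetric with unit diagonal")
  }
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("rho is not positive semi-definite (min eigenvalue ",
         format(min(ev)), "); project it to the nearest PSD matrix ",
         "(eigenvalue clipping) first")
  }
  stopifnot(sigma > 0, phi >= 0, phi < 1)
  cr <- chol(rho + diag(1e-10, nres))
  if (!is.null(seed)) set.seed(seed)
  ref <- frame_coords(reference, 1)
  res_of <- match(paste(reference$top$atoms$chain,
                        reference$top$atoms$resid),
                  paste(reference$top$residues$chain,
                        reference$top$residues$resid))
  coords <- array(NA_real_, dim = c(n_frames, nrow(ref), 3))
  for (k in 1:3) {
    z <- matrix(rnorm(n_frames * nres), n_frames, nres) %*% cr
    if (phi > 0) {
      for (f in 2:n_frames) {
        z[f, ] <- phi * z[f - 1, ] + sqrt(1 - phi^2) * z[f, ]
      }
    }
    d <- sigma * z
    coords[, , k] <- matrix(ref[, k], n_frames, nrow(ref), byrow = TRUE) +
      d[, res_of, drop = FALSE]
  }
  out <- trajectory(reference$top, coords,
                    times = (seq_len(n_frames) - 1) * dt)
  attr(out, "fitted") <- TRUE
  out
}

#' Ensemble with a planted high-correlation chain
#'
#' Builds a correlation matrix with a weak constant background
#' (`rho_bg`) and first-order autoregressive structure
#' `rho_chain^|a - b|` along an ordered residue chain (so consecutive chain
#' pairs correlate at `rho_chain`), completes it to positive-definite by
#' eigenvalue clipping, and samples a [gaussian_ensemble()]. Consecutive
#' chain residues must be contacts of the scaffold, so the chain is a
#' connected path of the contact network and an optimal-path search should
#' recover it.
#'
#' @param scaffold result of [make_scaffold()].
#' @param chain ordered residue indices of the planted chain.
#' @param rho_chain correlation of consecutive chain pairs.
#' @param rho_bg background correlation.
#' @param n_frames,sigma,dt,seed,phi see [gaussian_ensemble()].
#' @return a [trajectory()] with attribute `rho` (the completed matrix).
#' @export
planted_path_ensemble <- function(scaffold, chain, rho_chain = 0.9,
                                  rho_bg = 0.05, n_frames = 1200,
                                  sigma = 0.05, dt = 1000, seed = 1,
                                  phi = 0) {
  traj <- scaffold$traj
  nres <- n_residues(traj$top)
  stopifnot(length(chain) >= 2, all(chain >= 1), all(chain <= nres))
  if (sigma > 0.1) {
    stop("sigma too large to preserve the scaffold's contact topology")
  }
  ref <- frame_coords(traj, 1)
  for (a in seq_len(length(chain) - 1)) {
    ia <- select_atoms(traj$top, resid = chain[a], class = "heavy")
    ib <- select_atoms(traj$top, resid = chain[a + 1], class = "heavy")
    d <- min_pair_distance(ref[ia, , drop = FALSE], ref[ib, , drop = FALSE])
    if (d >= 0.45) {
      stop("chain residues ", chain[a], " and ", chain[a + 1],
           " are not contacts in the scaffold")
    }
  }
  rho <- matrix(rho_bg, nres, nres)
  diag(rho) <- 1
  for (a in seq_along(chain)) {
    for (b in seq_along(chain)) {
      if (a != b) rho[chain[a], chain[b]] <- rho_chain^abs(a - b)
    }
  }
  es <- eigen(rho, symmetric = TRUE)
  vals <- pmax(es$values, 1e-8)
  rho2 <- es$vectors %*% diag(vals) %*% t(es$vectors)
  s <- 1 / sqrt(diag(rho2))
  rho2 <- rho2 * outer(s, s)
  rho2 <- (rho2 + t(rho2)) / 2
  out <- gaussian_ensemble(traj, rho2, sigma, n_frames, dt, seed, phi)
  attr(out, "rho") <- rho2
  out
}

#' Minimal two-residue interaction fixture
#'
#' Builds a tiny system whose per-frame geometry satisfies (or violates)
#' one interaction predicate exactly according to a presence bit pattern:
#' in "on" frames the interacting groups sit at the requested distance (and
#' donor angle, for hydrogen bonds); in "off" frames the second residue is
#' displaced 5 nm away.
#'
#' @param kind `"hbond"`, `"hydrophobic"` or `"saltbridge"`.
#' @param pattern logical (or 0/1) vector, one entry per frame.
#' @param distance interaction distance in "on" frames, nm: donor-acceptor
#'   heavy-atom distance (hbond), carbon-carbon distance (hydrophobic), or
#'   charged-centroid separation (saltbridge).
#' @param angle donor-H...acceptor angle at the hydrogen, degrees (hbond
#'   only).
#' @return a [trajectory()] of `length(pattern)` frames; partners are
#'   residues 1 and 3.
#' @export
interaction_fixture <- function(kind = c("hbond", "hydrophobic",
                                         "saltbridge"),
                                pattern, distance, angle = 150) {
  kind <- match.arg(kind)
  pattern <- as.logical(pattern)
  stopifnot(length(pattern) >= 1, distance > 0)
  if (kind == "hbond") {
    if (distance <= 0.1) {
      stop("contradictory geometry: donor-acceptor distance must exceed ",
           "the 0.1 nm O-H bond length")
    }
    if (angle <= 0 || angle > 180) stop("contradictory geometry: angle")
    # donor O at origin, H at (0.1, 0, 0); acceptor placed in the xy-plane
    # so that the angle at H between H->D and H->A equals `angle` and
    # |D - A| = distance.
    al <- (180 - angle) * pi / 180
    u <- c(cos(al), sin(al), 0)
    cc <- 0.01 - distance^2
    tt <- (-0.2 * u[1] + sqrt(0.04 * u[1]^2 - 4 * cc)) / 2
    acc <- c(0.1, 0, 0) + tt * u
    a1 <- data.frame(name = c("CA", "OG", "HG"), elem = c("C", "O", "H"),
                     resid = 1, resname = "SER", chain = "A")
    a2 <- data.frame(name = c("CA", "O"), elem = c("C", "O"),
                     resid = 3, resname = "GLY", chain = "A")
    base <- rbind(c(0, -0.8, 0), c(0, 0, 0), c(0.1, 0, 0),
                  acc + c(0, 0.8, 0), acc)
    movers <- 4:5
  } else if (kind == "hydrophobic") {
    a1 <- data.frame(name = "CB", elem = "C", resid = 1, resname = "ALA",
                     chain = "A")
    a2 <- data.frame(name = "CB", elem = "C", resid = 3, resname = "ALA",
                     chain = "A")
    base <- rbind(c(0, 0, 0), c(distance, 0, 0))
    movers <- 2
  } else {
    a1 <- data.frame(name = c("OE1", "OE2"), elem = c("O", "O"),
                     resid = 1, resname = "GLU", chain = "A")
    a2 <- data.frame(name = "NZ", elem = "N", resid = 3, resname = "LYS",
                     chain = "A")
    base <- rbind(c(0, 0.05, 0), c(0, -0.05, 0), c(distance, 0, 0))
    movers <- 3
  }
  top <- topology(rbind(a1, a2))
  nf <- length(pattern)
  coords <- array(NA_real_, dim = c(nf, nrow(base), 3))
  for (f in seq_len(nf)) {
    x <- base
    if (!pattern[f]) x[movers, 1] <- x[movers, 1] + 5
    coords[f, , ] <- x
  }
  trajectory(top, coords, times = seq_len(nf) - 1)
}

#' Multi-basin trajectory with known cluster structure
#'
#' Frames jitter around `n_basins` distinct conformers: each basin centre
#' is the reference structure plus an independent Gaussian deformation
#' pattern scaled so that expected inter-basin RMSD equals
#' `inter_basin_rmsd`; within a basin, frames add isotropic per-atom jitter
#' of `basin_spread` per coordinate. With a clustering cutoff between the
#' within-basin spread and the basin separation, single-linkage clustering
#' recovers exactly the planted basins and sizes.
#'
#' @param n_basins number of basins.
#' @param frames_per_basin integer vector (recycled to `n_basins`).
#' @param basin_spread within-basin per-coordinate jitter sd, nm.
#' @param inter_basin_rmsd expected centre-to-centre RMSD, nm; must exceed
#'   `3 * basin_spread`.
#' @param reference single-frame trajectory (default: a 3x4 scaffold).
#' @param seed RNG seed.
#' @return a [trajectory()] with attribute `basins` (ground-truth per-frame
#'   basin id, ordered by descending basin size).
#' @export
multibasin_trajectory <- function(n_basins = 3, frames_per_basin = c(10, 6, 4),
                                  basin_spread = 0.02,
                                  inter_basin_rmsd = 0.5,
                                  reference = NULL, seed = 1) {
  stopifnot(n_basins >= 1, inter_basin_rmsd > 3 * basin_spread)
  if (is.null(reference)) reference <- make_scaffold(3, 4)$traj
  frames_per_basin <- rep_len(frames_per_basin, n_basins)
  set.seed(seed)
  ref <- frame_coords(reference, 1)
  na <- nrow(ref)
  centres <- lapply(seq_len(n_basins), function(b) {
    p <- matrix(rnorm(na * 3), na, 3)
    p <- sweep(p, 2, colMeans(p))
    ref + p * inter_basin_rmsd / sqrt(6)
  })
  nf <- sum(frames_per_basin)
  coords <- array(NA_real_, dim = c(nf, na, 3))
  basin <- integer(nf)
  f <- 0
  for (b in seq_len(n_basins)) {
    for (r in seq_len(frames_per_basin[b])) {
      f <- f + 1
      coords[f, , ] <- centres[[b]] + matrix(rnorm(na * 3, sd = basin_spread),
                                             na, 3)
      basin[f] <- b
    }
  }
  out <- trajectory(reference$top, coords, times = seq_len(nf) - 1)
  attr(out, "basins") <- basin
  out
}

#' Pocket phantom with analytically known free volume
#'
#' A maximum-englobing sphere containing zero or more non-overlapping
#' obstacle spheres (dummy atoms with explicit per-atom occupancy radii).
#' The exact free volume is the MER volume minus each obstacle's
#' sphere-sphere intersection with the MER, available as
#' `attr(traj, "analytic_volume")`.
#'
#' @param obstacles list of `list(centre = <xyz nm>, radius = <nm>)`.
#' @param radius MER radius, nm.
#' @param centre MER centre.
#' @param spacing grid spacing for the paired [define_mer()].
#' @return list with `traj` (single-frame trajectory, flagged as fitted)
#'   and `pocket` (a [define_mer()] definition).
#' @export
pocket_phantom <- function(obstacles = list(), radius = 1.3,
                           centre = c(0, 0, 0), spacing = 0.05) {
  n <- length(obstacles)
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        d <- sqrt(sum((obstacles[[i]]$centre - obstacles[[j]]$centre)^2))
        if (d < obstacles[[i]]$radius + obstacles[[j]]$radius) {
          stop("obstacles overlap: analytic volume would be inexact")
        }
      }
    }
  }
  atoms <- data.frame(name = rep("DU", n),
                      elem = rep("X", n),
                      resid = seq_len(max(n, 1))[seq_len(n)],
                      resname = rep("OBS", n),
                      chain = rep("A", n),
                      radius = vapply(obstacles, `[[`, numeric(1), "radius"),
                      stringsAsFactors = FALSE)
  top <- topology(atoms)
  xyz <- if (n > 0) {
    do.call(rbind, lapply(obstacles, `[[`, "centre"))
  } else {
    matrix(numeric(0), ncol = 3)
  }
  traj <- trajectory(top, array(xyz, dim = c(1, n, 3)), times = 0)
  attr(traj, "fitted") <- TRUE
  vol <- 4 / 3 * pi * radius^3
  for (ob in obstacles) {
    d <- sqrt(sum((ob$centre - centre)^2))
    vol <- vol - sphere_intersection_volume(radius, ob$radius, d)
  }
  attr(traj, "analytic_volume") <- vol
  pocket <- define_mer(centre = centre, radius = radius, spacing = spacing,
                       exclude_ligand = FALSE)
  list(traj = traj, pocket = pocket)
}
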