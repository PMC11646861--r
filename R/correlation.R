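#' Parameters for the Kraskov mutual-information estimator
#'
#' @param k neighbour count (default 6, the conventional choice for
#'   residue-residue generalized correlations).
#' @param stride_ps sampling interval, ps (default 1000 = 1 ns, chosen so
#'   that successive analysed frames are effectively decorrelated).
#' @return list of class `"kraskov_params"`.
#' @export
kraskov_params <- function(k = 6, stride_ps = 1000) {
  stopifnot(k >= 1, stride_ps > 0)
  structure(list(k = k, stride_ps = stride_ps), class = "kraskov_params")
}

#' Kraskov k-nearest-neighbour mutual information
#'
#' Estimates I(X; Y) in nats between two vector-valued samples (typically
#' per-frame alpha-carbon positions of two residues) with the
#' k-nearest-neighbour density estimator, algorithm 1: for each joint
#' sample, `eps` is the distance to its k-th neighbour in the joint space
#' under the max-norm across the two marginal blocks (Euclidean within each
#' block), `n_x`/`n_y` count marginal samples strictly within `eps`, and
#'
#'   I = psi(k) - < psi(n_x + 1) + psi(n_y + 1) > + psi(N).
#'
#' Raw estimates can be slightly negative near independence; the reported
#' `I` is clamped at zero (the raw value is kept in `I_raw`).
#'
#' @param x,y numeric matrices `N x d` (vectors are treated as `N x 1`).
#' @param k neighbour count, `1 <= k < N`.
#' @return object of class `"mi_estimate"`: list with `I` (clamped, nats),
#'   `I_raw`, `N`, `k`, `n_x`, `n_y`, `eps`.
#' @export
kraskov_mi <- function(x, y, k = 6) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  if (is.vector(y)) y <- matrix(y, ncol = 1)
  n <- nrow(x)
  if (nrow(y) != n) stop("x and y must have the same number of samples")
  if (n <= k) stop("need more than k = ", k, " samples (got ", n, ")")
  st <- kraskov_neighbour_stats(x, y, as.integer(k))
  if (any(st$eps == 0)) {
    stop("degenerate samples (repeated points): the kNN estimator is ",
         "undefined; jitter the input or check for a frozen trajectory")
  }
  i_raw <- digamma(k) - mean(digamma(st$nx + 1) + digamma(st$ny + 1)) +
    digamma(n)
  structure(list(I = max(0, i_raw), I_raw = i_raw, N = n, k = k,
                 n_x = st$nx, n_y = st$ny, eps = st$eps),
            class = "mi_estimate")
}

#' Generalized correlation coefficient from mutual information
#'
#' Maps a mutual information (nats) between two 3-D variables to a
#' correlation-like coefficient in `[0, 1]`:
#' `r_MI = sqrt(1 - exp(-2/3 * I))`. For jointly Gaussian 3-D pairs with
#' per-axis correlation `rho`, `r_MI` equals `|rho|` exactly.
#'
#' @param I mutual information in nats (numeric vector or an
#'   `"mi_estimate"`); must be non-negative (clamping happens upstream in
#'   [kraskov_mi()]).
#' @return numeric in `[0, 1]`.
#' @export
generalized_correlation <- function(I) {
  if (inherits(I, "mi_estimate")) I <- I$I
  if (any(I < 0)) stop("mutual information must be non-negative")
  sqrt(1 - exp(-2 / 3 * I))
}

# per-node coordinate matrix list: residues at their alpha carbon, ligand
# (if requested) at its representative atom — the heavy atom closest to the
# ligand's mass-weighted centroid in frame 1.
node_coordinates <- function(traj, include_ligand = FALSE) {
  top <- traj$top
  res <- top$residues
  prot <- if (is.null(top$ligand)) res else
    res[res$resname != top$ligand, , drop = FALSE]
  nodes <- as.character(prot$resid)
  idx <- vapply(prot$resid, function(r) {
    i <- select_atoms(top, resid = r, name = "CA")
    if (length(i) != 1) {
      stop("residue ", r, " has no (unique) alpha carbon")
    }
    i
  }, numeric(1))
  if (include_ligand) {
    if (is.null(top$ligand)) stop("topology declares no ligand")
    li <- select_atoms(top, class = "ligand")
    lh <- li[top$atoms$heavy[li]]
    x1 <- frame_coords(traj, 1)
    m <- .atomic_masses[top$atoms$elem[li]]
    m[is.na(m)] <- .atomic_masses["X"]
    com <- colSums(x1[li, , drop = FALSE] * m) / sum(m)
    rep_atom <- lh[which.min(rowSums(sweep(x1[lh, , drop = FALSE], 2,
                                           com)^2))]
    nodes <- c(nodes, top$ligand)
    idx <- c(idx, rep_atom)
  }
  list(nodes = nodes, atom_idx = idx)
}

strided_frames <- function(traj, stride_ps) {
  t0 <- traj$times[1]
  dt <- if (n_frames(traj) > 1) min(diff(traj$times)) else stride_ps
  step <- max(1L, as.integer(round(stride_ps / dt)))
  seq(1L, n_frames(traj), by = step)
}

#' Residue-residue generalized correlation matrix
#'
#' Estimates the Kraskov mutual information between the alpha-carbon
#' position samples of every residue pair (at the decorrelation stride) and
#' converts to generalized correlation coefficients. The matrix is
#' symmetric with unit diagonal. The trajectory should be fitted
#' ([rms_fit()]) so that rigid-body motion does not masquerade as
#' correlation.
#'
#' @param traj a [trajectory()].
#' @param params a [kraskov_params()].
#' @param pairs optional 2-column matrix of node-name pairs to compute
#'   (e.g. contact pairs only); uncomputed off-diagonal entries are `NA`.
#' @param include_ligand add a ligand node at its representative atom.
#' @param state optional state label (e.g. `"Holo"`).
#' @return square matrix of class `"correlation_matrix"` with node names as
#'   dimnames and attributes `state` and `N` (samples used).
#' @export
correlation_matrix <- function(traj, params = kraskov_params(),
                               pairs = NULL, include_ligand = FALSE,
                               state = NULL) {
  nc <- node_coordinates(traj, include_ligand)
  frames <- strided_frames(traj, params$stride_ps)
  nn <- length(nc$nodes)
  xs <- lapply(seq_len(nn), function(i) {
    matrix(traj$coords[frames, nc$atom_idx[i], ], ncol = 3)
  })
  m <- matrix(NA_real_, nn, nn, dimnames = list(nc$nodes, nc$nodes))
  diag(m) <- 1
  want <- if (is.null(pairs)) {
    which(upper.tri(m), arr.ind = TRUE)
  } else {
    cbind(match(as.character(pairs[, 1]), nc$nodes),
          match(as.character(pairs[, 2]), nc$nodes))
  }
  if (any(is.na(want))) stop("pair refers to an unknown node")
  for (r in seq_len(nrow(want))) {
    i <- want[r, 1]; j <- want[r, 2]
    if (i == j) next
    mi <- kraskov_mi(xs[[i]], xs[[j]], params$k)
    m[i, j] <- m[j, i] <- generalized_correlation(mi)
  }
  structure(m, state = state, N = length(frames), k = params$k,
            class = c("correlation_matrix", "matrix"))
}

#' Difference of two correlation matrices
#'
#' Element-wise `A - B` over a shared residue set — the standard map for
#' localising correlation gained or lost between two receptor states.
#'
#' @param A,B `correlation_matrix` objects over the same nodes.
#' @return signed matrix in `[-1, 1]` with zero diagonal, class
#'   `"delta_matrix"`, with attribute `states = c(A state, B state)`.
#' @export
delta_matrix <- function(A, B) {
  if (!identical(dimnames(A), dimnames(B))) {
    stop("correlation matrices cover different residue sets")
  }
  d <- unclass(A) - unclass(B)
  diag(d) <- 0
  structure(d, states = c(attr(A, "state"), attr(B, "state")),
            class = c("delta_matrix", "matrix"))
}
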