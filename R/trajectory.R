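#' Construct a trajectory
#'
#' @param top a [topology()].
#' @param coords numeric array `frames x atoms x 3`, nm. A single frame may
#'   be given as an `atoms x 3` matrix.
#' @param times per-frame times in ps, strictly increasing. Defaults to
#'   0, 1, 2, ... ps.
#' @param box optional per-frame orthorhombic periodic cell, a `frames x 3`
#'   matrix of edge lengths (nm); when present, inter-atomic distances use
#'   the minimum-image convention.
#' @return object of class `"trajectory"`.
#' @export
trajectory <- function(top, coords, times = NULL, box = NULL) {
  stopifnot(inherits(top, "topology"))
  if (is.matrix(coords)) coords <- array(coords, dim = c(1, dim(coords)))
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  if (dim(coords)[2] != nrow(top$atoms)) {
    stop("coordinate array has ", dim(coords)[2],
         " atoms but topology has ", nrow(top$atoms),
         " (topology/trajectory incompatibility)")
  }
  if (!all(is.finite(coords))) stop("coordinates must all be finite")
  nf <- dim(coords)[1]
  if (is.null(times)) times <- as.numeric(seq_len(nf) - 1)
  if (length(times) != nf) stop("times length must equal frame count")
  if (nf > 1 && any(diff(times) <= 0)) {
    stop("times must be strictly increasing")
  }
  if (!is.null(box)) {
    if (is.vector(box)) box <- matrix(box, nrow = nf, ncol = 3, byrow = TRUE)
    stopifnot(nrow(box) == nf, ncol(box) == 3, all(box > 0))
  }
  structure(list(top = top, coords = coords, times = as.numeric(times),
                 box = box),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", n_frames(x), "frames,", dim(x$coords)[2], "atoms, ",
      sprintf("%.6g-%.6g ps", x$times[1], x$times[n_frames(x)]),
      if (isTRUE(attr(x, "fitted"))) "(rms-fitted)" else "", "\n")
  invisible(x)
}

#' @rdname trajectory
#' @param traj a trajectory.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Extract one frame's coordinates
#'
#' @param traj a trajectory.
#' @param i frame index.
#' @return `atoms x 3` matrix, nm.
#' @export
frame_coords <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  matrix(traj$coords[i, , ], ncol = 3)
}

#' Keep a subset of frames
#'
#' @param traj a trajectory.
#' @param idx frame indices to keep, in order.
#' @return trajectory restricted to those frames (times preserved).
#' @export
subset_frames <- function(traj, idx) {
  stopifnot(all(idx >= 1), all(idx <= n_frames(traj)))
  out <- trajectory(traj$top,
                    traj$coords[idx, , , drop = FALSE],
                    traj$times[idx],
                    if (is.null(traj$box)) NULL else
                      traj$box[idx, , drop = FALSE])
  attr(out, "fitted") <- attr(traj, "fitted")
  prov <- attr(traj, "provenance")
  if (!is.null(prov)) attr(out, "provenance") <- prov[idx, , drop = FALSE]
  out
}

#' Concatenate the equilibrated tails of replica trajectories
#'
#' Keeps, from each replica, only the frames with time at least
#' `discard` ps past the replica's first frame, and concatenates the tails
#' in replica order. This reproduces the common practice of discarding an
#' initial relaxation window from each replica and pooling the remainder
#' into a single analysis trajectory.
#'
#' @param replicas list of [trajectory()] objects sharing a topology.
#' @param discard leading time window to drop from each replica, ps.
#' @return single trajectory; per-frame provenance (replica id and original
#'   time) is retained in `attr(, "provenance")`. Times are rebuilt as a
#'   strictly increasing sequence with the first replica's frame spacing.
#' @export
concatenate_tails <- function(replicas, discard = 0) {
  stopifnot(length(replicas) >= 1, discard >= 0)
  na <- dim(replicas[[1]]$coords)[2]
  nm <- replicas[[1]]$top$atoms$name
  tails <- lapply(seq_along(replicas), function(r) {
    tr <- replicas[[r]]
    stopifnot(inherits(tr, "trajectory"))
    if (dim(tr$coords)[2] != na || !identical(tr$top$atoms$name, nm)) {
      stop("replicas must share one topology")
    }
    t0 <- tr$times[1]
    tend <- tr$times[n_frames(tr)]
    dt <- if (n_frames(tr) > 1) tr$times[2] - t0 else 0
    if (discard >= (tend - t0) + dt) {
      stop("replica ", r, " is shorter than the discard window")
    }
    keep <- which(tr$times >= t0 + discard)
    list(coords = tr$coords[keep, , , drop = FALSE],
         times = tr$times[keep],
         box = if (is.null(tr$box)) NULL else tr$box[keep, , drop = FALSE],
         prov = data.frame(replica = r, orig_time = tr$times[keep]))
  })
  coords <- do.call(abind3, lapply(tails, `[[`, "coords"))
  boxes <- lapply(tails, `[[`, "box")
  box <- if (any(vapply(boxes, is.null, logical(1)))) NULL else
    do.call(rbind, boxes)
  dt <- if (dim(coords)[1] > 1) {
    t1 <- tails[[1]]$times
    if (length(t1) > 1) t1[2] - t1[1] else 1
  } else 1
  times <- tails[[1]]$times[1] + (seq_len(dim(coords)[1]) - 1) * dt
  out <- trajectory(replicas[[1]]$top, coords, times, box)
  attr(out, "provenance") <- do.call(rbind, lapply(tails, `[[`, "prov"))
  out
}

# rbind for frame x atom x 3 arrays
abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  total <- sum(vapply(parts, function(p) dim(p)[1], numeric(1)))
  out <- array(NA_real_, dim = c(total, d[2], d[3]))
  at <- 0
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

# Pairwise displacement honouring an orthorhombic periodic cell.
# a: n x 3, b: m x 3 -> n*m x 3 matrix of minimum-image displacements.
min_image_delta <- function(a, b, box = NULL) {
  n <- nrow(a); m <- nrow(b)
  d <- a[rep(seq_len(n), times = m), , drop = FALSE] -
    b[rep(seq_len(m), each = n), , drop = FALSE]
  if (!is.null(box)) {
    for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  }
  d
}

# Minimum distance between two atom sets (nm), minimum-image when box given.
min_pair_distance <- function(a, b, box = NULL) {
  d <- min_image_delta(a, b, box)
  sqrt(min(rowSums(d * d)))
}
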