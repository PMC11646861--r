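#' Single-linkage conformational clustering
#'
#' Builds the pairwise RMSD matrix over (strided) frames — each pair
#' optimally superposed before measuring — joins frames whose RMSD is at
#' most `cutoff`, and takes connected components as clusters. This mirrors
#' the classic linkage clustering of MD frames used to count conformational
#' states, where a 0.1 nm backbone cutoff is the conventional scale for a
#' single GPCR conformational basin.
#'
#' Cluster ids are contiguous from 1 and ordered by decreasing size, ties
#' broken by the earlier medoid frame. The medoid of a cluster is its frame
#' with the smallest summed RMSD to the other members.
#'
#' @param traj a [trajectory()].
#' @param cutoff RMSD join threshold, nm (> 0).
#' @param selection atom indices used for fitting and RMSD
#'   (default backbone).
#' @param stride analyse every `stride`-th frame.
#' @return object of class `"cluster_result"`: list with `assignments`
#'   (per analysed frame), `sizes`, `medoids` (original frame indices),
#'   `frames` (analysed original frame indices), `cutoff`, `rmsd`
#'   (the pairwise matrix).
#' @export
linkage_cluster <- function(traj, cutoff = 0.1,
                            selection = select_atoms(traj$top,
                                                     class = "backbone"),
                            stride = 1) {
  stopifnot(cutoff > 0, stride >= 1)
  frames <- seq(1, n_frames(traj), by = stride)
  m <- length(frames)
  sel_xyz <- lapply(frames, function(f) {
    frame_coords(traj, f)[selection, , drop = FALSE]
  })
  rmat <- matrix(0, m, m)
  if (m > 1) {
    for (i in 1:(m - 1)) {
      for (j in (i + 1):m) {
        rmat[i, j] <- rmat[j, i] <- fitted_rmsd(sel_xyz[[i]], sel_xyz[[j]])
      }
    }
  }
  adj <- rmat <= cutoff
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  ids <- sort(unique(comp))
  medoid_of <- vapply(ids, function(cid) {
    memb <- which(comp == cid)
    if (length(memb) == 1) return(memb)
    memb[which.min(rowSums(rmat[memb, memb, drop = FALSE]))]
  }, numeric(1))
  sizes <- as.integer(table(comp)[as.character(ids)])
  ord <- order(-sizes, frames[medoid_of])
  remap <- integer(length(ids))
  remap[ids[ord]] <- seq_along(ids)
  structure(list(assignments = remap[comp],
                 sizes = sizes[ord],
                 medoids = frames[medoid_of[ord]],
                 frames = frames,
                 cutoff = cutoff,
                 rmsd = rmat),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("linkage clustering:", length(x$sizes), "clusters at cutoff",
      x$cutoff, "nm; sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Write cluster medoid frames as a multi-model PDB
#'
#' @param traj the clustered [trajectory()].
#' @param clusters a `cluster_result`.
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
write_medoids <- function(traj, clusters, path) {
  write_trajectory(subset_frames(traj, clusters$medoids), path)
}
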