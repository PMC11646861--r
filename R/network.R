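#' Contact frequency matrix
#'
#' Two nodes (residues, optionally the ligand) are in contact in a frame if
#' the shortest distance between their heavy atoms is strictly below the
#' cutoff; the frequency is the fraction of frames in contact. Sequence
#' neighbours (`|delta resid| = 1`) are flagged in
#' `attr(, "seq_neighbour")` but retained.
#'
#' @param traj a [trajectory()].
#' @param distance_cutoff heavy-atom distance threshold, nm.
#' @param include_ligand add a ligand node (all its heavy atoms).
#' @return symmetric matrix in `[0, 1]` of class `"contact_matrix"` with
#'   node names as dimnames; diagonal is `NA`.
#' @export
contact_frequency <- function(traj, distance_cutoff = 0.45,
                              include_ligand = FALSE) {
  top <- traj$top
  nc <- node_coordinates(traj, include_ligand)
  nodes <- nc$nodes
  nn <- length(nodes)
  atom_sets <- lapply(nodes, function(nd) {
    if (!is.null(top$ligand) && nd == top$ligand) {
      select_atoms(top, class = "ligand")[
        top$atoms$heavy[select_atoms(top, class = "ligand")]]
    } else {
      select_atoms(top, resid = as.integer(nd), class = "heavy")
    }
  })
  counts <- matrix(0, nn, nn)
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    x <- frame_coords(traj, f)
    box <- if (is.null(traj$box)) NULL else traj$box[f, ]
    for (i in 1:(nn - 1)) {
      xi <- x[atom_sets[[i]], , drop = FALSE]
      for (j in (i + 1):nn) {
        d <- min_pair_distance(xi, x[atom_sets[[j]], , drop = FALSE], box)
        if (d < distance_cutoff) {
          counts[i, j] <- counts[i, j] + 1
        }
      }
    }
  }
  freq <- counts / nf
  freq <- freq + t(freq)
  diag(freq) <- NA_real_
  dimnames(freq) <- list(nodes, nodes)
  resid_num <- suppressWarnings(as.numeric(nodes))
  nb <- abs(outer(resid_num, resid_num, `-`)) == 1
  nb[is.na(nb)] <- FALSE
  structure(freq, cutoff = distance_cutoff, seq_neighbour = nb,
            class = c("contact_matrix", "matrix"))
}

#' Build the contact-filtered, correlation-weighted dynamic network
#'
#' Nodes are residues (alpha-carbon sites) and optionally the ligand; an
#' edge joins two nodes when their contact frequency is at least
#' `frequency_cutoff` (inclusive), and carries weight `w = r_MI` and length
#' `l = -log(w)`, so that minimum-length paths maximise the product of
#' correlations along the path.
#'
#' @param contacts a [contact_frequency()] matrix.
#' @param correlations a [correlation_matrix()] over the same nodes (entries
#'   must be available for every contact pair).
#' @param frequency_cutoff inclusive edge-formation threshold.
#' @return object of class `"dynamic_network"`: list with `graph` (igraph,
#'   vertex names = node names), `edges` (data.frame `from`, `to`,
#'   `weight`, `length`, `frequency`), `nodes`.
#' @export
build_network <- function(contacts, correlations, frequency_cutoff = 0.75) {
  if (!identical(rownames(contacts), rownames(correlations))) {
    stop("contact and correlation matrices cover different node sets")
  }
  nodes <- rownames(contacts)
  sel <- which(upper.tri(contacts) & contacts >= frequency_cutoff,
               arr.ind = TRUE)
  w <- unclass(correlations)[sel]
  if (anyNA(w)) {
    stop("missing correlation entries for ", sum(is.na(w)), " contact pairs")
  }
  drop0 <- w <= 0
  if (any(drop0)) {
    warning(sum(drop0), " zero-weight candidate edge(s) dropped")
  }
  sel <- sel[!drop0, , drop = FALSE]
  w <- w[!drop0]
  edges <- data.frame(from = nodes[sel[, 1]], to = nodes[sel[, 2]],
                      weight = w, length = -log(w),
                      frequency = unclass(contacts)[sel],
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  structure(list(graph = g, edges = edges, nodes = nodes),
            class = "dynamic_network")
}

#' @export
print.dynamic_network <- function(x, ...) {
  cat("dynamic network:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges\n")
  invisible(x)
}

#' Betweenness centrality with size normalization
#'
#' Node and edge betweenness under shortest paths of length `-log(w)`
#' (Brandes accumulation; equal-length paths split the count), normalized
#' for comparability across networks of different size by
#' `2 / ((n - 1)(n - 2))` for nodes and `2 / (n (n - 1))` for edges, where
#' `n` is the node count. Endpoints are excluded from their own path
#' counts; disconnected pairs contribute zero.
#'
#' @param net a [build_network()] result.
#' @return list of class `"centrality_table"`: `nodes` (data.frame `node`,
#'   `betweenness`), `edges` (data.frame `from`, `to`, `betweenness`), `n`.
#' @export
betweenness_centrality <- function(net) {
  g <- net$graph
  n <- igraph::vcount(g)
  if (n < 3) stop("node betweenness needs at least 3 nodes")
  len <- igraph::E(g)$length
  bn <- igraph::betweenness(g, weights = len) * 2 / ((n - 1) * (n - 2))
  be <- igraph::edge_betweenness(g, weights = len) * 2 / (n * (n - 1))
  el <- igraph::as_edgelist(g)
  structure(list(nodes = data.frame(node = igraph::V(g)$name,
                                    betweenness = as.numeric(bn),
                                    stringsAsFactors = FALSE),
                 edges = data.frame(from = el[, 1], to = el[, 2],
                                    betweenness = as.numeric(be),
                                    stringsAsFactors = FALSE),
                 n = n),
            class = "centrality_table")
}

#' Eigenvector centrality of the correlation-weighted adjacency
#'
#' Principal eigenpair of the weighted adjacency matrix, computed per
#' connected component (the Perron vector is only defined within a
#' component). Centralities are non-negative and unit-Euclidean-norm within
#' each component; the defining relation `A x = lambda x` holds to solver
#' precision.
#'
#' @param net a [build_network()] result.
#' @return data.frame `node`, `centrality`, `lambda`, `component`.
#' @export
eigenvector_centrality <- function(net) {
  g <- net$graph
  if (igraph::vcount(g) == 0) stop("empty graph")
  A <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight",
                                             sparse = FALSE))
  comp <- igraph::components(g)$membership
  out <- data.frame(node = igraph::V(g)$name,
                    centrality = NA_real_, lambda = NA_real_,
                    component = as.integer(comp),
                    stringsAsFactors = FALSE)
  for (cid in unique(comp)) {
    memb <- which(comp == cid)
    if (length(memb) == 1) {
      out$centrality[memb] <- 1
      out$lambda[memb] <- 0
      next
    }
    es <- eigen(A[memb, memb, drop = FALSE], symmetric = TRUE)
    v <- es$vectors[, 1]
    if (sum(v) < 0) v <- -v
    v <- pmax(v, 0)
    v <- v / sqrt(sum(v^2))
    out$centrality[memb] <- v
    out$lambda[memb] <- es$values[1]
  }
  out
}

#' Knee of a ranked centrality curve
#'
#' Given centrality values sorted in descending order, returns the value at
#' the point of maximum perpendicular distance from the chord joining the
#' first and last rank on the rank-value curve — a deterministic,
#' parameter-free elbow criterion used to threshold centrality
#' distributions. Ties break toward the higher rank (later index).
#'
#' @param values numeric vector, sorted descending (at least 3 values).
#' @return the knee value (scalar), with attribute `rank`.
#' @export
knee_threshold <- function(values) {
  if (length(values) < 3) stop("knee detection needs at least 3 values")
  if (is.unsorted(rev(values))) stop("values must be sorted descending")
  m <- length(values)
  if (max(values) == min(values)) {
    warning("degenerate (constant) centrality curve")
    return(structure(values[1], rank = m))
  }
  x <- seq_len(m)
  p1 <- c(1, values[1])
  p2 <- c(m, values[m])
  chord <- p2 - p1
  chord <- chord / sqrt(sum(chord^2))
  dx <- x - p1[1]
  dy <- values - p1[2]
  dist <- abs(dx * chord[2] - dy * chord[1])
  best <- max(which(dist == max(dist)))
  structure(values[best], rank = best)
}

#' Group node centralities by receptor segment
#'
#' @param centralities data.frame with columns `node` and a value column
#'   (`betweenness` or `centrality`), or a named numeric vector.
#' @param map a [bw_map()].
#' @param threshold optional: drop nodes with value at or below it before
#'   grouping (as done after knee thresholding).
#' @return data.frame `node`, `segment`, `value`; nodes outside any mapped
#'   segment get segment `"loop"`.
#' @export
per_segment_centrality <- function(centralities, map, threshold = NULL) {
  if (is.data.frame(centralities)) {
    vcol <- intersect(c("betweenness", "centrality", "value"),
                      names(centralities))[1]
    v <- setNames(centralities[[vcol]], centralities$node)
  } else {
    v <- centralities
  }
  if (!is.null(threshold)) v <- v[v > threshold]
  resid <- suppressWarnings(as.integer(names(v)))
  seg <- vapply(seq_along(v), function(i) {
    if (is.na(resid[i])) return("ligand")
    lb <- bw_label(map, resid[i])
    if (grepl("^[0-9]+\\.", lb)) {
      paste0("TM", split_bw_label(lb)$tm)
    } else {
      lb
    }
  }, character(1))
  data.frame(node = names(v), segment = seg, value = as.numeric(v),
             stringsAsFactors = FALSE)
}

#' Rank-based comparison of two segments' centralities
#'
#' Compares the centrality distributions of two segments with a Wilcoxon
#' rank test. Segments of unequal size use the unpaired rank-sum variant
#' (the default); the signed-rank variant pairs values by descending rank
#' after truncating both groups to the smaller size.
#'
#' @param grouped output of [per_segment_centrality()].
#' @param segA,segB segment names.
#' @param variant `"rank-sum"` (unpaired) or `"signed-rank"` (paired by
#'   rank).
#' @return `htest` object from [stats::wilcox.test()].
#' @export
compare_segments <- function(grouped, segA, segB,
                             variant = c("rank-sum", "signed-rank")) {
  variant <- match.arg(variant)
  a <- grouped$value[grouped$segment == segA]
  b <- grouped$value[grouped$segment == segB]
  if (length(a) == 0 || length(b) == 0) {
    stop("segment with no surviving nodes")
  }
  if (variant == "rank-sum") {
    stats::wilcox.test(a, b, exact = FALSE)
  } else {
    m <- min(length(a), length(b))
    stats::wilcox.test(sort(a, decreasing = TRUE)[1:m],
                       sort(b, decreasing = TRUE)[1:m],
                       paired = TRUE, exact = FALSE)
  }
}

#' Optimal communication path between two nodes
#'
#' The optimal path maximises the product of edge correlations, i.e.
#' minimises the total length `sum(-log w)` (Dijkstra). With
#' `mode = "sum"` the literal maximum-sum-of-correlations objective is
#' used instead, over simple paths of at most `max_hops` edges (exhaustive;
#' small graphs only) — provided because the sum objective is ill-posed
#' without a hop bound.
#'
#' @param net a [build_network()] result.
#' @param source,target node names (residue id as character, or ligand
#'   name).
#' @param mode `"product"` (default) or `"sum"`.
#' @param max_hops hop bound for `mode = "sum"`.
#' @return object of class `"network_path"`: list with `nodes` (ordered),
#'   `length` (sum of `-log w`; `NA` if unreachable), `weights`,
#'   `reachable`.
#' @export
optimal_path <- function(net, source, target,
                         mode = c("product", "sum"), max_hops = 6) {
  mode <- match.arg(mode)
  source <- as.character(source)
  target <- as.character(target)
  g <- net$graph
  stopifnot(source %in% net$nodes, target %in% net$nodes)
  if (source == target) {
    return(structure(list(nodes = source, length = 0,
                          weights = numeric(0), reachable = TRUE),
                     class = "network_path"))
  }
  if (mode == "sum") {
    return(best_sum_path(net, source, target, max_hops))
  }
  sp <- suppressWarnings(
    igraph::shortest_paths(g, from = source, to = target,
                           weights = igraph::E(g)$length,
                           output = "both"))
  if (length(sp$vpath[[1]]) == 0) {
    return(structure(list(nodes = character(0), length = NA_real_,
                          weights = numeric(0), reachable = FALSE),
                     class = "network_path"))
  }
  w <- igraph::E(g)$weight[as.integer(sp$epath[[1]])]
  structure(list(nodes = igraph::V(g)$name[as.integer(sp$vpath[[1]])],
                 length = sum(-log(w)), weights = w, reachable = TRUE),
            class = "network_path")
}

# exhaustive max-sum-of-correlations path with a hop bound
best_sum_path <- function(net, source, target, max_hops) {
  adj <- lapply(setNames(seq_along(net$nodes), net$nodes), function(i) {
    nd <- net$nodes[i]
    rbind(
      data.frame(nb = net$edges$to[net$edges$from == nd],
                 w = net$edges$weight[net$edges$from == nd]),
      data.frame(nb = net$edges$from[net$edges$to == nd],
                 w = net$edges$weight[net$edges$to == nd]))
  })
  best <- list(sum = -Inf, nodes = character(0), weights = numeric(0))
  walk <- function(path, ws, total) {
    last <- path[length(path)]
    if (last == target) {
      if (total > best$sum) {
        best <<- list(sum = total, nodes = path, weights = ws)
      }
      return()
    }
    if (length(path) > max_hops) return()
    nb <- adj[[last]]
    for (r in seq_len(nrow(nb))) {
      if (nb$nb[r] %in% path) next
      walk(c(path, nb$nb[r]), c(ws, nb$w[r]), total + nb$w[r])
    }
  }
  walk(source, numeric(0), 0)
  if (!is.finite(best$sum)) {
    return(structure(list(nodes = character(0), length = NA_real_,
                          weights = numeric(0), reachable = FALSE),
                     class = "network_path"))
  }
  structure(list(nodes = best$nodes, length = sum(-log(best$weights)),
                 weights = best$weights, reachable = TRUE),
            class = "network_path")
}

#' @export
print.network_path <- function(x, ...) {
  if (!x$reachable) {
    cat("no path\n")
  } else {
    cat("path:", paste(x$nodes, collapse = " -> "),
        sprintf("  (length %.4f, product of correlations %.4f)\n",
                x$length, prod(x$weights)))
  }
  invisible(x)
}

#' Edges bridging two segments
#'
#' All network edges with one endpoint in each of two residue segments —
#' e.g. the inter-helix links whose appearance or loss distinguishes
#' receptor states.
#'
#' @param net a [build_network()] result.
#' @param map a [bw_map()].
#' @param segA,segB segment names.
#' @return subset of `net$edges`.
#' @export
inter_segment_edges <- function(net, map, segA, segB) {
  ra <- as.character(segment_residues(map, segA))
  rb <- as.character(segment_residues(map, segB))
  e <- net$edges
  keep <- (e$from %in% ra & e$to %in% rb) | (e$from %in% rb & e$to %in% ra)
  out <- e[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a network as an edge-list TSV
#'
#' Columns: `from  to  weight  length  frequency`.
#'
#' @param net a [build_network()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
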