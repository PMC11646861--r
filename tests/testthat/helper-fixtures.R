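# Shared fixtures and independent brute-force oracles.

# Build a dynamic network directly from an edge table (from, to, w), with
# all contact frequencies set to 1 so every listed edge survives.
toy_network <- function(edges, extra_nodes = character(0)) {
  nodes <- sort(unique(c(edges$from, edges$to, extra_nodes)))
  nn <- length(nodes)
  cf <- matrix(0, nn, nn, dimnames = list(nodes, nodes))
  cm <- matrix(NA_real_, nn, nn, dimnames = list(nodes, nodes))
  diag(cm) <- 1
  for (r in seq_len(nrow(edges))) {
    i <- edges$from[r]; j <- edges$to[r]
    cf[i, j] <- cf[j, i] <- 1
    cm[i, j] <- cm[j, i] <- edges$w[r]
  }
  diag(cf) <- NA
  cm[is.na(cm)] <- 0  # never edges (freq 0)
  diag(cm) <- 1
  build_network(structure(cf, class = c("contact_matrix", "matrix")),
                structure(cm, class = c("correlation_matrix", "matrix")),
                frequency_cutoff = 0.75)
}

# Random connected undirected graph with continuous weights in (0, 1).
random_connected_graph <- function(n, seed, p = 0.5) {
  set.seed(seed)
  repeat {
    pairs <- t(combn(n, 2))
    keep <- runif(nrow(pairs)) < p
    # always keep a random spanning path so connectivity is common
    if (sum(keep) == 0) next
    e <- data.frame(from = as.character(pairs[keep, 1]),
                    to = as.character(pairs[keep, 2]),
                    w = runif(sum(keep), 0.05, 0.95),
                    stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(e, directed = FALSE,
                                       vertices = data.frame(
                                         name = as.character(1:n)))
    if (igraph::is_connected(g)) return(e)
  }
}

# Enumerate all simple paths s -> t over an edge table; returns list of
# list(nodes, len = sum(-log w), prod = prod w).
enumerate_paths <- function(edges, s, t) {
  nodes <- sort(unique(c(edges$from, edges$to)))
  nbrs <- lapply(setNames(nodes, nodes), function(v) {
    rbind(data.frame(n = edges$to[edges$from == v],
                     w = edges$w[edges$from == v]),
          data.frame(n = edges$from[edges$to == v],
                     w = edges$w[edges$to == v]))
  })
  found <- list()
  recurse <- function(path, ws) {
    v <- path[length(path)]
    if (v == t) {
      found[[length(found) + 1]] <<- list(nodes = path,
                                          len = sum(-log(ws)),
                                          prod = prod(ws))
      return()
    }
    nb <- nbrs[[v]]
    for (r in seq_len(nrow(nb))) {
      if (nb$n[r] %in% path) next
      recurse(c(path, nb$n[r]), c(ws, nb$w[r]))
    }
  }
  recurse(s, numeric(0))
  found
}

# Brute-force node and edge betweenness with the size normalization
# 2/((n-1)(n-2)) and 2/(n(n-1)), via exhaustive path enumeration.
brute_betweenness <- function(edges, rel_tol = 1e-12) {
  nodes <- sort(unique(c(edges$from, edges$to)))
  n <- length(nodes)
  bn <- setNames(numeric(n), nodes)
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  be <- setNames(numeric(nrow(edges)), ekey(edges$from, edges$to))
  for (si in seq_len(n - 1)) {
    for (ti in (si + 1):n) {
      s <- nodes[si]; t <- nodes[ti]
      ps <- enumerate_paths(edges, s, t)
      if (length(ps) == 0) next
      lens <- vapply(ps, `[[`, numeric(1), "len")
      lmin <- min(lens)
      short <- ps[lens <= lmin + rel_tol * max(1, abs(lmin))]
      sigma <- length(short)
      for (p in short) {
        inner <- setdiff(p$nodes, c(s, t))
        bn[inner] <- bn[inner] + 1 / sigma
        for (k in seq_len(length(p$nodes) - 1)) {
          be[ekey(p$nodes[k], p$nodes[k + 1])] <-
            be[ekey(p$nodes[k], p$nodes[k + 1])] + 1 / sigma
        }
      }
    }
  }
  list(nodes = bn * 2 / ((n - 1) * (n - 2)),
       edges = be * 2 / (n * (n - 1)))
}

# Pure-R reference implementation of the Kraskov algorithm-1 estimator
# (independent of the compiled kernel).
r_kraskov <- function(x, y, k) {
  n <- nrow(x)
  dx <- as.matrix(stats::dist(x))
  dy <- as.matrix(stats::dist(y))
  dj <- pmax(dx, dy)
  s <- 0
  for (i in seq_len(n)) {
    eps <- sort(dj[i, -i])[k]
    nx <- sum(dx[i, -i] < eps)
    ny <- sum(dy[i, -i] < eps)
    s <- s + digamma(nx + 1) + digamma(ny + 1)
  }
  digamma(k) - s / n + digamma(n)
}

# Correlated 3-D Gaussian pair with per-axis correlation rho.
gaussian_pair <- function(rho, n, seed) {
  set.seed(seed)
  x <- matrix(rnorm(n * 3), n, 3)
  y <- rho * x + sqrt(1 - rho^2) * matrix(rnorm(n * 3), n, 3)
  list(x = x, y = y)
}

# Single-frame trajectory from an explicit coordinate matrix.
frame_traj <- function(top, xyz, box = NULL) {
  trajectory(top, array(xyz, dim = c(1, nrow(xyz), 3)), times = 0, box = box)
}
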