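test_that("contact frequencies match an exhaustive per-frame scan", {
  sc <- make_scaffold(2, 4)
  ens <- gaussian_ensemble(sc$traj, diag(8), sigma = 0.05, n_frames = 20,
                           seed = 3)
  cf <- contact_frequency(ens, 0.45)
  # brute-force oracle
  top <- ens$top
  oracle <- matrix(0, 8, 8)
  for (f in seq_len(20)) {
    x <- frame_coords(ens, f)
    for (i in 1:7) {
      for (j in (i + 1):8) {
        ia <- select_atoms(top, resid = i, class = "heavy")
        ja <- select_atoms(top, resid = j, class = "heavy")
        dm <- sqrt(outer(rowSums(x[ia, ]^2), rowSums(x[ja, ]^2), `+`) -
                     2 * x[ia, ] %*% t(x[ja, ]))
        if (min(dm) < 0.45) oracle[i, j] <- oracle[i, j] + 1
      }
    }
  }
  oracle <- (oracle + t(oracle)) / 20
  diag(oracle) <- NA
  expect_equal(unclass(cf), oracle, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("contact frequency counts fractions exactly", {
  # two residues in contact in 3 of 4 frames
  top <- topology(data.frame(name = c("CA", "CA"), elem = "C",
                             resid = c(1, 5), resname = "ALA", chain = "A"))
  co <- array(0, c(4, 2, 3))
  co[, 2, 1] <- c(0.3, 0.3, 0.3, 2.0)
  tr <- trajectory(top, co, times = 0:3)
  cf <- contact_frequency(tr, 0.45)
  expect_equal(cf["1", "5"], 0.75)
})

test_that("edge formation is inclusive at the frequency cutoff", {
  cf <- matrix(c(NA, 0.75, 0.75, NA), 2, 2,
               dimnames = list(c("1", "2"), c("1", "2")))
  cm <- matrix(c(1, 0.8, 0.8, 1), 2, 2,
               dimnames = list(c("1", "2"), c("1", "2")))
  net <- build_network(structure(cf, class = c("contact_matrix", "matrix")),
                       structure(cm, class = c("correlation_matrix",
                                               "matrix")),
                       frequency_cutoff = 0.75)
  expect_equal(nrow(net$edges), 1)   # exactly 0.75 -> edge present
  expect_equal(net$edges$weight, 0.8)
  expect_equal(net$edges$length, -log(0.8))

  cf2 <- cf; cf2["1", "2"] <- cf2["2", "1"] <- 0.7499
  net2 <- build_network(structure(cf2, class = c("contact_matrix", "matrix")),
                        structure(cm, class = c("correlation_matrix",
                                                "matrix")), 0.75)
  expect_equal(nrow(net2$edges), 0)
})

test_that("network edge set equals the explicit threshold predicate", {
  set.seed(17)
  n <- 10
  nodes <- as.character(1:n)
  cf <- matrix(runif(n * n), n, n, dimnames = list(nodes, nodes))
  cf[lower.tri(cf)] <- t(cf)[lower.tri(cf)]
  diag(cf) <- NA
  cm <- matrix(runif(n * n, 0.1, 0.95), n, n,
               dimnames = list(nodes, nodes))
  cm[lower.tri(cm)] <- t(cm)[lower.tri(cm)]
  diag(cm) <- 1
  net <- build_network(structure(cf, class = c("contact_matrix", "matrix")),
                       structure(cm, class = c("correlation_matrix",
                                               "matrix")), 0.75)
  want <- which(upper.tri(cf) & cf >= 0.75, arr.ind = TRUE)
  expect_equal(nrow(net$edges), nrow(want))
  got <- paste(net$edges$from, net$edges$to)
  expect_setequal(got, paste(nodes[want[, 1]], nodes[want[, 2]]))
  expect_equal(net$edges$weight,
               cm[cbind(match(net$edges$from, nodes),
                        match(net$edges$to, nodes))])
})

test_that("betweenness matches hand-enumerated path and star graphs", {
  path3 <- toy_network(data.frame(from = c("1", "2"), to = c("2", "3"),
                                  w = 0.9))
  bc <- betweenness_centrality(path3)
  expect_equal(bc$nodes$betweenness[bc$nodes$node == "2"], 1.0)
  expect_equal(sum(bc$nodes$betweenness), 1.0)
  # each edge of the 3-path lies on 2 of the 3 pairs' paths: C = 2/(3*2)
  expect_equal(sort(bc$edges$betweenness), c(2 / 3, 2 / 3))

  star <- toy_network(data.frame(from = rep("c", 3),
                                 to = c("a", "b", "d"), w = 0.5))
  bs <- betweenness_centrality(star)
  expect_equal(bs$nodes$betweenness[bs$nodes$node == "c"], 1.0)
  expect_equal(bs$nodes$betweenness[bs$nodes$node != "c"], rep(0, 3))
})

test_that("betweenness and optimal paths equal brute-force enumeration", {
  for (seed in 1:50) {
    n <- sample(4:7, 1)
    e <- random_connected_graph(n, seed = 1000 + seed)
    net <- toy_network(e)
    bc <- betweenness_centrality(net)
    oracle <- brute_betweenness(e)
    expect_equal(setNames(bc$nodes$betweenness, bc$nodes$node),
                 oracle$nodes[bc$nodes$node], tolerance = 1e-10)
    got_e <- setNames(bc$edges$betweenness,
                      paste(pmin(bc$edges$from, bc$edges$to),
                            pmax(bc$edges$from, bc$edges$to)))
    expect_equal(got_e[names(oracle$edges)], oracle$edges, tolerance = 1e-10)

    # optimal path between two random nodes vs exhaustive max product
    st <- sample(as.character(1:n), 2)
    p <- optimal_path(net, st[1], st[2])
    all_paths <- enumerate_paths(e, st[1], st[2])
    best <- all_paths[[which.max(vapply(all_paths, `[[`, numeric(1),
                                        "prod"))]]
    expect_equal(prod(p$weights), best$prod, tolerance = 1e-12)
    expect_equal(p$length, best$len, tolerance = 1e-12)
  }
})

test_that("optimal paths prefer high-correlation multi-hop routes", {
  # two-hop 0.9*0.9 = 0.81 beats the direct 0.5 edge
  net <- toy_network(data.frame(from = c("s", "m", "s"),
                                to = c("m", "t", "t"),
                                w = c(0.9, 0.9, 0.5)))
  p <- optimal_path(net, "s", "t")
  expect_equal(p$nodes, c("s", "m", "t"))
  expect_equal(prod(p$weights), 0.81)

  same <- optimal_path(net, "s", "s")
  expect_equal(same$nodes, "s")
  expect_equal(same$length, 0)

  # disconnected pair: a no-path result, not an exception
  disc <- toy_network(data.frame(from = c("a", "x"), to = c("b", "y"),
                                 w = c(0.9, 0.9)))
  p2 <- optimal_path(disc, "a", "x")
  expect_false(p2$reachable)
  expect_true(is.na(p2$length))

  # literal sum objective with a hop bound
  psum <- optimal_path(net, "s", "t", mode = "sum", max_hops = 3)
  expect_equal(psum$nodes, c("s", "m", "t"))   # 1.8 > 0.5
})

test_that("eigenvector centrality solves Ax = lambda x on random graphs", {
  for (seed in 1:50) {
    n <- sample(4:8, 1)
    e <- random_connected_graph(n, seed = 2000 + seed)
    net <- toy_network(e)
    ev <- eigenvector_centrality(net)
    A <- as.matrix(igraph::as_adjacency_matrix(net$graph, attr = "weight",
                                               sparse = FALSE))
    x <- ev$centrality[match(rownames(A), ev$node)]
    lam <- ev$lambda[1]
    expect_lt(sqrt(sum((A %*% x - lam * x)^2)), 1e-8)
    expect_true(all(x >= 0))
    expect_equal(sum(x^2), 1, tolerance = 1e-10)
  }
  # uniform on a cycle
  cyc <- toy_network(data.frame(from = c("1", "2", "3", "4", "5"),
                                to = c("2", "3", "4", "5", "1"), w = 0.7))
  ev <- eigenvector_centrality(cyc)
  expect_equal(ev$centrality, rep(1 / sqrt(5), 5), tolerance = 1e-10)
  expect_equal(ev$lambda, rep(2 * 0.7, 5), tolerance = 1e-10)
})

test_that("scaling all weights rescales lambda but not the eigenvector", {
  e <- random_connected_graph(6, seed = 77)
  net1 <- toy_network(e)
  e2 <- e; e2$w <- e2$w / 2
  net2 <- toy_network(e2)
  ev1 <- eigenvector_centrality(net1)
  ev2 <- eigenvector_centrality(net2)
  expect_equal(ev2$centrality, ev1$centrality, tolerance = 1e-9)
  expect_equal(ev2$lambda, ev1$lambda / 2, tolerance = 1e-9)
})

test_that("triangle eigenvector matches a dense eigendecomposition", {
  net <- toy_network(data.frame(from = c("1", "2", "3"),
                                to = c("2", "3", "1"),
                                w = c(0.9, 0.5, 0.1)))
  ev <- eigenvector_centrality(net)
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- 0.9
  A[2, 3] <- A[3, 2] <- 0.5
  A[1, 3] <- A[3, 1] <- 0.1
  es <- eigen(A)
  v <- abs(es$vectors[, 1])
  expect_equal(sort(ev$centrality), sort(v / sqrt(sum(v^2))),
               tolerance = 1e-10)
  expect_equal(ev$lambda[1], es$values[1], tolerance = 1e-10)
})

test_that("knee detection equals the max-chord-distance oracle", {
  knee_oracle <- function(v) {
    m <- length(v)
    ch <- c(m - 1, v[m] - v[1])
    ch <- ch / sqrt(sum(ch^2))
    d <- abs((seq_len(m) - 1) * ch[2] - (v - v[1]) * ch[1])
    v[max(which(d == max(d)))]
  }
  decay <- sort(2^-(1:20) * 10, decreasing = TRUE)
  expect_equal(as.numeric(knee_threshold(decay)), knee_oracle(decay))
  lshape <- c(10, 9.5, 9, 1, 0.9, 0.8)
  expect_equal(as.numeric(knee_threshold(lshape)), knee_oracle(lshape))
  # linear ramp: no curvature, knee at an extreme
  ramp <- seq(10, 1, length.out = 10)
  kn <- knee_threshold(ramp)
  expect_true(attr(kn, "rank") %in% c(1, 10))
  expect_warning(knee_threshold(rep(2, 5)), "degenerate")
  expect_error(knee_threshold(c(1, 2)), "at least 3")
  expect_error(knee_threshold(c(1, 2, 3)), "descending")
})

test_that("segment grouping and rank tests behave at the extremes", {
  sc <- make_scaffold(3, 5)
  v <- setNames(rep(0.5, 15), as.character(1:15))
  grouped <- per_segment_centrality(v, sc$map)
  expect_equal(sort(unique(grouped$segment)), c("TM1", "TM2", "TM3"))
  expect_equal(nrow(grouped), 15)

  # identical distributions -> p ~ 1
  set.seed(5)
  v2 <- setNames(c(rnorm(5, 1, 0.1), rnorm(5, 1, 0.1), rnorm(5, 1, 0.1)),
                 as.character(1:15))
  g2 <- per_segment_centrality(v2, sc$map)
  expect_gt(compare_segments(g2, "TM1", "TM2")$p.value, 0.05)

  # +10 sigma shift -> clear separation (larger groups for rank resolution)
  sc8 <- make_scaffold(2, 8)
  set.seed(6)
  v3 <- setNames(c(rnorm(8, 1, 0.1), rnorm(8, 1, 0.1) + 1),
                 as.character(1:16))
  g3 <- per_segment_centrality(v3, sc8$map)
  expect_lt(compare_segments(g3, "TM1", "TM2")$p.value, 1e-2)

  # statistic equals the exhaustive rank computation (Mann-Whitney U)
  a <- c(1.2, 3.4, 0.4)
  b <- c(2.2, 5.1, 0.1, 7.0)
  g <- data.frame(node = as.character(1:7),
                  segment = rep(c("TM1", "TM2"), c(3, 4)),
                  value = c(a, b))
  u <- sum(outer(a, b, `>`))
  expect_equal(unname(compare_segments(g, "TM1", "TM2")$statistic), u)
  # thresholding drops nodes at or below the threshold
  gt <- per_segment_centrality(setNames(c(0.1, 0.5, 0.9),
                                        as.character(1:3)),
                               sc$map, threshold = 0.5)
  expect_equal(nrow(gt), 1)
  expect_error(compare_segments(g, "TM1", "TM9"), "no surviving")
})

test_that("inter-segment edges are exactly the cross-segment subset", {
  sc <- make_scaffold(2, 5)
  e <- data.frame(from = c("1", "2", "5", "3"),
                  to = c("2", "3", "6", "9"),
                  w = c(0.9, 0.8, 0.7, 0.6))
  net <- toy_network(e)
  cross <- inter_segment_edges(net, sc$map, "TM1", "TM2")
  oracle <- e[(as.integer(e$from) <= 5) != (as.integer(e$to) <= 5), ]
  expect_equal(nrow(cross), nrow(oracle))
  expect_setequal(paste(cross$from, cross$to),
                  paste(oracle$from, oracle$to))
  none <- inter_segment_edges(toy_network(e[1:2, ]), sc$map, "TM1", "TM2")
  expect_equal(nrow(none), 0)
})

test_that("network serialises to an edge-list TSV", {
  net <- toy_network(data.frame(from = c("1", "2"), to = c("2", "3"),
                                w = c(0.9, 0.4)))
  f <- tempfile(fileext = ".tsv")
  write_network(net, f)
  back <- utils::read.delim(f, colClasses = c(from = "character",
                                              to = "character"))
  expect_equal(back$weight, net$edges$weight)
  expect_equal(back$from, net$edges$from)
})
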