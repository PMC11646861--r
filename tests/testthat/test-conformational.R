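test_that("rmsd_series matches the direct formula and rigid-shift cases", {
  sc <- make_scaffold(2, 3)
  x <- frame_coords(sc$traj, 1)
  shifted <- x
  shifted[, 1] <- shifted[, 1] + 0.1
  set.seed(3)
  wob <- x + matrix(rnorm(length(x), sd = 0.05), nrow(x), 3)
  tr <- trajectory(sc$traj$top,
                   allonet:::abind3(array(x, c(1, nrow(x), 3)),
                                    array(shifted, c(1, nrow(x), 3)),
                                    array(wob, c(1, nrow(x), 3))),
                   times = 0:2)
  sel <- select_atoms(tr$top, class = "all")
  s <- rmsd_series(tr, 1, selection = sel, fit = FALSE)
  expect_equal(s$value[1], 0)
  expect_equal(s$value[2], 0.1, tolerance = 1e-12)
  # direct formula oracle
  expect_equal(s$value[3], sqrt(mean(rowSums((wob - x)^2))),
               tolerance = 1e-12)
  # with fitting, the uniform translation is removed entirely
  sf <- rmsd_series(tr, 1, selection = sel, fit = TRUE)
  expect_lt(sf$value[2], 1e-9)
  expect_error(rmsd_series(tr, 1, selection = integer(0)), "empty")
})

test_that("rmsf matches closed forms for frozen, two-state and Gaussian motion", {
  sc <- make_scaffold(2, 3)
  n_at <- dim(sc$traj$coords)[2]
  frozen <- trajectory(sc$traj$top,
                       array(rep(frame_coords(sc$traj, 1), each = 5),
                             c(5, n_at, 3)), times = 0:4)
  expect_equal(rmsf_profile(frozen)$value, rep(0, 6))
  expect_error(rmsf_profile(sc$traj), "2 frames")

  # one CA oscillating +-a along x with equal occupancy -> RMSF = a
  a <- 0.07
  ca1 <- select_atoms(sc$traj$top, resid = 1, name = "CA")
  co <- frozen$coords
  co[c(1, 3), ca1, 1] <- co[c(1, 3), ca1, 1] + a
  co[c(2, 4), ca1, 1] <- co[c(2, 4), ca1, 1] - a
  two <- trajectory(sc$traj$top, co[1:4, , , drop = FALSE], times = 0:3)
  prof <- rmsf_profile(two)
  expect_equal(prof$value[1], a, tolerance = 1e-12)
  expect_equal(prof$value[-1], rep(0, 5))

  # isotropic Gaussian displacements, sd sigma per axis -> RMSF -> sigma*sqrt(3)
  sigma <- 0.04
  ens <- gaussian_ensemble(sc$traj, diag(6), sigma = sigma, n_frames = 4000,
                           seed = 9)
  g <- rmsf_profile(ens)
  expect_equal(mean(g$value), sigma * sqrt(3), tolerance = 0.03)
})

test_that("rmsf is invariant under a global rigid motion after re-fitting", {
  sc <- make_scaffold(2, 3)
  ens <- gaussian_ensemble(sc$traj, diag(6), n_frames = 60, seed = 4)
  base <- rmsf_profile(rms_fit(ens, 1))
  th <- 1.1
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- ens
  for (f in seq_len(n_frames(ens))) {
    moved$coords[f, , ] <- frame_coords(ens, f) %*% rot +
      matrix(rep(c(3, -1, 2), each = dim(ens$coords)[2]), ncol = 3)
  }
  again <- rmsf_profile(rms_fit(moved, 1))
  expect_equal(again$value, base$value, tolerance = 1e-8)
})

test_that("dihedral hand geometries, rigid-motion invariance and mirror flip", {
  # explicit atan2-constructed geometry: cis 0, trans 180, right-handed +90
  top <- topology(data.frame(name = c("CA", "CB", "CG", "CD1"),
                             elem = c("C", "C", "C", "C"),
                             resid = 1, resname = "TYR", chain = "A"))
  geo <- function(p4) rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), p4)
  for (case in list(list(p4 = c(1, 1, 0), want = 0),
                    list(p4 = c(1, -1, 0), want = 180),
                    list(p4 = c(1, 0, 1), want = 90))) {
    tr <- frame_traj(top, geo(case$p4))
    expect_equal(sidechain_dihedral(tr, 1)$value, case$want,
                 tolerance = 1e-10)
  }
  # rigid-motion invariance; mirror reflection flips the sign
  x <- geo(c(1, 0, 1))
  th <- 0.8
  rot <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
  moved <- x %*% rot + matrix(rep(c(1, 2, 3), each = 4), ncol = 3)
  expect_equal(sidechain_dihedral(frame_traj(top, moved), 1)$value, 90,
               tolerance = 1e-10)
  mirror <- x
  mirror[, 3] <- -mirror[, 3]
  expect_equal(sidechain_dihedral(frame_traj(top, mirror), 1)$value, -90,
               tolerance = 1e-10)
  expect_error(sidechain_dihedral(frame_traj(top, x), 1,
                                  atoms = c("CA", "CB", "CG", "CD2")),
               "CD2")
})

test_that("minimum distances honour brute force and periodic images", {
  set.seed(21)
  at <- data.frame(name = rep(c("CA", "CB", "CG"), 2),
                   elem = "C", resid = rep(c(1, 4), each = 3),
                   resname = "ALA", chain = "A")
  top <- topology(at)
  xyz <- matrix(runif(18, 0, 2), 6, 3)
  tr <- frame_traj(top, xyz)
  got <- min_distance_series(tr, 1, 4)$value
  oracle <- min(as.matrix(stats::dist(xyz))[1:3, 4:6])
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_equal(min_distance_series(tr, 4, 1)$value, got)

  # straddling a periodic boundary: naive 7.6 nm, true image distance 0.4 nm
  top2 <- topology(data.frame(name = c("CA", "CA"), elem = "C",
                              resid = c(1, 3), resname = "ALA", chain = "A"))
  co <- rbind(c(0.2, 0, 0), c(7.8, 0, 0))
  trb <- frame_traj(top2, co, box = matrix(c(8, 8, 8), 1))
  expect_equal(min_distance_series(trb, 1, 3)$value, 0.4, tolerance = 1e-12)
  # brute force over the 27 neighbouring images
  imgs <- as.matrix(expand.grid(-1:1, -1:1, -1:1)) * 8
  oracle_pbc <- min(sqrt(rowSums(sweep(imgs, 2, co[2, ] - co[1, ], `+`)^2)))
  expect_equal(min_distance_series(trb, 1, 3)$value, oracle_pbc)
})

test_that("segment distances reduce to atom distances and match brute force", {
  sc <- make_scaffold(2, 5)
  tr <- sc$traj
  # single-residue segments, min mode == min_distance_series
  expect_equal(segment_distance_series(tr, 1, 8, mode = "min")$value,
               min_distance_series(tr, 1, 8)$value)
  # centre-of-geometry oracle on multi-residue segments
  ia <- select_atoms(tr$top, resid = 1:3, class = "heavy")
  ib <- select_atoms(tr$top, resid = 6:8, class = "heavy")
  x <- frame_coords(tr, 1)
  oracle <- sqrt(sum((colMeans(x[ia, ]) - colMeans(x[ib, ]))^2))
  expect_equal(segment_distance_series(tr, 1:3, 6:8, mode = "com")$value,
               oracle, tolerance = 1e-12)
  expect_error(segment_distance_series(tr, 1:3, 3:5), "overlap")
})

test_that("linkage clustering separates planted conformers and ranks by size", {
  mb <- multibasin_trajectory(3, c(10, 6, 4), seed = 2)
  cl <- linkage_cluster(mb, cutoff = 0.1)
  expect_equal(length(cl$sizes), 3)
  expect_equal(cl$sizes, c(10L, 6L, 4L))
  # planted assignment recovered up to relabelling
  expect_equal(length(unique(paste(cl$assignments, attr(mb, "basins")))), 3)
  expect_equal(sum(cl$sizes), n_frames(mb))

  # all frames identical -> one cluster; cutoff above separation -> one cluster
  frozen <- trajectory(mb$top, mb$coords[rep(1, 5), , , drop = FALSE],
                       times = 0:4)
  expect_equal(length(linkage_cluster(frozen, cutoff = 0.1)$sizes), 1)
  expect_equal(length(linkage_cluster(mb, cutoff = 10)$sizes), 1)

  # frame-order invariance: same partition, ids re-ranked by size
  perm <- sample(seq_len(n_frames(mb)))
  shuffled <- trajectory(mb$top, mb$coords[perm, , , drop = FALSE],
                         times = seq_along(perm) - 1)
  cl2 <- linkage_cluster(shuffled, cutoff = 0.1)
  expect_equal(cl2$sizes, cl$sizes)
  expect_equal(cl2$assignments, cl$assignments[perm])
})

test_that("two rigid conformers at RMSD 0.5 split at cutoff 0.1", {
  sc <- make_scaffold(2, 3)
  x <- frame_coords(sc$traj, 1)
  set.seed(8)
  pat <- matrix(rnorm(length(x)), nrow(x), 3)
  pat <- sweep(pat, 2, colMeans(pat))
  y <- x + pat * 0.5 / sqrt(6)
  tr <- trajectory(sc$traj$top,
                   allonet:::abind3(array(x, c(1, nrow(x), 3)),
                                    array(x, c(1, nrow(x), 3)),
                                    array(y, c(1, nrow(x), 3))),
                   times = 0:2)
  cl <- linkage_cluster(tr, cutoff = 0.1)
  expect_equal(length(cl$sizes), 2)
  expect_equal(cl$sizes, c(2L, 1L))
})
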