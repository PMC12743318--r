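test_that("minimum-image distance matches 27-image brute force", {
  expect_equal(minimum_image_distance(c(1, 2, 3), c(1, 2, 3), c(10, 10, 10)), 0)
  expect_equal(minimum_image_distance(c(1, 0, 0), c(59, 0, 0), c(60, 60, 60)), 2)
  set.seed(101)
  for (i in 1:300) {
    box <- runif(3, 5, 40)
    a <- runif(3, 0, box); b <- runif(3, 0, box)
    expect_equal(minimum_image_distance(a, b, box), brute_min_image(a, b, box),
                 tolerance = 1e-9)
  }
  # below half the smallest box edge, imaging changes nothing
  a <- c(1, 1, 1); b <- c(3, 2, 1)
  expect_equal(minimum_image_distance(a, b, c(50, 50, 50)),
               sqrt(sum((a - b)^2)))
})

test_that("Kabsch recovers exact rigid motions and matches bio3d on noisy data", {
  set.seed(102)
  P <- matrix(rnorm(30), 10, 3)
  s0 <- kabsch_superpose(P, P)
  expect_equal(s0$rmsd, 0, tolerance = 1e-10)
  expect_equal(s0$rotation, diag(3), tolerance = 1e-8)
  for (i in 1:50) {
    Q <- rigid_motion(P)
    s <- kabsch_superpose(Q, P)
    expect_lt(s$rmsd, 1e-6)
    expect_equal(det(s$rotation), 1, tolerance = 1e-6)
  }
  # independent optimiser oracle on non-superposable sets
  for (i in 1:20) {
    A <- matrix(rnorm(15), 5, 3); B <- matrix(rnorm(15), 5, 3)
    ref <- bio3d::rmsd(as.vector(t(A)), as.vector(t(B)), fit = TRUE)
    expect_equal(kabsch_superpose(A, B)$rmsd, ref, tolerance = 1e-3)
  }
  expect_error(kabsch_superpose(matrix(c(0, 0, 0, 1, 0, 0, 2, 0, 0), 3,
                                       byrow = TRUE), P[1:3, ]), "collinear")
})

test_that("RMSD series is zero for rigid motion and matches hand arithmetic", {
  set.seed(103)
  base <- matrix(rnorm(24, sd = 3), 8, 3)
  top <- toy_topology(8)
  xyz <- rbind(as.vector(t(base)), as.vector(t(rigid_motion(base))),
               as.vector(t(base)))
  tr <- pet_trajectory(top, xyz)
  r <- rmsd_series(tr, seq_len(8))
  expect_equal(r, c(0, 0, 0), tolerance = 1e-6)
  # 2-frame toy: reference square vs square stretched along x by 2a.
  # After optimal superposition (identity), rmsd = sqrt(mean(dev^2)) = a.
  a <- 0.7
  sq <- matrix(c(1, 0, 0, -1, 0, 0, 0, 1, 0, 0, -1, 0), 4, 3, byrow = TRUE)
  sq2 <- sq; sq2[1:2, 1] <- c(1 + a, -1 - a)
  tr2 <- pet_trajectory(toy_topology(4), rbind(as.vector(t(sq)), as.vector(t(sq2))))
  expect_equal(rmsd_series(tr2, 1:4)[2], sqrt(mean(c(a, a, 0, 0)^2)),
               tolerance = 1e-6)
})

test_that("RMSF matches closed forms and the OU stationary sd", {
  top <- toy_topology(4)
  base <- matrix(c(0, 0, 0, 5, 0, 0, 0, 5, 0, 5, 5, 3), 4, 3, byrow = TRUE)
  # one atom oscillating +/- a along x, others fixed (no fitting)
  a <- 0.8
  xyz <- rbind(as.vector(t(base)), as.vector(t(base)), as.vector(t(base)))
  xyz[1, 10] <- base[4, 1] + a
  xyz[2, 10] <- base[4, 1] - a
  xyz[3, 10] <- base[4, 1] + a
  tr <- pet_trajectory(top, xyz)
  f <- rmsf(tr, 1:4, fit = FALSE)
  expect_equal(f[1:3], rep(0, 3), tolerance = 1e-10)
  expect_equal(f[4], sqrt(mean((c(a, -a, a) - a / 3)^2)), tolerance = 1e-10)
  expect_error(rmsf(pet_trajectory(top, xyz[1, , drop = FALSE]), 1:4), "2 frames")
  # OU marker trajectory: RMSF of the moving marker ~ process sd
  sim <- simulate_site(site_dynamics_params(d3 = distance_dynamics(5, 0.4, 10)),
                       n_frames = 4000, seed = 11)
  idx <- select_atoms(sim$trajectory$topology, "name ND1 and resid 234")$indices
  f2 <- rmsf(sim$trajectory, idx, fit = FALSE)
  expect_equal(f2, 0.4, tolerance = 0.2)
})

test_that("dihedrals follow the IUPAC convention and are rotation invariant", {
  p1 <- c(1, 1, 0); p2 <- c(1, 0, 0); p3 <- c(2, 0, 0)
  expect_equal(dihedral_angle(p1, p2, p3, c(2, 1, 0)), 0)     # cis
  expect_equal(dihedral_angle(p1, p2, p3, c(2, -1, 0)), 180)  # anti
  set.seed(104)
  for (i in 1:100) {
    q <- matrix(rnorm(12, sd = 2), 4, 3)
    q[2, ] <- q[1, ] + c(1.5, 0, 0); q[3, ] <- q[2, ] + c(0, 1.5, 0)
    ang <- dihedral_angle(q[1, ], q[2, ], q[3, ], q[4, ])
    qr <- rigid_motion(q)
    expect_equal(dihedral_angle(qr[1, ], qr[2, ], qr[3, ], qr[4, ]), ang,
                 tolerance = 1e-6)
    expect_gt(ang, -180); expect_lte(ang, 180)
  }
  expect_error(dihedral_angle(p1, p1, p3, c(2, 1, 0)), "degenerate")
})

test_that("contact counts equal the O(n^2) brute force and respect the boundary", {
  co <- matrix(c(0, 0, 0, 4.9, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(count_contacts(co, 1, 2, cutoff = 5), 1)
  co[2, 1] <- 5.1
  expect_equal(count_contacts(co, 1, 2, cutoff = 5), 0)
  expect_equal(count_contacts(co, integer(0), 2), 0)
  expect_error(count_contacts(co, 1:2, 2), "disjoint")
  set.seed(105)
  for (i in 1:100) {
    n <- 50
    co <- matrix(runif(3 * n, 0, 25), n, 3)
    box <- c(25, 25, 25)
    A <- 1:20; B <- 21:50
    brute <- 0
    for (a in A) for (b in B)
      if (brute_min_image(co[a, ], co[b, ], box) < 5) brute <- brute + 1
    expect_equal(count_contacts(co, A, B, cutoff = 5, box = box), brute)
  }
})

test_that("residue distance maps equal brute force and are symmetric", {
  top <- toy_topology(8)
  set.seed(106)
  residues <- list(r1 = 1:2, r2 = 3:4, r3 = 5:6, r4 = 7:8)
  xyz <- matrix(runif(2 * 24, 0, 20), 2, 24)
  tr <- pet_trajectory(top, xyz)
  dm <- residue_distance_map(tr, residues)
  expect_equal(unclass(dm), t(unclass(dm)))
  expect_equal(diag(unclass(dm)), rep(0, 4), ignore_attr = TRUE)
  brute <- matrix(0, 4, 4)
  for (f in 1:2) {
    fr <- frame_coords(tr, f)
    for (i in 1:4) for (j in 1:4) {
      m <- Inf
      for (a in residues[[i]]) for (b in residues[[j]])
        m <- min(m, sqrt(sum((fr[a, ] - fr[b, ])^2)))
      brute[i, j] <- brute[i, j] + m / 2
    }
  }
  diag(brute) <- 0
  expect_equal(unclass(dm), brute, ignore_attr = TRUE, tolerance = 1e-12)
  # two single-atom residues at fixed 7 A
  tr2 <- toy_trajectory(matrix(c(0, 0, 0, 7, 0, 0), 2, 3, byrow = TRUE))
  dm2 <- residue_distance_map(tr2, list(a = 1, b = 2))
  expect_equal(dm2["a", "b"], 7)
})

test_that("SASA matches closed forms, is additive, monotone and rigid-invariant", {
  r <- 1.8; p <- 1.4
  one <- shrake_rupley_sasa(matrix(0, 1, 3), r, probe = p)
  expect_equal(attr(one, "total"), 4 * pi * (r + p)^2, tolerance = 0.01)
  # far-separated atoms: additivity
  two <- shrake_rupley_sasa(matrix(c(0, 0, 0, 50, 0, 0), 2, 3, byrow = TRUE),
                            c(r, r), probe = p)
  expect_equal(attr(two, "total"), 2 * attr(one, "total"), tolerance = 1e-9)
  # two overlapping spheres vs the spherical-cap closed form
  r2 <- 1.5; d <- 2.0
  R1 <- r + p; R2 <- r2 + p
  cap1 <- 2 * pi * R1 * (R1 - (d^2 + R1^2 - R2^2) / (2 * d))
  cap2 <- 2 * pi * R2 * (R2 - (d^2 + R2^2 - R1^2) / (2 * d))
  expected <- (4 * pi * R1^2 - cap1) + (4 * pi * R2^2 - cap2)
  got <- shrake_rupley_sasa(matrix(c(0, 0, 0, d, 0, 0), 2, 3, byrow = TRUE),
                            c(r, r2), probe = p)
  expect_equal(attr(got, "total"), expected, tolerance = 0.02)
  # monotone non-increasing as occluders are added; rigid invariance
  set.seed(107)
  co <- matrix(rnorm(30, sd = 2), 10, 3)
  rad <- runif(10, 1.2, 1.9)
  a5 <- attr(shrake_rupley_sasa(co[1:5, ], rad[1:5]), "total")
  a5ctx <- attr(shrake_rupley_sasa(co, rad, subset = 1:5, context = 6:10), "total")
  expect_lte(a5ctx, a5 + 1e-9)
  # rigid invariance up to the angular resolution of the 960-point grid
  moved <- rigid_motion(co)
  expect_equal(attr(shrake_rupley_sasa(moved, rad), "total"),
               attr(shrake_rupley_sasa(co, rad), "total"), tolerance = 0.02)
  expect_error(shrake_rupley_sasa(co, c(rad[-1], NA)), "radius")
})
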