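test_that("PET chain has 22n + 2 atoms and exact sampled torsions", {
  ch <- build_pet_chain(9, conformer_mixture(), seed = 21)
  expect_equal(ch$topology$n_atoms, 200)
  expect_equal(build_pet_chain(1, conformer_mixture(), seed = 1)$topology$n_atoms, 24)
  mono <- pettraj:::.pet_monomers(ch$topology)
  fr <- ch$coords
  ang <- dihedral_angles(fr[mono$o3, ], fr[mono$c9, ], fr[mono$c10, ], fr[mono$o1, ])
  expect_equal(ang[order(mono$resid)], ch$angles, tolerance = 1e-9)
  expect_lt(max(abs(ang[order(mono$resid)] - ch$angles)), 1e-3)
  expect_equal(classify_conformer(ch$angles), ch$classes, ignore_attr = TRUE)
})

test_that("degenerate mixtures force their class; fractions converge binomially", {
  g <- build_pet_chain(20, conformer_mixture(1, 0, 0, sd = 0), seed = 22)
  expect_true(all(abs(abs(g$angles) - 70) < 1e-9))
  t <- build_pet_chain(20, conformer_mixture(0, 1, 0, sd = 0), seed = 23)
  expect_true(all(abs(abs(t$angles) - 180) < 1e-9))
  expect_error(conformer_mixture(0.5, 0.4, 0.2), "sum to 1")
  set.seed(24)
  s <- pettraj:::.sample_torsions(10000, conformer_mixture(0.82, 0.14, 0.04))
  for (cl in c("gauche", "trans", "other")) {
    p <- c(gauche = 0.82, trans = 0.14, other = 0.04)[[cl]]
    expect_lt(abs(mean(s$class == cl) - p), 3 * sqrt(p * (1 - p) / 10000))
  }
  expect_equal(classify_conformer(s$angle), s$class, ignore_attr = TRUE)
})

test_that("melt composition, density arithmetic and packing behaviour", {
  m <- build_melt(4, 9, seed = 25, box = c(60, 60, 60))
  expect_equal(m$topology$n_atoms, 4 * 200)
  # density oracle from the exact H-capped composition
  chain_mass <- 9 * (10 * 12.011 + 8 * 1.008 + 4 * 15.999) + 2 * 1.008
  expect_equal(m$density, 4 * chain_mass / 6.02214076e23 / (60^3 * 1e-24),
               tolerance = 1e-9)
  # one chain in a huge box: clash check passes, density ~ 0
  m1 <- build_melt(1, 9, seed = 26, box = c(500, 500, 500), clash_tol = 2)
  expect_lt(m1$density, 1e-3)
  # impossible packing errors out with advice
  expect_error(build_melt(40, 9, seed = 27, box = c(20, 20, 20), clash_tol = 3,
                          max_attempts = 5), "larger box")
})

test_that("fixed seed gives bit-identical generator output", {
  a <- build_melt(3, 9, seed = 31, box = c(70, 70, 70))
  b <- build_melt(3, 9, seed = 31, box = c(70, 70, 70))
  expect_identical(a$coords, b$coords)
  expect_identical(a$ground_truth, b$ground_truth)
  s1 <- generate_scenario(scenario_preset(n_frames = 50), seed = 32)
  s2 <- generate_scenario(scenario_preset(n_frames = 50), seed = 32)
  expect_identical(s1$trajectory$xyz, s2$trajectory$xyz)
  s3 <- generate_scenario(scenario_preset(n_frames = 50), seed = 33)
  expect_false(identical(s1$trajectory$xyz, s3$trajectory$xyz))
})

test_that("site simulation: sigma = 0 gives constant distances, switches move d3", {
  sim <- simulate_site(site_dynamics_params(
    d1 = distance_dynamics(6.5, 0), d2 = distance_dynamics(8.5, 0),
    d3 = distance_dynamics(3.0, 0), d4 = distance_dynamics(5.0, 0)),
    n_frames = 20, seed = 41)
  d <- compute_site_distances(sim$trajectory, site_preset("PETaseSM14"))
  expect_equal(d$d1, rep(6.5, 20), tolerance = 1e-9)
  expect_equal(d$d3, rep(3.0, 20), tolerance = 1e-9)
  expect_equal(sim$truth$distances[, "d3"], d$d3, tolerance = 1e-9,
               ignore_attr = TRUE)
  # irreversible switch at frame 51 of 500 to 15 A: active fraction 0.1
  sim2 <- simulate_site(site_dynamics_params(
    d3 = distance_dynamics(3.0, 0, switch = list(at = 51, to = 15))),
    n_frames = 500, seed = 42)
  expect_equal(sim2$truth$active_fraction, 0.1)
  # OU stationary mean within 3 standard errors
  sim3 <- simulate_site(site_dynamics_params(d3 = distance_dynamics(5, 0.5, 20)),
                        n_frames = 10000, seed = 43)
  x <- sim3$truth$distances[, "d3"]
  se <- 0.5 / sqrt(10000 / (2 * 20))
  expect_lt(abs(mean(x) - 5), 3 * se)
})

test_that("water placement is exact near/far with a sharp boundary", {
  w <- place_waters(c(10, 10, 10), n_near = 7, near_radius = 6, n_far = 20,
                    box = c(60, 60, 60), seed = 51)
  d <- minimum_image_distance(w, matrix(c(10, 10, 10), nrow(w), 3, byrow = TRUE),
                              c(60, 60, 60))
  expect_equal(sum(d < 6), 7)
  expect_true(all(d[8:27] >= 6))
  w0 <- place_waters(c(10, 10, 10), n_near = 0, near_radius = 6, n_far = 5,
                     box = c(60, 60, 60), seed = 52)
  expect_equal(sum(minimum_image_distance(
    w0, matrix(c(10, 10, 10), 5, 3, byrow = TRUE), c(60, 60, 60)) < 6), 0)
})

test_that("scenario ground truth matches emitted coordinates by construction", {
  cfg <- scenario_config(n_frames = 80, reactive_fraction = 0.5,
                         water_lambda = 5)
  scn <- generate_scenario(cfg, seed = 61)
  expect_equal(scn$truth$reactive_total, 40)
  an <- analyze_trajectory(scn$trajectory, scn$site)
  expect_equal(attr(an$reactive, "total"), 40)
  expect_equal(an$hydration$count, scn$truth$water_count)
  expect_equal(an$state$active_fraction, scn$truth$active_fraction)
  # measured torsions equal the sampled ground truth monomer by monomer
  ct <- an$conformers
  key <- paste(ct$chain, ct$resid)
  mkey <- paste(scn$truth$monomers$chain, scn$truth$monomers$resid)
  truth_ang <- scn$truth$angles[cbind(match(key, mkey), ct$frame)]
  expect_lt(max(abs(ct$angle - truth_ang)), 1e-3)
  truth_cls <- scn$truth$classes[cbind(match(key, mkey), ct$frame)]
  expect_equal(ct$class, truth_cls)
  # measured partition equals the generator's per-frame bound labels
  truth_bnd <- scn$truth$bound[cbind(match(key, mkey), ct$frame)]
  expect_equal(ct$partition == "bound", truth_bnd)
})

test_that("scenario files round-trip through the standard formats", {
  scn <- generate_scenario(scenario_preset(n_frames = 12), seed = 71)
  dir <- tempfile()
  files <- write_scenario(scn, dir, "rep1")
  expect_true(all(file.exists(files)))
  top <- read_topology(files[["pdb"]])
  tr <- read_trajectory(files[["dcd"]], top)
  expect_equal(n_frames(tr), 12)
  expect_lt(max(abs(tr$xyz - scn$trajectory$xyz)), 1e-3)
  truth <- jsonlite::read_json(files[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$active_fraction, scn$truth$active_fraction)
  expect_equal(length(truth$d3), 12)
})
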