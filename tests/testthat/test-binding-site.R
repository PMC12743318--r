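test_that("site presets map the published atom pairs", {
  sm <- site_preset("PETaseSM14")
  expect_equal(sm$pairs$d4[[1]]$resid, 155)
  expect_equal(sm$pairs$d4[[1]]$name, "ND1")
  expect_equal(sm$pairs$d4[[2]]$resid, 238)
  expect_equal(sm$pairs$d4[[2]]$name, "CG")
  expect_equal(sm$pairs$d3[[1]]$name, "OG")
  expect_equal(sm$his_ne$name, "NE2")
  is <- site_preset("IsPETase")
  expect_equal(is$pairs$d1[[1]]$resid, 87)
  expect_equal(is$pairs$d1[[2]]$resid, 208)
  expect_equal(is$pairs$d4[[1]]$resname, "TRP")
  expect_equal(is$binding_site$asp$resid, 206)
})

test_that("site distances match hand arithmetic and constants", {
  sim <- sm14_marker_frame(c(d1 = 6.5, d2 = 8.5, d3 = 3.0, d4 = 5.0))
  d <- compute_site_distances(sim$trajectory, site_preset("PETaseSM14"))
  expect_equal(d$d1, c(6.5, 6.5), tolerance = 1e-9)
  expect_equal(d$d2, c(8.5, 8.5), tolerance = 1e-9)
  expect_equal(d$d4, c(5.0, 5.0), tolerance = 1e-9)
  # hand-placed 4-atom check through a raw topology
  atoms <- data.frame(serial = 1:4, name = c("OH", "CD1", "OG", "ND1"),
                      resname = c("TYR", "ILE", "SER", "HIS"),
                      resid = c(88, 204, 156, 234), segid = "PROT")
  co <- matrix(c(0, 0, 0, 3, 4, 0, 10, 0, 0, 10, 0, 12), 4, 3, byrow = TRUE)
  top <- pet_topology(atoms)
  tr <- pet_trajectory(top, matrix(as.vector(t(co)), 1))
  sp <- site_spec("toy",
                  d1 = list(list(resid = 88, name = "OH"), list(resid = 204, name = "CD1")),
                  d2 = list(list(resid = 88, name = "OH"), list(resid = 204, name = "CD1")),
                  d3 = list(list(resid = 156, name = "OG"), list(resid = 234, name = "ND1")),
                  d4 = list(list(resid = 156, name = "OG"), list(resid = 234, name = "ND1")),
                  ser_og = list(resid = 156, name = "OG"),
                  his_ne = list(resid = 234, name = "ND1"),
                  binding_site = list(ser = list(resid = 156), his = list(resid = 234)))
  d2 <- compute_site_distances(tr, sp)
  expect_equal(d2$d1, 5)    # 3-4-5 triangle
  expect_equal(d2$d3, 12)
  # unresolved atom names the role
  sp2 <- sp; sp2$pairs$d1[[2]]$resid <- 999
  expect_error(compute_site_distances(tr, sp2), "d1/atom2")
})

test_that("activity classification counts transitions, dwell and reversibility", {
  s1 <- classify_activity(rep(3, 50))
  expect_equal(s1$active_fraction, 1)
  expect_equal(nrow(s1$transitions), 0)
  expect_false(s1$reversible)
  s2 <- classify_activity(c(rep(4, 85), rep(12, 15)))
  expect_equal(s2$active_fraction, 0.85)
  expect_equal(nrow(s2$transitions), 1)
  expect_false(s2$reversible)
  expect_equal(s2$dwell$length, c(85, 15))
  # constructed trace crossing the threshold 7 times
  d3 <- rep(c(3, 8), length.out = 8 * 10, each = 10)[1:80]
  s3 <- classify_activity(d3)
  expect_equal(nrow(s3$transitions), 7)
  expect_true(s3$reversible)
  # boundary: exactly at threshold counts as active
  expect_equal(classify_activity(c(5, 5.001))$active_fraction, 0.5)
})

test_that("reactive counting needs the Ser-His and Ser-ester conjunction", {
  atoms <- data.frame(
    serial = 1:5,
    name = c("OG", "NE2", "ND1", "C1", "C8"),
    resname = c("SER", "HIS", "HIS", "PET", "PET"),
    resid = c(156, 234, 234, 1, 1),
    segid = c("PROT", "PROT", "PROT", "PET", "PET"))
  top <- pet_topology(atoms)
  site <- site_preset("PETaseSM14")
  mk <- function(ne2, c1, c8 = c(40, 40, 40)) {
    co <- rbind(c(0, 0, 0), ne2, c(0, 0, 2), c1, c8)
    pet_trajectory(top, matrix(as.vector(t(co)), 1))
  }
  r1 <- count_reactive_states(mk(ne2 = c(3, 0, 0), c1 = c(0, 3, 0)), site)
  expect_equal(r1$count, 1)
  # Ser-His too far: no reactive state regardless of esters
  r2 <- count_reactive_states(mk(ne2 = c(6, 0, 0), c1 = c(0, 3, 0)), site)
  expect_equal(r2$count, 0)
  # strict inequality at the cutoff
  r3 <- count_reactive_states(mk(ne2 = c(3, 0, 0), c1 = c(5, 0, 0)), site)
  expect_equal(r3$count, 0)
  # both esters close -> count 2 (ester carbons, not chains)
  r4 <- count_reactive_states(mk(ne2 = c(3, 0, 0), c1 = c(0, 3, 0),
                                 c8 = c(0, -3, 0)), site)
  expect_equal(r4$count, 2)
  # brute-force oracle over random ester positions
  set.seed(201)
  for (i in 1:50) {
    n_est <- 20
    est <- matrix(runif(3 * n_est, -8, 8), n_est, 3)
    atoms2 <- rbind(atoms[1:3, ],
                    data.frame(serial = 3 + seq_len(n_est), name = "C1",
                               resname = "PET", resid = seq_len(n_est),
                               segid = "PET"))
    top2 <- pet_topology(atoms2)
    ne2 <- runif(3, -4, 4)
    co <- rbind(c(0, 0, 0), ne2, c(0, 0, 2), est)
    tr <- pet_trajectory(top2, matrix(as.vector(t(co)), 1))
    got <- count_reactive_states(tr, site)$count
    brute <- if (sqrt(sum(ne2^2)) < 5) sum(sqrt(rowSums(est^2)) < 5) else 0L
    expect_equal(got, brute)
  }
})

test_that("reactive counts are anti-monotone in the cutoff", {
  scn <- generate_scenario(scenario_preset(n_frames = 40), seed = 202)
  cuts <- c(3, 4, 5, 6)
  tot <- vapply(cuts, function(cc)
    attr(count_reactive_states(scn$trajectory, scn$site, cutoff = cc), "total"),
    numeric(1))
  expect_true(all(diff(tot) >= 0))
})

test_that("pocket water counting is exact, bounded and brute-force identical", {
  # forced placement through the generator
  scn <- generate_scenario(scenario_config(n_frames = 30, water_lambda = 7),
                           seed = 203)
  h <- count_pocket_waters(scn$trajectory, scn$site)
  expect_equal(h$count, scn$truth$water_count)
  # boundary: 6.05 A excluded, brute force on random waters
  atoms <- data.frame(serial = 1:2, name = c("OG", "OH2"),
                      resname = c("SER", "TIP3"), resid = c(156, 1),
                      segid = c("PROT", "WAT"))
  top <- pet_topology(atoms)
  site <- site_preset("PETaseSM14")
  tr <- pet_trajectory(top, matrix(c(0, 0, 0, 6.05, 0, 0), 1))
  expect_equal(count_pocket_waters(tr, site)$count, 0)
  tr2 <- pet_trajectory(top, matrix(c(0, 0, 0, 5.95, 0, 0), 1))
  expect_equal(count_pocket_waters(tr2, site)$count, 1)
  set.seed(204)
  nw <- 1000
  wat <- matrix(runif(3 * nw, 0, 30), nw, 3)
  atoms3 <- rbind(atoms[1, ], data.frame(serial = 1 + seq_len(nw), name = "OH2",
                                         resname = "TIP3", resid = seq_len(nw),
                                         segid = "WAT"))
  tr3 <- pet_trajectory(pet_topology(atoms3),
                        matrix(as.vector(t(rbind(c(15, 15, 15), wat))), 1),
                        box = c(30, 30, 30))
  brute <- sum(apply(wat, 1, function(w)
    brute_min_image(w, c(15, 15, 15), c(30, 30, 30))) <= 6)
  expect_equal(count_pocket_waters(tr3, site)$count, brute)
  expect_error(count_pocket_waters(pet_trajectory(
    pet_topology(atoms[1, , drop = FALSE]), matrix(c(0, 0, 0), 1)), site),
    "no water")
})

test_that("binding-site SASA: closed form for one residue, decreases on contact", {
  atoms <- data.frame(serial = 1:2, name = c("OG", "ND1"),
                      resname = c("SER", "HIS"), resid = c(156, 234),
                      segid = "PROT")
  top <- pet_topology(atoms)
  sp <- site_spec("toy",
                  d1 = list(list(resid = 156, name = "OG"), list(resid = 234, name = "ND1")),
                  d2 = list(list(resid = 156, name = "OG"), list(resid = 234, name = "ND1")),
                  d3 = list(list(resid = 156, name = "OG"), list(resid = 234, name = "ND1")),
                  d4 = list(list(resid = 156, name = "OG"), list(resid = 234, name = "ND1")),
                  ser_og = list(resid = 156, name = "OG"),
                  his_ne = list(resid = 234, name = "ND1"),
                  binding_site = list(ser = list(resid = 156)))
  far <- pet_trajectory(top, matrix(c(0, 0, 0, 50, 0, 0), 1))
  s_far <- binding_site_sasa(far, sp, context = "site")
  expect_equal(s_far$sasa, 4 * pi * (1.52 + 1.4)^2, tolerance = 0.01)
  near <- pet_trajectory(top, matrix(c(0, 0, 0, 2, 0, 0), 1))
  s_near <- binding_site_sasa(near, sp, context = "protein")
  expect_lt(s_near$sasa, s_far$sasa)
})
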