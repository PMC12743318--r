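#' Configuration of a synthetic enzyme-PET-water scenario
#'
#' A scenario composes, in one periodic box: the binding-site marker atoms
#' driven by [site_dynamics_params()], one PET chain adsorbed at the
#' binding site, a slab of bulk PET chains well below the site, water
#' oxygens exchanging between the pocket and the bulk, and an ester-carbon
#' probe that realises a configurable reactive-state frequency. Every
#' downstream observable has an exact per-frame ground truth.
#'
#' @param enzyme `"IsPETase"` or `"PETaseSM14"` (selects the marker preset).
#' @param condition free-text condition tag (e.g. `"150 mM"`).
#' @param n_frames,time_step trajectory length and spacing (ns).
#' @param site_params a [site_dynamics_params()].
#' @param water_lambda Poisson mean of the per-frame pocket water count.
#' @param n_waters total water count in the box.
#' @param pocket_radius pocket radius (A) used when placing waters.
#' @param reactive_fraction fraction of all frames that are reactive
#'   states; must be attainable within the active frames.
#' @param reactive_cutoff,bound_cutoff analysis cutoffs the generator must
#'   respect when placing atoms (A).
#' @param bulk_mixture,bound_mixture [conformer_mixture()]s for bulk
#'   monomers and for monomers within `bound_cutoff` of the serine.
#' @param n_bulk_chains,n_monomers bulk slab composition.
#' @param box box edge lengths (A).
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(enzyme = "PETaseSM14", condition = "150 mM",
                            n_frames = 1000, time_step = 0.5,
                            site_params = site_dynamics_params(),
                            water_lambda = 6, n_waters = 60,
                            pocket_radius = 6,
                            reactive_fraction = 0.1, reactive_cutoff = 5,
                            bound_cutoff = 8,
                            bulk_mixture = conformer_mixture(),
                            bound_mixture = conformer_mixture(),
                            n_bulk_chains = 20, n_monomers = 9,
                            box = c(90, 90, 110)) {
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (reactive_fraction < 0 || reactive_fraction > 1)
    stop("reactive_fraction must be in [0, 1]")
  if (!inherits(site_params, "site_dynamics_params"))
    stop("site_params must be a site_dynamics_params object")
  if (any(box <= 0) || box[3] < 80)
    stop("box must be positive with a z edge of at least 80 A")
  structure(as.list(environment()), class = "scenario_config")
}

#' Study-condition presets for the four simulated systems
#'
#' Default scenario parameters emulating the behaviour of the two enzymes
#' at the two salt concentrations: marker-distance levels and
#' activation/inactivation switches, pocket hydration levels,
#' reactive-state frequencies, and bound/bulk conformer mixtures. The
#' vignette documents the choice of every value.
#'
#' @param enzyme `"IsPETase"` or `"PETaseSM14"`.
#' @param salt `"150 mM"` or `"900 mM"`.
#' @param n_frames frames per replica.
#' @return a [scenario_config()].
#' @export
scenario_preset <- function(enzyme = c("PETaseSM14", "IsPETase"),
                            salt = c("150 mM", "900 mM"), n_frames = 1000) {
  enzyme <- match.arg(enzyme)
  salt <- match.arg(salt)
  fr <- function(f) max(2L, min(n_frames - 1L, as.integer(round(f * n_frames))))
  bulk <- conformer_mixture(0.82, 0.14, 0.04)
  if (enzyme == "PETaseSM14" && salt == "150 mM") {
    scenario_config(
      enzyme = enzyme, condition = salt, n_frames = n_frames,
      site_params = site_dynamics_params(
        d1 = distance_dynamics(6.75, 0.25),
        d2 = distance_dynamics(8.5, 0.4),
        d3 = distance_dynamics(3.8, 0.35,
          switch = list(at = fr(0.76) + 1L, to = 12, revert_at = fr(0.91) + 1L)),
        d4 = distance_dynamics(5.0, 0.3)),
      water_lambda = 5.7, reactive_fraction = 0.096,
      bulk_mixture = bulk,
      bound_mixture = conformer_mixture(0.9574, 0.0026, 0.04))
  } else if (enzyme == "PETaseSM14") {
    scenario_config(
      enzyme = enzyme, condition = salt, n_frames = n_frames,
      site_params = site_dynamics_params(
        d1 = distance_dynamics(6.75, 0.25),
        d2 = distance_dynamics(10.5, 0.4),
        d3 = distance_dynamics(2.75, 0.3),
        d4 = distance_dynamics(5.0, 0.3)),
      water_lambda = 7.7, reactive_fraction = 0.192,
      bulk_mixture = bulk, bound_mixture = bulk)
  } else if (salt == "150 mM") {
    scenario_config(
      enzyme = enzyme, condition = salt, n_frames = n_frames,
      site_params = site_dynamics_params(
        d1 = distance_dynamics(9.0, 0.3),
        d2 = distance_dynamics(10.25, 0.4),
        d3 = distance_dynamics(3.8, 0.35, switch = list(at = fr(0.2) + 1L, to = 12)),
        d4 = distance_dynamics(5.0, 0.3, switch = list(at = fr(0.24) + 1L, to = 8))),
      water_lambda = 9.0, reactive_fraction = 0.12,
      bulk_mixture = bulk, bound_mixture = bulk)
  } else {
    scenario_config(
      enzyme = enzyme, condition = salt, n_frames = n_frames,
      site_params = site_dynamics_params(
        d1 = distance_dynamics(10.7, 0.3),
        d2 = distance_dynamics(10.25, 0.4),
        d3 = distance_dynamics(3.8, 0.35, switch = list(at = fr(0.08) + 1L, to = 16)),
        d4 = distance_dynamics(5.0, 0.3, switch = list(at = fr(0.04) + 1L, to = 8.5))),
      water_lambda = 9.5, reactive_fraction = 0.06,
      bulk_mixture = bulk,
      bound_mixture = conformer_mixture(0.56, 0.32, 0.12))
  }
}

#' Generate a complete synthetic scenario with ground truth
#'
#' @param config a [scenario_config()].
#' @param seed integer RNG seed; a fixed seed gives bit-identical output.
#' @return object of class `pet_scenario`: list with `topology`,
#'   `trajectory`, `truth`, `site` (the [site_spec()] preset) and
#'   `config`. `truth` carries per-frame state labels, marker distances
#'   and their mean paths, reactive frames, pocket water counts, and
#'   per-monomer-per-frame conformer classes, angles and bound labels.
#' @export
generate_scenario <- function(config, seed = 1) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(seed)
  cf <- config
  nf <- cf$n_frames
  center <- c(cf$box[1] / 2, cf$box[2] / 2, cf$box[3] - 40)
  site <- site_preset(cf$enzyme)

  # 1. binding-site markers --------------------------------------------
  sim <- simulate_site(cf$site_params, nf, site = site, center = center,
                       box = cf$box, time_step = cf$time_step)
  mark_atoms <- sim$trajectory$topology$atoms
  n_mark <- nrow(mark_atoms)

  # 2. adsorbed PET chain: extended coil along x, offset (0, 6, 4) from
  # the serine so ester carbons clear the reactive cutoff while two to
  # three monomers stay within the bound cutoff
  bc <- build_pet_chain(cf$n_monomers, cf$bulk_mixture, chain_id = "B",
                        start_resid = 1001L)
  cc <- sweep(bc$coords, 2, colMeans(bc$coords))
  xyz_b <- cc %*% svd(cc)$v
  xyz_b <- sweep(xyz_b, 2, center + c(0, 6, 4), "+")
  eidx_b <- which(bc$topology$atoms$name %in% c("C1", "C8"))
  dirv <- c(0, 6, 4) / sqrt(52)
  for (i in 1:20) {
    de <- sqrt(rowSums(sweep(xyz_b[eidx_b, , drop = FALSE], 2, center)^2))
    if (min(de) >= cf$reactive_cutoff + 0.3) break
    xyz_b <- sweep(xyz_b, 2, dirv * (cf$reactive_cutoff + 0.3 - min(de) + 0.05), "+")
  }
  # Slide the chain along its axis so that no monomer's bound/bulk
  # membership depends on the per-frame O1 placement: a monomer whose
  # nearest *static* atom sits between the cutoff and cutoff + 2.8 A
  # (the maximal O1 swing) would be classified bound preferentially at
  # certain torsions, biasing the bound-partition class statistics.
  b_resid <- bc$topology$atoms$resid
  b_mono <- split(seq_len(nrow(xyz_b)), b_resid)
  o1_idx <- which(bc$topology$atoms$name == "O1")
  band_count <- function(xyz) {
    vapply(b_mono, function(idx) {
      st <- min(sqrt(rowSums(sweep(xyz[setdiff(idx, o1_idx), , drop = FALSE],
                                   2, center)^2)))
      st > cf$bound_cutoff && st < cf$bound_cutoff + 2.8
    }, logical(1))
  }
  est_ok <- function(xyz) {
    min(sqrt(rowSums(sweep(xyz[eidx_b, , drop = FALSE], 2, center)^2))) >=
      cf$reactive_cutoff + 0.3
  }
  best <- xyz_b; best_n <- sum(band_count(xyz_b))
  for (dx in seq(-2.75, 2.75, by = 0.25)) {
    cand <- sweep(xyz_b, 2, c(dx, 0, 0), "+")
    if (!est_ok(cand)) next
    nb <- sum(band_count(cand))
    if (nb < best_n) { best <- cand; best_n <- nb }
    if (best_n == 0) break
  }
  xyz_b <- best

  db_all <- sqrt(rowSums(sweep(xyz_b, 2, center)^2))
  if (min(db_all) > cf$bound_cutoff - 0.5)
    stop("inconsistent scenario geometry: adsorbed chain has no bound monomer")

  # 3. bulk slab, fully contained well below the site
  slab_box <- c(cf$box[1] - 30, cf$box[2] - 30, center[3] - 30)
  slab_origin <- c(15, 15, 10)
  melt <- build_melt(cf$n_bulk_chains, cf$n_monomers, cf$bulk_mixture,
                     box = slab_box, clash_tol = 0.5, contain = TRUE)
  xyz_m <- sweep(melt$coords, 2, slab_origin, "+")

  # 4. assemble the static topology ------------------------------------
  b_atoms <- bc$topology$atoms
  m_atoms <- melt$topology$atoms
  w_atoms <- .water_topology(cf$n_waters)
  cols <- c("serial", "name", "resname", "resid", "segid", "chain")
  atoms <- rbind(mark_atoms[cols], b_atoms[cols], m_atoms[cols], w_atoms[cols])
  atoms$serial <- seq_len(nrow(atoms))
  top <- pet_topology(atoms)
  off_b <- n_mark
  off_m <- n_mark + nrow(b_atoms)
  off_w <- off_m + nrow(m_atoms)
  n_atoms <- nrow(atoms)
  static <- rbind(frame_coords(sim$trajectory, 1), xyz_b, xyz_m,
                  matrix(rep(c(5, 5, 5), cf$n_waters), ncol = 3, byrow = TRUE))

  # melt ester carbons must be nowhere near the serine
  em <- off_m + which(m_atoms$name %in% c("C1", "C8"))
  if (min(sqrt(rowSums(sweep(static[em, , drop = FALSE], 2, center)^2))) <
      cf$reactive_cutoff + 1)
    stop("inconsistent scenario geometry: bulk ester carbon near the site")

  # 5. per-monomer conformer resampling --------------------------------
  mono <- .pet_monomers(top)
  M <- nrow(mono)
  static_min <- vapply(mono$atoms, function(idx)
    min(sqrt(rowSums(sweep(static[idx, , drop = FALSE], 2, center)^2))),
    numeric(1))
  # a monomer gets the bound mixture if it can ever be measured as bound:
  # static distance within the cutoff plus the maximal O1 swing (the O1
  # re-placement moves on a circle of radius 1.44*sin(70.5 deg) = 1.36 A,
  # so positions differ by at most 2.72 A between frames)
  use_bound_mix <- static_min <= cf$bound_cutoff + 2.75
  classes <- matrix(NA_character_, M, nf)
  angles <- matrix(NA_real_, M, nf)
  for (grp in list(which(use_bound_mix), which(!use_bound_mix))) {
    if (length(grp) == 0) next
    mix <- if (isTRUE(use_bound_mix[grp[1]])) cf$bound_mixture else cf$bulk_mixture
    s <- .sample_torsions(length(grp) * nf, mix)
    classes[grp, ] <- s$class
    angles[grp, ] <- s$angle
  }

  # re-place every monomer's O1 on the cone about C9->C10 so that the
  # measured O3-C9-C10-O1 torsion equals the sampled angle exactly
  A <- static[mono$o3, , drop = FALSE]
  B <- static[mono$c9, , drop = FALSE]
  C <- static[mono$c10, , drop = FALSE]
  e1 <- (C - B) / sqrt(rowSums((C - B)^2))
  ab <- B - A
  e3 <- .rowcross(ab, e1); e3 <- e3 / sqrt(rowSums(e3^2))
  e2 <- .rowcross(e3, e1)
  bond <- 1.44; th <- (180 - 109.5) * pi / 180
  cph <- cos(angles * pi / 180); sph <- sin(angles * pi / 180)
  o1x <- C[, 1] + bond * (cos(th) * e1[, 1] + sin(th) * (cph * e2[, 1] + sph * e3[, 1]))
  o1y <- C[, 2] + bond * (cos(th) * e1[, 2] + sin(th) * (cph * e2[, 2] + sph * e3[, 2]))
  o1z <- C[, 3] + bond * (cos(th) * e1[, 3] + sin(th) * (cph * e2[, 3] + sph * e3[, 3]))

  # 6. reactive-state probe ---------------------------------------------
  probe_mono <- which.min(ifelse(mono$chain == "B", static_min, Inf))
  probe_idx <- mono$atoms[[probe_mono]][
    match("C1", top$atoms$name[mono$atoms[[probe_mono]]])]
  eligible <- which(sim$truth$distances[, "d3"] < cf$reactive_cutoff - 0.1)
  n_react <- as.integer(round(cf$reactive_fraction * nf))
  if (n_react > length(eligible))
    stop("inconsistent scenario config: reactive_fraction ", cf$reactive_fraction,
         " exceeds the available active frames (", length(eligible), "/", nf, ")")
  react_frames <- sort(sample(eligible, n_react))
  reactive <- rep(FALSE, nf); reactive[react_frames] <- TRUE
  probe_pos <- center + 3.0 * c(0, 0.8, 0.6)

  # 7. pocket/bulk water exchange ---------------------------------------
  wcount <- pmin(stats::rpois(nf, cf$water_lambda), cf$n_waters)
  W <- matrix(NA_real_, nf, 3 * cf$n_waters)
  far_lo <- c(5, 5, center[3] + 10)
  far_hi <- c(cf$box[1] - 5, cf$box[2] - 5, cf$box[3] - 5)
  for (f in seq_len(nf)) {
    k <- wcount[f]
    coords <- matrix(NA_real_, cf$n_waters, 3)
    if (k > 0) {
      r <- cf$pocket_radius * 0.98 * stats::runif(k)^(1 / 3)
      u <- matrix(stats::rnorm(3 * k), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      coords[seq_len(k), ] <- sweep(u * r, 2, center, "+")
    }
    if (k < cf$n_waters) {
      nf_far <- cf$n_waters - k
      coords[(k + 1):cf$n_waters, ] <-
        matrix(stats::runif(3 * nf_far, far_lo, far_hi), ncol = 3, byrow = TRUE)
    }
    W[f, ] <- as.vector(t(coords))
  }

  # 8. assemble the coordinate matrix -----------------------------------
  xyz <- matrix(as.vector(t(static)), nf, 3 * n_atoms, byrow = TRUE)
  xyz[, seq_len(3 * n_mark)] <- sim$trajectory$xyz
  xyz[, 3 * mono$o1 - 2] <- t(o1x)
  xyz[, 3 * mono$o1 - 1] <- t(o1y)
  xyz[, 3 * mono$o1] <- t(o1z)
  xyz[react_frames, 3 * probe_idx - 2] <- probe_pos[1]
  xyz[react_frames, 3 * probe_idx - 1] <- probe_pos[2]
  xyz[react_frames, 3 * probe_idx] <- probe_pos[3]
  xyz[, (3 * off_w + 1):(3 * n_atoms)] <- W
  traj <- pet_trajectory(top, xyz, box = cf$box,
                         time = (seq_len(nf) - 1) * cf$time_step)

  # 9. exact per-frame ground truth -------------------------------------
  stat_excl <- vapply(seq_len(M), function(m) {
    idx <- setdiff(mono$atoms[[m]], c(mono$o1[m], probe_idx))
    min(sqrt(rowSums(sweep(static[idx, , drop = FALSE], 2, center)^2)))
  }, numeric(1))
  o1d <- sqrt((o1x - center[1])^2 + (o1y - center[2])^2 + (o1z - center[3])^2)
  mind <- pmin(matrix(stat_excl, M, nf), o1d)
  pd_static <- sqrt(sum((static[probe_idx, ] - center)^2))
  pm_d <- ifelse(reactive, 3.0, pd_static)
  mind[probe_mono, ] <- pmin(mind[probe_mono, ], pm_d)
  bound <- mind <= cf$bound_cutoff

  truth <- list(
    active = sim$truth$active,
    active_fraction = sim$truth$active_fraction,
    threshold = cf$site_params$activity_threshold,
    distances = sim$truth$distances,
    mean_paths = sim$truth$mean_paths,
    reactive = reactive,
    reactive_total = n_react,
    water_count = wcount,
    monomers = data.frame(chain = mono$chain, resid = mono$resid,
                          mixture = ifelse(use_bound_mix, "bound", "bulk"),
                          static_min = static_min, stringsAsFactors = FALSE),
    classes = classes, angles = angles, bound = bound,
    probe = list(chain = "B", resid = mono$resid[probe_mono], atom = "C1"))
  structure(list(topology = top, trajectory = traj, truth = truth,
                 site = site, config = cf, seed = seed),
            class = "pet_scenario")
}

#' @export
print.pet_scenario <- function(x, ...) {
  cat("pet_scenario:", x$config$enzyme, "at", x$config$condition, "-",
      n_frames(x$trajectory), "frames,", x$topology$n_atoms, "atoms\n")
  cat(sprintf("  true active fraction %.3f, reactive frames %d, <pocket waters> %.2f\n",
              x$truth$active_fraction, x$truth$reactive_total,
              mean(x$truth$water_count)))
  invisible(x)
}

#' Write a scenario to standard files
#'
#' Emits a multi-model PDB of the first frame (topology carrier), a DCD
#' trajectory, and a JSON ground-truth sidecar with per-frame state,
#' reactive and water-count channels and the marker-distance series.
#'
#' @param scenario a `pet_scenario`.
#' @param dir output directory (created if needed).
#' @param name file basename.
#' @return named character vector of the files written, invisibly.
#' @export
write_scenario <- function(scenario, dir, name = "replica") {
  stopifnot(inherits(scenario, "pet_scenario"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pdb <- file.path(dir, paste0(name, ".pdb"))
  dcd <- file.path(dir, paste0(name, ".dcd"))
  js <- file.path(dir, paste0(name, "_truth.json"))
  first <- pet_trajectory(scenario$topology,
                          scenario$trajectory$xyz[1, , drop = FALSE],
                          box = scenario$trajectory$box[1, ],
                          time = scenario$trajectory$time[1])
  write_trajectory(first, pdb, format = "pdb")
  write_trajectory(scenario$trajectory, dcd, format = "dcd")
  tr <- scenario$truth
  jsonlite::write_json(list(
    enzyme = scenario$config$enzyme, condition = scenario$config$condition,
    seed = scenario$seed, n_frames = n_frames(scenario$trajectory),
    active_fraction = tr$active_fraction, reactive_total = tr$reactive_total,
    active = as.integer(tr$active), reactive = as.integer(tr$reactive),
    water_count = tr$water_count,
    d1 = tr$distances[, "d1"], d2 = tr$distances[, "d2"],
    d3 = tr$distances[, "d3"], d4 = tr$distances[, "d4"]),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(pdb = pdb, dcd = dcd, truth = js))
}
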