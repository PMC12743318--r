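#' Conformer mixture for synthetic PET chains
#'
#' Defaults reproduce the conformational composition of amorphous PET:
#' 82% gauche, 14% trans, 4% unclassified. Sampled angles are drawn inside
#' the closed classification windows (gauche `|angle|` in `[50, 90]` with
#' random sign, trans in `[160, 180]`, other in the complement), so the
#' generated class always equals the measured class.
#'
#' @param p_gauche,p_trans,p_other class probabilities (sum to 1).
#' @param sd angular standard deviation (degrees) around the class centre
#'   (70 / 180); draws are rejected back into the class window.
#' @return object of class `conformer_mixture`.
#' @export
conformer_mixture <- function(p_gauche = 0.82, p_trans = 0.14,
                              p_other = 0.04, sd = 8) {
  p <- c(gauche = p_gauche, trans = p_trans, other = p_other)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("mixture fractions must be non-negative and sum to 1")
  if (sd < 0) stop("angular sd must be >= 0")
  structure(list(p = p, sd = sd), class = "conformer_mixture")
}

# Sample n torsion angles and their classes from a mixture.
.sample_torsions <- function(n, mixture) {
  cls <- sample(names(mixture$p), n, replace = TRUE, prob = mixture$p)
  ang <- numeric(n)
  g <- cls == "gauche"
  if (any(g)) {
    a <- 70 + stats::rnorm(sum(g), 0, mixture$sd)
    while (any(bad <- a < 50 | a > 90))
      a[bad] <- 70 + stats::rnorm(sum(bad), 0, mixture$sd)
    ang[g] <- a * sample(c(-1, 1), sum(g), replace = TRUE)
  }
  t <- cls == "trans"
  if (any(t)) {
    a <- 180 + stats::rnorm(sum(t), 0, mixture$sd)
    a <- ifelse(a > 180, a - 360, a)           # wrap: trans spans +/-180
    while (any(bad <- abs(a) < 160)) {
      a[bad] <- 180 + stats::rnorm(sum(bad), 0, mixture$sd)
      a <- ifelse(a > 180, a - 360, a)
    }
    ang[t] <- a
  }
  o <- cls == "other"
  if (any(o)) {
    # uniform over the complement of the two windows:
    # (-50, 50), (90, 160), (-160, -90), total measure 240 degrees
    u <- stats::runif(sum(o), 0, 240)
    ang[o] <- ifelse(u < 100, u - 50,
                     ifelse(u < 170, 90 + (u - 100) + 1e-6,
                            -160 + (u - 170) + 1e-6))
  }
  list(class = cls, angle = ang)
}

# NeRF placement: atom D bonded to C with |CD| = bond, angle(B,C,D) = ang
# and dihedral(A,B,C,D) = tor (degrees, IUPAC sign convention).
.place_atom <- function(A, B, C, bond, ang, tor) {
  th <- (180 - ang) * pi / 180
  ph <- tor * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- bond * c(cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  C + d[1] * bc + d[2] * m + d[3] * n
}

# Internal-coordinate recipe for one PET monomer (CHARMM-GUI-like atom
# names; the backbone runs O1' -> C8 -> C2 -> C3 -> C4 -> C5 -> C1 -> O3
# -> C9 -> C10 -> O1). Only the O3-C9-C10-O1 torsion is statistically
# meaningful; all other internals are idealised constants.
.pet_monomer_atoms <- c("C8", "C2", "C3", "C4", "C5", "C1", "O3", "C9",
                        "C10", "O1", "C6", "C7", "H3", "H4", "H6", "H7",
                        "O2", "O4", "H91", "H92", "H101", "H102")

#' Build a synthetic PET chain with prescribed torsion statistics
#'
#' Constructs an idealised 3D PET chain (fixed bond lengths and angles)
#' whose ethylene-glycol O3-C9-C10-O1 torsions are drawn from a
#' [conformer_mixture()]. The chain is capped with two terminal hydrogens,
#' giving `22 * n_monomers + 2` atoms. Measuring the generated torsions
#' with [dihedral_angles()] reproduces the sampled angles to better than
#' 1e-3 degrees.
#'
#' @param n_monomers number of monomers (>= 1).
#' @param mixture a [conformer_mixture()].
#' @param seed optional RNG seed (uses the current RNG stream when `NULL`).
#' @param chain_id chain tag stored per atom.
#' @param random_backbone draw the non-glycol backbone torsions uniformly
#'   (random coil) instead of the extended default.
#' @param start_resid resid of the first monomer.
#' @return list with `topology` ([pet_topology()]), `coords`
#'   (`n_atoms x 3`), `classes` and `angles` (length `n_monomers`).
#' @export
build_pet_chain <- function(n_monomers, mixture = conformer_mixture(),
                            seed = NULL, chain_id = "A",
                            random_backbone = FALSE, start_resid = 1L) {
  if (n_monomers < 1) stop("n_monomers must be >= 1")
  if (!inherits(mixture, "conformer_mixture")) stop("invalid mixture")
  if (!is.null(seed)) set.seed(seed)
  tor <- .sample_torsions(n_monomers, mixture)
  n_atoms <- 22 * n_monomers + 2
  xyz <- matrix(NA_real_, n_atoms, 3)
  name <- character(n_atoms); resid <- integer(n_atoms)

  idx <- function(m, a) (m - 1) * 22 + match(a, .pet_monomer_atoms)
  rnd <- function() if (random_backbone) stats::runif(1, -180, 180) else 180

  for (m in seq_len(n_monomers)) {
    base <- (m - 1) * 22
    name[base + seq_len(22)] <- .pet_monomer_atoms
    resid[base + seq_len(22)] <- start_resid + m - 1L
    if (m == 1) {
      xyz[idx(1, "C8"), ] <- c(0, 0, 0)
      xyz[idx(1, "C2"), ] <- c(1.49, 0, 0)
      a <- 120 * pi / 180
      xyz[idx(1, "C3"), ] <- c(1.49 + 1.39 * cos(pi - a), 1.39 * sin(pi - a), 0)
    } else {
      p <- function(a) xyz[idx(m - 1, a), ]
      xyz[idx(m, "C8"), ] <- .place_atom(p("C9"), p("C10"), p("O1"), 1.34, 115, rnd())
      xyz[idx(m, "C2"), ] <- .place_atom(p("C10"), p("O1"), xyz[idx(m, "C8"), ], 1.49, 111, rnd())
      xyz[idx(m, "C3"), ] <- .place_atom(p("O1"), xyz[idx(m, "C8"), ], xyz[idx(m, "C2"), ], 1.39, 120,
                                         if (random_backbone) stats::runif(1, -180, 180) else 150)
    }
    q <- function(a) xyz[idx(m, a), ]
    xyz[idx(m, "C4"), ] <- .place_atom(q("C8"), q("C2"), q("C3"), 1.39, 120, 0)
    xyz[idx(m, "C5"), ] <- .place_atom(q("C2"), q("C3"), q("C4"), 1.39, 120, 0)
    xyz[idx(m, "C1"), ] <- .place_atom(q("C3"), q("C4"), q("C5"), 1.49, 120, 180)
    xyz[idx(m, "O3"), ] <- .place_atom(q("C4"), q("C5"), q("C1"), 1.34, 111, rnd())
    xyz[idx(m, "C9"), ] <- .place_atom(q("C5"), q("C1"), q("O3"), 1.44, 115, rnd())
    xyz[idx(m, "C10"), ] <- .place_atom(q("C1"), q("O3"), q("C9"), 1.53, 109.5, rnd())
    xyz[idx(m, "O1"), ] <- .place_atom(q("O3"), q("C9"), q("C10"), 1.44, 109.5,
                                       tor$angle[m])
    # ring completion, ring hydrogens, carbonyl oxygens, glycol hydrogens
    xyz[idx(m, "C6"), ] <- .place_atom(q("C3"), q("C4"), q("C5"), 1.39, 120, 0)
    xyz[idx(m, "C7"), ] <- .place_atom(q("C4"), q("C5"), q("C6"), 1.39, 120, 0)
    xyz[idx(m, "H3"), ] <- .place_atom(q("C5"), q("C4"), q("C3"), 1.08, 120, 180)
    xyz[idx(m, "H4"), ] <- .place_atom(q("C2"), q("C3"), q("C4"), 1.08, 120, 180)
    xyz[idx(m, "H6"), ] <- .place_atom(q("C4"), q("C5"), q("C6"), 1.08, 120, 180)
    xyz[idx(m, "H7"), ] <- .place_atom(q("C5"), q("C6"), q("C7"), 1.08, 120, 180)
    xyz[idx(m, "O2"), ] <- .place_atom(q("C4"), q("C5"), q("C1"), 1.21, 125,
                                       dihedral_angle(q("C4"), q("C5"), q("C1"), q("O3")) + 180)
    if (m == 1) {
      xyz[idx(m, "O4"), ] <- .place_atom(q("C3"), q("C2"), q("C8"), 1.21, 125, 0)
    } else {
      xyz[idx(m, "O4"), ] <- .place_atom(xyz[idx(m - 1, "C10"), ],
                                         xyz[idx(m - 1, "O1"), ], q("C8"), 1.21, 125, 0)
    }
    tg <- dihedral_angle(q("C1"), q("O3"), q("C9"), q("C10"))
    xyz[idx(m, "H91"), ] <- .place_atom(q("C1"), q("O3"), q("C9"), 1.09, 109.5, tg + 120)
    xyz[idx(m, "H92"), ] <- .place_atom(q("C1"), q("O3"), q("C9"), 1.09, 109.5, tg - 120)
    xyz[idx(m, "H101"), ] <- .place_atom(q("O3"), q("C9"), q("C10"), 1.09, 109.5,
                                         tor$angle[m] + 120)
    xyz[idx(m, "H102"), ] <- .place_atom(q("O3"), q("C9"), q("C10"), 1.09, 109.5,
                                         tor$angle[m] - 120)
  }
  # terminal caps: one on the first carbonyl carbon, one on the last ester O
  i_ht1 <- 22 * n_monomers + 1
  i_ht2 <- 22 * n_monomers + 2
  xyz[i_ht1, ] <- .place_atom(xyz[idx(1, "C3"), ], xyz[idx(1, "C2"), ],
                              xyz[idx(1, "C8"), ], 1.09, 110, 180)
  m <- n_monomers
  xyz[i_ht2, ] <- .place_atom(xyz[idx(m, "C9"), ], xyz[idx(m, "C10"), ],
                              xyz[idx(m, "O1"), ], 0.96, 108, 180)
  name[c(i_ht1, i_ht2)] <- c("HT1", "HT2")
  resid[c(i_ht1, i_ht2)] <- c(start_resid, start_resid + n_monomers - 1L)

  atoms <- data.frame(serial = seq_len(n_atoms), name = name, resname = "PET",
                      resid = resid, segid = "PET", chain = chain_id,
                      stringsAsFactors = FALSE)
  list(topology = pet_topology(atoms), coords = xyz,
       classes = tor$class, angles = tor$angle)
}

.atomic_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06)

# Uniform random rotation matrix (via normalised quaternion).
.random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Build a multi-chain PET melt frame
#'
#' Places `n_chains` random-coil PET chains at random positions and
#' orientations inside the box (minimum-image clash check against already
#' placed chains), recording each monomer's true conformer class. This is
#' a geometric emulation of an amorphous melt, not a physically relaxed
#' one.
#'
#' @param n_chains,n_monomers melt composition (default 100 chains of 9
#'   monomers, i.e. 20,000 atoms).
#' @param mixture a [conformer_mixture()].
#' @param box length-3 box edge lengths (A).
#' @param seed optional RNG seed.
#' @param clash_tol minimum allowed inter-chain atom distance (A). The
#'   default 0 disables the check: at amorphous-PET density (~1.2 g/cm^3)
#'   hard-sphere rejection sampling cannot converge, and chain
#'   interpenetration is acceptable for a melt whose only statistically
#'   meaningful feature is the glycol torsion. Set a positive tolerance
#'   for dilute systems.
#' @param max_attempts placement attempts per chain before giving up.
#' @param contain require every atom inside `[0, box]` (no wrapping); the
#'   clash check is then plain Euclidean instead of minimum-image.
#' @return list with `topology`, `coords`, `ground_truth` (data.frame
#'   `chain`, `resid`, `class`, `angle`) and `density` (g/cm^3).
#' @export
build_melt <- function(n_chains = 100, n_monomers = 9,
                       mixture = conformer_mixture(), box = c(61.8, 61.8, 61.8),
                       seed = NULL, clash_tol = 0, max_attempts = 500,
                       contain = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  img_box <- if (contain) NULL else box
  atoms_list <- vector("list", n_chains)
  coords_list <- vector("list", n_chains)
  truth <- vector("list", n_chains)
  placed <- NULL
  for (k in seq_len(n_chains)) {
    # globally unique resids so monomers stay addressable even through
    # formats that cannot carry multi-character chain tags
    ch <- build_pet_chain(n_monomers, mixture, chain_id = as.character(k),
                          random_backbone = TRUE,
                          start_resid = (k - 1L) * n_monomers + 1L)
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      R <- .random_rotation()
      shift <- stats::runif(3, 0, box)
      xyz <- sweep(ch$coords, 2, colMeans(ch$coords)) %*% R
      xyz <- sweep(xyz, 2, shift, "+")
      if (contain && (any(xyz < 0) || any(sweep(xyz, 2, box) > 0))) next
      if (clash_tol <= 0 || is.null(placed) ||
          .min_cross_distance(xyz, placed, img_box) >= clash_tol) { ok <- TRUE; break }
    }
    if (!ok)
      stop("could not place chain ", k, " after ", max_attempts,
           " attempts; use a larger box or smaller clash_tol")
    placed <- rbind(placed, xyz)
    coords_list[[k]] <- xyz
    at <- ch$topology$atoms
    at$chain <- as.character(k)
    atoms_list[[k]] <- at
    truth[[k]] <- data.frame(chain = as.character(k),
                             resid = (k - 1L) * n_monomers + seq_len(n_monomers),
                             class = ch$classes, angle = ch$angles,
                             stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, atoms_list)
  atoms$serial <- seq_len(nrow(atoms))
  top <- pet_topology(atoms)
  mass <- sum(.atomic_masses[top$atoms$element])
  density <- mass / 6.02214076e23 / (prod(box) * 1e-24)
  list(topology = top, coords = do.call(rbind, coords_list),
       ground_truth = do.call(rbind, truth), density = density)
}

# Minimum minimum-image distance between two coordinate sets, chunked to
# bound memory.
.min_cross_distance <- function(A, B, box = NULL, chunk = 5000L) {
  m <- Inf
  nb <- nrow(B)
  for (s in seq(1, nb, by = chunk)) {
    e <- min(s + chunk - 1L, nb)
    m <- min(m, min(.cross_distances(A, B[s:e, , drop = FALSE], box)))
  }
  m
}

#' Mean-reverting dynamics parameters for one marker distance
#'
#' Discrete-time Ornstein-Uhlenbeck-like process: stationary mean `mean`
#' (A), stationary standard deviation `sd` (A), relaxation time `tau`
#' (frames). An optional deterministic switch moves the process mean to
#' `to` at frame `at` (emulating binding-site remodelling); a reversible
#' switch returns to the original mean at `revert_at`.
#'
#' @param mean,sd,tau process parameters (`mean > 0`, `sd >= 0`,
#'   `tau >= 1`).
#' @param switch `NULL` or `list(at =, to =, revert_at = NULL)`.
#' @return list of class `distance_dynamics`.
#' @export
distance_dynamics <- function(mean, sd = 0.3, tau = 20, switch = NULL) {
  if (mean <= 0) stop("mean must be > 0")
  if (sd < 0) stop("sd must be >= 0")
  if (tau < 1) stop("tau must be >= 1 frame")
  if (!is.null(switch)) {
    if (is.null(switch$at) || is.null(switch$to))
      stop("switch needs 'at' (frame) and 'to' (A)")
  }
  structure(list(mean = mean, sd = sd, tau = tau, switch = switch),
            class = "distance_dynamics")
}

# Mean path over n frames (base mean with optional switch window).
.mean_path <- function(dyn, n) {
  mu <- rep(dyn$mean, n)
  sw <- dyn$switch
  if (!is.null(sw)) {
    if (sw$at >= n) stop("switch frame must be < n_frames")
    to_end <- if (!is.null(sw$revert_at)) min(sw$revert_at - 1, n) else n
    mu[(sw$at):to_end] <- sw$to
  }
  mu
}

# AR(1) realisation around a (possibly switching) mean path.
.ou_series <- function(dyn, n) {
  mu <- .mean_path(dyn, n)
  phi <- exp(-1 / dyn$tau)
  x <- numeric(n)
  x[1] <- mu[1] + stats::rnorm(1, 0, dyn$sd)
  if (n > 1) {
    eps <- stats::rnorm(n - 1, 0, dyn$sd * sqrt(1 - phi^2))
    for (t in 2:n) x[t] <- mu[t] + phi * (x[t - 1] - mu[t - 1]) + eps[t - 1]
  }
  pmax(x, 0.1)  # distances stay positive
  }

#' Parameter set for the synthetic binding-site marker dynamics
#'
#' @param d1,d2,d3,d4 [distance_dynamics()] objects for the four marker
#'   distances.
#' @param activity_threshold d3 value (A) at or below which the true state
#'   is active.
#' @return list of class `site_dynamics_params`.
#' @export
site_dynamics_params <- function(d1 = distance_dynamics(6.75, 0.25),
                                 d2 = distance_dynamics(8.5, 0.4),
                                 d3 = distance_dynamics(3.8, 0.35),
                                 d4 = distance_dynamics(5.0, 0.3),
                                 activity_threshold = 5.0) {
  structure(list(d1 = d1, d2 = d2, d3 = d3, d4 = d4,
                 activity_threshold = activity_threshold),
            class = "site_dynamics_params")
}

# Fixed local-frame geometry of the marker construction (Ser O-gamma at
# the origin). Directions are unit vectors; the Tyr O-eta sits 6 A from
# the serine, which is also the rationale for the 6 A pocket-water cutoff.
.site_geometry <- list(
  og = c(0, 0, 0),
  oh = c(0, 6, 0),
  u_d1 = c(1, 0, 0),
  u_d2 = c(-1, 0, 0),
  u_d3 = c(0.80, 0.47, 0.37),
  u_d3b = c(0.87, 0.35, 0.35),   # His NE2 direction; |OG-NE2| = d3 exactly
  d4_base = c(-4, -4, 0),
  u_d4 = c(0, -0.6, 0.8),
  met = c(2, 4, 1),
  asp = c(-2, -5, 2)
)

# Marker topology for a given enzyme site_spec (one or two atoms per
# binding-site residue, segid PROT).
.marker_topology <- function(site) {
  p <- site$pairs
  sp <- list(
    list(p$d3[[1]], "og"),          # catalytic Ser OG
    list(p$d3[[2]], "his_nd1"),
    list(site$his_ne, "his_ne2"),
    list(p$d1[[1]], "tyr_oh"),
    list(p$d1[[2]], "ile_cd1"),
    list(p$d2[[2]], "trp_cg"),
    list(p$d4[[1]], "d4_a"),
    list(p$d4[[2]], "d4_b"),
    list(list(resid = site$binding_site$met$resid, name = "SD",
              resname = site$binding_site$met$resname), "met_sd"),
    list(list(resid = site$binding_site$asp$resid, name = "CG",
              resname = site$binding_site$asp$resname), "asp_cg"))
  atoms <- do.call(rbind, lapply(sp, function(x)
    data.frame(name = x[[1]]$name, resname = x[[1]]$resname %||% "UNK",
               resid = x[[1]]$resid, stringsAsFactors = FALSE)))
  atoms <- data.frame(serial = seq_len(nrow(atoms)), name = atoms$name,
                      resname = atoms$resname, resid = atoms$resid,
                      segid = "PROT", chain = "E", stringsAsFactors = FALSE)
  list(topology = pet_topology(atoms),
       roles = vapply(sp, function(x) x[[2]], character(1)))
}

# Marker coordinates for given per-frame distances (n x 4 matrix),
# returned as an n_frames x (3 * n_markers) xyz block in the local frame.
.marker_coords <- function(d, roles) {
  g <- .site_geometry
  unit <- function(v) v / sqrt(sum(v^2))
  n <- nrow(d)
  pos <- list(
    og = matrix(g$og, n, 3, byrow = TRUE),
    his_nd1 = d[, "d3"] %o% unit(g$u_d3),
    his_ne2 = d[, "d3"] %o% unit(g$u_d3b),
    tyr_oh = matrix(g$oh, n, 3, byrow = TRUE),
    ile_cd1 = matrix(g$oh, n, 3, byrow = TRUE) + d[, "d1"] %o% g$u_d1,
    trp_cg = matrix(g$oh, n, 3, byrow = TRUE) + d[, "d2"] %o% g$u_d2,
    d4_a = matrix(g$d4_base, n, 3, byrow = TRUE),
    d4_b = matrix(g$d4_base, n, 3, byrow = TRUE) + d[, "d4"] %o% unit(g$u_d4),
    met_sd = matrix(g$met, n, 3, byrow = TRUE),
    asp_cg = matrix(g$asp, n, 3, byrow = TRUE))
  xyz <- matrix(NA_real_, n, 3 * length(roles))
  for (k in seq_along(roles)) {
    xyz[, (3 * k - 2):(3 * k)] <- pos[[roles[k]]]
  }
  xyz
}

#' Simulate the binding-site marker trajectory
#'
#' Generates the four marker distances as mean-reverting processes (with
#' optional activation-to-inactivation switches) and realises them as 3D
#' marker-atom coordinates whose measured pairwise distances equal the
#' generated series exactly. The true per-frame state label is active
#' where the d3 process *mean* is at or below the activity threshold.
#'
#' @param params a [site_dynamics_params()].
#' @param n_frames number of frames (>= 2).
#' @param seed optional RNG seed.
#' @param site a [site_spec()] naming the marker atoms (default the
#'   PETaseSM14 preset).
#' @param center translation applied to the local site frame (A).
#' @param box optional box edges stored in the trajectory.
#' @param time_step ns per frame.
#' @return list with `trajectory` ([pet_trajectory()]) and `truth` (list:
#'   `distances` n x 4 matrix, `mean_paths`, `active`, `active_fraction`).
#' @export
simulate_site <- function(params, n_frames, seed = NULL,
                          site = site_preset("PETaseSM14"),
                          center = c(0, 0, 0), box = NULL, time_step = 1) {
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  d <- sapply(c("d1", "d2", "d3", "d4"), function(nm) .ou_series(params[[nm]], n_frames))
  colnames(d) <- c("d1", "d2", "d3", "d4")
  mu <- sapply(c("d1", "d2", "d3", "d4"), function(nm) .mean_path(params[[nm]], n_frames))
  mk <- .marker_topology(site)
  xyz <- .marker_coords(d, mk$roles)
  xyz <- xyz + matrix(rep(center, ncol(xyz) / 3), nrow(xyz), ncol(xyz), byrow = TRUE)
  active <- mu[, "d3"] <= params$activity_threshold
  traj <- pet_trajectory(mk$topology, xyz, box = box,
                         time = (seq_len(n_frames) - 1) * time_step)
  list(trajectory = traj,
       truth = list(distances = d, mean_paths = mu, active = active,
                    active_fraction = mean(active),
                    threshold = params$activity_threshold))
}

#' Place water oxygens around a pocket centre
#'
#' Exactly `n_near` oxygens uniformly inside the sphere of radius
#' `near_radius` around `pocket_center`, plus `n_far` oxygens uniformly in
#' the box but never closer than `near_radius` to the centre.
#'
#' @param pocket_center length-3 position (A).
#' @param n_near,n_far water counts.
#' @param near_radius pocket radius (A).
#' @param box length-3 box edges (A).
#' @param seed optional RNG seed.
#' @param max_attempts rejection-sampling bound for the far waters.
#' @return `(n_near + n_far) x 3` coordinate matrix with attribute
#'   `n_near`.
#' @export
place_waters <- function(pocket_center, n_near, near_radius = 6, n_far = 0,
                         box = c(90, 90, 110), seed = NULL,
                         max_attempts = 1000) {
  if (near_radius <= 0) stop("near_radius must be > 0")
  if (!is.null(seed)) set.seed(seed)
  near <- matrix(numeric(0), 0, 3)
  if (n_near > 0) {
    r <- near_radius * (stats::runif(n_near)^(1 / 3)) * (1 - 1e-9)
    u <- matrix(stats::rnorm(3 * n_near), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    near <- sweep(u * r, 2, pocket_center, "+")
  }
  far <- matrix(numeric(0), 0, 3)
  if (n_far > 0) {
    got <- 0; out <- matrix(NA_real_, n_far, 3); tries <- 0
    while (got < n_far) {
      tries <- tries + 1
      if (tries > max_attempts)
        stop("cannot place far waters outside the pocket; box too small?")
      m <- matrix(stats::runif(3 * n_far, 0, box), ncol = 3, byrow = TRUE)
      d <- minimum_image_distance(m, matrix(pocket_center, n_far, 3, byrow = TRUE), box)
      keep <- which(d >= near_radius)
      take <- utils::head(keep, n_far - got)
      if (length(take) > 0) {
        out[(got + 1):(got + length(take)), ] <- m[take, , drop = FALSE]
        got <- got + length(take)
      }
    }
    far <- out
  }
  res <- rbind(near, far)
  attr(res, "n_near") <- n_near
  res
}

.water_topology <- function(n, start_serial = 1L) {
  if (n == 0) return(NULL)
  data.frame(serial = start_serial + seq_len(n) - 1L, name = "OH2",
             resname = "TIP3", resid = seq_len(n), segid = "WAT",
             chain = "W", stringsAsFactors = FALSE)
}
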