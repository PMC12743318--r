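#' Per-frame binding-site marker distances d1-d4
#'
#' d1 (Tyr-Ile) and d2 (Tyr-Trp) measure the width of the substrate cleft;
#' d3 (catalytic Ser O-gamma to His ND1) reports catalytic-triad integrity;
#' d4 (the residue adjacent to the catalytic serine to the conserved Asn)
#' reports the support interaction whose loss precedes inactivation.
#' These are intramolecular distances and are computed without minimum
#' imaging (the enzyme never spans the periodic box).
#'
#' @param traj a [pet_trajectory()].
#' @param site a [site_spec()].
#' @return data.frame with columns `frame`, `time`, `d1`, `d2`, `d3`, `d4` (A).
#' @export
compute_site_distances <- function(traj, site) {
  pairs <- .resolve_pairs(site, traj$topology)
  out <- data.frame(frame = seq_len(n_frames(traj)), time = traj$time)
  for (nm in names(pairs)) {
    p <- pairs[[nm]]
    ca <- traj$xyz[, (3 * p[1] - 2):(3 * p[1]), drop = FALSE]
    cb <- traj$xyz[, (3 * p[2] - 2):(3 * p[2]), drop = FALSE]
    out[[nm]] <- sqrt(rowSums((ca - cb)^2))
  }
  out
}

#' Classify per-frame active/inactive state from the d3 distance
#'
#' A frame is active when the catalytic Ser O-gamma-His distance d3 is at
#' most `threshold` (default 5 A): in that configuration the His can
#' deprotonate the Ser and hydrolysis can start. The series is summarised
#' into transitions, dwell times and a reversibility flag (any
#' inactive-to-active transition after the first inactivation).
#'
#' @param d3 numeric vector of per-frame d3 distances (A), or the
#'   data.frame returned by [compute_site_distances()].
#' @param threshold activity threshold (A), default 5.
#' @return object of class `state_series`: list with `labels`
#'   (character vector "active"/"inactive"), `threshold`,
#'   `active_fraction`, `transitions` (data.frame `frame`, `direction`),
#'   `dwell` (data.frame `state`, `start`, `length`), `reversible`.
#' @export
classify_activity <- function(d3, threshold = 5.0) {
  if (is.data.frame(d3)) d3 <- d3$d3
  if (length(d3) == 0) stop("empty d3 series")
  active <- d3 <= threshold
  labels <- ifelse(active, "active", "inactive")
  n <- length(active)
  chg <- which(diff(active) != 0)
  transitions <- data.frame(
    frame = chg + 1L,
    direction = ifelse(active[chg + 1L], "inactive->active", "active->inactive"),
    stringsAsFactors = FALSE)
  r <- rle(labels)
  dwell <- data.frame(state = r$values,
                      start = cumsum(c(1L, r$lengths[-length(r$lengths)])),
                      length = r$lengths, stringsAsFactors = FALSE)
  first_inact <- if (any(!active)) which(!active)[1] else NA_integer_
  reversible <- !is.na(first_inact) &&
    any(transitions$direction == "inactive->active" & transitions$frame > first_inact)
  structure(list(labels = labels, threshold = threshold,
                 active_fraction = mean(active), transitions = transitions,
                 dwell = dwell, reversible = reversible),
            class = "state_series")
}

#' @export
print.state_series <- function(x, ...) {
  cat(sprintf("state_series: %d frames, active fraction %.3f, %d transition(s), %s\n",
              length(x$labels), x$active_fraction, nrow(x$transitions),
              if (x$reversible) "reversible" else "irreversible"))
  invisible(x)
}

#' Count catalysis-competent (reactive) configurations per frame
#'
#' A reactive configuration requires the catalytic Ser O-gamma to be
#' simultaneously strictly within `cutoff` (default 5 A) of the catalytic
#' His nitrogen (NE2 by default, separately configurable from the ND1 atom
#' used for d3) and of a PET ester carbon. The per-frame count is the
#' number of ester carbons satisfying the conjunction; substrate proximity
#' uses minimum imaging when the trajectory has a box.
#'
#' @param traj a [pet_trajectory()].
#' @param site a [site_spec()].
#' @param cutoff distance cutoff (A), strict inequality.
#' @return data.frame `frame`, `time`, `count` with attributes `total` and
#'   `cutoff`.
#' @export
count_reactive_states <- function(traj, site, cutoff = 5.0) {
  esters <- select_atoms(traj$topology, site$ester_selection, quiet = TRUE)$indices
  if (length(esters) == 0)
    stop("ester-carbon selection '", site$ester_selection, "' matched no atoms")
  ser_og <- .resolve_atom(traj$topology, site$ser_og, "ser_og")
  his_ne <- .resolve_atom(traj$topology, site$his_ne, "his_ne")
  ser <- traj$xyz[, (3 * ser_og - 2):(3 * ser_og), drop = FALSE]
  his <- traj$xyz[, (3 * his_ne - 2):(3 * his_ne), drop = FALSE]
  d_sh <- sqrt(rowSums((ser - his)^2))
  de <- .series_distances_to_point(traj, esters, ser)
  counts <- as.integer(rowSums(de < cutoff) * (d_sh < cutoff))
  out <- data.frame(frame = seq_len(n_frames(traj)), time = traj$time,
                    count = counts)
  attr(out, "total") <- sum(counts)
  attr(out, "cutoff") <- cutoff
  out
}

# Per-frame minimum-image distances from a set of atoms to a per-frame
# reference point: returns an n_frames x n_atoms matrix.
.series_distances_to_point <- function(traj, atoms, ref_xyz) {
  dx <- traj$xyz[, 3 * atoms - 2, drop = FALSE] - ref_xyz[, 1]
  dy <- traj$xyz[, 3 * atoms - 1, drop = FALSE] - ref_xyz[, 2]
  dz <- traj$xyz[, 3 * atoms, drop = FALSE] - ref_xyz[, 3]
  if (!is.null(traj$box)) {
    dx <- dx - traj$box[, 1] * round(dx / traj$box[, 1])
    dy <- dy - traj$box[, 2] * round(dy / traj$box[, 2])
    dz <- dz - traj$box[, 3] * round(dz / traj$box[, 3])
  }
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Count water molecules inside the binding pocket
#'
#' A water is inside the pocket when its oxygen lies within `cutoff`
#' (default 6 A, the Ser O-gamma to Tyr O-eta distance that spans the
#' cleft) of the catalytic serine O-gamma, under minimum imaging.
#'
#' @param traj a [pet_trajectory()].
#' @param site a [site_spec()].
#' @param cutoff pocket radius (A).
#' @param water_selection selection for water oxygens.
#' @return data.frame `frame`, `time`, `count`.
#' @export
count_pocket_waters <- function(traj, site, cutoff = 6.0,
                                water_selection = "water and name OH2 OW O OW1") {
  ser_og <- .resolve_atom(traj$topology, site$ser_og, "ser_og")
  wat <- select_atoms(traj$topology, water_selection, quiet = TRUE)$indices
  if (length(wat) == 0) stop("no water oxygens in topology")
  ser <- traj$xyz[, (3 * ser_og - 2):(3 * ser_og), drop = FALSE]
  dw <- .series_distances_to_point(traj, wat, ser)
  data.frame(frame = seq_len(n_frames(traj)), time = traj$time,
             count = as.integer(rowSums(dw <= cutoff)))
}

#' Per-frame solvent-accessible surface area of the binding site
#'
#' Shrake-Rupley SASA (probe 1.4 A) of the six binding-site residues,
#' summed over their heavy atoms. By default the whole protein occludes
#' while only binding-site atoms are reported; `context = "site"` restricts
#' occlusion to the binding-site atoms themselves.
#'
#' @param traj a [pet_trajectory()].
#' @param site a [site_spec()].
#' @param probe probe radius (A).
#' @param n_points Shrake-Rupley sphere points per atom.
#' @param context `"protein"` (default) or `"site"`.
#' @return data.frame `frame`, `time`, `sasa` (A^2), plus one column per
#'   binding-site residue.
#' @export
binding_site_sasa <- function(traj, site, probe = 1.4, n_points = 960,
                              context = c("protein", "site")) {
  context <- match.arg(context)
  top <- traj$topology
  residues <- .resolve_residues(site, top)
  site_idx <- sort(unique(unlist(residues)))
  ctx_idx <- if (context == "protein") {
    prot <- select_atoms(top, "protein and heavy", quiet = TRUE)$indices
    if (length(prot) == 0) site_idx else prot
  } else site_idx
  radii <- top$atoms$radius
  nf <- n_frames(traj)
  per_res <- matrix(0, nf, length(residues),
                    dimnames = list(NULL, names(residues)))
  pos <- match(site_idx, site_idx)  # identity; map residue atoms into subset
  for (f in seq_len(nf)) {
    fr <- frame_coords(traj, f)
    a <- shrake_rupley_sasa(fr, radii, subset = site_idx, context = ctx_idx,
                            probe = probe, n_points = n_points)
    for (k in seq_along(residues)) {
      per_res[f, k] <- sum(a[match(residues[[k]], site_idx)])
    }
  }
  out <- data.frame(frame = seq_len(nf), time = traj$time,
                    sasa = rowSums(per_res))
  cbind(out, as.data.frame(per_res))
}

#' Per-residue contacts between the binding site and the PET substrate
#'
#' Counts heavy-atom pairs within `cutoff` (default 5 A, minimum imaging)
#' between each binding-site residue and all PET atoms, per frame.
#'
#' @param traj a [pet_trajectory()].
#' @param site a [site_spec()].
#' @param cutoff contact cutoff (A).
#' @param pet_selection selection string for substrate heavy atoms.
#' @return data.frame with `frame`, `time`, one count column per residue,
#'   and `total`.
#' @export
binding_site_contacts <- function(traj, site, cutoff = 5.0,
                                  pet_selection = "segid PET and heavy") {
  residues <- .resolve_residues(site, traj$topology)
  pet <- select_atoms(traj$topology, pet_selection, quiet = TRUE)$indices
  pet <- intersect(pet, which(.is_heavy(traj$topology)))
  if (length(pet) == 0) stop("substrate selection matched no atoms")
  nf <- n_frames(traj)
  counts <- matrix(0L, nf, length(residues),
                   dimnames = list(NULL, names(residues)))
  for (f in seq_len(nf)) {
    fr <- frame_coords(traj, f)
    box <- if (!is.null(traj$box)) traj$box[f, ] else NULL
    for (k in seq_along(residues)) {
      counts[f, k] <- count_contacts(fr, residues[[k]], pet,
                                     cutoff = cutoff, box = box)
    }
  }
  out <- data.frame(frame = seq_len(nf), time = traj$time)
  out <- cbind(out, as.data.frame(counts))
  out$total <- rowSums(counts)
  out
}
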