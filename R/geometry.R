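#' Minimum-image distance under orthorhombic periodic boundaries
#'
#' With a box, each Cartesian separation component is wrapped into
#' `[-L/2, L/2]` before taking the norm, i.e. the distance to the nearest
#' periodic copy. Without a box the plain Euclidean distance is returned.
#'
#' @param a,b numeric length-3 vectors or `n x 3` matrices (A).
#' @param box `NULL` or length-3 vector of box edge lengths (A).
#' @return numeric vector of distances (A).
#' @export
minimum_image_distance <- function(a, b, box = NULL) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 3)
  if (is.null(dim(b))) b <- matrix(b, ncol = 3)
  if (nrow(a) == 1 && nrow(b) > 1) a <- a[rep(1, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1 && nrow(a) > 1) b <- b[rep(1, nrow(a)), , drop = FALSE]
  d <- a - b
  if (!is.null(box)) {
    if (any(box <= 0)) stop("box edge lengths must be positive")
    for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  }
  sqrt(rowSums(d * d))
}

# All pairwise minimum-image distances between rows of A and rows of B.
.cross_distances <- function(A, B, box = NULL) {
  dx <- outer(A[, 1], B[, 1], "-")
  dy <- outer(A[, 2], B[, 2], "-")
  dz <- outer(A[, 3], B[, 3], "-")
  if (!is.null(box)) {
    dx <- dx - box[1] * round(dx / box[1])
    dy <- dy - box[2] * round(dy / box[2])
    dz <- dz - box[3] * round(dz / box[3])
  }
  sqrt(dx * dx + dy * dy + dz * dz)
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' corresponding atoms, via singular value decomposition of the covariance
#' matrix with the usual reflection correction.
#'
#' @param mobile,reference `n x 3` coordinate matrices (A) of corresponding
#'   atoms, `n >= 3` and not collinear.
#' @return object of class `superposition`: `rotation` (3x3, det +1),
#'   `translation` (length 3), `rmsd` (A). The fitted coordinates of any
#'   matrix `X` are `X %*% rotation + translation` (rows).
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference) || ncol(mobile) != 3 || ncol(reference) != 3)
    stop("mobile and reference must be n x 3 matrices of equal size")
  if (nrow(mobile) < 3) stop("superposition needs at least 3 atoms")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  sv <- svd(crossprod(P, Q))
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    stop("degenerate (collinear) atom set: superposition is not unique")
  d <- sign(det(tcrossprod(sv$u, sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- P %*% R
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  structure(list(rotation = R, translation = as.numeric(cr - cm %*% R),
                 rmsd = rmsd), class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat("superposition: rmsd =", signif(x$rmsd, 6), "A\n")
  invisible(x)
}

#' Apply a fitted superposition to coordinates
#'
#' @param sup a `superposition` from [kabsch_superpose()].
#' @param coords `n x 3` coordinate matrix (A).
#' @return transformed `n x 3` matrix.
#' @export
apply_superposition <- function(sup, coords) {
  sweep(as.matrix(coords) %*% sup$rotation, 2, sup$translation, "+")
}

#' Per-frame RMSD after optimal superposition
#'
#' Each frame is superposed onto the reference frame on the selected atoms
#' (Kabsch), and the minimised RMSD over that selection is reported.
#'
#' @param traj a [pet_trajectory()].
#' @param selection an `atom_selection`, integer atom indices, or a
#'   selection string.
#' @param reference_frame frame used as reference (default first).
#' @return numeric vector, one RMSD (A) per frame.
#' @export
rmsd_series <- function(traj, selection, reference_frame = 1L) {
  idx <- .as_indices(traj$topology, selection)
  if (length(idx) == 0) stop("empty selection for RMSD")
  ref <- frame_coords(traj, reference_frame)[idx, , drop = FALSE]
  vapply(seq_len(n_frames(traj)), function(i) {
    kabsch_superpose(frame_coords(traj, i)[idx, , drop = FALSE], ref)$rmsd
  }, numeric(1))
}

#' Per-atom root-mean-square fluctuation
#'
#' Frames are first superposed onto the reference frame using `fit_selection`
#' (so that rigid-body motion does not inflate fluctuations), then each
#' selected atom's RMSF is `sqrt(mean(|r - <r>|^2))` over frames.
#'
#' @param traj a [pet_trajectory()] with at least 2 frames.
#' @param selection atoms to report (selection string, indices or
#'   `atom_selection`).
#' @param fit_selection atoms used for the superposition (defaults to
#'   `selection`).
#' @param fit set `FALSE` to skip the superposition.
#' @return numeric vector of RMSF values (A), one per selected atom.
#' @export
rmsf <- function(traj, selection, fit_selection = selection, fit = TRUE) {
  if (n_frames(traj) < 2) stop("RMSF needs at least 2 frames")
  idx <- .as_indices(traj$topology, selection)
  if (length(idx) == 0) stop("empty selection for RMSF")
  fidx <- .as_indices(traj$topology, fit_selection)
  nf <- n_frames(traj)
  coords <- array(NA_real_, c(length(idx), 3, nf))
  ref <- frame_coords(traj, 1)[fidx, , drop = FALSE]
  for (i in seq_len(nf)) {
    fr <- frame_coords(traj, i)
    if (fit) {
      sup <- kabsch_superpose(fr[fidx, , drop = FALSE], ref)
      coords[, , i] <- apply_superposition(sup, fr[idx, , drop = FALSE])
    } else coords[, , i] <- fr[idx, , drop = FALSE]
  }
  mean_pos <- apply(coords, c(1, 2), mean)
  dev2 <- sweep(coords, c(1, 2), mean_pos)^2
  sqrt(apply(dev2, 1, sum) / nf)
}

#' Signed dihedral (torsion) angle of four points
#'
#' Standard IUPAC convention: looking along p2->p3, the angle from the
#' p1-p2-p3 plane to the p2-p3-p4 plane, positive clockwise, in
#' `(-180, 180]` degrees.
#'
#' @param p1,p2,p3,p4 numeric length-3 vectors (A).
#' @return angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  as.numeric(dihedral_angles(rbind(p1), rbind(p2), rbind(p3), rbind(p4)))
}

#' Vectorised dihedral angles
#'
#' @param P1,P2,P3,P4 `n x 3` matrices of corresponding points.
#' @return numeric vector of `n` angles in `(-180, 180]` degrees.
#' @export
dihedral_angles <- function(P1, P2, P3, P4) {
  b1 <- P2 - P1; b2 <- P3 - P2; b3 <- P4 - P3
  if (any(rowSums(b1^2) < 1e-12) || any(rowSums(b2^2) < 1e-12) ||
      any(rowSums(b3^2) < 1e-12))
    stop("degenerate dihedral: consecutive points coincide")
  n1 <- .rowcross(b1, b2); n2 <- .rowcross(b2, b3)
  if (any(rowSums(n1^2) < 1e-16) || any(rowSums(n2^2) < 1e-16))
    stop("degenerate dihedral: collinear points")
  b2n <- b2 / sqrt(rowSums(b2^2))
  x <- rowSums(n1 * n2)
  y <- rowSums(.rowcross(n1, n2) * b2n)
  ang <- atan2(y, x) * 180 / pi
  ang[ang <= -180] <- ang[ang <= -180] + 360
  ang
}

.rowcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Count inter-group atom contacts within a cutoff
#'
#' A contact is a pair (a in A, b in B) whose minimum-image distance is
#' strictly below the cutoff. The groups must be disjoint. Heavy-atom
#' restriction is the caller's responsibility (the binding-site metrics
#' pass heavy-atom selections).
#'
#' @param coords `n_atoms x 3` frame coordinate matrix (A).
#' @param groupA,groupB integer atom index vectors (disjoint).
#' @param cutoff contact cutoff (A), default 5.
#' @param box `NULL` or length-3 box edges for minimum imaging.
#' @return integer contact count.
#' @export
count_contacts <- function(coords, groupA, groupB, cutoff = 5, box = NULL) {
  if (length(intersect(groupA, groupB)) > 0)
    stop("contact groups must be disjoint")
  if (length(groupA) == 0 || length(groupB) == 0) return(0L)
  D <- .cross_distances(coords[groupA, , drop = FALSE],
                        coords[groupB, , drop = FALSE], box)
  sum(D < cutoff)
}

#' Time-averaged residue-residue minimum-distance map
#'
#' Entry (i, j) is the average over frames of the per-frame minimum
#' heavy-atom distance between residues i and j. The display cap (the
#' paper-style colour saturation at >= 14 A) is retained as an attribute
#' and applied only when rendering, never to the stored values.
#'
#' @param traj a [pet_trajectory()].
#' @param residues named list of atom index vectors (or `atom_selection`s),
#'   one per residue; each must contain at least one heavy atom.
#' @param cap display cap (A).
#' @param pbc use minimum imaging with the per-frame box.
#' @return object of class `distance_map`: symmetric matrix (A) with zero
#'   diagonal and attributes `cap`.
#' @export
residue_distance_map <- function(traj, residues, cap = 14, pbc = FALSE) {
  if (length(residues) < 2) stop("need at least 2 residues")
  top <- traj$topology
  heavy <- which(.is_heavy(top))
  groups <- lapply(residues, function(r) intersect(.as_indices(top, r), heavy))
  if (any(lengths(groups) == 0))
    stop("residue with no heavy atoms: ",
         paste(names(residues)[lengths(groups) == 0], collapse = ", "))
  nr <- length(groups)
  acc <- matrix(0, nr, nr, dimnames = list(names(residues), names(residues)))
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    fr <- frame_coords(traj, f)
    box <- if (pbc && !is.null(traj$box)) traj$box[f, ] else NULL
    for (i in seq_len(nr - 1)) {
      Ai <- fr[groups[[i]], , drop = FALSE]
      for (j in (i + 1):nr) {
        m <- min(.cross_distances(Ai, fr[groups[[j]], , drop = FALSE], box))
        acc[i, j] <- acc[i, j] + m
      }
    }
  }
  acc <- acc / nf
  acc <- acc + t(acc)
  structure(acc, cap = cap, class = c("distance_map", "matrix"))
}

#' @export
print.distance_map <- function(x, ...) {
  cat("distance_map:", nrow(x), "residues; display cap",
      attr(x, "cap"), "A\n")
  print(round(unclass(x), 2))
  invisible(x)
}

# Deterministic golden-section spiral points on the unit sphere.
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Classic point-sampling SASA: each atom's sphere of radius
#' `vdW + probe` is covered with a deterministic golden-section spiral of
#' `n_points` test points; points not buried inside any neighbour's
#' expanded sphere count as accessible.
#'
#' @param coords `n_atoms x 3` coordinate matrix (A).
#' @param radii vdW radii (A) for every row of `coords`; no missing values.
#' @param subset atom indices to report (default: all). Only these atoms
#'   get an area.
#' @param context additional atom indices that occlude but are not
#'   reported (e.g. the rest of the protein around a binding site).
#' @param probe probe radius (A), default 1.4.
#' @param n_points test points per atom, default 960.
#' @return numeric vector of per-atom areas (A^2) for `subset`, with the
#'   total as attribute `total`.
#' @export
shrake_rupley_sasa <- function(coords, radii, subset = NULL, context = NULL,
                               probe = 1.4, n_points = 960) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (length(radii) != n) stop("need one radius per atom")
  if (anyNA(radii) || any(radii <= 0)) stop("missing or non-positive vdW radius")
  if (is.null(subset)) subset <- seq_len(n)
  occl <- sort(union(subset, context))
  pts <- sphere_points(n_points)
  R <- radii + probe
  oc <- coords[occl, , drop = FALSE]
  oR2 <- (R[occl])^2
  areas <- vapply(subset, function(i) {
    p <- sweep(pts * R[i], 2, coords[i, ], "+")
    # candidate occluders: expanded spheres that can reach atom i's surface
    d2 <- rowSums(sweep(oc, 2, coords[i, ])^2)
    cand <- which(d2 < (R[occl] + R[i])^2 & occl != i)
    acc <- rep(TRUE, n_points)
    for (j in cand) {
      dd <- sweep(p, 2, oc[j, ])
      acc <- acc & (rowSums(dd * dd) >= oR2[j])
      if (!any(acc)) break
    }
    4 * pi * R[i]^2 * sum(acc) / n_points
  }, numeric(1))
  names(areas) <- NULL
  attr(areas, "total") <- sum(areas)
  areas
}

# Coerce selection strings / atom_selection objects / index vectors to
# 1-based integer atom indices.
.as_indices <- function(topology, selection) {
  if (inherits(selection, "atom_selection")) return(selection$indices)
  if (is.character(selection) && length(selection) == 1)
    return(select_atoms(topology, selection, quiet = TRUE)$indices)
  idx <- as.integer(selection)
  if (length(idx) > 0 && (min(idx) < 1 || max(idx) > topology$n_atoms))
    stop("atom index out of range")
  idx
}
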