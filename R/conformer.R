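#' Classify a PET ethylene-glycol torsion as gauche, trans or other
#'
#' The classification follows the absolute-value convention used for
#' amorphous PET: gauche when `|angle|` is within 70 +/- 20 degrees
#' (closed windows, i.e. `[50, 90]`), trans when `|angle|` is within
#' 180 +/- 20 degrees (`[160, 180]`), and other outside both windows.
#' Angles must lie in `(-180, 180]`.
#'
#' @param angle numeric vector of torsion angles (degrees).
#' @return character vector with values `"gauche"`, `"trans"`, `"other"`.
#' @export
classify_conformer <- function(angle) {
  if (any(angle <= -180 | angle > 180))
    stop("angle out of range (-180, 180]")
  a <- abs(angle)
  ifelse(a >= 50 & a <= 90, "gauche",
         ifelse(a >= 160, "trans", "other"))
}

# Identify PET monomers and their dihedral quadruples.
# Returns a data.frame (chain, resid, o3, c9, c10, o1) plus a list column
# of all atom indices per monomer.
.pet_monomers <- function(topology, pet_resname = "PET") {
  a <- topology$atoms
  sel <- which(a$resname == pet_resname)
  if (length(sel) == 0) stop("no PET residues in topology")
  key <- paste(a$segid[sel], a$chain[sel], a$resid[sel], sep = "|")
  groups <- split(sel, key)
  rows <- lapply(groups, function(idx) {
    nm <- a$name[idx]
    quad <- idx[match(c("O3", "C9", "C10", "O1"), nm)]
    if (anyNA(quad)) return(NULL)
    data.frame(chain = a$chain[idx[1]], resid = a$resid[idx[1]],
               o3 = quad[1], c9 = quad[2], c10 = quad[3], o1 = quad[4],
               stringsAsFactors = FALSE)
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) stop("no PET monomer carries the O3-C9-C10-O1 quadruple")
  out <- do.call(rbind, rows[keep])
  out$atoms <- unname(groups[keep])
  out <- out[order(out$chain, out$resid), ]
  rownames(out) <- NULL
  out
}

#' Partition PET monomers into enzyme-bound and bulk for one frame
#'
#' A monomer is bound when any of its atoms lies within `cutoff`
#' (default 8 A, minimum imaging) of the catalytic serine O-gamma;
#' otherwise it belongs to the bulk.
#'
#' @param coords `n_atoms x 3` frame coordinates (A).
#' @param monomer_atoms list of atom index vectors, one per monomer
#'   (non-empty).
#' @param ser_og index of the catalytic serine O-gamma atom.
#' @param cutoff bound/bulk cutoff (A).
#' @param box `NULL` or length-3 box edges.
#' @return character vector per monomer: `"bound"` or `"bulk"`.
#' @export
partition_bound_bulk <- function(coords, monomer_atoms, ser_og, cutoff = 8,
                                 box = NULL) {
  if (any(lengths(monomer_atoms) == 0)) stop("empty monomer atom group")
  ref <- coords[ser_og, , drop = FALSE]
  vapply(monomer_atoms, function(idx) {
    d <- minimum_image_distance(coords[idx, , drop = FALSE],
                                ref[rep(1, length(idx)), , drop = FALSE], box)
    if (min(d) <= cutoff) "bound" else "bulk"
  }, character(1))
}

#' Per-monomer, per-frame conformer table
#'
#' For every PET monomer and frame: the O3-C9-C10-O1 torsion angle, its
#' gauche/trans/other class, and the bound/bulk partition at `cutoff`
#' (default 8 A) from the catalytic serine O-gamma.
#'
#' @param traj a [pet_trajectory()].
#' @param site a [site_spec()].
#' @param cutoff bound/bulk partition cutoff (A).
#' @return data.frame (`chain`, `resid`, `frame`, `angle`, `class`,
#'   `partition`), one row per monomer per frame.
#' @export
conformer_table <- function(traj, site, cutoff = 8) {
  ser_og <- .resolve_atom(traj$topology, site$ser_og, "ser_og")
  mono <- .pet_monomers(traj$topology)
  nm <- nrow(mono)
  nf <- n_frames(traj)
  tabs <- vector("list", nf)
  for (f in seq_len(nf)) {
    fr <- frame_coords(traj, f)
    box <- if (!is.null(traj$box)) traj$box[f, ] else NULL
    ang <- dihedral_angles(fr[mono$o3, , drop = FALSE], fr[mono$c9, , drop = FALSE],
                           fr[mono$c10, , drop = FALSE], fr[mono$o1, , drop = FALSE])
    part <- partition_bound_bulk(fr, mono$atoms, ser_og, cutoff, box)
    tabs[[f]] <- data.frame(chain = mono$chain, resid = mono$resid, frame = f,
                            angle = ang, class = classify_conformer(ang),
                            partition = part, stringsAsFactors = FALSE)
  }
  do.call(rbind, tabs)
}

#' Conformer class fractions per partition, with replica mean +/- SD
#'
#' Given one conformer table per replica, computes the gauche/trans/other
#' fractions for the bound and bulk partitions within each replica, then
#' the cross-replica mean and sample standard deviation, plus the
#' trans:gauche ratio string in the conventional percent form (e.g.
#' `"14:82"`).
#'
#' @param tables a single conformer table or a list with one per replica
#'   (see [conformer_table()]).
#' @return object of class `conformer_summary`: data.frame with columns
#'   `partition`, `class`, `mean`, `sd`, `n`; attribute `ratio` holds the
#'   per-partition trans:gauche strings.
#' @export
conformer_distribution <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  classes <- c("gauche", "trans", "other")
  per_rep <- lapply(tables, function(tb) {
    out <- expand.grid(partition = c("bound", "bulk"), class = classes,
                       stringsAsFactors = FALSE)
    out$frac <- NA_real_
    for (p in c("bound", "bulk")) {
      sub <- tb$class[tb$partition == p]
      n <- length(sub)
      for (cl in classes) {
        out$frac[out$partition == p & out$class == cl] <-
          if (n == 0) NA_real_ else sum(sub == cl) / n
      }
    }
    out
  })
  base <- per_rep[[1]][, c("partition", "class")]
  fr <- sapply(per_rep, function(x) x$frac)
  fr <- matrix(fr, nrow = nrow(base))
  base$mean <- rowMeans(fr, na.rm = FALSE)
  base$sd <- apply(fr, 1, stats::sd)
  base$n_replicas <- length(tables)
  ratio <- vapply(c("bound", "bulk"), function(p) {
    tr <- base$mean[base$partition == p & base$class == "trans"]
    ga <- base$mean[base$partition == p & base$class == "gauche"]
    if (is.na(tr)) "empty partition"
    else paste0(round(100 * tr), ":", round(100 * ga))
  }, character(1))
  structure(base, ratio = ratio, class = c("conformer_summary", "data.frame"))
}

#' @export
print.conformer_summary <- function(x, ...) {
  cat("conformer_summary (trans:gauche",
      paste(names(attr(x, "ratio")), attr(x, "ratio"), collapse = ", "), ")\n")
  print(as.data.frame(x))
  invisible(x)
}
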