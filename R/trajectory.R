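#' Construct a trajectory
#'
#' Frames are stored bio3d-style as an `n_frames x 3*n_atoms` coordinate
#' matrix (A), with per-frame orthorhombic box edges (A) and times (ns).
#'
#' @param topology a [pet_topology()].
#' @param xyz numeric matrix, `n_frames x 3*n_atoms`, columns ordered
#'   x1,y1,z1,x2,...
#' @param box `NULL`, a length-3 vector, or an `n_frames x 3` matrix of box
#'   edge lengths (A). Triclinic cells are not supported.
#' @param time numeric vector of frame times (ns), strictly increasing.
#' @return object of class `pet_trajectory`.
#' @export
pet_trajectory <- function(topology, xyz, box = NULL, time = NULL) {
  stopifnot(inherits(topology, "pet_topology"))
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3 * topology$n_atoms)
    stop("coordinate matrix has ", ncol(xyz) / 3, " atoms but topology has ",
         topology$n_atoms)
  n <- nrow(xyz)
  if (n < 1) stop("trajectory must contain at least one frame")
  if (!is.null(box)) {
    if (is.null(dim(box))) box <- matrix(box, nrow = n, ncol = 3, byrow = TRUE)
    box <- as.matrix(box)
    if (nrow(box) != n || ncol(box) != 3)
      stop("box must be a length-3 vector or an n_frames x 3 matrix")
    if (any(box <= 0)) stop("box edge lengths must be positive")
  }
  if (is.null(time)) time <- seq_len(n) - 1
  if (length(time) != n) stop("time vector length must equal frame count")
  if (n > 1 && any(diff(time) <= 0)) stop("frame times must be strictly increasing")
  structure(list(topology = topology, xyz = xyz, box = box, time = as.numeric(time)),
            class = "pet_trajectory")
}

#' @export
print.pet_trajectory <- function(x, ...) {
  cat("pet_trajectory:", nrow(x$xyz), "frames x", x$topology$n_atoms, "atoms;",
      if (is.null(x$box)) "no box" else paste0("box ", paste(signif(x$box[1, ], 4), collapse = " x "), " A"),
      "\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [pet_trajectory()].
#' @return integer frame count.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Extract one frame as an n_atoms x 3 coordinate matrix
#' @param traj a [pet_trajectory()].
#' @param i frame index (1-based).
#' @return numeric matrix `n_atoms x 3` (A).
#' @export
frame_coords <- function(traj, i) {
  matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE)
}

#' Read a trajectory from a DCD file or a multi-model PDB
#'
#' DCD frames are read with \pkg{bio3d}; a truncated trailing frame is
#' dropped with a warning. Multi-model PDB files take their (single) box
#' from the CRYST1 record. Only orthorhombic cells are supported; triclinic
#' input is an error.
#'
#' @param path file path.
#' @param topology a [pet_topology()] whose atom count must match the file.
#' @param format `"auto"` (by extension), `"dcd"` or `"pdb"`.
#' @param stride keep every `stride`-th frame starting from the first.
#' @param time_step time between stored frames (ns), used to synthesise
#'   frame times (neither format stores times in ns).
#' @return a [pet_trajectory()].
#' @export
read_trajectory <- function(path, topology, format = c("auto", "dcd", "pdb"),
                            stride = 1L, time_step = 1) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  stride <- as.integer(stride)
  if (stride < 1) stop("stride must be >= 1")
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "dcd") "dcd" else "pdb"
  }
  res <- if (format == "dcd") .read_dcd_frames(path, topology)
         else .read_pdb_frames(path, topology)
  keep <- seq(1, nrow(res$xyz), by = stride)
  box <- res$box
  if (!is.null(box)) box <- box[keep, , drop = FALSE]
  pet_trajectory(topology, res$xyz[keep, , drop = FALSE], box = box,
                 time = (keep - 1) * time_step)
}

# Read the icntrl block of a DCD header (natom, frame count, cell flag).
.dcd_header_info <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  blk <- readBin(con, "integer", 1)
  if (!identical(blk, 84L)) stop("not a DCD file (bad header block): ", path)
  readChar(con, 4)
  icntrl <- readBin(con, "integer", 20)
  readBin(con, "integer", 1)
  tlen <- readBin(con, "integer", 1)
  seek(con, where = tlen, origin = "current")
  readBin(con, "integer", 1)
  readBin(con, "integer", 1)
  natom <- readBin(con, "integer", 1)
  readBin(con, "integer", 1)
  list(nframe = icntrl[1], cryst = icntrl[11] == 1L && icntrl[20] != 0L,
       natom = natom, data_start = seek(con, where = NA))
}

.read_dcd_frames <- function(path, topology) {
  hdr <- .dcd_header_info(path)
  if (hdr$natom != topology$n_atoms)
    stop("DCD atom count (", hdr$natom, ") does not match topology (",
         topology$n_atoms, ")")
  # bytes per frame: optional 48-byte cell block + three float records
  per <- (if (hdr$cryst) 48 + 8 else 0) + 3 * (hdr$natom * 4 + 8)
  avail <- file.size(path) - hdr$data_start
  ncomplete <- avail %/% per
  if (avail %% per != 0) {
    warning("DCD file ends mid-frame; dropping truncated final frame")
  }
  if (ncomplete < 1) stop("DCD file contains no complete frame")
  use_path <- path
  if (avail %% per != 0 || ncomplete < hdr$nframe) {
    # rewrite a clean copy so the reader sees a consistent header
    use_path <- tempfile(fileext = ".dcd")
    raw_all <- readBin(path, "raw", hdr$data_start + ncomplete * per)
    raw_all[9:12] <- writeBin(as.integer(ncomplete), raw())
    writeBin(raw_all, use_path)
    on.exit(unlink(use_path), add = TRUE)
  }
  xyz <- bio3d::read.dcd(use_path, verbose = FALSE)
  box <- NULL
  if (hdr$cryst) {
    cell <- bio3d::read.dcd(use_path, verbose = FALSE, cell = TRUE)
    ang <- cell[, 4:6, drop = FALSE]
    if (any(abs(ang - 90) > 1e-4))
      stop("triclinic unit cell found; only orthorhombic boxes are supported")
    box <- cell[, 1:3, drop = FALSE]
    if (all(box < 1e-9)) box <- NULL   # zero cell written for box-less data
  }
  list(xyz = unclass(xyz), box = box)
}

.read_pdb_frames <- function(path, topology) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- unclass(pdb$xyz)
  if (ncol(xyz) != 3 * topology$n_atoms)
    stop("PDB atom count (", ncol(xyz) / 3, ") does not match topology (",
         topology$n_atoms, ")")
  box <- NULL
  cr <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
  if (length(cr) > 0) {
    f <- as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                      substr(cr[1], 25, 33), substr(cr[1], 34, 40),
                      substr(cr[1], 41, 47), substr(cr[1], 48, 54)))
    if (any(abs(f[4:6] - 90) > 1e-4))
      stop("triclinic unit cell found; only orthorhombic boxes are supported")
    box <- matrix(f[1:3], nrow = nrow(xyz), ncol = 3, byrow = TRUE)
  }
  list(xyz = xyz, box = box)
}

#' Write a trajectory to DCD or multi-model PDB
#'
#' Both formats round-trip coordinates through [read_trajectory()] to
#' format precision (DCD stores single-precision floats; PDB prints three
#' decimals). Box-less trajectories written to DCD get a zero cell with a
#' warning.
#'
#' @param traj a [pet_trajectory()].
#' @param path output file path.
#' @param format `"auto"` (by extension), `"dcd"` or `"pdb"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("auto", "dcd", "pdb")) {
  stopifnot(inherits(traj, "pet_trajectory"))
  format <- match.arg(format)
  if (nrow(traj$xyz) < 1) stop("cannot write an empty trajectory")
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "dcd") "dcd" else "pdb"
  }
  ok <- tryCatch({ con <- file(path, "wb"); close(con); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("cannot write to path: ", path)
  if (format == "dcd") .write_dcd(traj, path) else .write_pdb_frames(traj, path)
  invisible(path)
}

.write_dcd <- function(traj, path) {
  nf <- nrow(traj$xyz)
  na <- traj$topology$n_atoms
  box <- traj$box
  if (is.null(box)) {
    warning("trajectory has no box; writing DCD with zero cell")
    box <- matrix(0, nf, 3)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[11] <- 1L          # crystal block present
  icntrl[20] <- 24L         # CHARMM-format version tag
  writeBin(84L, con); writeChar("CORD", con, nchars = 4, eos = NULL)
  writeBin(icntrl, con); writeBin(84L, con)
  title <- sprintf("%-80s", "Created by pettraj")
  writeBin(84L, con); writeBin(1L, con)
  writeChar(title, con, nchars = 80, eos = NULL); writeBin(84L, con)
  writeBin(4L, con); writeBin(as.integer(na), con); writeBin(4L, con)
  nb <- as.integer(na * 4)
  for (i in seq_len(nf)) {
    cellrec <- c(box[i, 1], 0, box[i, 2], 0, 0, box[i, 3])
    writeBin(48L, con); writeBin(cellrec, con, size = 8); writeBin(48L, con)
    fr <- matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE)
    for (d in 1:3) {
      writeBin(nb, con); writeBin(fr[, d], con, size = 4); writeBin(nb, con)
    }
  }
}

.pdb_atom_name <- function(name) {
  # names of <4 characters start in column 14 by PDB convention
  ifelse(nchar(name) >= 4, substr(sprintf("%-4s", name), 1, 4),
         sprintf(" %-3s", name))
}

.write_pdb_frames <- function(traj, path) {
  top <- traj$topology
  a <- top$atoms
  chain <- ifelse(nchar(a$chain) == 1, a$chain, " ")
  lines <- character(0)
  if (!is.null(traj$box)) {
    lines <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     traj$box[1, 1], traj$box[1, 2], traj$box[1, 3], 90, 90, 90)
  }
  nm <- .pdb_atom_name(a$name)
  el <- sub("\\.$", "", a$element)
  pre <- sprintf("ATOM  %5d %s%1s%-4s%1s%4d    ",
                 a$serial %% 100000, nm, " ", substr(a$resname, 1, 4),
                 chain, a$resid %% 10000)
  post <- sprintf("%6.2f%6.2f      %-4s%2s", 1, 0, substr(a$segid, 1, 4),
                  substr(el, 1, 2))
  out <- file(path, "wt")
  on.exit(close(out))
  writeLines(lines, out)
  for (i in seq_len(nrow(traj$xyz))) {
    fr <- matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE)
    writeLines(sprintf("MODEL     %4d", i), out)
    writeLines(paste0(pre, sprintf("%8.3f%8.3f%8.3f", fr[, 1], fr[, 2], fr[, 3]), post), out)
    writeLines("ENDMDL", out)
  }
  writeLines("END", out)
}
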