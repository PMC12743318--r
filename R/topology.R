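#' Bondi-style van der Waals radii by element
#'
#' Default radii (in Angstrom) used to build solvent-accessible surfaces and
#' to decide atomic overlap. Values follow the Bondi compilation with a
#' generic 1.50 A fallback for elements not listed.
#'
#' @return Named numeric vector of radii (A); the `"default"` entry is the
#'   fallback used for unknown elements.
#' @export
#' @examples
#' vdw_radii()[["C"]]
vdw_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
    NA. = 2.27, K = 2.75, MG = 1.73, CA = 2.31, ZN = 1.39, FE = 2.00,
    default = 1.50)
}

# CHARMM ion / special residue names that encode the element directly
.special_elements <- c(SOD = "NA.", CLA = "CL", POT = "K", MG = "MG",
                       CAL = "CA", ZN2 = "ZN", FE2 = "FE")

#' Infer the chemical element from a CHARMM atom name
#'
#' @param name character vector of atom names (CHARMM nomenclature).
#' @return character vector of element symbols (upper case; sodium is coded
#'   `"NA."` to avoid clashing with missing values).
#' @keywords internal
guess_element <- function(name) {
  name <- toupper(trimws(name))
  el <- character(length(name))
  hit <- name %in% names(.special_elements)
  el[hit] <- .special_elements[name[hit]]
  rest <- !hit
  # strip leading digits (e.g. "1HB2"), take first alphabetic character
  core <- sub("^[0-9]+", "", name[rest])
  el[rest] <- substr(core, 1, 1)
  el[el == ""] <- "X"
  el
}

.assign_radii <- function(atoms, radii = NULL) {
  tab <- vdw_radii()
  if (!is.null(radii)) {
    # per-atom-name overrides take precedence over the element table
    r <- tab[atoms$element]
    r[is.na(r)] <- tab[["default"]]
    ov <- match(atoms$name, names(radii))
    r[!is.na(ov)] <- radii[ov[!is.na(ov)]]
  } else {
    r <- tab[atoms$element]
    unknown <- is.na(r)
    if (any(unknown)) {
      warning("unknown element(s) ", paste(unique(atoms$element[unknown]), collapse = ", "),
              "; using default vdW radius ", tab[["default"]], " A")
      r[unknown] <- tab[["default"]]
    }
  }
  unname(r)
}

#' Construct a topology from an atom table
#'
#' The topology is the address space for every selection in the package:
#' each atom carries its CHARMM name, residue, segment, optional chain tag
#' and a van der Waals radius. Internal atom indices are 0-based only at the
#' I/O boundary (PDB serials); within R the usual 1-based indexing is used.
#'
#' @param atoms data.frame with columns `serial`, `name`, `resname`, `resid`,
#'   `segid`; optional `chain`, `element`, `radius`.
#' @param radii optional named numeric vector of per-atom-name radius
#'   overrides (A).
#' @return object of class `pet_topology` with elements `atoms` (data.frame)
#'   and `n_atoms`.
#' @export
pet_topology <- function(atoms, radii = NULL) {
  req <- c("serial", "name", "resname", "resid", "segid")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0)
    stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  atoms$serial <- as.integer(atoms$serial)
  atoms$resid <- as.integer(atoms$resid)
  if (anyDuplicated(atoms$serial))
    stop("duplicated atom serial(s): ",
         paste(unique(atoms$serial[duplicated(atoms$serial)]), collapse = ", "))
  if (is.null(atoms$chain)) atoms$chain <- ""
  atoms$chain[is.na(atoms$chain)] <- ""
  if (is.null(atoms$element)) atoms$element <- guess_element(atoms$name)
  if (is.null(atoms$radius)) atoms$radius <- .assign_radii(atoms, radii)
  if (any(atoms$radius <= 0 & atoms$element != "H"))
    stop("non-positive vdW radius assigned to a heavy atom")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, n_atoms = nrow(atoms)),
            class = "pet_topology")
}

#' @export
print.pet_topology <- function(x, ...) {
  cat("pet_topology:", x$n_atoms, "atoms,",
      length(unique(paste(x$atoms$segid, x$atoms$chain, x$atoms$resid))),
      "residues,", length(unique(x$atoms$segid)), "segment(s)\n")
  invisible(x)
}

#' Read a topology from a PDB or PSF file
#'
#' PDB files are parsed with \pkg{bio3d}; PSF topologies (CHARMM/X-PLOR
#' space-delimited flavours) are parsed directly from the `!NATOM` section.
#' Van der Waals radii are assigned from the bundled element table
#' ([vdw_radii()]) and can be overridden per atom name.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"psf"`.
#' @param radii optional named numeric vector of per-atom-name radius
#'   overrides (A).
#' @return a [pet_topology()].
#' @export
read_topology <- function(path, format = c("auto", "pdb", "psf"), radii = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "psf") "psf" else "pdb"
  }
  if (format == "pdb") .read_topology_pdb(path, radii) else .read_topology_psf(path, radii)
}

.read_topology_pdb <- function(path, radii = NULL) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  a <- pdb$atom
  atoms <- data.frame(
    serial = as.integer(a$eleno),
    name = trimws(a$elety),
    resname = trimws(a$resid),
    resid = as.integer(a$resno),
    segid = ifelse(is.na(a$segid) | trimws(a$segid) == "",
                   ifelse(is.na(a$chain), "", trimws(a$chain)),
                   trimws(a$segid)),
    chain = ifelse(is.na(a$chain), "", trimws(a$chain)),
    stringsAsFactors = FALSE
  )
  elesy <- trimws(a$elesy)
  el <- guess_element(atoms$name)
  use <- !is.na(elesy) & elesy != ""
  el[use] <- toupper(elesy[use])
  el[el == "NA"] <- "NA."
  atoms$element <- el
  pet_topology(atoms, radii)
}

.read_topology_psf <- function(path, radii = NULL) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("!NATOM", lines)
  if (length(hdr) != 1)
    stop("malformed PSF: expected exactly one !NATOM section in ", path)
  natom <- suppressWarnings(as.integer(strsplit(trimws(lines[hdr]), "\\s+")[[1]][1]))
  if (is.na(natom) || natom < 1)
    stop("malformed PSF record at line ", hdr, ": cannot parse atom count")
  body <- lines[(hdr + 1):(hdr + natom)]
  fields <- strsplit(trimws(body), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 8)) {
    bad <- which(nf < 8)[1]
    stop("malformed PSF atom record at line ", hdr + bad, ": ", body[bad])
  }
  m <- do.call(rbind, lapply(fields, function(f) f[1:8]))
  resid <- suppressWarnings(as.integer(m[, 3]))
  if (anyNA(resid)) {
    bad <- which(is.na(resid))[1]
    stop("malformed PSF atom record at line ", hdr + bad, ": non-integer resid")
  }
  atoms <- data.frame(
    serial = as.integer(m[, 1]),
    segid = m[, 2],
    resid = resid,
    resname = m[, 4],
    name = m[, 5],
    stringsAsFactors = FALSE
  )
  pet_topology(atoms, radii)
}

# logical: heavy (non-hydrogen) atoms
.is_heavy <- function(topology) topology$atoms$element != "H"

# unique residue key (segid|chain|resid) per atom
.residue_key <- function(topology) {
  with(topology$atoms, paste(segid, chain, resid, sep = "|"))
}
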