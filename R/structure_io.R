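# Structure input/output: PDB reading via bio3d, heavy-atom convention,
# per-atom masses and contact radii, cofactor groups, reduced-vdW masks.

# Bondi-style van der Waals contact radii (Angstrom), keyed by element symbol,
# with common biological metals appended.  Pairs combine by summation
# (r_min_ij = r_i + r_j); see vdw_params() for the arithmetic-mean switch.
.default_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80, S = 1.80,
  CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90, B = 1.92,
  FE = 2.00, CU = 1.40, ZN = 1.39, MG = 1.73, MN = 2.00, MO = 2.10,
  CO = 2.00, NI = 1.63, "NA" = 2.27, K = 2.75, CA = 2.31, W = 2.10
)

.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998, P = 30.974,
  S = 32.06, CL = 35.45, BR = 79.904, I = 126.904, SE = 78.971, B = 10.81,
  FE = 55.845, CU = 63.546, ZN = 65.38, MG = 24.305, MN = 54.938,
  MO = 95.95, CO = 58.933, NI = 58.693, "NA" = 22.990, K = 39.098,
  CA = 40.078, W = 183.84
)

.standard_aa <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "MSE", "HSD", "HSE", "HSP", "HID", "HIE", "HIP", "CYX"
)

#' Default per-element van der Waals contact radius table
#'
#' Radii (r_min, Angstrom) used in the quartic repulsive potential; pairs
#' combine by summation by default.  The table is keyed by element symbol and
#' can be replaced wholesale or overridden per atom name via the
#' `radius_overrides` argument of [read_structure()].
#'
#' @return Named numeric vector of radii in Angstrom.
#' @export
default_radius_table <- function() .default_radii

#' Read a two-column radius table
#'
#' Plain-text table with one `element_or_atomname  r_min` pair per line
#' (whitespace separated, `#` comments allowed).  Entries whose key matches an
#' element symbol replace the element default; any other key is treated as an
#' atom-name override.
#'
#' @param path file path.
#' @return Named numeric vector.
#' @export
read_radius_table <- function(path) {
  tab <- read.table(path, header = FALSE, comment.char = "#",
                    col.names = c("key", "rmin"),
                    colClasses = c("character", "numeric"))
  setNames(tab$rmin, toupper(tab$key))
}

.guess_element <- function(name, resname) {
  # strip digits and primes from the PDB atom name, take leading letters
  nm <- gsub("[0-9']", "", toupper(name))
  nm <- sub("^\\s+|\\s+$", "", nm)
  two <- substr(nm, 1, 2)
  if (two %in% names(.element_masses) && two %in% c("FE", "CU", "ZN", "MG",
                                                   "MN", "MO", "CO", "NI",
                                                   "CL", "BR", "SE", "NA",
                                                   "CA")) {
    # two-letter symbols only when unambiguous for hetero groups; CA in a
    # standard residue is an alpha carbon
    if (!(two == "CA" && resname %in% .standard_aa)) return(two)
  }
  substr(nm, 1, 1)
}

#' Read a PDB structure as a rigid body
#'
#' Parses a PDB file (via \pkg{bio3d}), drops hydrogens and deuteriums
#' (heavy-atom convention), resolves alternate locations to the highest
#' occupancy (ties to altloc "A"), and assigns per-atom masses and van der
#' Waals contact radii.  The reduced-vdW activity mask (backbone + C-beta +
#' all non-amino-acid atoms) is computed immediately.
#'
#' @param path PDB file.
#' @param model model number for multi-model files (default 1).
#' @param radius_table named radii vector, see [default_radius_table()].
#' @param radius_overrides optional named vector of per-atom-name radii.
#' @param label structure label (defaults to the file name).
#' @return A `RigidStructure`: a list with an `atoms` data frame (serial,
#'   name, element, resname, resno, chain, x, y, z, mass, rmin, hetero),
#'   a named `cofactors` list, a logical `reduced_mask`, and `label`.
#' @export
read_structure <- function(path, model = 1, radius_table = default_radius_table(),
                           radius_overrides = NULL, label = basename(path)) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                  verbose = FALSE),
                  error = function(e) stop("unreadable PDB file '", path,
                                           "': ", conditionMessage(e)))
  at <- pdb$atom
  nmodel <- nrow(pdb$xyz)
  if (model < 1 || model > nmodel)
    stop("requested model ", model, " but file has ", nmodel, " model(s)")
  xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]

  elem <- toupper(at$elesy)
  miss <- is.na(elem) | elem == ""
  if (any(miss))
    elem[miss] <- mapply(.guess_element, at$elety[miss], at$resid[miss])

  keep <- !(elem %in% c("H", "D"))
  at <- at[keep, , drop = FALSE]
  elem <- elem[keep]
  if (nrow(at) == 0L) stop("zero heavy atoms in '", path, "'")

  # alternate locations: highest occupancy, tie broken by altloc letter
  alt <- at$alt
  if (any(!is.na(alt) & alt != "")) {
    key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety)
    occ <- ifelse(is.na(at$o), 1, at$o)
    ord <- order(key, -occ, ifelse(is.na(alt) | alt == "", "A", alt))
    first <- !duplicated(key[ord])
    sel <- sort(ord[first])
    at <- at[sel, , drop = FALSE]
    elem <- elem[sel]
  }

  mass <- unname(.element_masses[elem])
  rmin <- unname(radius_table[elem])
  if (!is.null(radius_overrides)) {
    hit <- match(toupper(at$elety), names(radius_overrides))
    rmin[!is.na(hit)] <- radius_overrides[hit[!is.na(hit)]]
  }
  bad <- which(is.na(rmin) | is.na(mass))
  if (length(bad))
    stop("no radius/mass entry for element '", elem[bad[1]], "' (atom ",
         at$eleno[bad[1]], " ", at$elety[bad[1]], " in residue ",
         at$resid[bad[1]], at$resno[bad[1]], ")")

  atoms <- data.frame(
    serial = at$eleno, name = at$elety, element = elem,
    resname = at$resid, resno = at$resno,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    x = at$x, y = at$y, z = at$z,
    mass = mass, rmin = rmin,
    hetero = at$type == "HETATM",
    stringsAsFactors = FALSE
  )
  rownames(atoms) <- NULL
  new_rigid_structure(atoms, label = label)
}

#' Construct a RigidStructure from an atom table
#'
#' @param atoms data frame with the columns documented in [read_structure()].
#' @param cofactors named list of integer index vectors.
#' @param label structure label.
#' @return A `RigidStructure`.
#' @export
new_rigid_structure <- function(atoms, cofactors = list(), label = "structure") {
  stopifnot(nrow(atoms) >= 1L, all(is.finite(atoms$x)), all(is.finite(atoms$y)),
            all(is.finite(atoms$z)), all(atoms$mass > 0), all(atoms$rmin > 0))
  s <- structure(list(atoms = atoms, cofactors = cofactors,
                      reduced_mask = NULL, label = label),
                 class = "RigidStructure")
  s$reduced_mask <- reduced_vdw_mask(s)
  s
}

#' @export
print.RigidStructure <- function(x, ...) {
  cat("RigidStructure '", x$label, "': ", nrow(x$atoms), " heavy atoms, ",
      length(x$cofactors), " cofactor group(s)",
      if (length(x$cofactors)) paste0(" [", paste(names(x$cofactors),
                                                  collapse = ", "), "]"),
      "\n", sep = "")
  invisible(x)
}

#' Atom coordinates as an n x 3 matrix
#' @param structure a `RigidStructure`.
#' @return Numeric matrix (Angstrom).
#' @export
coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' Replace atom coordinates
#' @param structure a `RigidStructure`.
#' @param xyz n x 3 matrix.
#' @return The updated structure.
#' @export
set_coords <- function(structure, xyz) {
  stopifnot(nrow(xyz) == nrow(structure$atoms), ncol(xyz) == 3)
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}

#' Apply a rigid transform
#'
#' New coordinates are `rotation %*% (x - center) + center + translation`.
#' With the default `center = c(0,0,0)` this is the plain affine map
#' `R x + t`.
#'
#' @param structure a `RigidStructure`.
#' @param rotation 3 x 3 proper rotation.
#' @param translation length-3 vector (Angstrom).
#' @param center rotation origin.
#' @return The transformed structure.
#' @export
apply_transform <- function(structure, rotation = diag(3),
                            translation = c(0, 0, 0), center = c(0, 0, 0)) {
  xyz <- coords(structure)
  xyz <- sweep(xyz, 2, center) %*% t(rotation)
  xyz <- sweep(xyz, 2, center + translation, "+")
  set_coords(structure, xyz)
}

#' Write a structure to PDB
#'
#' Coordinates are written at the standard PDB precision (3 decimals) through
#' \pkg{bio3d}; ATOM/HETATM record types follow the `hetero` flag.
#'
#' @param structure a `RigidStructure`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  a <- structure$atoms
  n <- nrow(a)
  bio3d::write.pdb(file = path, xyz = as.vector(t(coords(structure))),
                   type = ifelse(a$hetero, "HETATM", "ATOM"),
                   resno = a$resno, resid = a$resname, eleno = a$serial,
                   elety = a$name, chain = a$chain, o = rep(1, n),
                   b = rep(0, n), elesy = a$element)
  invisible(path)
}

#' Write a conformer set as a multi-model PDB
#' @param conformers a `ConformerSet` or list of `RigidStructure`s.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_conformers <- function(conformers, path) {
  cl <- if (inherits(conformers, "ConformerSet")) conformers$conformers
        else conformers
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  lines <- character(0)
  for (m in seq_along(cl)) {
    write_structure(cl[[m]], tmp)
    body <- grep("^(ATOM|HETATM|TER)", readLines(tmp), value = TRUE)
    lines <- c(lines, sprintf("MODEL     %4d", m), body, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# Ring-atom name sets for the "sidechain-ring" selection keyword.
.ring_atoms <- list(
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)

#' Select a cofactor group
#'
#' Selection grammar: clauses joined by `" and "`, each one of
#' `resname <code>`, `resid <number>`, `chain <id>`, `name <atom> [<atom>...]`,
#' or `sidechain-ring` (the aromatic ring heavy atoms of Trp/Phe/Tyr/His; for
#' Trp these are the nine indole ring atoms CG CD1 CD2 NE1 CE2 CE3 CZ2 CZ3
#' CH2, C-beta excluded).  Matching atoms are returned in serial order.
#'
#' @param structure a `RigidStructure`.
#' @param spec selection string, e.g. `"resname HEM"` or
#'   `"resid 191 and sidechain-ring"`.
#' @param name group name (defaults to the selection string).
#' @return A `CofactorGroup`: list with `name` and `atom_indices` (row indices
#'   into `structure$atoms`).
#' @export
select_cofactor <- function(structure, spec, name = spec) {
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  for (clause in strsplit(spec, "\\s+and\\s+")[[1]]) {
    tok <- strsplit(trimws(clause), "\\s+")[[1]]
    if (length(tok) == 0L) next
    kw <- tolower(tok[1])
    if (kw == "resname") {
      keep <- keep & a$resname %in% toupper(tok[-1])
    } else if (kw == "resid") {
      keep <- keep & a$resno %in% as.integer(tok[-1])
    } else if (kw == "chain") {
      keep <- keep & a$chain %in% tok[-1]
    } else if (kw == "name") {
      keep <- keep & a$name %in% toupper(tok[-1])
    } else if (kw == "sidechain-ring") {
      ok <- rep(FALSE, nrow(a))
      for (rn in names(.ring_atoms))
        ok <- ok | (a$resname == rn & a$name %in% .ring_atoms[[rn]])
      keep <- keep & ok
    } else {
      stop("unknown selection clause '", clause, "' in spec '", spec, "'")
    }
  }
  idx <- which(keep)
  if (length(idx) == 0L)
    stop("cofactor selection '", spec, "' matched no heavy atoms")
  idx <- idx[order(a$serial[idx])]
  structure(list(name = name, atom_indices = idx), class = "CofactorGroup")
}

#' Attach a named cofactor group to a structure
#' @inheritParams select_cofactor
#' @return The structure with `cofactors[[name]]` set.
#' @export
add_cofactor <- function(structure, spec, name = spec) {
  structure$cofactors[[name]] <- select_cofactor(structure, spec, name)
  structure
}

#' Reduced-vdW activity mask
#'
#' Implements the reduced repulsion scheme: the vdW term is switched off for
#' all side-chain atoms extending beyond C-beta, mimicking side-chain
#' reorganisation on binding.  Backbone atoms (N, CA, C, O, OXT), C-beta and
#' every non-amino-acid (hetero/cofactor) atom stay active.  Atoms of
#' unrecognised polymer residues default to active with a message.
#'
#' @param structure a `RigidStructure`.
#' @return Logical vector, `TRUE` = vdW-active under the reduced scheme.
#' @export
reduced_vdw_mask <- function(structure) {
  a <- structure$atoms
  backbone <- c("N", "CA", "C", "O", "OXT", "CB")
  is_aa <- a$resname %in% .standard_aa
  mask <- rep(TRUE, nrow(a))
  mask[is_aa] <- a$name[is_aa] %in% backbone
  unknown <- !is_aa & !a$hetero
  if (any(unknown)) {
    message("reduced_vdw_mask: ", sum(unknown),
            " atom(s) in unrecognised residue(s) kept vdW-active: ",
            paste(unique(a$resname[unknown]), collapse = ", "))
  }
  mask
}

#' Center of mass
#'
#' Mass-weighted mean of the heavy-atom positions (element masses).  Set
#' `weighted = FALSE` for the geometric centroid.
#'
#' @param structure a `RigidStructure`.
#' @param weighted mass-weight the mean (default) or not.
#' @return Length-3 vector (Angstrom).
#' @export
center_of_mass <- function(structure, weighted = TRUE) {
  xyz <- coords(structure)
  if (nrow(xyz) == 0L) stop("empty structure")
  w <- if (weighted) structure$atoms$mass else rep(1, nrow(xyz))
  unname(colSums(xyz * w) / sum(w))
}

# active-mask helper honouring the reduced flag of a VdwParams
.active_mask <- function(structure, vdw) {
  if (isTRUE(vdw$reduced)) structure$reduced_mask
  else rep(TRUE, nrow(structure$atoms))
}

# coordinates of a cofactor group (resolving a name or a CofactorGroup)
.cof_indices <- function(structure, cof) {
  if (inherits(cof, "CofactorGroup")) return(cof$atom_indices)
  if (is.character(cof) && length(cof) == 1L) {
    if (!is.null(structure$cofactors[[cof]]))
      return(structure$cofactors[[cof]]$atom_indices)
    return(select_cofactor(structure, cof)$atom_indices)
  }
  if (is.numeric(cof)) return(as.integer(cof))
  stop("cannot interpret cofactor specification")
}
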