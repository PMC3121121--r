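#' Van der Waals radius table
#'
#' Element-keyed heavy-atom radii (Angstrom) in the Chothia/NACCESS lineage:
#' C 1.87, N 1.65, O 1.40, S 1.85, P 1.90.  Water oxygen uses the O entry
#' (1.40 A).  A replacement table can be supplied as a CSV file with columns
#' `element,radius`.
#'
#' @param file optional path to a CSV replacement table.
#' @return named numeric vector of radii keyed by element symbol.
#' @export
vdw_radius_table <- function(file = NULL) {
  if (is.null(file)) {
    if (is.null(.dbac_env$radii)) {
      path <- system.file("extdata", "vdw_radii.csv", package = "dbac",
                          mustWork = TRUE)
      tab <- utils::read.csv(path, stringsAsFactors = FALSE)
      .dbac_env$radii <- stats::setNames(tab$radius, toupper(tab$element))
    }
    return(.dbac_env$radii)
  }
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  stats::setNames(tab$radius, toupper(tab$element))
}

#' Assign a van der Waals radius to atoms
#'
#' @param element character vector of element symbols (no hydrogens).
#' @param table radius table from [vdw_radius_table()].
#' @param label optional atom labels used in error messages.
#' @return numeric vector of radii in Angstrom.
#' @examples
#' assign_vdw_radius("N")  # 1.65
#' @export
assign_vdw_radius <- function(element, table = vdw_radius_table(),
                              label = NULL) {
  el <- toupper(element)
  r <- unname(table[el])
  if (anyNA(r)) {
    bad <- which(is.na(r))[1]
    who <- if (!is.null(label)) label[bad] else el[bad]
    stop("no van der Waals radius for element '", el[bad], "' (atom ", who,
         "); supply a radius table that covers it", call. = FALSE)
  }
  r
}

#' Chemical class dictionary
#'
#' Maps (residue name, atom name) to a subset of
#' \{POSITIVE, NEGATIVE, DONOR, ACCEPTOR\}.  Backbone entries use residue
#' name `*`.  Shipped as an editable CSV (`resname,atom,class`, one class per
#' row) so an alternative classification can be swapped in without code
#' change.
#'
#' @param file optional path to a replacement CSV dictionary.
#' @return data.frame with columns `resname`, `atom`, `class`.
#' @export
chem_class_dict <- function(file = NULL) {
  if (is.null(file)) {
    if (is.null(.dbac_env$classes)) {
      path <- system.file("extdata", "atom_classes.csv", package = "dbac",
                          mustWork = TRUE)
      .dbac_env$classes <- utils::read.csv(path, stringsAsFactors = FALSE)
    }
    return(.dbac_env$classes)
  }
  utils::read.csv(file, stringsAsFactors = FALSE)
}

#' Chemical classes of one atom
#'
#' @param resname 3-letter residue name.
#' @param atom_name PDB atom name (e.g. "NZ", "OD1").
#' @param dict dictionary from [chem_class_dict()].
#' @return character vector, a subset of
#'   `c("POSITIVE", "NEGATIVE", "DONOR", "ACCEPTOR")`; empty for apolar or
#'   unknown atoms.
#' @examples
#' assign_chem_classes("LYS", "NZ")   # POSITIVE, DONOR
#' assign_chem_classes("LEU", "CD1")  # character(0)
#' @export
assign_chem_classes <- function(resname, atom_name, dict = chem_class_dict()) {
  hit <- (dict$resname == resname | dict$resname == "*") &
    dict$atom == atom_name
  sort(unique(dict$class[hit]))
}

# Vectorised variant: semicolon-joined class strings, aligned to input.
chem_class_strings <- function(resname, atom_name, dict = chem_class_dict()) {
  key <- paste(dict$resname, dict$atom, sep = "|")
  agg <- tapply(dict$class, key, function(z) paste(sort(unique(z)),
                                                   collapse = ";"))
  specific <- unname(agg[paste(resname, atom_name, sep = "|")])
  generic <- unname(agg[paste("*", atom_name, sep = "|")])
  out <- ifelse(is.na(specific), ifelse(is.na(generic), "", generic),
                ifelse(is.na(generic), specific,
                       paste(specific, generic, sep = ";")))
  # re-canonicalise merged strings
  vapply(strsplit(out, ";", fixed = TRUE), function(z)
    paste(sort(unique(z[nzchar(z)])), collapse = ";"), character(1))
}

WATER_RESNAMES <- c("HOH", "WAT", "DOD")

derive_element <- function(elety, elesy) {
  el <- toupper(trimws(ifelse(is.na(elesy), "", elesy)))
  need <- !nzchar(el)
  if (any(need)) {
    nm <- toupper(gsub("[^A-Za-z]", "", elety[need]))
    el[need] <- substr(nm, 1L, 1L)
  }
  el
}

residue_key <- function(chain, resno, insert) {
  ins <- ifelse(is.na(insert) | insert == " ", "", insert)
  paste(chain, resno, ins, sep = ":")
}

# Internal constructor + validation shared by the reader and the generators.
structure_from_atoms <- function(atoms, side_a, side_b,
                                 sides_required = TRUE) {
  stopifnot(is.data.frame(atoms))
  side_a <- unique(as.character(side_a))
  side_b <- unique(as.character(side_b))
  if (length(intersect(side_a, side_b)))
    stop("side_a and side_b must be disjoint chain sets", call. = FALSE)
  if (sides_required && (!length(side_a) || !length(side_b)))
    stop("both sides of the chain partition must be non-empty", call. = FALSE)
  prot <- !atoms$is_water
  if (sides_required && any(prot)) {
    bad <- setdiff(unique(atoms$chain[prot]), c(side_a, side_b))
    if (length(bad))
      stop("chains not assigned to either side: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  key <- paste(residue_key(atoms$chain, atoms$resno, atoms$insert),
               atoms$name, atoms$is_water)
  if (anyDuplicated(key))
    stop("duplicate (residue, atom name) after alternate-location resolution",
         call. = FALSE)
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates", call. = FALSE)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, side_a = side_a, side_b = side_b),
            class = "dbac_structure")
}

#' Read a protein complex from a PDB file
#'
#' Parses the first model of a PDB file into a heavy-atom structure: all
#' non-hydrogen atoms of the requested chains plus all crystallographic water
#' oxygens (residue names HOH/WAT/DOD).  Alternate locations are resolved to
#' the highest-occupancy conformer (ties broken by altloc letter).  Non-water
#' heteroatoms are excluded unless listed in `hetero_include`.  Parsing is
#' delegated to \pkg{bio3d}.
#'
#' @param file path to a PDB file.
#' @param side_a,side_b chain identifiers of the two interacting sides.
#' @param keep_waters retain water oxygens (default TRUE).
#' @param hetero_include residue names of non-water HETATM groups to retain.
#' @param radius_table radii from [vdw_radius_table()].
#' @param class_dict dictionary from [chem_class_dict()].
#' @return an object of class `dbac_structure`: a list with `atoms` (ordered
#'   data.frame: serial, name, resname, chain, resno, insert, element, x, y,
#'   z, occupancy, is_water, radius, classes) and the chain partition
#'   `side_a`, `side_b`.
#' @export
read_structure <- function(file, side_a, side_b, keep_waters = TRUE,
                           hetero_include = character(),
                           radius_table = vdw_radius_table(),
                           class_dict = chem_class_dict()) {
  if (!file.exists(file)) stop("PDB file not found: ", file, call. = FALSE)
  pdb <- suppressWarnings(bio3d::read.pdb(file, multi = FALSE,
                                          rm.alt = FALSE, verbose = FALSE))
  at <- pdb$atom
  at$element <- derive_element(at$elety, at$elesy)
  at <- at[!(at$element %in% c("H", "D")), , drop = FALSE]
  is_water <- at$resid %in% WATER_RESNAMES
  keep <- (!is_water & at$chain %in% c(side_a, side_b) &
             (at$type == "ATOM" | at$resid %in% hetero_include)) |
    (is_water & keep_waters & at$element == "O")
  at <- at[keep, , drop = FALSE]
  is_water <- at$resid %in% WATER_RESNAMES
  if (!nrow(at[!is_water, ])) stop("no protein atoms for the requested chains",
                                   call. = FALSE)
  for (ch in c(side_a, side_b))
    if (!any(at$chain[!is_water] == ch))
      stop("no atoms found for requested chain '", ch, "'", call. = FALSE)
  # alternate locations: highest occupancy, ties by altloc letter order
  occ <- ifelse(is.na(at$o), 1, at$o)
  alt <- ifelse(is.na(at$alt), "", at$alt)
  grp <- paste(at$chain, at$resno,
               ifelse(is.na(at$insert), "", at$insert), at$resid, at$elety,
               is_water)
  ord <- order(match(grp, unique(grp)), -occ, alt)
  at <- at[ord, , drop = FALSE][!duplicated(grp[ord]), , drop = FALSE]
  at <- at[order(match(rownames(at), rownames(pdb$atom))), , drop = FALSE]
  is_water <- at$resid %in% WATER_RESNAMES
  atoms <- data.frame(
    serial = at$eleno,
    name = at$elety,
    resname = at$resid,
    chain = ifelse(is_water, NA_character_, at$chain),
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    element = at$element,
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    is_water = is_water,
    stringsAsFactors = FALSE)
  atoms$radius <- assign_vdw_radius(atoms$element, radius_table,
                                    label = paste0(atoms$resname, "/",
                                                   atoms$name))
  atoms$classes <- chem_class_strings(
    ifelse(atoms$is_water, "HOH", atoms$resname), atoms$name, class_dict)
  structure_from_atoms(atoms, side_a, side_b)
}

#' Write a structure back to PDB format
#'
#' Protein atoms are emitted as ATOM records and waters as HETATM records,
#' via \pkg{bio3d}.  Round-tripping through [read_structure()] preserves
#' names, residue identifiers and coordinates to 3 decimals.
#'
#' @param x a `dbac_structure`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_structure <- function(x, file) {
  at <- x$atoms
  bio3d::write.pdb(
    pdb = NULL, file = file,
    type = ifelse(at$is_water, "HETATM", "ATOM"),
    xyz = as.vector(t(as.matrix(at[, c("x", "y", "z")]))),
    resno = at$resno,
    resid = at$resname,
    eleno = at$serial,
    elety = at$name,
    chain = ifelse(is.na(at$chain), "W", at$chain),
    insert = ifelse(at$insert == "", NA, at$insert),
    o = at$occupancy,
    b = rep(0, nrow(at)),
    elesy = at$element)
  invisible(file)
}

#' @export
print.dbac_structure <- function(x, ...) {
  at <- x$atoms
  cat("dbac structure:", sum(!at$is_water), "protein atoms,",
      sum(at$is_water), "waters\n")
  cat("  side A chains:", paste(x$side_a, collapse = ", "), "\n")
  cat("  side B chains:", paste(x$side_b, collapse = ", "), "\n")
  nres <- length(unique(residue_key(at$chain, at$resno,
                                    at$insert)[!at$is_water]))
  cat("  residues:", nres, "\n")
  invisible(x)
}

# chain side of each atom: "A", "B" or NA (waters / unassigned)
atom_side <- function(x) {
  s <- rep(NA_character_, nrow(x$atoms))
  s[x$atoms$chain %in% x$side_a & !x$atoms$is_water] <- "A"
  s[x$atoms$chain %in% x$side_b & !x$atoms$is_water] <- "B"
  s
}
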