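#' Build the atomic contact graph
#'
#' Nodes are the atoms of a (water-pruned) structure; an undirected edge
#' joins atoms i and j iff they are Delaunay neighbours (their Voronoi cells
#' share a facet) AND their distance is strictly less than
#' `r_i + r_j + pad`, where `pad` defaults to 2.75 A, the diameter of a
#' water molecule.  Buried waters participate as ordinary nodes.
#'
#' @param x a `dbac_structure`, already pruned of exposed waters.
#' @param exposed logical exposure flags aligned to `x$atoms` (from
#'   [label_exposure()] on the same atoms).
#' @param pad distance padding added to the two van der Waals radii
#'   (Angstrom).
#' @param include_waters keep water atoms as graph nodes (default TRUE).
#'   Setting FALSE drops them before triangulation, for sensitivity
#'   analysis of the role of buried waters.
#' @param jitter apply a deterministic coordinate jitter (uniform within
#'   `+/- jitter_amp`, seed `jitter_seed`) before triangulation, for
#'   degenerate/cocircular inputs.
#' @param jitter_amp,jitter_seed jitter magnitude (Angstrom) and seed.
#' @return object of class `dbac_contact_graph`: list with `edges`
#'   (m x 2 integer, i < j, indices into `x$atoms`), `d` (edge lengths),
#'   `n`, `exposed`, and the `structure` the graph was built on.
#' @export
build_contact_graph <- function(x, exposed, pad = 2.75,
                                include_waters = TRUE,
                                jitter = FALSE, jitter_amp = 1e-6,
                                jitter_seed = 0L) {
  at <- x$atoms
  stopifnot(length(exposed) == nrow(at))
  if (!include_waters) {
    keep <- !at$is_water
    x <- structure_from_atoms(at[keep, , drop = FALSE], x$side_a, x$side_b,
                              sides_required = FALSE)
    at <- x$atoms
    exposed <- exposed[keep]
  }
  n <- nrow(at)
  if (n < 5)
    stop("need at least 5 atoms to build the contact graph", call. = FALSE)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  if (jitter)
    xyz <- xyz + with_private_seed(jitter_seed,
      matrix(runif(3 * n, -jitter_amp, jitter_amp), n, 3))
  e <- delaunay_edges(xyz)
  d <- sqrt(rowSums((xyz[e[, 1], , drop = FALSE] -
                       xyz[e[, 2], , drop = FALSE])^2))
  gate <- at$radius[e[, 1]] + at$radius[e[, 2]] + pad
  keep <- d < gate  # strict: the boundary is not a contact
  structure(list(edges = e[keep, , drop = FALSE], d = d[keep], n = n,
                 exposed = exposed, structure = x),
            class = "dbac_contact_graph")
}

#' @export
print.dbac_contact_graph <- function(x, ...) {
  cat("atomic contact graph:", x$n, "atoms,", nrow(x$edges), "contacts,",
      sum(x$exposed), "exposed atoms\n")
  invisible(x)
}

#' Burial level of every atom
#'
#' The burial level of an atom is the length of the shortest path in the
#' contact graph from the atom to its nearest exposed atom.  It is computed
#' by adding a pseudo node representing bulk solvent, connected to exactly
#' the exposed atoms, and taking unit-weight shortest-path distances from it
#' minus one (breadth-first search; with unit weights this coincides with
#' Dijkstra).  Exposed atoms get level 0.  Atoms with no path to any exposed
#' atom receive `Inf` with a warning.
#'
#' @param graph a `dbac_contact_graph`.
#' @return object of class `dbac_burial`: list with `atom_level` (numeric,
#'   `Inf` sentinel for unreachable atoms).
#' @export
atom_burial_levels <- function(graph) {
  n <- graph$n
  if (!any(graph$exposed))
    stop("no exposed atoms: burial levels are undefined", call. = FALSE)
  pseudo <- n + 1L
  pe <- cbind(pseudo, which(graph$exposed))
  g <- igraph::make_graph(edges = as.vector(t(rbind(graph$edges, pe))),
                          n = pseudo, directed = FALSE)
  lev <- as.vector(igraph::distances(g, v = pseudo))[seq_len(n)] - 1
  if (any(is.infinite(lev)))
    warning(sum(is.infinite(lev)),
            " atom(s) unreachable from any exposed atom (isolated buried ",
            "pocket); level set to Inf", call. = FALSE)
  structure(list(atom_level = lev), class = "dbac_burial")
}

#' @export
print.dbac_burial <- function(x, ...) {
  lv <- x$atom_level[is.finite(x$atom_level)]
  cat("burial levels for", length(x$atom_level), "atoms: max",
      max(lv), "| mean", round(mean(lv), 2), "\n")
  print(table(factor(lv, levels = 0:max(lv))))
  invisible(x)
}

#' Burial level of one residue
#'
#' Arithmetic mean of the burial levels of the residue's heavy atoms
#' (backbone included).  Unreachable atoms (infinite level) are excluded
#' from the mean with a warning; a residue with no finite-level atom is an
#' error.
#'
#' @param x a `dbac_structure`.
#' @param burial a `dbac_burial` aligned to `x$atoms`.
#' @param chain,resno,insert residue identity.
#' @return residue burial level (non-negative real).
#' @export
residue_burial_level <- function(x, burial, chain, resno, insert = "") {
  at <- x$atoms
  sel <- !at$is_water & at$chain == chain & at$resno == resno &
    at$insert == insert
  sel[is.na(sel)] <- FALSE
  if (!any(sel))
    stop("residue ", chain, ":", resno, insert, " not found in structure",
         call. = FALSE)
  lv <- burial$atom_level[sel]
  fin <- is.finite(lv)
  if (!any(fin))
    stop("residue ", chain, ":", resno, insert,
         " has no atom reachable from the surface", call. = FALSE)
  if (!all(fin))
    warning("residue ", chain, ":", resno, insert, ": ", sum(!fin),
            " unreachable atom(s) excluded from the mean", call. = FALSE)
  mean(lv[fin])
}

#' Burial levels of all residues
#'
#' @param x a `dbac_structure`.
#' @param burial a `dbac_burial` aligned to `x$atoms`.
#' @return data.frame with columns chain, resno, insert, resname, n_atoms,
#'   level, in order of first appearance.
#' @export
residue_burial_levels <- function(x, burial) {
  at <- x$atoms
  prot <- which(!at$is_water)
  key <- residue_key(at$chain[prot], at$resno[prot], at$insert[prot])
  first <- prot[!duplicated(key)]
  lv <- split(burial$atom_level[prot], match(key, unique(key)))
  data.frame(
    chain = at$chain[first],
    resno = at$resno[first],
    insert = at$insert[first],
    resname = at$resname[first],
    n_atoms = lengths(lv),
    level = vapply(lv, function(z) mean(z[is.finite(z)]), numeric(1)),
    stringsAsFactors = FALSE)
}

#' Burial level of an atomic contact
#'
#' The smaller of the two endpoint levels (equal to the shared value when
#' the endpoints agree; contacting atoms can differ by at most one level).
#'
#' @param burial a `dbac_burial`.
#' @param i,j atom indices of the contact endpoints.
#' @return integer vector of contact burial levels.
#' @export
contact_burial_level <- function(burial, i, j) {
  li <- burial$atom_level[i]
  lj <- burial$atom_level[j]
  if (any(is.infinite(li) | is.infinite(lj)))
    stop("contact endpoint has infinite burial level", call. = FALSE)
  pmin(li, lj)
}
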