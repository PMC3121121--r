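# Deterministic synthetic structure and dataset generators.  They emit their
# own ground truth (reference burial levels, planted contact counts, class
# labels) so the whole pipeline can be validated without any external data.

carbon_atoms <- function(xyz, chain, resno_start = 1L, serial_start = 1L,
                         resname = "ALA", name = "CB") {
  n <- nrow(xyz)
  data.frame(
    serial = seq.int(serial_start, length.out = n),
    name = name, resname = resname, chain = chain,
    resno = seq.int(resno_start, length.out = n), insert = "",
    element = "C", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, is_water = FALSE,
    radius = unname(vdw_radius_table()["C"]),
    classes = "", stringsAsFactors = FALSE)
}

#' Cubic lattice burial fixture
#'
#' A block of carbon-like atoms on a jittered cubic lattice, together with
#' reference burial levels computed by the independent brute-force pipeline
#' ([oracle_sasa()] exposure + [oracle_contact_edges()] +
#' [oracle_bfs_levels()]).  The jitter (default 0.05 A, well below any
#' contact-gate margin) puts the points in general position so the Delaunay
#' tessellation is unique.
#'
#' @param nx,ny,nz lattice dimensions (>= 1).
#' @param spacing lattice constant in Angstrom; must lie in (2.0, 6.5) so
#'   that lattice neighbours are contacts under the carbon gate.
#' @param seed jitter seed.
#' @param jitter jitter amplitude in Angstrom.
#' @param probe,threshold,pad SASA probe, exposure cutoff, contact padding.
#' @return list with `structure` (a `dbac_structure`, single chain "A"),
#'   `exposed` (reference flags), `edges` (reference contact edges) and
#'   `levels` (reference per-atom burial levels).
#' @export
make_lattice_block <- function(nx = 3, ny = 3, nz = 3, spacing = 3.8,
                               seed = 0, jitter = 0.05, probe = 1.4,
                               threshold = 10, pad = 2.75) {
  stopifnot(nx >= 1, ny >= 1, nz >= 1)
  if (spacing <= 2.0 || spacing >= 6.5)
    stop("spacing must lie in (2.0, 6.5) Angstrom for lattice neighbours ",
         "to form contacts", call. = FALSE)
  g <- expand.grid(x = seq_len(nx), y = seq_len(ny), z = seq_len(nz))
  xyz <- as.matrix(g) * spacing
  n <- nrow(xyz)
  xyz <- xyz + with_private_seed(seed,
    matrix(runif(3 * n, -jitter, jitter), n, 3))
  at <- carbon_atoms(xyz, chain = "A")
  x <- structure_from_atoms(at, side_a = "A", side_b = character(),
                            sides_required = FALSE)
  ref <- oracle_sasa(xyz, at$radius, probe, threshold)
  if (n >= 4) {
    edges <- oracle_contact_edges(xyz, at$radius, pad)
  } else {
    edges <- matrix(integer(), 0, 2)
  }
  levels <- oracle_bfs_levels(n, edges, ref$exposed)
  list(structure = x, exposed = ref$exposed, edges = edges, levels = levels)
}

# Fibonacci shell of carbons at radius R around `center`; `spacing` sets the
# surface density (approximate nearest-neighbour distance in Angstrom).
shell_points <- function(R, center, spacing) {
  n <- max(12L, ceiling(4 * pi * R^2 / (0.866 * spacing^2)))
  p <- sphere_points(n) * R
  sweep(p, 2, center, "+")
}

TOY_RESIDUE <- list(
  I = list(resname = "LYS", atom = "NZ", element = "N",
           partner_resname = "ASP", partner_atom = "OD1",
           partner_element = "O"),
  II = list(resname = "SER", atom = "OG", element = "O",
            partner_resname = "GLY", partner_atom = "O",
            partner_element = "O"),
  III = list(resname = "LEU", atom = "CD1", element = "C",
             partner_resname = "GLY", partner_atom = "CA",
             partner_element = "C"))

# shell radii for burial bands 1..3; inner shells are dense (2.2 A spacing),
# the outermost is looser (4.0 A) so its atoms stay above the 10 A^2
# exposure threshold while the layer still blocks the 1.4 A probe.
TOY_SHELL_RADII <- c(5.2, 9.5, 13.8)
TOY_PARTNER_OFFSET <- 2.9

#' Planted-contact toy complex
#'
#' Builds a two-chain mini-complex in which each requested residue forms a
#' known number of Type-I/II/III cross-chain atomic contacts at a known
#' burial band, and returns the planted counts as ground truth.  One
#' pseudo-residue is planted per request, at its own well-separated site:
#' a side-chain atom (LYS NZ / SER OG / LEU CD1 for Types I/II/III) with
#' `n` partner atoms (ASP OD1 / GLY O / GLY CA) 2.9 A away on the other
#' chain, wrapped in `band` concentric carbon shells on a non-interfacial
#' chain flank to force the burial band.  Four distant anchor atoms keep
#' the point set 3D.  Pseudo-residues use real residue/atom names so the
#' chemistry dictionary is exercised rather than bypassed.
#'
#' @param planted data.frame with columns `type` ("I", "II" or "III"),
#'   `band` (0, 1, 2 or 3) and `n` (contacts to plant, >= 0); one planted
#'   residue per row.  May have zero rows (empty interface).
#' @param seed reserved for future stochastic variants; the construction is
#'   deterministic.
#' @return list with `structure` (chains: planted residues "A", partners
#'   "B", shields+anchors "C"; side_a = \{A, C\}, side_b = \{B\}) and
#'   `expected`: one row per planted residue with chain, resno, resname and
#'   the 11 planted count columns in the AC layout.
#' @export
make_toy_complex <- function(planted, seed = 0) {
  stopifnot(is.data.frame(planted))
  if (nrow(planted)) {
    if (!all(planted$type %in% c("I", "II", "III")))
      stop("planted$type must be I, II or III", call. = FALSE)
    if (!all(planted$band %in% 0:3))
      stop("planted$band must be 0, 1, 2 or 3", call. = FALSE)
    if (!all(planted$n >= 0))
      stop("planted$n must be non-negative", call. = FALSE)
    if (any(planted$n > 8))
      stop("at most 8 contacts can be planted per residue ",
           "(partner directions would collide)", call. = FALSE)
  }
  rows <- list()
  expected <- list()
  serial <- 1L
  partner_resno <- 1L
  shield_resno <- 1L
  count_cols <- setdiff(AC_COLUMNS, "RBL")
  rad <- vdw_radius_table()
  for (k in seq_len(nrow(planted))) {
    site <- c(40 * k, 0, 0)
    spec <- TOY_RESIDUE[[planted$type[k]]]
    band <- planted$band[k]
    n <- planted$n[k]
    res_atom <- data.frame(
      serial = serial, name = spec$atom, resname = spec$resname,
      chain = "A", resno = k, insert = "", element = spec$element,
      x = site[1], y = site[2], z = site[3], occupancy = 1,
      is_water = FALSE, radius = unname(rad[spec$element]), classes = "",
      stringsAsFactors = FALSE)
    serial <- serial + 1L
    rows[[length(rows) + 1L]] <- res_atom
    if (n > 0) {
      dirs <- sphere_points(n)
      pxyz <- sweep(dirs * TOY_PARTNER_OFFSET, 2, site, "+")
      partners <- data.frame(
        serial = seq.int(serial, length.out = n),
        name = spec$partner_atom, resname = spec$partner_resname,
        chain = "B", resno = seq.int(partner_resno, length.out = n),
        insert = "", element = spec$partner_element,
        x = pxyz[, 1], y = pxyz[, 2], z = pxyz[, 3], occupancy = 1,
        is_water = FALSE, radius = unname(rad[spec$partner_element]),
        classes = "", stringsAsFactors = FALSE)
      serial <- serial + n
      partner_resno <- partner_resno + n
      rows[[length(rows) + 1L]] <- partners
      if (band > 0) {
        for (s in seq_len(band)) {
          sp <- if (s == band) 4.0 else 2.2
          sxyz <- shell_points(TOY_SHELL_RADII[s], site, sp)
          sh <- carbon_atoms(sxyz, chain = "C",
                             resno_start = shield_resno,
                             serial_start = serial)
          serial <- serial + nrow(sxyz)
          shield_resno <- shield_resno + nrow(sxyz)
          rows[[length(rows) + 1L]] <- sh
        }
      }
    }
    cnt <- stats::setNames(numeric(length(count_cols)), count_cols)
    if (n > 0) {
      bandlab <- if (planted$type[k] == "I") {
        if (band >= 2) "ge2" else as.character(band)
      } else if (band >= 3) "ge3" else as.character(band)
      cnt[paste0("C_", planted$type[k], "_", bandlab)] <- n
    }
    expected[[k]] <- cbind(
      data.frame(chain = "A", resno = k, resname = spec$resname,
                 type = planted$type[k], band = band,
                 stringsAsFactors = FALSE),
      as.data.frame(as.list(cnt)))
  }
  anchor <- 180 + 8 * rbind(c(0, 0, 0), c(1, 1, 0), c(1, 0, 1), c(0, 1, 1),
                            c(2, 2, 2))
  rows[[length(rows) + 1L]] <- carbon_atoms(anchor, chain = "C",
                                            resno_start = shield_resno,
                                            serial_start = serial)
  atoms <- do.call(rbind, rows)
  atoms$classes <- chem_class_strings(atoms$resname, atoms$name)
  x <- structure_from_atoms(atoms, side_a = c("A", "C"), side_b = "B",
                            sides_required = FALSE)
  list(structure = x,
       expected = if (length(expected)) do.call(rbind, expected) else
         data.frame())
}

#' Synthetic labelled feature dataset
#'
#' Draws DBAC-layout feature vectors (RBL plus five deep-contact counts)
#' for a two-class classification benchmark.  Non hot spots sit near the
#' origin (exposed, few deep contacts); hot spots are shifted by
#' `separation` standard deviations along the unit diagonal of feature
#' space.  Gaussian noise has unit standard deviation; count columns are
#' rounded to integers and clipped at zero, RBL is clipped at zero.
#'
#' @param n_pos,n_neg class sizes (>= 2).
#' @param separation centroid distance in sigma units (0 = no signal).
#' @param seed RNG seed; same seed, same table.
#' @return list with `x` (data.frame of 6 features) and `y` (logical,
#'   TRUE = hot spot).
#' @export
make_feature_dataset <- function(n_pos, n_neg, separation, seed = 0) {
  stopifnot(n_pos >= 2, n_neg >= 2, separation >= 0)
  base <- c(RBL = 0.8, C_I_ge2 = 0.1, C_II_2 = 0.3, C_II_ge3 = 0.1,
            C_III_2 = 0.8, C_III_ge3 = 0.4)
  shift <- separation / sqrt(6)
  n <- n_pos + n_neg
  y <- rep(c(TRUE, FALSE), c(n_pos, n_neg))
  x <- with_private_seed(seed, {
    m <- matrix(rnorm(n * 6), n, 6)
    m + matrix(base, n, 6, byrow = TRUE) + shift * y
  })
  colnames(x) <- names(base)
  x[, -1] <- round(x[, -1])
  x[x < 0] <- 0
  list(x = as.data.frame(x), y = y)
}
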