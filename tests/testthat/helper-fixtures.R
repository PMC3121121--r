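# Shared test helpers: hand-built structures, a tiny PDB writer, closed-form
# oracles for SASA and metrics, and random abstract contact graphs.

atoms_df <- function(name, resname, chain, resno, element, xyz,
                     insert = "", is_water = FALSE, serial = NULL) {
  n <- length(name)
  xyz <- matrix(xyz, ncol = 3)
  rad <- vdw_radius_table()
  df <- data.frame(
    serial = serial %||% seq_len(n), name = name, resname = resname,
    chain = chain, resno = resno, insert = insert, element = element,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occupancy = 1,
    is_water = is_water, radius = unname(rad[element]),
    stringsAsFactors = FALSE)
  df$classes <- dbac:::chem_class_strings(
    ifelse(df$is_water, "HOH", df$resname), df$name)
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

mk_structure <- function(atoms, side_a = "A", side_b = character()) {
  dbac:::structure_from_atoms(atoms, side_a, side_b,
                              sides_required = length(side_b) > 0)
}

pdb_line <- function(rec, serial, name, alt, resname, chain, resno, icode,
                     x, y, z, occ, element) {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, name, alt, resname, chain, resno, icode,
          x, y, z, occ, 0, element)
}

# Fixture: 1 ALA (chain A, with hydrogens and an altloc pair on CB),
# 1 GLY (chain B), 1 water.
write_parser_fixture <- function(path) {
  lines <- c(
    pdb_line("ATOM", 1, "N",   " ", "ALA", "A", 1, " ", 0.0, 0.0, 0.0, 1.0, "N"),
    pdb_line("ATOM", 2, "CA",  " ", "ALA", "A", 1, " ", 1.5, 0.0, 0.0, 1.0, "C"),
    pdb_line("ATOM", 3, "C",   " ", "ALA", "A", 1, " ", 2.1, 1.4, 0.0, 1.0, "C"),
    pdb_line("ATOM", 4, "O",   " ", "ALA", "A", 1, " ", 1.5, 2.4, 0.4, 1.0, "O"),
    pdb_line("ATOM", 5, "CB",  "A", "ALA", "A", 1, " ", 2.2, -0.8, 1.1, 0.6, "C"),
    pdb_line("ATOM", 6, "CB",  "B", "ALA", "A", 1, " ", 2.4, -0.9, 1.3, 0.4, "C"),
    pdb_line("ATOM", 7, "HB1", " ", "ALA", "A", 1, " ", 2.9, -1.1, 0.9, 1.0, "H"),
    pdb_line("ATOM", 8, "H",   " ", "ALA", "A", 1, " ", -0.5, 0.7, 0.2, 1.0, "H"),
    pdb_line("ATOM", 9, "N",   " ", "GLY", "B", 7, " ", 6.0, 0.0, 0.0, 1.0, "N"),
    pdb_line("ATOM", 10, "CA", " ", "GLY", "B", 7, " ", 7.4, 0.0, 0.3, 1.0, "C"),
    pdb_line("ATOM", 11, "C",  " ", "GLY", "B", 7, " ", 8.1, 1.3, 0.0, 1.0, "C"),
    pdb_line("ATOM", 12, "O",  " ", "GLY", "B", 7, " ", 7.6, 2.4, 0.3, 1.0, "O"),
    pdb_line("HETATM", 13, "O", " ", "HOH", "W", 101, " ", 4.0, 3.0, 1.0, 1.0, "O"),
    "END")
  writeLines(lines, path)
  path
}

# Closed-form accessible area of sphere 1 (expanded radius R1) occluded by
# sphere 2 (expanded radius R2) at centre distance d (intersecting case).
two_sphere_area <- function(R1, R2, d) {
  h <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  4 * pi * R1^2 - 2 * pi * R1 * h
}

metrics_direct <- function(tp, fp, tn, fn) {
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  c(sens = sens, prec = prec,
    spec = if (tn + fp > 0) tn / (tn + fp) else 0,
    acc = (tp + tn) / (tp + fp + tn + fn),
    f1 = if (tp == 0) 0 else 2 * prec * sens / (prec + sens))
}

# Random abstract contact graph (no geometry): for graph-level burial
# properties.  Guarantees at least one exposed atom.
random_graph <- function(n, p = 0.08, seed = 1) {
  set.seed(seed)
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p
  exposed <- runif(n) < 0.25
  if (!any(exposed)) exposed[sample(n, 1)] <- TRUE
  structure(list(edges = unname(pairs[keep, , drop = FALSE]), n = n,
                 exposed = exposed),
            class = "dbac_contact_graph")
}

# Full production pipeline on a structure: SASA -> exposure -> prune ->
# graph -> burial.
run_burial_pipeline <- function(x, probe = 1.4, threshold = 10,
                                pad = 2.75, n_points = 960) {
  s <- compute_sasa(x, probe, n_points)
  ex <- label_exposure(s, threshold)
  xp <- prune_exposed_waters(x, ex)
  keep <- !(x$atoms$is_water & ex)
  g <- build_contact_graph(xp, ex[keep], pad = pad)
  list(sasa = s, exposed = ex, graph = g,
       burial = atom_burial_levels(g))
}
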