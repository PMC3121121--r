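test_that("contact edges require both Delaunay adjacency and the distance gate", {
  # regular tetrahedron of carbons (edge 3.0) plus a distant anchor:
  # all 6 tetrahedron pairs are contacts (3.0 < 1.87 + 1.87 + 2.75)
  s <- 3.0 / sqrt(2)
  tet <- rbind(c(s, s, s), c(s, -s, -s), c(-s, s, -s), c(-s, -s, s)) / sqrt(2)
  xyz <- rbind(tet, c(40, 0, 0))
  at <- atoms_df("CB", "ALA", "A", 1:5, "C", xyz)
  x <- mk_structure(at)
  g <- build_contact_graph(x, exposed = rep(TRUE, 5))
  pairs <- apply(g$edges, 1, paste, collapse = "-")
  for (p in c("1-2", "1-3", "1-4", "2-3", "2-4", "3-4"))
    expect_true(p %in% pairs, info = p)
  # two carbons 7.0 A apart share a Delaunay facet but fail the gate
  xyz2 <- rbind(c(0, 0, 0), c(7, 0, 0), c(3.5, 12, 0), c(3.5, 12, 3),
                c(3.5, 15, 1.5))
  x2 <- mk_structure(atoms_df("CB", "ALA", "A", 1:5, "C", xyz2))
  g2 <- build_contact_graph(x2, exposed = rep(TRUE, 5))
  expect_true(any(delaunay_edges(xyz2)[, 1] == 1 &
                    delaunay_edges(xyz2)[, 2] == 2))
  expect_false(any(g2$edges[, 1] == 1 & g2$edges[, 2] == 2))
})

test_that("random-cloud edge set equals the brute-force double-filter oracle", {
  set.seed(42)
  xyz <- matrix(runif(150, 0, 18), 50, 3)
  at <- atoms_df("CB", "ALA", "A", 1:50, "C", xyz)
  g <- build_contact_graph(mk_structure(at), exposed = rep(TRUE, 50))
  prod <- g$edges[order(g$edges[, 1], g$edges[, 2]), ]
  orac <- oracle_contact_edges(xyz, at$radius)
  expect_identical(prod, orac)
})

test_that("graph construction rejects degenerate inputs with advice", {
  at <- atoms_df("CB", "ALA", "A", 1:4, "C",
                 matrix(c(0, 0, 0, 3, 0, 0, 0, 3, 0, 3, 3, 0), 4,
                        byrow = TRUE))
  expect_error(build_contact_graph(mk_structure(at), rep(TRUE, 4)),
               "at least 5")
  coplanar <- cbind(matrix(runif(10, 0, 9), 5, 2), 0)
  at2 <- atoms_df("CB", "ALA", "A", 1:5, "C", coplanar)
  expect_error(build_contact_graph(mk_structure(at2), rep(TRUE, 5)),
               "jitter")
  # jitter mode rescues the coplanar case deterministically
  g1 <- build_contact_graph(mk_structure(at2), rep(TRUE, 5), jitter = TRUE)
  g2 <- build_contact_graph(mk_structure(at2), rep(TRUE, 5), jitter = TRUE)
  expect_identical(g1$edges, g2$edges)
})

test_that("burial levels are BFS distances from the exposed shell", {
  # path graph a-b-c with only a exposed: levels 0, 1, 2
  g <- structure(list(edges = rbind(c(1L, 2L), c(2L, 3L)), n = 3L,
                      exposed = c(TRUE, FALSE, FALSE)),
                 class = "dbac_contact_graph")
  expect_equal(atom_burial_levels(g)$atom_level, c(0, 1, 2))
  # all atoms exposed: all levels zero
  g2 <- structure(list(edges = rbind(c(1L, 2L)), n = 4L,
                       exposed = rep(TRUE, 4)),
                  class = "dbac_contact_graph")
  expect_equal(atom_burial_levels(g2)$atom_level, rep(0, 4))
  # zero exposed atoms is an error
  g3 <- g
  g3$exposed <- rep(FALSE, 3)
  expect_error(atom_burial_levels(g3), "no exposed")
  # unreachable atoms get the Inf sentinel with a warning
  g4 <- structure(list(edges = rbind(c(1L, 2L)), n = 3L,
                       exposed = c(TRUE, FALSE, FALSE)),
                  class = "dbac_contact_graph")
  expect_warning(b4 <- atom_burial_levels(g4), "unreachable")
  expect_equal(b4$atom_level, c(0, 1, Inf))
})

test_that("levels on random graphs satisfy all structural invariants and match the oracle", {
  for (seed in 1:50) {
    n <- sample(8:40, 1)
    g <- random_graph(n, p = runif(1, 0.04, 0.25), seed = seed)
    lev <- suppressWarnings(atom_burial_levels(g)$atom_level)
    # equality with the independent relaxation oracle
    expect_equal(lev, oracle_bfs_levels(g$n, g$edges, g$exposed))
    # exposed atoms are level 0; no other atom is
    expect_true(all(lev[g$exposed] == 0))
    expect_true(all(lev[!g$exposed] >= 1))
    fin <- is.finite(lev)
    if (nrow(g$edges)) {
      dl <- abs(lev[g$edges[, 1]] - lev[g$edges[, 2]])
      # adjacent atoms differ by at most one level
      expect_true(all(dl[is.finite(dl)] <= 1))
      # buried atom adjacent to an exposed atom has level exactly 1
      touch_exposed <- unique(c(g$edges[g$exposed[g$edges[, 2]], 1],
                                g$edges[g$exposed[g$edges[, 1]], 2]))
      touch_exposed <- touch_exposed[!g$exposed[touch_exposed]]
      expect_true(all(lev[touch_exposed] == 1))
      # contact level is the min of the endpoints
      cl <- contact_burial_level(
        structure(list(atom_level = ifelse(fin, lev, 99)),
                  class = "dbac_burial"),
        g$edges[, 1], g$edges[, 2])
      expect_equal(cl, pmin(ifelse(fin, lev, 99)[g$edges[, 1]],
                            ifelse(fin, lev, 99)[g$edges[, 2]]))
    }
  }
})

test_that("removing an edge never decreases any burial level", {
  g <- random_graph(25, p = 0.15, seed = 99)
  lev <- suppressWarnings(atom_burial_levels(g)$atom_level)
  for (k in sample(nrow(g$edges), 5)) {
    g2 <- g
    g2$edges <- g$edges[-k, , drop = FALSE]
    lev2 <- suppressWarnings(atom_burial_levels(g2)$atom_level)
    expect_true(all(lev2 >= lev))
  }
})

test_that("residue burial level is the mean over the residue's heavy atoms", {
  at <- atoms_df(c("N", "CA", "CB"), "ALA", "A", 1, "C",
                 matrix(c(0, 0, 0, 1.5, 0, 0, 3, 0, 0), 3, byrow = TRUE))
  x <- mk_structure(at)
  b <- structure(list(atom_level = c(1, 2, 3)), class = "dbac_burial")
  expect_equal(residue_burial_level(x, b, "A", 1), 2.0)
  b0 <- structure(list(atom_level = c(0, 0, 0)), class = "dbac_burial")
  expect_equal(residue_burial_level(x, b0, "A", 1), 0.0)
  expect_error(residue_burial_level(x, b, "A", 99), "not found")
  tab <- residue_burial_levels(x, b)
  expect_equal(tab$level, 2)
  expect_equal(tab$n_atoms, 3L)
})

test_that("contact burial level takes the smaller endpoint level", {
  b <- structure(list(atom_level = c(2, 3, 0, 0, 4, 3, Inf)),
                 class = "dbac_burial")
  expect_equal(contact_burial_level(b, 1, 2), 2)
  expect_equal(contact_burial_level(b, 3, 4), 0)
  expect_equal(contact_burial_level(b, 5, 6), 3)
  expect_error(contact_burial_level(b, 1, 7), "infinite")
})
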