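# small two-chain structure for contact bookkeeping tests:
# SER (N, CA, CB, OG) on chain A; GLY (CA) and LYS (NZ) and ASP (OD1) on
# chain B; one water.  Edges are supplied by hand so the bookkeeping can be
# tested independently of geometry.
mini_complex <- function() {
  at <- rbind(
    atoms_df(c("N", "CA", "CB", "OG"), "SER", "A", 1,
             c("N", "C", "C", "O"),
             matrix(c(0, 0, 0, 1.5, 0, 0, 2.2, 1.2, 0, 3.4, 1.1, 0.8),
                    4, byrow = TRUE)),
    atoms_df("CA", "GLY", "B", 10, "C", c(5.5, 1.5, 1.0), serial = 5),
    atoms_df("NZ", "LYS", "B", 11, "N", c(6.5, 3.5, 1.0), serial = 6),
    atoms_df("OD1", "ASP", "B", 12, "O", c(4.5, 4.0, 2.0), serial = 7),
    atoms_df("O", "HOH", NA, 100, "O", c(3.0, 3.0, 3.0),
             is_water = TRUE, serial = 8))
  mk_structure(at, side_a = "A", side_b = "B")
}

mini_graph <- function(x, edges) {
  structure(list(edges = edges, n = nrow(x$atoms),
                 exposed = rep(TRUE, nrow(x$atoms)), structure = x),
            class = "dbac_contact_graph")
}

test_that("interfacial contacts cross the partition and never involve waters", {
  x <- mini_complex()
  edges <- rbind(c(1L, 2L),  # intra-residue, side A
                 c(4L, 5L),  # OG - GLY CA: interfacial
                 c(3L, 5L),  # CB - GLY CA: interfacial
                 c(5L, 6L),  # both side B
                 c(4L, 8L),  # OG - water: excluded
                 c(6L, 8L))  # NZ - water: excluded
  g <- mini_graph(x, edges)
  ic <- interfacial_contacts(g, x)
  expect_equal(ic, rbind(c(4L, 5L), c(3L, 5L)))
  # empty partition side errors
  x2 <- x
  x2$side_b <- character()
  expect_error(interfacial_contacts(g, x2), "non-empty")
})

test_that("directly broken contacts require a side-chain atom beyond C-beta", {
  x <- mini_complex()
  edges <- rbind(c(4L, 5L),  # SER OG - GLY CA: directly broken
                 c(3L, 5L),  # SER CB - GLY CA: survives mutation
                 c(2L, 6L))  # SER CA - LYS NZ: survives mutation
  ic <- interfacial_contacts(mini_graph(x, edges), x)
  db <- directly_broken_contacts(x, ic, "A", 1)
  expect_equal(db, rbind(c(4L, 5L)))
  # from the partner's perspective the GLY backbone contributes nothing
  expect_equal(nrow(directly_broken_contacts(x, ic, "B", 10)), 0)
  expect_error(directly_broken_contacts(x, ic, "A", 99), "not found")
})

test_that("GLY and ALA residues have no directly broken contacts", {
  tc <- make_toy_complex(data.frame(type = "II", band = 0, n = 2))
  x <- tc$structure
  # shield/anchor chain C residues are single-CB ALA pseudo-residues
  p <- run_burial_pipeline(x)
  ic <- interfacial_contacts(p$graph, x)
  ala <- x$atoms[x$atoms$chain == "C", ][1, ]
  expect_equal(nrow(directly_broken_contacts(x, ic, "C", ala$resno)), 0)
})

test_that("contact typing has exclusive I > II > III precedence", {
  expect_equal(classify_contact(c("POSITIVE", "DONOR"),
                                c("NEGATIVE", "ACCEPTOR")), "I")
  expect_equal(classify_contact(c("DONOR", "ACCEPTOR"), "ACCEPTOR"), "II")
  expect_equal(classify_contact(character(), character()), "III")
  # dual-role pairing that is not POSITIVE-NEGATIVE falls through to II
  expect_equal(classify_contact(c("POSITIVE", "DONOR"), "ACCEPTOR"), "II")
  # orientation symmetric
  expect_equal(classify_contact("ACCEPTOR", "DONOR"), "II")
  expect_equal(classify_contact(c("NEGATIVE", "ACCEPTOR"),
                                c("POSITIVE", "DONOR")), "I")
  # exhaustive: every class-set pair gets exactly one type
  pool <- list(character(), "DONOR", "ACCEPTOR", c("POSITIVE", "DONOR"),
               c("NEGATIVE", "ACCEPTOR"), c("DONOR", "ACCEPTOR"),
               c("POSITIVE", "DONOR", "ACCEPTOR"))
  for (a in pool) for (b in pool) {
    t <- classify_contact(a, b)
    expect_true(t %in% c("I", "II", "III"))
    if (t == "I")
      expect_true(("POSITIVE" %in% a && "NEGATIVE" %in% b) ||
                    ("NEGATIVE" %in% a && "POSITIVE" %in% b))
  }
})

test_that("feature vectors count planted contacts per type and band", {
  tc <- make_toy_complex(data.frame(type = c("I", "III"), band = c(2, 1),
                                    n = c(2, 3)))
  x <- tc$structure
  p <- run_burial_pipeline(x)
  fv <- feature_vector(x, p$graph, p$burial, "A", 1, mode = "DBAC")
  expect_named(fv, c("RBL", "C_I_ge2", "C_II_2", "C_II_ge3", "C_III_2",
                     "C_III_ge3"))
  expect_equal(unname(fv["C_I_ge2"]), 2)
  fv2 <- feature_vector(x, p$graph, p$burial, "A", 2, mode = "AC")
  expect_length(fv2, 12)
  expect_equal(unname(fv2["C_III_1"]), 3)
  expect_equal(unname(fv2["C_III_2"]), 0)
})

test_that("residues without interfacial contacts get all-zero counts", {
  tc <- make_toy_complex(data.frame(type = "II", band = 0, n = 2))
  x <- tc$structure
  p <- run_burial_pipeline(x)
  # a shield/anchor residue is not interfacial at all
  anchor_resno <- utils::tail(x$atoms$resno[x$atoms$chain == "C"], 1)
  fv <- feature_vector(x, p$graph, p$burial, "C", anchor_resno,
                       mode = "DBAC")
  expect_equal(unname(fv[-1]), rep(0, 5))
})

test_that("feature vectors are invariant under partition swap", {
  tc <- make_toy_complex(data.frame(type = c("II", "III"), band = c(2, 0),
                                    n = c(3, 2)))
  x <- tc$structure
  p <- run_burial_pipeline(x)
  ft1 <- feature_table(x, p$graph, p$burial,
                       residues = data.frame(chain = "A", resno = 1:2),
                       mode = "AC")
  xs <- x
  xs$side_a <- x$side_b
  xs$side_b <- x$side_a
  gs <- p$graph
  gs$structure <- xs
  ft2 <- feature_table(xs, gs, p$burial,
                       residues = data.frame(chain = "A", resno = 1:2),
                       mode = "AC")
  expect_equal(ft1, ft2)
})

test_that("AC counts conserve the number of directly broken contacts", {
  tc <- make_toy_complex(data.frame(type = c("I", "II", "III"),
                                    band = c(1, 2, 0), n = c(2, 4, 3)))
  x <- tc$structure
  p <- run_burial_pipeline(x)
  ic <- interfacial_contacts(p$graph, x)
  for (r in 1:3) {
    fv <- feature_vector(x, p$graph, p$burial, "A", r, mode = "AC")
    db <- directly_broken_contacts(x, ic, "A", r)
    expect_equal(sum(fv[-1]), nrow(db))
  }
})

test_that("deep bands are coherent: level-2 and level>=3 partition level>=2", {
  tc <- make_toy_complex(data.frame(type = c("II", "II"), band = c(2, 3),
                                    n = c(2, 3)))
  x <- tc$structure
  p <- run_burial_pipeline(x)
  ic <- interfacial_contacts(p$graph, x)
  for (r in 1:2) {
    fv <- feature_vector(x, p$graph, p$burial, "A", r, mode = "AC")
    db <- directly_broken_contacts(x, ic, "A", r)
    lev <- contact_burial_level(p$burial, db[, 1], db[, 2])
    types <- vapply(seq_len(nrow(db)), function(k)
      classify_contact(assign_chem_classes(x$atoms$resname[db[k, 1]],
                                           x$atoms$name[db[k, 1]]),
                       assign_chem_classes(x$atoms$resname[db[k, 2]],
                                           x$atoms$name[db[k, 2]])),
      character(1))
    expect_equal(unname(fv["C_II_2"] + fv["C_II_ge3"]),
                 sum(types == "II" & lev >= 2))
    expect_equal(unname(fv["C_II_ge3"]), sum(types == "II" & lev >= 3))
  }
})
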