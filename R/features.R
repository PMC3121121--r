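# Atoms surviving an alanine substitution: the mutated residue keeps its
# backbone (incl. terminal OXT) and C-beta.  Contacts formed by any other
# atom of the residue are "directly broken" by the mutation.
ALA_REMAINDER <- c("N", "CA", "C", "O", "CB", "OXT")

#' Interfacial atomic contacts
#'
#' Contacts whose endpoints lie on opposite sides of the configured chain
#' partition.  Waters carry no chain-side membership and are never contact
#' partners for interfacial counting (they influence features only by
#' deepening burial levels).
#'
#' @param graph a `dbac_contact_graph`.
#' @param x the `dbac_structure` the graph was built on (defaults to the one
#'   stored in the graph).
#' @return integer matrix, m x 2, subset of the graph's edges.
#' @export
interfacial_contacts <- function(graph, x = graph$structure) {
  if (!length(x$side_a) || !length(x$side_b))
    stop("both sides of the chain partition must be non-empty", call. = FALSE)
  side <- atom_side(x)
  e <- graph$edges
  s1 <- side[e[, 1]]
  s2 <- side[e[, 2]]
  keep <- !is.na(s1) & !is.na(s2) & s1 != s2
  e[keep, , drop = FALSE]
}

#' Directly broken interfacial contacts of a residue
#'
#' The interfacial contacts lost purely by atom removal when the residue is
#' mutated to alanine: those formed by an atom of the residue beyond the
#' alanine remainder \{N, CA, C, O, CB, OXT\} and any atom of the other
#' chain side (the partner may be any atom, including backbone).  GLY and
#' ALA residues therefore have none.
#'
#' @param x a `dbac_structure`.
#' @param contacts interfacial contacts from [interfacial_contacts()].
#' @param chain,resno,insert residue identity.
#' @return integer matrix, k x 2, with the residue-side atom in column 1.
#' @export
directly_broken_contacts <- function(x, contacts, chain, resno,
                                     insert = "") {
  at <- x$atoms
  inres <- !at$is_water & at$chain == chain & at$resno == resno &
    at$insert == insert
  inres[is.na(inres)] <- FALSE
  if (!any(inres))
    stop("residue ", chain, ":", resno, insert, " not found in structure",
         call. = FALSE)
  broken <- which(inres & !(at$name %in% ALA_REMAINDER))
  if (!nrow(contacts))
    return(matrix(integer(), 0, 2))
  in1 <- contacts[, 1] %in% broken
  in2 <- contacts[, 2] %in% broken
  out <- rbind(contacts[in1, , drop = FALSE],
               contacts[in2, 2:1, drop = FALSE])
  dimnames(out) <- NULL
  out
}

#' Classify an atomic contact as Type I, II or III
#'
#' Type-I: one endpoint positively and the other negatively charged (a
#' salt-bridge-like pair).  Otherwise Type-II: one endpoint a hydrogen-bond
#' donor and the other an acceptor, in either orientation (a hydrogen-bond
#' like pair).  Everything else is Type-III.  Precedence is I > II > III and
#' exclusive: a POSITIVE-ACCEPTOR pairing that is not POSITIVE-NEGATIVE
#' falls through to the donor/acceptor test.
#'
#' @param classes_i,classes_j chemical class sets of the two endpoints
#'   (character vectors from [assign_chem_classes()], possibly empty).
#' @return `"I"`, `"II"` or `"III"`.
#' @export
classify_contact <- function(classes_i, classes_j) {
  if (("POSITIVE" %in% classes_i && "NEGATIVE" %in% classes_j) ||
      ("NEGATIVE" %in% classes_i && "POSITIVE" %in% classes_j))
    return("I")
  if (("DONOR" %in% classes_i && "ACCEPTOR" %in% classes_j) ||
      ("ACCEPTOR" %in% classes_i && "DONOR" %in% classes_j))
    return("II")
  "III"
}

# vectorised over edge matrix, using the structure's cached class strings
classify_edges <- function(x, e) {
  if (!nrow(e)) return(character(0))
  cl <- strsplit(x$atoms$classes, ";", fixed = TRUE)
  vapply(seq_len(nrow(e)), function(k)
    classify_contact(cl[[e[k, 1]]], cl[[e[k, 2]]]), character(1))
}

band_of <- function(level) {
  ifelse(level >= 3, "ge3", as.character(level))
}

DBAC_COLUMNS <- c("RBL", "C_I_ge2", "C_II_2", "C_II_ge3", "C_III_2",
                  "C_III_ge3")
AC_COLUMNS <- c(DBAC_COLUMNS, "C_I_0", "C_I_1", "C_II_0", "C_II_1",
                "C_III_0", "C_III_1")

#' Feature vector of a residue
#'
#' Counts of the residue's directly broken interfacial atomic contacts,
#' binned by contact type (I/II/III) and burial band, plus the residue
#' burial level (RBL).  Deep bands follow the model definition: Type-I
#' merges levels >= 2 into one count `C_I_ge2`; Types II and III distinguish
#' level 2 from level >= 3.  `mode = "DBAC"` returns the 6 deeply-buried
#' features; `mode = "AC"` appends the exposed (level 0) and slightly buried
#' (level 1) counts for 12 features.
#'
#' @param x a `dbac_structure`.
#' @param graph a `dbac_contact_graph` built on `x`.
#' @param burial a `dbac_burial` for the graph.
#' @param chain,resno,insert residue identity.
#' @param mode `"DBAC"` (deeply buried contacts only) or `"AC"` (all bands).
#' @param contacts optionally precomputed [interfacial_contacts()].
#' @return named numeric vector of length 6 (DBAC) or 12 (AC).
#' @export
feature_vector <- function(x, graph, burial, chain, resno, insert = "",
                           mode = c("DBAC", "AC"),
                           contacts = interfacial_contacts(graph, x)) {
  mode <- match.arg(mode)
  cols <- if (mode == "DBAC") DBAC_COLUMNS else AC_COLUMNS
  v <- stats::setNames(numeric(length(cols)), cols)
  v["RBL"] <- residue_burial_level(x, burial, chain, resno, insert)
  db <- directly_broken_contacts(x, contacts, chain, resno, insert)
  if (nrow(db)) {
    type <- classify_edges(x, db)
    lev <- contact_burial_level(burial, db[, 1], db[, 2])
    band <- band_of(lev)
    band[type == "I" & lev >= 2] <- "ge2"
    key <- paste0("C_", type, "_", band)
    for (k in key) if (k %in% names(v)) v[k] <- v[k] + 1
  }
  v
}

#' Interface residues of a complex
#'
#' A residue is interfacial when at least one of its atoms has an
#' interfacial atomic contact (graph definition, the default), or when its
#' SASA decreases on complex formation (`method = "dsasa"`, computed by
#' comparing the complex against each side in isolation).
#'
#' @param x a `dbac_structure`.
#' @param graph a `dbac_contact_graph` built on `x`.
#' @param method `"contact"` or `"dsasa"`.
#' @param probe,n_points SASA parameters for `method = "dsasa"`.
#' @return data.frame with columns chain, resno, insert, resname.
#' @export
interface_residues <- function(x, graph, method = c("contact", "dsasa"),
                               probe = 1.4, n_points = 960) {
  method <- match.arg(method)
  at <- x$atoms
  if (method == "contact") {
    e <- interfacial_contacts(graph, x)
    idx <- sort(unique(as.vector(e)))
  } else {
    side <- atom_side(x)
    full <- compute_sasa(x, probe, n_points)$area
    idx <- integer(0)
    for (s in c("A", "B")) {
      keep <- which(side == s)
      sub <- structure_from_atoms(at[keep, , drop = FALSE], x$side_a,
                                  x$side_b, sides_required = FALSE)
      apart <- compute_sasa(sub, probe, n_points)$area
      idx <- c(idx, keep[apart - full[keep] > 1e-6])
    }
    idx <- sort(idx)
  }
  key <- residue_key(at$chain[idx], at$resno[idx], at$insert[idx])
  first <- idx[!duplicated(key)]
  data.frame(chain = at$chain[first], resno = at$resno[first],
             insert = at$insert[first], resname = at$resname[first],
             stringsAsFactors = FALSE)
}

#' Feature table for a set of residues
#'
#' @param x a `dbac_structure`.
#' @param graph a `dbac_contact_graph` built on `x`.
#' @param burial a `dbac_burial` for the graph.
#' @param residues data.frame with columns chain, resno and optionally
#'   insert; defaults to all interface residues.
#' @param mode `"DBAC"` or `"AC"` (see [feature_vector()]).
#' @return data.frame: chain, resno, insert, resname, then the feature
#'   columns.
#' @export
feature_table <- function(x, graph, burial,
                          residues = interface_residues(x, graph),
                          mode = c("DBAC", "AC")) {
  mode <- match.arg(mode)
  if (is.null(residues$insert)) residues$insert <- ""
  contacts <- interfacial_contacts(graph, x)
  at <- x$atoms
  feats <- t(vapply(seq_len(nrow(residues)), function(k)
    feature_vector(x, graph, burial, residues$chain[k], residues$resno[k],
                   residues$insert[k], mode, contacts),
    numeric(if (mode == "DBAC") 6L else 12L)))
  resname <- vapply(seq_len(nrow(residues)), function(k) {
    sel <- which(!at$is_water & at$chain == residues$chain[k] &
                   at$resno == residues$resno[k] &
                   at$insert == residues$insert[k])
    at$resname[sel[1]]
  }, character(1))
  cbind(data.frame(chain = residues$chain, resno = residues$resno,
                   insert = residues$insert, resname = resname,
                   stringsAsFactors = FALSE),
        as.data.frame(feats))
}
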