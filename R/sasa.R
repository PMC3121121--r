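#' Deterministic unit-sphere point set (golden-spiral / Fibonacci lattice)
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @keywords internal
sphere_points <- function(n) {
  i <- seq_len(n) - 1L
  z <- 1 - (2 * i + 1) / n
  theta <- i * pi * (3 - sqrt(5))
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(theta), s * sin(theta), z)
}

#' Solvent accessible surface area (Shrake-Rupley)
#'
#' Per-atom SASA with a rolling probe, computed by the Shrake-Rupley point
#' method on a deterministic golden-spiral lattice (default 960 points per
#' atom).  All atoms present in the structure participate as occluders,
#' including waters.
#'
#' @param x a `dbac_structure`.
#' @param probe probe radius in Angstrom (default 1.4, a water probe).
#' @param n_points sphere test points per atom; more points, finer areas.
#' @return object of class `dbac_sasa`: list with `area` (Angstrom^2, aligned
#'   to atom order), `probe`, `n_points`.
#' @export
compute_sasa <- function(x, probe = 1.4, n_points = 960) {
  at <- x$atoms
  n <- nrow(at)
  if (n == 0) stop("empty structure", call. = FALSE)
  if (probe <= 0) stop("probe radius must be positive", call. = FALSE)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  r <- at$radius + probe
  pts <- sphere_points(n_points)
  area <- 4 * pi * r^2
  if (n > 1) {
    rad <- 2 * max(r)
    k <- min(n, 32L)
    repeat {
      nn <- RANN::nn2(xyz, xyz, k = k, searchtype = "radius", radius = rad)
      if (k == n || all(nn$nn.idx[, k] == 0L)) break
      k <- min(n, 2L * k)
    }
    for (i in seq_len(n)) {
      idx <- nn$nn.idx[i, ]
      d <- sqrt(nn$nn.dists[i, ])
      valid <- idx > 0L & idx != i
      idx <- idx[valid]
      idx <- idx[d[valid] < r[i] + r[idx]]
      if (!length(idx)) next
      p <- pts * r[i]
      p[, 1] <- p[, 1] + xyz[i, 1]
      p[, 2] <- p[, 2] + xyz[i, 2]
      p[, 3] <- p[, 3] + xyz[i, 3]
      cen <- xyz[idx, , drop = FALSE]
      d2 <- outer(rowSums(p * p), rowSums(cen * cen), "+") -
        2 * p %*% t(cen)
      inside <- d2 < matrix(r[idx]^2, n_points, length(idx), byrow = TRUE)
      area[i] <- area[i] * sum(rowSums(inside) == 0L) / n_points
    }
  }
  structure(list(area = area, probe = probe, n_points = n_points),
            class = "dbac_sasa")
}

#' @export
print.dbac_sasa <- function(x, ...) {
  cat("SASA for", length(x$area), "atoms (probe", x$probe, "A,",
      x$n_points, "points/atom): total",
      round(sum(x$area), 1), "A^2\n")
  invisible(x)
}

#' Label atoms exposed or buried
#'
#' An atom is EXPOSED when its SASA is not less than the threshold
#' (boundary inclusive, default 10.0 Angstrom^2), otherwise BURIED.
#'
#' @param sasa a `dbac_sasa` object (or bare numeric vector of areas).
#' @param threshold exposure cutoff in Angstrom^2.
#' @return logical vector, TRUE = exposed.
#' @export
label_exposure <- function(sasa, threshold = 10.0) {
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  area <- if (inherits(sasa, "dbac_sasa")) sasa$area else sasa
  area >= threshold
}

#' Remove exposed water molecules
#'
#' Exposed waters belong to bulk solvent and are removed; buried waters are
#' retained as part of the complex (and later become contact-graph nodes).
#' Single pass: flags must come from a SASA computation on the structure that
#' still contains all waters.
#'
#' @param x a `dbac_structure` containing the waters the flags were computed
#'   on.
#' @param exposed logical exposure flags aligned to `x$atoms`.
#' @return the structure with exposed waters deleted, atom order preserved.
#' @export
prune_exposed_waters <- function(x, exposed) {
  stopifnot(length(exposed) == nrow(x$atoms))
  keep <- !(x$atoms$is_water & exposed)
  structure_from_atoms(x$atoms[keep, , drop = FALSE], x$side_a, x$side_b,
                       sides_required = FALSE)
}
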