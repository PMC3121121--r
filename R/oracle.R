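# Independent brute-force reference pipeline used by the synthetic fixture
# generators (and the test suite) to produce ground-truth burial levels.
# These functions deliberately share no code with the production path:
# Delaunay adjacency by exhaustive empty-circumsphere enumeration instead of
# Qhull, shortest paths by iterative relaxation instead of igraph BFS, and
# SASA by randomly oriented sphere points instead of the golden spiral.

#' Brute-force Delaunay neighbour pairs
#'
#' Enumerates every 4-point subset, keeps those whose circumsphere contains
#' no other point (the Delaunay tetrahedra, for points in general position)
#' and returns the union of their edges.  O(n^5): reference use on small
#' point sets only.
#'
#' @param xyz n x 3 coordinate matrix (general position).
#' @param tol relative tolerance for the empty-sphere test.
#' @return integer matrix, m x 2, rows `i < j`.
#' @keywords internal
#' @export
oracle_delaunay_edges <- function(xyz, tol = 1e-9) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  stopifnot(n >= 4)
  quad <- utils::combn(n, 4)
  m <- ncol(quad)
  p1 <- xyz[quad[1, ], , drop = FALSE]
  a1 <- xyz[quad[2, ], , drop = FALSE] - p1
  a2 <- xyz[quad[3, ], , drop = FALSE] - p1
  a3 <- xyz[quad[4, ], , drop = FALSE] - p1
  cross <- function(u, v)
    cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
          u[, 3] * v[, 1] - u[, 1] * v[, 3],
          u[, 1] * v[, 2] - u[, 2] * v[, 1])
  c23 <- cross(a2, a3)
  c31 <- cross(a3, a1)
  c12 <- cross(a1, a2)
  det <- rowSums(a1 * c23)
  b1 <- 0.5 * rowSums(a1 * a1)
  b2 <- 0.5 * rowSums(a2 * a2)
  b3 <- 0.5 * rowSums(a3 * a3)
  scale <- pmax(rowSums(a1^2), rowSums(a2^2), rowSums(a3^2))^1.5
  ok <- abs(det) > 1e-12 * scale  # skip (near-)coplanar quadruples
  cen <- (b1 * c23 + b2 * c31 + b3 * c12) / det + p1
  r2 <- rowSums((cen - p1)^2)
  edges <- matrix(integer(), 0, 2)
  block <- max(1L, floor(2e7 / n))
  for (s in seq(1, m, by = block)) {
    ix <- seq(s, min(m, s + block - 1L))
    ix <- ix[ok[ix]]
    if (!length(ix)) next
    d2 <- outer(rowSums(cen[ix, , drop = FALSE]^2), rowSums(xyz^2), "+") -
      2 * cen[ix, , drop = FALSE] %*% t(xyz)
    inside <- d2 < r2[ix] * (1 - tol)
    # the subset's own four points sit on the sphere, not inside
    inside[cbind(seq_along(ix), quad[1, ix])] <- FALSE
    inside[cbind(seq_along(ix), quad[2, ix])] <- FALSE
    inside[cbind(seq_along(ix), quad[3, ix])] <- FALSE
    inside[cbind(seq_along(ix), quad[4, ix])] <- FALSE
    keep <- ix[rowSums(inside) == 0L]
    if (length(keep)) {
      q <- quad[, keep, drop = FALSE]
      pairs <- rbind(q[c(1, 2), ], q[c(1, 3), ], q[c(1, 4), ],
                     q[c(2, 3), ], q[c(2, 4), ], q[c(3, 4), ])
      e <- matrix(pairs, ncol = 2, byrow = TRUE)
      edges <- rbind(edges, e)
    }
  }
  edges <- unique(cbind(pmin(edges[, 1], edges[, 2]),
                        pmax(edges[, 1], edges[, 2])))
  edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
}

#' Brute-force contact edges
#'
#' Independent double filter: brute-force Delaunay pairs intersected with
#' the strict distance gate `d < r_i + r_j + pad` computed from the full
#' pairwise distance matrix.
#'
#' @param xyz coordinates; `radii` per-atom van der Waals radii; `pad`
#'   distance padding (Angstrom).
#' @return integer matrix, m x 2.
#' @keywords internal
#' @export
oracle_contact_edges <- function(xyz, radii, pad = 2.75) {
  e <- oracle_delaunay_edges(xyz)
  d <- sqrt(rowSums((xyz[e[, 1], , drop = FALSE] -
                       xyz[e[, 2], , drop = FALSE])^2))
  e[d < radii[e[, 1]] + radii[e[, 2]] + pad, , drop = FALSE]
}

#' Brute-force burial levels
#'
#' Iterative relaxation (Bellman-Ford style) of
#' `level[i] = min(level[i], 1 + min(level[neighbours]))`, seeded with 0 at
#' the exposed atoms, until a fixed point.  Equivalent to min distance to
#' any exposed atom.
#'
#' @param n atom count; `edges` m x 2 integer; `exposed` logical.
#' @return numeric vector of levels (`Inf` where unreachable).
#' @keywords internal
#' @export
oracle_bfs_levels <- function(n, edges, exposed) {
  lev <- ifelse(exposed, 0, Inf)
  repeat {
    new <- lev
    if (nrow(edges)) {
      cand1 <- lev[edges[, 2]] + 1
      cand2 <- lev[edges[, 1]] + 1
      for (k in seq_len(nrow(edges))) {
        if (cand1[k] < new[edges[k, 1]]) new[edges[k, 1]] <- cand1[k]
        if (cand2[k] < new[edges[k, 2]]) new[edges[k, 2]] <- cand2[k]
      }
    }
    if (identical(new, lev)) break
    lev <- new
  }
  lev
}

#' Brute-force SASA and exposure flags
#'
#' Plain Shrake-Rupley with randomly oriented sphere points (fixed seed) and
#' no neighbour lists: every atom is tested against every other atom.
#'
#' @param xyz coordinates; `radii` van der Waals radii; `probe` probe
#'   radius; `threshold` exposure cutoff; `n_points` points per atom;
#'   `seed` RNG seed for the point directions.
#' @return list with `area` and logical `exposed`.
#' @keywords internal
#' @export
oracle_sasa <- function(xyz, radii, probe = 1.4, threshold = 10,
                        n_points = 1500, seed = 1) {
  n <- nrow(xyz)
  dirs <- with_private_seed(seed, {
    v <- matrix(rnorm(3 * n_points), n_points, 3)
    v / sqrt(rowSums(v^2))
  })
  r <- radii + probe
  area <- numeric(n)
  for (i in seq_len(n)) {
    p <- dirs * r[i]
    p[, 1] <- p[, 1] + xyz[i, 1]
    p[, 2] <- p[, 2] + xyz[i, 2]
    p[, 3] <- p[, 3] + xyz[i, 3]
    free <- rep(TRUE, n_points)
    for (j in seq_len(n)) {
      if (j == i) next
      dx <- p[, 1] - xyz[j, 1]
      dy <- p[, 2] - xyz[j, 2]
      dz <- p[, 3] - xyz[j, 3]
      free <- free & (dx * dx + dy * dy + dz * dz >= r[j]^2)
    }
    area[i] <- 4 * pi * r[i]^2 * mean(free)
  }
  list(area = area, exposed = area >= threshold)
}
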