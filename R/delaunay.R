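# 3D Delaunay tessellation via Qhull (scipy.spatial.Delaunay), invoked
# through the bundled helper script.  Two atoms share a Voronoi facet iff
# they are joined by an edge of the Delaunay tessellation.

python_binary <- function() {
  bin <- getOption("dbac.python", "")
  if (nzchar(bin)) return(bin)
  for (cand in c("python3", "python")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(unname(p))
  }
  stop("no python interpreter found; set options(dbac.python = ...)",
       call. = FALSE)
}

#' Delaunay neighbour pairs of a 3D point set
#'
#' Returns every pair of points that shares a tetrahedron of the Delaunay
#' tessellation (equivalently, whose Voronoi cells share a facet).  The
#' tessellation is computed by Qhull.
#'
#' @param xyz numeric matrix, n x 3 coordinates (n >= 5, non-degenerate).
#' @return integer matrix, m x 2, each row an unordered pair `i < j`.
#' @export
delaunay_edges <- function(xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 5)
    stop("need at least 5 points for a 3D Delaunay tessellation",
         call. = FALSE)
  fin <- tempfile(fileext = ".txt")
  fout <- tempfile(fileext = ".txt")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  utils::write.table(format(xyz, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     fin, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  script <- system.file("python", "delaunay_edges.py", package = "dbac",
                        mustWork = TRUE)
  res <- suppressWarnings(system2(python_binary(), c(script, fin, fout),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0)
    stop("Delaunay tessellation failed (degenerate geometry? consider ",
         "jitter = TRUE):\n", paste(utils::tail(res, 3), collapse = "\n"),
         call. = FALSE)
  e <- as.matrix(utils::read.table(fout, col.names = c("i", "j")))
  storage.mode(e) <- "integer"
  dimnames(e) <- NULL
  e
}
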