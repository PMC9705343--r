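# Surface reconstruction from stacked contours, and mesh file IO.

#' Build a shell mesh from stacked wall contours
#'
#' Connects the per-slice contour rings of one surface (endocardial or
#' epicardial) into a triangulated shell. All slices must carry the same
#' number of contour vertices, vertex order is assumed consistent across
#' slices (as written by [generateCMR()]). Node z is the slice mid-plane,
#' `(slice + 0.5) * sliceThickness`.
#'
#' @param contours a [WallContours-class].
#' @param surface `"endo"` or `"epi"`.
#' @param sliceThickness slice thickness (mm).
#' @return a [TriangleMesh-class].
#' @export
contourSurfaceMesh <- function(contours, surface = c("endo", "epi"),
                               sliceThickness) {
  surface <- match.arg(surface)
  cc <- contourTable(contours)
  cc <- cc[cc$surface == surface, , drop = FALSE]
  slices <- sort(unique(cc$slice))
  nv <- vapply(slices, function(s) sum(cc$slice == s), integer(1))
  if (length(unique(nv)) != 1L)
    stop("all slices must have the same number of contour vertices")
  nv <- nv[1L]
  nodes <- do.call(rbind, lapply(slices, function(s) {
    ring <- cc[cc$slice == s, , drop = FALSE]
    cbind(ring$x, ring$y, (s + 0.5) * sliceThickness)
  }))
  ns <- length(slices)
  tris <- NULL
  if (ns > 1L) {
    tris <- vector("list", ns - 1L)
    for (k in seq_len(ns - 1L)) {
      a <- (k - 1L) * nv + seq_len(nv)          # ring k
      b <- k * nv + seq_len(nv)                 # ring k + 1
      a2 <- c(a[-1L], a[1L])
      b2 <- c(b[-1L], b[1L])
      tris[[k]] <- rbind(cbind(a, a2, b), cbind(a2, b2, b))
    }
    tris <- do.call(rbind, tris)
  } else {
    stop("need >= 2 contour slices to build a surface mesh")
  }
  TriangleMesh(nodes, tris)
}

#' Read and write OFF surface meshes
#'
#' Plain-text Object File Format: a header line `OFF`, counts, node
#' coordinates, then polygon rows `3 i j k` (0-based indices).
#'
#' @param mesh a [TriangleMesh-class].
#' @param path file path.
#' @return `readMeshOFF` returns a [TriangleMesh-class];
#'   `writeMeshOFF` returns `path` invisibly.
#' @export
writeMeshOFF <- function(mesh, path) {
  nodes <- meshNodes(mesh); tris <- meshTriangles(mesh)
  con <- file(path, "w"); on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(nodes), nrow(tris)), con)
  writeLines(sprintf("%.6f %.6f %.6f", nodes[, 1], nodes[, 2], nodes[, 3]), con)
  writeLines(sprintf("3 %d %d %d", tris[, 1] - 1L, tris[, 2] - 1L,
                     tris[, 3] - 1L), con)
  invisible(path)
}

#' @rdname writeMeshOFF
#' @export
readMeshOFF <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  if (trimws(ln[1L]) != "OFF") stop("not an OFF file")
  cnt <- as.integer(strsplit(trimws(ln[2L]), "\\s+")[[1L]])
  nv <- cnt[1L]; nf <- cnt[2L]
  nodes <- do.call(rbind, lapply(ln[3:(2 + nv)], function(s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1L]][1:3])))
  tris <- do.call(rbind, lapply(ln[(3 + nv):(2 + nv + nf)], function(s) {
    v <- as.integer(strsplit(trimws(s), "\\s+")[[1L]])
    if (v[1L] != 3L) stop("only triangle faces supported")
    v[2:4] + 1L
  }))
  TriangleMesh(nodes, tris)
}

#' Subdivide every mesh triangle into four
#'
#' Midpoint (loop-style, linear) subdivision used for refinement-convergence
#' checks of area quantification.
#'
#' @param mesh a [TriangleMesh-class].
#' @return a [TriangleMesh-class] with 4x the triangles.
#' @export
subdivideMesh <- function(mesh) {
  nodes <- meshNodes(mesh); tris <- meshTriangles(mesh)
  edgeKey <- function(i, j) paste(pmin(i, j), pmax(i, j))
  env <- new.env()
  newNodes <- list()
  midIndex <- function(i, j) {
    k <- edgeKey(i, j)
    if (!is.null(env[[k]])) return(env[[k]])
    newNodes[[length(newNodes) + 1L]] <<- (nodes[i, ] + nodes[j, ]) / 2
    env[[k]] <- nrow(nodes) + length(newNodes)
    env[[k]]
  }
  out <- vector("list", nrow(tris))
  for (t in seq_len(nrow(tris))) {
    a <- tris[t, 1L]; b <- tris[t, 2L]; c <- tris[t, 3L]
    ab <- midIndex(a, b); bc <- midIndex(b, c); ca <- midIndex(c, a)
    out[[t]] <- rbind(c(a, ab, ca), c(ab, b, bc), c(ca, bc, c), c(ab, bc, ca))
  }
  TriangleMesh(rbind(nodes, do.call(rbind, newNodes)), do.call(rbind, out))
}
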