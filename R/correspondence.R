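#' Thin-plate-spline warp driven by landmarks
#'
#' 3D TPS interpolant (radial kernel U(r) = r plus an affine part) taking
#' each source landmark exactly onto its target when `lambda = 0`, with
#' minimal bending energy elsewhere. Affine maps of the landmarks are
#' reproduced exactly. A small `lambda` relaxes exact interpolation for
#' noisy landmarks.
#'
#' @param sourceLandmarks,targetLandmarks [LandmarkSet-class] objects or
#'   named point matrices with identical names (>= 4, non-coplanar)
#' @param points (n x 3) matrix of points to warp
#' @param lambda non-negative regularization weight (default 0: exact
#'   interpolation)
#' @return the warped (n x 3) point matrix
#' @export
tpsWarp <- function(sourceLandmarks, targetLandmarks, points, lambda = 0) {
  X <- asPointMatrix(sourceLandmarks)
  Y <- asPointMatrix(targetLandmarks)
  if (!is.null(rownames(X)) && !is.null(rownames(Y))) {
    if (!setequal(rownames(X), rownames(Y)))
      stop("landmark names differ between source and target")
    Y <- Y[rownames(X), , drop = FALSE]
  } else if (nrow(X) != nrow(Y)) {
    stop("source and target landmark counts differ")
  }
  n <- nrow(X)
  if (n < 4) stop("at least 4 landmarks required for a 3D warp")
  D <- rowDist(X, X)
  if (any(D[upper.tri(D)] < 1e-9))
    stop("coincident source landmarks: TPS system is singular")
  Xc <- sweep(X, 2, colMeans(X))
  dsv <- svd(Xc, nu = 0, nv = 0)$d
  if (dsv[3] < max(dsv[1], 1) * 1e-9)
    stop("coplanar landmark configuration: 3D warp is not determined")
  P <- cbind(1, X)
  L <- rbind(cbind(D + lambda * diag(n), P),
             cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(Y, matrix(0, 4, 3))
  sol <- solve(L, rhs)
  W <- sol[seq_len(n), , drop = FALSE]
  A <- sol[n + 1:4, , drop = FALSE]
  pts <- asPointMatrix(points)
  cbind(1, pts) %*% A + rowDist(pts, X) %*% W
}

#' Project points onto the nearest point of a mesh surface
#'
#' Exact point-to-triangle projection over all faces of the mesh, returning
#' the nearest surface point for each query as a face index plus barycentric
#' coordinates.
#'
#' @param points (n x 3) matrix of query points
#' @param mesh target [SurfaceMesh-class]
#' @return a [Correspondence-class]
#' @export
projectToSurface <- function(points, mesh) {
  stopifnot(is(mesh, "SurfaceMesh"))
  if (nrow(mesh@faces) == 0) stop("cannot project onto an empty mesh")
  pts <- asPointMatrix(points)
  res <- .closestPointOnMesh(pts, mesh@vertices, mesh@faces)
  bary <- pmax(res$bary, 0)
  bary <- bary / rowSums(bary)
  new("Correspondence", faceIndex = as.integer(res$face), bary = bary,
      positions = res$points)
}

#' Dense point correspondence from a base mesh onto a subject surface
#'
#' The landmark-guided two-step mapping: TPS-warp the base-mesh vertices by
#' the base-to-subject landmark displacement, then project each warped point
#' onto the nearest point of the subject surface. Both meshes are expected
#' in the common aligned frame.
#'
#' @param baseMesh,baseLandmarks the base (or average) mesh and its landmarks
#' @param subjectMesh,subjectLandmarks the target subject surface
#' @param lambda TPS regularization (default 0)
#' @param refine number of optional relaxation passes (neighbourhood
#'   smoothing followed by re-projection); 0 (default) keeps the mapping
#'   deterministic two-step
#' @return a [Correspondence-class] with one target per base vertex
#' @export
denseCorrespondence <- function(baseMesh, baseLandmarks, subjectMesh,
                                subjectLandmarks, lambda = 0, refine = 0) {
  warped <- tpsWarp(baseLandmarks, subjectLandmarks, vertices(baseMesh),
                    lambda = lambda)
  corr <- projectToSurface(warped, subjectMesh)
  if (refine > 0) {
    nb <- .neighborList(baseMesh)
    for (i in seq_len(refine)) {
      pos <- positions(corr)
      smoothed <- 0.5 * pos + 0.5 * t(vapply(nb, function(j) {
        colMeans(pos[j, , drop = FALSE])
      }, numeric(3)))
      corr <- projectToSurface(smoothed, subjectMesh)
    }
  }
  corr
}

.neighborList <- function(mesh) {
  g <- meshAdjacency(mesh)
  lapply(igraph::adjacent_vertices(g, igraph::V(g)), as.integer)
}

#' Barycentric-interpolated unit normals at correspondence targets
#'
#' Vertex normals of the target mesh interpolated with the correspondence's
#' barycentric weights and renormalized.
#'
#' @param mesh the target [SurfaceMesh-class]
#' @param corr a [Correspondence-class] onto `mesh`
#' @return (n x 3) matrix of unit normals
#' @export
interpolateNormals <- function(mesh, corr) {
  stopifnot(is(mesh, "SurfaceMesh"), is(corr, "Correspondence"))
  f <- mesh@faces[corr@faceIndex, , drop = FALSE]
  N <- mesh@normals
  raw <- corr@bary[, 1] * N[f[, 1], , drop = FALSE] +
         corr@bary[, 2] * N[f[, 2], , drop = FALSE] +
         corr@bary[, 3] * N[f[, 3], , drop = FALSE]
  normalizeRows(raw, "interpolated normal")
}

#' Cohort average mesh from dense correspondences
#'
#' Vertex-wise arithmetic mean of the corresponding positions across the
#' cohort; faces are inherited from the base mesh and normals recomputed.
#'
#' @param baseMesh the base [SurfaceMesh-class] the correspondences index
#' @param correspondences list of [Correspondence-class], one per subject,
#'   each with one target per base vertex
#' @param provenance optional character vector of subject ids
#' @return an [AverageMesh-class]
#' @export
computeAverageMesh <- function(baseMesh, correspondences,
                               provenance = character()) {
  stopifnot(is(baseMesh, "SurfaceMesh"))
  if (length(correspondences) < 2)
    stop("at least 2 correspondences required to average")
  np <- nrow(baseMesh@vertices)
  ok <- vapply(correspondences,
               function(cr) nrow(positions(cr)) == np, logical(1))
  if (!all(ok)) stop("correspondence point counts do not match the base mesh")
  avg <- Reduce(`+`, lapply(correspondences, positions)) /
    length(correspondences)
  m <- SurfaceMesh(avg, baseMesh@faces)
  new("AverageMesh", vertices = m@vertices, faces = m@faces,
      normals = m@normals, provenance = as.character(provenance))
}

#' Write a correspondence as a columnar table
#'
#' Columns `base_index, face_index, b0, b1, b2, x, y, z`.
#'
#' @param corr a [Correspondence-class]
#' @param path output TSV path
#' @return invisibly, `path`
#' @export
writeCorrespondence <- function(corr, path) {
  stopifnot(is(corr, "Correspondence"))
  df <- data.frame(base_index = seq_along(corr@faceIndex),
                   face_index = corr@faceIndex,
                   b0 = corr@bary[, 1], b1 = corr@bary[, 2],
                   b2 = corr@bary[, 3],
                   x = corr@positions[, 1], y = corr@positions[, 2],
                   z = corr@positions[, 3])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a correspondence written by [writeCorrespondence()]
#'
#' @param path TSV path
#' @return a [Correspondence-class]
#' @export
readCorrespondence <- function(path) {
  df <- utils::read.delim(path)
  new("Correspondence", faceIndex = as.integer(df$face_index),
      bary = as.matrix(df[, c("b0", "b1", "b2")]),
      positions = as.matrix(df[, c("x", "y", "z")]))
}
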