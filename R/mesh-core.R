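#' Construct a SurfaceMesh
#'
#' @param vertices numeric matrix (n x 3) of vertex positions in mm.
#' @param faces integer matrix (m x 3) of 1-based vertex indices. Winding is
#'   assumed consistent with outward normals.
#' @param normals optional (n x 3) matrix of unit vertex normals; computed
#'   from the faces (area-weighted) when `NULL`.
#' @return a [SurfaceMesh-class]
#' @examples
#' sq <- SurfaceMesh(rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0)),
#'                   rbind(c(1,2,3), c(1,3,4)))
#' normals(sq)
#' @export
SurfaceMesh <- function(vertices, faces, normals = NULL) {
  vertices <- asPointMatrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (is.null(normals)) normals <- computeVertexNormals(vertices, faces)
  storage.mode(normals) <- "double"
  dimnames(vertices) <- dimnames(faces) <- dimnames(normals) <- NULL
  new("SurfaceMesh", vertices = vertices, faces = faces, normals = normals)
}

# Area-weighted vertex normals: unnormalized face cross products (magnitude
# 2*area) accumulated at incident vertices, then normalized. Orientation
# follows face winding.
computeVertexNormals <- function(V, F) {
  if (nrow(F) == 0) stop("mesh has no faces")
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  idx <- c(F[, 1], F[, 2], F[, 3])
  acc <- rowsum(rbind(fn, fn, fn), group = idx)
  present <- as.integer(rownames(acc))
  if (length(present) != nrow(V))
    stop("isolated vertex: every vertex must belong to at least one face")
  N <- matrix(0, nrow(V), 3)
  N[present, ] <- acc
  normalizeRows(N, "vertex normal")
}

#' Per-vertex outward unit normals
#'
#' Recomputes area-weighted vertex normals from the face winding.
#'
#' @param mesh a [SurfaceMesh-class]
#' @return an (n x 3) matrix of unit normals
#' @export
vertexNormals <- function(mesh) {
  stopifnot(is(mesh, "SurfaceMesh"))
  computeVertexNormals(mesh@vertices, mesh@faces)
}

#' Least-squares rigid landmark alignment (Procrustes fit without scaling)
#'
#' Finds the rotation and translation minimizing the sum of squared distances
#' between the subject landmarks and the reference landmarks (Kabsch
#' algorithm). Scaling is deliberately excluded: asymmetry magnitudes are
#' physical distances in mm.
#'
#' @param landmarks subject [LandmarkSet-class] (or named point matrix)
#' @param referenceLandmarks reference landmarks with the same names
#' @return an [AlignmentFrame-class]; `applyFrame(frame, landmarks)` best
#'   superimposes the subject onto the reference
#' @export
landmarkRigidAlign <- function(landmarks, referenceLandmarks) {
  X <- asPointMatrix(landmarks)
  Y <- asPointMatrix(referenceLandmarks)
  if (is.null(rownames(X)) || is.null(rownames(Y)))
    stop("landmarks must be named")
  common <- intersect(rownames(X), rownames(Y))
  if (!setequal(rownames(X), rownames(Y)))
    stop("landmark names differ between subject and reference")
  if (length(common) < 3) stop("at least 3 landmarks required")
  X <- X[common, , drop = FALSE]
  Y <- Y[common, , drop = FALSE]
  xbar <- colMeans(X); ybar <- colMeans(Y)
  Xc <- sweep(X, 2, xbar); Yc <- sweep(Y, 2, ybar)
  sv <- svd(crossprod(Xc, Yc))  # H = Xc' Yc
  if (sv$d[2] < max(sv$d[1], 1) * 1e-10)
    stop("collinear landmark configuration: rotation is not determined")
  s <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, s)) %*% t(sv$u)
  t <- as.numeric(ybar - R %*% xbar)
  resid <- sweep(tcrossprod(X, R), 2, t, "+") - Y
  new("AlignmentFrame", rotation = R, translation = t,
      rmsd = sqrt(mean(rowSums(resid^2))))
}

#' @rdname applyFrame
#' @export
setMethod("applyFrame", signature("AlignmentFrame", "matrix"),
  function(frame, x) {
    sweep(tcrossprod(x, frame@rotation), 2, frame@translation, "+")
  })

#' @rdname applyFrame
#' @export
setMethod("applyFrame", signature("AlignmentFrame", "SurfaceMesh"),
  function(frame, x) {
    v <- sweep(tcrossprod(x@vertices, frame@rotation), 2, frame@translation, "+")
    SurfaceMesh(v, x@faces, normals = tcrossprod(x@normals, frame@rotation))
  })

#' @rdname applyFrame
#' @export
setMethod("applyFrame", signature("AlignmentFrame", "LandmarkSet"),
  function(frame, x) {
    p <- sweep(tcrossprod(x@points, frame@rotation), 2, frame@translation, "+")
    rownames(p) <- rownames(x@points)
    new("LandmarkSet", points = p, pairs = x@pairs, midline = x@midline)
  })

#' Mirror a mesh and its landmarks across the midsagittal plane
#'
#' Reflects the aligned mesh about x = 0 (vertex (x, y, z) becomes
#' (-x, y, z)), reverses face winding so normals stay outward, and relabels
#' the landmarks left/right per the pairing table. Applying the operation
#' twice returns the original objects bit-exactly.
#'
#' @param mesh an aligned [SurfaceMesh-class] (midline at x = 0)
#' @param landmarks the subject's [LandmarkSet-class]
#' @return `list(mesh = , landmarks = )` with the mirrored pair
#' @export
mirrorMesh <- function(mesh, landmarks) {
  stopifnot(is(mesh, "SurfaceMesh"), is(landmarks, "LandmarkSet"))
  v <- mesh@vertices; v[, 1] <- -v[, 1]
  n <- mesh@normals;  n[, 1] <- -n[, 1]
  f <- mesh@faces[, c(1L, 3L, 2L), drop = FALSE]
  m <- new("SurfaceMesh", vertices = v, faces = f, normals = n)

  p <- landmarks@points
  p[, 1] <- -p[, 1]
  pr <- landmarks@pairs
  if (nrow(pr)) {
    missing <- setdiff(as.vector(pr), rownames(p))
    if (length(missing)) stop("paired landmark missing from points: ",
                              paste(missing, collapse = ", "))
    nm <- rownames(p)
    swap <- nm
    swap[match(pr[, 1], nm)] <- pr[, 2]
    swap[match(pr[, 2], nm)] <- pr[, 1]
    rownames(p) <- swap
    p <- p[nm, , drop = FALSE]  # keep original row order
  }
  lm <- new("LandmarkSet", points = p, pairs = landmarks@pairs,
            midline = landmarks@midline)
  list(mesh = m, landmarks = lm)
}

#' Crop a mesh to the region below the eyes
#'
#' Keeps vertices at or below the mean height (y) of the left and right
#' endocanthion landmarks; faces touching a removed vertex are dropped.
#'
#' @param mesh aligned [SurfaceMesh-class] (+y superior)
#' @param landmarks [LandmarkSet-class] containing both endocanthions
#' @param leftName,rightName endocanthion landmark names
#' @param minVertices minimum number of retained vertices before the crop is
#'   considered degenerate
#' @return `list(mesh = cropped SurfaceMesh, keptIndices = old indices of the
#'   retained vertices (new -> old), indexMap = old -> new index vector with
#'   NA for dropped vertices)`
#' @export
cropBelowEyes <- function(mesh, landmarks,
                          leftName = "endocanthion_l",
                          rightName = "endocanthion_r",
                          minVertices = 100) {
  stopifnot(is(mesh, "SurfaceMesh"), is(landmarks, "LandmarkSet"))
  p <- landmarks@points
  if (!all(c(leftName, rightName) %in% rownames(p)))
    stop("both endocanthion landmarks are required for the crop")
  threshold <- mean(p[c(leftName, rightName), 2])
  keep <- which(mesh@vertices[, 2] <= threshold)
  if (length(keep) < minVertices)
    stop("crop leaves fewer than ", minVertices,
         " vertices: degenerate face region")
  indexMap <- rep(NA_integer_, nrow(mesh@vertices))
  indexMap[keep] <- seq_along(keep)
  f <- mesh@faces
  fk <- f[!is.na(indexMap[f[, 1]]) & !is.na(indexMap[f[, 2]]) &
          !is.na(indexMap[f[, 3]]), , drop = FALSE]
  fk[] <- indexMap[fk]
  cropped <- new("SurfaceMesh",
                 vertices = mesh@vertices[keep, , drop = FALSE],
                 faces = fk,
                 normals = mesh@normals[keep, , drop = FALSE])
  list(mesh = cropped, keptIndices = keep, indexMap = indexMap)
}

#' Vertex adjacency graph of a mesh
#'
#' Undirected igraph over the mesh's edges; vertex names are the vertex
#' indices. Used for coherent-region extraction and geodesic distances.
#'
#' @param mesh a [SurfaceMesh-class]
#' @param weighted if `TRUE`, edges carry their Euclidean length
#' @return an igraph object with `nVertices(mesh)` vertices
#' @export
meshAdjacency <- function(mesh, weighted = FALSE) {
  f <- mesh@faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(mesh@vertices) - igraph::vcount(g)))
  igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  if (weighted) {
    v <- mesh@vertices
    igraph::E(g)$weight <- rowNorms(v[e[, 1], , drop = FALSE] -
                                    v[e[, 2], , drop = FALSE])
  }
  g
}
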