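#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib facesym, .registration = TRUE
NULL

## ---------------------------------------------------------------------------
## Central S4 data objects: a triangulated facial surface, a named landmark
## set with bilateral pairing, a rigid alignment frame, a dense surface
## correspondence, per-point feature heat maps, the population model of
## normal asymmetry, and the spatially augmented histogram.
## ---------------------------------------------------------------------------

.checkMatrix3 <- function(x, what) {
  if (!is.matrix(x) || ncol(x) != 3 || !is.numeric(x))
    return(sprintf("%s must be a numeric matrix with 3 columns", what))
  if (anyNA(x)) return(sprintf("%s contains missing values", what))
  NULL
}

#' SurfaceMesh: a triangulated 2-manifold surface
#'
#' Vertices are 3D points in millimetres, faces are vertex-index triples
#' (1-based), and normals are outward per-vertex unit vectors. Validity
#' enforces index bounds, triangle-only 2-manifoldness (every edge shared by
#' at most two faces) and unit normals.
#'
#' @slot vertices numeric matrix (n x 3), mm
#' @slot faces integer matrix (m x 3) of vertex indices
#' @slot normals numeric matrix (n x 3) of per-vertex unit normals
#' @exportClass SurfaceMesh
setClass("SurfaceMesh",
  slots = c(vertices = "matrix", faces = "matrix", normals = "matrix"),
  validity = function(object) {
    v <- object@vertices; f <- object@faces; n <- object@normals
    msg <- c(.checkMatrix3(v, "vertices"), .checkMatrix3(n, "normals"))
    if (!is.null(msg)) return(msg[1])
    if (!is.matrix(f) || ncol(f) != 3) return("faces must be a 3-column matrix")
    if (nrow(n) != nrow(v)) return("one normal per vertex required")
    if (nrow(f) > 0) {
      if (min(f) < 1 || max(f) > nrow(v)) return("face index out of range")
      if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
        return("degenerate face (repeated vertex index)")
      ## each undirected edge may appear in at most two faces
      e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
      key <- pmin(e[, 1], e[, 2]) * (nrow(v) + 1) + pmax(e[, 1], e[, 2])
      if (max(tabulate(match(key, unique(key)))) > 2)
        return("mesh is not 2-manifold: an edge is shared by more than two faces")
    }
    len <- sqrt(rowSums(n^2))
    if (nrow(n) > 0 && max(abs(len - 1)) > 1e-8)
      return("normals must have unit length")
    TRUE
  })

#' AverageMesh: cohort-average surface
#'
#' A [SurfaceMesh] whose vertices are per-point arithmetic means of a
#' cohort's corresponding positions; `provenance` records the subject ids
#' that were averaged.
#'
#' @slot provenance character vector of subject ids
#' @exportClass AverageMesh
setClass("AverageMesh", contains = "SurfaceMesh",
  slots = c(provenance = "character"))

#' LandmarkSet: named anatomical landmarks with bilateral pairing
#'
#' @slot points numeric matrix (k x 3) with landmark names as rownames, mm
#' @slot pairs character matrix (p x 2), columns `left`, `right`
#' @slot midline character vector of unpaired midline landmark names
#' @exportClass LandmarkSet
setClass("LandmarkSet",
  slots = c(points = "matrix", pairs = "matrix", midline = "character"),
  validity = function(object) {
    p <- object@points
    msg <- .checkMatrix3(p, "points")
    if (!is.null(msg)) return(msg)
    if (is.null(rownames(p)) || anyDuplicated(rownames(p)))
      return("points must have unique rownames")
    pr <- object@pairs
    if (!is.character(pr) || (length(pr) && ncol(pr) != 2))
      return("pairs must be a 2-column character matrix")
    paired <- as.vector(pr)
    if (anyDuplicated(paired)) return("a landmark appears in more than one pair")
    if (length(intersect(paired, object@midline)))
      return("paired and midline landmark names must be disjoint")
    missing <- setdiff(c(paired, object@midline), rownames(p))
    if (length(missing))
      return(paste("landmark(s) not present in points:", paste(missing, collapse = ", ")))
    TRUE
  })

#' AlignmentFrame: rigid motion into the common face frame
#'
#' Applying the frame maps points `x` to `R x + t`. The aligned convention
#' is: midsagittal plane at x = 0, +y superior, +z anterior.
#'
#' @slot rotation 3 x 3 orthonormal matrix, det +1
#' @slot translation length-3 numeric, mm
#' @slot rmsd root-mean-square landmark residual after alignment, mm
#' @exportClass AlignmentFrame
setClass("AlignmentFrame",
  slots = c(rotation = "matrix", translation = "numeric", rmsd = "numeric"),
  validity = function(object) {
    R <- object@rotation
    if (!all(dim(R) == c(3, 3))) return("rotation must be 3x3")
    if (max(abs(crossprod(R) - diag(3))) > 1e-9)
      return("rotation is not orthonormal")
    if (abs(det(R) - 1) > 1e-9) return("rotation must have determinant +1")
    if (length(object@translation) != 3) return("translation must have length 3")
    TRUE
  })

#' Correspondence: dense mapping from base-mesh points onto a subject surface
#'
#' For each base point, the target is a subject face plus barycentric
#' coordinates; `positions` caches the resulting 3D points.
#'
#' @slot faceIndex integer vector of subject face indices
#' @slot bary numeric matrix (n x 3), non-negative, rows sum to 1
#' @slot positions numeric matrix (n x 3), points on the subject surface, mm
#' @exportClass Correspondence
setClass("Correspondence",
  slots = c(faceIndex = "integer", bary = "matrix", positions = "matrix"),
  validity = function(object) {
    n <- length(object@faceIndex)
    if (nrow(object@bary) != n || nrow(object@positions) != n)
      return("faceIndex, bary and positions must agree in length")
    if (n && min(object@bary) < -1e-9) return("negative barycentric coordinate")
    if (n && max(abs(rowSums(object@bary) - 1)) > 1e-9)
      return("barycentric coordinates must sum to 1")
    TRUE
  })

.featureNames <- c("surface_orientation_angle", "deformation_angle",
                   "deformation_magnitude")

#' FeatureHeatMap: one scalar per scored mesh point for one subject
#'
#' Angles are in degrees (range 0-180), magnitudes in mm (non-negative).
#'
#' @slot feature one of `surface_orientation_angle`, `deformation_angle`,
#'   `deformation_magnitude`
#' @slot values numeric vector, one value per scored point
#' @slot subjectId character scalar
#' @exportClass FeatureHeatMap
setClass("FeatureHeatMap",
  slots = c(feature = "character", values = "numeric", subjectId = "character"),
  validity = function(object) {
    if (!object@feature %in% .featureNames)
      return(paste("unknown feature:", object@feature))
    v <- object@values
    if (anyNA(v) || any(!is.finite(v))) return("values must be finite")
    if (grepl("angle", object@feature)) {
      if (length(v) && (min(v) < -1e-9 || max(v) > 180 + 1e-9))
        return("angles must lie in [0, 180] degrees")
    } else if (length(v) && min(v) < -1e-12) {
      return("magnitudes must be non-negative")
    }
    TRUE
  })

#' NormalAsymmetryModel: per-point mean/SD of a feature over a cohort
#'
#' @slot mesh the (cropped) average mesh the model lives on
#' @slot feature feature name
#' @slot mu per-point cohort mean
#' @slot sigma per-point cohort sample SD, floored at a small positive value
#' @slot n integer cohort size
#' @exportClass NormalAsymmetryModel
setClass("NormalAsymmetryModel",
  slots = c(mesh = "SurfaceMesh", feature = "character", mu = "numeric",
            sigma = "numeric", n = "integer"),
  validity = function(object) {
    np <- nrow(object@mesh@vertices)
    if (length(object@mu) != np || length(object@sigma) != np)
      return("mu and sigma must have one value per mesh vertex")
    if (length(object@sigma) && min(object@sigma) <= 0)
      return("sigma must be strictly positive (floored)")
    if (object@n < 2) return("model requires a cohort of at least 2")
    TRUE
  })

#' AugmentedHistogram: feature histogram with per-bin coherent mesh regions
#'
#' Bin `b` carries its point count `counts[b]`, the list of coherent
#' connected regions (point-index vectors, each of size >= tau) and the
#' pooled incoherent points of the bin.
#'
#' @slot edges numeric vector of B+1 bin edges
#' @slot counts integer vector of B bin counts
#' @slot regions list of B lists of integer vectors
#' @slot incoherent list of B integer vectors
#' @slot tau numeric coherence threshold (minimum region size)
#' @exportClass AugmentedHistogram
setClass("AugmentedHistogram",
  slots = c(edges = "numeric", counts = "integer", regions = "list",
            incoherent = "list", tau = "numeric"),
  validity = function(object) {
    B <- length(object@edges) - 1L
    if (length(object@counts) != B || length(object@regions) != B ||
        length(object@incoherent) != B)
      return("counts, regions and incoherent must have one entry per bin")
    for (b in seq_len(B)) {
      reg <- object@regions[[b]]
      sizes <- vapply(reg, length, integer(1))
      if (length(sizes) && min(sizes) < object@tau)
        return("a coherent region is smaller than tau")
      pts <- c(unlist(reg, use.names = FALSE), object@incoherent[[b]])
      if (length(pts) != object@counts[b] || anyDuplicated(pts))
        return("bin membership must partition into disjoint regions + incoherent")
    }
    TRUE
  })

#' ScoreResult: a subject's asymmetry score against the normal model
#'
#' @slot subjectId character scalar
#' @slot feature feature name
#' @slot score non-negative symmetric spatiogram distance to the model mean
#' @slot psiSubject per-bin spatial weights of the subject-side directed term
#' @slot psiReference per-bin spatial weights of the model-side directed term
#' @exportClass ScoreResult
setClass("ScoreResult",
  slots = c(subjectId = "character", feature = "character", score = "numeric",
            psiSubject = "numeric", psiReference = "numeric"),
  validity = function(object) {
    if (length(object@score) != 1 || object@score < 0)
      return("score must be a single non-negative number")
    TRUE
  })
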