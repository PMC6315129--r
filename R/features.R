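#' Asymmetry flow field
#'
#' Per average-mesh point, the 3D displacement from the corresponding point
#' on the original subject surface to the corresponding point on its
#' mirrored copy. This vector field is the raw signal all local asymmetry
#' features derive from; it vanishes for an exactly mirror-symmetric face.
#'
#' @param corrOriginal [Correspondence-class] of the average mesh onto the
#'   original subject surface
#' @param corrMirror [Correspondence-class] onto the mirrored surface
#' @return (n x 3) numeric matrix of flow vectors in mm
#' @export
asymmetryFlow <- function(corrOriginal, corrMirror) {
  po <- positions(corrOriginal)
  pm <- positions(corrMirror)
  if (nrow(po) != nrow(pm))
    stop("original and mirror correspondences map different point counts")
  pm - po
}

#' Angle of surface orientation
#'
#' Angle (degrees) between the surface normals at corresponding points of
#' the original and mirrored surfaces; a magnitude-independent measure of
#' local orientation asymmetry.
#'
#' @param normalsOriginal,normalsMirror (n x 3) matrices of unit normals
#'   sampled at corresponding points
#' @param subjectId subject identifier carried in the heat map
#' @return a [FeatureHeatMap-class] with values in `[0, 180]` degrees
#' @export
surfaceOrientationAngle <- function(normalsOriginal, normalsMirror,
                                    subjectId = "") {
  n1 <- normalizeRows(asPointMatrix(normalsOriginal), "normal")
  n2 <- normalizeRows(asPointMatrix(normalsMirror), "normal")
  if (nrow(n1) != nrow(n2)) stop("normal matrices differ in length")
  theta <- acos(clampUnit(rowSums(n1 * n2))) * 180 / pi
  new("FeatureHeatMap", feature = "surface_orientation_angle",
      values = theta, subjectId = as.character(subjectId))
}

#' Angle of deformation
#'
#' Angle (degrees) between the asymmetry flow vector and the surface normal
#' on the original surface: the direction of the mirror transformation.
#' Where the flow magnitude is below `epsFlow` the point is treated as
#' symmetric and the angle is 0 (a symmetric point contributes no
#' asymmetry, rather than an undefined direction).
#'
#' @param flow (n x 3) flow matrix from [asymmetryFlow()]
#' @param normalsOriginal (n x 3) unit normals on the original surface
#' @param epsFlow degenerate-flow threshold in mm (default 1e-6)
#' @param subjectId subject identifier
#' @return a [FeatureHeatMap-class] with values in `[0, 180]` degrees
#' @export
deformationAngle <- function(flow, normalsOriginal, epsFlow = 1e-6,
                             subjectId = "") {
  v <- asPointMatrix(flow)
  n <- normalizeRows(asPointMatrix(normalsOriginal), "normal")
  if (nrow(v) != nrow(n)) stop("flow and normals differ in length")
  mag <- rowNorms(v)
  phi <- numeric(nrow(v))
  live <- mag >= epsFlow
  phi[live] <- acos(clampUnit(rowSums(v[live, , drop = FALSE] *
                                      n[live, , drop = FALSE]) /
                              mag[live])) * 180 / pi
  new("FeatureHeatMap", feature = "deformation_angle", values = phi,
      subjectId = as.character(subjectId))
}

#' Deformation magnitude
#'
#' Euclidean length (mm) of the asymmetry flow vector at each point.
#'
#' @param flow (n x 3) flow matrix from [asymmetryFlow()]
#' @param subjectId subject identifier
#' @return a [FeatureHeatMap-class] with non-negative values in mm
#' @export
deformationMagnitude <- function(flow, subjectId = "") {
  new("FeatureHeatMap", feature = "deformation_magnitude",
      values = rowNorms(asPointMatrix(flow)),
      subjectId = as.character(subjectId))
}

#' Population model of normal asymmetry
#'
#' Per-point sample mean and sample standard deviation (denominator n - 1)
#' of one feature across the cohort's heat maps. The SD is floored at
#' `epsSD` so downstream standardized errors stay finite; the floor is only
#' reached where the cohort is (numerically) constant at a point.
#'
#' @param heatMaps list of [FeatureHeatMap-class] objects of the same
#'   feature with identical point counts (>= 2 subjects)
#' @param mesh the (cropped) average [SurfaceMesh-class] the maps live on
#' @param epsSD positive SD floor (default 1e-6)
#' @return a [NormalAsymmetryModel-class]
#' @export
buildNormalModel <- function(heatMaps, mesh, epsSD = 1e-6) {
  if (length(heatMaps) < 2)
    stop("standard deviation undefined: at least 2 subjects required")
  feats <- unique(vapply(heatMaps, featureName, ""))
  if (length(feats) != 1)
    stop("heat maps mix features: ", paste(feats, collapse = ", "))
  M <- do.call(rbind, lapply(heatMaps, featureValues))
  if (ncol(M) != nrow(mesh@vertices))
    stop("heat map point count does not match the model mesh")
  S <- nrow(M)
  mu <- colMeans(M)
  ss <- colSums(M^2) - S * mu^2
  sigma <- sqrt(pmax(ss, 0) / (S - 1))
  new("NormalAsymmetryModel", mesh = mesh, feature = feats,
      mu = mu, sigma = pmax(sigma, epsSD), n = as.integer(S))
}
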