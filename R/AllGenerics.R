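#' @rdname SurfaceMesh-class
#' @param x,object a facesym S4 object
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))

#' @rdname SurfaceMesh-class
#' @export
setGeneric("faces", function(x) standardGeneric("faces"))

#' @rdname SurfaceMesh-class
#' @export
setGeneric("normals", function(x) standardGeneric("normals"))

#' @rdname SurfaceMesh-class
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' @rdname LandmarkSet-class
#' @export
setGeneric("landmarkPoints", function(x) standardGeneric("landmarkPoints"))

#' @rdname LandmarkSet-class
#' @export
setGeneric("landmarkPairs", function(x) standardGeneric("landmarkPairs"))

#' @rdname LandmarkSet-class
#' @export
setGeneric("midlineNames", function(x) standardGeneric("midlineNames"))

#' @rdname Correspondence-class
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' Apply a rigid alignment frame
#'
#' Maps points `x` to `R x + t`. For meshes, normals are rotated; for
#' landmark sets, all points are moved.
#'
#' @param frame an [AlignmentFrame-class]
#' @param x a point matrix, [SurfaceMesh-class] or [LandmarkSet-class]
#' @return an object of the same kind as `x`
#' @export
setGeneric("applyFrame", function(frame, x) standardGeneric("applyFrame"))

#' @rdname FeatureHeatMap-class
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname FeatureHeatMap-class
#' @export
setGeneric("featureName", function(x) standardGeneric("featureName"))

#' @rdname FeatureHeatMap-class
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname NormalAsymmetryModel-class
#' @export
setGeneric("modelMean", function(x) standardGeneric("modelMean"))

#' @rdname NormalAsymmetryModel-class
#' @export
setGeneric("modelSD", function(x) standardGeneric("modelSD"))

#' @rdname NormalAsymmetryModel-class
#' @export
setGeneric("modelMesh", function(x) standardGeneric("modelMesh"))

#' @rdname AugmentedHistogram-class
#' @export
setGeneric("binEdges", function(x) standardGeneric("binEdges"))

#' @rdname AugmentedHistogram-class
#' @export
setGeneric("binCounts", function(x) standardGeneric("binCounts"))

#' @rdname AugmentedHistogram-class
#' @export
setGeneric("binRegions", function(x) standardGeneric("binRegions"))

#' @rdname AugmentedHistogram-class
#' @export
setGeneric("incoherentPoints", function(x) standardGeneric("incoherentPoints"))

#' @rdname ScoreResult-class
#' @export
setGeneric("scoreValue", function(x) standardGeneric("scoreValue"))
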