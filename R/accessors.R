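## Accessors and show methods.

#' @rdname SurfaceMesh-class
#' @export
setMethod("vertices", "SurfaceMesh", function(x) x@vertices)

#' @rdname SurfaceMesh-class
#' @export
setMethod("faces", "SurfaceMesh", function(x) x@faces)

#' @rdname SurfaceMesh-class
#' @export
setMethod("normals", "SurfaceMesh", function(x) x@normals)

#' @rdname SurfaceMesh-class
#' @export
setMethod("nVertices", "SurfaceMesh", function(x) nrow(x@vertices))

#' @rdname LandmarkSet-class
#' @export
setMethod("landmarkPoints", "LandmarkSet", function(x) x@points)

#' @rdname LandmarkSet-class
#' @export
setMethod("landmarkPairs", "LandmarkSet", function(x) x@pairs)

#' @rdname LandmarkSet-class
#' @export
setMethod("midlineNames", "LandmarkSet", function(x) x@midline)

#' @rdname Correspondence-class
#' @export
setMethod("positions", "Correspondence", function(x) x@positions)

#' @rdname FeatureHeatMap-class
#' @export
setMethod("featureValues", "FeatureHeatMap", function(x) x@values)

#' @rdname FeatureHeatMap-class
#' @export
setMethod("featureName", "FeatureHeatMap", function(x) x@feature)

#' @rdname FeatureHeatMap-class
#' @export
setMethod("subjectId", "FeatureHeatMap", function(x) x@subjectId)

#' @rdname NormalAsymmetryModel-class
#' @export
setMethod("modelMean", "NormalAsymmetryModel", function(x) x@mu)

#' @rdname NormalAsymmetryModel-class
#' @export
setMethod("modelSD", "NormalAsymmetryModel", function(x) x@sigma)

#' @rdname NormalAsymmetryModel-class
#' @export
setMethod("modelMesh", "NormalAsymmetryModel", function(x) x@mesh)

#' @rdname AugmentedHistogram-class
#' @export
setMethod("binEdges", "AugmentedHistogram", function(x) x@edges)

#' @rdname AugmentedHistogram-class
#' @export
setMethod("binCounts", "AugmentedHistogram", function(x) x@counts)

#' @rdname AugmentedHistogram-class
#' @export
setMethod("binRegions", "AugmentedHistogram", function(x) x@regions)

#' @rdname AugmentedHistogram-class
#' @export
setMethod("incoherentPoints", "AugmentedHistogram", function(x) x@incoherent)

#' @rdname ScoreResult-class
#' @export
setMethod("scoreValue", "ScoreResult", function(x) x@score)

setMethod("show", "SurfaceMesh", function(object) {
  cat(class(object), "with", nrow(object@vertices), "vertices and",
      nrow(object@faces), "faces\n")
  if (is(object, "AverageMesh") && length(object@provenance))
    cat("  averaged over", length(object@provenance), "subjects\n")
})

setMethod("show", "LandmarkSet", function(object) {
  cat("LandmarkSet with", nrow(object@points), "landmarks:",
      nrow(object@pairs), "bilateral pairs,", length(object@midline),
      "midline\n")
})

setMethod("show", "AlignmentFrame", function(object) {
  cat("AlignmentFrame (rigid), landmark RMSD",
      format(object@rmsd, digits = 4), "mm\n")
})

setMethod("show", "Correspondence", function(object) {
  cat("Correspondence for", length(object@faceIndex), "base points\n")
})

setMethod("show", "FeatureHeatMap", function(object) {
  unit <- if (grepl("angle", object@feature)) "deg" else "mm"
  cat("FeatureHeatMap", sQuote(object@feature), "for subject",
      sQuote(object@subjectId), "\n  ", length(object@values), " points, ",
      "range [", format(min(object@values), digits = 4), ", ",
      format(max(object@values), digits = 4), "] ", unit, "\n", sep = "")
})

setMethod("show", "NormalAsymmetryModel", function(object) {
  cat("NormalAsymmetryModel for", sQuote(object@feature), "\n  cohort n =",
      object@n, "on", nrow(object@mesh@vertices), "points\n")
})

setMethod("show", "AugmentedHistogram", function(object) {
  nreg <- sum(vapply(object@regions, length, integer(1)))
  cat("AugmentedHistogram:", length(object@counts), "bins,",
      sum(object@counts), "points,", nreg, "coherent regions (tau =",
      object@tau, ")\n")
})

setMethod("show", "ScoreResult", function(object) {
  cat("ScoreResult:", sQuote(object@subjectId), object@feature, "=",
      format(object@score, digits = 6), "\n")
})
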