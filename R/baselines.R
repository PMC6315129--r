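#' Mean-deformation-magnitude baseline score
#'
#' The classical surface-registration asymmetry summary: the arithmetic
#' mean of the per-point deformation magnitudes over the scored (cropped)
#' region, in mm.
#'
#' @param magnitudeMap a `deformation_magnitude` [FeatureHeatMap-class] or
#'   numeric vector of per-point magnitudes
#' @return a one-row data.frame with columns `subject_id`, `method`,
#'   `value`
#' @export
meanMagnitudeScore <- function(magnitudeMap) {
  id <- ""
  if (is(magnitudeMap, "FeatureHeatMap")) {
    if (featureName(magnitudeMap) != "deformation_magnitude")
      stop("expected a deformation_magnitude heat map")
    id <- subjectId(magnitudeMap)
    magnitudeMap <- featureValues(magnitudeMap)
  }
  if (!length(magnitudeMap)) stop("empty magnitude map")
  data.frame(subject_id = id, method = "mean_magnitude",
             value = mean(magnitudeMap), stringsAsFactors = FALSE)
}

#' Landmark-based Procrustes asymmetry baseline
#'
#' The traditional sparse phenotype: mirror the bilaterally paired
#' landmarks across the midsagittal plane (with left/right relabeling),
#' rigidly align the mirrored configuration back onto the original by
#' least squares, and average the residual distances between each original
#' landmark and its relabeled mirrored counterpart. Zero for a perfectly
#' bilaterally symmetric configuration and invariant to rigid motion of
#' the whole set.
#'
#' @param landmarks a [LandmarkSet-class]
#' @param pairs optional two-column character matrix of (left, right) pairs
#'   to use; defaults to the set's own pairing table
#' @param subjectId subject identifier for the output row
#' @param allowScaling if `TRUE` a similarity (scaled) fit is used instead
#'   of the rigid default
#' @return a one-row data.frame with columns `subject_id`, `method`,
#'   `value` (mm)
#' @export
landmarkProcrustesScore <- function(landmarks, pairs = NULL, subjectId = "",
                                    allowScaling = FALSE) {
  stopifnot(is(landmarks, "LandmarkSet"))
  if (is.null(pairs)) pairs <- landmarks@pairs
  pairs <- as.matrix(pairs)
  if (nrow(pairs) < 2)
    stop("at least 2 bilateral pairs (>= 3 landmarks) required")
  nm <- as.vector(pairs)
  missing <- setdiff(nm, rownames(landmarks@points))
  if (length(missing))
    stop("unpaired landmark referenced: ", paste(missing, collapse = ", "))
  X <- landmarks@points[nm, , drop = FALSE]
  ## mirror about x = 0 and relabel left <-> right
  M <- X
  M[, 1] <- -M[, 1]
  rownames(M) <- as.vector(pairs[, 2:1])
  M <- M[nm, , drop = FALSE]
  ## least-squares superimposition of the mirrored set onto the original
  xbar <- colMeans(M); ybar <- colMeans(X)
  Mc <- sweep(M, 2, xbar); Xc <- sweep(X, 2, ybar)
  sv <- svd(crossprod(Mc, Xc))
  s <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, s)) %*% t(sv$u)
  scale <- 1
  if (allowScaling)
    scale <- sum(sv$d * c(1, 1, s)) / sum(Mc^2)
  aligned <- sweep(scale * tcrossprod(Mc, R), 2, ybar, "+")
  data.frame(subject_id = subjectId, method = "landmark_procrustes",
             value = mean(rowNorms(aligned - X)), stringsAsFactors = FALSE)
}
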