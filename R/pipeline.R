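#' Full asymmetry-scoring pipeline for a cohort
#'
#' Runs the complete score-assignment chain: rigid landmark alignment of
#' every subject into the common frame, dense correspondence from the base
#' mesh onto each subject, construction of the cohort average mesh, the
#' below-eyes crop, per-subject asymmetry features sampled through the
#' original and mirrored correspondences, the population model of normal
#' asymmetry, the spatiogram score of every subject against that model,
#' and the two baseline phenotypes.
#'
#' @param meshes list of subject [SurfaceMesh-class] objects
#' @param landmarks list of matching [LandmarkSet-class] objects
#' @param baseMesh,baseLandmarks the base mesh defining the point set; by
#'   default the first subject. Supplying the synthetic template here is
#'   recommended for simulated cohorts
#' @param features subset of the three feature names to compute
#' @param bins number of histogram bins (default 10)
#' @param tau coherence threshold (default 20)
#' @param align rigidly align subjects to the base landmarks first
#'   (disable only if the cohort is already in the common frame)
#' @param iterations average-mesh construction passes (default 1; a second
#'   pass re-maps the cohort onto the first-pass average)
#' @param leaveOneOut score each subject against the model built from the
#'   other subjects (default `TRUE`). At population scale one subject's
#'   contribution to the model is negligible, but in a small cohort a
#'   subject's own asymmetry inflates the model SD at exactly its own
#'   points and standardizes its deviation away; leave-one-out scoring
#'   restores the interpretation of the score as deviation from *normal*
#'   asymmetry. The returned `models` are always the pooled ones.
#' @param variant histogram dissimilarity variant, see [directedDistance()]
#' @param lambda TPS regularization for noisy landmarks (default 0)
#' @return a list with elements `averageMesh`, `croppedMesh`,
#'   `keptIndices`, `heatMaps` (per feature, a subjects x points matrix),
#'   `models` (per feature [NormalAsymmetryModel-class]), `scores`
#'   (data.frame subject_id/feature/score), and `baselines` (data.frame
#'   subject_id/method/value)
#' @export
asymmetryPipeline <- function(meshes, landmarks, baseMesh = NULL,
                              baseLandmarks = NULL,
                              features = c("surface_orientation_angle",
                                           "deformation_angle",
                                           "deformation_magnitude"),
                              bins = 10, tau = 20, align = TRUE,
                              iterations = 1, leaveOneOut = TRUE,
                              variant = c("bhattacharyya", "ratio"),
                              lambda = 0) {
  variant <- match.arg(variant)
  features <- match.arg(features, several.ok = TRUE)
  nS <- length(meshes)
  stopifnot(nS >= 2, length(landmarks) == nS)
  ids <- names(meshes)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(nS))
  if (is.null(baseMesh)) baseMesh <- meshes[[1]]
  if (is.null(baseLandmarks)) baseLandmarks <- landmarks[[1]]

  ## 1. rigid alignment into the base frame
  if (align) {
    for (i in seq_len(nS)) {
      fr <- landmarkRigidAlign(landmarks[[i]], baseLandmarks)
      meshes[[i]] <- applyFrame(fr, meshes[[i]])
      landmarks[[i]] <- applyFrame(fr, landmarks[[i]])
    }
  }

  ## 2. base -> subject correspondences and the cohort average mesh
  avgMesh <- baseMesh
  avgLm <- baseLandmarks
  for (it in seq_len(max(1, iterations))) {
    corrs <- lapply(seq_len(nS), function(i) {
      denseCorrespondence(avgMesh, avgLm, meshes[[i]], landmarks[[i]],
                          lambda = lambda)
    })
    avgMesh <- computeAverageMesh(avgMesh, corrs, provenance = ids)
    lmStack <- Reduce(`+`, lapply(landmarks, landmarkPoints)) / nS
    avgLm <- LandmarkSet(lmStack, pairs = landmarkPairs(baseLandmarks),
                         midline = midlineNames(baseLandmarks))
  }

  ## 3. below-eyes crop of the average mesh; all scoring happens there
  crop <- cropBelowEyes(avgMesh, avgLm)
  scored <- vertices(avgMesh)[crop$keptIndices, , drop = FALSE]
  graph <- meshAdjacency(crop$mesh)

  ## 4. per-subject features through the original and mirrored surfaces
  heatMaps <- lapply(features, function(f) vector("list", nS))
  names(heatMaps) <- features
  magnitudeMaps <- vector("list", nS)
  for (i in seq_len(nS)) {
    mir <- mirrorMesh(meshes[[i]], landmarks[[i]])
    wO <- tpsWarp(avgLm, landmarks[[i]], scored, lambda = lambda)
    wM <- tpsWarp(avgLm, mir$landmarks, scored, lambda = lambda)
    corrO <- projectToSurface(wO, meshes[[i]])
    corrM <- projectToSurface(wM, mir$mesh)
    flow <- asymmetryFlow(corrO, corrM)
    nO <- interpolateNormals(meshes[[i]], corrO)
    nM <- interpolateNormals(mir$mesh, corrM)
    if ("surface_orientation_angle" %in% features)
      heatMaps[["surface_orientation_angle"]][[i]] <-
        surfaceOrientationAngle(nO, nM, subjectId = ids[i])
    if ("deformation_angle" %in% features)
      heatMaps[["deformation_angle"]][[i]] <-
        deformationAngle(flow, nO, subjectId = ids[i])
    mm <- deformationMagnitude(flow, subjectId = ids[i])
    magnitudeMaps[[i]] <- mm
    if ("deformation_magnitude" %in% features)
      heatMaps[["deformation_magnitude"]][[i]] <- mm
  }

  ## 5. normal model + spatiogram score per feature
  models <- list()
  scores <- NULL
  for (f in features) {
    maps <- heatMaps[[f]]
    models[[f]] <- buildNormalModel(maps, crop$mesh)
    edges <- defaultBinEdges(f, maps, bins)
    sc <- vapply(seq_along(maps), function(i) {
      mod <- if (leaveOneOut && nS > 2)
        buildNormalModel(maps[-i], crop$mesh) else models[[f]]
      scoreValue(scoreSubject(maps[[i]], mod, edges = edges, tau = tau,
                              graph = graph, variant = variant))
    }, numeric(1))
    scores <- rbind(scores,
                    data.frame(subject_id = ids, feature = f, score = sc,
                               stringsAsFactors = FALSE))
  }

  ## 6. baseline phenotypes
  baselines <- do.call(rbind, c(
    lapply(seq_len(nS), function(i) {
      b <- meanMagnitudeScore(magnitudeMaps[[i]])
      b$subject_id <- ids[i]
      b
    }),
    lapply(seq_len(nS), function(i) {
      landmarkProcrustesScore(landmarks[[i]], subjectId = ids[i])
    })))
  rownames(baselines) <- NULL

  list(averageMesh = avgMesh, averageLandmarks = avgLm,
       croppedMesh = crop$mesh,
       keptIndices = crop$keptIndices,
       heatMaps = lapply(heatMaps, function(hm) {
         m <- do.call(rbind, lapply(hm, featureValues))
         rownames(m) <- ids
         m
       }),
       models = models, scores = scores, baselines = baselines)
}

#' Write per-subject scores as TSV
#'
#' The common output table of the spatiogram and baseline phenotypes:
#' columns `subject_id`, `feature` (or `method`), `score`.
#'
#' @param scores a data.frame of scores
#' @param path output TSV path
#' @return invisibly, `path`
#' @export
writeScores <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Score new subjects against a fitted normal-asymmetry model
#'
#' The deployment form of the scoring system: the average mesh and the
#' population model of normal asymmetry come from a reference cohort
#' (a [asymmetryPipeline()] fit), and new subjects are aligned, mapped,
#' mirrored and scored against that fixed model. Because the reference is
#' held fixed, more asymmetry always means more deviation from it — the
#' score is monotone in a subject's asymmetry rather than U-shaped around
#' the scored cohort's own mean.
#'
#' @param meshes,landmarks lists of subject meshes and landmark sets
#' @param fit the result of [asymmetryPipeline()] on the reference cohort
#' @param features features to score (must be among the fit's models)
#' @param bins,tau,variant histogram parameters, as in the pipeline
#' @param lambda TPS regularization
#' @return `list(scores = data.frame(subject_id, feature, score),
#'   heatMaps = per-feature subjects x points matrix,
#'   baselines = data.frame)`
#' @export
scoreWithModel <- function(meshes, landmarks, fit,
                           features = names(fit$models), bins = 10,
                           tau = 20,
                           variant = c("bhattacharyya", "ratio"),
                           lambda = 0) {
  variant <- match.arg(variant)
  nS <- length(meshes)
  stopifnot(nS >= 1, length(landmarks) == nS)
  ids <- names(meshes)
  if (is.null(ids)) ids <- sprintf("Q%03d", seq_len(nS))
  avgLm <- fit$averageLandmarks
  scored <- vertices(fit$averageMesh)[fit$keptIndices, , drop = FALSE]
  graph <- meshAdjacency(fit$croppedMesh)
  heatMaps <- lapply(features, function(f) vector("list", nS))
  names(heatMaps) <- features
  magnitudeMaps <- vector("list", nS)
  for (i in seq_len(nS)) {
    fr <- landmarkRigidAlign(landmarks[[i]], avgLm)
    mesh <- applyFrame(fr, meshes[[i]])
    lm <- applyFrame(fr, landmarks[[i]])
    mir <- mirrorMesh(mesh, lm)
    corrO <- projectToSurface(tpsWarp(avgLm, lm, scored, lambda), mesh)
    corrM <- projectToSurface(tpsWarp(avgLm, mir$landmarks, scored, lambda),
                              mir$mesh)
    flow <- asymmetryFlow(corrO, corrM)
    nO <- interpolateNormals(mesh, corrO)
    nM <- interpolateNormals(mir$mesh, corrM)
    if ("surface_orientation_angle" %in% features)
      heatMaps[["surface_orientation_angle"]][[i]] <-
        surfaceOrientationAngle(nO, nM, subjectId = ids[i])
    if ("deformation_angle" %in% features)
      heatMaps[["deformation_angle"]][[i]] <-
        deformationAngle(flow, nO, subjectId = ids[i])
    mm <- deformationMagnitude(flow, subjectId = ids[i])
    magnitudeMaps[[i]] <- mm
    if ("deformation_magnitude" %in% features)
      heatMaps[["deformation_magnitude"]][[i]] <- mm
  }
  scores <- NULL
  for (f in features) {
    model <- fit$models[[f]]
    ## fixed bin range covering the reference cohort and the new subjects
    edges <- defaultBinEdges(f, c(list(fit$heatMaps[[f]], modelMean(model)),
                                  heatMaps[[f]]), bins)
    sc <- vapply(heatMaps[[f]], function(m) {
      scoreValue(scoreSubject(m, model, edges = edges, tau = tau,
                              graph = graph, variant = variant))
    }, numeric(1))
    scores <- rbind(scores,
                    data.frame(subject_id = ids, feature = f, score = sc,
                               stringsAsFactors = FALSE))
  }
  baselines <- do.call(rbind, c(
    lapply(seq_len(nS), function(i) {
      b <- meanMagnitudeScore(magnitudeMaps[[i]])
      b$subject_id <- ids[i]
      b
    }),
    lapply(seq_len(nS), function(i) {
      landmarkProcrustesScore(landmarks[[i]], subjectId = ids[i])
    })))
  rownames(baselines) <- NULL
  list(scores = scores,
       heatMaps = lapply(heatMaps, function(hm) {
         m <- do.call(rbind, lapply(hm, featureValues))
         rownames(m) <- ids
         m
       }),
       baselines = baselines)
}
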