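mkCorr <- function(pos) {
  n <- nrow(pos)
  new("Correspondence", faceIndex = rep(1L, n),
      bary = matrix(rep(c(1, 0, 0), each = n), n),
      positions = pos)
}

test_that("asymmetry flow is the mirror-minus-original displacement", {
  po <- rbind(c(1, 0, 0), c(0, 1, 0))
  pm <- rbind(c(1.5, 0, 0), c(0, 1, 0))
  v <- asymmetryFlow(mkCorr(po), mkCorr(pm))
  expect_equal(v[1, ], c(0.5, 0, 0))
  expect_equal(sqrt(sum(v[1, ]^2)), 0.5)
  expect_equal(v[2, ], c(0, 0, 0))
  expect_error(asymmetryFlow(mkCorr(po), mkCorr(pm[1, , drop = FALSE])),
               "point counts")
})

test_that("angle features reproduce hand-computed cases", {
  n0 <- rbind(c(0, 0, 1), c(0, 0, 1), c(0, 0, 1))
  n1 <- rbind(c(0, 0, 1), c(1, 0, 0), c(0, 0, -1))
  th <- surfaceOrientationAngle(n0, n1)
  expect_equal(featureValues(th), c(0, 90, 180), tolerance = 1e-12)

  flow <- rbind(c(0, 0, 2), c(1, 0, 0), c(0, 0, 0))
  phi <- deformationAngle(flow, n0)
  # zero flow falls back to 0 degrees by the degenerate-flow convention
  expect_equal(featureValues(phi), c(0, 90, 0), tolerance = 1e-12)

  mag <- deformationMagnitude(rbind(c(3, 4, 0), c(0, 0, 0)))
  expect_equal(featureValues(mag), c(5, 0))

  # magnitudes equal brute-force Euclidean norms on random flows
  set.seed(2)
  vr <- matrix(rnorm(300), 100)
  expect_equal(featureValues(deformationMagnitude(vr)),
               apply(vr, 1, function(r) sqrt(sum(r^2))), tolerance = 1e-12)
})

test_that("an exactly mirror-symmetric subject has all-zero feature maps", {
  tpl <- testTemplate()
  mir <- mirrorMesh(tpl$mesh, tpl$landmarks)
  crop <- cropBelowEyes(tpl$mesh, tpl$landmarks)
  pts <- vertices(crop$mesh)
  corrO <- projectToSurface(pts, tpl$mesh)
  corrM <- projectToSurface(pts, mir$mesh)
  flow <- asymmetryFlow(corrO, corrM)
  expect_lt(max(abs(flow)), 1e-6)
  expect_lt(max(featureValues(deformationMagnitude(flow))), 1e-6)
  th <- surfaceOrientationAngle(interpolateNormals(tpl$mesh, corrO),
                                interpolateNormals(mir$mesh, corrM))
  expect_lt(max(featureValues(th)), 1e-4)
  expect_lt(max(featureValues(deformationAngle(flow,
             interpolateNormals(tpl$mesh, corrO)))), 1e-4)
})

test_that("features grow monotonically with the injected bump amplitude", {
  tpl <- testTemplate()
  crop <- cropBelowEyes(tpl$mesh, tpl$landmarks)
  pts <- vertices(crop$mesh)
  regionalMax <- c(); regionalOri <- c(); regionalMag <- c()
  for (h in c(0.5, 1, 2)) {
    spec <- asymmetrySpec("zygion_l", radius = 14, amplitude = h,
                          side = "left")
    subj <- injectAsymmetry(tpl$mesh, tpl$landmarks, spec)
    mir <- mirrorMesh(subj, tpl$landmarks)
    corrO <- projectToSurface(pts, subj)
    corrM <- projectToSurface(pts, mir$mesh)
    flow <- asymmetryFlow(corrO, corrM)
    mag <- featureValues(deformationMagnitude(flow))
    ori <- featureValues(surfaceOrientationAngle(
      interpolateNormals(subj, corrO),
      interpolateNormals(mir$mesh, corrM)))
    regionalMax <- c(regionalMax, max(mag))
    regionalMag <- c(regionalMag, mean(mag))
    regionalOri <- c(regionalOri, mean(ori))
  }
  expect_true(all(diff(regionalMax) > 0))
  expect_true(all(diff(regionalMag) > 0))
  expect_true(all(diff(regionalOri) > 0))
  # the 2 mm bump shows up at roughly its injected magnitude
  expect_gt(regionalMax[3], 1.5)
  expect_lt(regionalMax[3], 2.5)
})

test_that("features are invariant to a common rigid motion of the subject", {
  tpl <- testTemplate()
  spec <- asymmetrySpec("pronasale", radius = 14, amplitude = 1,
                        side = "left")
  subj <- injectAsymmetry(tpl$mesh, tpl$landmarks, spec)
  lm <- tpl$landmarks

  runFeatures <- function(mesh, landmarks) {
    fr <- landmarkRigidAlign(landmarks, tpl$landmarks)
    mesh <- applyFrame(fr, mesh)
    landmarks <- applyFrame(fr, landmarks)
    crop <- cropBelowEyes(tpl$mesh, tpl$landmarks)
    pts <- vertices(crop$mesh)
    mir <- mirrorMesh(mesh, landmarks)
    wO <- tpsWarp(tpl$landmarks, landmarks, pts)
    wM <- tpsWarp(tpl$landmarks, mir$landmarks, pts)
    corrO <- projectToSurface(wO, mesh)
    corrM <- projectToSurface(wM, mir$mesh)
    flow <- asymmetryFlow(corrO, corrM)
    list(mag = featureValues(deformationMagnitude(flow)),
         ori = featureValues(surfaceOrientationAngle(
           interpolateNormals(mesh, corrO),
           interpolateNormals(mir$mesh, corrM))))
  }

  base <- runFeatures(subj, lm)
  fr <- new("AlignmentFrame", rotation = rotY(18),
            translation = c(10, -5, 3), rmsd = 0)
  moved <- runFeatures(applyFrame(fr, subj), applyFrame(fr, lm))
  expect_lt(max(abs(base$mag - moved$mag)), 1e-3)
  expect_lt(max(abs(base$ori - moved$ori)), 1e-1)
})

test_that("the normal model matches per-point mean and sample SD", {
  flat <- gridMesh(4, 4)
  hm <- function(v, id) new("FeatureHeatMap",
                            feature = "deformation_magnitude",
                            values = v, subjectId = id)
  m1 <- hm(rep(10, 16), "a"); m2 <- hm(rep(20, 16), "b")
  mod <- buildNormalModel(list(m1, m2), flat)
  expect_equal(modelMean(mod), rep(15, 16))
  expect_equal(modelSD(mod), rep(sqrt(50), 16), tolerance = 1e-12)

  # identical cohort: SD hits the positive floor
  modSame <- buildNormalModel(list(m1, m1, m1), flat)
  expect_equal(modelSD(modSame), rep(1e-6, 16))

  # brute-force column mean/SD oracle on a random 50-subject stack
  set.seed(13)
  maps <- lapply(1:50, function(i) hm(abs(rnorm(16, 5, 2)), paste0("s", i)))
  mod50 <- buildNormalModel(maps, flat)
  M <- do.call(rbind, lapply(maps, featureValues))
  expect_equal(modelMean(mod50), colMeans(M), tolerance = 1e-9)
  expect_equal(modelSD(mod50), apply(M, 2, sd), tolerance = 1e-9)

  expect_error(buildNormalModel(list(m1), flat), "at least 2")
})
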