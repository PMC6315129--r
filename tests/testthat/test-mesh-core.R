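test_that("mesh I/O round-trips vertices and faces in OBJ and PLY", {
  m <- tetraMesh()
  for (ext in c("obj", "ply")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    writeMesh(m, path)
    m2 <- readMesh(path)
    expect_equal(vertices(m2), vertices(m), tolerance = 1e-9)
    expect_identical(faces(m2), faces(m))
  }
  # high-precision coordinates survive to 1e-6 mm
  tpl <- testTemplate()
  path <- withr::local_tempfile(fileext = ".ply")
  writeMesh(tpl$mesh, path)
  back <- readMesh(path)
  expect_identical(nVertices(back), nVertices(tpl$mesh))
  expect_lt(max(abs(vertices(back) - vertices(tpl$mesh))), 1e-6)
})

test_that("non-triangular faces and unreadable files are rejected", {
  quad <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0", "f 1 2 3 4"),
             quad)
  expect_error(readMesh(quad), "non-triangular")
  expect_error(readMesh("no/such/file.ply"), "not found")
  expect_error(readMesh(withr::local_tempfile(fileext = ".xyz")),
               "not found")
})

test_that("rigid landmark alignment recovers known motions", {
  lm <- symmetricLandmarks()
  # identity case
  fr <- landmarkRigidAlign(lm, lm)
  expect_equal(fr@rotation, diag(3), tolerance = 1e-12)
  expect_equal(fr@translation, rep(0, 3), tolerance = 1e-12)
  expect_equal(fr@rmsd, 0, tolerance = 1e-12)

  # known motion: reference = 90 deg about y plus a shift; the recovered
  # frame must invert it with ~zero residual
  R <- rotY(90)
  P <- landmarkPoints(lm)
  ref <- LandmarkSet(t(R %*% t(P)) + rep(1, nrow(P)) %o% c(1, 0, 0),
                     pairs = landmarkPairs(lm), midline = midlineNames(lm))
  fr <- landmarkRigidAlign(lm, ref)
  expect_lt(fr@rmsd, 1e-9)
  expect_equal(applyFrame(fr, P), landmarkPoints(ref), tolerance = 1e-9,
               ignore_attr = TRUE)

  # noisy reference: residual > 0 but the frame stays close to noiseless
  set.seed(11)
  for (rep in 1:5) {
    noisy <- LandmarkSet(landmarkPoints(ref) +
                           matrix(rnorm(length(P), 0, 0.1), nrow(P)),
                         pairs = landmarkPairs(lm),
                         midline = midlineNames(lm))
    frN <- landmarkRigidAlign(lm, noisy)
    expect_gt(frN@rmsd, 0)
    expect_lt(max(abs(frN@rotation - fr@rotation)), 0.05)
    expect_lt(max(abs(frN@translation - fr@translation)), 0.5)
  }
})

test_that("alignment rejects degenerate landmark configurations", {
  p2 <- rbind(a = c(0, 0, 0), b = c(1, 0, 0))
  expect_error(landmarkRigidAlign(p2, p2), "at least 3")
  line <- rbind(a = c(0, 0, 0), b = c(1, 0, 0), c = c(2, 0, 0))
  expect_error(landmarkRigidAlign(line, line), "collinear")
})

test_that("alignment is invariant to a pre-applied rigid motion", {
  lm <- symmetricLandmarks()
  ref <- symmetricLandmarks()
  set.seed(3)
  P <- landmarkPoints(lm) + matrix(rnorm(24, 0, 1), 8)
  rownames(P) <- rownames(landmarkPoints(lm))
  fr0 <- landmarkRigidAlign(P, ref)
  R <- rotY(37); t <- c(5, -2, 1)
  Pm <- t(R %*% t(P)) + rep(1, nrow(P)) %o% t
  rownames(Pm) <- rownames(P)
  frM <- landmarkRigidAlign(Pm, ref)
  # aligned positions agree even though the input was pre-rotated
  expect_equal(applyFrame(frM, Pm), applyFrame(fr0, P), tolerance = 1e-6)
})

test_that("mirroring flips x, preserves geometry and is an involution", {
  tpl <- testTemplate()
  mir <- mirrorMesh(tpl$mesh, tpl$landmarks)
  expect_equal(vertices(mir$mesh)[, 1], -vertices(tpl$mesh)[, 1])
  expect_equal(vertices(mir$mesh)[, 2:3], vertices(tpl$mesh)[, 2:3])

  # involution: bit-exact round trip for mesh and landmarks
  back <- mirrorMesh(mir$mesh, mir$landmarks)
  expect_equal(vertices(back$mesh), vertices(tpl$mesh))
  expect_identical(faces(back$mesh), faces(tpl$mesh))
  expect_equal(landmarkPoints(back$landmarks), landmarkPoints(tpl$landmarks))

  # left/right relabeling: the mirrored left landmark is the reflected right
  p <- landmarkPoints(tpl$landmarks)
  pm <- landmarkPoints(mir$landmarks)
  expect_equal(pm["endocanthion_l", ],
               p["endocanthion_r", ] * c(-1, 1, 1))

  # edge lengths (hence areas) are preserved exactly
  f <- faces(tpl$mesh)
  edgeLen <- function(V) sqrt(rowSums((V[f[, 1], ] - V[f[, 2], ])^2))
  expect_equal(edgeLen(vertices(mir$mesh)), edgeLen(vertices(tpl$mesh)))

  # mirrored normals: x component flips; recomputing from the mirrored
  # winding agrees
  expect_equal(normals(mir$mesh), normals(tpl$mesh) %*% diag(c(-1, 1, 1)),
               tolerance = 1e-12)
  expect_equal(vertexNormals(mir$mesh), normals(mir$mesh), tolerance = 1e-9)
})

test_that("below-eyes crop keeps exactly the vertices at or below the threshold", {
  tpl <- testTemplate()
  crop <- cropBelowEyes(tpl$mesh, tpl$landmarks)
  thr <- mean(landmarkPoints(tpl$landmarks)[c("endocanthion_l",
                                              "endocanthion_r"), 2])
  expect_setequal(crop$keptIndices, which(vertices(tpl$mesh)[, 2] <= thr))
  expect_true(all(vertices(crop$mesh)[, 2] <= thr))
  # old -> new map is consistent
  expect_equal(vertices(tpl$mesh)[crop$keptIndices, ],
               vertices(crop$mesh))
  expect_identical(crop$indexMap[crop$keptIndices],
                   seq_along(crop$keptIndices))

  # threshold arithmetic: endocanthions at y=10 and 12 -> cut at 11
  g <- gridMesh(5, 5, xlim = c(-2, 2), ylim = c(0, 22))
  lm <- LandmarkSet(rbind(endocanthion_l = c(1, 10, 0),
                          endocanthion_r = c(-1, 12, 0),
                          nasion = c(0, 5, 0)),
                    pairs = rbind(c("endocanthion_l", "endocanthion_r")),
                    midline = "nasion")
  cr <- cropBelowEyes(g, lm, minVertices = 1)
  y <- vertices(g)[, 2]
  expect_true(all(c(which(abs(y - 11) < 0.2 & y <= 11)) %in% cr$keptIndices))
  expect_setequal(cr$keptIndices, which(y <= 11))

  # mesh entirely below the eyes is unchanged
  gAll <- gridMesh(6, 6, ylim = c(0, 5))
  lmHigh <- LandmarkSet(rbind(endocanthion_l = c(1, 50, 0),
                              endocanthion_r = c(-1, 50, 0)),
                        pairs = rbind(c("endocanthion_l", "endocanthion_r")))
  crAll <- cropBelowEyes(gAll, lmHigh, minVertices = 10)
  expect_identical(crAll$keptIndices, seq_len(36L))
  expect_equal(vertices(crAll$mesh), vertices(gAll))

  # degenerate crop errors
  lmLow <- LandmarkSet(rbind(endocanthion_l = c(1, -50, 0),
                             endocanthion_r = c(-1, -50, 0)),
                       pairs = rbind(c("endocanthion_l", "endocanthion_r")))
  expect_error(cropBelowEyes(gAll, lmLow), "degenerate")
})

test_that("vertex normals are unit, outward and match analytic references", {
  flat <- gridMesh(8, 8)
  n <- vertexNormals(flat)
  expect_equal(sqrt(rowSums(n^2)), rep(1, 64), tolerance = 1e-9)
  expect_equal(n[, 3], rep(1, 64), tolerance = 1e-12)

  sph <- icoSphere(2)
  n <- vertexNormals(sph)
  v <- vertices(sph) / sqrt(rowSums(vertices(sph)^2))
  ang <- acos(pmin(1, rowSums(n * v))) * 180 / pi
  expect_lt(max(ang), 2)  # within 2 degrees of the analytic sphere normal
  # outward: positive dot with the radial direction everywhere
  expect_true(all(rowSums(n * v) > 0))
})

test_that("meshes with isolated vertices or bad faces are rejected", {
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(5, 5, 5))
  expect_error(SurfaceMesh(V, rbind(c(1, 2, 3))), "isolated")
  expect_error(SurfaceMesh(V[1:3, ], rbind(c(1, 2, 4))), "out of range|subscript")
})
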