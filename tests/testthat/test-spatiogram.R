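test_that("histograms use half-open bins with a closed last bin", {
  h <- buildHistogram(c(0, 45, 90, 135), seq(0, 180, length.out = 5))
  expect_identical(h$counts, c(1L, 1L, 1L, 1L))
  # value exactly on an interior edge belongs to the upper bin; the range
  # maximum belongs to the last bin
  h2 <- buildHistogram(c(0, 45, 180), seq(0, 180, length.out = 5))
  expect_identical(h2$counts, c(1L, 1L, 0L, 1L))
  # all-zero map lands in bin 1
  h3 <- buildHistogram(rep(0, 7), seq(0, 180, length.out = 5))
  expect_identical(h3$counts, c(7L, 0L, 0L, 0L))
  expect_identical(h3$points[[1]], 1:7)
  expect_error(buildHistogram(c(-1, 5), c(0, 10)), "outside")
  expect_error(buildHistogram(c(1, 15), c(0, 10)), "outside")

  # counts match brute-force binning on random maps
  set.seed(31)
  for (rep in 1:5) {
    vals <- runif(200, 0, 180)
    edges <- seq(0, 180, length.out = 26)
    h <- buildHistogram(vals, edges)
    expect_identical(h$counts,
                     as.integer(vapply(seq_len(25), function(b) {
                       sum(vapply(vals, bfBin, 1L, edges = edges) == b)
                     }, numeric(1))))
    expect_identical(sum(h$counts), 200L)
  }
})

test_that("coherent regions are the >= tau connected components", {
  # a long path (25 vertices) and a short one (5) in the same point set
  g <- gridMesh(31, 2)
  graph <- meshAdjacency(g)
  pts <- c(1:25, 27:31)  # vertex 26 missing splits the bottom row
  cr <- coherentRegions(pts, graph, tau = 20)
  expect_length(cr$regions, 1)
  expect_identical(cr$regions[[1]], 1:25)
  expect_identical(cr$incoherent, c(27:31))

  # fully connected 30-point patch: one region of 30
  patch <- gridMesh(6, 5)
  cr2 <- coherentRegions(1:30, meshAdjacency(patch), tau = 20)
  expect_length(cr2$regions, 1)
  expect_identical(sort(cr2$regions[[1]]), 1:30)

  # 30 pairwise-nonadjacent vertices: all incoherent
  big <- gridMesh(20, 20)
  iso <- as.integer(seq(1, 400, by = 13)[1:30])
  cr3 <- coherentRegions(iso, meshAdjacency(big), tau = 20)
  expect_length(cr3$regions, 0)
  expect_identical(cr3$incoherent, iso)

  # empty set is fine
  cr4 <- coherentRegions(integer(), meshAdjacency(big), tau = 20)
  expect_length(cr4$regions, 0)

  # agreement with the BFS oracle on random subsets
  set.seed(41)
  adj <- bfAdjacency(faces(big), nVertices(big))
  for (rep in 1:3) {
    pts <- sort(sample(400, 150))
    cr <- coherentRegions(pts, meshAdjacency(big), tau = 5)
    comps <- bfComponents(pts, adj)
    want <- comps[vapply(comps, length, integer(1)) >= 5]
    got <- lapply(cr$regions, sort)
    expect_setequal(lapply(got, paste, collapse = ","),
                    lapply(want, paste, collapse = ","))
  }
})

test_that("augmented histograms partition every bin into regions + incoherent", {
  g <- gridMesh(12, 12)
  graph <- meshAdjacency(g)
  edges <- seq(0, 1, length.out = 6)

  # constant map: one bin holds the whole mesh as one coherent region
  ah <- augmentHistogram(rep(0.5, 144), graph, edges, tau = 20)
  expect_identical(sum(binCounts(ah)), 144L)
  occupied <- which(binCounts(ah) > 0)
  expect_length(occupied, 1)
  expect_length(binRegions(ah)[[occupied]], 1)
  expect_identical(sort(binRegions(ah)[[occupied]][[1]]), 1:144)

  # two disjoint high-value patches in one bin give two regions
  vals <- rep(0.1, 144)
  patchA <- as.vector(outer(1:5, 0:4 * 12, `+`))        # 25 vertices
  patchB <- as.vector(outer(8:12, 7:11 * 12, `+`))      # 25 vertices
  vals[c(patchA, patchB)] <- 0.9
  ah2 <- augmentHistogram(vals, graph, edges, tau = 20)
  hi <- bfBin(0.9, edges)
  expect_length(binRegions(ah2)[[hi]], 2)
  expect_setequal(unlist(binRegions(ah2)[[hi]]), c(patchA, patchB))

  # invariants on random maps: conservation and disjoint partition
  set.seed(51)
  for (rep in 1:3) {
    vals <- runif(144)
    ah <- augmentHistogram(vals, graph, edges, tau = 4)
    expect_identical(sum(binCounts(ah)), 144L)
    for (b in seq_along(binCounts(ah))) {
      pts <- c(unlist(binRegions(ah)[[b]]), incoherentPoints(ah)[[b]])
      expect_identical(length(pts), as.integer(binCounts(ah)[b]))
      expect_false(anyDuplicated(pts) > 0)
      sizes <- vapply(binRegions(ah)[[b]], length, integer(1))
      if (length(sizes)) expect_true(all(sizes >= 4))
    }
  }
})

test_that("spatial weights equal the stated region-weighted standardized error", {
  # one region of two points with errors of 1 and 3 SD: Psi = 2
  A <- c(1, 3, 0); B <- c(0, 0, 0); sigma <- c(1, 1, 1)
  expect_equal(spatialWeight(list(c(1, 2)), A, B, sigma), 2)
  # identical maps: zero for any regions
  expect_equal(spatialWeight(list(c(1, 2), 3), A, A, sigma), 0)
  # no regions: zero
  expect_equal(spatialWeight(list(), A, B, sigma), 0)
  expect_error(spatialWeight(list(1), A, B, numeric()), "empty sigma")
  expect_error(spatialWeight(list(5), A, B, sigma), "out of range")

  # random fixtures vs the direct formula
  set.seed(61)
  for (rep in 1:5) {
    n <- 40
    A <- runif(n); B <- runif(n); s <- runif(n, 0.5, 2)
    regions <- list(sample(n, 8), sample(n, 5), sample(n, 3))
    tot <- sum(lengths(regions))
    want <- sum(vapply(regions, function(r) {
      (length(r) / tot) * mean(abs(A[r] - B[r]) / s[r])
    }, numeric(1)))
    expect_equal(spatialWeight(regions, A, B, s), want, tolerance = 1e-12)
  }
})

test_that("directed and symmetric distances follow the composed formula", {
  g <- gridMesh(10, 10)
  graph <- meshAdjacency(g)
  edges <- seq(0, 1, length.out = 5)
  set.seed(71)
  A <- runif(100); B <- runif(100); s <- runif(100, 0.5, 2)
  hA <- augmentHistogram(A, graph, edges, tau = 4)
  hB <- augmentHistogram(B, graph, edges, tau = 4)

  # identical maps: distance 0
  expect_equal(directedDistance(hA, hA, A, A, s)$distance, 0)

  # disjoint supports: the dissimilarity factor is 1 in every occupied bin
  lo <- rep(0.1, 100); hi <- rep(0.9, 100)
  hLo <- augmentHistogram(lo, graph, edges, tau = 4)
  hHi <- augmentHistogram(hi, graph, edges, tau = 4)
  dd <- directedDistance(hLo, hHi, lo, hi, s)
  expect_equal(dd$distance, sum(dd$psi), tolerance = 1e-12)
  expect_gt(dd$distance, 0)

  # matches the brute-force composed evaluation, both variants
  for (variant in c("bhattacharyya", "ratio")) {
    rho <- symmetricDistance(hA, hB, A, B, s, variant = variant)$rho
    want <- bfSpatiogramScore(A, B, s, edges, faces(g), 100, tau = 4,
                              variant = variant)
    expect_equal(rho, want, tolerance = 1e-9)
  }

  # symmetry to 1e-12 and scale behavior in sigma
  r1 <- symmetricDistance(hA, hB, A, B, s)$rho
  r2 <- symmetricDistance(hB, hA, B, A, s)$rho
  expect_equal(r1, r2, tolerance = 1e-12)
  r3 <- symmetricDistance(hA, hB, A, B, 2.5 * s)$rho
  expect_equal(r3, r1 / 2.5, tolerance = 1e-12)

  expect_error(directedDistance(hA, augmentHistogram(B, graph,
    seq(0, 2, length.out = 5), tau = 4), A, B, s), "mismatched bin edges")
})

test_that("scoring a subject against the model behaves like a distance", {
  g <- gridMesh(10, 10)
  set.seed(81)
  maps <- lapply(1:8, function(i) {
    new("FeatureHeatMap", feature = "surface_orientation_angle",
        values = runif(100, 0, 40), subjectId = paste0("s", i))
  })
  model <- buildNormalModel(maps, g)

  # subject exactly at the model mean scores 0
  atMean <- new("FeatureHeatMap", feature = "surface_orientation_angle",
                values = modelMean(model), subjectId = "mean")
  expect_equal(scoreValue(scoreSubject(atMean, model, tau = 4)), 0)

  # a subject deviating by >= 1 SD over a coherent patch scores > 0
  dev <- modelMean(model)
  patch <- as.vector(outer(1:5, 0:4 * 10, `+`))
  dev[patch] <- dev[patch] + 3 * modelSD(model)[patch] + 30
  devMap <- new("FeatureHeatMap", feature = "surface_orientation_angle",
                values = pmin(dev, 180), subjectId = "dev")
  expect_gt(scoreValue(scoreSubject(devMap, model, tau = 4)), 0)

  # deterministic given inputs
  s1 <- scoreValue(scoreSubject(devMap, model, tau = 4))
  s2 <- scoreValue(scoreSubject(devMap, model, tau = 4))
  expect_identical(s1, s2)

  expect_error(scoreSubject(new("FeatureHeatMap",
    feature = "surface_orientation_angle", values = runif(50, 0, 10),
    subjectId = "bad"), model), "point count")
  expect_error(scoreSubject(new("FeatureHeatMap",
    feature = "deformation_magnitude", values = runif(100),
    subjectId = "bad"), model), "feature")
})
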