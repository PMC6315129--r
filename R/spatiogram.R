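#' Default histogram bin edges for a feature
#'
#' Equal-width bins on `[0, max]`, the maximum taken over all supplied
#' maps — normally the whole cohort, so every subject is binned on the
#' same fixed range and histograms stay comparable. Realistic asymmetry
#' features occupy only a small part of their theoretical range (a normal
#' face's orientation asymmetry stays far below 180 degrees), so binning
#' the observed cohort range keeps the histogram informative instead of
#' collapsing all mass into the first bin. Angle ranges are capped at
#' 180 degrees. With no maps supplied, angles fall back to `[0, 180]`.
#'
#' @param feature feature name (see [FeatureHeatMap-class])
#' @param maps list of [FeatureHeatMap-class] or numeric vectors fixing
#'   the cohort range
#' @param bins number of equal-width bins (default 10)
#' @return numeric vector of `bins + 1` edges
#' @export
defaultBinEdges <- function(feature, maps = NULL, bins = 10) {
  stopifnot(bins >= 1)
  vals <- unlist(lapply(maps, function(m) {
    if (is(m, "FeatureHeatMap")) featureValues(m) else as.numeric(m)
  }), use.names = FALSE)
  angle <- grepl("angle", feature)
  top <- if (length(vals)) max(vals) else if (angle) 180 else 1
  if (top <= 0) top <- 1
  if (angle) top <- min(top, 180)
  seq(0, top, length.out = bins + 1)
}

#' Feature histogram over fixed bin edges
#'
#' Half-open equal-footing bins `[e_k, e_{k+1})`, last bin closed. Values
#' outside the edge range are an error: ranges are fixed per feature so
#' that histograms are comparable.
#'
#' @param values numeric vector or [FeatureHeatMap-class]
#' @param edges numeric vector of B+1 increasing bin edges
#' @return `list(counts = integer B-vector, binIndex = per-point bin,
#'   points = list of per-bin point-index vectors)`
#' @export
buildHistogram <- function(values, edges) {
  if (is(values, "FeatureHeatMap")) values <- featureValues(values)
  if (any(!is.finite(values))) stop("histogram values must be finite")
  B <- length(edges) - 1L
  if (B < 1 || is.unsorted(edges, strictly = TRUE))
    stop("edges must be strictly increasing with at least 2 values")
  if (length(values) &&
      (min(values) < edges[1] || max(values) > edges[B + 1]))
    stop("value outside the fixed histogram range [",
         edges[1], ", ", edges[B + 1], "]")
  bin <- findInterval(values, edges, rightmost.closed = TRUE)
  list(counts = tabulate(bin, nbins = B),
       binIndex = bin,
       points = split(seq_along(values), factor(bin, levels = seq_len(B))))
}

#' Coherent regions of a point set on the mesh adjacency graph
#'
#' Connected components of the subgraph induced by `pointSet`; components
#' with at least `tau` points are the coherent regions, the remainder is
#' pooled as incoherent. With the reference regime of ~20,000 scored points,
#' the default tau = 20 corresponds to 0.1% of the image.
#'
#' @param pointSet integer vector of mesh vertex indices (may be empty)
#' @param graph mesh adjacency igraph from [meshAdjacency()]
#' @param tau minimum coherent component size (default 20)
#' @return `list(regions = list of integer vectors (size >= tau, largest
#'   first), incoherent = sorted integer vector)`
#' @export
coherentRegions <- function(pointSet, graph, tau = 20) {
  pointSet <- as.integer(pointSet)
  if (!length(pointSet)) return(list(regions = list(), incoherent = integer()))
  sub <- igraph::induced_subgraph(graph, as.character(pointSet))
  comp <- igraph::components(sub)
  members <- split(as.integer(igraph::V(sub)$name), comp$membership)
  sizes <- vapply(members, length, integer(1))
  ## deterministic order: largest first, ties by smallest vertex index
  ord <- order(-sizes, vapply(members, min, integer(1)))
  members <- lapply(members[ord], sort)
  keep <- vapply(members, length, integer(1)) >= tau
  inc <- unlist(members[!keep], use.names = FALSE)
  list(regions = unname(members[keep]),
       incoherent = sort(as.integer(c(inc, integer()))))
}

#' Spatially augmented histogram of a feature heat map
#'
#' The feature histogram with each bin's points decomposed into coherent
#' connected regions on the mesh (and a pooled incoherent remainder).
#'
#' @param values numeric vector or [FeatureHeatMap-class] over the mesh
#'   vertices
#' @param graph mesh adjacency igraph from [meshAdjacency()]
#' @param edges histogram bin edges
#' @param tau coherence threshold (default 20)
#' @return an [AugmentedHistogram-class]
#' @export
augmentHistogram <- function(values, graph, edges, tau = 20) {
  h <- buildHistogram(values, edges)
  B <- length(h$counts)
  regions <- vector("list", B)
  incoh <- vector("list", B)
  for (b in seq_len(B)) {
    cr <- coherentRegions(h$points[[b]], graph, tau)
    regions[[b]] <- cr$regions
    incoh[[b]] <- cr$incoherent
  }
  new("AugmentedHistogram", edges = as.numeric(edges),
      counts = as.integer(h$counts), regions = regions, incoherent = incoh,
      tau = tau)
}

#' Spatial weight of one histogram bin
#'
#' The coherent-region-weighted mean standardized error between two feature
#' maps: with region weights proportional to region size, this is the
#' average of |A - A'|/sigma over all coherent points of the bin. Bins with
#' no coherent regions weigh 0; incoherent points are counted in the bin
#' population but never enter the weight.
#'
#' @param regions list of coherent regions (integer point-index vectors) of
#'   the bin
#' @param mapA,mapB numeric feature maps over the full point universe
#' @param sigma strictly positive per-point SDs from the normal model
#' @return the non-negative spatial weight Psi_b
#' @export
spatialWeight <- function(regions, mapA, mapB, sigma) {
  if (!length(sigma)) stop("empty sigma")
  if (any(sigma <= 0)) stop("sigma must be strictly positive")
  if (!length(regions)) return(0)
  idxAll <- unlist(regions, use.names = FALSE)
  if (max(idxAll) > length(mapA) || max(idxAll) > length(sigma))
    stop("region index out of range of the feature maps")
  total <- length(idxAll)
  psi <- 0
  for (r in regions) {
    w <- length(r) / total
    psi <- psi + w * mean(abs(mapA[r] - mapB[r]) / sigma[r])
  }
  psi
}

#' Directed spatiogram distance
#'
#' Sum over bins of the spatial weight (computed from the first histogram's
#' coherent regions) times a histogram dissimilarity between the bins'
#' normalized frequencies. The default is the Bhattacharyya-style factor
#' `1 - sqrt(p_b p'_b)`; `variant = "ratio"` uses `1 - min/max` as a
#' sensitivity alternative.
#'
#' @param h,hRef [AugmentedHistogram-class] objects over identical bin edges
#'   and point universe; regions and Psi are taken from `h`
#' @param map,mapRef the two feature maps (numeric, full point universe)
#' @param sigma per-point SDs from the normal model
#' @param variant `"bhattacharyya"` (default) or `"ratio"`
#' @return `list(distance = , psi = per-bin spatial weights,
#'   dissimilarity = per-bin frequency factors)`
#' @export
directedDistance <- function(h, hRef, map, mapRef, sigma,
                             variant = c("bhattacharyya", "ratio")) {
  variant <- match.arg(variant)
  if (!isTRUE(all.equal(h@edges, hRef@edges, tolerance = 0)))
    stop("histograms have mismatched bin edges")
  n <- sum(h@counts); nRef <- sum(hRef@counts)
  if (n != nRef) stop("histograms cover different point universes")
  p <- h@counts / n
  q <- hRef@counts / nRef
  psi <- vapply(seq_along(h@counts), function(b) {
    spatialWeight(h@regions[[b]], map, mapRef, sigma)
  }, numeric(1))
  dis <- if (variant == "bhattacharyya") {
    1 - sqrt(p * q)
  } else {
    mx <- pmax(p, q)
    ifelse(mx > 0, 1 - pmin(p, q) / mx, 0)
  }
  list(distance = sum(psi * dis), psi = psi, dissimilarity = dis)
}

#' Symmetric spatiogram distance
#'
#' Mean of the two directed distances; symmetric by construction and zero
#' when the two maps agree.
#'
#' @inheritParams directedDistance
#' @param hPrime second histogram; `mapPrime` its map
#' @param mapPrime second feature map
#' @return `list(rho = , forward = , backward = )` where forward/backward
#'   are the two [directedDistance()] results
#' @export
symmetricDistance <- function(h, hPrime, map, mapPrime, sigma,
                              variant = c("bhattacharyya", "ratio")) {
  variant <- match.arg(variant)
  fw <- directedDistance(h, hPrime, map, mapPrime, sigma, variant)
  bw <- directedDistance(hPrime, h, mapPrime, map, sigma, variant)
  list(rho = (fw$distance + bw$distance) / 2, forward = fw, backward = bw)
}

#' Score a subject's asymmetry against the normal model
#'
#' The symmetric spatiogram distance between the subject's feature heat map
#' and the model's mean map, standardized by the model's per-point SDs.
#' Zero if and only if the subject's map equals the model mean everywhere
#' it matters; larger scores mean more abnormal asymmetry.
#'
#' @param heatMap the subject's [FeatureHeatMap-class] on the model mesh
#' @param model a [NormalAsymmetryModel-class] for the same feature
#' @param edges histogram bin edges; defaults to equal-width bins over the
#'   joint range of the subject map and the model mean
#' @param bins number of bins when `edges` is `NULL` (default 10)
#' @param tau coherence threshold (default 20)
#' @param graph optional precomputed adjacency of the model mesh
#' @param variant histogram dissimilarity variant, see [directedDistance()]
#' @return a [ScoreResult-class]
#' @export
scoreSubject <- function(heatMap, model, edges = NULL, bins = 10, tau = 20,
                         graph = NULL,
                         variant = c("bhattacharyya", "ratio")) {
  variant <- match.arg(variant)
  stopifnot(is(heatMap, "FeatureHeatMap"), is(model, "NormalAsymmetryModel"))
  if (featureName(heatMap) != model@feature)
    stop("heat map feature does not match the model feature")
  vals <- featureValues(heatMap)
  if (length(vals) != length(model@mu))
    stop("heat map point count does not match the model")
  if (is.null(edges))
    edges <- defaultBinEdges(model@feature, list(vals, model@mu), bins)
  if (is.null(graph)) graph <- meshAdjacency(model@mesh)
  h <- augmentHistogram(vals, graph, edges, tau)
  hRef <- augmentHistogram(model@mu, graph, edges, tau)
  sd2 <- symmetricDistance(h, hRef, vals, model@mu, model@sigma, variant)
  new("ScoreResult", subjectId = subjectId(heatMap),
      feature = model@feature, score = sd2$rho,
      psiSubject = sd2$forward$psi, psiReference = sd2$backward$psi)
}
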