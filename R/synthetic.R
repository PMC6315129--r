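## Synthetic face-like templates, asymmetry injection, and cohort
## simulation with a planted causal variant. This module is the test
## surface for the whole pipeline: templates are exactly mirror-symmetric
## by construction, so any non-zero asymmetry signal downstream is either
## injected or numerical.

# Height field of the face-like surface: an ellipsoidal dome with Gaussian
# nose, lip and chin bumps. Every term is even in x, so the surface is
# exactly symmetric about x = 0. Units mm; x lateral (left > 0),
# y superior, z anterior.
.faceHeight <- function(x, y) {
  ## the ellipsoid term stays strictly positive over the sampled domain
  ## (|x| <= 60, -70 <= y <= 60), so the surface is smooth everywhere
  dome <- 40 * sqrt(pmax(0.05, 1 - (x / 95)^2 - ((y + 5) / 115)^2))
  nose <- 14 * exp(-(x / 7)^2 - ((y - 3) / 13)^2)
  lips <- 4 * exp(-(x / 18)^2 - ((y + 23.5) / 5)^2)
  chin <- 6 * exp(-(x / 15)^2 - ((y + 52) / 11)^2)
  dome + nose + lips + chin
}

.templateLandmarkXY <- function() {
  rbind(
    nasion           = c(0, 35),
    pronasale        = c(0, 3),
    subnasale        = c(0, -8),
    labiale_superius = c(0, -20),
    labiale_inferius = c(0, -27),
    pogonion         = c(0, -52),
    endocanthion_l   = c(12, 30),  endocanthion_r = c(-12, 30),
    exocanthion_l    = c(30, 30),  exocanthion_r  = c(-30, 30),
    alare_l          = c(9, -2),   alare_r        = c(-9, -2),
    cheilion_l       = c(17, -23.5), cheilion_r   = c(-17, -23.5),
    zygion_l         = c(45, 12),  zygion_r       = c(-45, 12),
    gonion_l         = c(40, -42), gonion_r       = c(-40, -42))
}

#' Symmetric face-like template mesh with 18 landmarks
#'
#' A smooth height-field surface (ellipsoidal dome plus nose, lip and chin
#' bumps) sampled on a `(2*resolution+1)^2` grid over x in `[-60, 60]` mm,
#' y in `[-70, 60]` mm. The x grid and the height function are exactly
#' even in x and the triangulation mirrors its diagonals across x = 0, so
#' the template surface is mirror-symmetric to machine precision. Carries
#' the default 18-landmark schema (6 midline, 6 bilateral pairs).
#'
#' @param resolution grid half-density (>= 20); the mesh has
#'   `(2*resolution+1)^2` vertices
#' @return `list(mesh = SurfaceMesh, landmarks = LandmarkSet)`
#' @export
makeTemplate <- function(resolution = 40) {
  if (resolution < 20) stop("resolution must be at least 20")
  r <- as.integer(resolution)
  xhalf <- seq(0, 60, length.out = r + 1)
  xs <- c(-rev(xhalf[-1]), xhalf)         # exactly negation-symmetric
  ys <- seq(-70, 60, length.out = 2 * r + 1)
  nx <- length(xs); ny <- length(ys)
  V <- cbind(rep(xs, times = ny), rep(ys, each = nx), 0)
  V[, 3] <- .faceHeight(V[, 1], V[, 2])
  idx <- function(i, j) (j - 1L) * nx + i
  faces <- vector("list", (nx - 1) * (ny - 1))
  k <- 0L
  for (j in seq_len(ny - 1)) {
    for (i in seq_len(nx - 1)) {
      v00 <- idx(i, j); v10 <- idx(i + 1L, j)
      v01 <- idx(i, j + 1L); v11 <- idx(i + 1L, j + 1L)
      k <- k + 1L
      ## mirror the diagonal across x = 0 so the triangulated surface (not
      ## just the vertex set) is exactly symmetric
      faces[[k]] <- if (xs[i] + xs[i + 1] < 0)
        rbind(c(v00, v10, v11), c(v00, v11, v01))
      else
        rbind(c(v00, v10, v01), c(v10, v11, v01))
    }
  }
  mesh <- SurfaceMesh(V, do.call(rbind, faces))
  lmXY <- .templateLandmarkXY()
  lmP <- cbind(lmXY, .faceHeight(lmXY[, 1], lmXY[, 2]))
  rownames(lmP) <- rownames(lmXY)
  schema <- defaultLandmarkSchema()
  list(mesh = mesh,
       landmarks = LandmarkSet(lmP, pairs = schema$pairs,
                               midline = schema$midline))
}

#' Specify one injected asymmetry
#'
#' A smooth one-sided displacement of the surface: within a geodesic
#' radius of the centre, displaced along the vertex normals
#' (`normal_bump`), along the superior tangent direction
#' (`tangential_shear`), or rotated about the centre normal
#' (`regional_rotation`), with a cosine taper to zero at the region
#' boundary. Only vertices on the requested side (left: x > 0) move, so
#' the deformation is a genuine asymmetry.
#'
#' @param center a landmark name or an explicit xyz position; for a
#'   bilateral landmark the side-matching copy is used
#' @param radius geodesic region radius in mm
#' @param kind `normal_bump`, `tangential_shear` or `regional_rotation`
#' @param amplitude displacement in mm (or degrees for
#'   `regional_rotation`), >= 0
#' @param side `left` or `right`
#' @return an `asymmetrySpec` list
#' @export
asymmetrySpec <- function(center, radius = 14,
                          kind = c("normal_bump", "tangential_shear",
                                   "regional_rotation"),
                          amplitude = 1, side = c("left", "right")) {
  kind <- match.arg(kind)
  side <- match.arg(side)
  stopifnot(amplitude >= 0, radius > 0)
  structure(list(center = center, radius = radius, kind = kind,
                 amplitude = amplitude, side = side),
            class = "asymmetrySpec")
}

.resolveCenter <- function(spec, landmarks) {
  sgn <- if (spec$side == "left") 1 else -1
  if (is.numeric(spec$center)) return(as.numeric(spec$center))
  nm <- spec$center
  p <- landmarks@points
  suffix <- if (spec$side == "left") "_l" else "_r"
  for (cand in c(paste0(nm, suffix), nm)) {
    if (cand %in% rownames(p)) {
      pt <- p[cand, ]
      if (abs(pt[1]) < 1e-9) {
        ## a one-sided deviation of a midline feature is centred beside
        ## the midline: offset laterally so the smooth side mask does not
        ## attenuate the bump at its own centre
        pt[1] <- sgn * spec$radius / 2
      } else {
        pt[1] <- sgn * abs(pt[1])
      }
      return(pt)
    }
  }
  stop("asymmetry region centre not found among landmarks: ", nm)
}

#' Inject controlled asymmetries into a mesh
#'
#' Applies each spec's smooth one-sided displacement (cosine-tapered
#' within the geodesic region), then adds iid Gaussian vertex noise. With
#' zero amplitudes and zero noise the input mesh is returned bit-exactly.
#'
#' @param mesh a [SurfaceMesh-class] (aligned frame)
#' @param landmarks the template's [LandmarkSet-class] (region centres)
#' @param specs a single [asymmetrySpec()] or list of them
#' @param noiseSD iid vertex noise SD in mm (default 0)
#' @param seed optional integer seed for the noise draw
#' @param returnLandmarks if `TRUE`, also return the landmark set with the
#'   same displacement field applied (noise-free), so on-landmark bumps
#'   move the landmarks they cover
#' @return the deformed [SurfaceMesh-class], or
#'   `list(mesh =, landmarks =)` when `returnLandmarks = TRUE`
#' @export
injectAsymmetry <- function(mesh, landmarks, specs, noiseSD = 0,
                            seed = NULL, returnLandmarks = FALSE) {
  stopifnot(is(mesh, "SurfaceMesh"), noiseSD >= 0)
  if (inherits(specs, "asymmetrySpec")) specs <- list(specs)
  live <- Filter(function(s) s$amplitude > 0, specs)
  if (!length(live) && noiseSD == 0) {
    if (returnLandmarks) return(list(mesh = mesh, landmarks = landmarks))
    return(mesh)
  }
  V <- mesh@vertices
  N <- mesh@normals
  g <- meshAdjacency(mesh, weighted = TRUE)
  disp <- matrix(0, nrow(V), 3)
  lmP <- landmarks@points
  lmDisp <- matrix(0, nrow(lmP), 3)
  for (spec in live) {
    ctr <- .resolveCenter(spec, landmarks)
    src <- which.min(rowSums(sweep(V, 2, ctr)^2))
    gd <- as.numeric(igraph::distances(g, v = as.character(src)))
    ## smooth one-sided mask: 0 on the opposite half, ramping up over
    ## radius/2 from the midline so the deformed surface has no crease at
    ## the midsagittal plane
    sideW <- .sideWeight(V[, 1], spec$side, spec$radius / 2)
    inside <- which(gd < spec$radius & sideW > 0)
    if (!length(inside))
      stop("asymmetry region covers no vertices on the requested side")
    taper <- 0.5 * (1 + cos(pi * gd[inside] / spec$radius)) * sideW[inside]
    disp[inside, ] <- disp[inside, ] +
      .specDisplacement(spec, V[inside, , drop = FALSE],
                        N[inside, , drop = FALSE], taper, ctr, N[src, ])
    ## evaluate the same field at the landmarks (Euclidean distance to the
    ## centre vertex approximates the geodesic at landmark scale)
    ld <- rowNorms(sweep(lmP, 2, V[src, ]))
    lSideW <- .sideWeight(lmP[, 1], spec$side, spec$radius / 2)
    lin <- which(ld < spec$radius & lSideW > 0)
    if (length(lin)) {
      ltaper <- 0.5 * (1 + cos(pi * ld[lin] / spec$radius)) * lSideW[lin]
      lmN <- matrix(rep(N[src, ], length(lin)), ncol = 3, byrow = TRUE)
      lmDisp[lin, ] <- lmDisp[lin, ] +
        .specDisplacement(spec, lmP[lin, , drop = FALSE], lmN, ltaper,
                          ctr, N[src, ])
    }
  }
  V2 <- V + disp
  if (noiseSD > 0)
    V2 <- V2 + withSeed(seed, matrix(stats::rnorm(length(V2), 0, noiseSD),
                                     nrow(V2), 3))
  out <- SurfaceMesh(V2, mesh@faces)
  if (!returnLandmarks) return(out)
  p2 <- lmP + lmDisp
  rownames(p2) <- rownames(lmP)
  list(mesh = out,
       landmarks = new("LandmarkSet", points = p2,
                       pairs = landmarks@pairs,
                       midline = landmarks@midline))
}

# Per-subject random region centres: vertices of the template sampled
# uniformly from the below-eyes scoring region on the requested side (with
# a lateral margin so the smooth side mask does not null the bump). Unique
# locations emulate real inter-individual variation, where each face's
# dominant asymmetry sits somewhere different.
.sampleRegionCenters <- function(template, n, side, radius) {
  V <- template$mesh@vertices
  lm <- template$landmarks@points
  thr <- mean(lm[c("endocanthion_l", "endocanthion_r"), 2])
  ok <- V[, 2] <= thr & V[, 2] >= min(V[, 2]) + 5 &
    abs(V[, 1]) >= radius / 4 & abs(V[, 1]) <= max(V[, 1]) - 5
  idx <- which(ok)
  pick <- idx[sample.int(length(idx), n, replace = TRUE)]
  ctr <- V[pick, , drop = FALSE]
  sgn <- ifelse(side == "left", 1, -1)
  ctr[, 1] <- sgn * abs(ctr[, 1])
  ctr
}

# A subject's whole-face asymmetry field: k Gaussian patches at random
# locations and signs, summed and rescaled so the peak |displacement|
# equals `amplitude` (mm). The subject's overall asymmetry is thus a
# graded trait, spread over broad smooth patches the way real facial
# asymmetry heat maps look, rather than a single localized deformation.
.fieldAsymmetry <- function(template, amplitude, k) {
  mesh <- template$mesh
  V <- mesh@vertices
  lmP <- template$landmarks@points
  ctrIdx <- sample.int(nrow(V), k, replace = TRUE)
  sgn <- sample(c(-1, 1), k, replace = TRUE)
  width <- stats::runif(k, 10, 25)
  field <- numeric(nrow(V))
  lfield <- numeric(nrow(lmP))
  lmMirror <- lmP %*% diag(c(-1, 1, 1))
  lfieldM <- numeric(nrow(lmP))
  for (j in seq_len(k)) {
    field <- field + sgn[j] *
      exp(-rowSums(sweep(V, 2, V[ctrIdx[j], ])^2) / (2 * width[j]^2))
    lfield <- lfield + sgn[j] *
      exp(-rowSums(sweep(lmP, 2, V[ctrIdx[j], ])^2) / (2 * width[j]^2))
    lfieldM <- lfieldM + sgn[j] *
      exp(-rowSums(sweep(lmMirror, 2, V[ctrIdx[j], ])^2) / (2 * width[j]^2))
  }
  ## keep only the antisymmetric component: a displacement field moves
  ## both halves, and only the left-right difference is asymmetry.
  ## Antisymmetrizing makes every subject differ from the template purely
  ## asymmetrically, and the peak deformation magnitude (distance between
  ## a point and its mirror correspondent) equals `amplitude` exactly.
  ## The template vertex set is exactly closed under mirroring.
  mirrorIdx <- match(paste(-V[, 1], V[, 2], V[, 3]),
                     paste(V[, 1], V[, 2], V[, 3]))
  field <- (field - field[mirrorIdx]) / 2
  lfield <- (lfield - lfieldM) / 2
  peak <- 2 * max(abs(field))
  if (peak < 1e-9) peak <- 1
  field <- amplitude * field / peak
  lfield <- amplitude * lfield / peak
  p2 <- lmP + lfield * .landmarkNormals(mesh, lmP)
  rownames(p2) <- rownames(lmP)
  list(mesh = SurfaceMesh(V + field * mesh@normals, mesh@faces),
       landmarks = new("LandmarkSet", points = p2,
                       pairs = template$landmarks@pairs,
                       midline = template$landmarks@midline))
}

# Smoothstep side mask: 0 at and beyond the midline on the opposite side,
# rising over `ramp` mm on the requested side.
.sideWeight <- function(x, side, ramp) {
  t <- if (side == "left") x / ramp else -x / ramp
  t <- pmin(1, pmax(0, t))
  t * t * (3 - 2 * t)
}

# Smooth per-subject baseline asymmetry: k Gaussian patches at random
# surface locations (both sides), displacing along vertex normals with
# signed amplitudes ~ N(0, sd) and widths ~ U(10, 25) mm. Emulates the
# normal asymmetry every real face carries across its whole surface, on
# top of which the controlled bump is injected. Draws from the current
# RNG stream (callers seed it). Landmarks ride along with the field.
.baselineAsymmetry <- function(template, k, sd) {
  if (k == 0 || sd == 0) return(template)
  mesh <- template$mesh
  V <- mesh@vertices
  N <- mesh@normals
  lmP <- template$landmarks@points
  ctrIdx <- sample.int(nrow(V), k, replace = TRUE)
  amp <- stats::rnorm(k, 0, sd)
  width <- stats::runif(k, 10, 25)
  field <- numeric(nrow(V))
  lfield <- numeric(nrow(lmP))
  for (j in seq_len(k)) {
    d2 <- rowSums(sweep(V, 2, V[ctrIdx[j], ])^2)
    field <- field + amp[j] * exp(-d2 / (2 * width[j]^2))
    ld2 <- rowSums(sweep(lmP, 2, V[ctrIdx[j], ])^2)
    lfield <- lfield + amp[j] * exp(-ld2 / (2 * width[j]^2))
  }
  p2 <- lmP + lfield * .landmarkNormals(mesh, lmP)
  rownames(p2) <- rownames(lmP)
  list(mesh = SurfaceMesh(V + field * N, mesh@faces),
       landmarks = new("LandmarkSet", points = p2,
                       pairs = template$landmarks@pairs,
                       midline = template$landmarks@midline))
}

# Normal direction at each landmark: the normal of the nearest mesh vertex.
.landmarkNormals <- function(mesh, lmP) {
  idx <- vapply(seq_len(nrow(lmP)), function(i) {
    which.min(rowSums(sweep(mesh@vertices, 2, lmP[i, ])^2))
  }, integer(1))
  mesh@normals[idx, , drop = FALSE]
}

# Displacement field of one spec, evaluated at `pts` (k x 3) with local
# unit normals `n` (k x 3), per-point taper weights, region centre and the
# rotation axis (mesh normal at the centre vertex).
.specDisplacement <- function(spec, pts, n, taper, ctr, axis) {
  switch(spec$kind,
    normal_bump = spec$amplitude * taper * n,
    tangential_shear = {
      up <- cbind(0, 1, 0)[rep(1, nrow(pts)), , drop = FALSE]
      tang <- up - rowSums(up * n) * n
      spec$amplitude * taper * normalizeRows(tang, "tangent")
    },
    regional_rotation = {
      rel <- sweep(pts, 2, ctr)
      ang <- spec$amplitude * pi / 180 * taper
      ## Rodrigues rotation of each point about (ctr, axis) by its own angle
      kxr <- cbind(axis[2] * rel[, 3] - axis[3] * rel[, 2],
                   axis[3] * rel[, 1] - axis[1] * rel[, 3],
                   axis[1] * rel[, 2] - axis[2] * rel[, 1])
      kdot <- as.numeric(rel %*% axis)
      rot <- rel * cos(ang) + kxr * sin(ang) +
        outer(kdot * (1 - cos(ang)), axis)
      rot - rel
    })
}

#' Cohort simulation configuration
#'
#' Bundles the generator's study conditions: cohort size, the distribution
#' of injected asymmetry amplitudes, the genotype panel with one planted
#' causal SNP whose alleles add to the amplitude, and the covariate
#' distributions. Defaults emulate a normal-range cohort: amplitudes are a
#' truncated Normal(1.0, 0.5) mm, regions are drawn per subject from the
#' facial areas where normal asymmetry concentrates (nasal tip, nasal
#' bridge, upper lip, chin) on a random side, ages span 3-40 years and
#' sexes are balanced.
#'
#' @param nSubjects cohort size
#' @param nSNPs number of simulated SNPs (0 for a meshes-only cohort)
#' @param causalSNP index of the causal SNP (used when `nSNPs > 0`)
#' @param causalEffect additive amplitude effect per minor allele, mm
#' @param amplitudeMean,amplitudeSD base amplitude distribution: the
#'   amplitude is `|Normal(mean, sd)|` (folded normal, mm), so the default
#'   `mean = 0` gives the right-skewed magnitude distribution of normal
#'   facial asymmetry (most subjects nearly symmetric)
#' @param asymmetryModel `"field"` (default): each subject's asymmetry is
#'   a smooth random multi-patch displacement field over the whole face,
#'   scaled so its peak displacement equals the subject's amplitude —
#'   emulating overall facial asymmetry as a graded trait. `"bump"`: a
#'   single one-sided bump at a region drawn from `regionCenters`
#'   (controlled localized asymmetry, used for baseline contrasts)
#' @param regionCenters candidate region centre landmark names
#' @param regionRadius geodesic region radius, mm
#' @param baselineFields number of smooth baseline asymmetry patches per
#'   subject (0 disables the baseline field, leaving subjects symmetric
#'   outside the injected bump)
#' @param baselineSD amplitude SD (mm) of each baseline patch
#' @param noiseSD iid vertex noise SD, mm
#' @param mafRange minor-allele-frequency range for simulated SNPs
#' @param ageRange,sexRatio covariate distributions (uniform age; P(sex=1))
#' @param seed mandatory integer seed: all randomness flows from it
#' @return a `cohortConfig` list
#' @export
cohortConfig <- function(nSubjects, nSNPs = 0, causalSNP = 1,
                         causalEffect = 0, amplitudeMean = 0,
                         amplitudeSD = 0.8,
                         asymmetryModel = c("field", "bump"),
                         regionCenters = c("pronasale", "nasion",
                                           "labiale_superius", "pogonion"),
                         regionRadius = 14, baselineFields = 6,
                         baselineSD = 0.25, noiseSD = 0.02,
                         mafRange = c(0.05, 0.5), ageRange = c(3, 40),
                         sexRatio = 0.5, seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  asymmetryModel <- match.arg(asymmetryModel)
  stopifnot(nSubjects >= 1, nSNPs >= 0, amplitudeSD >= 0, regionRadius > 0,
            causalSNP >= 1, noiseSD >= 0, baselineFields >= 0,
            baselineSD >= 0)
  structure(list(nSubjects = as.integer(nSubjects),
                 asymmetryModel = asymmetryModel,
                 nSNPs = as.integer(nSNPs),
                 causalSNP = as.integer(causalSNP),
                 causalEffect = causalEffect,
                 amplitudeMean = amplitudeMean, amplitudeSD = amplitudeSD,
                 regionCenters = regionCenters,
                 regionRadius = regionRadius,
                 baselineFields = as.integer(baselineFields),
                 baselineSD = baselineSD, noiseSD = noiseSD,
                 mafRange = mafRange, ageRange = ageRange,
                 sexRatio = sexRatio, seed = as.integer(seed)),
            class = "cohortConfig")
}

#' Simulate a synthetic cohort
#'
#' Draws per-subject asymmetry amplitudes (base truncated-Normal plus the
#' causal-SNP allele effect), injects a one-sided bump of that amplitude
#' at a randomly chosen region and side, and simulates an independent SNP
#' panel (binomial with per-SNP MAF ~ Uniform over `mafRange`), ages and
#' sexes. The true amplitude vector is returned for recovery tests.
#'
#' @param config a [cohortConfig()]
#' @param template a template from [makeTemplate()]; required when
#'   `makeMeshes = TRUE`
#' @param makeMeshes if `FALSE`, only genotypes/covariates/amplitudes are
#'   generated (association-scale cohorts)
#' @return list with `subjects` (ids), `genotypes` (or NULL), `snpInfo`,
#'   `covariates` (subject_id, age, sex), `truth` (subject_id, amplitude,
#'   region, side), `meshes` and `landmarks` (lists, when
#'   `makeMeshes = TRUE`), and `config`
#' @export
simulateCohort <- function(config, template = NULL, makeMeshes = TRUE) {
  stopifnot(inherits(config, "cohortConfig"))
  if (makeMeshes && is.null(template))
    stop("a template is required to simulate meshes")
  withSeed(config$seed, {
    n <- config$nSubjects
    ids <- sprintf("S%03d", seq_len(n))
    G <- NULL; snpInfo <- NULL
    gCausal <- rep(0, n)
    if (config$nSNPs > 0) {
      maf <- stats::runif(config$nSNPs, config$mafRange[1],
                          config$mafRange[2])
      G <- vapply(maf, function(m) stats::rbinom(n, 2, m), numeric(n))
      dimnames(G) <- list(ids, sprintf("snp%04d", seq_len(config$nSNPs)))
      gCausal <- G[, config$causalSNP]
      snpInfo <- data.frame(snp = colnames(G),
                            chr = rep_len(1:22, config$nSNPs),
                            pos = seq_len(config$nSNPs) * 1000L)
    }
    ## folded-normal base: asymmetry magnitudes are right-skewed in real
    ## cohorts (most faces near-symmetric, a tail of strong asymmetry),
    ## and the abnormality score is monotone in amplitude only when the
    ## cohort norm sits at the low end
    amplitude <- abs(stats::rnorm(n, config$amplitudeMean,
                                  config$amplitudeSD)) +
      config$causalEffect * gCausal
    region <- sample(config$regionCenters, n, replace = TRUE)
    side <- sample(c("left", "right"), n, replace = TRUE)
    centers <- NULL
    if (config$asymmetryModel == "field") {
      region <- rep("field", n)
      side <- rep(NA_character_, n)
    } else if (identical(config$regionCenters, "random") && makeMeshes) {
      centers <- .sampleRegionCenters(template, n, side, config$regionRadius)
    }
    age <- stats::runif(n, config$ageRange[1], config$ageRange[2])
    sex <- stats::rbinom(n, 1, config$sexRatio)
    meshes <- NULL; lms <- NULL
    if (makeMeshes) {
      meshes <- vector("list", n)
      lms <- vector("list", n)
      for (i in seq_len(n)) {
        if (config$asymmetryModel == "field") {
          out <- .fieldAsymmetry(template, amplitude[i],
                                 max(1L, config$baselineFields))
          if (config$noiseSD > 0) {
            V <- out$mesh@vertices +
              matrix(stats::rnorm(3 * nrow(out$mesh@vertices), 0,
                                  config$noiseSD),
                     ncol = 3)
            out$mesh <- SurfaceMesh(V, out$mesh@faces)
          }
        } else {
          base <- .baselineAsymmetry(template, config$baselineFields,
                                     config$baselineSD)
          ctr <- if (is.null(centers)) region[i] else centers[i, ]
          spec <- asymmetrySpec(ctr, radius = config$regionRadius,
                                kind = "normal_bump",
                                amplitude = amplitude[i], side = side[i])
          out <- injectAsymmetry(base$mesh, base$landmarks, spec,
                                 noiseSD = config$noiseSD,
                                 returnLandmarks = TRUE)
        }
        meshes[[i]] <- out$mesh
        lms[[i]] <- out$landmarks
      }
      names(meshes) <- names(lms) <- ids
    }
    list(subjects = ids, genotypes = G, snpInfo = snpInfo,
         covariates = data.frame(subject_id = ids, age = age, sex = sex),
         truth = {
           tr <- data.frame(subject_id = ids, amplitude = amplitude,
                            region = region, side = side)
           if (!is.null(centers)) {
             tr$center_x <- centers[, 1]
             tr$center_y <- centers[, 2]
             tr$center_z <- centers[, 3]
           }
           tr
         },
         meshes = meshes, landmarks = lms, config = config)
  })
}

#' Write a simulated cohort to a directory
#'
#' Lays out `meshes/*.ply`, `landmarks/*.csv`, `genotypes.tsv`,
#' `covariates.tsv`, `truth.tsv` and `config.json`.
#'
#' @param cohort a cohort from [simulateCohort()]
#' @param dir output directory (created if needed)
#' @return invisibly, `dir`
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(cohort$meshes)) {
    dir.create(file.path(dir, "meshes"), showWarnings = FALSE)
    dir.create(file.path(dir, "landmarks"), showWarnings = FALSE)
    for (id in cohort$subjects) {
      writeMesh(cohort$meshes[[id]],
                file.path(dir, "meshes", paste0(id, ".ply")))
      writeLandmarks(cohort$landmarks[[id]],
                     file.path(dir, "landmarks", paste0(id, ".csv")))
    }
  }
  if (!is.null(cohort$genotypes))
    writeGenotypesTSV(cohort$genotypes, file.path(dir, "genotypes.tsv"))
  utils::write.table(cohort$covariates, file.path(dir, "covariates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- unclass(cohort$config)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
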