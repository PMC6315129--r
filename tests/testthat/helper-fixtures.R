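# Fixture builders: small meshes and landmark sets constructed in code.

# Rectangular height-field grid mesh (nx x ny vertices).
gridMesh <- function(nx = 10, ny = 10, xlim = c(0, 1), ylim = c(0, 1),
                     heightFn = function(x, y) rep(0, length(x))) {
  xs <- seq(xlim[1], xlim[2], length.out = nx)
  ys <- seq(ylim[1], ylim[2], length.out = ny)
  V <- cbind(rep(xs, times = ny), rep(ys, each = nx), 0)
  V[, 3] <- heightFn(V[, 1], V[, 2])
  idx <- function(i, j) (j - 1L) * nx + i
  f <- list()
  for (j in seq_len(ny - 1)) for (i in seq_len(nx - 1)) {
    f[[length(f) + 1]] <- rbind(
      c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
      c(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
  }
  SurfaceMesh(V, do.call(rbind, f))
}

# Icosphere: subdivided icosahedron projected to the unit sphere.
icoSphere <- function(subdiv = 2) {
  t <- (1 + sqrt(5)) / 2
  V <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  F <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid <- new.env()
    key <- function(a, b) paste(min(a, b), max(a, b))
    midpoint <- function(a, b) {
      k <- key(a, b)
      if (!is.null(mid[[k]])) return(mid[[k]])
      p <- (V[a, ] + V[b, ]) / 2
      p <- p / sqrt(sum(p^2))
      V <<- rbind(V, p)
      mid[[k]] <- nrow(V)
      nrow(V)
    }
    F2 <- matrix(0L, 0, 3)
    for (r in seq_len(nrow(F))) {
      a <- F[r, 1]; b <- F[r, 2]; c <- F[r, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      F2 <- rbind(F2, c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
    }
    F <- F2
  }
  SurfaceMesh(V, F)
}

# Open tetrahedron-like fixture: 4 vertices, 4 faces (closed tetrahedron),
# outward winding.
tetraMesh <- function() {
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  F <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  SurfaceMesh(V, F)
}

# Small synthetic landmark set: a symmetric 8-landmark configuration.
symmetricLandmarks <- function(jitter = 0) {
  p <- rbind(nasion = c(0, 35, 30), pronasale = c(0, 3, 40),
             pogonion = c(0, -52, 25), subnasale = c(0, -8, 33),
             endocanthion_l = c(12, 30, 28), endocanthion_r = c(-12, 30, 28),
             cheilion_l = c(17, -23, 28), cheilion_r = c(-17, -23, 28))
  if (jitter > 0) p <- p + matrix(rnorm(length(p), 0, jitter), nrow(p))
  LandmarkSet(p,
              pairs = rbind(c("endocanthion_l", "endocanthion_r"),
                            c("cheilion_l", "cheilion_r")),
              midline = c("nasion", "pronasale", "pogonion", "subnasale"))
}

# Rotation matrix about the y axis.
rotY <- function(deg) {
  a <- deg * pi / 180
  rbind(c(cos(a), 0, sin(a)), c(0, 1, 0), c(-sin(a), 0, cos(a)))
}

# Shared low-resolution template (built once per test run).
.tplCache <- new.env()
testTemplate <- function(resolution = 20) {
  k <- as.character(resolution)
  if (is.null(.tplCache[[k]])) .tplCache[[k]] <- makeTemplate(resolution)
  .tplCache[[k]]
}
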