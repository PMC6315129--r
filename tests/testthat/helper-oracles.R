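# Independent brute-force oracles. These share no code with the package:
# plain loops and first-principles formulas only.

# Adjacency list from a face matrix.
bfAdjacency <- function(faces, nVert) {
  adj <- vector("list", nVert)
  for (r in seq_len(nrow(faces))) {
    tri <- faces[r, ]
    for (e in list(tri[1:2], tri[2:3], tri[c(3, 1)])) {
      adj[[e[1]]] <- c(adj[[e[1]]], e[2])
      adj[[e[2]]] <- c(adj[[e[2]]], e[1])
    }
  }
  lapply(adj, unique)
}

# Connected components of a vertex subset by BFS.
bfComponents <- function(pts, adj) {
  pts <- sort(pts)
  inSet <- logical(length(adj))
  inSet[pts] <- TRUE
  seen <- logical(length(adj))
  comps <- list()
  for (p in pts) {
    if (seen[p]) next
    queue <- p
    seen[p] <- TRUE
    comp <- integer()
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      for (w in adj[[v]]) {
        if (inSet[w] && !seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

# Bin index with [e_k, e_{k+1}) bins, last bin closed.
bfBin <- function(v, edges) {
  B <- length(edges) - 1
  for (b in seq_len(B)) {
    if (v >= edges[b] && (v < edges[b + 1] || (b == B && v <= edges[b + 1])))
      return(b)
  }
  stop("value out of range")
}

# Full spatiogram score from first principles: histogram both maps, find
# coherent regions per bin by BFS, compute the region-size-weighted mean
# standardized error per bin, the directed distances with the frequency
# dissimilarity factor, and average the two directions.
bfSpatiogramScore <- function(mapA, mapB, sigma, edges, faces, nVert,
                              tau = 20, variant = "bhattacharyya") {
  adj <- bfAdjacency(faces, nVert)
  B <- length(edges) - 1
  directed <- function(m1, m2) {
    bins1 <- lapply(seq_len(B), function(b) integer())
    bins2 <- lapply(seq_len(B), function(b) integer())
    for (i in seq_along(m1)) {
      b <- bfBin(m1[i], edges); bins1[[b]] <- c(bins1[[b]], i)
      b2 <- bfBin(m2[i], edges); bins2[[b2]] <- c(bins2[[b2]], i)
    }
    n1 <- vapply(bins1, length, integer(1))
    n2 <- vapply(bins2, length, integer(1))
    d <- 0
    for (b in seq_len(B)) {
      comps <- bfComponents(bins1[[b]], adj)
      coh <- comps[vapply(comps, length, integer(1)) >= tau]
      psi <- 0
      if (length(coh)) {
        tot <- sum(vapply(coh, length, integer(1)))
        for (r in coh) {
          err <- 0
          for (j in r) err <- err + abs(m1[j] - m2[j]) / sigma[j]
          psi <- psi + (length(r) / tot) * (err / length(r))
        }
      }
      p1 <- n1[b] / length(m1); p2 <- n2[b] / length(m2)
      fac <- if (variant == "bhattacharyya") 1 - sqrt(p1 * p2)
             else if (max(p1, p2) > 0) 1 - min(p1, p2) / max(p1, p2) else 0
      d <- d + psi * fac
    }
    d
  }
  (directed(mapA, mapB) + directed(mapB, mapA)) / 2
}

# Closest point on one triangle: plane projection with inside test, else the
# best of the three clamped edge projections (independent of the package's
# Voronoi-region method).
bfClosestOnTriangle <- function(p, a, b, c) {
  u <- b - a; w <- c - a
  n <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
         u[1] * w[2] - u[2] * w[1])
  candidates <- list()
  if (sum(n^2) > 0) {
    n <- n / sqrt(sum(n^2))
    q <- p - sum((p - a) * n) * n
    M <- cbind(b - a, c - a)
    uv <- qr.solve(crossprod(M), crossprod(M, q - a))
    if (uv[1] >= 0 && uv[2] >= 0 && sum(uv) <= 1)
      candidates <- c(candidates, list(q))
  }
  seg <- function(p, s, t) {
    d <- t - s
    u <- sum((p - s) * d) / sum(d * d)
    s + min(1, max(0, u)) * d
  }
  candidates <- c(candidates, list(seg(p, a, b), seg(p, b, c), seg(p, c, a)))
  d2 <- vapply(candidates, function(q) sum((p - q)^2), numeric(1))
  candidates[[which.min(d2)]]
}

bfProject <- function(points, V, F) {
  t(apply(points, 1, function(p) {
    best <- NULL; bestD <- Inf
    for (r in seq_len(nrow(F))) {
      q <- bfClosestOnTriangle(p, V[F[r, 1], ], V[F[r, 2], ], V[F[r, 3], ])
      d <- sum((p - q)^2)
      if (d < bestD) { bestD <- d; best <- q }
    }
    best
  }))
}

# OLS from the normal equations.
bfOLS <- function(X, y) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  se <- unname(sqrt(s2 * diag(solve(XtX))))
  tv <- as.numeric(beta) / se
  list(beta = as.numeric(beta), se = se, t = tv,
       p = 2 * pt(-abs(tv), df))
}

# Benjamini-Hochberg step-up from the definition.
bfBH <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}
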