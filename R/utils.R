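## Internal helpers.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's global RNG afterwards. seed = NULL leaves the RNG stream alone.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Pairwise Euclidean distances between rows of A and rows of B.
rowDist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

rowNorms <- function(x) sqrt(rowSums(x^2))

# Row-normalize, erroring on (near-)zero rows.
normalizeRows <- function(x, what = "vector") {
  len <- rowNorms(x)
  if (any(len < 1e-12)) stop("zero-length ", what, " cannot be normalized")
  x / len
}

clampUnit <- function(x) pmin(1, pmax(-1, x))

asPointMatrix <- function(x) {
  if (is(x, "LandmarkSet")) return(x@points)
  if (is(x, "SurfaceMesh")) return(x@vertices)
  if (is.numeric(x) && is.null(dim(x)) && length(x) == 3) return(matrix(x, 1))
  if (!is.matrix(x) || ncol(x) != 3) stop("expected a 3-column point matrix")
  x
}
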