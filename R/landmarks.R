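#' Construct a LandmarkSet
#'
#' @param points named numeric matrix (k x 3) or data.frame with landmark
#'   names as rownames, coordinates in mm
#' @param pairs two-column character matrix (or list of length-2 vectors) of
#'   (left, right) landmark name pairs
#' @param midline character vector of unpaired midline landmark names
#' @return a [LandmarkSet-class]
#' @export
LandmarkSet <- function(points, pairs = NULL, midline = character()) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (is.null(pairs)) pairs <- matrix(character(), 0, 2)
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  pairs <- as.matrix(pairs)
  colnames(pairs) <- NULL
  new("LandmarkSet", points = points, pairs = pairs,
      midline = as.character(midline))
}

#' The default 18-landmark schema
#'
#' Standard anthropometric naming: 6 midline landmarks and 6 bilateral
#' pairs (`*_l` on the subject's left, at x > 0 in the aligned frame).
#' Shipped as package data (`inst/extdata/landmark_schema_18.json`) and
#' user-overridable; the pairing drives mirroring, the landmark-based
#' baseline and the below-eyes crop.
#'
#' @param path optional path to an alternative JSON schema with fields
#'   `midline` and `pairs`
#' @return `list(midline = character, pairs = 2-column character matrix)`
#' @export
defaultLandmarkSchema <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "landmark_schema_18.json",
                        package = "facesym", mustWork = TRUE)
  schema <- jsonlite::fromJSON(path)
  pairs <- as.matrix(schema$pairs)
  colnames(pairs) <- NULL
  list(midline = as.character(schema$midline), pairs = pairs)
}

#' Read landmarks from CSV
#'
#' Expects columns `name,x,y,z` (mm). Pairing defaults to the shipped
#' 18-landmark schema, restricted to the names present.
#'
#' @param path CSV file path
#' @param schema a schema list as from [defaultLandmarkSchema()]
#' @return a [LandmarkSet-class]
#' @export
readLandmarks <- function(path, schema = defaultLandmarkSchema()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("landmark CSV must have columns name,x,y,z")
  p <- as.matrix(df[, c("x", "y", "z")])
  rownames(p) <- df$name
  keepPairs <- schema$pairs[schema$pairs[, 1] %in% df$name &
                            schema$pairs[, 2] %in% df$name, , drop = FALSE]
  LandmarkSet(p, pairs = keepPairs,
              midline = intersect(schema$midline, df$name))
}

#' Write landmarks to CSV (columns name,x,y,z)
#'
#' @param landmarks a [LandmarkSet-class]
#' @param path output CSV path
#' @return invisibly, `path`
#' @export
writeLandmarks <- function(landmarks, path) {
  stopifnot(is(landmarks, "LandmarkSet"))
  p <- landmarks@points
  utils::write.csv(data.frame(name = rownames(p), x = p[, 1], y = p[, 2],
                              z = p[, 3], row.names = NULL),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
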