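#' Read a triangulated mesh from OBJ or PLY (ASCII)
#'
#' Minimal readers for the two interchange formats facial scans ship in.
#' Only triangular faces are accepted; vertex positions are read at full
#' printed precision.
#'
#' @param path file path ending in `.obj` or `.ply`
#' @return a [SurfaceMesh-class]
#' @export
readMesh <- function(path) {
  if (!file.exists(path)) stop("cannot read mesh: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         obj = .readOBJ(path),
         ply = .readPLY(path),
         stop("unsupported mesh format: .", ext, " (expected .obj or .ply)"))
}

#' Write a mesh to OBJ or PLY (ASCII)
#'
#' @param mesh a [SurfaceMesh-class]
#' @param path output path; the extension selects the format
#' @return invisibly, `path`
#' @export
writeMesh <- function(mesh, path) {
  stopifnot(is(mesh, "SurfaceMesh"))
  ext <- tolower(tools::file_ext(path))
  fmt <- function(x) sprintf("%.10g", x)
  v <- mesh@vertices; f <- mesh@faces
  if (ext == "obj") {
    lines <- c(paste("v", fmt(v[, 1]), fmt(v[, 2]), fmt(v[, 3])),
               paste("f", f[, 1], f[, 2], f[, 3]))
  } else if (ext == "ply") {
    lines <- c("ply", "format ascii 1.0",
               paste("element vertex", nrow(v)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(f)),
               "property list uchar int vertex_indices",
               "end_header",
               paste(fmt(v[, 1]), fmt(v[, 2]), fmt(v[, 3])),
               paste(3, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L))
  } else {
    stop("unsupported mesh format: .", ext, " (expected .obj or .ply)")
  }
  writeLines(lines, path)
  invisible(path)
}

.readOBJ <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  if (!length(vlines) || !length(flines))
    stop("not a valid OBJ mesh (no vertices or no faces): ", path)
  v <- do.call(rbind, lapply(strsplit(vlines, "[[:space:]]+"), function(x) {
    as.numeric(x[2:4])
  }))
  f <- lapply(strsplit(flines, "[[:space:]]+"), function(x) {
    idx <- x[-1]
    if (length(idx) != 3)
      stop("non-triangular face (", length(idx), " vertices) in OBJ file")
    # face entries may be v, v/vt, v/vt/vn or v//vn; the leading int is the
    # vertex index
    as.integer(vapply(strsplit(idx, "/", fixed = TRUE), `[`, "", 1))
  })
  SurfaceMesh(v, do.call(rbind, f))
}

.readPLY <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || trimws(lines[1]) != "ply")
    stop("not a PLY file: ", path)
  endHdr <- match("end_header", trimws(lines))
  if (is.na(endHdr)) stop("malformed PLY header (no end_header): ", path)
  hdr <- trimws(lines[seq_len(endHdr)])
  if (!any(grepl("^format[[:space:]]+ascii", hdr)))
    stop("only ASCII PLY is supported: ", path)
  nv <- as.integer(sub("^element[[:space:]]+vertex[[:space:]]+", "",
                       grep("^element[[:space:]]+vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("^element[[:space:]]+face[[:space:]]+", "",
                       grep("^element[[:space:]]+face", hdr, value = TRUE)))
  if (!length(nv) || !length(nf)) stop("PLY header lacks vertex/face counts")
  body <- trimws(lines[(endHdr + 1):length(lines)])
  body <- body[nzchar(body)]
  if (length(body) < nv + nf) stop("truncated PLY body: ", path)
  vtok <- strsplit(body[seq_len(nv)], "[[:space:]]+")
  v <- do.call(rbind, lapply(vtok, function(x) as.numeric(x[1:3])))
  ftok <- strsplit(body[nv + seq_len(nf)], "[[:space:]]+")
  f <- lapply(ftok, function(x) {
    k <- as.integer(x[1])
    if (k != 3) stop("non-triangular face (", k, " vertices) in PLY file")
    as.integer(x[2:4]) + 1L
  })
  SurfaceMesh(v, do.call(rbind, f))
}

#' Write a per-vertex scalar field as an ASCII PLY with a quality property
#'
#' Heat-map export for external 3D viewers: vertex positions plus one scalar
#' (`quality`) per vertex, e.g. a feature heat map on the cropped mesh.
#'
#' @param mesh a [SurfaceMesh-class]
#' @param values numeric vector, one value per vertex
#' @param path output `.ply` path
#' @return invisibly, `path`
#' @export
writeHeatMapPLY <- function(mesh, values, path) {
  stopifnot(is(mesh, "SurfaceMesh"), length(values) == nrow(mesh@vertices))
  fmt <- function(x) sprintf("%.10g", x)
  v <- mesh@vertices; f <- mesh@faces
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(v)),
               "property float x", "property float y", "property float z",
               "property float quality",
               paste("element face", nrow(f)),
               "property list uchar int vertex_indices",
               "end_header",
               paste(fmt(v[, 1]), fmt(v[, 2]), fmt(v[, 3]), fmt(values)),
               paste(3, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)),
             path)
  invisible(path)
}
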