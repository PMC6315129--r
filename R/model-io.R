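#' Serialize a normal-asymmetry model to a single JSON archive
#'
#' Stores the cropped average mesh (vertices/faces), the per-point mean
#' and SD arrays, the feature name, the cohort size and a configuration
#' fingerprint in one structured text file.
#'
#' @param model a [NormalAsymmetryModel-class]
#' @param path output `.json` path
#' @param config optional named list recorded as the model's configuration
#'   fingerprint (bins, tau, variant, ...)
#' @return invisibly, `path`
#' @export
writeNormalModel <- function(model, path, config = list()) {
  stopifnot(is(model, "NormalAsymmetryModel"))
  obj <- list(format = "facesym-normal-model", version = 1L,
              feature = model@feature, n = model@n,
              mu = model@mu, sigma = model@sigma,
              vertices = model@mesh@vertices, faces = model@mesh@faces,
              config = config)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a normal-asymmetry model archive
#'
#' @param path path written by [writeNormalModel()]
#' @return `list(model = NormalAsymmetryModel, config = list)`
#' @export
readNormalModel <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (!identical(obj$format, "facesym-normal-model"))
    stop("not a facesym normal-model archive: ", path)
  mesh <- SurfaceMesh(obj$vertices, obj$faces)
  model <- new("NormalAsymmetryModel", mesh = mesh, feature = obj$feature,
               mu = as.numeric(obj$mu), sigma = as.numeric(obj$sigma),
               n = as.integer(obj$n))
  list(model = model, config = as.list(obj$config))
}

#' Write a feature heat map as a two-column table
#'
#' Columns `point_index`, `value`.
#'
#' @param heatMap a [FeatureHeatMap-class]
#' @param path output TSV path
#' @return invisibly, `path`
#' @export
writeHeatMap <- function(heatMap, path) {
  stopifnot(is(heatMap, "FeatureHeatMap"))
  v <- featureValues(heatMap)
  utils::write.table(data.frame(point_index = seq_along(v), value = v),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
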