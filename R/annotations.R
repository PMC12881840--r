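#' Region annotations for one slide
#'
#' Holds the manually segmented tumor and artifact polygons of a slide in
#' pixel coordinates (0-based, origin top-left). Polygons are stored as
#' closed-ring n x 2 matrices; the first and last vertex may but need not
#' coincide.
#'
#' @param slide_id Slide identifier.
#' @param tumor list of n x 2 coordinate matrices.
#' @param artifact list of n x 2 coordinate matrices.
#' @return A `net_annotation` object.
#' @export
region_annotation <- function(slide_id, tumor = list(), artifact = list()) {
  check_poly <- function(p, what) {
    p <- as.matrix(p)
    storage.mode(p) <- "double"
    if (ncol(p) != 2 || nrow(p) < 3)
      stop(what, " polygon must be an n x 2 matrix with n >= 3")
    if (!all(is.finite(p)) || any(p < 0))
      stop(what, " polygon coordinates must be finite and non-negative")
    # drop an explicit closing vertex
    if (all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
    if (nrow(p) < 3) stop(what, " polygon degenerate after closing-vertex removal")
    if (.poly_self_intersects(p))
      stop(what, " polygon is self-intersecting")
    p
  }
  structure(
    list(slide_id = as.character(slide_id),
         tumor = lapply(tumor, check_poly, what = "tumor"),
         artifact = lapply(artifact, check_poly, what = "artifact")),
    class = "net_annotation")
}

#' Read slide annotations from GeoJSON
#'
#' Parses a GeoJSON FeatureCollection in the dialect exported by QuPath-style
#' annotation tools: each feature carries `properties.classification.name`
#' equal to `"Tumor"` or `"Artifact"`. Features without a classification are
#' skipped with a warning; classified features with a non-polygon geometry are
#' an error. MultiPolygon parts are split into individual polygons (exterior
#' rings only; interior rings are not supported and raise an error).
#'
#' @param path Path to a `.geojson` file.
#' @param slide_id Slide identifier to attach; defaults to the file name
#'   without extension.
#' @return A `net_annotation`.
#' @export
read_annotations <- function(path, slide_id = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (is.null(slide_id))
    slide_id <- sub("\\.[^.]*$", "", basename(path))
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("expected a GeoJSON FeatureCollection: ", path)

  ring_to_matrix <- function(ring)
    do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
  polys_of <- function(geom) {
    if (geom$type == "Polygon") {
      if (length(geom$coordinates) > 1)
        stop("polygon interior rings (holes) are not supported")
      list(ring_to_matrix(geom$coordinates[[1]]))
    } else if (geom$type == "MultiPolygon") {
      lapply(geom$coordinates, function(p) {
        if (length(p) > 1) stop("polygon interior rings (holes) are not supported")
        ring_to_matrix(p[[1]])
      })
    } else {
      stop("classified feature has non-polygon geometry '", geom$type, "'")
    }
  }

  tumor <- list(); artifact <- list(); n_skipped <- 0L
  for (feat in gj$features) {
    cls <- feat$properties$classification$name
    if (is.null(cls)) cls <- feat$properties$classification  # plain-string dialect
    if (is.null(cls) || !is.character(cls)) {
      n_skipped <- n_skipped + 1L
      next
    }
    if (cls == "Tumor") {
      tumor <- c(tumor, polys_of(feat$geometry))
    } else if (cls == "Artifact") {
      artifact <- c(artifact, polys_of(feat$geometry))
    } else {
      n_skipped <- n_skipped + 1L
    }
  }
  if (n_skipped > 0)
    warning(sprintf("%s: skipped %d feature(s) without a Tumor/Artifact classification",
                    basename(path), n_skipped))
  region_annotation(slide_id, tumor = tumor, artifact = artifact)
}

#' Write slide annotations to GeoJSON
#'
#' Inverse of [read_annotations()]; emits a FeatureCollection with
#' `properties.classification.name` set to Tumor/Artifact.
#'
#' @param ann A `net_annotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "net_annotation"))
  feat <- function(poly, cls) {
    ring <- rbind(poly, poly[1, ])  # close the ring
    list(type = "Feature",
         geometry = list(
           type = "Polygon",
           coordinates = list(lapply(seq_len(nrow(ring)),
                                     function(i) as.list(unname(ring[i, ]))))),
         properties = list(classification = list(name = cls)))
  }
  fc <- list(type = "FeatureCollection",
             features = c(lapply(ann$tumor, feat, cls = "Tumor"),
                          lapply(ann$artifact, feat, cls = "Artifact")))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.net_annotation <- function(x, ...) {
  cat(sprintf("<net_annotation> slide %s: %d tumor, %d artifact polygon(s)\n",
              x$slide_id, length(x$tumor), length(x$artifact)))
  invisible(x)
}
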