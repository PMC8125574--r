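#' @rdname TriMesh-class
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return A \linkS4class{TriMesh}.
#' @export
TriMesh <- function(vertices, faces) {
  new("TriMesh", vertices = unname(as.matrix(vertices)),
      faces = unname(matrix(as.integer(as.matrix(faces)), ncol = 3L)))
}

#' @rdname LandmarkSet-class
#' @param points 6 x 3 numeric matrix with rownames equal to the landmark
#'   keys, or a named list of length-3 points.
#' @param side "left" or "right" (case-insensitive).
#' @return A \linkS4class{LandmarkSet}.
#' @export
LandmarkSet <- function(points, side) {
  if (is.list(points)) {
    missing <- setdiff(LANDMARK_NAMES, names(points))
    if (length(missing))
      stopSchema(paste0("missing landmark key(s): ", paste(missing, collapse = ", ")))
    points <- do.call(rbind, lapply(LANDMARK_NAMES, function(k) as.numeric(points[[k]])))
  }
  points <- as.matrix(points)
  rownames(points) <- LANDMARK_NAMES
  new("LandmarkSet", points = points, side = tolower(as.character(side)))
}

#' Accessors for mesh and landmark objects
#'
#' @param x a \linkS4class{TriMesh} or \linkS4class{LandmarkSet}.
#' @param name a landmark key, e.g. \code{"knee_center"}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))
#' @rdname accessors
#' @export
setMethod("meshVertices", "TriMesh", function(x) x@vertices)

#' @rdname accessors
#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))
#' @rdname accessors
#' @export
setMethod("meshFaces", "TriMesh", function(x) x@faces)

#' @rdname accessors
#' @export
setGeneric("landmark", function(x, name) standardGeneric("landmark"))
#' @rdname accessors
#' @export
setMethod("landmark", "LandmarkSet", function(x, name) {
  if (!name %in% LANDMARK_NAMES) stopSchema(paste0("unknown landmark key: ", name))
  x@points[name, ]
})

#' @rdname accessors
#' @export
setGeneric("kneeSide", function(x) standardGeneric("kneeSide"))
#' @rdname accessors
#' @export
setMethod("kneeSide", "LandmarkSet", function(x) x@side)

setMethod("show", "TriMesh", function(object) {
  cat(sprintf("TriMesh: %d vertices, %d faces\n",
              nrow(object@vertices), nrow(object@faces)))
  bb <- apply(object@vertices, 2L, range)
  cat(sprintf("  bounding box [mm]: x %.1f..%.1f  y %.1f..%.1f  z %.1f..%.1f\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
})

setMethod("show", "LandmarkSet", function(object) {
  cat(sprintf("LandmarkSet (%s knee):\n", object@side))
  print(round(object@points, 2))
})

setMethod("show", "KneeFrame", function(object) {
  cat(sprintf("KneeFrame at (%.1f, %.1f, %.1f) mm, %s-handed\n",
              object@origin[1], object@origin[2], object@origin[3],
              if (object@handedness > 0) "right" else "left"))
})

setMethod("show", "RotationAxis", function(object) {
  cat(sprintf("%s axis: direction (%.3f, %.3f, %.3f)\n", object@kind,
              object@direction[1], object@direction[2], object@direction[3]))
})

setMethod("show", "CircleFit", function(object) {
  cat(sprintf("CircleFit: center (%.2f, %.2f), radius %.2f mm, rms residual %.3f mm\n",
              object@center[1], object@center[2], object@radius, object@residual))
})

setMethod("show", "CutResult", function(object) {
  cat(sprintf("CutResult: %d anterior loop(s), %d distal loop(s)\n",
              length(object@anteriorSection), length(object@distalSection)))
})

setMethod("show", "FemurParams", function(object) {
  cat(sprintf("FemurParams (%s, %s side, seed %d):\n", object@archetype,
              object@side, as.integer(object@seed)))
  cat(sprintf("  ML width %.1f mm, AP depth %.1f mm, condylar radii %.1f/%.1f mm (med/lat)\n",
              object@mlWidth, object@apDepth, object@rCondMed, object@rCondLat))
  cat(sprintf("  anterior facet heights %.1f/%.1f mm (med/lat), noise %.2f mm\n",
              object@hAntMed, object@hAntLat, object@noiseAmplitude))
})
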