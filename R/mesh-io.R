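# Mesh and landmark file I/O. STL (ASCII and binary) and PLY (ASCII) are
# read/written directly: meshes are plain triangle soups / vertex-face lists
# and both formats are trivial containers. Units are millimetres throughout;
# a mesh whose bounding box exceeds 1000 (metre-scale input) is rejected.

#' Read a triangle mesh from an STL or PLY file
#'
#' The format is chosen from the file extension (\code{.stl}, \code{.ply});
#' both ASCII and binary STL are supported, PLY is read in ASCII form. STL
#' triangle soups are welded into an indexed mesh by exact vertex
#' coordinates. Meshes are expected in millimetres: a bounding-box extent
#' above 1000 raises an error with a unit hint.
#'
#' @param path file path.
#' @return A \linkS4class{TriMesh}.
#' @export
loadMesh <- function(path) {
  if (!file.exists(path)) stopSchema(paste0("mesh file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  mesh <- switch(ext,
                 stl = readSTL(path),
                 ply = readPLY(path),
                 stopSchema(paste0("unsupported mesh format '.", ext, "' (need STL or PLY)")))
  ext_mm <- max(apply(meshVertices(mesh), 2L, function(v) diff(range(v))))
  if (ext_mm > 1000)
    stopSchema("mesh bounding box exceeds 1000 units; expected millimetres (is this mesh in metres or micrometres?)")
  if (!meshIsClosed(mesh))
    warning("mesh is not watertight; plane sectioning will bridge small gaps", call. = FALSE)
  mesh
}

#' Write a triangle mesh to an STL or PLY file
#'
#' @param mesh a \linkS4class{TriMesh}.
#' @param path output path ending in \code{.stl} or \code{.ply}.
#' @param binary write binary STL (ignored for PLY, which is written ASCII).
#' @return \code{path}, invisibly.
#' @export
writeMesh <- function(mesh, path, binary = TRUE) {
  stopifnot(is(mesh, "TriMesh"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = writeSTL(mesh, path, binary = binary),
         ply = writePLY(mesh, path),
         stopSchema(paste0("unsupported mesh format '.", ext, "' (need STL or PLY)")))
  invisible(path)
}

## Weld a triangle soup (3m x 3 vertex rows, consecutive triples) into an
## indexed mesh by exact coordinate match. Vertices that collapse (e.g.
## through float32 rounding in binary STL) leave degenerate triangles,
## which are dropped; collapsing a zero-length edge this way keeps the
## surface closed.
weldSoup <- function(tri) {
  key <- paste(tri[, 1L], tri[, 2L], tri[, 3L], sep = "|")
  idx <- match(key, key)
  keep <- !duplicated(idx)
  remap <- cumsum(keep)[idx]
  f <- matrix(remap, ncol = 3L, byrow = TRUE)
  ok <- f[, 1L] != f[, 2L] & f[, 2L] != f[, 3L] & f[, 1L] != f[, 3L]
  TriMesh(tri[keep, , drop = FALSE], f[ok, , drop = FALSE])
}

readSTL <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", 80L)
  if (length(head) < 80L) stopSchema("truncated STL file")
  ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  sz <- file.size(path)
  if (length(ntri) == 1L && !is.na(ntri) && ntri > 0 && sz == 84 + 50 * ntri) {
    raw <- readBin(con, "raw", 50L * ntri)
    if (length(raw) < 50L * ntri) stopSchema("truncated binary STL file")
    m <- matrix(raw, nrow = 50L)
    flt <- readBin(as.vector(m[1:48, ]), "numeric", size = 4L, n = 12L * ntri,
                   endian = "little")
    flt <- matrix(flt, nrow = 12L)        # per-triangle: normal + 3 vertices
    tri <- matrix(as.vector(flt[4:12, ]), ncol = 3L, byrow = TRUE)
    return(weldSoup(tri))
  }
  ## fall back to ASCII
  txt <- readLines(path, warn = FALSE)
  if (!length(txt) || !grepl("^\\s*solid", txt[1L]))
    stopSchema("unreadable STL file (neither valid binary nor ASCII)")
  vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
  if (!length(vl) || length(vl) %% 3L != 0L ||
      !any(grepl("^\\s*endsolid", txt)))
    stopSchema("truncated or malformed ASCII STL file")
  nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                function(x) as.numeric(x[2:4])))
  if (any(!is.finite(nums))) stopSchema("non-numeric vertex in ASCII STL file")
  weldSoup(nums)
}

writeSTL <- function(mesh, path, binary = TRUE) {
  v <- meshVertices(mesh); f <- meshFaces(mesh)
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  d <- v[f[, 3L], , drop = FALSE]
  e1 <- b - a; e2 <- d - a
  n <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
             e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
             e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  len <- sqrt(rowSums(n * n)); len[len == 0] <- 1
  n <- n / len
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80L)), con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    block <- t(cbind(n, a, b, d))          # 12 floats per triangle
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(block[, i]), con, size = 4L, endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  } else {
    fmt <- function(m) sprintf("%.9g %.9g %.9g", m[, 1L], m[, 2L], m[, 3L])
    lines <- c("solid pianoSign",
               as.vector(rbind(paste0("  facet normal ", fmt(n)),
                               "    outer loop",
                               paste0("      vertex ", fmt(a)),
                               paste0("      vertex ", fmt(b)),
                               paste0("      vertex ", fmt(d)),
                               "    endloop",
                               "  endfacet")),
               "endsolid pianoSign")
    writeLines(lines, path)
  }
  invisible(path)
}

readPLY <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (!length(txt) || txt[1L] != "ply") stopSchema("not a PLY file")
  endh <- match("end_header", txt)
  if (is.na(endh)) stopSchema("truncated PLY file (no end_header)")
  hdr <- txt[seq_len(endh)]
  if (!any(grepl("^format ascii", hdr)))
    stopSchema("only ASCII PLY is supported")
  nv <- as.integer(sub("^element vertex\\s+", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("^element face\\s+", "", grep("^element face", hdr, value = TRUE)))
  if (!length(nv) || !length(nf)) stopSchema("PLY header lacks vertex/face elements")
  body <- txt[-seq_len(endh)]
  if (length(body) < nv + nf) stopSchema("truncated PLY file body")
  vparts <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  v <- do.call(rbind, lapply(vparts, function(x) as.numeric(x[1:3])))
  fparts <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  f <- do.call(rbind, lapply(fparts, function(x) {
    x <- as.integer(x)
    if (x[1L] != 3L) stopSchema("PLY faces must be triangles")
    x[2:4] + 1L
  }))
  if (any(!is.finite(v))) stopSchema("non-numeric vertex in PLY file")
  TriMesh(v, f)
}

writePLY <- function(mesh, path) {
  v <- meshVertices(mesh); f <- meshFaces(mesh)
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(v)),
           "property float x", "property float y", "property float z",
           sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices", "end_header")
  writeLines(c(hdr,
               sprintf("%.9g %.9g %.9g", v[, 1L], v[, 2L], v[, 3L]),
               sprintf("3 %d %d %d", f[, 1L] - 1L, f[, 2L] - 1L, f[, 3L] - 1L)),
             path)
  invisible(path)
}

#' Is every mesh edge shared by exactly two triangles?
#'
#' @param mesh a \linkS4class{TriMesh}.
#' @return Logical scalar.
#' @export
meshIsClosed <- function(mesh) {
  f <- meshFaces(mesh)
  nv <- nrow(meshVertices(mesh))
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- pmin(e[, 1L], e[, 2L]) * (nv + 1) + pmax(e[, 1L], e[, 2L])
  all(tabulate(match(key, unique(key))) == 2L)
}

#' Read a landmark file (JSON)
#'
#' The file must be a JSON object with keys exactly
#' \code{lat_epicondyle_prominence}, \code{med_epicondyle_sulcus},
#' \code{trochlear_groove_deepest}, \code{intercondylar_notch_highest},
#' \code{femoral_head_center}, \code{knee_center} (each an [x, y, z] array in
#' mm) and \code{side} ("left"/"right", case-insensitive).
#'
#' @param path file path.
#' @return A \linkS4class{LandmarkSet}.
#' @export
loadLandmarks <- function(path) {
  if (!file.exists(path)) stopSchema(paste0("landmark file not found: ", path))
  obj <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) stopSchema(paste0("unreadable landmark JSON: ",
                                                        conditionMessage(e))))
  missing <- setdiff(c(LANDMARK_NAMES, "side"), names(obj))
  if (length(missing))
    stopSchema(paste0("landmark file missing key(s): ", paste(missing, collapse = ", ")))
  side <- tolower(as.character(obj$side))
  if (!side %in% c("left", "right"))
    stopSchema(paste0("side must be 'left' or 'right', got '", obj$side, "'"))
  bad <- LANDMARK_NAMES[!vapply(obj[LANDMARK_NAMES],
                                function(p) is.numeric(p) && length(p) == 3L &&
                                  all(is.finite(p)), logical(1))]
  if (length(bad))
    stopSchema(paste0("landmark(s) not finite [x, y, z] triples: ",
                      paste(bad, collapse = ", ")))
  LandmarkSet(obj[LANDMARK_NAMES], side)
}

#' Write a landmark set to JSON
#'
#' @param landmarks a \linkS4class{LandmarkSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeLandmarks <- function(landmarks, path) {
  stopifnot(is(landmarks, "LandmarkSet"))
  p <- landmarks@points
  obj <- c(lapply(LANDMARK_NAMES, function(k) unname(p[k, ])),
           list(landmarks@side))
  names(obj) <- c(LANDMARK_NAMES, "side")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
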