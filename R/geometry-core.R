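# Canonical knee frame and rigid-transform plumbing.
#
# Convention (fixed once, used everywhere): origin at the knee center,
# +z proximal along the mechanical axis, +x medial, +y anterior. For left
# knees the anatomical triad is left-handed, so expressing geometry in
# frame coordinates mirrors them into the right-knee convention; all
# downstream medial/lateral logic is therefore single-pathed.

#' Canonical knee coordinate frame from landmarks
#'
#' \code{zMech} is the unit vector from the knee center to the femoral head
#' center; \code{xMed} points from the lateral epicondylar prominence toward
#' the medial epicondylar sulcus after projecting the epicondylar segment
#' orthogonal to \code{zMech}; \code{yAnt} completes the triad with its sign
#' fixed anterior using the trochlear groove landmark. Left knees yield a
#' left-handed triad (handedness -1) and are thereby mirrored into the
#' right-knee convention when geometry is expressed in frame coordinates.
#'
#' @param landmarks a \linkS4class{LandmarkSet}.
#' @return A \linkS4class{KneeFrame}.
#' @export
canonicalFrame <- function(landmarks) {
  stopifnot(is(landmarks, "LandmarkSet"))
  origin <- landmark(landmarks, "knee_center")
  zMech <- normalize(landmark(landmarks, "femoral_head_center") - origin)
  epi <- landmark(landmarks, "med_epicondyle_sulcus") -
    landmark(landmarks, "lat_epicondyle_prominence")
  epiPerp <- epi - sum(epi * zMech) * zMech
  if (vnorm(epiPerp) < 1e-6)
    stopGeometry("degenerate landmarks: epicondylar axis is parallel to the mechanical axis")
  xMed <- normalize(epiPerp)
  yAnt <- cross3(zMech, xMed)
  groove <- landmark(landmarks, "trochlear_groove_deepest") - origin
  if (abs(sum(groove * yAnt)) < 1e-9)
    stopGeometry("degenerate landmarks: trochlear groove point lies in the epicondylar-mechanical plane")
  handedness <- 1
  if (sum(groove * yAnt) < 0) {
    yAnt <- -yAnt
    handedness <- -1
  }
  new("KneeFrame", origin = origin, xMed = xMed, yAnt = yAnt, zMech = zMech,
      handedness = handedness)
}

#' Express points in canonical frame coordinates
#'
#' Columns of the result are (x medial, y anterior, z proximal) in mm. For a
#' left knee the transform is improper (a reflection), which is exactly the
#' sagittal mirroring that maps it onto the right-knee convention.
#'
#' @param points n x 3 matrix (or length-3 vector) of world coordinates.
#' @param frame a \linkS4class{KneeFrame}.
#' @return Matrix (or vector) of frame coordinates.
#' @export
frameCoords <- function(points, frame) {
  stopifnot(is(frame, "KneeFrame"))
  vec <- is.null(dim(points))
  p <- if (vec) matrix(points, 1L) else as.matrix(points)
  out <- sweep(p, 2L, frame@origin) %*% cbind(frame@xMed, frame@yAnt, frame@zMech)
  colnames(out) <- NULL
  if (vec) out[1L, ] else out
}

#' Re-express a mesh and its landmarks in the canonical frame
#'
#' After this call the knee center is at the origin, +x is medial, +y
#' anterior, +z proximal, and left knees have been mirrored; the returned
#' landmark set is relabelled as a right knee. Canonicalizing a right knee
#' already in canonical pose is the identity.
#'
#' @param mesh a \linkS4class{TriMesh}.
#' @param landmarks the matching \linkS4class{LandmarkSet}.
#' @return \code{list(mesh, landmarks, frame)} with geometry in canonical
#'   coordinates and the frame that produced them.
#' @export
toCanonical <- function(mesh, landmarks) {
  frame <- canonicalFrame(landmarks)
  m2 <- TriMesh(frameCoords(meshVertices(mesh), frame), meshFaces(mesh))
  l2 <- new("LandmarkSet", points = frameCoords(landmarks@points, frame),
            side = "right")
  rownames(l2@points) <- LANDMARK_NAMES
  list(mesh = m2, landmarks = l2, frame = frame)
}

#' Apply a rigid transform to a mesh and landmark set
#'
#' All points are mapped p -> R p + t. Only proper rotations are accepted.
#'
#' @param mesh a \linkS4class{TriMesh}.
#' @param landmarks a \linkS4class{LandmarkSet}.
#' @param R 3 x 3 proper rotation matrix (det +1).
#' @param t length-3 translation, mm.
#' @return \code{list(mesh, landmarks)}.
#' @export
applyRigid <- function(mesh, landmarks, R = diag(3), t = c(0, 0, 0)) {
  if (!isRotationMatrix(R))
    stop("R must be a proper rotation matrix (orthonormal, det +1)", call. = FALSE)
  xf <- function(p) sweep(as.matrix(p) %*% t(R), 2L, t, "+")
  m2 <- TriMesh(xf(meshVertices(mesh)), meshFaces(mesh))
  l2 <- new("LandmarkSet", points = xf(landmarks@points), side = landmarks@side)
  rownames(l2@points) <- LANDMARK_NAMES
  list(mesh = m2, landmarks = l2)
}

#' Mirror a mesh and landmark set about a world coordinate plane
#'
#' Used to fabricate left knees from right knees (and in mirror-consistency
#' tests). Face windings are reversed so the surface stays consistently
#' oriented; the side label is flipped.
#'
#' @param mesh a \linkS4class{TriMesh}.
#' @param landmarks a \linkS4class{LandmarkSet}.
#' @param axis which world axis to negate (1 = x).
#' @return \code{list(mesh, landmarks)}.
#' @export
mirrorWorld <- function(mesh, landmarks, axis = 1L) {
  v <- meshVertices(mesh); v[, axis] <- -v[, axis]
  f <- meshFaces(mesh)[, c(1L, 3L, 2L), drop = FALSE]
  p <- landmarks@points; p[, axis] <- -p[, axis]
  l2 <- new("LandmarkSet", points = p,
            side = if (landmarks@side == "right") "left" else "right")
  rownames(l2@points) <- LANDMARK_NAMES
  list(mesh = TriMesh(v, f), landmarks = l2)
}

## Construct a Plane3 from a point and normal, with a deterministic in-plane
## basis unless one is supplied.
makePlane <- function(point, normal, uDir = NULL, vDir = NULL) {
  n <- normalize(normal)
  if (is.null(uDir)) {
    seed <- if (abs(n[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    uDir <- normalize(seed - sum(seed * n) * n)
  } else uDir <- normalize(uDir - sum(uDir * n) * n)
  if (is.null(vDir)) vDir <- cross3(n, uDir)
  new("Plane3", point = point, normal = n, uDir = uDir, vDir = normalize(vDir))
}

## Signed distances of points to a plane (mm, positive along the normal).
planeDistance <- function(points, plane) {
  p <- if (is.null(dim(points))) matrix(points, 1L) else as.matrix(points)
  drop(sweep(p, 2L, plane@point) %*% plane@normal)
}

## Project world points into plane (u, v) coordinates.
planeUV <- function(points, plane) {
  p <- if (is.null(dim(points))) matrix(points, 1L) else as.matrix(points)
  d <- sweep(p, 2L, plane@point)
  cbind(drop(d %*% plane@uDir), drop(d %*% plane@vDir))
}
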