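# Rotational reference axes of the distal femur.
#
# sTEA: lateral epicondylar prominence -> medial epicondylar sulcus.
# WSL: deepest trochlear groove point -> highest intercondylar notch point;
#      its rotation reference is the perpendicular ML line in the axial plane.
# FEA: line joining the centers of circles fitted to each condyle's sagittal
#      posterior profile.
# PCA: tangent line through the most posterior point of each condyle.
#
# All functions accept geometry in any pose together with the KneeFrame that
# locates it; computations are frame-relative, results are expressed in
# world coordinates and oriented medially (+xMed).

fromFrameCoords <- function(points, frame) {
  p <- if (is.null(dim(points))) matrix(points, 1L) else as.matrix(points)
  sweep(p %*% rbind(frame@xMed, frame@yAnt, frame@zMech), 2L, frame@origin, "+")
}

orientMedial <- function(dir, frame) if (sum(dir * frame@xMed) < 0) -dir else dir

#' Surgical transepicondylar axis
#'
#' The line between the most prominent point of the lateral epicondyle and
#' the medial epicondylar sulcus, oriented medially.
#'
#' @param landmarks a \linkS4class{LandmarkSet}.
#' @param frame the matching \linkS4class{KneeFrame}.
#' @return A \linkS4class{RotationAxis} of kind "sTEA".
#' @export
steaAxis <- function(landmarks, frame) {
  lat <- landmark(landmarks, "lat_epicondyle_prominence")
  med <- landmark(landmarks, "med_epicondyle_sulcus")
  if (vnorm(med - lat) < 1e-6) stopGeometry("epicondylar landmarks coincide")
  new("RotationAxis", point = (lat + med) / 2,
      direction = orientMedial(normalize(med - lat), frame), kind = "sTEA")
}

#' Whiteside's line and its rotation reference
#'
#' \code{wslAxis} is the anteroposterior trochlear line from the deepest
#' groove point to the highest intercondylar notch point, oriented
#' anteriorly. \code{wslRotationReference} is that line rotated -90 degrees
#' about the mechanical axis within the axial plane -- the component ML line
#' perpendicular to Whiteside's line -- oriented medially.
#'
#' @param landmarks a \linkS4class{LandmarkSet}.
#' @param frame the matching \linkS4class{KneeFrame}.
#' @return A \linkS4class{RotationAxis} (kind "WSL").
#' @export
wslAxis <- function(landmarks, frame) {
  groove <- landmark(landmarks, "trochlear_groove_deepest")
  notch <- landmark(landmarks, "intercondylar_notch_highest")
  d <- groove - notch
  if (vnorm(d) < 1e-6) stopGeometry("trochlear landmarks coincide")
  dProj <- d - sum(d * frame@zMech) * frame@zMech
  if (vnorm(dProj) < 1e-6)
    stopGeometry("trochlear landmarks coincide after axial projection")
  dir <- normalize(d)
  if (sum(dir * frame@yAnt) < 0) dir <- -dir
  new("RotationAxis", point = (groove + notch) / 2, direction = dir, kind = "WSL")
}

#' @rdname wslAxis
#' @param wsl the axis returned by \code{wslAxis}.
#' @export
wslRotationReference <- function(wsl, frame) {
  stopifnot(is(wsl, "RotationAxis"))
  d <- wsl@direction
  dProj <- d - sum(d * frame@zMech) * frame@zMech
  if (vnorm(dProj) < 1e-6)
    stopGeometry("Whiteside's line is parallel to the mechanical axis")
  dProj <- normalize(dProj)
  ## -90 degrees about zMech within the axial plane: anterior -> medial
  ref <- cross3(dProj, frame@zMech)
  new("RotationAxis", point = wsl@point,
      direction = orientMedial(normalize(ref), frame), kind = "WSL")
}

#' Algebraic least-squares circle fit (Kasa)
#'
#' Solves the linear system of the algebraic circle equation
#' x^2 + y^2 = 2 a x + 2 b y + c in least squares; exact on exact circular
#' data. The rms radial residual is reported.
#'
#' @param points n x 2 matrix of 2D points (n >= 3, not collinear).
#' @return A \linkS4class{CircleFit}.
#' @export
fitCircle2d <- function(points) {
  P <- as.matrix(points)
  if (nrow(P) < 3L) stopGeometry("circle fit needs at least 3 points")
  ctr <- sweep(P, 2L, colMeans(P))
  sv <- svd(ctr, nu = 0L, nv = 0L)$d
  if (sv[2L] < 1e-9 * max(sv[1L], 1))
    stopGeometry("circle fit is degenerate: points are collinear")
  A <- cbind(2 * P[, 1L], 2 * P[, 2L], 1)
  b <- P[, 1L]^2 + P[, 2L]^2
  sol <- qr.solve(A, b)
  center <- sol[1:2]
  radius <- sqrt(sol[3L] + sum(center^2))
  rho <- sqrt((P[, 1L] - center[1L])^2 + (P[, 2L] - center[2L])^2)
  new("CircleFit", center = unname(center), radius = unname(radius),
      residual = sqrt(mean((rho - radius)^2)))
}

#' Flexion-extension axis from sagittal circle fits
#'
#' For each condyle, the posterior apex (most posterior surface vertex of
#' the condylar half) seeds two orthogonal circle fits
#' (\code{\link{fitCircle2d}}): a coronal-plane fit over the posterior belt
#' in a thin axial slab, which locates the condyle's mediolateral center,
#' and the sagittal-plane fit over the posterior-distal arc in a thin
#' sagittal slab through that center, which gives the flexion circle. The
#' FEA joins the two sagittal circle centers, each placed at its condyle's
#' coronal center.
#'
#' @param mesh a \linkS4class{TriMesh}.
#' @param frame the matching \linkS4class{KneeFrame}.
#' @param config configuration list (see \code{\link{defaultConfig}}), keys
#'   under \code{fea}: \code{bandFraction}, \code{posteriorMaxY},
#'   \code{distalMaxZ}, \code{slabHalfWidth}, \code{minPoints}.
#' @return A \linkS4class{RotationAxis} of kind "FEA"; the fitted sagittal
#'   \linkS4class{CircleFit}s and world-space centers are attached as
#'   attributes \code{"fits"} and \code{"centers"}.
#' @export
feaAxis <- function(mesh, frame, config = defaultConfig()) {
  fc <- config$fea
  V <- frameCoords(meshVertices(mesh), frame)
  fitSide <- function(sgn) {
    half <- sgn * V[, 1L] >= 3
    if (!any(half)) stopGeometry("empty condylar half for the sagittal circle fit")
    apex <- V[which(half)[which.min(V[half, 2L])], ]
    ## coronal fit in an axial slab at the apex level -> mediolateral center;
    ## the belt is kept within 10 mm of the apex so the contralateral condyle
    ## (which can cross the midline) cannot contaminate the fit
    sel1 <- half & abs(V[, 3L] - apex[3L]) <= fc$slabHalfWidth &
      V[, 2L] < apex[2L] + 6 & abs(V[, 1L] - apex[1L]) <= 10
    if (sum(sel1) < fc$minPoints)
      stopGeometry(sprintf("too few posterior-belt points (%d < %d) on the %s condyle",
                           sum(sel1), fc$minPoints, if (sgn > 0) "medial" else "lateral"))
    cx <- fitCircle2d(V[sel1, c(1L, 2L), drop = FALSE])@center[1L]
    ## sagittal fit in the slab through the coronal center
    sel <- abs(V[, 1L] - cx) <= fc$slabHalfWidth &
      V[, 2L] < fc$posteriorMaxY & V[, 3L] < fc$distalMaxZ
    if (sum(sel) < fc$minPoints)
      stopGeometry(sprintf("too few posterior-arc points (%d < %d) on the %s condyle",
                           sum(sel), fc$minPoints, if (sgn > 0) "medial" else "lateral"))
    yz <- V[sel, c(2L, 3L), drop = FALSE]
    fit <- fitCircle2d(yz)
    ## one trimmed refit: drop points off the condylar circle (blend regions)
    rho <- sqrt((yz[, 1L] - fit@center[1L])^2 + (yz[, 2L] - fit@center[2L])^2)
    keep <- abs(rho - fit@radius) <= 2 * max(fit@residual, 1e-6)
    if (sum(keep) >= fc$minPoints) fit <- fitCircle2d(yz[keep, , drop = FALSE])
    list(fit = fit, x = cx)
  }
  med <- fitSide(1); lat <- fitSide(-1)
  cMed <- c(med$x, med$fit@center)
  cLat <- c(lat$x, lat$fit@center)
  if (vnorm(cMed - cLat) < 1e-6) stopGeometry("condylar circle centers coincide")
  cMedW <- drop(fromFrameCoords(cMed, frame))
  cLatW <- drop(fromFrameCoords(cLat, frame))
  ax <- new("RotationAxis", point = (cMedW + cLatW) / 2,
            direction = orientMedial(normalize(cMedW - cLatW), frame), kind = "FEA")
  attr(ax, "fits") <- list(med = med$fit, lat = lat$fit)
  attr(ax, "centers") <- list(med = cMedW, lat = cLatW)
  ax
}

#' Posterior condylar axis
#'
#' The line through the most posterior surface point of each condyle (within
#' the condylar mediolateral bands), oriented medially.
#'
#' @inheritParams feaAxis
#' @return A \linkS4class{RotationAxis} of kind "PCA".
#' @export
pcaAxis <- function(mesh, frame, config = defaultConfig()) {
  fc <- config$fea
  V <- frameCoords(meshVertices(mesh), frame)
  ml <- diff(range(V[, 1L]))
  band <- fc$bandFraction * ml
  pick <- function(sgn) {
    sel <- which(sgn * V[, 1L] >= band[1L] & sgn * V[, 1L] <= band[2L])
    if (!length(sel)) stopGeometry("empty condylar band for the posterior condylar axis")
    V[sel[which.min(V[sel, 2L])], ]
  }
  pMed <- pick(1); pLat <- pick(-1)
  d <- pMed - pLat
  if (vnorm(d) < 1e-6) stopGeometry("posterior condylar points coincide")
  pMedW <- drop(fromFrameCoords(pMed, frame))
  pLatW <- drop(fromFrameCoords(pLat, frame))
  new("RotationAxis", point = (pMedW + pLatW) / 2,
      direction = orientMedial(normalize(pMedW - pLatW), frame), kind = "PCA")
}

#' Signed axial-plane angle between two axes
#'
#' Both directions are projected onto the plane perpendicular to the
#' mechanical axis; the returned angle (degrees) is positive when \code{a}
#' is externally rotated relative to \code{b} (external rotation turns the
#' medial end of an ML axis anteriorly).
#'
#' @param a,b \linkS4class{RotationAxis} objects.
#' @param frame a \linkS4class{KneeFrame}.
#' @return Signed angle in degrees.
#' @export
axialAngleBetween <- function(a, b, frame) {
  proj <- function(ax) {
    d <- frameCoords(ax@point + ax@direction, frame) - frameCoords(ax@point, frame)
    d[3L] <- 0
    if (vnorm(d) < 1e-9) stopGeometry("axis is parallel to the mechanical axis")
    normalize(d)
  }
  pa <- proj(a); pb <- proj(b)
  rad2deg(atan2(pb[1L] * pa[2L] - pb[2L] * pa[1L], sum(pa * pb)))
}
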