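# Virtual mechanically aligned femoral resection.
#
# The distal cut is perpendicular to the mechanical axis, 9 mm proximal to
# the most distal point of the femur. The anterior (flange) cut is flexed
# 3 degrees and referenced to the anterior cortex: it passes through the
# most anterior vertex within a configurable band above the distal cut, the
# standard no-notching surrogate for implant-driven flange placement. The
# anterior resection surface is the mesh cross-section in the anterior
# plane, clipped to the bone retained above the distal cut.

#' Distal cutting plane
#'
#' Perpendicular to the mechanical axis, \code{depthMm} proximal to the most
#' distal mesh vertex (the more distal condyle).
#'
#' @param mesh a \linkS4class{TriMesh}.
#' @param frame the matching \linkS4class{KneeFrame}.
#' @param depthMm resection depth, mm (default 9).
#' @return A \linkS4class{Plane3} whose normal is the proximal mechanical
#'   axis; attribute \code{"level"} holds the frame z level of the cut.
#' @export
distalCutPlane <- function(mesh, frame, depthMm = 9) {
  z <- frameCoords(meshVertices(mesh), frame)[, 3L]
  if (depthMm < 0) stopGeometry("resection depth must be nonnegative")
  if (depthMm >= diff(range(z)))
    stopGeometry("distal resection depth exceeds the mesh extent")
  level <- min(z) + depthMm
  pl <- makePlane(drop(fromFrameCoords(c(0, 0, level), frame)), frame@zMech,
                  uDir = frame@xMed)
  attr(pl, "level") <- level
  pl
}

#' Femoral component frame from a rotational reference
#'
#' The component ML axis is the axial-plane projection of the rotational
#' reference (optionally with extra external rotation); the proximal axis is
#' the mechanical axis flexed anteriorly by the flange flexion angle about
#' the component ML axis; the flange normal completes the triad anteriorly.
#'
#' @param frame a \linkS4class{KneeFrame}.
#' @param rotationRef a \linkS4class{RotationAxis} (pass
#'   \code{\link{wslRotationReference}} for Whiteside's line).
#' @param flexionDeg anterior flange flexion, degrees (default 3).
#' @param extraRotationDeg additional rotation about the mechanical axis,
#'   degrees, positive = external (used by rotation sweeps).
#' @return A \linkS4class{ComponentFrame}.
#' @export
componentFrame <- function(frame, rotationRef, flexionDeg = 3, extraRotationDeg = 0) {
  stopifnot(is(rotationRef, "RotationAxis"))
  d <- frameCoords(rotationRef@point + rotationRef@direction, frame) -
    frameCoords(rotationRef@point, frame)
  d[3L] <- 0
  if (vnorm(d) < 1e-9)
    stopGeometry("rotational reference is parallel to the mechanical axis")
  x0 <- normalize(d)
  if (x0[1L] < 0) x0 <- -x0
  th <- deg2rad(extraRotationDeg)       # positive = external: medial end moves anteriorly
  x0 <- c(cos(th) * x0[1L] - sin(th) * x0[2L],
          sin(th) * x0[1L] + cos(th) * x0[2L], 0)
  yAx <- c(-x0[2L], x0[1L], 0)          # axial normal to xComp, anterior
  f <- deg2rad(flexionDeg)
  zFlexF <- cos(f) * c(0, 0, 1) + sin(f) * yAx
  yFlangeF <- cross3(zFlexF, x0)
  toWorld <- function(v) drop(fromFrameCoords(v, frame)) - frame@origin
  new("ComponentFrame", origin = frame@origin,
      xComp = toWorld(x0), yFlange = toWorld(yFlangeF), zFlex = toWorld(zFlexF),
      flexionDeg = flexionDeg, reference = rotationRef@kind)
}

#' Anterior (flange) cutting plane by anterior-cortex referencing
#'
#' The plane has the flange normal of the component frame and passes through
#' the most anterior mesh vertex (largest flange-normal coordinate) whose
#' frame z lies within \code{bandMm} above the distal cut -- tangency to the
#' anterior cortex, which guarantees no notching within the band.
#'
#' @param mesh a \linkS4class{TriMesh}.
#' @param cf a \linkS4class{ComponentFrame}.
#' @param frame the \linkS4class{KneeFrame}.
#' @param distalLevel frame z level of the distal cut (attribute of
#'   \code{\link{distalCutPlane}}).
#' @param bandMm c(lo, hi) band above the distal cut, mm (default 25-45).
#' @return A \linkS4class{Plane3} with u = component ML axis and
#'   v = flexed proximal axis.
#' @export
anteriorCutPlane <- function(mesh, cf, frame, distalLevel, bandMm = c(25, 45)) {
  V <- meshVertices(mesh)
  z <- frameCoords(V, frame)[, 3L]
  inBand <- z >= distalLevel + bandMm[1L] & z <= distalLevel + bandMm[2L]
  if (!any(inBand))
    stopGeometry("anterior referencing band contains no mesh vertices")
  yc <- drop(V[inBand, , drop = FALSE] %*% cf@yFlange)
  p0 <- V[inBand, , drop = FALSE][which.max(yc), ]
  makePlane(p0, cf@yFlange, uDir = cf@xComp, vDir = cf@zFlex)
}

#' Cross-section of a mesh by a plane
#'
#' Edge-plane intersections are chained into closed loops and projected to
#' the plane's (u, v) coordinates. Open chains from non-watertight patches
#' are closed when the gap is below \code{gapTolMm}, otherwise dropped;
#' loops with area below \code{minAreaMm2} are dropped.
#'
#' @param mesh a \linkS4class{TriMesh}.
#' @param plane a \linkS4class{Plane3}.
#' @param minAreaMm2 minimum loop area kept, mm^2.
#' @param gapTolMm maximum chain gap bridged, mm.
#' @return List of k x 2 polygon matrices (closed loops, last vertex not
#'   repeated).
#' @export
crossSection <- function(mesh, plane, minAreaMm2 = 1, gapTolMm = 0.5) {
  V <- meshVertices(mesh); Fc <- meshFaces(mesh)
  d <- planeDistance(V, plane)
  d[d == 0] <- 1e-12
  neg <- d < 0
  nNeg <- neg[Fc[, 1L]] + neg[Fc[, 2L]] + neg[Fc[, 3L]]
  hit <- which(nNeg == 1L | nNeg == 2L)
  if (!length(hit)) stopGeometry("plane does not intersect the mesh")
  f <- Fc[hit, , drop = FALSE]
  fNeg <- neg[f]; dim(fNeg) <- dim(f)
  ## the "solo" vertex is on the minority side; its two edges cross the plane
  soloSide <- nNeg[hit] == 1L
  isSolo <- fNeg == soloSide   # TRUE where vertex is the solo one
  soloIdx <- max.col(isSolo, ties.method = "first")
  n <- length(hit)
  rows <- seq_len(n)
  solo <- f[cbind(rows, soloIdx)]
  o1 <- f[cbind(rows, soloIdx %% 3L + 1L)]
  o2 <- f[cbind(rows, (soloIdx + 1L) %% 3L + 1L)]
  edgeKey <- function(a, b) pmin(a, b) * (nrow(V) + 1) + pmax(a, b)
  crossPoint <- function(a, b) {
    t <- d[a] / (d[a] - d[b])
    V[a, , drop = FALSE] + t * (V[b, , drop = FALSE] - V[a, , drop = FALSE])
  }
  kA <- edgeKey(solo, o1); kB <- edgeKey(solo, o2)
  seg <- kA != kB                  # guard against degenerate faces
  kA <- kA[seg]; kB <- kB[seg]
  solo <- solo[seg]; o1 <- o1[seg]; o2 <- o2[seg]
  n <- length(kA)
  keys <- unique(c(kA, kB))
  nodeA <- match(kA, keys); nodeB <- match(kB, keys)
  pts <- matrix(NA_real_, length(keys), 3L)
  pts[nodeA, ] <- crossPoint(solo, o1)
  pts[nodeB, ] <- crossPoint(solo, o2)
  uv <- planeUV(pts, plane)

  ## chain segments (nodeA[i] -- nodeB[i]) into loops
  nNode <- length(keys)
  adj <- matrix(0L, nNode, 2L)
  deg <- integer(nNode)
  for (i in seq_len(n)) {
    a <- nodeA[i]; b <- nodeB[i]
    deg[a] <- deg[a] + 1L; adj[a, min(deg[a], 2L)] <- b
    deg[b] <- deg[b] + 1L; adj[b, min(deg[b], 2L)] <- a
  }
  visited <- logical(nNode)
  loops <- list()
  open <- list()
  for (start in seq_len(nNode)) {
    if (visited[start]) next
    chain <- integer(0)
    cur <- start; prev <- 0L
    repeat {
      visited[cur] <- TRUE
      chain <- c(chain, cur)
      nxt <- adj[cur, ]
      nxt <- nxt[nxt != 0L & nxt != prev]
      nxt <- nxt[!visited[nxt]]
      if (!length(nxt)) break
      prev <- cur; cur <- nxt[1L]
    }
    ## closed if the two chain ends are adjacent
    if (length(chain) >= 3L) {
      a <- chain[1L]; b <- chain[length(chain)]
      if (any(adj[b, ] == a) || sqrt(sum((uv[a, ] - uv[b, ])^2)) <= gapTolMm)
        loops[[length(loops) + 1L]] <- uv[chain, , drop = FALSE]
      else open[[length(open) + 1L]] <- chain
    }
  }
  ## try to bridge remaining open chains pairwise by nearest endpoints
  while (length(open) >= 2L) {
    c1 <- open[[1L]]; open <- open[-1L]
    ends1 <- uv[c(c1[1L], c1[length(c1)]), , drop = FALSE]
    best <- NULL; bestD <- gapTolMm
    for (j in seq_along(open)) {
      c2 <- open[[j]]
      ends2 <- uv[c(c2[1L], c2[length(c2)]), , drop = FALSE]
      dd <- as.matrix(stats::dist(rbind(ends1, ends2)))[1:2, 3:4]
      if (min(dd) <= bestD) { best <- j; bestD <- min(dd) }
    }
    if (is.null(best)) next
    c2 <- open[[best]]; open <- open[-best]
    ## orient c2 so its head is nearest c1's tail
    tail1 <- uv[c1[length(c1)], ]
    dHead <- sqrt(sum((uv[c2[1L], ] - tail1)^2))
    dTail <- sqrt(sum((uv[c2[length(c2)], ] - tail1)^2))
    if (dTail < dHead) c2 <- rev(c2)
    merged <- c(c1, c2)
    a <- merged[1L]; b <- merged[length(merged)]
    if (sqrt(sum((uv[a, ] - uv[b, ])^2)) <= gapTolMm && length(merged) >= 3L)
      loops[[length(loops) + 1L]] <- uv[merged, , drop = FALSE]
    else open[[length(open) + 1L]] <- merged
  }
  loops <- Filter(function(p) abs(polygonArea(p)) >= minAreaMm2, loops)
  if (!length(loops)) stopGeometry("plane intersects the mesh only in negligible slivers")
  loops
}

#' Polygon area (shoelace), mm^2
#'
#' @param poly k x 2 matrix of loop vertices (closed implicitly).
#' @return Signed area; use \code{abs()} for the geometric area.
#' @export
polygonArea <- function(poly) {
  u <- poly[, 1L]; v <- poly[, 2L]
  u2 <- c(u[-1L], u[1L]); v2 <- c(v[-1L], v[1L])
  sum(u * v2 - u2 * v) / 2
}

## Clip a polygon to the half-plane v >= v0 (Sutherland-Hodgman).
clipAboveV <- function(poly, v0) {
  n <- nrow(poly)
  out <- matrix(numeric(0), 0L, 2L)
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[if (i == n) 1L else i + 1L, ]
    aIn <- a[2L] >= v0; bIn <- b[2L] >= v0
    if (aIn) out <- rbind(out, a)
    if (xor(aIn, bIn)) {
      t <- (v0 - a[2L]) / (b[2L] - a[2L])
      out <- rbind(out, a + t * (b - a))
    }
  }
  if (nrow(out) >= 3L) out else NULL
}

#' Perform the virtual distal + anterior resection
#'
#' Runs the full cut sequence for one rotational reference: distal plane,
#' component frame, anterior-cortex-referenced flange plane, and the two
#' cross-sections. The anterior section is clipped to the geometry retained
#' above the distal cut; the distal cutting line is the exact plane-plane
#' intersection expressed in anterior-plane (u, v) coordinates.
#'
#' @param mesh a \linkS4class{TriMesh}.
#' @param frame the matching \linkS4class{KneeFrame}.
#' @param rotationRef a \linkS4class{RotationAxis} (for Whiteside's line
#'   pass the perpendicular \code{\link{wslRotationReference}}).
#' @param config configuration list (see \code{\link{defaultConfig}}), keys
#'   under \code{resection} and \code{profile}.
#' @return A \linkS4class{CutResult}; the \linkS4class{ComponentFrame} is
#'   attached as attribute \code{"componentFrame"}.
#' @export
performResection <- function(mesh, frame, rotationRef, config = defaultConfig()) {
  rc <- config$resection
  distal <- distalCutPlane(mesh, frame, rc$distalDepthMm)
  level <- attr(distal, "level")
  cf <- componentFrame(frame, rotationRef, rc$flexionDeg, rc$extraRotationDeg %||% 0)
  ## distal section with u along the anatomical ML axis, so the ML width is
  ## independent of the rotational reference
  distalPl <- makePlane(distal@point, distal@normal, uDir = frame@xMed)
  distalSec <- crossSection(mesh, distalPl, config$profile$minAreaMm2,
                            config$profile$gapTolMm)
  anterior <- anteriorCutPlane(mesh, cf, frame, level, rc$bandMm)
  antSecRaw <- crossSection(mesh, anterior, config$profile$minAreaMm2,
                            config$profile$gapTolMm)
  ## trace of the distal plane within the anterior plane: v = vStar
  vStar <- -sum((anterior@point - distal@point) * distal@normal) /
    sum(anterior@vDir * distal@normal)
  antSec <- Filter(function(p) !is.null(p) && abs(polygonArea(p)) >= config$profile$minAreaMm2,
                   lapply(antSecRaw, clipAboveV, v0 = vStar))
  if (!length(antSec))
    stopGeometry("anterior resection surface is empty above the distal cut")
  res <- new("CutResult", distalPlane = distalPl, anteriorPlane = anterior,
             anteriorSection = antSec, distalSection = distalSec,
             distalCutLine = rbind(c(0, vStar), c(1, 0)))
  attr(res, "componentFrame") <- cf
  res
}

#' Uniformly scale a cut result
#'
#' Multiplies every in-plane coordinate (section polygons and the distal
#' cutting line offset) by \code{s}; used by the scale-invariance property
#' checks on the dimensionless morphometry outputs.
#'
#' @param cut a \linkS4class{CutResult}.
#' @param s positive scale factor.
#' @return A \linkS4class{CutResult}.
#' @export
scaleCutResult <- function(cut, s) {
  stopifnot(s > 0)
  new("CutResult", distalPlane = cut@distalPlane, anteriorPlane = cut@anteriorPlane,
      anteriorSection = lapply(cut@anteriorSection, function(p) p * s),
      distalSection = lapply(cut@distalSection, function(p) p * s),
      distalCutLine = rbind(cut@distalCutLine[1L, ] * s, cut@distalCutLine[2L, ]))
}
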