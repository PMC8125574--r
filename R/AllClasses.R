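#' @import methods
NULL

LANDMARK_NAMES <- c("lat_epicondyle_prominence", "med_epicondyle_sulcus",
                    "trochlear_groove_deepest", "intercondylar_notch_highest",
                    "femoral_head_center", "knee_center")

#' Triangle surface mesh of a distal femur
#'
#' A watertight triangle surface in millimetre units. Vertices are stored as
#' an n x 3 numeric matrix, faces as an m x 3 integer matrix of 1-based
#' vertex indices.
#'
#' @slot vertices numeric matrix, n x 3, mm.
#' @slot faces integer matrix, m x 3, 1-based indices into \code{vertices}.
#' @exportClass TriMesh
setClass("TriMesh", representation(vertices = "matrix", faces = "matrix"))

setValidity("TriMesh", function(object) {
  v <- object@vertices; f <- object@faces
  if (!is.numeric(v) || ncol(v) != 3L) return("vertices must be an n x 3 numeric matrix")
  if (nrow(v) < 4L) return("a mesh needs at least 4 vertices")
  if (!all(is.finite(v))) return("vertices must be finite")
  if (ncol(f) != 3L || nrow(f) < 1L) return("faces must be an m x 3 index matrix")
  if (min(f) < 1L || max(f) > nrow(v)) return("face indices out of range")
  TRUE
})

#' The six anatomical landmarks of a distal femur
#'
#' Named points (mm) used to construct the canonical knee frame and the
#' rotational reference axes: the most prominent point of the lateral
#' epicondyle, the medial epicondylar sulcus, the deepest trochlear groove
#' point, the highest intercondylar notch point, the femoral head center and
#' the knee center (intramedullary entry).
#'
#' @slot points numeric 6 x 3 matrix with rownames equal to the landmark keys.
#' @slot side "left" or "right".
#' @exportClass LandmarkSet
setClass("LandmarkSet", representation(points = "matrix", side = "character"))

setValidity("LandmarkSet", function(object) {
  p <- object@points
  if (!is.numeric(p) || !identical(dim(p), c(6L, 3L)))
    return("points must be a 6 x 3 numeric matrix")
  if (!identical(rownames(p), LANDMARK_NAMES))
    return(paste("rownames must be exactly:", paste(LANDMARK_NAMES, collapse = ", ")))
  if (!all(is.finite(p))) return("landmark coordinates must be finite")
  if (vnorm(p["lat_epicondyle_prominence", ] - p["med_epicondyle_sulcus", ]) < 1e-6)
    return("epicondylar landmarks must be distinct")
  if (vnorm(p["femoral_head_center", ] - p["knee_center", ]) < 30)
    return("femoral head center must be well proximal of the knee center (>30 mm)")
  if (!object@side %in% c("left", "right")) return("side must be 'left' or 'right'")
  TRUE
})

#' Canonical knee coordinate frame
#'
#' Anatomical triad at the knee center: \code{zMech} proximal along the
#' mechanical axis, \code{xMed} medial, \code{yAnt} anterior. For left knees
#' the triad is left-handed (handedness -1); expressing geometry in this
#' frame mirrors left knees into the single right-knee convention used by all
#' downstream measurements.
#'
#' @slot origin knee center, mm.
#' @slot xMed,yAnt,zMech unit vectors.
#' @slot handedness +1 (right-handed) or -1 (left knee, mirrored).
#' @exportClass KneeFrame
setClass("KneeFrame", representation(origin = "numeric", xMed = "numeric",
                                     yAnt = "numeric", zMech = "numeric",
                                     handedness = "numeric"))

setValidity("KneeFrame", function(object) {
  M <- cbind(object@xMed, object@yAnt, object@zMech)
  if (max(abs(crossprod(M) - diag(3L))) > 1e-6) return("axes must be orthonormal")
  if (abs(det(M) - object@handedness) > 1e-6)
    return("handedness flag must equal det([xMed yAnt zMech])")
  if (!object@handedness %in% c(-1, 1)) return("handedness must be +-1")
  TRUE
})

#' An oriented plane with an in-plane basis
#'
#' @slot point a point on the plane, mm.
#' @slot normal unit normal.
#' @slot uDir,vDir in-plane orthonormal basis; section polygons are expressed
#'   in these (u, v) coordinates.
#' @exportClass Plane3
setClass("Plane3", representation(point = "numeric", normal = "numeric",
                                  uDir = "numeric", vDir = "numeric"))

setValidity("Plane3", function(object) {
  B <- cbind(object@uDir, object@vDir, object@normal)
  if (max(abs(crossprod(B) - diag(3L))) > 1e-6)
    return("uDir, vDir, normal must be orthonormal")
  TRUE
})

#' A rotational reference axis
#'
#' @slot point a point on the axis, mm.
#' @slot direction unit vector.
#' @slot kind one of "sTEA", "WSL", "FEA", "PCA", "other".
#' @exportClass RotationAxis
setClass("RotationAxis", representation(point = "numeric", direction = "numeric",
                                        kind = "character"))

setValidity("RotationAxis", function(object) {
  if (abs(vnorm(object@direction) - 1) > 1e-8) return("direction must be unit length")
  if (!object@kind %in% c("sTEA", "WSL", "FEA", "PCA", "other"))
    return("kind must be one of sTEA, WSL, FEA, PCA, other")
  TRUE
})

#' Least-squares circle fit in 2D
#'
#' @slot center length-2 numeric, mm.
#' @slot radius mm.
#' @slot residual root-mean-square radial residual, mm.
#' @exportClass CircleFit
setClass("CircleFit", representation(center = "numeric", radius = "numeric",
                                     residual = "numeric"))

setValidity("CircleFit", function(object) {
  if (object@radius <= 0) return("radius must be positive")
  if (object@residual < 0) return("residual must be nonnegative")
  TRUE
})

#' Femoral component coordinate frame
#'
#' The component's mediolateral axis \code{xComp} comes from the chosen
#' rotational reference projected into the axial plane; \code{zFlex} is the
#' mechanical axis flexed by the anterior-flange flexion angle about
#' \code{xComp}; \code{yFlange} is the anterior flange normal.
#'
#' @slot origin knee center, mm.
#' @slot xComp,yFlange,zFlex orthonormal triad.
#' @slot flexionDeg flange flexion angle, degrees.
#' @slot reference label of the rotational reference used.
#' @exportClass ComponentFrame
setClass("ComponentFrame", representation(origin = "numeric", xComp = "numeric",
                                          yFlange = "numeric", zFlex = "numeric",
                                          flexionDeg = "numeric", reference = "character"))

setValidity("ComponentFrame", function(object) {
  B <- cbind(object@xComp, object@yFlange, object@zFlex)
  if (max(abs(crossprod(B) - diag(3L))) > 1e-6) return("component axes must be orthonormal")
  TRUE
})

#' Result of the virtual distal + anterior resection
#'
#' Section polygons are closed loops in plane (u, v) coordinates; the
#' anterior section is already clipped to the bone retained above the distal
#' cut. The distal cutting line is the trace of the distal plane within the
#' anterior plane.
#'
#' @slot distalPlane,anteriorPlane \linkS4class{Plane3}.
#' @slot anteriorSection,distalSection lists of k x 2 polygon matrices (mm).
#' @slot distalCutLine 2 x 2 matrix: row 1 a point (u, v), row 2 the unit
#'   direction of the line in anterior-plane coordinates.
#' @exportClass CutResult
setClass("CutResult", representation(distalPlane = "Plane3", anteriorPlane = "Plane3",
                                     anteriorSection = "list", distalSection = "list",
                                     distalCutLine = "matrix"))

setValidity("CutResult", function(object) {
  if (!length(object@anteriorSection)) return("anterior section must be nonempty")
  ok <- vapply(c(object@anteriorSection, object@distalSection),
               function(p) is.matrix(p) && ncol(p) == 2L && nrow(p) >= 3L, logical(1))
  if (!all(ok)) return("section polygons must be k x 2 matrices with k >= 3")
  TRUE
})

#' Height profile of the anterior resection surface
#'
#' h(u) is the perpendicular distance (within the anterior plane) from the
#' distal cutting line to the proximal boundary of the anterior section at
#' mediolateral coordinate u (medial positive). NA where the section is absent.
#'
#' @slot u strictly increasing grid, mm.
#' @slot h heights, mm (NA outside the section).
#' @slot uAnterior,uDistal (min, max) mediolateral extents of the anterior and
#'   distal sections, mm.
#' @exportClass ResectionProfile
setClass("ResectionProfile", representation(u = "numeric", h = "numeric",
                                            uAnterior = "numeric", uDistal = "numeric"))

setValidity("ResectionProfile", function(object) {
  if (length(object@u) != length(object@h)) return("u and h must have equal length")
  if (any(diff(object@u) <= 0)) return("u grid must be strictly increasing")
  if (any(object@h[!is.na(object@h)] < -1e-9)) return("h must be nonnegative where defined")
  TRUE
})

#' Detected profile features: lateral peak and medial peak or inflection
#'
#' @slot lateralU,lateralH lateral peak position and height, mm.
#' @slot medialU,medialH medial feature position and height, mm.
#' @slot medialKind "peak" or "inflection".
#' @slot prominence topographic prominence of the medial peak (mm; NA for an
#'   inflection).
#' @slot valleyU,valleyH central valley position and height, mm.
#' @exportClass PeakResult
setClass("PeakResult", representation(lateralU = "numeric", lateralH = "numeric",
                                      medialU = "numeric", medialH = "numeric",
                                      medialKind = "character", prominence = "numeric",
                                      valleyU = "numeric", valleyH = "numeric"))

setValidity("PeakResult", function(object) {
  if (!object@medialKind %in% c("peak", "inflection"))
    return("medialKind must be 'peak' or 'inflection'")
  TRUE
})

#' Parameters of the synthetic distal-femur generator
#'
#' All lengths in mm. The femur is a smooth union of a shaft frustum, two
#' condylar spheres (sagittal circle radii \code{rCondMed}/\code{rCondLat})
#' and two anterior facet prisms of heights \code{hAntMed}/\code{hAntLat}
#' above the trochlear groove floor, minus a V-groove wedge and an
#' intercondylar notch, plus band-limited smooth surface noise.
#'
#' @slot mlWidth overall mediolateral width.
#' @slot apDepth overall anteroposterior depth (derived from the condylar
#'   radii, shaft radius and lateral facet height; recorded for reference).
#' @slot rCondMed,rCondLat condylar circle radii.
#' @slot shaftRadius,shaftTaper shaft frustum radius at the metaphysis and
#'   its proximal taper.
#' @slot grooveDepth,grooveApexAngle trochlear V-groove depth (mm, reached
#'   20 mm proximal of the distal datum) and apex angle (degrees).
#' @slot hAntMed,hAntLat anterior facet heights above the groove floor.
#' @slot facetTaperSlope proximal recession rate of the facet fronts (mm/mm).
#' @slot epiOffMed,epiOffLat small angular offsets (degrees, length 2) of the
#'   epicondylar landmark directions on the condylar spheres.
#' @slot noiseAmplitude,noiseWavelength smooth surface noise RMS amplitude and
#'   minimum wavelength.
#' @slot noiseBasis internal sinusoid table (m x 5: direction, wavenumber,
#'   phase), frozen at sampling time so the implicit field is a pure function
#'   of the parameters.
#' @slot side "left" or "right".
#' @slot archetype "female-like" or "male-like".
#' @slot seed integer seed the parameters were drawn with.
#' @exportClass FemurParams
setClass("FemurParams", representation(
  mlWidth = "numeric", apDepth = "numeric",
  rCondMed = "numeric", rCondLat = "numeric",
  shaftRadius = "numeric", shaftTaper = "numeric",
  grooveDepth = "numeric", grooveApexAngle = "numeric",
  hAntMed = "numeric", hAntLat = "numeric", facetTaperSlope = "numeric",
  epiOffMed = "numeric", epiOffLat = "numeric",
  noiseAmplitude = "numeric", noiseWavelength = "numeric", noiseBasis = "matrix",
  side = "character", archetype = "character", seed = "numeric"))

setValidity("FemurParams", function(object) {
  if (object@mlWidth < 55 || object@mlWidth > 100) return("mlWidth must be in [55, 100] mm")
  if (object@rCondMed < 15 || object@rCondMed > 35 ||
      object@rCondLat < 15 || object@rCondLat > 35)
    return("condylar radii must be in [15, 35] mm")
  if (object@hAntMed < 0 || object@hAntLat < 0) return("facet heights must be >= 0")
  lens <- c(object@apDepth, object@shaftRadius, object@grooveDepth)
  if (any(lens <= 0)) return("lengths must be positive")
  if (object@noiseAmplitude < 0) return("noiseAmplitude must be >= 0")
  if (object@noiseAmplitude > 0 && object@noiseWavelength < 8)
    return("noise wavelength must be >= 8 mm (smooth undulation only)")
  if (!object@side %in% c("left", "right")) return("side must be 'left' or 'right'")
  TRUE
})

#' Ground truth shipped with a synthetic femur
#'
#' @slot landmarks \linkS4class{LandmarkSet} in world (posed) coordinates.
#' @slot feaMed,feaLat true condylar circle centers (world coordinates) --
#'   the endpoints of the true flexion-extension axis.
#' @slot steaLat,steaMed true epicondylar landmark points (world coordinates).
#' @slot pose list(R = 3x3 rotation, t = translation) applied after (optional)
#'   left-side mirroring of the canonically built femur.
#' @slot params the generating \linkS4class{FemurParams}.
#' @exportClass FemurTruth
setClass("FemurTruth", representation(landmarks = "LandmarkSet",
                                      feaMed = "numeric", feaLat = "numeric",
                                      steaLat = "numeric", steaMed = "numeric",
                                      pose = "list", params = "FemurParams"))
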