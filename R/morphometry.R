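# Morphometry of the anterior resection surface.
#
# The cut face is reduced to a 1D height profile h(u): the in-plane
# perpendicular distance from the distal cutting line to the proximal
# boundary of the anterior section at mediolateral coordinate u (medial
# positive). The profile yields the lateral peak and the medial peak -- or,
# absent a definite medial peak, the medial inflection -- and from these the
# standard measurements: LatL, MedL, MedL/LatL, ML, M'L', M'L'/ML, LD and
# LD/ML, plus the double/single-peak shape class.

#' Height profile of the anterior resection surface
#'
#' Rasterizes the anterior-section polygons onto a regular u grid; at each u
#' the height is the maximum v over all loop boundary crossings minus the
#' distal cutting line's v (loops merged by max). The mediolateral extent of
#' the distal section is carried along for the ML width.
#'
#' @param cut a \linkS4class{CutResult}.
#' @param stepMm u grid step, mm (<= 0.25).
#' @return A \linkS4class{ResectionProfile}.
#' @export
buildProfile <- function(cut, stepMm = 0.25) {
  if (stepMm > 0.25 + 1e-9) stopGeometry("profile grid step must be <= 0.25 mm")
  vStar <- cut@distalCutLine[1L, 2L]
  uAll <- unlist(lapply(cut@anteriorSection, function(p) p[, 1L]))
  uAnterior <- range(uAll)
  if (diff(uAnterior) < 5)
    stopGeometry("anterior section is degenerate (mediolateral extent < 5 mm)")
  uDistal <- range(unlist(lapply(cut@distalSection, function(p) p[, 1L])))
  j0 <- ceiling(uAnterior[1L] / stepMm)
  j1 <- floor(uAnterior[2L] / stepMm)
  uGrid <- (j0:j1) * stepMm
  hMax <- rep(NA_real_, length(uGrid))
  for (poly in cut@anteriorSection) {
    n <- nrow(poly)
    u1 <- poly[, 1L]; v1 <- poly[, 2L]
    nxt <- c(2:n, 1L)
    u2 <- u1[nxt]; v2 <- v1[nxt]
    keep <- abs(u2 - u1) > 1e-12
    eu1 <- u1[keep]; ev1 <- v1[keep]; eu2 <- u2[keep]; ev2 <- v2[keep]
    lo <- ceiling(pmin(eu1, eu2) / stepMm - 1e-9)
    hi <- floor(pmax(eu1, eu2) / stepMm + 1e-9)
    cnt <- pmax(hi - lo + 1L, 0L)
    if (!sum(cnt)) next
    eIdx <- rep(seq_along(cnt), cnt)
    j <- lo[eIdx] + sequence(cnt) - 1L
    uc <- j * stepMm
    t <- (uc - eu1[eIdx]) / (eu2[eIdx] - eu1[eIdx])
    t <- pmin(pmax(t, 0), 1)
    v <- ev1[eIdx] + t * (ev2[eIdx] - ev1[eIdx])
    gi <- j - j0 + 1L
    ok <- gi >= 1L & gi <= length(uGrid)
    vm <- tapply(v[ok], gi[ok], max)
    at <- as.integer(names(vm))
    hMax[at] <- pmax(hMax[at], as.numeric(vm), na.rm = TRUE)
  }
  h <- hMax - vStar
  h[!is.na(h) & h < 0] <- 0
  new("ResectionProfile", u = uGrid, h = h, uAnterior = uAnterior, uDistal = uDistal)
}

movingAverage <- function(x, w) {
  if (w <= 1L) return(x)
  k <- rep(1 / w, w)
  pad <- (w - 1L) %/% 2L
  xp <- c(rep(x[1L], pad), x, rep(x[length(x)], w - 1L - pad))
  as.numeric(stats::filter(xp, k, sides = 1L))[(w - 1L + 1L):(w - 1L + length(x))]
}

## topographic prominence of a local maximum at index i of series s
peakProminence <- function(s, i) {
  n <- length(s)
  leftMin <- s[i]; j <- i
  while (j > 1L && s[j - 1L] <= s[i]) { j <- j - 1L; leftMin <- min(leftMin, s[j]) }
  rightMin <- s[i]; j <- i
  while (j < n && s[j + 1L] <= s[i]) { j <- j + 1L; rightMin <- min(rightMin, s[j]) }
  s[i] - max(leftMin, rightMin)
}

localMaxima <- function(s) {
  n <- length(s)
  if (n < 3L) return(integer(0))
  which(s[2:(n - 1L)] >= s[1:(n - 2L)] & s[2:(n - 1L)] >= s[3:n]) + 1L
}

#' Detect the lateral peak and the medial peak or inflection
#'
#' The profile is smoothed with a moving average (window \code{smoothMm});
#' the central valley is the minimum of the smoothed profile over the middle
#' third of the section; the lateral peak is the highest local maximum
#' lateral of the valley. A medial local maximum with topographic prominence
#' of at least \code{promMinMm} is a definite medial peak; otherwise the
#' medial feature is the most medial concave-to-convex transition of the
#' smoothed profile medial of the valley (the inflection fallback).
#'
#' @param profile a \linkS4class{ResectionProfile}.
#' @param smoothMm moving-average window, mm (default 2).
#' @param promMinMm minimum medial-peak prominence, mm (default 0.5).
#' @return A \linkS4class{PeakResult}.
#' @export
detectPeaks <- function(profile, smoothMm = 2, promMinMm = 0.5) {
  u <- profile@u
  h <- profile@h
  h[is.na(h)] <- 0                      # absent section counts as zero height
  step <- u[2L] - u[1L]
  w <- max(1L, 2L * floor(smoothMm / step / 2) + 1L)   # odd window
  s <- movingAverage(h, w)

  n <- length(u)
  third <- diff(range(u)) / 3
  midIdx <- which(u >= u[1L] + third & u <= u[n] - third)
  if (!length(midIdx)) stopGeometry("profile too short to locate a central valley")
  vIdx <- midIdx[which.min(s[midIdx])]

  latIdx <- localMaxima(s)
  latIdx <- latIdx[latIdx < vIdx]
  if (!length(latIdx))
    stopGeometry("no lateral maximum found (monotone profile); cannot classify the section")
  li <- latIdx[which.max(s[latIdx])]

  medIdx <- localMaxima(s)
  medIdx <- medIdx[medIdx > vIdx]
  if (length(medIdx)) {
    prom <- vapply(medIdx, function(i) peakProminence(s, i), numeric(1))
    medIdx <- medIdx[prom >= promMinMm]
    prom <- prom[prom >= promMinMm]
  } else prom <- numeric(0)

  if (length(medIdx)) {
    mi <- which.max(s[medIdx])
    res <- new("PeakResult", lateralU = u[li], lateralH = h[li],
               medialU = u[medIdx[mi]], medialH = h[medIdx[mi]],
               medialKind = "peak", prominence = prom[mi],
               valleyU = u[vIdx], valleyH = s[vIdx])
  } else {
    ## inflection fallback: most medial negative-to-nonnegative transition of
    ## the smoothed second difference, moving medially from the valley
    d2 <- c(NA, diff(s, differences = 2L), NA)
    cand <- integer(0)
    for (i in seq(vIdx, n - 1L)) {
      if (!is.na(d2[i]) && !is.na(d2[i + 1L]) && d2[i] < -1e-12 && d2[i + 1L] >= -1e-12)
        cand <- c(cand, i + 1L)
    }
    if (!length(cand)) {
      defined <- which(!is.na(profile@h))
      ii <- max(defined)                # no curvature transition: medial end
    } else ii <- max(cand)
    res <- new("PeakResult", lateralU = u[li], lateralH = h[li],
               medialU = u[ii], medialH = h[ii],
               medialKind = "inflection", prominence = NA_real_,
               valleyU = u[vIdx], valleyH = s[vIdx])
  }
  res
}

#' Measure the anterior resection surface
#'
#' Computes the published measurement set from a profile, its detected
#' features and the cut sections: LatL and MedL (heights above the distal
#' cutting line at the lateral peak and medial feature), their ratio, the
#' mediolateral widths ML (distal section) and M'L' (anterior section),
#' M'L'/ML, the lateral deviation LD (midline offset, lateral positive) and
#' LD/ML, and the double/single-peak shape class.
#'
#' @param profile a \linkS4class{ResectionProfile}.
#' @param peaks a \linkS4class{PeakResult}.
#' @param cut the originating \linkS4class{CutResult}.
#' @param reference label of the rotational reference used (recorded in the
#'   output).
#' @return A one-row data.frame with columns \code{LatL, MedL, MedL_LatL,
#'   ML, MpLp, MpLp_ML_pct, LD, LD_ML_pct, shape, reference}.
#' @export
measureResection <- function(profile, peaks, cut, reference = "sTEA") {
  latL <- peaks@lateralH
  medL <- peaks@medialH
  if (!is.finite(latL) || latL <= 0)
    stopGeometry("lateral length is zero; the anterior section has no lateral lobe")
  ml <- diff(profile@uDistal)
  mplp <- diff(profile@uAnterior)
  ld <- mean(profile@uDistal) - mean(profile@uAnterior)   # lateral (-u) positive
  data.frame(LatL = latL, MedL = medL, MedL_LatL = medL / latL,
             ML = ml, MpLp = mplp, MpLp_ML_pct = 100 * mplp / ml,
             LD = ld, LD_ML_pct = 100 * ld / ml,
             shape = if (peaks@medialKind == "peak") "double_peak" else "single_peak",
             reference = reference, stringsAsFactors = FALSE)
}

#' Medial-to-lateral anterior condylar height ratio
#'
#' The ratio medial/lateral, rounded half-up to two decimals -- the
#' convention used for published anterior condylar height tables.
#'
#' @param medial,lateral anterior condylar heights, mm (> 0).
#' @return Numeric scalar, two decimals.
#' @export
medLatRatio <- function(medial, lateral) {
  if (any(medial <= 0) || any(lateral <= 0))
    stop("anterior condylar heights must be positive", call. = FALSE)
  floor(medial / lateral * 100 + 0.5) / 100
}
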