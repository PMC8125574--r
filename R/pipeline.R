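# End-to-end orchestration: configuration, per-knee measurement across
# rotational references, cohort studies and rotation sweeps. Every output
# carries the seed and a hash of the configuration it was produced under.

#' Default pipeline configuration
#'
#' Nested list of all tunable parameters with their defaults:
#' \describe{
#'   \item{fea}{\code{bandFraction} (condylar bands as fractions of the ML
#'     width, default 0.15-0.45), \code{posteriorMaxY} / \code{distalMaxZ}
#'     (frame-coordinate thresholds, mm, selecting the posterior-distal
#'     arc), \code{minPoints} (minimum arc points per condyle, default 50).}
#'   \item{resection}{\code{distalDepthMm} (9), \code{flexionDeg} (3),
#'     \code{bandMm} (anterior referencing band above the distal cut,
#'     25-45), \code{reference} ("stea"), \code{extraRotationDeg} (0),
#'     \code{posteriorDepthMm} (9; recorded for completeness -- the
#'     posterior resection does not affect the anterior section under
#'     anterior referencing and is not applied).}
#'   \item{profile}{\code{stepMm} (0.25), \code{smoothMm} (2),
#'     \code{promMinMm} (0.5), \code{minAreaMm2} (1), \code{gapTolMm}
#'     (0.5).}
#' }
#'
#' @return Nested configuration list.
#' @export
defaultConfig <- function() {
  list(fea = list(bandFraction = c(0.15, 0.45), posteriorMaxY = -2,
                  distalMaxZ = 8, slabHalfWidth = 2.5, minPoints = 50L),
       resection = list(distalDepthMm = 9, flexionDeg = 3, bandMm = c(25, 45),
                        reference = "stea", extraRotationDeg = 0,
                        posteriorDepthMm = 9),
       profile = list(stepMm = 0.25, smoothMm = 2, promMinMm = 0.5,
                      minAreaMm2 = 1, gapTolMm = 0.5))
}

#' Read a run configuration from YAML
#'
#' Keys present in the file override the defaults; unknown keys raise a
#' schema error.
#'
#' @param path YAML file path.
#' @return Nested configuration list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stopSchema(paste0("config file not found: ", path))
  user <- yaml::read_yaml(path)
  cfg <- defaultConfig()
  for (section in names(user)) {
    if (!section %in% names(cfg))
      stopSchema(paste0("unknown config section: ", section))
    for (key in names(user[[section]])) {
      if (!key %in% names(cfg[[section]]))
        stopSchema(paste0("unknown config key: ", section, ".", key))
      cfg[[section]][[key]] <- user[[section]][[key]]
    }
  }
  cfg
}

#' Hash of a configuration list
#'
#' @param config configuration list.
#' @return 8-hex-digit hash, stamped into every output record.
#' @export
configHash <- function(config) {
  fnv1a(jsonlite::toJSON(config, auto_unbox = TRUE, digits = 10))
}

resolveReference <- function(ref, mesh, landmarks, frame, config) {
  switch(tolower(ref),
         stea = steaAxis(landmarks, frame),
         wsl = wslRotationReference(wslAxis(landmarks, frame), frame),
         fea = feaAxis(mesh, frame, config),
         pca = pcaAxis(mesh, frame, config),
         stopSchema(paste0("unknown rotational reference: ", ref,
                           " (use stea, wsl, fea or pca)")))
}

refLabel <- function(ref) c(stea = "sTEA", wsl = "WSL", fea = "FEA", pca = "PCA")[tolower(ref)]

#' Measure one knee for one or more rotational references
#'
#' Canonicalizes the mesh and landmarks, resolves each requested reference
#' axis, performs the virtual resection and returns one measurement row per
#' reference. The mediolateral width ML depends only on the distal cut and
#' is therefore identical across references.
#'
#' @param mesh a \linkS4class{TriMesh}.
#' @param landmarks the matching \linkS4class{LandmarkSet}.
#' @param references character vector among "stea", "wsl", "fea", "pca".
#' @param config configuration list (see \code{\link{defaultConfig}}).
#' @return data.frame, one row per reference (columns of
#'   \code{\link{measureResection}}); attributes \code{"configHash"} and
#'   \code{"cuts"} (named list of \linkS4class{CutResult}s).
#' @export
measureKnee <- function(mesh, landmarks, references = c("stea", "wsl", "fea"),
                        config = defaultConfig()) {
  can <- toCanonical(mesh, landmarks)
  frame <- canonicalFrame(can$landmarks)
  cuts <- list()
  rows <- lapply(references, function(ref) {
    axis <- resolveReference(ref, can$mesh, can$landmarks, frame, config)
    cut <- performResection(can$mesh, frame, axis, config)
    cuts[[ref]] <<- cut
    prof <- buildProfile(cut, config$profile$stepMm)
    peaks <- detectPeaks(prof, config$profile$smoothMm, config$profile$promMinMm)
    measureResection(prof, peaks, cut, reference = refLabel(ref))
  })
  out <- do.call(rbind, rows)
  attr(out, "configHash") <- configHash(config)
  attr(out, "cuts") <- cuts
  out
}

#' Measure a knee from files on disk
#'
#' @param meshPath STL/PLY mesh path.
#' @param landmarkPath landmark JSON path.
#' @inheritParams measureKnee
#' @return As \code{\link{measureKnee}}.
#' @export
measureKneeFiles <- function(meshPath, landmarkPath,
                             references = c("stea", "wsl", "fea"),
                             config = defaultConfig()) {
  measureKnee(loadMesh(meshPath), loadLandmarks(landmarkPath), references, config)
}

#' Rotation sweep: morphometry as a function of extra external rotation
#'
#' Re-runs the resection and measurement for each extra rotation angle
#' (positive = external) applied on top of the chosen reference.
#'
#' @param mesh a \linkS4class{TriMesh}.
#' @param landmarks the matching \linkS4class{LandmarkSet}.
#' @param reference one of "stea", "wsl", "fea", "pca".
#' @param angles numeric vector of extra rotations, degrees, within
#'   [-10, 10].
#' @param config configuration list.
#' @return data.frame: one measurement row per angle plus column
#'   \code{extraRotationDeg}.
#' @export
rotationSweep <- function(mesh, landmarks, reference = "stea",
                          angles = seq(-5, 5, by = 1), config = defaultConfig()) {
  if (any(angles < -10 | angles > 10))
    stopSchema("sweep angles must lie within [-10, 10] degrees")
  rows <- lapply(angles, function(a) {
    cfg <- config
    cfg$resection$extraRotationDeg <- a
    r <- measureKnee(mesh, landmarks, references = reference, config = cfg)
    r$extraRotationDeg <- a
    r
  })
  out <- do.call(rbind, rows)
  attr(out, "configHash") <- configHash(config)
  out
}

#' Run a synthetic cohort study in memory
#'
#' Draws per-knee seeds from \code{seed}, generates each femur, measures it
#' for the requested references and returns the pooled record table.
#' Failing knees are skipped and reported (attribute \code{"failures"}),
#' never aborting the run. \code{hAntMedShiftFemale} plants a configured
#' effect: it is added to the medial anterior facet height of every
#' female-like femur after sampling.
#'
#' @param nFemale,nMale cohort sizes.
#' @param seed global integer seed.
#' @param references character vector among "stea", "wsl", "fea", "pca".
#' @param config configuration list.
#' @param pitch voxel pitch for mesh generation, mm.
#' @param noiseAmplitude surface noise RMS amplitude, mm.
#' @param hAntMedShiftFemale planted medial facet height shift for
#'   female-like knees, mm (default 0).
#' @return data.frame of measurement rows with added columns \code{knee},
#'   \code{sex}, \code{seed}.
#' @export
runCohortStudy <- function(nFemale, nMale, seed, references = c("stea", "wsl", "fea"),
                           config = defaultConfig(), pitch = 0.8,
                           noiseAmplitude = 0.4, hAntMedShiftFemale = 0) {
  n <- nFemale + nMale
  seeds <- withSeed(seed, sample.int(2147483646L, n))
  sex <- rep(c("female", "male"), c(nFemale, nMale))
  rows <- list(); failures <- character(0)
  for (i in seq_len(n)) {
    rec <- tryCatch({
      params <- sampleFemurParams(if (sex[i] == "female") "female-like" else "male-like",
                                  seed = seeds[i], noiseAmplitude = noiseAmplitude)
      if (sex[i] == "female" && hAntMedShiftFemale != 0)
        params <- modifyFemurParams(params, hAntMed = params@hAntMed + hAntMedShiftFemale)
      fm <- buildFemur(params, pitch = pitch, pose = "random")
      r <- measureKnee(fm$mesh, fm$landmarks, references, config)
      r$knee <- sprintf("knee_%03d", i); r$sex <- sex[i]; r$seed <- seeds[i]
      r
    }, error = function(e) {
      failures <<- c(failures, sprintf("knee_%03d: %s", i, conditionMessage(e)))
      NULL
    })
    if (!is.null(rec)) rows[[length(rows) + 1L]] <- rec
  }
  out <- do.call(rbind, rows)
  attr(out, "configHash") <- configHash(config)
  attr(out, "failures") <- failures
  out
}

#' Measure every knee of an on-disk cohort manifest
#'
#' @param manifest data.frame with columns \code{mesh}, \code{landmarks},
#'   \code{sex} (as written by \code{\link{generateCohort}}), or the path of
#'   a manifest CSV.
#' @inheritParams runCohortStudy
#' @return As \code{\link{runCohortStudy}}.
#' @export
cohortFromManifest <- function(manifest, references = c("stea", "wsl", "fea"),
                               config = defaultConfig()) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest)
  need <- c("mesh", "landmarks", "sex")
  if (!all(need %in% names(manifest)))
    stopSchema("manifest needs columns mesh, landmarks, sex")
  rows <- list(); failures <- character(0)
  for (i in seq_len(nrow(manifest))) {
    rec <- tryCatch({
      r <- measureKneeFiles(manifest$mesh[i], manifest$landmarks[i], references, config)
      r$knee <- basename(manifest$mesh[i]); r$sex <- manifest$sex[i]
      r$seed <- if ("seed" %in% names(manifest)) manifest$seed[i] else NA
      r
    }, error = function(e) {
      failures <<- c(failures, sprintf("%s: %s", basename(manifest$mesh[i]),
                                       conditionMessage(e)))
      NULL
    })
    if (!is.null(rec)) rows[[length(rows) + 1L]] <- rec
  }
  if (!length(rows)) stopGeometry("every knee in the manifest failed to measure")
  out <- do.call(rbind, rows)
  attr(out, "configHash") <- configHash(config)
  attr(out, "failures") <- failures
  out
}

#' Write cohort summary tables to CSV
#'
#' @param summary list returned by \code{\link{summarizeCohort}}.
#' @param outDir output directory.
#' @return Paths of the written files, invisibly.
#' @export
writeSummaryTables <- function(summary, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(bySex = file.path(outDir, "medl_latl_by_sex.csv"),
             byReference = file.path(outDir, "medl_latl_by_reference.csv"),
             widths = file.path(outDir, "widths_by_sex.csv"),
             shapeCounts = file.path(outDir, "shape_counts.csv"))
  for (nm in names(paths)) utils::write.csv(summary[[nm]], paths[[nm]], row.names = FALSE)
  invisible(paths)
}
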