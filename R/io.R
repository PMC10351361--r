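# Persistence helpers for the standard interchange formats.

#' Persist a volume as NIfTI
#'
#' Dose grids, density volumes and masks are written as NIfTI-1 with the
#' phantom spacing in the header (requires the RNifti package).
#'
#' @param vol numeric or logical array.
#' @param phantom [Phantom] providing the geometry.
#' @param path output `.nii`/`.nii.gz` path.
#' @export
writeVolumeNifti <- function(vol, phantom, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI export")
  img <- RNifti::asNifti(array(as.numeric(vol), dim = phantom@gridShape),
                         pixdim = phantom@spacingMm)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeVolumeNifti
#' @return `readVolumeNifti` returns the volume as a numeric array.
#' @export
readVolumeNifti <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI import")
  arr <- RNifti::readNifti(path)
  array(as.numeric(arr), dim = dim(arr))
}

#' Serialize a plan as JSON
#'
#' Spots, optimized weights, robustness setting and the planning-phantom
#' fingerprint, round-trippable via [readPlanJSON()].
#'
#' @param plan a [ProtonPlan].
#' @param path output path.
#' @export
writePlanJSON <- function(plan, path) {
  jsonlite::write_json(list(
    spots = plan@spots@spots,
    weights = plan@spots@weights,
    isocenterMm = plan@spots@isocenterMm,
    setupUncertaintyMm = plan@robustness@setupUncertaintyMm,
    scenarioShifts = plan@robustness@scenarioShifts,
    objectiveValue = plan@objectiveValue,
    converged = plan@converged,
    phantomHash = plan@phantomHash), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writePlanJSON
#' @return `readPlanJSON` returns the reconstructed [ProtonPlan].
#' @export
readPlanJSON <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ss <- new("SpotSet", spots = as.data.frame(x$spots),
            weights = as.numeric(x$weights),
            isocenterMm = as.numeric(x$isocenterMm))
  rob <- new("RobustnessSetting",
             setupUncertaintyMm = x$setupUncertaintyMm,
             scenarioShifts = matrix(as.numeric(x$scenarioShifts),
                                     ncol = 3))
  new("ProtonPlan", spots = ss, robustness = rob,
      objectiveValue = x$objectiveValue, converged = x$converged,
      phantomHash = x$phantomHash)
}

#' Persist an influence matrix in MatrixMarket format
#'
#' The sparse operator goes to an `.mtx` file and the grid geometry to a
#' JSON sidecar next to it.
#'
#' @param influence an [InfluenceMatrix].
#' @param path output `.mtx` path.
#' @export
writeInfluenceMTX <- function(influence, path) {
  Matrix::writeMM(methods::as(influence@mat, "CsparseMatrix"), path)
  jsonlite::write_json(list(gridShape = influence@gridShape,
                            setupShiftMm = influence@setupShiftMm),
                       paste0(path, ".json"), digits = NA)
  invisible(path)
}
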