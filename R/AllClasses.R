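#' @useDynLib MorphoImprint, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats cutree dist hclust median prcomp quantile rnorm runif sd var cov setNames
#' @importFrom utils read.csv write.csv head modifyList
NULL

lesionClassLevels <- c("primary", "lymph_node_met", "solid_organ_met")

#' LesionVolume: a 3-D intensity volume with an aligned binary lesion mask
#'
#' The elementary imaging object of the package: one lesion, stored as a
#' 3-D scalar grid in Hounsfield units, a binary mask of the same shape, and
#' the voxel spacing in millimetres. Physical coordinates are
#' \code{(index - 1) * spacing} along each axis (0-based voxel indexing in
#' physical terms); NRRD \code{space directions} is the source of truth for
#' spacing when volumes are read from disk.
#'
#' @slot image numeric 3-D array, Hounsfield units.
#' @slot mask integer 3-D array of 0/1, same dimensions as \code{image}.
#' @slot spacing numeric length-3, voxel spacing in mm (x, y, z).
#'
#' @examples
#' vol <- LesionVolume(array(0, c(4, 4, 4)),
#'                     array(rep(c(0, 1), each = 32), c(4, 4, 4)),
#'                     spacing = c(1, 1, 1))
#' spacing(vol)
#' @export
setClass("LesionVolume",
  representation(image = "array", mask = "array", spacing = "numeric"))

setValidity("LesionVolume", function(object) {
  msg <- character()
  if (length(dim(object@image)) != 3L) msg <- c(msg, "image must be a 3-D array")
  if (!identical(dim(object@image), dim(object@mask)))
    msg <- c(msg, "image and mask dimensions differ")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive finite values (mm)")
  mv <- unique(as.vector(object@mask))
  if (!all(mv %in% c(0, 1))) msg <- c(msg, "mask must be binary (0/1)")
  if (sum(object@mask) < 1) msg <- c(msg, "mask must contain at least one foreground voxel")
  if (length(msg)) msg else TRUE
})

#' @param image,mask,spacing see slots.
#' @rdname LesionVolume-class
#' @export
LesionVolume <- function(image, mask, spacing = c(1, 1, 1)) {
  storage.mode(mask) <- "integer"
  new("LesionVolume", image = image, mask = mask, spacing = as.numeric(spacing))
}

#' LesionCohort: a set of lesion volumes plus per-lesion metadata
#'
#' Container pairing per-lesion \linkS4class{LesionVolume} objects with the
#' lesion metadata table (lesion id, patient id, primary tumor type,
#' anatomical environment, lesion class). Volumes are keyed by
#' \code{lesion_id}; metadata row order defines lesion order everywhere
#' downstream.
#'
#' @slot volumes named list of \linkS4class{LesionVolume}.
#' @slot meta data.frame with columns \code{lesion_id}, \code{patient_id},
#'   \code{tumor_type}, \code{environment}, \code{lesion_class}.
#' @export
setClass("LesionCohort", representation(volumes = "list", meta = "data.frame"))

setValidity("LesionCohort", function(object) {
  msg <- character()
  need <- c("lesion_id", "patient_id", "tumor_type", "environment", "lesion_class")
  if (!all(need %in% names(object@meta)))
    msg <- c(msg, paste("meta must have columns:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(object@meta$lesion_id)) msg <- c(msg, "duplicate lesion_id")
    if (!all(object@meta$lesion_class %in% lesionClassLevels))
      msg <- c(msg, paste("lesion_class values must be one of:",
                          paste(lesionClassLevels, collapse = ", ")))
    if (!identical(names(object@volumes), as.character(object@meta$lesion_id)))
      msg <- c(msg, "names(volumes) must equal meta$lesion_id in order")
  }
  if (!all(vapply(object@volumes, is, TRUE, "LesionVolume")))
    msg <- c(msg, "all volumes must be LesionVolume objects")
  if (length(msg)) msg else TRUE
})

#' @param volumes,meta see slots.
#' @rdname LesionCohort-class
#' @export
LesionCohort <- function(volumes, meta) {
  names(volumes) <- as.character(meta$lesion_id)
  new("LesionCohort", volumes = volumes, meta = meta)
}

#' ConcordanceResult: paired bootstrap ARI comparison of two labelings
#'
#' Holds the bootstrap ARI distributions of a morphological partition against
#' two ground-truth labelings (A = tumor type, B = anatomical environment by
#' convention), their means, 95\% percentile intervals, the paired mean
#' difference (B - A), the one-sided bootstrap p-value for H1: concordance
#' with B exceeds A, and the full-data (un-resampled) ARIs.
#'
#' @slot ariA,ariB numeric bootstrap ARI vectors, length \code{B}.
#' @slot labelNames character(2), names of the A and B labelings.
#' @slot meanA,meanB,meanDiff,pValue,ariAFull,ariBFull numeric scalars.
#' @slot ciA,ciB,ciDiff numeric length-2 95\% percentile intervals.
#' @slot B,seed integer.
#' @export
setClass("ConcordanceResult",
  representation(ariA = "numeric", ariB = "numeric", labelNames = "character",
                 meanA = "numeric", meanB = "numeric",
                 ciA = "numeric", ciB = "numeric",
                 meanDiff = "numeric", ciDiff = "numeric", pValue = "numeric",
                 ariAFull = "numeric", ariBFull = "numeric",
                 B = "integer", seed = "integer"))

setValidity("ConcordanceResult", function(object) {
  msg <- character()
  tol <- 1e-12
  if (length(object@ariA) != object@B || length(object@ariB) != object@B)
    msg <- c(msg, "bootstrap vectors must have length B")
  if (abs(object@meanA - mean(object@ariA)) > tol ||
      abs(object@meanB - mean(object@ariB)) > tol)
    msg <- c(msg, "stored means must equal means of the stored vectors")
  d <- object@ariB - object@ariA
  p <- (1 + sum(d <= 0)) / (object@B + 1)
  if (abs(object@pValue - p) > tol)
    msg <- c(msg, "p-value inconsistent with the stored difference vector")
  if (object@pValue <= 0 || object@pValue > 1) msg <- c(msg, "p-value out of (0, 1]")
  if (length(msg)) msg else TRUE
})
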