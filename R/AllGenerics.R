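#' @rdname LesionVolume-class
#' @param x,object a \linkS4class{LesionVolume} or \linkS4class{LesionCohort}.
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname LesionVolume-class
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))

#' @rdname LesionVolume-class
#' @export
setGeneric("imageArray", function(x) standardGeneric("imageArray"))

#' @rdname LesionCohort-class
#' @param x,object a \linkS4class{LesionCohort}.
#' @export
setGeneric("lesionMeta", function(x) standardGeneric("lesionMeta"))

#' @rdname LesionCohort-class
#' @export
setGeneric("lesionVolumes", function(x) standardGeneric("lesionVolumes"))

setMethod("spacing", "LesionVolume", function(x) x@spacing)
setMethod("maskArray", "LesionVolume", function(x) x@mask)
setMethod("imageArray", "LesionVolume", function(x) x@image)
setMethod("lesionMeta", "LesionCohort", function(x) x@meta)
setMethod("lesionVolumes", "LesionCohort", function(x) x@volumes)

setMethod("show", "LesionVolume", function(object) {
  d <- dim(object@image)
  cat("LesionVolume:", paste(d, collapse = " x "), "voxels at",
      paste(format(object@spacing, digits = 3), collapse = " x "), "mm |",
      sum(object@mask), "foreground voxels\n")
})

setMethod("show", "LesionCohort", function(object) {
  cat("LesionCohort with", nrow(object@meta), "lesions from",
      length(unique(object@meta$patient_id)), "patients\n")
  cat(" lesion classes:",
      paste(names(table(object@meta$lesion_class)),
            table(object@meta$lesion_class), collapse = ", ", sep = "="), "\n")
  cat(" environments:", paste(sort(unique(object@meta$environment)), collapse = ", "), "\n")
  cat(" tumor types: ", paste(sort(unique(object@meta$tumor_type)), collapse = ", "), "\n")
})

#' @rdname LesionCohort-class
#' @param i index, lesion id(s) or logical vector.
#' @export
setMethod("[", "LesionCohort", function(x, i) {
  if (is.character(i)) i <- match(i, x@meta$lesion_id)
  meta <- x@meta[i, , drop = FALSE]
  rownames(meta) <- NULL
  LesionCohort(x@volumes[i], meta)
})

#' @rdname LesionCohort-class
#' @export
setMethod("length", "LesionCohort", function(x) nrow(x@meta))

setMethod("show", "ConcordanceResult", function(object) {
  fmt <- function(m, ci) sprintf("%.3f [%.3f, %.3f]", m, ci[1], ci[2])
  cat("ConcordanceResult (paired bootstrap, B =", object@B, ")\n")
  cat(sprintf("  mean ARI %-14s %s (full-data %.3f)\n", object@labelNames[1],
              fmt(object@meanA, object@ciA), object@ariAFull))
  cat(sprintf("  mean ARI %-14s %s (full-data %.3f)\n", object@labelNames[2],
              fmt(object@meanB, object@ciB), object@ariBFull))
  cat(sprintf("  mean difference (%s - %s): %s\n", object@labelNames[2],
              object@labelNames[1], fmt(object@meanDiff, object@ciDiff)))
  cat(sprintf("  one-sided p-value: %.4g\n", object@pValue))
})

#' Tabular (Table-style) view of a ConcordanceResult
#'
#' One row per ground-truth labeling with mean ARI, 95\% CI, full-data ARI,
#' the paired mean difference and its CI, and the one-sided p-value.
#'
#' @param x a \linkS4class{ConcordanceResult}.
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return data.frame with two rows.
#' @export
as.data.frame.ConcordanceResult <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    ground_truth = x@labelNames,
    mean_ARI = c(x@meanA, x@meanB),
    CI_low = c(x@ciA[1], x@ciB[1]),
    CI_high = c(x@ciA[2], x@ciB[2]),
    original_ARI = c(x@ariAFull, x@ariBFull),
    mean_diff = x@meanDiff,
    diff_CI_low = x@ciDiff[1],
    diff_CI_high = x@ciDiff[2],
    p_value = x@pValue,
    stringsAsFactors = FALSE
  )
}
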