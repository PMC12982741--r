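#' Feature-extraction settings
#'
#' @param target_spacing isotropic resampling target, mm (default 1 mm^3).
#' @param discretization a [discretizationSpec()].
#' @param families texture families to compute.
#' @export
extractionSpec <- function(target_spacing = c(1, 1, 1),
                           discretization = discretizationSpec(),
                           families = textureFamilies) {
  if (length(target_spacing) == 1L) target_spacing <- rep(target_spacing, 3)
  structure(list(target_spacing = target_spacing,
                 discretization = discretization,
                 families = match.arg(families, textureFamilies, several.ok = TRUE)),
            class = "ExtractionSpec")
}

featureClassOf <- function(names) {
  fam <- sub("_.*$", "", names)
  cls <- c(shape = "shape", firstorder = "intensity",
           glcm = "texture", glrlm = "texture", glszm = "texture",
           ngtdm = "texture", gldm = "texture")[fam]
  data.frame(name = names, feature_class = unname(cls), family = unname(fam),
             stringsAsFactors = FALSE)
}

#' Extract the radiomic feature vector of one lesion
#'
#' Pipeline: isotropic resampling (cubic image / nearest-neighbour mask),
#' shape features on the mask, gray-level discretization, first-order
#' statistics, and all requested texture families. Every feature carries a
#' class tag (shape | intensity | texture) derived from its family. Features
#' undefined on a degenerate grid are returned as `NA` and imputed
#' downstream. Whole-voxel translations of image+mask leave the vector
#' unchanged (all operators are mask-relative).
#'
#' @param pair a \linkS4class{LesionVolume}.
#' @param spec an [extractionSpec()].
#' @return named numeric feature vector; attribute `meta` holds the
#'   name/class/family table.
#' @export
extractFeatures <- function(pair, spec = extractionSpec()) {
  pair <- resampleIsotropic(pair, spec$target_spacing)
  img <- imageArray(pair); msk <- maskArray(pair)
  # all operators are mask-relative: crop to the mask bounding box (+1 voxel)
  box <- maskBBox(msk, pad = 1L)
  img <- img[box[[1]], box[[2]], box[[3]], drop = FALSE]
  msk <- msk[box[[1]], box[[2]], box[[3]], drop = FALSE]
  shp <- shapeFeatures(msk, spacing(pair))
  fo <- firstOrderFeatures(img, msk, spec$discretization)
  lev <- discretizeIntensities(img, msk, spec$discretization)
  tex <- textureFeatures(lev$levels, lev$G, spec$families)
  out <- c(shp, fo, tex)
  attr(out, "meta") <- featureClassOf(names(out))
  out
}

#' Extract a cohort-level feature table
#'
#' Runs [extractFeatures()] on every lesion (optionally on one-voxel eroded
#' masks) and assembles the features x lesions matrix as a
#' \link[SummarizedExperiment]{SummarizedExperiment}: assay `"features"`,
#' `rowData` carrying the feature class/family tags, `colData` the lesion
#' metadata. Lesions whose eroded mask is empty are dropped with a warning
#' and listed in `metadata(se)$dropped_lesions`.
#'
#' @param cohort a \linkS4class{LesionCohort}.
#' @param spec an [extractionSpec()].
#' @param mask_variant `"full"` or `"eroded"` (one-voxel 6-connected
#'   erosion before extraction).
#' @return a SummarizedExperiment.
#' @export
extractCohortFeatures <- function(cohort, spec = extractionSpec(),
                                  mask_variant = c("full", "eroded")) {
  mask_variant <- match.arg(mask_variant)
  meta <- lesionMeta(cohort)
  vols <- lesionVolumes(cohort)
  rows <- vector("list", length(vols))
  dropped <- character()
  for (i in seq_along(vols)) {
    v <- vols[[i]]
    if (mask_variant == "eroded") {
      em <- erodeMask(maskArray(v))
      if (isTRUE(attr(em, "degenerate"))) {
        dropped <- c(dropped, meta$lesion_id[i])
        next
      }
      attributes(em) <- list(dim = dim(em))
      v <- LesionVolume(imageArray(v), em, spacing(v))
    }
    rows[[i]] <- extractFeatures(v, spec)
  }
  keep <- !vapply(rows, is.null, TRUE)
  if (!any(keep)) stop("all lesions degenerate under ", mask_variant, " masks")
  if (length(dropped))
    warning(length(dropped), " lesion(s) dropped: eroded mask empty (",
            paste(head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "", ")")
  mat <- t(do.call(rbind, rows[keep]))
  colnames(mat) <- meta$lesion_id[keep]
  fm <- featureClassOf(rownames(mat))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = mat),
    rowData = S4Vectors::DataFrame(feature_class = fm$feature_class, family = fm$family,
                                   row.names = fm$name),
    colData = S4Vectors::DataFrame(meta[keep, , drop = FALSE],
                                   row.names = meta$lesion_id[keep]))
  S4Vectors::metadata(se)$mask_variant <- mask_variant
  S4Vectors::metadata(se)$dropped_lesions <- dropped
  se
}

#' Feature-class tags of a feature table
#' @param se a SummarizedExperiment from [extractCohortFeatures()].
#' @return character vector (`shape`/`intensity`/`texture`) along rows.
#' @export
featureClasses <- function(se) SummarizedExperiment::rowData(se)$feature_class
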