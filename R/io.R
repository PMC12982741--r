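#' Write a lesion cohort to disk (NRRD + metadata CSV)
#'
#' One NRRD pair per lesion (`<lesion_id>_image.nrrd`,
#' `<lesion_id>_mask.nrrd`, `space directions` carrying the voxel spacing)
#' plus `metadata.csv` with header
#' `lesion_id,patient_id,tumor_type,environment,lesion_class`.
#'
#' @param cohort a \linkS4class{LesionCohort}.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- lesionMeta(cohort)
  vols <- lesionVolumes(cohort)
  for (id in meta$lesion_id) {
    v <- vols[[id]]
    writeNRRD(imageArray(v), file.path(dir, paste0(id, "_image.nrrd")), spacing(v))
    writeNRRD(maskArray(v) + 0, file.path(dir, paste0(id, "_mask.nrrd")),
              spacing(v), type = "uchar")
  }
  writeStableCSV(meta, file.path(dir, "metadata.csv"))
  invisible(dir)
}

#' Read and validate a lesion metadata table
#'
#' @param path CSV with header
#'   `lesion_id,patient_id,tumor_type,environment,lesion_class`.
#' @param nrrd_dir optional directory; when given, every lesion must have
#'   its `<lesion_id>_image.nrrd` / `<lesion_id>_mask.nrrd` pair there
#'   (dangling references are an error).
#' @return validated data.frame.
#' @export
readLesionTable <- function(path, nrrd_dir = NULL) {
  if (!file.exists(path)) stop("lesion table not found: ", path)
  meta <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lesion_id", "patient_id", "tumor_type", "environment", "lesion_class")
  if (!all(need %in% names(meta)))
    stop("lesion table must have columns: ", paste(need, collapse = ", "))
  dup <- meta$lesion_id[duplicated(meta$lesion_id)]
  if (length(dup)) stop("duplicate lesion_id: ", paste(unique(dup), collapse = ", "))
  bad <- which(!meta$lesion_class %in% lesionClassLevels)
  if (length(bad))
    stop("invalid lesion_class ", shQuote(meta$lesion_class[bad[1]]),
         " in row ", bad[1], "; allowed: ", paste(lesionClassLevels, collapse = ", "))
  if (!is.null(nrrd_dir)) {
    for (id in meta$lesion_id) {
      for (suffix in c("_image.nrrd", "_mask.nrrd")) {
        f <- file.path(nrrd_dir, paste0(id, suffix))
        if (!file.exists(f)) stop("dangling file reference for lesion ", id, ": ", f)
      }
    }
  }
  meta
}

#' Read a lesion cohort from a directory written by [writeCohort()]
#'
#' Alignment is keyed by `lesion_id`, so the metadata row order defines the
#' cohort order regardless of file listing order.
#'
#' @param dir cohort directory.
#' @return a \linkS4class{LesionCohort}.
#' @export
readCohort <- function(dir) {
  meta <- readLesionTable(file.path(dir, "metadata.csv"), nrrd_dir = dir)
  vols <- lapply(meta$lesion_id, function(id) {
    img <- readNRRD(file.path(dir, paste0(id, "_image.nrrd")))
    msk <- readNRRD(file.path(dir, paste0(id, "_mask.nrrd")))
    if (!identical(dim(img$data), dim(msk$data)))
      stop("image/mask dimension mismatch for lesion ", id)
    LesionVolume(img$data, array(as.integer(msk$data > 0.5), dim(msk$data)),
                 img$spacing)
  })
  LesionCohort(vols, meta)
}

#' Read and validate a YAML run configuration
#'
#' A single structured config file (versioned schema) drives the pipeline:
#' a `cohort` section (synthetic generator parameters or a data directory),
#' an `extraction` section, an `analysis` section and a `seeds` section.
#' Unknown keys are rejected before any computation.
#'
#' @param path YAML file.
#' @return list with `config` (a [cohortConfig()] or cohort directory),
#'   `extraction` ([extractionSpec()]), `analysis` parameters and `seeds`.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- c("schema_version", "cohort", "extraction", "analysis", "seeds", "output_dir")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cohort <- if (!is.null(raw$cohort$dir)) raw$cohort$dir else {
    ck <- raw$cohort %||% list()
    unknownC <- setdiff(names(ck),
      c("environments", "tumor_types", "n_patients", "lesions_per_patient",
        "lesion_class_mix", "short_axis_range", "grid_dim", "voxel_spacing",
        "noise_sd", "background_mean", "max_lesions_per_organ", "seed"))
    if (length(unknownC)) stop("unknown cohort config keys: ",
                               paste(unknownC, collapse = ", "))
    envs <- if (is.null(ck$environments)) defaultEnvironments() else
      lapply(ck$environments, function(e) do.call(environmentProfile, e))
    tts <- if (is.null(ck$tumor_types)) defaultTumorTypes() else
      lapply(ck$tumor_types, function(t) do.call(tumorTypeProfile, t))
    args <- ck[setdiff(names(ck), c("environments", "tumor_types"))]
    if (!is.null(args$lesion_class_mix)) args$lesion_class_mix <- unlist(args$lesion_class_mix)
    do.call(cohortConfig, c(list(environments = envs, tumor_types = tts), args))
  }
  ex <- raw$extraction %||% list()
  extraction <- extractionSpec(
    target_spacing = ex$target_spacing %||% c(1, 1, 1),
    discretization = if (is.null(ex$discretization)) discretizationSpec() else
      do.call(discretizationSpec, ex$discretization),
    families = ex$families %||% textureFamilies)
  an <- raw$analysis %||% list()
  seeds <- raw$seeds %||% list()
  seeds <- list(cohort = seeds$cohort %||% 1L, embedding = seeds$embedding %||% 11L,
                optimizer = seeds$optimizer %||% 12L,
                bootstrap = seeds$bootstrap %||% 13L)
  list(config = cohort, extraction = extraction,
       analysis = list(
         space = clusteringSearchSpace(
           k_range = unlist(an$k_range %||% c(2, 15)),
           linkages = an$linkages %||% c("ward", "complete", "average"),
           budget = an$budget %||% 50),
         perplexity = an$perplexity %||% 30,
         max_iter = an$max_iter %||% 1000,
         B = an$B %||% 100,
         ari_mode = an$ari_mode %||% "mean",
         representation = an$representation %||% "embedding"),
       seeds = seeds,
       output_dir = raw$output_dir %||% "experiments")
}
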