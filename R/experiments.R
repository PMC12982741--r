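#' Specification of one concordance experiment
#'
#' One experiment is one fully specified tuple: cohort source, lesion
#' subset (all / metastatic-only / solid-organ-metastases-only), feature
#' class subset, mask variant (full or one-voxel eroded), representation
#' (t-SNE embedding or raw standardized features), plus the search space,
#' bootstrap size and named seeds.
#'
#' @param cohort a \linkS4class{LesionCohort}, a [cohortConfig()] (generated
#'   on demand), or a directory previously written by [writeCohort()].
#' @param lesion_subset `"all"`, `"metastatic"` (drops primaries) or
#'   `"solid_organ"` (additionally drops lymph-node metastases).
#' @param feature_subset `"all"`, `"shape"`, `"intensity"` or `"texture"`.
#' @param mask_variant `"full"` or `"eroded"`.
#' @param representation `"embedding"` or `"raw"`.
#' @param extraction an [extractionSpec()].
#' @param space a [clusteringSearchSpace()].
#' @param perplexity,max_iter t-SNE hyperparameters.
#' @param B bootstrap iterations.
#' @param ari_mode objective ARI mode, see [optimizeClustering()].
#' @param env_grouping optional named character vector mapping environment
#'   labels onto grouped (systems-level) labels; applied to the metadata
#'   before analysis. Default identity.
#' @param seeds named list with independent `embedding`, `optimizer` and
#'   `bootstrap` seeds.
#' @export
experimentSpec <- function(cohort = NULL,
                           lesion_subset = c("all", "metastatic", "solid_organ"),
                           feature_subset = c("all", "shape", "intensity", "texture"),
                           mask_variant = c("full", "eroded"),
                           representation = c("embedding", "raw"),
                           extraction = extractionSpec(),
                           space = clusteringSearchSpace(),
                           perplexity = 30, max_iter = 1000,
                           B = 100, ari_mode = "mean", env_grouping = NULL,
                           seeds = list(embedding = 11L, optimizer = 12L,
                                        bootstrap = 13L)) {
  structure(list(cohort = cohort,
                 lesion_subset = match.arg(lesion_subset),
                 feature_subset = match.arg(feature_subset),
                 mask_variant = match.arg(mask_variant),
                 representation = match.arg(representation),
                 extraction = extraction, space = space,
                 perplexity = perplexity, max_iter = max_iter,
                 B = as.integer(B), ari_mode = ari_mode,
                 env_grouping = env_grouping, seeds = seeds),
            class = "ExperimentSpec")
}

#' Subset a feature table by lesion class
#'
#' `metastatic` drops primary tumors; `solid_organ` additionally drops
#' lymph-node metastases. Row (feature) content and lesion order are
#' preserved.
#'
#' @param se SummarizedExperiment with lesion metadata in `colData`.
#' @param subset `"all"`, `"metastatic"` or `"solid_organ"`.
#' @return the subset SummarizedExperiment (error if it would be empty).
#' @export
subsetLesions <- function(se, subset = c("all", "metastatic", "solid_organ")) {
  subset <- match.arg(subset)
  cls <- SummarizedExperiment::colData(se)$lesion_class
  keep <- switch(subset,
    all = rep(TRUE, ncol(se)),
    metastatic = cls != "primary",
    solid_organ = cls == "solid_organ_met")
  if (!any(keep)) stop("lesion subset '", subset, "' is empty")
  se[, keep]
}

#' Subset a feature table by feature class
#'
#' @param se SummarizedExperiment with `feature_class` tags in `rowData`.
#' @param feature_class `"all"`, `"shape"`, `"intensity"` or `"texture"`.
#' @return the subset SummarizedExperiment (error if no such features).
#' @export
subsetFeatures <- function(se, feature_class = c("all", "shape", "intensity",
                                                 "texture")) {
  feature_class <- match.arg(feature_class)
  if (feature_class == "all") return(se)
  keep <- featureClasses(se) == feature_class
  if (!any(keep)) stop("no features of class '", feature_class, "' in the table")
  se[keep, ]
}

applyEnvGrouping <- function(se, grouping) {
  if (is.null(grouping)) return(se)
  env <- SummarizedExperiment::colData(se)$environment
  hit <- env %in% names(grouping)
  env[hit] <- unname(grouping[env[hit]])
  SummarizedExperiment::colData(se)$environment <- env
  se
}

resolveCohort <- function(x) {
  if (is(x, "LesionCohort")) return(x)
  if (inherits(x, "CohortConfig")) return(generateCohort(x))
  if (is.character(x) && dir.exists(x)) return(readCohort(x))
  stop("cohort must be a LesionCohort, a cohortConfig(), or a cohort directory")
}

#' Run one end-to-end concordance experiment
#'
#' Pipeline: extract features (respecting the mask variant), group
#' environments, subset lesions and features, standardize + impute, embed
#' (or keep raw), optimize the clustering, bootstrap the concordance against
#' both ground truths, and build contingency tables. Fully determined by the
#' spec and its seeds.
#'
#' @param spec an [experimentSpec()].
#' @param features optional precomputed SummarizedExperiment from
#'   [extractCohortFeatures()] matching `spec$mask_variant` (avoids
#'   re-extraction across grid cells).
#' @param out_dir optional directory; when given, all artifacts are
#'   persisted there via [persistExperiment()].
#' @return an `ExperimentReport` list: selected `k`, `silhouette`,
#'   `concordance` (\linkS4class{ConcordanceResult}), `contingency` per
#'   ground truth, `partition`, `points`, `best_params`, `trace`,
#'   `dropped_lesions`, `provenance`, and the spec echo.
#' @export
runExperiment <- function(spec, features = NULL, out_dir = NULL) {
  stopifnot(inherits(spec, "ExperimentSpec"))
  if (is.null(features)) {
    cohort <- resolveCohort(spec$cohort)
    features <- extractCohortFeatures(cohort, spec$extraction, spec$mask_variant)
  } else if (!identical(S4Vectors::metadata(features)$mask_variant, spec$mask_variant)) {
    stop("precomputed features were extracted with mask_variant '",
         S4Vectors::metadata(features)$mask_variant, "' but the spec asks for '",
         spec$mask_variant, "'")
  }
  se <- applyEnvGrouping(features, spec$env_grouping)
  se <- subsetLesions(se, spec$lesion_subset)
  se <- subsetFeatures(se, spec$feature_subset)
  se <- standardizeImpute(se)
  cd <- SummarizedExperiment::colData(se)
  gt <- list(tumor_type = as.character(cd$tumor_type),
             environment = as.character(cd$environment))
  points <- if (spec$representation == "embedding") {
    embedLesions(se, perplexity = spec$perplexity, max_iter = spec$max_iter,
                 seed = spec$seeds$embedding)
  } else {
    t(SummarizedExperiment::assay(se, "features"))
  }
  space <- spec$space
  space$seed <- spec$seeds$optimizer
  opt <- optimizeClustering(points, gt, space, spec$ari_mode)
  conc <- bootstrapConcordance(opt$partition, gt$tumor_type, gt$environment,
                               B = spec$B, seed = spec$seeds$bootstrap)
  report <- list(
    spec = specEcho(spec),
    n_lesions = ncol(se), n_features = nrow(se),
    k = nlevels(opt$partition), silhouette = opt$silhouette,
    best_params = opt$best_params, objective = opt$objective,
    trace = opt$trace,
    concordance = conc,
    contingency = list(tumor_type = contingencyTable(opt$partition, gt$tumor_type),
                       environment = contingencyTable(opt$partition, gt$environment)),
    partition = opt$partition, points = points,
    dropped_lesions = S4Vectors::metadata(features)$dropped_lesions,
    provenance = provenanceStamp(specEcho(spec), spec$seeds))
  class(report) <- "ExperimentReport"
  if (!is.null(out_dir)) persistExperiment(report, out_dir, se)
  report
}

specEcho <- function(spec) {
  s <- unclass(spec)
  s$cohort <- if (is.null(spec$cohort)) "precomputed features" else
    if (inherits(spec$cohort, "CohortConfig")) unclass(spec$cohort) else
      "in-memory cohort"
  s
}

#' @export
print.ExperimentReport <- function(x, ...) {
  cat("ExperimentReport:", x$spec$lesion_subset, "lesions,",
      x$spec$feature_subset, "features,", x$spec$mask_variant, "masks,",
      x$spec$representation, "representation\n")
  cat("  n =", x$n_lesions, "| k =", x$k,
      "| silhouette =", round(x$silhouette, 3), "\n")
  show(x$concordance)
  invisible(x)
}

#' Persist all artifacts of an experiment
#'
#' Writes `features.csv` (standardized features used), `embedding.csv` (or
#' raw coordinates), `partition.csv`, `concordance.json`,
#' `contingency_<label>.csv`, `trace.csv` and `report.json` into a
#' directory. Output is byte-stable across re-runs with identical spec and
#' seeds.
#'
#' @param report an `ExperimentReport`.
#' @param dir output directory (created if needed).
#' @param se the standardized SummarizedExperiment used (optional; enables
#'   `features.csv`).
#' @return `dir`, invisibly.
#' @export
persistExperiment <- function(report, dir, se = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(se)) {
    m <- t(SummarizedExperiment::assay(se, "features"))
    writeStableCSV(data.frame(lesion_id = rownames(m), m, check.names = FALSE),
                   file.path(dir, "features.csv"))
  }
  pts <- report$points
  writeStableCSV(data.frame(lesion_id = rownames(pts),
                            dim1 = pts[, 1], dim2 = if (ncol(pts) > 1) pts[, 2] else 0),
                 file.path(dir, "embedding.csv"))
  writeStableCSV(data.frame(lesion_id = names(report$partition),
                            cluster = as.integer(report$partition)),
                 file.path(dir, "partition.csv"))
  writeConcordanceJSON(report$concordance, file.path(dir, "concordance.json"))
  for (gtName in names(report$contingency)) {
    ct <- report$contingency[[gtName]]
    writeStableCSV(data.frame(ground_truth = rownames(ct$row_pct),
                              as.data.frame.matrix(ct$row_pct), check.names = FALSE),
                   file.path(dir, paste0("contingency_", gtName, ".csv")))
  }
  writeStableCSV(report$trace, file.path(dir, "trace.csv"))
  summary <- list(spec = stripClasses(report$spec[setdiff(names(report$spec), "cohort")]),
                  n_lesions = report$n_lesions, n_features = report$n_features,
                  k = report$k, silhouette = report$silhouette,
                  best_params = report$best_params, objective = report$objective,
                  dropped_lesions = report$dropped_lesions,
                  concordance = as.data.frame(report$concordance),
                  provenance = report$provenance)
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Run a grid of experiments and summarize in result-table layout
#'
#' Enumerates the requested axes (lesion subset, feature subset, mask
#' variant, representation) around a base spec, re-using feature extraction
#' across cells that share a mask variant; each cell re-runs embedding and
#' optimization on its own subset. Failures are marked per cell and the grid
#' continues.
#'
#' @param base_spec an [experimentSpec()] with a resolvable cohort.
#' @param axes named list of axis values, e.g.
#'   `list(lesion_subset = c("all", "metastatic", "solid_organ"))`; empty
#'   axes run the base spec alone.
#' @param out_dir optional root directory; each cell is persisted into a
#'   subdirectory, with a combined `summary_table.csv` at the top.
#' @return list with `reports` (one per cell, or a `try-error`) and
#'   `summary` (one row per report and ground truth).
#' @export
runGrid <- function(base_spec, axes = list(), out_dir = NULL) {
  allowed <- c("lesion_subset", "feature_subset", "mask_variant", "representation")
  if (!all(names(axes) %in% allowed))
    stop("axes must be among: ", paste(allowed, collapse = ", "))
  grid <- if (length(axes)) expand.grid(axes, stringsAsFactors = FALSE) else
    data.frame(row.names = 1)
  cohort <- resolveCohort(base_spec$cohort)
  variants <- unique(if ("mask_variant" %in% names(grid)) grid$mask_variant else
    base_spec$mask_variant)
  featCache <- lapply(stats::setNames(variants, variants), function(v)
    extractCohortFeatures(cohort, base_spec$extraction, v))
  reports <- list(); rows <- list()
  for (r in seq_len(max(1L, nrow(grid)))) {
    spec <- base_spec
    for (ax in names(grid)) spec[[ax]] <- grid[[ax]][r]
    cellName <- paste(spec$lesion_subset, spec$feature_subset,
                      spec$mask_variant, spec$representation, sep = "_")
    rep <- try(runExperiment(spec, features = featCache[[spec$mask_variant]],
                             out_dir = if (is.null(out_dir)) NULL else
                               file.path(out_dir, cellName)),
               silent = TRUE)
    reports[[cellName]] <- rep
    if (inherits(rep, "try-error")) {
      rows[[cellName]] <- data.frame(analysis = cellName, cohort = NA,
        ground_truth = NA, mean_ARI = NA, CI_low = NA, CI_high = NA,
        original_ARI = NA, mean_diff = NA, diff_CI_low = NA, diff_CI_high = NA,
        p_value = NA, error = conditionMessage(attr(rep, "condition")))
    } else {
      df <- as.data.frame(rep$concordance)
      rows[[cellName]] <- data.frame(analysis = cellName,
        cohort = sprintf("synthetic (n = %d)", rep$n_lesions), df,
        error = NA_character_)
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writeStableCSV(summary, file.path(out_dir, "summary_table.csv"))
  }
  list(reports = reports, summary = summary)
}
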