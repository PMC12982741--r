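#' Environment profile for the synthetic lesion generator
#'
#' Describes the intensity/texture "imprint" a host anatomical environment
#' stamps on lesions growing in it: the in-mask HU distribution, the
#' correlation length of the smoothed-noise texture field, and an optional
#' additive rim within one voxel of the mask boundary.
#'
#' @param name unique environment label.
#' @param intensity_mean in-mask mean intensity, HU.
#' @param intensity_sd in-mask intensity SD, HU (> 0).
#' @param texture_smoothing_sigma Gaussian smoothing sigma of the in-mask
#'   noise field, in voxels (>= 0; 0 = white noise).
#' @param rim_contrast additive HU offset applied within 1 voxel of the mask
#'   boundary (may be 0 or negative).
#' @param nodal logical; marks the nodal (lymph node) environment, the fixed
#'   destination of lymph-node metastases.
#' @return a classed list usable in [cohortConfig()].
#' @export
environmentProfile <- function(name, intensity_mean, intensity_sd,
                               texture_smoothing_sigma = 1, rim_contrast = 0,
                               nodal = FALSE) {
  stopifnot(is.character(name), nchar(name) > 0)
  if (intensity_sd <= 0) stop("intensity_sd must be > 0")
  if (texture_smoothing_sigma < 0) stop("texture_smoothing_sigma must be >= 0")
  structure(list(name = name, intensity_mean = intensity_mean,
                 intensity_sd = intensity_sd,
                 texture_smoothing_sigma = texture_smoothing_sigma,
                 rim_contrast = rim_contrast, nodal = isTRUE(nodal)),
            class = "EnvironmentProfile")
}

#' Tumor-type (lineage) profile for the synthetic lesion generator
#'
#' Describes the (typically weak) lineage-driven shape effect: the
#' distribution of the major/short ellipsoid axis ratio and a radial surface
#' roughness amplitude. `home_environment` names the organ where primaries of
#' this type arise; primary lesions always reside there.
#'
#' @param name unique tumor-type label.
#' @param axis_ratio_mean mean major/short axis ratio (>= 1).
#' @param axis_ratio_sd SD of the axis ratio (>= 0; sampled truncated at 1).
#' @param surface_perturbation_amp radial roughness amplitude, voxels (>= 0).
#' @param home_environment environment name of the primary site.
#' @export
tumorTypeProfile <- function(name, axis_ratio_mean, axis_ratio_sd = 0.1,
                             surface_perturbation_amp = 0, home_environment) {
  stopifnot(is.character(name), nchar(name) > 0)
  if (axis_ratio_mean < 1) stop("axis_ratio_mean must be >= 1")
  if (surface_perturbation_amp < 0) stop("surface_perturbation_amp must be >= 0")
  structure(list(name = name, axis_ratio_mean = axis_ratio_mean,
                 axis_ratio_sd = axis_ratio_sd,
                 surface_perturbation_amp = surface_perturbation_amp,
                 home_environment = home_environment),
            class = "TumorTypeProfile")
}

#' Default environment profiles (strong environmental imprint)
#'
#' Four portal-venous-phase environments whose in-mask intensity means are
#' separated by at least three pooled SDs and whose texture correlation
#' lengths differ, giving downstream clustering a recoverable environment
#' signal. Values are synthetic stand-ins, not measured tissue HU.
#'
#' @return list of [environmentProfile()] objects.
#' @export
defaultEnvironments <- function() {
  list(
    environmentProfile("lung", intensity_mean = 35, intensity_sd = 12,
                       texture_smoothing_sigma = 0.6, rim_contrast = 0),
    environmentProfile("hepatobiliary", intensity_mean = 95, intensity_sd = 12,
                       texture_smoothing_sigma = 1.4, rim_contrast = 20),
    environmentProfile("lymph_node", intensity_mean = 155, intensity_sd = 12,
                       texture_smoothing_sigma = 1.0, rim_contrast = 0, nodal = TRUE),
    environmentProfile("bone", intensity_mean = 220, intensity_sd = 12,
                       texture_smoothing_sigma = 2.2, rim_contrast = 0)
  )
}

#' Default tumor-type profiles (weak lineage shape effect)
#'
#' Five lineages differing modestly in ellipsoid axis ratio and surface
#' roughness. Home-organ assignments are synthetic stand-ins so that primary
#' lesions have a well-defined environment.
#'
#' @return list of [tumorTypeProfile()] objects.
#' @export
defaultTumorTypes <- function() {
  list(
    tumorTypeProfile("lung", 1.15, 0.10, 0.2, home_environment = "lung"),
    tumorTypeProfile("colorectal", 1.30, 0.12, 0.6, home_environment = "hepatobiliary"),
    tumorTypeProfile("breast", 1.45, 0.12, 1.0, home_environment = "bone"),
    tumorTypeProfile("melanoma", 1.20, 0.10, 0.4, home_environment = "lung"),
    tumorTypeProfile("sarcoma", 1.60, 0.15, 1.4, home_environment = "bone")
  )
}

#' Configuration of a synthetic lesion cohort
#'
#' Bundles the environment and tumor-type profiles with cohort-level knobs:
#' patient count, lesions per patient, the lesion-class mixture
#' (primary / lymph-node metastasis / solid-organ metastasis), the short-axis
#' sampling range (lower bound >= 10 mm, the segmentation floor), grid and
#' voxel geometry, acquisition noise, and the master seed. The full cohort
#' (images, masks, metadata) is a pure function of this object.
#'
#' @param environments list of [environmentProfile()]; unique names.
#' @param tumor_types list of [tumorTypeProfile()]; home environments must be
#'   configured environments.
#' @param n_patients number of patients.
#' @param lesions_per_patient either a single integer (fixed count) or a
#'   length-2 integer range sampled uniformly per patient.
#' @param lesion_class_mix named proportions over
#'   `primary`, `lymph_node_met`, `solid_organ_met`; must sum to 1.
#' @param short_axis_range mm; lesions' short axis is sampled uniformly from
#'   this range. Lower bound must be >= 10 mm.
#' @param grid_dim voxel grid of each per-lesion volume.
#' @param voxel_spacing mm triple (configurable anisotropy to exercise
#'   resampling).
#' @param noise_sd independent voxel noise, HU.
#' @param background_mean constant background intensity, HU.
#' @param affinity optional tumor-type x environment matrix of solid-organ
#'   metastasis destination weights (rows = tumor types, cols = non-nodal
#'   environments); default uniform, i.e. metastasis environment independent
#'   of tumor type.
#' @param max_lesions_per_organ cap per (patient, environment); default 10.
#' @param seed master seed; every random draw in the cohort derives from it.
#' @return a classed config list, validated.
#' @export
cohortConfig <- function(environments = defaultEnvironments(),
                         tumor_types = defaultTumorTypes(),
                         n_patients = 200,
                         lesions_per_patient = 3,
                         lesion_class_mix = c(primary = 0.08,
                                              lymph_node_met = 0.25,
                                              solid_organ_met = 0.67),
                         short_axis_range = c(11, 18),
                         grid_dim = c(64, 64, 64),
                         voxel_spacing = c(1, 1, 1),
                         noise_sd = 10,
                         background_mean = -75,
                         affinity = NULL,
                         max_lesions_per_organ = 10,
                         seed = 1L) {
  if (length(environments) == 0 || length(tumor_types) == 0)
    stop("config error: environments and tumor_types must be non-empty")
  envNames <- vapply(environments, `[[`, "", "name")
  if (anyDuplicated(envNames)) stop("environment names must be unique")
  ttNames <- vapply(tumor_types, `[[`, "", "name")
  if (anyDuplicated(ttNames)) stop("tumor type names must be unique")
  homes <- vapply(tumor_types, `[[`, "", "home_environment")
  if (!all(homes %in% envNames))
    stop("tumor-type home environments must be configured environments")
  if (abs(sum(lesion_class_mix) - 1) > 1e-8)
    stop("lesion_class_mix must sum to 1")
  if (!all(names(lesion_class_mix) %in% lesionClassLevels) ||
      length(lesion_class_mix) != 3L)
    stop("lesion_class_mix must be named over: ", paste(lesionClassLevels, collapse = ", "))
  if (short_axis_range[1] < 10)
    stop("short_axis_range lower bound must be >= 10 mm (segmentation floor)")
  if (length(lesions_per_patient) == 1L) lesions_per_patient <- rep(lesions_per_patient, 2)
  solidEnvs <- envNames[!vapply(environments, `[[`, TRUE, "nodal")]
  if (length(solidEnvs) == 0) stop("at least one non-nodal environment is required")
  if (!is.null(affinity)) {
    affinity <- as.matrix(affinity)
    if (!all(rownames(affinity) == ttNames) || !all(colnames(affinity) %in% envNames))
      stop("affinity matrix must be tumor_types x environments with matching names")
  }
  structure(list(environments = stats::setNames(environments, envNames),
                 tumor_types = stats::setNames(tumor_types, ttNames),
                 n_patients = as.integer(n_patients),
                 lesions_per_patient = as.integer(lesions_per_patient),
                 lesion_class_mix = lesion_class_mix[lesionClassLevels],
                 short_axis_range = short_axis_range,
                 grid_dim = as.integer(grid_dim),
                 voxel_spacing = as.numeric(voxel_spacing),
                 noise_sd = noise_sd,
                 background_mean = background_mean,
                 affinity = affinity,
                 max_lesions_per_organ = as.integer(max_lesions_per_organ),
                 seed = as.integer(seed)),
            class = "CohortConfig")
}

truncNorm1 <- function(mean, sd, lower = 1) {
  for (i in 1:50) {
    v <- rnorm(1, mean, sd)
    if (v >= lower) return(v)
  }
  lower
}

randomRotation <- function() {
  qr <- qr(matrix(rnorm(9), 3))
  q <- qr.Q(qr)
  q * det(q) # proper rotation
}

#' Generate one synthetic lesion volume
#'
#' Builds a perturbed-ellipsoid binary mask whose short axis (second-largest
#' principal extent) respects the configured >= 10 mm floor, then fills the
#' in-mask image with the environment's imprint: a Gaussian random field with
#' mean `intensity_mean`, SD `intensity_sd` and correlation length
#' `texture_smoothing_sigma`, an additive `rim_contrast` within one voxel of
#' the boundary, plus independent voxel noise. Background is a distinct
#' constant plus noise. Deterministic given `(env, ttype, config, seed)`.
#'
#' @param env an [environmentProfile()] belonging to `config`.
#' @param ttype a [tumorTypeProfile()] belonging to `config`.
#' @param config a [cohortConfig()].
#' @param seed optional integer; when given, the RNG is seeded locally.
#' @return a \linkS4class{LesionVolume}.
#' @export
generateLesion <- function(env, ttype, config = cohortConfig(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dims <- config$grid_dim
  sp <- config$voxel_spacing
  fieldMM <- dims * sp
  sA <- runif(1, config$short_axis_range[1], config$short_axis_range[2])
  ratio <- truncNorm1(ttype$axis_ratio_mean, ttype$axis_ratio_sd)
  wMinor <- runif(1, 0.8, 1)
  semi <- c(ratio * sA / 2, sA / 2, wMinor * sA / 2) # major, short, least (mm)
  if (2 * semi[1] > min(fieldMM) - 6 * mean(sp))
    stop("sizing error: requested lesion (major axis ", round(2 * semi[1], 1),
         " mm) does not fit the ", paste(dims, collapse = "x"), " grid")
  rot <- randomRotation()
  center <- fieldMM / 2 + runif(3, -3, 3) * mean(sp)
  amp <- ttype$surface_perturbation_amp

  # work on a padded sub-grid around the lesion; fields need full kernel
  # support inside the mask, so the pad covers the smoothing radius too
  margin <- semi[1] + 3 * amp * mean(sp) +
    (3 * max(env$texture_smoothing_sigma, 3) + 2) * mean(sp)
  box <- lapply(1:3, function(a) {
    r <- max(1L, floor((center[a] - margin) / sp[a]) + 1L):
      min(dims[a], ceiling((center[a] + margin) / sp[a]) + 1L)
    r
  })
  bd <- lengths(box)
  gx <- array((box[[1]] - 1) * sp[1], bd) - center[1]
  gy <- array(rep((box[[2]] - 1) * sp[2], each = bd[1]), bd) - center[2]
  gz <- array(rep((box[[3]] - 1) * sp[3], each = bd[1] * bd[2]), bd) - center[3]
  u1 <- (rot[1, 1] * gx + rot[2, 1] * gy + rot[3, 1] * gz) / semi[1]
  u2 <- (rot[1, 2] * gx + rot[2, 2] * gy + rot[3, 2] * gz) / semi[2]
  u3 <- (rot[1, 3] * gx + rot[2, 3] * gy + rot[3, 3] * gz) / semi[3]
  rho <- sqrt(u1^2 + u2^2 + u3^2)
  floorMM <- max(10, config$short_axis_range[1])
  sub <- NULL
  for (attempt in 1:5) {
    if (amp > 0) {
      g <- gaussianSmooth3D(array(rnorm(prod(bd)), bd), 3)
      g <- g$field / g$sdFactor
      gmRadius <- prod(semi)^(1 / 3)
      cand <- array(as.integer(rho <= 1 + (amp * mean(sp) / gmRadius) * g), bd)
    } else {
      cand <- array(as.integer(rho <= 1), bd)
    }
    if (sum(cand) == 0) { amp <- amp / 2; next }
    cand <- largestComponent26(cand)
    if (shortAxisMM(cand, sp) >= floorMM) { sub <- cand; break }
    amp <- amp / 2 # roughness ate into the short axis; calm the surface
  }
  if (is.null(sub)) sub <- largestComponent26(array(as.integer(rho <= 1), bd))

  # environment imprint: smoothed, exactly-standardized noise field
  sm <- gaussianSmooth3D(array(rnorm(prod(bd)), bd), env$texture_smoothing_sigma)
  z <- sm$field / sm$sdFactor
  inSub <- sub == 1L
  subImg <- env$intensity_mean + env$intensity_sd * z
  subImg[inSub] <- subImg[inSub] + rnorm(sum(inSub), 0, config$noise_sd)
  if (env$rim_contrast != 0) {
    core <- array(cpp_erode6(as.integer(sub), bd), bd)
    rim <- inSub & core == 0L
    subImg[rim] <- subImg[rim] + env$rim_contrast
  }
  image <- array(rnorm(prod(dims), config$background_mean, config$noise_sd), dims)
  mask <- array(0L, dims)
  mask[box[[1]], box[[2]], box[[3]]][inSub] <- 1L
  imgView <- image[box[[1]], box[[2]], box[[3]]]
  imgView[inSub] <- subImg[inSub]
  image[box[[1]], box[[2]], box[[3]]] <- imgView
  LesionVolume(image, mask, sp)
}

sampleClass <- function(mix) sample(names(mix), 1, prob = mix)

#' Generate a full synthetic lesion cohort
#'
#' Draws patients, per-patient tumor types, lesion classes from the
#' configured mixture, and environments per the class rules: primaries grow
#' in the tumor type's home organ; lymph-node metastases in the nodal
#' environment (if one is configured, otherwise drawn like solid-organ
#' metastases); solid-organ metastases in an environment drawn independently
#' of tumor type (or per the optional affinity matrix). The per-(patient,
#' organ) lesion cap is enforced. The whole cohort is a pure function of the
#' config (including its seed).
#'
#' @param config a [cohortConfig()].
#' @param metadata_only when `TRUE`, draw only the lesion metadata (no
#'   volumes) and return the metadata data.frame -- useful for previewing a
#'   cohort design at scale.
#' @return a \linkS4class{LesionCohort}, or a data.frame when
#'   `metadata_only = TRUE`.
#' @export
generateCohort <- function(config = cohortConfig(), metadata_only = FALSE) {
  set.seed(config$seed)
  envNames <- names(config$environments)
  nodalEnvs <- envNames[vapply(config$environments, `[[`, TRUE, "nodal")]
  solidEnvs <- setdiff(envNames, nodalEnvs)
  recs <- list(); vols <- list(); li <- 0L
  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("P%04d", p)
    tt <- config$tumor_types[[sample(length(config$tumor_types), 1)]]
    nles <- if (config$lesions_per_patient[1] == config$lesions_per_patient[2])
      config$lesions_per_patient[1] else
      sample(config$lesions_per_patient[1]:config$lesions_per_patient[2], 1)
    organCount <- stats::setNames(integer(length(envNames)), envNames)
    for (l in seq_len(nles)) {
      cls <- sampleClass(config$lesion_class_mix)
      envName <- switch(cls,
        primary = tt$home_environment,
        lymph_node_met = if (length(nodalEnvs)) nodalEnvs[1] else
          sampleSolidEnv(config, tt, solidEnvs),
        solid_organ_met = sampleSolidEnv(config, tt, solidEnvs))
      if (organCount[envName] >= config$max_lesions_per_organ) {
        open <- envNames[organCount < config$max_lesions_per_organ]
        if (!length(open)) break
        envName <- if (length(open) == 1L) open else sample(open, 1)
        cls <- "solid_organ_met"
      }
      organCount[envName] <- organCount[envName] + 1L
      li <- li + 1L
      lid <- sprintf("L%05d", li)
      if (!metadata_only)
        vols[[lid]] <- generateLesion(config$environments[[envName]], tt, config)
      recs[[li]] <- data.frame(lesion_id = lid, patient_id = pid,
                               tumor_type = tt$name, environment = envName,
                               lesion_class = cls, stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, recs)
  if (metadata_only) return(meta)
  LesionCohort(vols, meta)
}

sampleSolidEnv <- function(config, tt, solidEnvs) {
  if (length(solidEnvs) == 1L) return(solidEnvs)
  w <- if (is.null(config$affinity)) rep(1, length(solidEnvs)) else
    config$affinity[tt$name, solidEnvs]
  sample(solidEnvs, 1, prob = w)
}

#' Cohort composition summary
#'
#' Counts and percentages of lesions by lesion class, tumor type and
#' anatomical environment (denominator: all lesions in the table). Categories
#' configured but absent are reported with zero count.
#'
#' @param meta a lesion metadata data.frame (or a \linkS4class{LesionCohort}).
#' @param levels optional named list of category levels to force into the
#'   summary (e.g. all configured environments).
#' @return data.frame with columns `category`, `level`, `n`, `pct`.
#' @export
cohortSummary <- function(meta, levels = NULL) {
  if (is(meta, "LesionCohort")) meta <- lesionMeta(meta)
  if (nrow(meta) == 0) stop("empty lesion table")
  one <- function(col, lev) {
    vals <- factor(meta[[col]], levels = union(lev, unique(meta[[col]])))
    tab <- table(vals)
    data.frame(category = col, level = names(tab), n = as.integer(tab),
               pct = round(100 * as.integer(tab) / nrow(meta), 2),
               stringsAsFactors = FALSE)
  }
  rbind(one("lesion_class", levels$lesion_class %||% lesionClassLevels),
        one("tumor_type", levels$tumor_type),
        one("environment", levels$environment))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
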