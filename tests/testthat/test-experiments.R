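toySE <- function() {
  cls <- c("primary", "primary", "lymph_node_met", "lymph_node_met",
           "solid_organ_met", "solid_organ_met")
  m <- matrix(rnorm(6 * 4), 4, 6)
  rownames(m) <- c("shape_volume", "firstorder_mean", "glcm_contrast", "glrlm_sre")
  colnames(m) <- paste0("L", 1:6)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = m),
    rowData = S4Vectors::DataFrame(
      feature_class = c("shape", "intensity", "texture", "texture"),
      family = c("shape3d", "firstorder", "glcm", "glrlm"),
      row.names = rownames(m)),
    colData = S4Vectors::DataFrame(lesion_id = colnames(m), patient_id = "P1",
      tumor_type = "lung", environment = "lung", lesion_class = cls,
      row.names = colnames(m)))
}

test_that("lesion subsetting follows the class taxonomy", {
  se <- toySE()
  expect_equal(ncol(subsetLesions(se, "all")), 6)
  expect_equal(ncol(subsetLesions(se, "metastatic")), 4)
  expect_equal(ncol(subsetLesions(se, "solid_organ")), 2)
  met <- subsetLesions(se, "metastatic")
  expect_true(all(SummarizedExperiment::colData(met)$lesion_class != "primary"))
  only <- se[, SummarizedExperiment::colData(se)$lesion_class == "primary"]
  expect_error(subsetLesions(only, "metastatic"), "empty")
})

test_that("feature subsetting partitions the feature set by class", {
  se <- sharedFeatures()
  shp <- subsetFeatures(se, "shape")
  expect_equal(nrow(shp), 14) # the full 3-D + 2-D shape panel
  int <- subsetFeatures(se, "intensity")
  tex <- subsetFeatures(se, "texture")
  expect_equal(sort(c(rownames(shp), rownames(int), rownames(tex))),
               sort(rownames(se)))
  expect_equal(length(intersect(rownames(shp), rownames(tex))), 0)
  noTex <- se[featureClasses(se) != "texture", ]
  expect_error(subsetFeatures(noTex, "texture"), "no features")
  expect_identical(subsetFeatures(se, "all"), se)
})

test_that("environment grouping remaps labels before analysis", {
  se <- toySE()
  SummarizedExperiment::colData(se)$environment <-
    c("lung", "liver", "bile_duct", "lung", "liver", "bile_duct")
  out <- MorphoImprint:::applyEnvGrouping(se,
    c(liver = "hepatobiliary", bile_duct = "hepatobiliary"))
  tab <- table(SummarizedExperiment::colData(out)$environment)
  expect_equal(as.vector(tab[c("hepatobiliary", "lung")]), c(4L, 2L))
})

test_that("experiments are deterministic: identical reports and artifacts", {
  se <- sharedFeatures()
  spec <- smallSpec(representation = "raw")
  d1 <- file.path(tempdir(), "exp_a"); d2 <- file.path(tempdir(), "exp_b")
  r1 <- runExperiment(spec, features = se, out_dir = d1)
  r2 <- runExperiment(spec, features = se, out_dir = d2)
  expect_identical(r1$partition, r2$partition)
  expect_identical(r1$concordance@ariA, r2$concordance@ariA)
  for (f in c("features.csv", "embedding.csv", "partition.csv",
              "concordance.json", "contingency_environment.csv",
              "trace.csv", "report.json")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("strong-imprint cohorts yield environment-dominant concordance", {
  se <- sharedFeatures()
  spec <- smallSpec(lesion_subset = "solid_organ", representation = "embedding")
  rep <- runExperiment(spec, features = se)
  expect_gt(rep$concordance@meanB, rep$concordance@meanA) # env > type
  expect_lt(rep$concordance@pValue, 0.05)
  expect_gte(rep$k, 2)
  # the report's numbers are recomputable from its own partition
  cd <- SummarizedExperiment::colData(
    subsetLesions(sharedFeatures(), "solid_organ"))
  expect_equal(rep$concordance@ariBFull,
               adjustedRandIndex(rep$partition, cd$environment))
})

test_that("feature-class ablation ranks intensity above shape for environment", {
  se <- sharedFeatures()
  ariEnv <- vapply(c("shape", "intensity", "texture"), function(fc) {
    spec <- smallSpec(lesion_subset = "solid_organ", feature_subset = fc,
                      representation = "raw")
    runExperiment(spec, features = se)$concordance@meanB
  }, 0)
  expect_gt(ariEnv["intensity"], ariEnv["shape"])
  expect_gt(ariEnv["texture"], ariEnv["shape"])
})

test_that("eroded-mask features preserve environment dominance", {
  seE <- sharedFeatures("eroded")
  spec <- smallSpec(lesion_subset = "solid_organ", mask_variant = "eroded",
                    representation = "raw")
  rep <- runExperiment(spec, features = seE)
  expect_gt(rep$concordance@meanB, rep$concordance@meanA)
  # mask-variant mismatch between spec and features is caught
  expect_error(runExperiment(smallSpec(representation = "raw"), features = seE),
               "mask_variant")
})

test_that("grids enumerate axes, reuse extraction, and summarize consistently", {
  spec <- smallSpec(cohort = tinyCohortConfig(n_patients = 15, seed = 19),
                    representation = "raw")
  g <- runGrid(spec, axes = list(lesion_subset = c("all", "metastatic")))
  expect_equal(length(g$reports), 2)
  expect_equal(nrow(g$summary), 4) # two ground truths per report
  for (nm in names(g$reports)) {
    df <- as.data.frame(g$reports[[nm]]$concordance)
    sub <- g$summary[g$summary$analysis == nm, ]
    expect_equal(sub$mean_ARI, df$mean_ARI)
    expect_equal(sub$p_value, df$p_value)
  }
  # empty axes: a single report of the base spec
  g0 <- runGrid(spec, axes = list())
  expect_equal(length(g0$reports), 1)
  # failures are marked per cell and the grid continues
  spec2 <- spec; spec2$perplexity <- 1e6; spec2$representation <- "embedding"
  g2 <- runGrid(spec2, axes = list(lesion_subset = c("all", "metastatic")))
  expect_true(all(!is.na(g2$summary$error)))
})
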