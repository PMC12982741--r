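test_that("lesion generation is bit-identical under a fixed seed", {
  cfg <- tinyCohortConfig(seed = 3)
  v1 <- generateLesion(cfg$environments[[1]], cfg$tumor_types[[2]], cfg, seed = 12)
  v2 <- generateLesion(cfg$environments[[1]], cfg$tumor_types[[2]], cfg, seed = 12)
  expect_identical(imageArray(v1), imageArray(v2))
  expect_identical(maskArray(v1), maskArray(v2))
})

test_that("every generated mask is 26-connected with short axis >= 10 mm", {
  cfg <- tinyCohortConfig(seed = 4)
  for (s in 1:12) {
    env <- cfg$environments[[(s %% 4) + 1]]
    tt <- cfg$tumor_types[[(s %% 5) + 1]]
    v <- generateLesion(env, tt, cfg, seed = s)
    m <- maskArray(v)
    expect_true(MorphoImprint:::isConnected26(m))
    expect_gte(MorphoImprint:::shortAxisMM(m, spacing(v)), 10)
  }
})

test_that("the in-mask sample mean tracks the environment intensity mean", {
  # Monte-Carlo over 50 regenerated lesions: smoothing correlates voxels, so
  # the SE of the in-mask mean is inflated relative to sd/sqrt(n); bound the
  # deviation of the mean-of-means by the empirical spread of the 50 means
  env <- environmentProfile("mc", intensity_mean = 80, intensity_sd = 5,
                            texture_smoothing_sigma = 1.2)
  cfg <- cohortConfig(environments = list(env,
                        environmentProfile("other", 0, 5, nodal = TRUE)),
                      tumor_types = list(tumorTypeProfile("t", 1.2, 0.05, 0,
                                                          home_environment = "mc")),
                      noise_sd = 0, seed = 1)
  means <- vapply(1:50, function(s) {
    v <- generateLesion(env, cfg$tumor_types[[1]], cfg, seed = s)
    mean(imageArray(v)[maskArray(v) == 1L])
  }, 0)
  se <- sd(means) / sqrt(50)
  expect_lt(abs(mean(means) - 80), 4 * se + 0.05)
  # and the inflation is real but bounded: per-lesion means deviate by less
  # than 3 * (5 / sqrt(n_vox)) * inflation with a generous inflation factor
  v <- generateLesion(env, cfg$tumor_types[[1]], cfg, seed = 99)
  nvox <- sum(maskArray(v))
  expect_true(all(abs(means - 80) < 3 * (5 / sqrt(nvox)) * 25))
})

test_that("lesion classes follow the configured mixture", {
  cfg <- cohortConfig(n_patients = 700, lesions_per_patient = 3, seed = 8)
  meta <- generateCohort(cfg, metadata_only = TRUE)
  expect_gte(nrow(meta), 2000)
  mix <- cfg$lesion_class_mix
  tab <- table(factor(meta$lesion_class, levels = names(mix)))
  n <- nrow(meta)
  for (cl in names(mix)) {
    sdBin <- sqrt(n * mix[[cl]] * (1 - mix[[cl]]))
    expect_lt(abs(tab[[cl]] - n * mix[[cl]]), 3 * sdBin)
  }
})

test_that("primary lesions reside in the tumor type's home organ", {
  cfg <- cohortConfig(n_patients = 80,
                      lesion_class_mix = c(primary = 1, lymph_node_met = 0,
                                           solid_organ_met = 0),
                      seed = 9)
  meta <- generateCohort(cfg, metadata_only = TRUE)
  homes <- vapply(cfg$tumor_types, `[[`, "", "home_environment")
  expect_true(all(meta$environment == homes[meta$tumor_type]))
  expect_true(all(meta$lesion_class == "primary"))
})

test_that("cohort size and per-organ caps hold", {
  cfg <- tinyCohortConfig(n_patients = 20, lesions_per_patient = 3, seed = 10)
  meta <- generateCohort(cfg, metadata_only = TRUE)
  expect_equal(nrow(meta), 60)
  perOrgan <- table(meta$patient_id, meta$environment)
  expect_true(all(perOrgan <= 10))
  # stress the cap with many lesions per patient and few organs
  cfg2 <- cohortConfig(n_patients = 4, lesions_per_patient = 25,
                       environments = defaultEnvironments()[1:2],
                       tumor_types = defaultTumorTypes()[1:2],
                       lesion_class_mix = c(primary = 0, lymph_node_met = 0,
                                            solid_organ_met = 1),
                       max_lesions_per_organ = 10, seed = 11)
  meta2 <- generateCohort(cfg2, metadata_only = TRUE)
  expect_true(all(table(meta2$patient_id, meta2$environment) <= 10))
})

test_that("full cohorts are a pure function of the config seed", {
  cfg <- tinyCohortConfig(n_patients = 3, seed = 21)
  c1 <- generateCohort(cfg)
  c2 <- generateCohort(cfg)
  expect_identical(lesionMeta(c1), lesionMeta(c2))
  expect_identical(lapply(lesionVolumes(c1), imageArray),
                   lapply(lesionVolumes(c2), imageArray))
})

test_that("config validation rejects invalid setups", {
  expect_error(cohortConfig(environments = list()), "non-empty")
  expect_error(cohortConfig(lesion_class_mix = c(primary = 0.5,
    lymph_node_met = 0.2, solid_organ_met = 0.2)), "sum to 1")
  expect_error(cohortConfig(short_axis_range = c(5, 12)), ">= 10 mm")
  expect_error(environmentProfile("x", 10, intensity_sd = 0), "intensity_sd")
  expect_error(tumorTypeProfile("x", 0.8, home_environment = "lung"),
               "axis_ratio_mean")
  # oversized lesions cannot fit the grid
  cfg <- cohortConfig(short_axis_range = c(40, 45), grid_dim = c(24, 24, 24))
  expect_error(generateLesion(cfg$environments[[1]], cfg$tumor_types[[1]], cfg,
                              seed = 1), "sizing")
})

test_that("cohortSummary reports counts, percentages and zero categories", {
  meta <- data.frame(lesion_id = paste0("L", 1:4), patient_id = "P1",
                     tumor_type = "lung",
                     environment = c("lung", "lung", "liver", "liver"),
                     lesion_class = "solid_organ_met")
  s <- cohortSummary(meta)
  env <- s[s$category == "environment", ]
  expect_equal(env$pct[env$level == "lung"], 50)
  expect_equal(env$pct[env$level == "liver"], 50)
  cls <- s[s$category == "lesion_class", ]
  expect_equal(cls$n[cls$level == "primary"], 0)
  expect_equal(cls$pct[cls$level == "primary"], 0)
  # deterministic across regeneration of the same seeded cohort
  cfg <- tinyCohortConfig(n_patients = 5, seed = 33)
  s1 <- cohortSummary(generateCohort(cfg, metadata_only = TRUE))
  s2 <- cohortSummary(generateCohort(cfg, metadata_only = TRUE))
  expect_identical(s1, s2)
  expect_error(cohortSummary(meta[0, ]), "empty")
})
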