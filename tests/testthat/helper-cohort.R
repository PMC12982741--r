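# lazily-built shared fixtures, computed once per test run
.fixtures <- new.env(parent = emptyenv())

sharedCohort <- function() {
  if (is.null(.fixtures$cohort))
    .fixtures$cohort <- generateCohort(tinyCohortConfig(n_patients = 40, seed = 7))
  .fixtures$cohort
}

sharedFeatures <- function(variant = "full") {
  key <- paste0("feat_", variant)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- extractCohortFeatures(sharedCohort(), mask_variant = variant)
  .fixtures[[key]]
}

smallSpace <- function(budget = 40)
  clusteringSearchSpace(k_range = c(2, 8), linkages = c("ward", "complete"),
                        budget = budget)

smallSpec <- function(...) {
  experimentSpec(space = smallSpace(), perplexity = 12, max_iter = 400, B = 50,
                 ...)
}

# raw-representation concordance of a tiny cohort, for dial/null properties
quickConcordance <- function(cfg, feature_subset = "all") {
  co <- generateCohort(cfg)
  se <- extractCohortFeatures(co)
  spec <- smallSpec(representation = "raw", lesion_subset = "all",
                    feature_subset = feature_subset)
  rep <- runExperiment(spec, features = se)
  c(env = rep$concordance@ariBFull, type = rep$concordance@ariAFull,
    p = rep$concordance@pValue)
}
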