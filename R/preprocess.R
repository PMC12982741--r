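#' Standardize and impute a feature table
#'
#' Missing values are replaced by the per-feature median (computed before
#' standardization); each feature is then z-scored to mean 0 and SD 1.
#' Zero-variance features (including all-missing ones) are dropped with a
#' warning; dropped names are recorded in `metadata(se)$dropped_features`.
#'
#' @param se a SummarizedExperiment (features x lesions) from
#'   [extractCohortFeatures()].
#' @return the standardized SummarizedExperiment.
#' @export
standardizeImpute <- function(se) {
  if (ncol(se) < 2) stop("need at least 2 lesions to standardize")
  m <- SummarizedExperiment::assay(se, "features")
  for (r in seq_len(nrow(m))) {
    miss <- is.na(m[r, ])
    if (any(miss)) {
      med <- median(m[r, !miss])
      m[r, miss] <- med # all-missing rows stay NA and fall to the variance filter
    }
  }
  mu <- rowMeans(m)
  sdv <- apply(m, 1, sd)
  drop <- !is.finite(sdv) | sdv == 0 | is.na(mu)
  if (any(drop)) {
    warning("dropping ", sum(drop), " zero-variance or all-missing feature(s): ",
            paste(head(rownames(m)[drop], 5), collapse = ", "),
            if (sum(drop) > 5) ", ..." else "")
  }
  m <- (m - mu) / sdv
  out <- se[!drop, ]
  SummarizedExperiment::assay(out, "features") <- m[!drop, , drop = FALSE]
  S4Vectors::metadata(out)$dropped_features <- rownames(se)[drop]
  S4Vectors::metadata(out)$standardized <- TRUE
  out
}
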