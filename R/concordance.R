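#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items
#' (Hubert-Arabie): `ARI = (Index - Expected) / (Max - Expected)` with
#' `Index = sum_ij C(n_ij, 2)` over the contingency cells,
#' `Expected = sum_i C(a_i, 2) * sum_j C(b_j, 2) / C(n, 2)` and
#' `Max = (sum_i C(a_i, 2) + sum_j C(b_j, 2)) / 2`. Symmetric in its
#' arguments and invariant to label renaming; returns 0 in the degenerate
#' case `Max == Expected` (e.g. both labelings constant or all-singleton).
#'
#' @param p1,p2 label vectors of equal length (n >= 2); any atomic type or
#'   factor.
#' @return numeric ARI (1 = identical partitions, ~0 = chance level).
#' @export
adjustedRandIndex <- function(p1, p2) {
  if (length(p1) != length(p2)) stop("label vectors differ in length")
  n <- length(p1)
  if (n < 2) stop("need at least 2 items")
  a <- as.integer(factor(p1)); b <- as.integer(factor(p2))
  na <- max(a); nb <- max(b)
  nij <- tabulate((a - 1L) * nb + b, nbins = na * nb)
  ai <- tabulate(a, nbins = na); bj <- tabulate(b, nbins = nb)
  ch2 <- function(x) sum(x * (x - 1)) / 2
  index <- ch2(nij)
  expd <- ch2(ai) * ch2(bj) / ch2(n)
  maxi <- (ch2(ai) + ch2(bj)) / 2
  if (abs(maxi - expd) < .Machine$double.eps * max(1, maxi)) return(0)
  (index - expd) / (maxi - expd)
}

#' Mean silhouette score of a partition
#'
#' For each point, `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with `a(i)` the
#' mean distance to the other members of its own cluster and `b(i)` the
#' smallest mean distance to any other cluster; points in singleton clusters
#' score 0 by convention. Euclidean distance on the supplied coordinates.
#'
#' @param points n x d coordinate matrix.
#' @param partition cluster labels aligned to rows (>= 2 non-empty
#'   clusters).
#' @return mean silhouette in \[-1, 1\].
#' @export
silhouetteScore <- function(points, partition) {
  Dm <- as.matrix(dist(points))
  silhouetteFromDist(Dm, partition)
}

silhouetteFromDist <- function(Dm, partition) {
  f <- factor(partition)
  if (nlevels(f) < 2) stop("silhouette undefined for a single cluster")
  sizes <- as.vector(table(f))
  # column c of M: for each point, summed distance to members of cluster c
  M <- vapply(levels(f), function(l) rowSums(Dm[, f == l, drop = FALSE]),
              numeric(nrow(Dm)))
  own <- as.integer(f)
  s <- numeric(nrow(Dm))
  for (i in seq_len(nrow(Dm))) {
    if (sizes[own[i]] == 1L) { s[i] <- 0; next }
    a <- M[i, own[i]] / (sizes[own[i]] - 1L)
    b <- min(M[i, -own[i]] / sizes[-own[i]])
    # coincident points in and out of the cluster: neutral score
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

#' Paired bootstrap concordance of a partition with two ground truths
#'
#' Draws `B` bootstrap resamples of the lesions (indices with replacement;
#' the same index draw serves both labelings, making the comparison paired)
#' and recomputes the ARI of the resampled partition against each resampled
#' labeling. Reports the mean and 95\% percentile CI per labeling, the
#' full-data ARIs, the paired mean difference `B - A`, its CI, and the
#' one-sided bootstrap p-value `(1 + #\{diff_b <= 0\}) / (B + 1)` for
#' H1: concordance with labeling B exceeds labeling A. Replicates whose
#' resample degenerates to a single label have ARI 0 (degenerate rule of
#' [adjustedRandIndex()]). Deterministic given the seed.
#'
#' @param partition cluster labels.
#' @param labels_A,labels_B aligned ground-truth label vectors (by package
#'   convention A = tumor type, B = anatomical environment).
#' @param B number of bootstrap iterations (default 100).
#' @param seed integer seed.
#' @param label_names character(2) naming the two labelings in reports.
#' @return a \linkS4class{ConcordanceResult}.
#' @export
bootstrapConcordance <- function(partition, labels_A, labels_B, B = 100,
                                 seed = 1L,
                                 label_names = c("tumor_type", "environment")) {
  n <- length(partition)
  if (length(labels_A) != n || length(labels_B) != n)
    stop("labels must align with the partition")
  if (B < 1) stop("B must be >= 1")
  set.seed(seed)
  ariA <- numeric(B); ariB <- numeric(B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    ariA[b] <- adjustedRandIndex(partition[idx], labels_A[idx])
    ariB[b] <- adjustedRandIndex(partition[idx], labels_B[idx])
  }
  d <- ariB - ariA
  ci <- function(x) unname(quantile(x, c(0.025, 0.975), type = 7))
  new("ConcordanceResult",
      ariA = ariA, ariB = ariB, labelNames = label_names,
      meanA = mean(ariA), meanB = mean(ariB),
      ciA = ci(ariA), ciB = ci(ariB),
      meanDiff = mean(d), ciDiff = ci(d),
      pValue = (1 + sum(d <= 0)) / (B + 1),
      ariAFull = adjustedRandIndex(partition, labels_A),
      ariBFull = adjustedRandIndex(partition, labels_B),
      B = as.integer(B), seed = as.integer(seed))
}

#' Contingency table of ground-truth classes across clusters
#'
#' Counts of lesions per (ground-truth class, cluster) cell with marginals
#' and the row-percentage view used in the result tables: each ground-truth
#' class is distributed across the clusters, so every row of `row_pct` sums
#' to 100.
#'
#' @param partition cluster labels.
#' @param labels aligned ground-truth labels.
#' @return list with `counts` (classes x clusters), `row_pct`,
#'   `row_marginals`, `col_marginals`, `n`.
#' @export
contingencyTable <- function(partition, labels) {
  if (length(partition) != length(labels)) stop("length mismatch")
  counts <- table(ground_truth = labels, cluster = partition)
  rp <- 100 * sweep(counts, 1, pmax(rowSums(counts), 1), "/")
  list(counts = unclass(counts), row_pct = round(unclass(rp), 2),
       row_marginals = rowSums(counts), col_marginals = colSums(counts),
       n = sum(counts))
}

#' Serialize a ConcordanceResult to JSON
#'
#' Writes all stored vectors plus the derived summaries so the result is
#' fully recomputable and auditable.
#'
#' @param x a \linkS4class{ConcordanceResult}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeConcordanceJSON <- function(x, path) {
  payload <- list(
    label_names = x@labelNames, B = x@B, seed = x@seed,
    ari_A_boot = x@ariA, ari_B_boot = x@ariB,
    mean_A = x@meanA, mean_B = x@meanB,
    ci_A = x@ciA, ci_B = x@ciB,
    ari_A_full = x@ariAFull, ari_B_full = x@ariBFull,
    mean_diff = x@meanDiff, ci_diff = x@ciDiff, p_value = x@pValue)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
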