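#' Agglomerative clustering of embedded or raw feature points
#'
#' Bottom-up hierarchical clustering: repeatedly merge the two least-distant
#' clusters under the linkage rule until `k` remain. Backed by
#' \code{stats::hclust} (`ward` maps to `ward.D2`, the squared-Euclidean
#' Ward criterion); deterministic given the input row order (on exact
#' distance ties \code{hclust} merges the earliest pair in its ordering).
#'
#' @param points n x d numeric matrix (rownames = lesion ids).
#' @param k number of clusters (2..n).
#' @param linkage one of `ward`, `complete`, `average`, `single`.
#' @param metric distance metric for \code{stats::dist}; `ward` requires
#'   `euclidean`.
#' @return factor of cluster labels, named by rownames of `points`.
#' @export
agglomerativeCluster <- function(points, k, linkage = c("ward", "complete",
                                                        "average", "single"),
                                 metric = "euclidean") {
  linkage <- match.arg(linkage)
  if (linkage == "ward" && metric != "euclidean")
    stop("parameter error: ward linkage requires the euclidean metric")
  if (k > nrow(points)) stop("k must be <= number of points")
  hc <- hclust(dist(points, method = metric), method = linkageMethod(linkage))
  cutPartition(hc, k, rownames(points))
}

linkageMethod <- function(linkage)
  switch(linkage, ward = "ward.D2", complete = "complete",
         average = "average", single = "single")

cutPartition <- function(hc, k, ids) {
  cl <- cutree(hc, k = k)
  f <- factor(cl)
  names(f) <- ids
  f
}

#' Hyperparameter search space for clustering optimization
#'
#' @param k_range integer interval of cluster counts (within \[2, n-1\]).
#' @param linkages subset of `ward`, `complete`, `average`, `single`.
#' @param metric distance metric (`ward` is only paired with `euclidean`).
#' @param budget number of objective evaluations.
#' @param seed seed for the optimizer.
#' @export
clusteringSearchSpace <- function(k_range = c(2, 15),
                                  linkages = c("ward", "complete", "average"),
                                  metric = "euclidean", budget = 50, seed = 1L) {
  stopifnot(length(k_range) == 2, k_range[1] >= 2, k_range[2] >= k_range[1])
  linkages <- match.arg(linkages, c("ward", "complete", "average", "single"),
                        several.ok = TRUE)
  if (budget < 1) stop("parameter error: budget must be >= 1")
  structure(list(k_range = as.integer(k_range), linkages = linkages,
                 metric = metric, budget = as.integer(budget),
                 seed = as.integer(seed)),
            class = "ClusteringSearchSpace")
}

#' Optimize clustering hyperparameters against the equal-weight objective
#'
#' Maximizes `0.5 * silhouette(points, partition) + 0.5 * ARI(partition,
#' ground truth)` over the discrete (k, linkage) space. The ARI term is, by
#' default, the mean ARI against both ground-truth labelings (tumor type and
#' environment) so that model selection does not presuppose either endpoint;
#' `ari_mode` switches to a single labeling. When the budget covers the
#' candidate grid the search is exhaustive (the exact maximizer); otherwise
#' a seeded Gaussian-process surrogate with expected-improvement acquisition
#' explores the grid within the budget.
#'
#' @param points n x d coordinate matrix (embedding or standardized
#'   features).
#' @param gt_labels named list of ground-truth label vectors aligned to the
#'   rows of `points` (typically `list(tumor_type = ..., environment =
#'   ...)`).
#' @param space a [clusteringSearchSpace()].
#' @param ari_mode `"mean"` (default), or the name of one element of
#'   `gt_labels`.
#' @return list: `partition` (factor), `best_params` (k, linkage, metric),
#'   `objective`, `silhouette`, `ari`, and `trace` (one row per evaluation).
#' @export
optimizeClustering <- function(points, gt_labels, space = clusteringSearchSpace(),
                               ari_mode = "mean") {
  if (!is.list(gt_labels)) gt_labels <- list(ground_truth = gt_labels)
  stopifnot(all(vapply(gt_labels, length, 0L) == nrow(points)))
  if (!ari_mode %in% c("mean", names(gt_labels)))
    stop("ari_mode must be 'mean' or one of: ", paste(names(gt_labels), collapse = ", "))
  kmax <- min(space$k_range[2], nrow(points) - 1L)
  cand <- expand.grid(k = space$k_range[1]:kmax, linkage = space$linkages,
                      stringsAsFactors = FALSE)
  if (nrow(cand) == 0) stop("parameter error: empty search space")
  D <- dist(points, method = space$metric)
  Dm <- as.matrix(D)
  trees <- lapply(space$linkages, function(lk) hclust(D, method = linkageMethod(lk)))
  names(trees) <- space$linkages

  evalCand <- function(i) {
    part <- cutPartition(trees[[cand$linkage[i]]], cand$k[i], rownames(points))
    sil <- silhouetteFromDist(Dm, part)
    aris <- vapply(gt_labels, function(l) adjustedRandIndex(part, l), 0)
    ari <- if (ari_mode == "mean") mean(aris) else aris[[ari_mode]]
    list(part = part, sil = sil, ari = ari, obj = 0.5 * sil + 0.5 * ari)
  }

  budget <- min(space$budget, nrow(cand))
  if (budget >= nrow(cand)) {
    order_eval <- seq_len(nrow(cand))
  } else {
    order_eval <- gpSearchOrder(cand, evalCand, budget, space$seed)
  }
  trace <- data.frame(); best <- NULL; bestIdx <- NA
  evals <- list()
  for (i in order_eval) {
    ev <- if (!is.null(evals[[as.character(i)]])) evals[[as.character(i)]] else evalCand(i)
    evals[[as.character(i)]] <- ev
    trace <- rbind(trace, data.frame(k = cand$k[i], linkage = cand$linkage[i],
                                     silhouette = ev$sil, ari = ev$ari,
                                     objective = ev$obj))
    if (is.null(best) || ev$obj > best$obj) { best <- ev; bestIdx <- i }
  }
  list(partition = best$part,
       best_params = list(k = cand$k[bestIdx], linkage = cand$linkage[bestIdx],
                          metric = space$metric),
       objective = best$obj, silhouette = best$sil, ari = best$ari,
       trace = trace)
}

# seeded GP-EI search over the discrete candidate grid; returns the
# evaluation order (indices into cand)
gpSearchOrder <- function(cand, evalCand, budget, seed) {
  set.seed(seed)
  X <- cbind(scale(cand$k), stats::model.matrix(~ linkage - 1,
             data.frame(linkage = factor(cand$linkage))))
  nInit <- min(max(4L, budget %/% 3L), budget)
  chosen <- sample(nrow(cand), nInit)
  y <- vapply(chosen, function(i) evalCand(i)$obj, 0)
  while (length(chosen) < budget) {
    mu <- gpPosterior(X[chosen, , drop = FALSE], y, X)
    s <- sqrt(pmax(mu$var, 1e-12))
    imp <- mu$mean - max(y)
    zq <- imp / s
    ei <- imp * stats::pnorm(zq) + s * stats::dnorm(zq)
    ei[chosen] <- -Inf
    nxt <- which.max(ei)
    chosen <- c(chosen, nxt)
    y <- c(y, evalCand(nxt)$obj)
  }
  chosen
}

gpPosterior <- function(Xtr, y, Xall, ell = 1, nug = 1e-4) {
  k <- function(A, B) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    exp(-pmax(d2, 0) / (2 * ell^2))
  }
  K <- k(Xtr, Xtr) + diag(nug, nrow(Xtr))
  Ks <- k(Xall, Xtr)
  mu0 <- mean(y)
  alpha <- solve(K, y - mu0)
  mean <- mu0 + Ks %*% alpha
  v <- 1 + nug - rowSums((Ks %*% solve(K)) * Ks)
  list(mean = as.vector(mean), var = pmax(as.vector(v), 0))
}

#' Cluster directly on the standardized raw feature vectors
#'
#' The raw-feature clustering variant: the same optimization as
#' [optimizeClustering()], applied to the standardized feature matrix itself
#' (Euclidean metric in feature space) instead of its 2-D embedding.
#'
#' @param se standardized SummarizedExperiment.
#' @param gt_labels named list of ground-truth label vectors (defaults to
#'   tumor type and environment from `colData`).
#' @param space a [clusteringSearchSpace()].
#' @param ari_mode see [optimizeClustering()].
#' @return as [optimizeClustering()].
#' @export
clusterRawFeatures <- function(se, gt_labels = NULL,
                               space = clusteringSearchSpace(), ari_mode = "mean") {
  pts <- t(SummarizedExperiment::assay(se, "features"))
  if (is.null(gt_labels)) {
    cd <- SummarizedExperiment::colData(se)
    gt_labels <- list(tumor_type = as.character(cd$tumor_type),
                      environment = as.character(cd$environment))
  }
  optimizeClustering(pts, gt_labels, space, ari_mode)
}
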