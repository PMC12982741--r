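# Independent oracles: deliberately naive reference implementations used to
# validate the package's fast paths. They share no code with the package.

# ARI by O(n^2) pair bookkeeping: classify every item pair as co-clustered in
# both labelings, in one, or in neither
oracleARI <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (sa && !sb) n10 <- n10 + 1
      else if (!sa && sb) n01 <- n01 + 1
      else n00 <- n00 + 1
    }
  }
  num <- 2 * (n11 * n00 - n10 * n01)
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) 0 else num / den
}

# silhouette by direct definition, one point at a time
oracleSilhouette <- function(points, labels) {
  labels <- as.character(labels)
  n <- nrow(points)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    mates <- setdiff(which(labels == own), i)
    if (length(mates) == 0) { s[i] <- 0; next }
    dists <- sqrt(rowSums((points - matrix(points[i, ], n, ncol(points),
                                           byrow = TRUE))^2))
    a <- mean(dists[mates])
    b <- min(vapply(setdiff(unique(labels), own),
                    function(l) mean(dists[labels == l]), 0))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# erosion by the literal rule: survive iff all 6 face-neighbours in-mask
oracleErode6 <- function(mask) {
  d <- dim(mask)
  out <- array(0L, d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (mask[x, y, z] != 1L) next
    ok <- TRUE
    for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
      p <- c(x, y, z) + o
      if (any(p < 1) || any(p > d) || mask[p[1], p[2], p[3]] != 1L) {
        ok <- FALSE; break
      }
    }
    if (ok) out[x, y, z] <- 1L
  }
  out
}

# quadratic naive agglomeration for tiny n: merge the closest pair of
# clusters under the linkage rule (lowest-index pair on ties)
oracleAgglomerate <- function(points, k, linkage = "complete") {
  n <- nrow(points)
  D <- as.matrix(dist(points))
  clusters <- as.list(seq_len(n))
  linkDist <- function(ci, cj) {
    vals <- D[ci, cj, drop = FALSE]
    switch(linkage, complete = max(vals), single = min(vals), average = mean(vals))
  }
  while (length(clusters) > k) {
    best <- c(NA, NA); bestD <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        dd <- linkDist(clusters[[i]], clusters[[j]])
        if (dd < bestD) { bestD <- dd; best <- c(i, j) }
      }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  lab <- integer(n)
  for (c in seq_along(clusters)) lab[clusters[[c]]] <- c
  lab
}

# random 26-connected blob mask: union of a few dilated random walks
randomBlobMask <- function(d = c(9, 9, 9), nSeeds = 3, nSteps = 40) {
  m <- array(0L, d)
  for (s in seq_len(nSeeds)) {
    p <- pmax(2, pmin(d - 1, round(d / 2 + rnorm(3, 0, 2))))
    for (t in seq_len(nSteps)) {
      m[p[1], p[2], p[3]] <- 1L
      p <- p + sample(c(-1, 0, 1), 3, replace = TRUE)
      p <- pmax(1, pmin(d, p))
    }
  }
  if (sum(m) == 0) m[ceiling(d[1] / 2), ceiling(d[2] / 2), ceiling(d[3] / 2)] <- 1L
  m
}

cubeMask <- function(side, grid = side + 4) {
  m <- array(0L, rep(grid, 3))
  lo <- floor((grid - side) / 2) + 1
  m[lo:(lo + side - 1), lo:(lo + side - 1), lo:(lo + side - 1)] <- 1L
  m
}

# small cohort config for pipeline tests
tinyCohortConfig <- function(n_patients = 20, seed = 1,
                             lesions_per_patient = 3, ...) {
  cohortConfig(n_patients = n_patients, lesions_per_patient = lesions_per_patient,
               seed = seed, ...)
}

# equalized environments: the imprint switched off (identical profiles,
# distinct names), or spread by `delta` HU between adjacent means
spreadEnvironments <- function(delta, sigma = 1, sd = 12) {
  base <- 100
  names <- c("env_a", "env_b", "env_c", "env_d")
  lapply(seq_along(names), function(i)
    environmentProfile(names[i], intensity_mean = base + (i - 1) * delta,
                       intensity_sd = sd, texture_smoothing_sigma = sigma,
                       rim_contrast = 0, nodal = FALSE))
}
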