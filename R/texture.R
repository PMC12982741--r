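# Texture-matrix families over discretized gray levels. All matrices are
# computed in-mask only (level 0 = outside). Probability normalizations sum
# to 1 exactly up to floating error; degenerate single-level grids fall back
# to the documented conventions (e.g. GLCM correlation = 0).

#' The 13 unique 3-D voxel offsets (half of the 26-neighbourhood)
#' @return integer matrix 13 x 3.
#' @export
defaultOffsets3D <- function() {
  o <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  o <- o[!(o[, 1] == 0 & o[, 2] == 0 & o[, 3] == 0), ]
  keep <- o[, 3] > 0 | (o[, 3] == 0 & o[, 2] > 0) |
    (o[, 3] == 0 & o[, 2] == 0 & o[, 1] > 0)
  unname(o[keep, , drop = FALSE])
}

as3d <- function(levels) {
  if (length(dim(levels)) == 2L) array(levels, c(dim(levels), 1L)) else levels
}

pad2d <- function(offsets) {
  offsets <- as.matrix(offsets)
  if (ncol(offsets) == 2L) cbind(offsets, 0L) else offsets
}

#' Gray-level co-occurrence matrix and features
#'
#' Counts co-occurrences of level pairs at each voxel offset, symmetrizes
#' (both directions of each offset), normalizes to a probability matrix per
#' offset, computes the feature set per offset, and averages features across
#' offsets (offsets with no valid pair are dropped from the average).
#'
#' @param levels integer gray-level grid (0 outside the mask), 2-D or 3-D.
#' @param G number of gray levels.
#' @param offsets integer matrix of voxel offsets (rows), 2 or 3 columns.
#' @return list with `features` (named numeric) and `matrices` (per-offset
#'   symmetric normalized matrices).
#' @export
glcmFeatures <- function(levels, G, offsets = defaultOffsets3D()) {
  levels <- as3d(levels)
  offsets <- pad2d(offsets)
  raw <- cpp_glcm(as.integer(levels), dim(levels), offsets, G)
  mats <- list(); feats <- NULL
  for (C in raw) {
    S <- C + t(C)
    tot <- sum(S)
    if (tot == 0) next
    P <- S / tot
    mats[[length(mats) + 1L]] <- P
    feats <- rbind(feats, glcmFromP(P))
  }
  f <- if (is.null(feats)) {
    stats::setNames(rep(NA_real_, 7), paste0("glcm_", c("contrast", "dissimilarity",
      "homogeneity", "energy", "entropy", "correlation", "sum_average")))
  } else colMeans(feats)
  list(features = f, matrices = mats)
}

glcmFromP <- function(P) {
  G <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P)
  mux <- sum(seq_len(G) * px)
  sx <- sqrt(sum((seq_len(G) - mux)^2 * px))
  corr <- if (sx > 0) (sum(P * i * j) - mux^2) / sx^2 else 0
  pv <- P[P > 0]
  c(glcm_contrast = sum(P * (i - j)^2),
    glcm_dissimilarity = sum(P * abs(i - j)),
    glcm_homogeneity = sum(P / (1 + (i - j)^2)),
    glcm_energy = sum(P^2),
    glcm_entropy = -sum(pv * log2(pv)),
    glcm_correlation = corr,
    glcm_sum_average = sum(P * (i + j)))
}

#' Gray-level run-length matrix and features
#'
#' Maximal same-level runs along each of the 13 unique 3-D directions;
#' features computed per direction and averaged.
#'
#' @inheritParams glcmFeatures
#' @param dirs run directions (rows).
#' @return list with `features` and per-direction count `matrices`.
#' @export
glrlmFeatures <- function(levels, G, dirs = defaultOffsets3D()) {
  levels <- as3d(levels)
  dirs <- pad2d(dirs)
  Np <- sum(levels > 0)
  raw <- cpp_glrlm(as.integer(levels), dim(levels), dirs, G)
  feats <- NULL
  for (R in raw) {
    Nr <- sum(R)
    if (Nr == 0) next
    g <- row(R); l <- col(R)
    feats <- rbind(feats, c(
      glrlm_sre = sum(R / l^2) / Nr,
      glrlm_lre = sum(R * l^2) / Nr,
      glrlm_gln = sum(rowSums(R)^2) / Nr,
      glrlm_rln = sum(colSums(R)^2) / Nr,
      glrlm_run_pct = Nr / Np,
      glrlm_lglre = sum(R / g^2) / Nr,
      glrlm_hglre = sum(R * g^2) / Nr))
  }
  f <- if (is.null(feats)) stats::setNames(rep(NA_real_, 7),
    paste0("glrlm_", c("sre", "lre", "gln", "rln", "run_pct", "lglre", "hglre")))
  else colMeans(feats)
  list(features = f, matrices = raw)
}

#' Gray-level size-zone matrix and features
#'
#' Zones are maximal 26-connected sets of equal-level in-mask voxels; the
#' matrix counts zones by (level, size).
#'
#' @inheritParams glcmFeatures
#' @return list with `features` and the count `matrix` (G x max zone size).
#' @export
glszmFeatures <- function(levels, G) {
  levels <- as3d(levels)
  zones <- cpp_glszm_zones(as.integer(levels), dim(levels))
  Np <- sum(levels > 0)
  maxs <- max(zones[, 2])
  S <- matrix(0, G, maxs)
  for (r in seq_len(nrow(zones))) S[zones[r, 1], zones[r, 2]] <- S[zones[r, 1], zones[r, 2]] + 1
  Nz <- sum(S)
  g <- row(S); s <- col(S)
  f <- c(glszm_sae = sum(S / s^2) / Nz,
         glszm_lae = sum(S * s^2) / Nz,
         glszm_gln = sum(rowSums(S)^2) / Nz,
         glszm_szn = sum(colSums(S)^2) / Nz,
         glszm_zone_pct = Nz / Np,
         glszm_lglze = sum(S / g^2) / Nz,
         glszm_hglze = sum(S * g^2) / Nz)
  list(features = f, matrix = S)
}

#' Neighbouring gray-tone difference features
#'
#' For each in-mask voxel with at least one in-mask 26-neighbour, accumulates
#' the absolute difference between its level and the mean level of those
#' neighbours. Features: coarseness, contrast, busyness, complexity,
#' strength. Degenerate single-level grids yield contrast/busyness/strength 0
#' and a capped coarseness.
#'
#' @inheritParams glcmFeatures
#' @return list with `features` and the per-level `table` (s_i, n_i, p_i).
#' @export
ngtdmFeatures <- function(levels, G) {
  levels <- as3d(levels)
  m <- cpp_ngtdm(as.integer(levels), dim(levels), G)
  s <- m[, 1]; n <- m[, 2]
  N <- sum(n)
  p <- if (N > 0) n / N else n
  act <- which(p > 0)
  Ngp <- length(act)
  iv <- seq_len(G)
  denomCoarse <- sum(p * s)
  coarseness <- if (denomCoarse > 0) 1 / denomCoarse else 1e6
  if (Ngp > 1) {
    pi_ <- p[act]; ii <- iv[act]
    dif2 <- outer(ii, ii, function(a, b) (a - b)^2)
    contrast <- (sum(outer(pi_, pi_) * dif2) / (Ngp * (Ngp - 1))) * (sum(s) / N)
    busyDen <- sum(abs(outer(ii * pi_, ii * pi_, "-")))
    busyness <- if (busyDen > 0) denomCoarse / busyDen else 0
    absd <- abs(outer(ii, ii, "-"))
    num <- outer(pi_ * s[act], pi_ * s[act], "+") / outer(pi_, pi_, "+")
    complexity <- sum(absd * num) / N
    strength <- if (sum(s) > 0) sum(outer(pi_, pi_, "+") * dif2) / sum(s) else 0
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  }
  list(features = c(ngtdm_coarseness = coarseness, ngtdm_contrast = contrast,
                    ngtdm_busyness = busyness, ngtdm_complexity = complexity,
                    ngtdm_strength = strength),
       table = cbind(s = s, n = n, p = p))
}

#' Gray-level dependence matrix and features
#'
#' A voxel's dependence is the number of its 26-neighbours whose level
#' differs by at most `alpha`; the dependence size j = dependence + 1 (the
#' center voxel counts itself), so j >= 1.
#'
#' @inheritParams glcmFeatures
#' @param alpha level-difference tolerance (default 0).
#' @return list with `features` and the count `matrix` (G x max dependence
#'   size).
#' @export
gldmFeatures <- function(levels, G, alpha = 0L) {
  levels <- as3d(levels)
  D <- cpp_gldm(as.integer(levels), dim(levels), G, as.integer(alpha))
  keep <- max(which(colSums(D) > 0))
  D <- D[, seq_len(keep), drop = FALSE]
  Nz <- sum(D)
  g <- row(D); j <- col(D) # column c = dependence size c (= c-1 neighbours + center)
  P <- D / Nz
  pv <- P[P > 0]
  f <- c(gldm_sde = sum(D / j^2) / Nz,
         gldm_lde = sum(D * j^2) / Nz,
         gldm_gln = sum(rowSums(D)^2) / Nz,
         gldm_dn = sum(colSums(D)^2) / Nz,
         gldm_dependence_entropy = -sum(pv * log2(pv)),
         gldm_lgle = sum(D / g^2) / Nz,
         gldm_hgle = sum(D * g^2) / Nz)
  list(features = f, matrix = D)
}

textureFamilies <- c("glcm", "glrlm", "glszm", "ngtdm", "gldm")

#' All texture features of a discretized grid
#'
#' @inheritParams glcmFeatures
#' @param families subset of `c("glcm","glrlm","glszm","ngtdm","gldm")`.
#' @return named numeric vector (33 features for all five families).
#' @export
textureFeatures <- function(levels, G, families = textureFamilies) {
  families <- match.arg(families, textureFamilies, several.ok = TRUE)
  out <- c(
    if ("glcm" %in% families) glcmFeatures(levels, G)$features,
    if ("glrlm" %in% families) glrlmFeatures(levels, G)$features,
    if ("glszm" %in% families) glszmFeatures(levels, G)$features,
    if ("ngtdm" %in% families) ngtdmFeatures(levels, G)$features,
    if ("gldm" %in% families) gldmFeatures(levels, G)$features)
  out
}
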