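#' Resample a lesion volume to isotropic spacing
#'
#' Resamples the intensity volume onto an isotropic grid (default 1 mm^3)
#' with separable cubic (Keys) interpolation, the convolution-based
#' equivalent of cubic spline interpolation; the binary mask is resampled
#' with nearest-neighbour interpolation and re-binarized at 0.5 so it stays
#' crisp. A volume already on the target grid is returned unchanged.
#'
#' @param pair a \linkS4class{LesionVolume}.
#' @param target_spacing numeric length-1 or -3 target spacing in mm.
#' @return a \linkS4class{LesionVolume} on the target grid.
#' @export
resampleIsotropic <- function(pair, target_spacing = c(1, 1, 1)) {
  if (length(target_spacing) == 1L) target_spacing <- rep(target_spacing, 3)
  stopifnot(all(target_spacing > 0))
  sp <- spacing(pair)
  if (all(abs(sp - target_spacing) < 1e-9)) return(pair)
  dims <- dim(imageArray(pair))
  newDims <- pmax(1L, as.integer(round(dims * sp / target_spacing)))
  img <- imageArray(pair)
  msk <- maskArray(pair)
  for (axis in 1:3) {
    if (abs(sp[axis] - target_spacing[axis]) < 1e-9 && newDims[axis] == dims[axis]) next
    Wc <- cubicWeightMatrix(dims[axis], newDims[axis], sp[axis], target_spacing[axis])
    Wn <- nearestWeightMatrix(dims[axis], newDims[axis], sp[axis], target_spacing[axis])
    img <- applyAlongAxis(img, Wc, axis)
    msk <- applyAlongAxis(msk, Wn, axis)
  }
  msk <- array(as.integer(msk >= 0.5), dim(msk))
  if (sum(msk) == 0)
    stop("degenerate lesion: mask emptied by resampling to ",
         paste(target_spacing, collapse = "x"), " mm")
  LesionVolume(img, msk, target_spacing)
}

# Keys cubic convolution kernel (a = -0.5), interpolating
keysKernel <- function(t) {
  t <- abs(t)
  ifelse(t <= 1, 1.5 * t^3 - 2.5 * t^2 + 1,
         ifelse(t < 2, -0.5 * t^3 + 2.5 * t^2 - 4 * t + 2, 0))
}

# new_len x old_len interpolation weights along one axis; voxel centers at
# (i - 1) * spacing, edge samples clamped (replicated)
cubicWeightMatrix <- function(oldN, newN, oldSp, newSp) {
  W <- matrix(0, newN, oldN)
  pos <- ((seq_len(newN) - 1) * newSp) / oldSp # in old index units (0-based)
  for (i in seq_len(newN)) {
    base <- floor(pos[i])
    for (j in (base - 1):(base + 2)) {
      w <- keysKernel(pos[i] - j)
      if (w == 0) next
      jc <- min(max(j, 0), oldN - 1) # clamp to the grid
      W[i, jc + 1] <- W[i, jc + 1] + w
    }
  }
  W
}

nearestWeightMatrix <- function(oldN, newN, oldSp, newSp) {
  W <- matrix(0, newN, oldN)
  pos <- ((seq_len(newN) - 1) * newSp) / oldSp
  j <- pmin(pmax(round(pos), 0), oldN - 1)
  W[cbind(seq_len(newN), j + 1)] <- 1
  W
}

applyAlongAxis <- function(a, W, axis) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = d[axis])
  out <- W %*% m
  newD <- c(nrow(W), d[setdiff(1:3, axis)])
  aperm(array(out, newD), order(perm))
}
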