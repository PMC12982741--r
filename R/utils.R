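# internal helpers shared across modules

# derive an independent sub-seed from a master seed; kept below 2^31
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647L)
}

# voxel-center coordinates (mm) of foreground voxels, 0-based index * spacing
maskCoordsMM <- function(mask, spacing) {
  idx <- which(mask == 1L, arr.ind = TRUE)
  sweep(idx - 1, 2, spacing, "*")
}

# sorted principal extents (mm) of a mask: project voxel centers on the
# principal axes, extent = range + one voxel (mean spacing) to account for
# voxel width; returns decreasing order (major, middle=short axis, least)
principalExtentsMM <- function(mask, spacing) {
  xyz <- maskCoordsMM(mask, spacing)
  if (nrow(xyz) == 1L) return(rep(mean(spacing), 3))
  xyz <- sweep(xyz, 2, colMeans(xyz))
  ev <- eigen(cov(xyz), symmetric = TRUE)$vectors
  proj <- xyz %*% ev
  ext <- apply(proj, 2, function(p) diff(range(p))) + mean(spacing)
  sort(ext, decreasing = TRUE)
}

# the radiological short axis: second-largest principal extent, in mm
shortAxisMM <- function(mask, spacing) principalExtentsMM(mask, spacing)[2]

largestComponent26 <- function(mask) {
  lab <- cpp_label(as.integer(mask), dim(mask), 26L)
  if (max(lab) <= 1L) return(mask)
  keep <- which.max(tabulate(lab[lab > 0L]))
  out <- array(as.integer(lab == keep), dim(mask))
  out
}

nComponents26 <- function(mask) max(cpp_label(as.integer(mask), dim(mask), 26L))

isConnected26 <- function(mask) nComponents26(mask) == 1L

# padded bounding box of a mask's foreground, as per-axis index ranges
maskBBox <- function(mask, pad = 1L) {
  d <- dim(mask)
  idx <- which(mask == 1L, arr.ind = TRUE)
  lapply(1:3, function(ax)
    max(1L, min(idx[, ax]) - pad):min(d[ax], max(idx[, ax]) + pad))
}

# gaussian smoothing of a 3-D array by separable discrete convolution;
# returns the filtered array and the exact variance shrink factor of the
# discrete kernel so callers can standardize filtered white noise
gaussianSmooth3D <- function(x, sigma) {
  if (sigma <= 0) return(list(field = x, sdFactor = 1))
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  out <- cpp_conv3d_sep(as.numeric(x), dim(x), k)
  list(field = array(out, dim(x)), sdFactor = sum(k^2)^(3 / 2))
}

# stable run identifier for provenance stamps
configHash <- function(x) rlang::hash(x)

# no timestamp: persisted artifacts must be hash-identical across re-runs
provenanceStamp <- function(config, seeds) {
  list(config_hash = configHash(config),
       seeds = seeds,
       package_version = as.character(utils::packageVersion("MorphoImprint")))
}

# recursively strip S3 classes from nested config lists so they serialize
# as plain JSON objects
stripClasses <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(unclass(x), stripClasses))
  x
}

# locale-independent numeric formatting for CSV writers
writeStableCSV <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
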