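#' First-order (intensity) statistics of the in-mask voxels
#'
#' Fourteen first-order descriptors of the raw in-mask intensity
#' distribution: mean, median, min, max, range, variance (population),
#' skewness and kurtosis (population moment definitions, kurtosis not
#' excess), energy (sum of squared intensities), entropy in bits over the
#' discretized gray levels, the 10th/90th percentiles, interquartile range,
#' and robust mean absolute deviation (mean absolute deviation of the values
#' inside the 10-90 percentile band from that band's mean).
#'
#' @param image 3-D intensity array.
#' @param mask aligned binary mask, non-empty.
#' @param spec [discretizationSpec()] used for the entropy term.
#' @return named numeric vector of 14 features.
#' @export
firstOrderFeatures <- function(image, mask, spec = discretizationSpec()) {
  v <- image[mask == 1L]
  if (length(v) == 0) stop("mask is empty")
  n <- length(v)
  m <- mean(v)
  m2 <- mean((v - m)^2)
  skew <- if (m2 > 0) mean((v - m)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((v - m)^4) / m2^2 else 0
  lev <- discretizeIntensities(image, mask, spec)
  p <- tabulate(lev$levels[mask == 1L], nbins = lev$G) / n
  p <- p[p > 0]
  entropy <- -sum(p * log2(p))
  q <- quantile(v, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  band <- v[v >= q[1] & v <= q[4]]
  rmad <- if (length(band)) mean(abs(band - mean(band))) else 0
  c(firstorder_mean = m,
    firstorder_median = median(v),
    firstorder_min = min(v),
    firstorder_max = max(v),
    firstorder_range = max(v) - min(v),
    firstorder_variance = m2,
    firstorder_skewness = skew,
    firstorder_kurtosis = kurt,
    firstorder_energy = sum(v^2),
    firstorder_entropy = entropy,
    firstorder_p10 = q[1],
    firstorder_p90 = q[4],
    firstorder_iqr = q[3] - q[2],
    firstorder_rmad = rmad)
}
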