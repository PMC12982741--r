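#' Gray-level discretization specification
#'
#' Texture matrices operate on discretized gray levels 1..G. Two standard
#' modes: `fixed_bin_width` maps intensity v to
#' `floor((v - min) / bin_width) + 1` (default width 25 HU, a common
#' IBSI-compliant choice for CT); `fixed_bin_count` maps the in-mask range
#' onto `n_bins` equal bins.
#'
#' @param mode `"fixed_bin_width"` or `"fixed_bin_count"`.
#' @param bin_width bin width in HU (width mode; > 0).
#' @param n_bins number of bins (count mode; >= 1).
#' @export
discretizationSpec <- function(mode = c("fixed_bin_width", "fixed_bin_count"),
                               bin_width = 25, n_bins = 32) {
  mode <- match.arg(mode)
  if (mode == "fixed_bin_width" && bin_width <= 0) stop("bin_width must be > 0")
  if (mode == "fixed_bin_count" && n_bins < 1) stop("n_bins must be >= 1")
  structure(list(mode = mode, bin_width = bin_width, n_bins = as.integer(n_bins)),
            class = "DiscretizationSpec")
}

#' Discretize in-mask intensities to integer gray levels
#'
#' @param image 3-D intensity array.
#' @param mask aligned binary mask.
#' @param spec a [discretizationSpec()].
#' @return list with `levels` (integer array, 0 outside the mask, 1..G
#'   inside) and `G` (number of levels). A constant in-mask image yields a
#'   single level 1 in either mode.
#' @export
discretizeIntensities <- function(image, mask, spec = discretizationSpec()) {
  stopifnot(identical(dim(image), dim(mask)))
  inM <- mask == 1L
  if (!any(inM)) stop("mask is empty")
  v <- image[inM]
  lo <- min(v); hi <- max(v)
  lev <- if (spec$mode == "fixed_bin_width") {
    floor((v - lo) / spec$bin_width) + 1
  } else if (hi == lo) {
    rep(1L, length(v))
  } else {
    pmin(spec$n_bins, floor((v - lo) / ((hi - lo) / spec$n_bins)) + 1)
  }
  levels <- array(0L, dim(image))
  levels[inM] <- as.integer(lev)
  list(levels = levels, G = max(lev))
}
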