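#' One-voxel 6-connected binary mask erosion
#'
#' Morphological binary erosion with the 3-D 6-connected (face-neighbour,
#' cross-shaped) structuring element: a voxel survives iff it and all six
#' face neighbours are foreground, with out-of-grid counting as background.
#' This removes the peripheral boundary, shrinking the lesion by one voxel in
#' all directions. If the result is empty the returned (empty) mask carries
#' attribute `degenerate = TRUE`; if it is disconnected, only the largest
#' 26-connected component is retained (attribute `reconnected = TRUE`), so
#' connectivity is preserved.
#'
#' @param mask 3-D binary array (or a \linkS4class{LesionVolume}, whose mask
#'   is eroded).
#' @return eroded binary array of the same dimensions.
#' @export
erodeMask <- function(mask) {
  if (is(mask, "LesionVolume")) mask <- maskArray(mask)
  stopifnot(length(dim(mask)) == 3L)
  if (sum(mask) == 0) stop("empty input mask")
  out <- array(cpp_erode6(as.integer(mask), dim(mask)), dim(mask))
  if (sum(out) == 0) {
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  if (!isConnected26(out)) {
    out <- largestComponent26(out)
    attr(out, "reconnected") <- TRUE
  }
  out
}
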