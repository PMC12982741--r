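#' t-SNE embedding of a standardized feature table
#'
#' Embeds lesions into 2-D with t-distributed stochastic neighbour embedding
#' (exact gradient, `theta = 0`), which preserves local neighbourhood
#' structure of the high-dimensional morphological feature space.
#' Initialization is deterministic (first two principal components scaled to
#' 1e-4), so coordinates are a pure function of the input, the
#' hyperparameters and the seed.
#'
#' @param x a standardized SummarizedExperiment (features x lesions) or a
#'   lesions x features numeric matrix.
#' @param perplexity t-SNE perplexity (effective neighbourhood size);
#'   requires `n >= 3 * perplexity + 2`.
#' @param max_iter gradient iterations.
#' @param seed integer seed.
#' @param exaggeration early exaggeration factor.
#' @return lesions x 2 coordinate matrix (rownames = lesion ids) with
#'   attributes `params` and `seed`.
#' @export
embedLesions <- function(x, perplexity = 30, max_iter = 1000, seed = 1L,
                         exaggeration = 12) {
  m <- if (is(x, "SummarizedExperiment"))
    t(SummarizedExperiment::assay(x, "features")) else as.matrix(x)
  n <- nrow(m)
  if (n < 3 * perplexity + 2)
    stop("parameter error: perplexity ", perplexity, " needs at least ",
         ceiling(3 * perplexity + 2), " lesions, got ", n)
  pc <- prcomp(m, center = TRUE, scale. = FALSE, rank. = 2)
  init <- pc$x[, 1:2, drop = FALSE]
  if (ncol(init) < 2) init <- cbind(init, 0)
  init <- init / max(1e-12, stats::sd(init[, 1])) * 1e-4
  set.seed(seed)
  fit <- Rtsne::Rtsne(m, dims = 2, perplexity = perplexity, theta = 0,
                      max_iter = max_iter, Y_init = init, pca = FALSE,
                      exaggeration_factor = exaggeration,
                      check_duplicates = FALSE, verbose = FALSE)
  coords <- fit$Y
  rownames(coords) <- rownames(m)
  colnames(coords) <- c("dim1", "dim2")
  attr(coords, "params") <- list(perplexity = perplexity, max_iter = max_iter,
                                 exaggeration = exaggeration, theta = 0)
  attr(coords, "seed") <- as.integer(seed)
  coords
}

#' Export an embedding scatter plot colored by a labeling
#'
#' Writes a PDF (or PNG) scatter plot of a 2-D embedding with points colored
#' by any per-lesion labeling (cluster, tumor type, environment, ...) and a
#' legend. Purely a reporting aid; all quantitative output lives in the CSV
#' and JSON artifacts.
#'
#' @param coords lesions x 2 coordinate matrix (e.g. from [embedLesions()]).
#' @param labels per-lesion labeling aligned to the rows of `coords`.
#' @param file output path ending in `.pdf` or `.png`.
#' @param main plot title.
#' @return `file`, invisibly.
#' @export
plotEmbedding <- function(coords, labels, file, main = "Morphological embedding") {
  stopifnot(nrow(coords) == length(labels))
  f <- factor(labels)
  pal <- grDevices::hcl.colors(max(3L, nlevels(f)), "Dark 3")[seq_len(nlevels(f))]
  if (grepl("\\.png$", file)) grDevices::png(file, 900, 800) else
    grDevices::pdf(file, width = 7, height = 6.5)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::plot(coords[, 1], coords[, 2], col = pal[as.integer(f)], pch = 19,
                 cex = 0.6, xlab = "dim 1", ylab = "dim 2", main = main)
  graphics::legend("topright", legend = levels(f), col = pal, pch = 19,
                   cex = 0.8, bty = "n")
  invisible(file)
}
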