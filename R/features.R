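#' Convert RGB pixels to HSV hue angles
#'
#' Standard HSV hue in degrees `[0, 360)`; saturation and value are
#' discarded, since hue isolates the red-to-blue chromatic content that
#' tracks hemoglobin while being comparatively robust to brightness.
#' Achromatic pixels (max channel equals min channel, hue undefined) are
#' assigned hue 0 and flagged in the `"achromatic"` attribute.
#'
#' @param pixels H x W x 3 array or n x 3 matrix of 8-bit RGB values.
#' @return numeric vector of hue angles (column-major for array input)
#'   with a logical `"achromatic"` attribute.
#' @export
#' @examples
#' rgb_to_hue(matrix(c(255, 0, 0), 1))  # 0 (pure red)
rgb_to_hue <- function(pixels) {
  m <- if (length(dim(pixels)) == 3) {
    cbind(as.vector(pixels[, , 1]), as.vector(pixels[, , 2]),
          as.vector(pixels[, , 3]))
  } else {
    matrix(pixels, ncol = 3)
  }
  if (any(m < 0 | m > 255)) stop("RGB values must lie in [0, 255]")
  hsv <- grDevices::rgb2hsv(t(m), maxColorValue = 255)
  hue <- hsv[1, ] * 360
  achrom <- m[, 1] == m[, 2] & m[, 2] == m[, 3]
  hue[achrom] <- 0
  attr(hue, "achromatic") <- achrom
  hue
}

#' Normalized hue histogram over a region of interest
#'
#' Counts hues over `bins` equal-width bins on `[0, 360)` and normalizes
#' the mass to sum to one. Achromatic pixels and pixels outside the mask
#' are excluded.
#'
#' @param hues hue vector from [rgb_to_hue()].
#' @param mask optional logical mask (same layout as the image the hues
#'   came from); `NULL` keeps every pixel.
#' @param bins number of bins (default 36, i.e. 10-degree bins).
#' @param achromatic optional logical vector; defaults to the
#'   `"achromatic"` attribute of `hues`.
#' @return object of class `hue_histogram`: `bin_edges` (length
#'   `bins + 1`), `mass` (sums to 1), `n_pixels`.
#' @export
hue_histogram <- function(hues, mask = NULL, bins = 36,
                          achromatic = NULL) {
  achrom <- achromatic %||% attr(hues, "achromatic") %||%
    rep(FALSE, length(hues))
  keep <- !achrom
  if (!is.null(mask)) keep <- keep & as.vector(mask)
  h <- as.vector(hues)[keep]
  if (length(h) == 0) stop("empty ROI: no usable chromatic pixels")
  width <- 360 / bins
  idx <- pmin(floor(h / width) + 1L, bins)
  mass <- tabulate(idx, bins) / length(h)
  structure(list(bin_edges = seq(0, 360, length.out = bins + 1),
                 mass = mass, n_pixels = length(h)),
            class = "hue_histogram")
}

#' Fit a principal component model to hue histograms
#'
#' Mean-centers the histogram matrix and takes the top-`k` right singular
#' vectors (ordered by decreasing singular value) as loading vectors.
#' Sign convention: the largest-magnitude loading of each component is
#' positive, which makes the fit reproducible across BLAS
#' implementations.
#'
#' @param histograms N x B matrix (rows = histograms); `N > k` required.
#' @param k number of components (`1 <= k <= B`).
#' @return object of class `hue_pca`: `mean_vector`, `components`
#'   (B x k, orthonormal columns), `sdev`, `k`.
#' @export
fit_pca <- function(histograms, k) {
  X <- as.matrix(histograms)
  n <- nrow(X); b <- ncol(X)
  if (k < 1 || k > b) stop("k must satisfy 1 <= k <= ncol(histograms)")
  if (n <= k) stop("need more rows than components (N > k)")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  rank <- pca_rank_(sv$d, dim(Xc))
  if (rank < k) {
    stop(sprintf("input has rank %d < k = %d; use k <= %d",
                 rank, k, rank))
  }
  comp <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (comp[which.max(abs(comp[, j])), j] < 0) comp[, j] <- -comp[, j]
  }
  structure(list(mean_vector = mu, components = comp,
                 sdev = sv$d[seq_len(k)] / sqrt(max(n - 1, 1)), k = k),
            class = "hue_pca")
}

pca_rank_ <- function(d, dims) {
  if (max(d) == 0) return(0L)
  # relative tolerance in the spirit of Matrix::rankMatrix
  sum(d > max(dims) * max(d) * .Machine$double.eps * 100)
}

#' Numerical rank of a centered histogram matrix
#'
#' The number of principal components that can be extracted from the
#' matrix; narrow hue distributions occupy few histogram bins, which
#' bounds the usable component count.
#'
#' @param histograms N x B matrix.
#' @return integer rank.
#' @export
pca_max_components <- function(histograms) {
  X <- as.matrix(histograms)
  Xc <- sweep(X, 2, colMeans(X))
  pca_rank_(svd(Xc)$d, dim(Xc))
}

#' Project histograms onto a fitted principal component model
#'
#' Scores are `t(components) %*% (mass - mean_vector)`; optional
#' metadata columns (e.g. standardized age, sex indicator) are appended
#' unchanged.
#'
#' @param x a `hue_histogram`, a mass vector, or an N x B matrix.
#' @param model a [fit_pca()] model.
#' @param metadata optional data.frame / matrix of extra feature columns
#'   (one row per histogram).
#' @return numeric matrix of feature rows (`score_1..score_k`, then
#'   metadata columns).
#' @export
project_features <- function(x, model, metadata = NULL) {
  stopifnot(inherits(model, "hue_pca"))
  X <- if (inherits(x, "hue_histogram")) matrix(x$mass, nrow = 1)
       else if (is.null(dim(x))) matrix(x, nrow = 1)
       else as.matrix(x)
  if (ncol(X) != length(model$mean_vector)) {
    stop("histogram length does not match the PCA model")
  }
  scores <- sweep(X, 2, model$mean_vector) %*% model$components
  colnames(scores) <- paste0("score_", seq_len(model$k))
  if (!is.null(metadata)) {
    metadata <- as.matrix(metadata)
    if (nrow(metadata) != nrow(scores)) {
      stop("metadata must have one row per histogram")
    }
    scores <- cbind(scores, metadata)
  }
  scores
}
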