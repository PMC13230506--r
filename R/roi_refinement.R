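shift_mask <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(FALSE, H, W)
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# one 4-connected erosion step: a pixel survives iff it and its four
# edge-neighbors are foreground (neighbors outside the image count as
# background, so the mask erodes at the image border too)
erode_once <- function(m) {
  m & shift_mask(m, 1, 0) & shift_mask(m, -1, 0) &
    shift_mask(m, 0, 1) & shift_mask(m, 0, -1)
}

#' Refine a coarse mask by iterative boundary erosion
#'
#' Repeatedly removes the 4-connected boundary pixels of the mask and,
#' among the snapshots (original, after 1 erosion, after 2, ...), returns
#' the one whose retained pixel fraction is closest to `target_fraction`
#' (ties resolve to fewer erosions). The default target of 30% discards
#' the over-segmented rim (skin edges, uncut nail) while keeping the
#' well-perfused core of the region.
#'
#' Masks smaller than `min_px` foreground pixels are returned unchanged
#' with `degenerate = TRUE`.
#'
#' @param mask logical (or 0/1) matrix; foreground must be non-empty.
#' @param target_fraction retained-fraction target in `(0, 1]`.
#' @param min_px minimum foreground size for refinement.
#' @return list of class `refined_mask` with elements `mask`,
#'   `retained_fraction` (relative to the input mask), `iterations`,
#'   `degenerate`.
#' @export
#' @examples
#' m <- matrix(TRUE, 10, 10)
#' erode_mask(m)$retained_fraction  # 0.36: closest snapshot to 0.30
erode_mask <- function(mask, target_fraction = 0.30, min_px = 25) {
  if (is.numeric(mask)) mask <- mask > 0
  stopifnot(is.matrix(mask), is.logical(mask))
  if (target_fraction <= 0 || target_fraction > 1) {
    stop("target_fraction must lie in (0, 1]")
  }
  n0 <- sum(mask)
  if (n0 == 0) stop("mask has no foreground pixels")
  if (n0 < min_px) {
    return(structure(list(mask = mask, retained_fraction = 1,
                          iterations = 0L, degenerate = TRUE),
                     class = "refined_mask"))
  }
  best <- mask
  best_frac <- 1
  best_iter <- 0L
  best_diff <- abs(1 - target_fraction)
  cur <- mask
  frac <- 1
  iter <- 0L
  while (frac > target_fraction) {
    cur <- erode_once(cur)
    iter <- iter + 1L
    frac <- sum(cur) / n0
    d <- abs(frac - target_fraction)
    if (d < best_diff) {       # strict: ties keep the earlier snapshot
      best <- cur; best_frac <- frac; best_iter <- iter; best_diff <- d
    }
    if (frac == 0) break
  }
  structure(list(mask = best, retained_fraction = best_frac,
                 iterations = best_iter, degenerate = FALSE),
            class = "refined_mask")
}

grayscale <- function(pixels) {
  (0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] +
     0.114 * pixels[, , 3]) / 255
}

gradient_magnitude <- function(img) {
  H <- nrow(img); W <- ncol(img)
  gx <- (img[, c(2:W, W)] - img[, c(1, 1:(W - 1))]) / 2
  gy <- (img[c(2:H, H), ] - img[c(1, 1:(H - 1)), ]) / 2
  sqrt(gx^2 + gy^2)
}

# Otsu's between-class-variance threshold on a 256-bin histogram.
otsu_threshold <- function(x, nbins = 256) {
  x <- as.vector(x)
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1)
  counts <- as.numeric(
    tabulate(pmin(findInterval(x, breaks, rightmost.closed = TRUE),
                  nbins), nbins))
  w <- cumsum(counts)
  mu <- cumsum(counts * seq_len(nbins))
  tot <- w[nbins]; mut <- mu[nbins]
  w0 <- w[-nbins]; w1 <- tot - w0
  between <- (mut * w0 - mu[-nbins] * tot)^2 / (w0 * w1)
  between[w0 == 0 | w1 == 0] <- 0
  breaks[which.max(between) + 1]
}

#' Detect the circular eyelid arc by a Hough circle transform
#'
#' Builds an edge map by thresholding the gradient magnitude of the
#' grayscale patch (Otsu's automatic threshold unless `edge_threshold` is
#' given), then votes over a discretized (center, radius) accumulator
#' with 1-pixel steps. Radii range over `radius_range` times the smaller
#' patch dimension. The maximum-vote circle is returned; equal votes
#' resolve to the larger radius. When no accumulator cell reaches
#' `min_votes`, detection fails (`found = FALSE`) and the caller may fall
#' back to the coarse mask.
#'
#' @param patch an `image_sample`, an RGB array, or a grayscale matrix.
#' @param radius_range radii as fractions of `min(H, W)`.
#' @param min_votes minimum accumulator count for a valid detection.
#' @param edge_threshold optional fixed gradient threshold.
#' @return object of class `circle_fit`: `row`, `col`, `radius`
#'   (1-based pixel coordinates), `score` (accumulator votes), `found`.
#' @export
detect_eyelid_arc <- function(patch, radius_range = c(0.2, 0.6),
                              min_votes = 20, edge_threshold = NULL) {
  pixels <- if (inherits(patch, "image_sample")) patch$pixels else patch
  img <- if (length(dim(pixels)) == 3) grayscale(pixels) else pixels
  H <- nrow(img); W <- ncol(img)
  mag <- gradient_magnitude(img)
  thr <- edge_threshold %||% otsu_threshold(mag)
  edges <- which(mag > thr, arr.ind = TRUE)
  fail <- structure(list(row = NA_real_, col = NA_real_,
                         radius = NA_real_, score = 0, found = FALSE),
                    class = "circle_fit")
  if (nrow(edges) == 0) return(fail)
  m <- min(H, W)
  radii <- seq.int(max(3L, as.integer(round(radius_range[1] * m))),
                   max(4L, as.integer(round(radius_range[2] * m))))
  fit <- hough_best_circle_cpp(as.integer(edges[, 1]),
                               as.integer(edges[, 2]), H, W,
                               as.integer(radii))
  if (fit$votes < min_votes) return(fail)
  structure(list(row = as.numeric(fit$row), col = as.numeric(fit$col),
                 radius = as.numeric(fit$radius),
                 score = as.numeric(fit$votes), found = TRUE),
            class = "circle_fit")
}

#' Lower segment of a fitted circle as a binary mask
#'
#' The relevant eyelid area is the lower segment of the fitted circle:
#' pixels strictly inside the circle whose row coordinate is at or below
#' the center row, clipped to the image bounds.
#'
#' @param circle a `circle_fit` from [detect_eyelid_arc()].
#' @param image_shape `c(H, W)`.
#' @return logical H x W matrix.
#' @export
lower_segment_mask <- function(circle, image_shape) {
  if (!isTRUE(circle$found)) stop("circle fit is not valid")
  H <- image_shape[1]; W <- image_shape[2]
  rowm <- matrix(seq_len(H), H, W)
  colm <- matrix(seq_len(W), H, W, byrow = TRUE)
  d2 <- (rowm - circle$row)^2 + (colm - circle$col)^2
  mask <- d2 < circle$radius^2 & rowm >= circle$row
  if (!any(mask)) stop("circle lies entirely outside the image")
  mask
}

#' Refine the measurement region of an image sample
#'
#' Modality-specific routes: fingernail patches use the coarse mask plus
#' [erode_mask()]; eyelid patches crop to the coarse-mask neighborhood,
#' detect the eyelid arc with [detect_eyelid_arc()] and keep the lower
#' circle segment, falling back to the eroded coarse mask when detection
#' fails.
#'
#' @param sample an `image_sample`.
#' @param target_fraction erosion retention target.
#' @param ... passed on to [detect_eyelid_arc()].
#' @return list with `mask`, `method` (`"erosion"`, `"hough_arc"` or
#'   `"fallback_erosion"`), `retained_fraction`, and `circle` (eyelid
#'   route only).
#' @export
refine_roi <- function(sample, target_fraction = 0.30, ...) {
  stopifnot(inherits(sample, "image_sample"))
  coarse <- sample$coarse_mask
  if (sample$modality == "fingernail") {
    er <- erode_mask(coarse, target_fraction)
    return(list(mask = er$mask, method = "erosion",
                retained_fraction = er$retained_fraction,
                degenerate = er$degenerate))
  }
  # eyelid: crop to the coarse bounding box (with margin), detect arc
  idx <- which(coarse, arr.ind = TRUE)
  H <- nrow(coarse); W <- ncol(coarse)
  r1 <- range(idx[, 1]); c1 <- range(idx[, 2])
  mr <- ceiling(0.6 * diff(r1) + 2)
  mc <- ceiling(0.6 * diff(c1) + 2)
  rows <- max(1, r1[1] - mr):min(H, r1[2] + mr)
  cols <- max(1, c1[1] - mc):min(W, c1[2] + mc)
  crop <- sample$pixels[rows, cols, , drop = FALSE]
  fit <- detect_eyelid_arc(crop, ...)
  if (fit$found) {
    full <- structure(list(row = fit$row + rows[1] - 1,
                           col = fit$col + cols[1] - 1,
                           radius = fit$radius, score = fit$score,
                           found = TRUE), class = "circle_fit")
    mask <- lower_segment_mask(full, c(H, W))
    return(list(mask = mask, method = "hough_arc",
                retained_fraction = sum(mask) / sum(coarse),
                circle = full))
  }
  er <- erode_mask(coarse, target_fraction)
  list(mask = er$mask, method = "fallback_erosion",
       retained_fraction = er$retained_fraction, circle = fit)
}
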