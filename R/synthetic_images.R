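#' Rendering parameters for synthetic eyelid / fingernail patches
#'
#' The renderer draws a region of interest (ROI) on a near-white
#' background: a lower half-disk (the exposed palpebral conjunctiva under
#' the everted eyelid) for eyelid patches, a filled ellipse (nail plate)
#' for fingernail patches. ROI pixel hue follows the documented linear
#' hue--Hb link [hue_link()] plus a per-image lighting hue offset and
#' per-pixel noise; pixel value carries a multiplicative lighting gain.
#' The coarse mask handed downstream strictly contains the true ROI plus
#' a contaminating rim (over-segmentation that the erosion refinement has
#' to remove); rim pixels are hue-shifted surrounding skin.
#'
#' @param width,height patch size in pixels.
#' @param images_per_visit images rendered per modality per visit.
#' @param nails_per_image number of nail ellipses per fingernail image.
#' @param h0,beta hue link intercept (degrees) and slope (degrees per
#'   mmol/L); hue decreases red-ward as Hb rises.
#' @param pixel_hue_sd per-pixel hue noise SD (degrees).
#' @param image_hue_sd per-image lighting hue offset SD (degrees).
#' @param lighting_gain_sd SD of the multiplicative lighting gain.
#' @param rim_width contaminating rim width in pixels.
#' @param rim_hue_shift hue shift of rim pixels relative to the ROI
#'   (degrees).
#' @param roi_saturation,roi_value HSV saturation / value of ROI pixels.
#' @param bg_saturation,bg_value HSV saturation / value of the
#'   background.
#' @return object of class `render_params`.
#' @export
render_params <- function(width = 64, height = 64, images_per_visit = 2,
                          nails_per_image = 1,
                          h0 = 60, beta = 3.75,
                          pixel_hue_sd = 4, image_hue_sd = 2,
                          lighting_gain_sd = 0.05,
                          rim_width = 4, rim_hue_shift = 25,
                          roi_saturation = 0.65, roi_value = 0.75,
                          bg_saturation = 0.02, bg_value = 0.97) {
  stopifnot(width >= 16, height >= 16, images_per_visit >= 1,
            nails_per_image >= 1, pixel_hue_sd >= 0, image_hue_sd >= 0,
            lighting_gain_sd >= 0, rim_width >= 1)
  structure(as.list(environment()), class = "render_params")
}

#' Hue--hemoglobin link used by the renderer
#'
#' `hue = h0 - beta * hb`, clipped to `[0, 120]` degrees (the red-green
#' side of the color wheel, so no circular wrap-around occurs in
#' synthetic data). With the defaults the clinical Hb span of ~8 mmol/L
#' maps to a red-ward hue shift of ~30 degrees.
#'
#' @param hb hemoglobin in mmol/L.
#' @param params a [render_params()] object.
#' @return hue angle(s) in degrees.
#' @export
hue_link <- function(hb, params = render_params()) {
  clip(params$h0 - params$beta * hb, 0, 120)
}

# Draw one patch. Returns an `image_sample`.
render_one_image <- function(hb, modality, params, patient_id = "P0000",
                             visit_index = 0L) {
  H <- params$height
  W <- params$width
  rowm <- matrix(seq_len(H), H, W)
  colm <- matrix(seq_len(W), H, W, byrow = TRUE)
  rim <- params$rim_width

  if (modality == "eyelid") {
    r0 <- runif(1, 0.28, 0.34) * min(H, W)
    cy <- runif(1, 0.35, 0.50) * H
    cx <- runif(1, 0.40, 0.60) * W
    d2 <- (rowm - cy)^2 + (colm - cx)^2
    true_mask <- d2 <= r0^2 & rowm >= cy
    coarse <- d2 <= (r0 + rim)^2 & rowm >= cy - rim
    geom <- list(center = c(row = cy, col = cx), radius = r0)
  } else {
    k <- params$nails_per_image
    true_mask <- matrix(FALSE, H, W)
    coarse <- matrix(FALSE, H, W)
    centers <- (seq_len(k) - 0.5) / k * W
    a <- runif(1, 0.18, 0.25) * W / k
    b <- runif(1, 0.24, 0.34) * H
    cy <- runif(1, 0.40, 0.60) * H
    for (cx in centers) {
      true_mask <- true_mask |
        ((colm - cx) / a)^2 + ((rowm - cy) / b)^2 <= 1
      coarse <- coarse |
        ((colm - cx) / (a + rim))^2 + ((rowm - cy) / (b + rim))^2 <= 1
    }
    geom <- list(center = c(row = cy, col = centers[1]), axes = c(a, b))
  }

  hue_offset <- rnorm(1, 0, params$image_hue_sd)
  gain <- rnorm(1, 0, params$lighting_gain_sd)
  base_hue <- hue_link(hb, params)

  h <- matrix(30, H, W)  # background hue (irrelevant, nearly achromatic)
  s <- matrix(params$bg_saturation, H, W)
  v <- matrix(params$bg_value, H, W)

  rim_px <- coarse & !true_mask
  n_rim <- sum(rim_px)
  n_roi <- sum(true_mask)
  h[rim_px] <- clip(base_hue + params$rim_hue_shift + hue_offset +
                      rnorm(n_rim, 0, params$pixel_hue_sd), 0, 120)
  h[true_mask] <- clip(base_hue + hue_offset +
                         rnorm(n_roi, 0, params$pixel_hue_sd), 0, 120)
  s[coarse] <- params$roi_saturation
  v[coarse] <- clip(params$roi_value * (1 + gain), 0.05, 1)

  rgb <- hsv_to_rgb(as.vector(h), as.vector(s), as.vector(v))
  pixels <- array(as.integer(round(255 * rgb)), dim = c(H, W, 3))

  structure(list(
    entry_ref = list(patient_id = patient_id, visit_index = visit_index),
    modality = modality,
    pixels = pixels,
    coarse_mask = coarse,
    ground_truth = list(true_mask = true_mask, hue = base_hue,
                        hue_offset = hue_offset, lighting_gain = gain,
                        geometry = geom)),
    class = "image_sample")
}

#' Render the photographs of one study visit
#'
#' Renders `images_per_visit` eyelid and `images_per_visit` fingernail
#' patches for one cohort entry. Deterministic given the seed. The mean
#' ROI hue of each patch is the [hue_link()] value at the entry's Hb plus
#' the per-image lighting offset; the coarse mask always strictly
#' contains the true ROI.
#'
#' @param entry one row of an [generate_cohort()] cohort (or any list
#'   with `patient_id`, `visit_index`, `hb_true`).
#' @param params a [render_params()] object.
#' @param seed integer seed.
#' @return list of `image_sample` objects.
#' @export
render_visit_images <- function(entry, params = render_params(),
                                seed = 1L) {
  hb <- entry$hb_true
  if (is.null(hb) || is.na(hb)) stop("entry must carry hb_true")
  with_seed(seed, {
    out <- list()
    for (modality in c("eyelid", "fingernail")) {
      for (i in seq_len(params$images_per_visit)) {
        out[[length(out) + 1L]] <- render_one_image(
          hb, modality, params,
          patient_id = entry$patient_id %||% "P0000",
          visit_index = entry$visit_index %||% 0L)
      }
    }
    out
  })
}

#' Render images for a whole cohort
#'
#' @param cohort an [generate_cohort()] cohort.
#' @param params a [render_params()] object.
#' @param seed integer master seed; each entry gets its own substream.
#' @return flat list of `image_sample` objects.
#' @export
render_cohort_images <- function(cohort, params = render_params(),
                                 seed = 1L) {
  base <- substream_seed(seed, "images")
  out <- vector("list", 0)
  for (i in seq_len(nrow(cohort))) {
    entry_seed <- as.integer((as.numeric(base) + 131 * i) %% 2147483647)
    out <- c(out, render_visit_images(cohort[i, ], params, entry_seed))
  }
  out
}
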