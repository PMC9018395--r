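#' Configuration for synthetic colony-well images
#'
#' @param image_shape (height, width) in pixels.
#' @param well_radius_frac Well-disk radius as a fraction of the smaller
#'   image dimension.
#' @param stain_level,background_level,outside_level Mean intensities (16-bit
#'   counts) of crystal-violet stain, the unstained well interior and the
#'   area outside the well disk. Stain is dark on a light background.
#' @param noise_sigma Gaussian pixel noise SD, counts.
#' @param blur_sigma Gaussian blur applied to the ideal image (soft colony
#'   edges), pixels.
#' @param colony_radius_cv Coefficient of variation of relative colony sizes.
#' @return A list of class `momp_colony_config`.
#' @export
colony_config <- function(image_shape = c(512L, 512L),
                          well_radius_frac = 0.45,
                          stain_level = 18000,
                          background_level = 55000,
                          outside_level = 62000,
                          noise_sigma = 600,
                          blur_sigma = 1,
                          colony_radius_cv = 0.4) {
  structure(list(image_shape = as.integer(image_shape),
                 well_radius_frac = well_radius_frac,
                 stain_level = stain_level,
                 background_level = background_level,
                 outside_level = outside_level, noise_sigma = noise_sigma,
                 blur_sigma = blur_sigma, colony_radius_cv = colony_radius_cv),
            class = "momp_colony_config")
}

#' Render a synthetic crystal-violet colony well
#'
#' Draws `n_colonies` seed centres in the well disk and builds the stained
#' mask as a sub-level set of the signed distance field
#' `min_i(dist(p, c_i) - r_i)`; the level is found by bisection so that the
#' realized covered fraction of the well disk matches `covered_fraction`
#' within one part in a thousand (well within the +/-1 percentage-point
#' contract). Colonies merge naturally as the level grows, mimicking
#' confluent growth. The image is the mask painted dark on a light well
#' background, blurred and noised.
#'
#' @param covered_fraction Requested fraction of the well disk covered by
#'   stain, in `[0, 1]`.
#' @param n_colonies Number of colony seeds.
#' @param config A [colony_config()].
#' @param seed Integer seed.
#' @param well_id Metadata label.
#' @return A list of class `momp_colony`: `image` (integer matrix), `mask`
#'   (logical matrix, ground truth), `realized_fraction`,
#'   `requested_fraction`, `well_center`, `well_radius`, `well_id`.
#' @export
render_colony_well <- function(covered_fraction, n_colonies = 50,
                               config = colony_config(), seed = 1L,
                               well_id = "A1") {
  stopifnot_scalar_number(covered_fraction, "covered_fraction")
  if (covered_fraction < 0 || covered_fraction > 1) {
    abort("`covered_fraction` must lie in [0, 1].")
  }
  h <- config$image_shape[1]; w <- config$image_shape[2]
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  wr <- config$well_radius_frac * min(h, w)
  yy <- matrix(seq_len(h), h, w); xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  in_well <- (yy - cy)^2 + (xx - cx)^2 <= wr^2
  disk_px <- sum(in_well)

  with_seed(seed, {
    mask <- matrix(FALSE, h, w)
    if (covered_fraction > 0 && n_colonies > 0) {
      # seeds uniform in the well disk, sizes lognormal-ish around 1
      r <- wr * 0.92 * sqrt(stats::runif(n_colonies))
      a <- stats::runif(n_colonies, 0, 2 * pi)
      sy <- cy + r * sin(a); sx <- cx + r * cos(a)
      rel <- pmax(0.2, 1 + stats::rnorm(n_colonies, 0, config$colony_radius_cv))
      # signed distance field to the nearest (inflated) seed
      d <- matrix(Inf, h, w)
      for (i in seq_len(n_colonies)) {
        d <- pmin(d, sqrt((yy - sy[i])^2 + (xx - sx[i])^2) / rel[i])
      }
      target <- round(covered_fraction * disk_px)
      lo <- -1; hi <- max(d[in_well]) + 1
      for (k in 1:50) {
        mid <- (lo + hi) / 2
        cnt <- sum(d[in_well] < mid)
        if (cnt < target) lo <- mid else hi <- mid
      }
      mask <- d < hi & in_well
    }
    realized <- sum(mask) / disk_px

    img <- matrix(config$outside_level, h, w)
    img[in_well] <- config$background_level
    img[mask] <- config$stain_level
    if (config$blur_sigma > 0) {
      img <- as_matrix(EBImage::gblur(EBImage::Image(img), config$blur_sigma))
    }
    if (config$noise_sigma > 0) {
      img <- img + stats::rnorm(length(img), 0, config$noise_sigma)
    }
    img <- round(clamp(img, 0, 65535))
    storage.mode(img) <- "integer"
    structure(list(image = img, mask = mask, realized_fraction = realized,
                   requested_fraction = covered_fraction,
                   well_center = c(cy, cx), well_radius = wr,
                   well_id = well_id),
              class = "momp_colony")
  })
}

#' @export
print.momp_colony <- function(x, ...) {
  cat(sprintf("<momp_colony> well %s: requested %.3f, realized %.4f of well disk\n",
              x$well_id, x$requested_fraction, x$realized_fraction))
  invisible(x)
}
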