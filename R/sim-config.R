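#' Simulation configuration for synthetic screen data
#'
#' Bundles every tunable of the synthetic-plate generator: image geometry,
#' plate format and edge exclusion, per-field cell density, the per-well
#' phenotype mixture, reporter puncta properties, diffuse fluorescence levels
#' and the camera noise model. Defaults emulate a 384-well etoposide + Q-VD
#' screen of a Venus-BAX / OMI-mCherry reporter line imaged at 20x widefield
#' (0.65 um/px, 16-bit), with the two outer rows and columns of every plate
#' excluded from use.
#'
#' Phenotype labels are `BAX_POSITIVE` (apoptotic: translocated BAX puncta,
#' OMI released and degraded), `INTACT` (mitochondrial OMI puncta, diffuse
#' cytoplasmic BAX), `DOUBLE_POSITIVE` (non-colocalized BAX and OMI puncta:
#' heterogeneous MOMP) and `NONDETERMINED` (nonfluorescent in both reporter
#' channels).
#'
#' @param image_shape Integer vector (height, width) in pixels.
#' @param pixel_size Micrometers per pixel.
#' @param plate_format Integer vector (rows, columns) of the plate.
#' @param edge_margin Number of outer rows/columns left untransfected.
#' @param sites_per_well Imaging sites per well.
#' @param cells_per_field Mean cell count per field (Poisson).
#' @param phenotype_mixture Named probability vector over the four phenotype
#'   labels; must be non-negative and sum to 1.
#' @param puncta Per-channel puncta specification: a named list with entries
#'   `YFP` and `TexasRed`, each a list with `count_mean`, `diameter_range`
#'   (FWHM, pixels) and `amplitude` (peak intensity counts).
#' @param nucleus_amplitude,nucleus_radius_range Nuclear stain peak intensity
#'   and the (min, max) range of normal nucleus radii in pixels.
#' @param fragment_radius_range,fragment_spread Radius range of apoptotic
#'   nuclear fragments and their maximum offset from the cell centroid (px).
#' @param frag_prob_apoptotic Probability that a BAX_POSITIVE or
#'   DOUBLE_POSITIVE cell carries a fragmented nucleus.
#' @param cell_radius Cytoplasm radius in pixels (diffuse signal footprint).
#' @param puncta_zone (min, max) radial distance of puncta from the cell
#'   centroid, pixels.
#' @param min_puncta_separation Minimum distance between same-channel puncta
#'   centroids within a cell (px).
#' @param min_bax_omi_separation Minimum distance between BAX and OMI puncta
#'   in DOUBLE_POSITIVE cells (px); enforces non-colocalization.
#' @param diffuse Per-phenotype, per-channel diffuse cytoplasmic amplitudes.
#' @param min_cell_separation,border_margin Minimum centroid spacing between
#'   cells and the margin kept from the image border, pixels.
#' @param background_level Constant background offset, intensity counts.
#' @param illumination_gradient Linear relative illumination slope
#'   `c(dy, dx)` across the field (e.g. `c(0.2, 0)` makes the bottom edge
#'   20% brighter than the centre); `c(0, 0)` (flat illumination) by
#'   default.
#' @param noise_sigma Gaussian read-noise standard deviation (counts).
#'   `noise_sigma = 0` turns off both read and shot noise (noiseless mode).
#' @param gain Counts per photon used by the Poisson shot-noise model.
#' @param seed Default master seed.
#'
#' @return A list of class `momp_sim_config`.
#' @export
sim_config <- function(image_shape = c(1024L, 1024L),
                       pixel_size = 0.65,
                       plate_format = c(16L, 24L),
                       edge_margin = 2L,
                       sites_per_well = 4L,
                       cells_per_field = 60,
                       phenotype_mixture = c(BAX_POSITIVE = 0.25,
                                             INTACT = 0.60,
                                             DOUBLE_POSITIVE = 0.10,
                                             NONDETERMINED = 0.05),
                       puncta = list(
                         YFP = list(count_mean = 8, diameter_range = c(3, 6),
                                    amplitude = 3000),
                         TexasRed = list(count_mean = 10, diameter_range = c(3, 6),
                                         amplitude = 3000)),
                       nucleus_amplitude = 3000,
                       nucleus_radius_range = c(8, 11),
                       fragment_radius_range = c(2.2, 2.8),
                       fragment_spread = 6,
                       frag_prob_apoptotic = 0.6,
                       cell_radius = 18,
                       puncta_zone = c(5, 16),
                       min_puncta_separation = 8,
                       min_bax_omi_separation = 6,
                       diffuse = list(
                         BAX_POSITIVE = c(YFP = 120, TexasRed = 0),
                         INTACT = c(YFP = 200, TexasRed = 120),
                         DOUBLE_POSITIVE = c(YFP = 120, TexasRed = 100),
                         NONDETERMINED = c(YFP = 0, TexasRed = 0)),
                       min_cell_separation = 40,
                       border_margin = 26,
                       background_level = 200,
                       illumination_gradient = c(0, 0),
                       noise_sigma = 15,
                       gain = 2,
                       seed = 1L) {
  cfg <- list(
    image_shape = as.integer(image_shape), pixel_size = pixel_size,
    plate_format = as.integer(plate_format), edge_margin = as.integer(edge_margin),
    sites_per_well = as.integer(sites_per_well),
    cells_per_field = cells_per_field, phenotype_mixture = phenotype_mixture,
    puncta = puncta, nucleus_amplitude = nucleus_amplitude,
    nucleus_radius_range = nucleus_radius_range,
    fragment_radius_range = fragment_radius_range,
    fragment_spread = fragment_spread,
    frag_prob_apoptotic = frag_prob_apoptotic,
    cell_radius = cell_radius, puncta_zone = puncta_zone,
    min_puncta_separation = min_puncta_separation,
    min_bax_omi_separation = min_bax_omi_separation,
    diffuse = diffuse, min_cell_separation = min_cell_separation,
    border_margin = border_margin, background_level = background_level,
    illumination_gradient = illumination_gradient,
    noise_sigma = noise_sigma, gain = gain, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "momp_sim_config")
}

phenotype_levels <- function() {
  c("BAX_POSITIVE", "INTACT", "DOUBLE_POSITIVE", "NONDETERMINED")
}

validate_sim_config <- function(cfg) {
  mix <- cfg$phenotype_mixture
  if (!all(phenotype_levels() %in% names(mix))) {
    abort("`phenotype_mixture` must name all four phenotype classes.")
  }
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8) {
    abort("`phenotype_mixture` entries must be >= 0 and sum to 1.")
  }
  for (ch in names(cfg$puncta)) {
    dr <- cfg$puncta[[ch]]$diameter_range
    if (length(dr) != 2 || dr[1] >= dr[2]) {
      abort(sprintf("puncta diameter range for %s must satisfy min < max.", ch))
    }
  }
  if (cfg$noise_sigma < 0) abort("`noise_sigma` must be >= 0.")
  if (length(cfg$image_shape) != 2 || any(cfg$image_shape < 64)) {
    abort("`image_shape` must be two integers >= 64.")
  }
  invisible(cfg)
}

#' @export
print.momp_sim_config <- function(x, ...) {
  cat("<momp_sim_config>\n")
  cat(sprintf("  field: %d x %d px @ %.2f um/px, %d sites/well\n",
              x$image_shape[1], x$image_shape[2], x$pixel_size, x$sites_per_well))
  cat(sprintf("  plate: %d x %d wells, edge margin %d\n",
              x$plate_format[1], x$plate_format[2], x$edge_margin))
  cat(sprintf("  cells/field (mean): %g; mixture: %s\n", x$cells_per_field,
              paste(sprintf("%s=%.2f", names(x$phenotype_mixture),
                            x$phenotype_mixture), collapse = " ")))
  invisible(x)
}
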