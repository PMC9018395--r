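#' Detection parameters for the imaging front end
#'
#' Houses every stringency threshold of the analysis: nuclear segmentation
#' sizes, the cell-region expansion radius, and the two published granule
#' criteria per reporter channel (an expected diameter range and an
#' integrated-intensity threshold), plus the per-cell fluorescence floor
#' below which a cell is considered nonfluorescent.
#'
#' Coordinates are (row, column) with pixel centres at integer positions;
#' all areas are px^2, radii and diameters px, intensities in camera counts.
#'
#' @param nucleus_smooth_sigma Gaussian pre-smoothing of the DAPI channel.
#' @param min_fragment_area Objects below this area are discarded as debris.
#' @param normal_nucleus_min_area Total nuclear area below which a nucleus is
#'   scored as fragmented (apoptotic).
#' @param fragment_group_radius Sub-normal-size objects whose centroids fall
#'   within this radius are merged into one fragmented nucleus.
#' @param cell_expansion_radius Maximum dilation of a nucleus mask when
#'   assigning its cell region; collisions are split by the nearest-nucleus
#'   rule.
#' @param granule_diameter_range Named list per channel (`YFP`, `TexasRed`)
#'   of (min, max) equivalent diameters in px, or a single numeric pair
#'   applied to both.
#' @param granule_intensity_threshold Named vector (or single value) of
#'   minimum integrated (background-free) granule intensity per channel.
#' @param granule_peak_cut Top-hat intensity above which pixels seed granule
#'   support; also the absolute scale for watershed splitting.
#' @param granule_tophat_radius Structuring-element radius of the white
#'   top-hat; structures wider than this are treated as diffuse signal.
#' @param fluorescence_floor Minimum mean background-subtracted per-pixel
#'   reporter intensity for a cell to count as fluorescent (per channel or
#'   single value).
#' @param min_cells_per_well Wells with fewer analysed cells are flagged
#'   invalid in [summarize_wells()].
#' @return A list of class `momp_detection_params`.
#' @export
detection_params <- function(nucleus_smooth_sigma = 1,
                             min_fragment_area = 12,
                             normal_nucleus_min_area = 200,
                             fragment_group_radius = 15,
                             cell_expansion_radius = 20,
                             granule_diameter_range = c(2, 10),
                             granule_intensity_threshold = 8000,
                             granule_peak_cut = 500,
                             granule_tophat_radius = 7,
                             fluorescence_floor = 40,
                             min_cells_per_well = 50L) {
  chans <- c("YFP", "TexasRed")
  per_channel <- function(x, what) {
    if (is.list(x) || !is.null(names(x))) {
      if (!all(chans %in% names(x))) {
        abort(sprintf("`%s` must name channels %s", what,
                      paste(chans, collapse = ", ")))
      }
      x[chans]
    } else {
      stats::setNames(rep(list(x), 2), chans)
    }
  }
  dr <- per_channel(granule_diameter_range, "granule_diameter_range")
  for (ch in chans) {
    if (dr[[ch]][1] >= dr[[ch]][2]) abort("granule diameter range must have min < max.")
  }
  p <- list(nucleus_smooth_sigma = nucleus_smooth_sigma,
            min_fragment_area = min_fragment_area,
            normal_nucleus_min_area = normal_nucleus_min_area,
            fragment_group_radius = fragment_group_radius,
            cell_expansion_radius = cell_expansion_radius,
            granule_diameter_range = dr,
            granule_intensity_threshold =
              unlist(per_channel(granule_intensity_threshold,
                                 "granule_intensity_threshold")),
            granule_peak_cut = unlist(per_channel(granule_peak_cut,
                                                  "granule_peak_cut")),
            granule_tophat_radius = granule_tophat_radius,
            fluorescence_floor = unlist(per_channel(fluorescence_floor,
                                                    "fluorescence_floor")),
            min_cells_per_well = min_cells_per_well)
  if (any(c(p$min_fragment_area, p$normal_nucleus_min_area,
            p$fragment_group_radius, p$cell_expansion_radius) <= 0)) {
    abort("all areas and radii must be positive.")
  }
  structure(p, class = "momp_detection_params")
}

#' Segment nuclei in a DAPI channel image
#'
#' Gaussian smoothing, Otsu thresholding, hole filling, watershed splitting
#' of touching nuclei on the distance transform, removal of sub-debris
#' objects, then single-linkage grouping of sub-normal-size objects (nuclear
#' fragments) within `fragment_group_radius` so that one apoptotic cell
#' yields one nucleus object. A nucleus is `fragmented` when its total area
#' falls below `normal_nucleus_min_area`.
#'
#' @param dapi 2-D intensity matrix (or `momp_field`, from which the DAPI
#'   channel is taken).
#' @param params A [detection_params()].
#' @return A list of class `nucleus_seg`: `nuclei` (tibble: `label`, `y`,
#'   `x`, `area`, `mean_dapi`, `fragment_count`, `fragmented`) and `labels`
#'   (integer matrix; merged fragments share one label). Blank or constant
#'   images yield zero nuclei.
#' @export
segment_nuclei <- function(dapi, params = detection_params()) {
  if (inherits(dapi, "momp_field")) dapi <- dapi$channels$DAPI
  dapi <- as_matrix(dapi)
  if (any(dapi < 0)) abort("DAPI image must be non-negative.")
  if (any(dapi >= 65535)) warn("saturated pixels in DAPI image")
  empty <- tibble(label = integer(), y = double(), x = double(),
                  area = double(), mean_dapi = double(),
                  fragment_count = integer(), fragmented = logical())
  empty_seg <- structure(list(nuclei = empty,
                              labels = matrix(0L, nrow(dapi), ncol(dapi))),
                         class = "nucleus_seg")
  if (diff(range(dapi)) < 1e-9) return(empty_seg)

  sm <- as_matrix(EBImage::gblur(EBImage::Image(dapi / 65535),
                                 params$nucleus_smooth_sigma))
  thr <- EBImage::otsu(EBImage::Image(sm), range = range(sm))
  bw <- sm > thr
  # guard: degenerate threshold that selects almost everything is background
  if (mean(bw) > 0.9) return(empty_seg)
  bw <- as_matrix(EBImage::fillHull(EBImage::Image(bw))) > 0
  dm <- EBImage::distmap(EBImage::Image(bw))
  lab <- as_matrix(EBImage::watershed(dm, tolerance = 1, ext = 1))
  storage.mode(lab) <- "integer"

  feats <- label_features(lab, dapi)
  feats <- feats |> filter(.data$area >= params$min_fragment_area)
  if (nrow(feats) == 0) return(empty_seg)
  # drop discarded labels from the raster
  keep <- feats$label
  lab[!(lab %in% keep)] <- 0L

  groups <- group_fragments(feats, params)
  relab <- stats::setNames(groups$new_label, as.character(groups$label))
  lab_new <- lab
  changed <- groups |> filter(.data$label != .data$new_label)
  for (i in seq_len(nrow(changed))) {
    lab_new[lab == changed$label[i]] <- changed$new_label[i]
  }

  nuclei <- feats |>
    mutate(new_label = relab[as.character(.data$label)]) |>
    group_by(.data$new_label) |>
    summarise(y = sum(.data$y * .data$area) / sum(.data$area),
              x = sum(.data$x * .data$area) / sum(.data$area),
              mean_dapi = sum(.data$mean_dapi * .data$area) / sum(.data$area),
              area = sum(.data$area),
              fragment_count = dplyr::n(), .groups = "drop") |>
    rename(label = "new_label") |>
    mutate(fragmented = .data$area < params$normal_nucleus_min_area) |>
    select("label", "y", "x", "area", "mean_dapi", "fragment_count",
           "fragmented") |>
    arrange(.data$label)

  structure(list(nuclei = nuclei, labels = lab_new), class = "nucleus_seg")
}

# Area, intensity-free centroid and mean intensity per label of a raster.
label_features <- function(lab, intensity = NULL) {
  idx <- which(lab > 0L)
  if (length(idx) == 0) {
    return(tibble(label = integer(), y = double(), x = double(),
                  area = double(), mean_dapi = double()))
  }
  l <- lab[idx]
  ys <- (idx - 1L) %% nrow(lab) + 1L
  xs <- (idx - 1L) %/% nrow(lab) + 1L
  area <- tapply(rep(1, length(l)), l, sum)
  labs <- as.integer(names(area))
  out <- tibble(label = labs,
                y = as.numeric(tapply(ys, l, mean)),
                x = as.numeric(tapply(xs, l, mean)),
                area = as.numeric(area))
  out$mean_dapi <- if (is.null(intensity)) NA_real_
                   else as.numeric(tapply(intensity[idx], l, mean))
  out
}

# Single-linkage union-find over sub-normal-size objects within the grouping
# radius. Normal-size nuclei are never merged.
group_fragments <- function(feats, params) {
  n <- nrow(feats)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  small <- feats$area < params$normal_nucleus_min_area
  idx <- which(small)
  if (length(idx) > 1) {
    for (a in seq_along(idx)[-1]) {
      for (b in seq_len(a - 1)) {
        i <- idx[a]; j <- idx[b]
        d2 <- (feats$y[i] - feats$y[j])^2 + (feats$x[i] - feats$x[j])^2
        if (d2 <= params$fragment_group_radius^2) {
          parent[find(i)] <- find(j)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  tibble(label = feats$label, new_label = feats$label[roots])
}

#' Assign a cell region to every nucleus
#'
#' Expands each nucleus mask by at most `cell_expansion_radius` pixels;
#' where expansions collide, pixels go to the nearest nucleus (geodesic
#' propagation from the nucleus masks). Regions are disjoint by construction
#' and every region contains its nucleus.
#'
#' @param seg A `nucleus_seg` from [segment_nuclei()].
#' @param params A [detection_params()].
#' @return A list of class `cell_regions`: `labels` (integer matrix of cell
#'   ids, 0 = background) and `cells` (tibble: `cell_id`, `area`).
#' @export
assign_cell_regions <- function(seg, params = detection_params()) {
  lab <- seg$labels
  if (nrow(seg$nuclei) == 0) {
    return(structure(list(labels = matrix(0L, nrow(lab), ncol(lab)),
                          cells = tibble(cell_id = integer(), area = double())),
                     class = "cell_regions"))
  }
  r <- params$cell_expansion_radius
  brush <- EBImage::makeBrush(2L * as.integer(r) + 1L, "disc")
  mask <- as_matrix(EBImage::dilate(EBImage::Image(lab > 0), brush)) > 0
  reg <- as_matrix(EBImage::propagate(EBImage::Image(matrix(0, nrow(lab), ncol(lab))),
                                      EBImage::Image(lab), mask = mask))
  storage.mode(reg) <- "integer"
  cells <- label_features(reg) |>
    select(cell_id = "label", "area")
  structure(list(labels = reg, cells = cells), class = "cell_regions")
}

#' Detect suprathreshold granules (puncta) in a reporter channel
#'
#' Open re-implementation of a granularity-style module: a white top-hat at
#' the maximum-diameter scale removes diffuse signal, pixels above
#' `granule_peak_cut` form candidate support, touching puncta are split by
#' an intensity watershed, and candidates are kept only if their equivalent
#' diameter lies within the channel's expected range, their integrated
#' (top-hat) intensity exceeds the channel threshold, and their centroid
#' falls inside a cell region (granules are tagged with that `cell_id`).
#'
#' @param channel_image 2-D intensity matrix or a `momp_field`.
#' @param regions A `cell_regions` from [assign_cell_regions()].
#' @param params A [detection_params()].
#' @param channel `"YFP"` (Venus-BAX) or `"TexasRed"` (OMI-mCherry).
#' @return Tibble: `channel`, `cell_id`, `y`, `x`, `equivalent_diameter`,
#'   `integrated_intensity`, `area`.
#' @export
detect_granules <- function(channel_image, regions, params = detection_params(),
                            channel = c("YFP", "TexasRed")) {
  channel <- match.arg(channel)
  if (inherits(channel_image, "momp_field")) {
    channel_image <- channel_image$channels[[channel]]
  }
  img <- as_matrix(channel_image)
  empty <- tibble(channel = character(), cell_id = integer(), y = double(),
                  x = double(), equivalent_diameter = double(),
                  integrated_intensity = double(), area = double())
  if (diff(range(img)) < 1e-9) return(empty)

  brush <- EBImage::makeBrush(2L * as.integer(params$granule_tophat_radius) + 1L,
                              "disc")
  th <- as_matrix(EBImage::whiteTopHat(EBImage::Image(img / 65535), brush)) * 65535
  cut <- params$granule_peak_cut[[channel]]
  mask <- th > cut
  if (!any(mask)) return(empty)
  lab <- as_matrix(EBImage::watershed(EBImage::Image(th * mask),
                                      tolerance = cut / 2, ext = 1))
  storage.mode(lab) <- "integer"

  idx <- which(lab > 0L)
  l <- lab[idx]
  ys <- (idx - 1L) %% nrow(lab) + 1L
  xs <- (idx - 1L) %/% nrow(lab) + 1L
  wts <- th[idx]
  area <- as.numeric(tapply(rep(1, length(l)), l, sum))
  g <- tibble(label = as.integer(names(tapply(rep(1, length(l)), l, sum))),
              area = area,
              y = as.numeric(tapply(ys * wts, l, sum) / tapply(wts, l, sum)),
              x = as.numeric(tapply(xs * wts, l, sum) / tapply(wts, l, sum)),
              integrated_intensity = as.numeric(tapply(wts, l, sum))) |>
    mutate(equivalent_diameter = 2 * sqrt(.data$area / pi))

  dr <- params$granule_diameter_range[[channel]]
  ithr <- params$granule_intensity_threshold[[channel]]
  g <- g |>
    filter(.data$equivalent_diameter >= dr[1],
           .data$equivalent_diameter <= dr[2],
           .data$integrated_intensity >= ithr)
  if (nrow(g) == 0) return(empty)
  ri <- clamp(round(g$y), 1, nrow(img))
  ci <- clamp(round(g$x), 1, ncol(img))
  g$cell_id <- regions$labels[cbind(ri, ci)]
  g |>
    filter(.data$cell_id > 0L) |>
    mutate(channel = channel) |>
    select("channel", "cell_id", "y", "x", "equivalent_diameter",
           "integrated_intensity", "area")
}

#' @export
print.nucleus_seg <- function(x, ...) {
  cat(sprintf("<nucleus_seg> %d nuclei (%d fragmented)\n", nrow(x$nuclei),
              sum(x$nuclei$fragmented)))
  invisible(x)
}

#' @export
print.cell_regions <- function(x, ...) {
  cat(sprintf("<cell_regions> %d regions covering %d px\n", nrow(x$cells),
              sum(x$cells$area)))
  invisible(x)
}
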