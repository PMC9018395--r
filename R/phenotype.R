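#' Build per-cell feature records from detection results
#'
#' Joins segmented nuclei, cell regions and detected granules into one row
#' per cell: granule counts and total granule intensities per reporter
#' channel, mean background-subtracted per-pixel cell fluorescence per
#' channel (background estimated as the image median), and nuclear
#' fragmentation. These are the quantities the phenotype rule consumes.
#'
#' @param seg A `nucleus_seg` from [segment_nuclei()].
#' @param regions A `cell_regions` from [assign_cell_regions()].
#' @param granules Tibble of granules (both channels row-bound) from
#'   [detect_granules()].
#' @param field A `momp_field` (supplies the reporter channel images and
#'   well/site metadata).
#' @return Tibble with one row per cell: `cell_id`, `well_id`, `site_index`,
#'   `y`, `x`, `nucleus_area`, `fragment_count`, `nucleus_fragmented`,
#'   `bax_granule_count`, `bax_granule_total_intensity`, `omi_granule_count`,
#'   `omi_granule_total_intensity`, `mean_yfp_intensity`,
#'   `mean_txred_intensity`.
#' @export
build_cell_records <- function(seg, regions, granules, field) {
  nuc <- seg$nuclei
  if (nrow(nuc) == 0) {
    return(tibble(cell_id = integer(), well_id = character(),
                  site_index = integer(), y = double(), x = double(),
                  nucleus_area = double(), fragment_count = integer(),
                  nucleus_fragmented = logical(),
                  bax_granule_count = integer(),
                  bax_granule_total_intensity = double(),
                  omi_granule_count = integer(),
                  omi_granule_total_intensity = double(),
                  mean_yfp_intensity = double(),
                  mean_txred_intensity = double()))
  }
  gsum <- function(ch) {
    granules |>
      filter(.data$channel == ch) |>
      group_by(.data$cell_id) |>
      summarise(count = dplyr::n(),
                total = sum(.data$integrated_intensity), .groups = "drop")
  }
  bax <- gsum("YFP"); omi <- gsum("TexasRed")

  mean_above_bg <- function(img) {
    img <- as.numeric(img)
    bg <- stats::median(img)
    v <- tapply(pmax(img[regions$labels > 0] - bg, 0),
                regions$labels[regions$labels > 0], mean)
    stats::setNames(as.numeric(v), names(v))
  }
  yfp_mean <- mean_above_bg(field$channels$YFP)
  txr_mean <- mean_above_bg(field$channels$TexasRed)
  key <- as.character(nuc$label)

  nuc |>
    transmute(cell_id = .data$label, well_id = field$well_id,
              site_index = field$site_index, y = .data$y, x = .data$x,
              nucleus_area = .data$area, fragment_count = .data$fragment_count,
              nucleus_fragmented = .data$fragmented) |>
    left_join(bax |> rename(bax_granule_count = "count",
                            bax_granule_total_intensity = "total"),
              by = "cell_id") |>
    left_join(omi |> rename(omi_granule_count = "count",
                            omi_granule_total_intensity = "total"),
              by = "cell_id") |>
    mutate(bax_granule_count = as.integer(replace_na(.data$bax_granule_count, 0L)),
           omi_granule_count = as.integer(replace_na(.data$omi_granule_count, 0L)),
           bax_granule_total_intensity = replace_na(.data$bax_granule_total_intensity, 0),
           omi_granule_total_intensity = replace_na(.data$omi_granule_total_intensity, 0),
           mean_yfp_intensity = unname(yfp_mean[key]),
           mean_txred_intensity = unname(txr_mean[key])) |>
    mutate(mean_yfp_intensity = replace_na(.data$mean_yfp_intensity, 0),
           mean_txred_intensity = replace_na(.data$mean_txred_intensity, 0))
}

#' Classify cells into the four MOMP phenotype labels
#'
#' Applies the two counting criteria per cell: a cell with suprathreshold
#' granules in both reporter channels is `DOUBLE_POSITIVE` (heterogeneous
#' MOMP); with only Venus-BAX granules, `BAX_POSITIVE` (apoptotic); with
#' only OMI granules, `INTACT`; with no granules at all it is
#' `NONDETERMINED` when its mean fluorescence is below the floor in both
#' reporter channels, and `INTACT` (fluorescent, diffuse) otherwise.
#' The labels are exhaustive and mutually exclusive.
#'
#' @param records Tibble from [build_cell_records()] (granule counts are
#'   already threshold-filtered by [detect_granules()]).
#' @param params A [detection_params()] (supplies `fluorescence_floor`).
#' @return `records` with a `label` column added.
#' @export
classify_cells <- function(records, params = detection_params()) {
  floor_yfp <- params$fluorescence_floor[["YFP"]]
  floor_txr <- params$fluorescence_floor[["TexasRed"]]
  records |>
    mutate(label = case_when(
      .data$bax_granule_count > 0 & .data$omi_granule_count > 0 ~ "DOUBLE_POSITIVE",
      .data$bax_granule_count > 0 ~ "BAX_POSITIVE",
      .data$omi_granule_count > 0 ~ "INTACT",
      .data$mean_yfp_intensity < floor_yfp &
        .data$mean_txred_intensity < floor_txr ~ "NONDETERMINED",
      TRUE ~ "INTACT"))
}

#' Summarise phenotype fractions per well
#'
#' Pools cells across a well's imaging sites (pooled counts, not per-site
#' averages, so sparse sites are weighted by their cell numbers) and reports
#' the fraction of each phenotype label plus the fragmented-nucleus
#' fraction. Fractions over the four labels sum to 1 exactly. Wells with
#' fewer than `min_cells_per_well` analysed cells are flagged invalid and a
#' warning is emitted; downstream scoring skips them.
#'
#' @param records Labelled cell records (from [classify_cells()]), any number
#'   of wells.
#' @param params A [detection_params()].
#' @param wells Optional character vector of wells that must appear in the
#'   output; wells with no cells are returned with `n_cells = 0`,
#'   `valid = FALSE`.
#' @return Tibble: `well_id`, `n_cells`, `frac_bax_positive`, `frac_intact`,
#'   `frac_double_positive`, `frac_nondetermined`, `frac_fragmented`,
#'   `valid`.
#' @export
summarize_wells <- function(records, params = detection_params(), wells = NULL) {
  frac_of <- function(label, labels) mean(labels == label)
  out <- records |>
    group_by(.data$well_id) |>
    summarise(n_cells = dplyr::n(),
              frac_bax_positive = frac_of("BAX_POSITIVE", .data$label),
              frac_intact = frac_of("INTACT", .data$label),
              frac_double_positive = frac_of("DOUBLE_POSITIVE", .data$label),
              frac_nondetermined = frac_of("NONDETERMINED", .data$label),
              frac_fragmented = mean(.data$nucleus_fragmented),
              .groups = "drop")
  if (!is.null(wells)) {
    missing <- setdiff(wells, out$well_id)
    if (length(missing) > 0) {
      out <- bind_rows(out, tibble(well_id = missing, n_cells = 0L,
                                   frac_bax_positive = NA_real_,
                                   frac_intact = NA_real_,
                                   frac_double_positive = NA_real_,
                                   frac_nondetermined = NA_real_,
                                   frac_fragmented = NA_real_))
    }
  }
  out <- out |>
    mutate(valid = .data$n_cells >= params$min_cells_per_well) |>
    arrange(.data$well_id)
  n_bad <- sum(!out$valid)
  if (n_bad > 0) {
    warn(sprintf("%d well(s) below the %d-cell minimum flagged invalid",
                 n_bad, params$min_cells_per_well))
  }
  out
}

#' Run the full imaging front end on one field
#'
#' Convenience wrapper: nuclear segmentation, cell-region assignment,
#' granule detection in both reporter channels, and per-cell classification.
#'
#' @param field A `momp_field`.
#' @param params A [detection_params()].
#' @return A list: `records` (labelled cell tibble), `granules`, `seg`,
#'   `regions`.
#' @export
analyze_field <- function(field, params = detection_params()) {
  seg <- segment_nuclei(field$channels$DAPI, params)
  regions <- assign_cell_regions(seg, params)
  granules <- bind_rows(
    detect_granules(field$channels$YFP, regions, params, "YFP"),
    detect_granules(field$channels$TexasRed, regions, params, "TexasRed"))
  records <- build_cell_records(seg, regions, granules, field) |>
    classify_cells(params)
  list(records = records, granules = granules, seg = seg, regions = regions)
}
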