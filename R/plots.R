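#' @importFrom ggplot2 ggplot aes geom_raster geom_col geom_point geom_errorbar
#'   geom_line geom_hline geom_vline facet_wrap labs theme_minimal autoplot
#'   scale_fill_viridis_c scale_fill_brewer position_dodge coord_equal
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

field_to_long <- function(field, downsample = 2L) {
  map_dfr(names(field$channels), function(ch) {
    m <- field$channels[[ch]]
    ri <- seq(1, nrow(m), by = downsample)
    ci <- seq(1, ncol(m), by = downsample)
    tibble(channel = ch,
           y = rep(ri, times = length(ci)),
           x = rep(ci, each = length(ri)),
           intensity = as.vector(m[ri, ci]))
  })
}

#' Plot a simulated or loaded field image
#'
#' Raster view of the three channels, faceted.
#'
#' @param object A `momp_field`.
#' @param downsample Keep every n-th pixel (display only).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.momp_field <- function(object, downsample = 2L, ...) {
  field_to_long(object, downsample) |>
    ggplot(aes(x = .data$x, y = .data$y, fill = .data$intensity)) +
    geom_raster() +
    facet_wrap(~channel) +
    scale_fill_viridis_c() +
    coord_equal() +
    labs(title = sprintf("well %s, site %d", object$well_id, object$site_index),
         x = NULL, y = NULL) +
    theme_minimal()
}

#' Plot a synthetic colony well
#'
#' @param object A `momp_colony`.
#' @param downsample Keep every n-th pixel.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.momp_colony <- function(object, downsample = 2L, ...) {
  m <- object$image
  ri <- seq(1, nrow(m), by = downsample)
  ci <- seq(1, ncol(m), by = downsample)
  tibble(y = rep(ri, times = length(ci)), x = rep(ci, each = length(ri)),
         intensity = as.vector(m[ri, ci])) |>
    ggplot(aes(x = .data$x, y = .data$y, fill = .data$intensity)) +
    geom_raster() +
    scale_fill_viridis_c(option = "magma") +
    coord_equal() +
    labs(title = sprintf("colony well %s: realized %.1f%%", object$well_id,
                         100 * object$realized_fraction),
         x = NULL, y = NULL) +
    theme_minimal()
}

#' Stacked phenotype fractions per well
#'
#' Mirrors the usual presentation of per-well phenotype quantification:
#' one bar per well, stacked by label.
#'
#' @param summaries Well-summary tibble from [summarize_wells()].
#' @return A ggplot object.
#' @export
plot_well_phenotypes <- function(summaries) {
  summaries <- normalize_summary_keys(summaries)
  if (!("well_id" %in% names(summaries))) {
    summaries$well_id <- if ("plate" %in% names(summaries)) {
      paste(summaries$plate, summaries$well, sep = ":")
    } else summaries$well
  }
  summaries |>
    filter(.data$valid) |>
    pivot_longer(c("frac_bax_positive", "frac_intact", "frac_double_positive",
                   "frac_nondetermined"),
                 names_to = "phenotype", values_to = "fraction") |>
    mutate(phenotype = factor(.data$phenotype,
                              levels = c("frac_bax_positive", "frac_intact",
                                         "frac_double_positive",
                                         "frac_nondetermined"),
                              labels = c("BAX positive", "intact",
                                         "BAX/OMI double positive",
                                         "nondetermined"))) |>
    ggplot(aes(x = .data$well_id, y = .data$fraction, fill = .data$phenotype)) +
    geom_col() +
    scale_fill_brewer(palette = "Set2") +
    labs(x = "well", y = "fraction of cells", fill = NULL) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}

#' Rank-sorted score distribution with the hit tail highlighted
#'
#' The classic sorted-score screen plot: genes ranked by the category
#' statistic with mean +/- SEM, and a vertical cut at the calling tail.
#'
#' @param scores Gene-score tibble from [score_genes()].
#' @param category Hit category (`"I"`, `"II"`, `"III"`).
#' @param tail_fraction Tail used for calling.
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(scores, category = "III",
                                    tail_fraction = 0.10) {
  stat <- switch(category, I = , II = "fold_bax_positive",
                 III = "pct_double_positive")
  sem <- switch(category, I = , II = "sem_fold_bax_positive",
                III = "sem_pct_double_positive")
  descending <- category != "II"
  df <- scores |>
    mutate(score = .data[[stat]], sem = .data[[sem]]) |>
    arrange(if (descending) dplyr::desc(.data$score) else .data$score,
            .data$gene) |>
    mutate(rank = dplyr::row_number())
  cut <- floor(tail_fraction * nrow(df))
  ggplot(df, aes(x = .data$rank, y = .data$score)) +
    geom_errorbar(aes(ymin = .data$score - .data$sem,
                      ymax = .data$score + .data$sem),
                  color = "grey70", width = 0) +
    geom_point(size = 0.6) +
    geom_vline(xintercept = cut + 0.5, linetype = "dashed", color = "red") +
    labs(x = "gene rank", y = switch(category,
                                     I = "fold-change %BAX-positive vs control",
                                     II = "fold-change %BAX-positive vs control",
                                     III = "% BAX/OMI double-positive cells"),
         title = sprintf("category %s, top %.0f%% tail: %d hits", category,
                         100 * tail_fraction, cut)) +
    theme_minimal()
}

#' Survival bar plot by genotype and dose
#'
#' @param records Survival tibble (e.g. from [normalize_survival()]).
#' @param dose_col Name of the dose column.
#' @return A ggplot object.
#' @export
plot_survival <- function(records, dose_col = "dose_uM") {
  records |>
    group_by(.data$genotype, dose = factor(.data[[dose_col]])) |>
    summarise(mean_survival = mean(.data$survival),
              sd_survival = stats::sd(.data$survival), .groups = "drop") |>
    ggplot(aes(x = .data$dose, y = .data$mean_survival, fill = .data$genotype)) +
    geom_col(position = position_dodge(width = 0.9)) +
    geom_errorbar(aes(ymin = .data$mean_survival - .data$sd_survival,
                      ymax = .data$mean_survival + .data$sd_survival),
                  position = position_dodge(width = 0.9), width = 0.2) +
    labs(x = "dose (µM)", y = "survival (% of control)", fill = NULL) +
    theme_minimal()
}
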