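#' Z-prime factor for plate quality control
#'
#' `Z' = 1 - 3 (sd_pos + sd_neg) / |mean_pos - mean_neg|` with sample
#' standard deviations, computed from positive-control (e.g. etoposide
#' treated) and negative-control (untreated) well statistics. Values near 1
#' indicate a wide, reliable assay window; Z' is undefined when the control
#' means coincide.
#'
#' @param positive_values,negative_values Numeric vectors of well statistics,
#'   each of length >= 2.
#' @return The Z-prime factor (a single number, always <= 1).
#' @export
compute_zprime <- function(positive_values, negative_values) {
  if (length(positive_values) < 2 || length(negative_values) < 2) {
    abort("both control groups need at least 2 values.")
  }
  mu_p <- mean(positive_values); mu_n <- mean(negative_values)
  if (mu_p == mu_n) abort("Z' undefined: control means are equal.")
  1 - 3 * (stats::sd(positive_values) + stats::sd(negative_values)) /
    abs(mu_p - mu_n)
}

#' Aggregate well summaries into per-gene screen scores
#'
#' For every gene, over its replicate plates: the category I/II statistic is
#' the mean fold-change of the well's %BAX-positive relative to the mean of
#' the same plate's nontargeting negative-control wells; the category III
#' statistic is the mean %double-positive across replicates. SEM = sd /
#' sqrt(n) over replicates (0 when a single replicate remains). Wells
#' flagged invalid are skipped with `n_replicates` decremented; genes with
#' no valid well are dropped with a warning.
#'
#' @param summaries Well-summary tibble (from [summarize_wells()] or
#'   [simulate_screen_scores()]); must carry `plate` and `well` columns (a
#'   `well_id` column of the form `"plate:well"` is split automatically).
#' @param plate_map Plate-map tibble from [generate_plate_layout()] (or the
#'   `plate_map` of a `screen_sim`).
#' @return Tibble: `gene`, `n_replicates`, `fold_bax_positive`,
#'   `sem_fold_bax_positive`, `pct_double_positive`,
#'   `sem_pct_double_positive`.
#' @export
score_genes <- function(summaries, plate_map) {
  summaries <- normalize_summary_keys(summaries)
  joined <- plate_map |>
    select("plate", "well", "role", "gene") |>
    inner_join(summaries, by = c("plate", "well"))

  neg <- joined |>
    filter(.data$role == "NEG_CONTROL", .data$valid) |>
    group_by(.data$plate) |>
    summarise(neg_mean_bax = mean(.data$frac_bax_positive),
              n_neg = dplyr::n(), .groups = "drop")
  short <- neg |> filter(.data$n_neg < 2)
  if (nrow(short) > 0 || nrow(neg) < length(unique(joined$plate))) {
    abort("every plate needs >= 2 valid negative-control wells.")
  }
  if (any(neg$neg_mean_bax <= 0)) {
    abort("negative-control mean %BAX-positive is zero on some plate; fold-change undefined.")
  }

  sample_wells <- joined |>
    filter(.data$role == "SAMPLE") |>
    inner_join(neg, by = "plate")
  n_invalid <- sum(!sample_wells$valid)
  sample_wells <- sample_wells |> filter(.data$valid)

  sem <- function(x) if (length(x) < 2) 0 else stats::sd(x) / sqrt(length(x))
  scores <- sample_wells |>
    mutate(fold = .data$frac_bax_positive / .data$neg_mean_bax,
           pct_dp = 100 * .data$frac_double_positive) |>
    group_by(.data$gene) |>
    summarise(n_replicates = dplyr::n(),
              fold_bax_positive = mean(.data$fold),
              sem_fold_bax_positive = sem(.data$fold),
              pct_double_positive = mean(.data$pct_dp),
              sem_pct_double_positive = sem(.data$pct_dp),
              .groups = "drop")
  lost <- setdiff(stats::na.omit(unique(joined$gene[joined$role == "SAMPLE"])),
                  scores$gene)
  if (length(lost) > 0) {
    warn(sprintf("%d gene(s) had no valid replicate well and were excluded",
                 length(lost)))
  }
  arrange(scores, .data$gene)
}

normalize_summary_keys <- function(summaries) {
  if (!("plate" %in% names(summaries)) && "well_id" %in% names(summaries)) {
    summaries <- summaries |>
      tidyr::separate_wider_delim("well_id", delim = ":",
                                  names = c("plate", "well"))
  }
  summaries
}

#' Call primary screen hits from the tail of the score distribution
#'
#' Genes are ranked by the category statistic -- category I: fold-change of
#' %BAX-positive, descending; category II: the same fold-change, ascending;
#' category III: %double-positive, descending -- and the top
#' `floor(tail_fraction * n)` genes are returned. Ties at the cutoff are
#' broken by lexicographic gene identifier so calls are deterministic; a
#' `tie_degenerate` flag marks hits whose score equals that of the first
#' excluded gene. `method = "range"` instead cuts at 10% of the numeric
#' score range from the extreme (the rank-tail reading is the default).
#'
#' @param scores Gene-score tibble from [score_genes()].
#' @param category `"I"`, `"II"` or `"III"`.
#' @param tail_fraction Fraction of genes called, in (0, 0.5).
#' @param method `"rank"` (top/bottom decile by rank) or `"range"` (cut in
#'   the numeric score range).
#' @return Tibble: `gene`, `category`, `score`, `rank`, `tail_fraction`,
#'   `tie_degenerate`.
#' @export
call_primary_hits <- function(scores, category = c("III", "I", "II"),
                              tail_fraction = 0.10,
                              method = c("rank", "range")) {
  category <- match.arg(category)
  method <- match.arg(method)
  if (!(tail_fraction > 0 && tail_fraction < 0.5)) {
    abort("`tail_fraction` must lie in (0, 0.5).")
  }
  if (nrow(scores) < 1) abort("need at least one scored gene.")
  stat <- switch(category, I = scores$fold_bax_positive,
                 II = scores$fold_bax_positive,
                 III = scores$pct_double_positive)
  descending <- category != "II"
  key <- if (descending) -stat else stat
  ord <- order(key, scores$gene)
  ranked <- tibble(gene = scores$gene[ord], category = category,
                   score = stat[ord], rank = seq_along(ord),
                   tail_fraction = tail_fraction)
  n_hits <- if (method == "rank") {
    floor(tail_fraction * nrow(ranked))
  } else {
    rng <- range(ranked$score)
    cutv <- if (descending) rng[2] - tail_fraction * diff(rng)
            else rng[1] + tail_fraction * diff(rng)
    if (descending) sum(ranked$score >= cutv) else sum(ranked$score <= cutv)
  }
  hits <- ranked[seq_len(n_hits), , drop = FALSE]
  boundary <- if (n_hits > 0 && n_hits < nrow(ranked)) ranked$score[n_hits + 1] else NA_real_
  hits$tie_degenerate <- !is.na(boundary) & hits$score == boundary
  hits
}

#' Confirm primary hits in a secondary single-siRNA screen
#'
#' Each gene's four individual siRNAs are scored by the same rule as the
#' primary screen; the gene is confirmed when at least `min_concordant` of
#' them reproduce the phenotype. Missing siRNAs (fewer than 4 rows for a
#' gene) count as non-concordant.
#'
#' @param sirna_scores Tibble with columns `gene`, `sirna_id` and either a
#'   logical `hit` column or a numeric `score` column.
#' @param threshold Numeric score cutoff applied when `hit` is absent.
#' @param direction `"above"` (score >= threshold is a hit) or `"below"`.
#' @param min_concordant Minimum concordant siRNAs for confirmation.
#' @param n_sirnas The designed number of siRNAs per gene (denominator for
#'   missing-siRNA accounting).
#' @return Tibble: `gene`, `n_tested`, `n_concordant`, `confirmed`.
#' @export
confirm_secondary <- function(sirna_scores, threshold = NULL,
                              direction = c("above", "below"),
                              min_concordant = 3L, n_sirnas = 4L) {
  direction <- match.arg(direction)
  if (!("hit" %in% names(sirna_scores))) {
    if (is.null(threshold)) {
      abort("supply a `hit` column or a `threshold` for the score rule.")
    }
    sirna_scores <- sirna_scores |>
      mutate(hit = if (direction == "above") .data$score >= threshold
                   else .data$score <= threshold)
  }
  extra <- sirna_scores |> count(.data$gene) |> filter(.data$n > n_sirnas)
  if (nrow(extra) > 0) {
    abort(sprintf("gene(s) with more than %d siRNAs: %s", n_sirnas,
                  paste(utils::head(extra$gene, 3), collapse = ", ")))
  }
  sirna_scores |>
    group_by(.data$gene) |>
    summarise(n_tested = dplyr::n(),
              n_concordant = sum(.data$hit, na.rm = TRUE), .groups = "drop") |>
    mutate(confirmed = .data$n_concordant >= min_concordant) |>
    arrange(.data$gene)
}
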