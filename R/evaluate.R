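#' Match detected objects to ground truth by centroid proximity
#'
#' Greedy nearest-pair matching: the closest (truth, detection) pair within
#' `tolerance` is matched first, both are removed, and so on. Used to score
#' detection against the generator's ground truth.
#'
#' @param truth,detected Data frames with `y` and `x` columns.
#' @param tolerance Maximum centroid distance (px) for a match.
#' @return A list: `n_matched`, `truth_idx`, `detected_idx` (parallel integer
#'   vectors of matched rows).
#' @export
match_points <- function(truth, detected, tolerance = 4) {
  nt <- nrow(truth); nd <- nrow(detected)
  if (nt == 0 || nd == 0) {
    return(list(n_matched = 0L, truth_idx = integer(0), detected_idx = integer(0)))
  }
  d <- outer(truth$y, detected$y, "-")^2 + outer(truth$x, detected$x, "-")^2
  d[d > tolerance^2] <- Inf
  ti <- integer(0); di <- integer(0)
  repeat {
    m <- which.min(d)
    if (length(m) == 0 || !is.finite(d[m])) break
    i <- (m - 1L) %% nt + 1L; j <- (m - 1L) %/% nt + 1L
    ti <- c(ti, i); di <- c(di, j)
    d[i, ] <- Inf; d[, j] <- Inf
  }
  list(n_matched = length(ti), truth_idx = ti, detected_idx = di)
}

#' Granule-detection precision, recall and F1 against ground truth
#'
#' Matches detected granules to true puncta per channel within `tolerance`
#' pixels and reports the usual detection scores.
#'
#' @param truth_puncta Ground-truth puncta tibble (from a `momp_truth`).
#' @param granules Detected granules (from [detect_granules()]).
#' @param tolerance Match radius, px.
#' @return One-row tibble: `n_truth`, `n_detected`, `n_matched`, `precision`,
#'   `recall`, `f1`.
#' @export
granule_f1 <- function(truth_puncta, granules, tolerance = 4) {
  n_matched <- 0L
  for (ch in unique(c(truth_puncta$channel, granules$channel))) {
    m <- match_points(truth_puncta[truth_puncta$channel == ch, ],
                      granules[granules$channel == ch, ], tolerance)
    n_matched <- n_matched + m$n_matched
  }
  nt <- nrow(truth_puncta); nd <- nrow(granules)
  precision <- if (nd > 0) n_matched / nd else NA_real_
  recall <- if (nt > 0) n_matched / nt else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  tibble(n_truth = nt, n_detected = nd, n_matched = n_matched,
         precision = precision, recall = recall, f1 = f1)
}

#' Per-cell phenotype agreement with ground truth
#'
#' Matches analysed cells to ground-truth cells by nucleus centroid and
#' reports the fraction of matched cells whose assigned label equals the
#' true phenotype.
#'
#' @param truth_cells Ground-truth cell tibble (from a `momp_truth`).
#' @param records Labelled cell records (from [classify_cells()]).
#' @param tolerance Match radius, px.
#' @return One-row tibble: `n_truth`, `n_detected`, `n_matched`, `n_correct`,
#'   `accuracy`. Accuracy is strict: unmatched ground-truth cells count as
#'   disagreements (`accuracy = n_correct / n_truth`).
#' @export
phenotype_agreement <- function(truth_cells, records, tolerance = 6) {
  m <- match_points(truth_cells, records, tolerance)
  correct <- sum(truth_cells$phenotype[m$truth_idx] ==
                   records$label[m$detected_idx])
  tibble(n_truth = nrow(truth_cells), n_detected = nrow(records),
         n_matched = m$n_matched, n_correct = correct,
         accuracy = if (nrow(truth_cells) > 0) correct / nrow(truth_cells)
                    else NA_real_)
}
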