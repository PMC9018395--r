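#' Generate a screen plate layout
#'
#' Arrays genes (one well per gene per replicate plate, or one well per
#' individual siRNA for secondary-screen maps) across as many plates as
#' needed, reserving the outer `edge_margin` rows and columns of every plate
#' as untransfected `EMPTY_EDGE` wells and placing control wells on every
#' plate: nontargeting negative controls, a BAX-pool positive control
#' (inhibits BAX puncta formation), cytotoxic transfection-marker wells and
#' untreated (no etoposide) wells.
#'
#' @param gene_list Character vector of gene identifiers (may be empty, in
#'   which case the layout carries only control and edge wells).
#' @param config A [sim_config()] supplying `plate_format` and `edge_margin`.
#' @param replicates Number of replicate plates per master plate.
#' @param sirnas_per_gene 1 for pooled primary-screen maps; 4 for secondary
#'   maps, in which the four siRNAs of a gene are arrayed in different plate
#'   chunks so they land on different plates whenever capacity allows.
#' @param controls Named integer vector giving the number of wells per plate
#'   for each control role.
#'
#' @return A tibble with one row per well and columns `plate`, `master_plate`,
#'   `replicate`, `well`, `row`, `column`, `role`, `gene`, `sirna_id`,
#'   `treatment`. Roles are `SAMPLE`, `NEG_CONTROL`, `POS_CONTROL`,
#'   `TOX_MARKER`, `UNTREATED`, `EMPTY_EDGE`; treatment is `ETOPOSIDE_QVD`
#'   except for untreated and edge wells (`NONE`).
#' @export
generate_plate_layout <- function(gene_list, config = sim_config(),
                                  replicates = 3L, sirnas_per_gene = 1L,
                                  controls = c(NEG_CONTROL = 2L, POS_CONTROL = 2L,
                                               TOX_MARKER = 2L, UNTREATED = 2L)) {
  nr <- config$plate_format[1]; nc <- config$plate_format[2]
  m <- config$edge_margin
  usable_rows <- seq(m + 1L, nr - m); usable_cols <- seq(m + 1L, nc - m)
  n_usable <- length(usable_rows) * length(usable_cols)
  n_ctrl <- sum(controls)
  capacity <- n_usable - n_ctrl
  if (capacity <= 0) {
    abort(sprintf("no sample capacity: %d usable wells but %d control wells per plate",
                  n_usable, n_ctrl))
  }
  slots <- length(gene_list) * sirnas_per_gene
  n_plates <- max(1L, ceiling(slots / capacity))
  if (slots > n_plates * capacity) {
    abort(sprintf("capacity exceeded: %d sample wells required, %d available on %d plates",
                  slots, n_plates * capacity, n_plates))
  }

  # usable positions in row-major order; controls take the first n_ctrl slots
  pos <- tidyr::expand_grid(row = usable_rows, column = usable_cols)
  roles <- rep(names(controls), controls)

  # siRNA-major ordering: all first siRNAs, then all second, ... so that a
  # gene's four siRNAs are separated across plates when genes >= capacity
  assign_tbl <- tidyr::expand_grid(sirna = seq_len(sirnas_per_gene),
                                   gene = gene_list)
  one_plate <- function(p) {
    lo <- (p - 1L) * capacity + 1L
    hi <- min(slots, p * capacity)
    smp <- if (slots > 0 && lo <= hi) assign_tbl[lo:hi, ] else assign_tbl[0, ]
    n_smp <- nrow(smp)
    filled <- pos[seq_len(n_ctrl + n_smp), ]
    filled$role <- c(roles, rep("SAMPLE", n_smp))
    filled$gene <- c(rep(NA_character_, n_ctrl), smp$gene)
    filled$sirna_id <- c(
      sprintf("CTRL_%s_%d", roles, stats::ave(seq_len(n_ctrl), roles, FUN = seq_along)),
      if (sirnas_per_gene == 1L && n_smp > 0) paste0(smp$gene, "_pool")
      else if (n_smp > 0) sprintf("%s_si%d", smp$gene, smp$sirna) else character(0))
    # unused non-edge wells stay empty medium-only wells at the plate end
    rest <- pos[-seq_len(n_ctrl + n_smp), , drop = FALSE]
    if (nrow(rest) > 0) {
      rest$role <- "EMPTY_EDGE"; rest$gene <- NA_character_
      rest$sirna_id <- NA_character_
      filled <- bind_rows(filled, rest)
    }
    edge <- tidyr::expand_grid(row = seq_len(nr), column = seq_len(nc)) |>
      anti_join(pos, by = c("row", "column")) |>
      mutate(role = "EMPTY_EDGE", gene = NA_character_, sirna_id = NA_character_)
    bind_rows(filled, edge) |> mutate(master_plate = p)
  }
  layout <- map_dfr(seq_len(n_plates), one_plate)

  out <- tidyr::expand_grid(master_plate = seq_len(n_plates),
                            replicate = seq_len(replicates)) |>
    inner_join(layout, by = "master_plate", relationship = "many-to-many") |>
    mutate(plate = sprintf("P%02d_R%d", .data$master_plate, .data$replicate),
           well = sprintf("%s%02d", LETTERS[.data$row], .data$column),
           treatment = if_else(.data$role %in% c("UNTREATED", "EMPTY_EDGE"),
                               "NONE", "ETOPOSIDE_QVD")) |>
    select("plate", "master_plate", "replicate", "well", "row", "column",
           "role", "gene", "sirna_id", "treatment") |>
    arrange(.data$plate, .data$row, .data$column)

  dup <- out |>
    filter(.data$role == "SAMPLE") |>
    count(.data$plate, .data$gene) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    warn(sprintf("%d gene(s) appear more than once on the same plate", nrow(dup)))
  }
  out
}

#' Count usable (non-edge) wells per plate
#'
#' @inheritParams generate_plate_layout
#' @return Integer: wells inside the edge-exclusion band.
#' @export
usable_wells <- function(config = sim_config()) {
  prod(pmax(config$plate_format - 2L * config$edge_margin, 0L))
}

#' Simulate an imageless screen score table
#'
#' Generates per-gene, per-replicate phenotype percentages around control
#' baselines for testing the screen statistics without rendering images.
#' Spiked genes have their baseline multiplied by a per-category effect.
#' Noise is multiplicative (`noise_cv`, lognormal-free plain Gaussian CV)
#' plus additive (`noise_sd`, percentage-point units); both default to 0, in
#' which case every unspiked gene's score equals the control baseline
#' exactly.
#'
#' @param n_genes Number of genes (>= 1).
#' @param spiked_effects Either `NULL`, a named numeric vector of category-III
#'   multipliers (names are genes), or a tibble with columns `gene`,
#'   `category` (`"I"`, `"II"` or `"III"`) and `multiplier`. Category I/II
#'   effects multiply the %BAX-positive baseline; category III effects the
#'   %double-positive baseline.
#' @param replicates Replicate plates.
#' @param noise_sd Additive score noise SD, percentage points (>= 0).
#' @param noise_cv Multiplicative coefficient of variation (>= 0).
#' @param baseline Named vector: control `pct_bax_positive` and
#'   `pct_double_positive`, in percent.
#' @param n_neg_controls Negative-control wells per replicate plate.
#' @param seed Integer seed.
#'
#' @return A list of class `screen_sim`: `summaries` (well-summary tibble
#'   compatible with [score_genes()]), `plate_map` (matching plate-map
#'   tibble), `spikes` (ground-truth spike table) and `baseline`.
#' @export
simulate_screen_scores <- function(n_genes, spiked_effects = NULL,
                                   replicates = 3L, noise_sd = 0,
                                   noise_cv = 0,
                                   baseline = c(pct_bax_positive = 25,
                                                pct_double_positive = 3),
                                   n_neg_controls = 4L, seed = 1L) {
  if (n_genes < 1) abort("`n_genes` must be >= 1.")
  if (replicates < 1) abort("`replicates` must be >= 1.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (noise_cv < 0) abort("`noise_cv` must be >= 0.")
  spikes <- normalize_spikes(spiked_effects)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  bad <- setdiff(spikes$gene, genes)
  if (length(bad) > 0) {
    abort(sprintf("spiked genes not in the simulated gene set: %s",
                  paste(utils::head(bad, 3), collapse = ", ")))
  }

  mult_bax <- stats::setNames(rep(1, n_genes), genes)
  mult_dp <- stats::setNames(rep(1, n_genes), genes)
  for (i in seq_len(nrow(spikes))) {
    if (spikes$category[i] %in% c("I", "II")) {
      mult_bax[spikes$gene[i]] <- spikes$multiplier[i]
    } else {
      mult_dp[spikes$gene[i]] <- spikes$multiplier[i]
    }
  }

  noisy <- function(mu, n) {
    clamp(mu * (1 + stats::rnorm(n, 0, noise_cv)) + stats::rnorm(n, 0, noise_sd),
          0, 100)
  }
  with_seed(seed, {
    rows <- map_dfr(seq_len(replicates), function(r) {
      plate <- sprintf("P01_R%d", r)
      gene_rows <- tibble(
        plate = plate, well = sprintf("S%04d", seq_len(n_genes)),
        role = "SAMPLE", gene = genes,
        pct_bax_positive = noisy(baseline[["pct_bax_positive"]] * mult_bax, n_genes),
        pct_double_positive = noisy(baseline[["pct_double_positive"]] * mult_dp, n_genes))
      ctrl_rows <- tibble(
        plate = plate, well = sprintf("N%02d", seq_len(n_neg_controls)),
        role = "NEG_CONTROL", gene = NA_character_,
        pct_bax_positive = noisy(rep(baseline[["pct_bax_positive"]], n_neg_controls),
                                 n_neg_controls),
        pct_double_positive = noisy(rep(baseline[["pct_double_positive"]], n_neg_controls),
                                    n_neg_controls))
      bind_rows(gene_rows, ctrl_rows)
    })
    frac_nd <- 0.02
    summaries <- rows |>
      mutate(n_cells = 500L,
             frac_bax_positive = .data$pct_bax_positive / 100,
             frac_double_positive = .data$pct_double_positive / 100,
             frac_nondetermined = frac_nd,
             frac_intact = pmax(0, 1 - .data$frac_bax_positive -
                                  .data$frac_double_positive - frac_nd),
             frac_fragmented = .data$frac_bax_positive, valid = TRUE) |>
      select("plate", "well", "n_cells", "frac_bax_positive", "frac_intact",
             "frac_double_positive", "frac_nondetermined", "frac_fragmented",
             "valid")
    plate_map <- rows |>
      mutate(sirna_id = if_else(is.na(.data$gene), NA_character_,
                                paste0(.data$gene, "_pool")),
             treatment = "ETOPOSIDE_QVD") |>
      select("plate", "well", "role", "gene", "sirna_id", "treatment")
    structure(list(summaries = summaries, plate_map = plate_map,
                   spikes = spikes, baseline = baseline),
              class = "screen_sim")
  })
}

normalize_spikes <- function(spiked_effects) {
  if (is.null(spiked_effects)) {
    return(tibble(gene = character(), category = character(),
                  multiplier = double()))
  }
  if (is.numeric(spiked_effects) && !is.null(names(spiked_effects))) {
    return(tibble(gene = names(spiked_effects), category = "III",
                  multiplier = unname(spiked_effects)))
  }
  spiked_effects <- as_tibble(spiked_effects)
  stopifnot(all(c("gene", "category", "multiplier") %in% names(spiked_effects)))
  spiked_effects
}

#' @export
print.screen_sim <- function(x, ...) {
  cat(sprintf("<screen_sim> %d wells x %d plates, %d spiked gene(s)\n",
              nrow(x$summaries) / length(unique(x$summaries$plate)),
              length(unique(x$summaries$plate)), nrow(x$spikes)))
  invisible(x)
}
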