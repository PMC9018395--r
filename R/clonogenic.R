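#' Measure colony-covered area in a stained well image
#'
#' Quantifies the fraction of the well disk occupied by crystal-violet
#' stained colonies. The image is inverted (stain becomes bright),
#' restricted to the well disk, and thresholded by Otsu's rule. Because only
#' the total area matters, merged colonies need no splitting. Wells whose
#' intensity spread inside the disk is below `min_contrast` are treated as
#' homogeneous (fully blank or fully confluent, decided by comparing the
#' median inverted intensity to `homogeneous_stain_cut`), since a two-class
#' threshold is undefined without both phases present.
#'
#' @param image A `momp_colony` object, an integer/numeric matrix, or a path
#'   to a single-channel TIFF/PNG file.
#' @param well_center,well_radius Well-disk geometry in pixels; default is a
#'   centred disk of radius 0.45 x the smaller image dimension (the geometry
#'   written by [render_colony_well()]); a `momp_colony` input supplies its
#'   own.
#' @param min_contrast Minimum 1st-to-99th percentile intensity spread
#'   (counts) required to attempt Otsu thresholding.
#' @param homogeneous_stain_cut Inverted-intensity level above which a
#'   homogeneous well is scored as 100% covered.
#' @param well_id Label used when `image` is not a `momp_colony`.
#' @return A one-row tibble: `well_id`, `covered_area` (percent of the well
#'   disk), `threshold` (inverted-intensity units; `NA` for homogeneous
#'   wells), `n_disk_px`.
#' @export
measure_colony_area <- function(image, well_center = NULL, well_radius = NULL,
                                min_contrast = 8000,
                                homogeneous_stain_cut = 25000,
                                well_id = "well") {
  if (inherits(image, "momp_colony")) {
    well_center <- well_center %||% image$well_center
    well_radius <- well_radius %||% image$well_radius
    well_id <- image$well_id
    image <- image$image
  } else if (is.character(image)) {
    image <- read_grayscale_image(image)
  }
  img <- as_matrix(image)
  h <- nrow(img); w <- ncol(img)
  well_center <- well_center %||% c((h + 1) / 2, (w + 1) / 2)
  well_radius <- well_radius %||% (0.45 * min(h, w))
  if (well_radius <= 0 || any(well_center < 1) ||
      well_center[1] > h || well_center[2] > w) {
    abort("well disk not locatable: invalid `well_center`/`well_radius`")
  }
  yy <- matrix(seq_len(h), h, w); xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  in_well <- (yy - well_center[1])^2 + (xx - well_center[2])^2 <= well_radius^2

  inv <- max(img) - img[in_well]  # stain is dark: invert so stain is bright
  spread <- diff(stats::quantile(inv, c(0.01, 0.99), names = FALSE))
  if (spread < min_contrast) {
    covered <- if (stats::median(inv) > homogeneous_stain_cut) 100 else 0
    thr <- NA_real_
  } else {
    thr <- otsu_threshold(inv)
    covered <- 100 * mean(inv > thr)
  }
  tibble(well_id = well_id, covered_area = covered, threshold = thr,
         n_disk_px = sum(in_well))
}

# Otsu threshold on a numeric vector (256-bin histogram over its own range).
# Affine changes of the input move the threshold by the same affine map.
otsu_threshold <- function(v, n_bins = 256L) {
  r <- range(v)
  b <- seq(r[1], r[2], length.out = n_bins + 1L)
  hcounts <- tabulate(findInterval(v, b, rightmost.closed = TRUE), n_bins)
  p <- hcounts / sum(hcounts)
  mids <- (b[-1] + b[-length(b)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sb2 <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb2[!is.finite(sb2)] <- -Inf
  mids[which.max(sb2)]
}

read_grayscale_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                tif = , tiff = tiff::readTIFF(path, as.is = TRUE),
                png = {
                  m <- png::readPNG(path)
                  if (length(dim(m)) == 3) m <- m[, , 1]
                  round(m * 65535)
                },
                abort(sprintf("unsupported image format: .%s", ext)))
  if (length(dim(img)) == 3) img <- img[, , 1]
  as.matrix(img)
}

#' Clonogenic survival relative to the untreated growth control
#'
#' Survival is the treated colony-covered area as a percentage of the
#' matched untreated control (sorted non-caspase-engaged cells, defined as
#' 100% growth). Values above 100 are permitted and returned as-is.
#'
#' @param treated,control Covered-area values (percent of well disk);
#'   vectors are recycled in the usual way.
#' @return Numeric vector of survival percentages.
#' @export
compute_survival <- function(treated, control) {
  if (any(!is.finite(control)) || any(control <= 0)) {
    abort("control covered area must be positive (100% growth reference).")
  }
  if (any(treated < 0)) abort("treated covered area must be >= 0.")
  100 * treated / control
}

#' Normalise a clonogenic design table to percent survival
#'
#' @param design Tibble with columns `genotype`, `drug`, `dose_uM`,
#'   `replicate`, `covered_area` and logical `is_control`. Control rows are
#'   the untreated 100%-growth wells; each genotype needs at least one.
#' @return The treated rows with a `survival` column (percent of the
#'   genotype's mean control area).
#' @export
normalize_survival <- function(design) {
  need <- c("genotype", "covered_area", "is_control")
  if (!all(need %in% names(design))) {
    abort(sprintf("`design` must contain columns: %s", paste(need, collapse = ", ")))
  }
  ctrl <- design |>
    filter(.data$is_control) |>
    group_by(.data$genotype) |>
    summarise(control_area = mean(.data$covered_area), .groups = "drop")
  missing <- setdiff(unique(design$genotype), ctrl$genotype)
  if (length(missing) > 0) {
    abort(sprintf("no control wells for genotype(s): %s",
                  paste(missing, collapse = ", ")))
  }
  design |>
    filter(!.data$is_control) |>
    inner_join(ctrl, by = "genotype") |>
    mutate(survival = compute_survival(.data$covered_area, .data$control_area)) |>
    select(-"control_area")
}

#' Two-way fixed-effects ANOVA for genotype x dose survival designs
#'
#' Fits `response ~ factor1 * factor2` (or the additive model) by least
#' squares and reports Type II sums of squares, so balanced and unbalanced
#' designs are both handled. Degenerate designs in which every group mean is
#' identical and the residual variance is zero report `F = 0`, `p = 1`.
#'
#' @param records Data frame of survival measurements.
#' @param response Name of the response column (default `"survival"`).
#' @param factors Character vector of two factor column names.
#' @param interaction Include the interaction term (requires replication).
#' @return An object of class `momp_anova`: a list with `table` (tibble of
#'   `term`, `sumsq`, `df`, `statistic`, `p.value`), the fitted `lm` object
#'   and the call metadata. [tidy()] and [glance()] methods are provided.
#' @export
two_way_anova <- function(records, response = "survival",
                          factors = c("genotype", "dose_uM"),
                          interaction = TRUE) {
  records <- as_tibble(records)
  if (length(factors) != 2) abort("`factors` must name exactly two columns.")
  miss <- setdiff(c(response, factors), names(records))
  if (length(miss) > 0) {
    abort(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  }
  df <- records |>
    mutate(across(all_of(factors), ~ factor(.x))) |>
    select(all_of(c(response, factors))) |>
    stats::na.omit()
  for (f in factors) {
    if (nlevels(df[[f]]) < 2) {
      abort(sprintf("factor `%s` has fewer than 2 levels.", f))
    }
  }
  min_rep <- df |> count(across(all_of(factors))) |> pull(.data$n) |> min()
  use_int <- interaction && min_rep >= 2
  fml <- stats::reformulate(
    if (use_int) paste(factors[1], factors[2], sep = " * ")
    else paste(factors, collapse = " + "),
    response = response)
  fit <- stats::lm(fml, data = df)

  resid_df <- stats::df.residual(fit)
  resid_ss <- sum(stats::residuals(fit)^2)
  terms_ <- attr(stats::terms(fit), "term.labels")
  if (stats::var(df[[response]]) < 1e-24) {
    # constant response: every between-group SS is 0; report no evidence
    dfs <- vapply(terms_, function(tm) {
      prod(vapply(strsplit(tm, ":")[[1]],
                  function(f) nlevels(df[[f]]) - 1L, integer(1)))
    }, double(1))
    tab <- tibble(term = terms_, sumsq = 0, df = dfs, statistic = 0,
                  p.value = 1)
  } else {
    atab <- car::Anova(fit, type = 2)
    tab <- tibble(term = rownames(atab),
                  sumsq = atab[["Sum Sq"]],
                  df = atab[["Df"]],
                  statistic = atab[["F value"]],
                  p.value = atab[["Pr(>F)"]]) |>
      filter(.data$term != "Residuals")
  }
  tab <- bind_rows(tab, tibble(term = "Residuals", sumsq = resid_ss,
                               df = resid_df, statistic = NA_real_,
                               p.value = NA_real_))
  structure(list(table = tab, fit = fit, response = response,
                 factors = factors, interaction = use_int,
                 n = nrow(df)),
            class = "momp_anova")
}

#' @export
print.momp_anova <- function(x, ...) {
  cat(sprintf("Two-way ANOVA (Type II): %s ~ %s%s, n = %d\n", x$response,
              paste(x$factors, collapse = " x "),
              if (x$interaction) " + interaction" else "", x$n))
  print(as.data.frame(x$table), row.names = FALSE)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname two_way_anova
#' @param x A `momp_anova` object.
#' @param ... Unused.
#' @export
tidy.momp_anova <- function(x, ...) x$table

#' @rdname two_way_anova
#' @export
glance.momp_anova <- function(x, ...) {
  s <- summary(x$fit)
  tibble(r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
         sigma = s$sigma, df.residual = stats::df.residual(x$fit),
         nobs = x$n)
}
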