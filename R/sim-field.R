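#' Simulate ground-truth cells for one imaging field
#'
#' Draws cell positions, phenotypes, nuclear geometry (normal ellipse or 2-4
#' apoptotic fragments) and per-channel puncta for a single field.
#' BAX_POSITIVE cells receive YFP (Venus-BAX) puncta only; INTACT cells
#' Texas Red (OMI-mCherry) puncta only; DOUBLE_POSITIVE cells receive both,
#' with BAX and OMI puncta kept at least `min_bax_omi_separation` px apart
#' (non-colocalized); NONDETERMINED cells carry no puncta and no diffuse
#' reporter signal.
#'
#' @param config A [sim_config()].
#' @param well_id,site_index Metadata attached to every cell.
#' @param seed Integer seed; identical arguments give identical truth.
#' @param n_cells Number of cells; default draws Poisson(`cells_per_field`).
#' @param phenotypes Optional character vector of labels to use verbatim
#'   (overrides both `n_cells` and the mixture).
#'
#' @return A list of class `momp_truth` with tibbles `cells` (one row per
#'   cell), `nuclei` (one row per nuclear blob; fragmented nuclei have
#'   several) and `puncta` (one row per punctum: channel, centroid, FWHM
#'   diameter, peak amplitude).
#' @export
simulate_field_truth <- function(config, well_id = "B03", site_index = 1L,
                                 seed = config$seed, n_cells = NULL,
                                 phenotypes = NULL) {
  with_seed(seed, {
    h <- config$image_shape[1]; w <- config$image_shape[2]
    m <- config$border_margin
    if (is.null(phenotypes)) {
      if (is.null(n_cells)) n_cells <- stats::rpois(1, config$cells_per_field)
      phenotypes <- sample(phenotype_levels(), n_cells, replace = TRUE,
                           prob = config$phenotype_mixture[phenotype_levels()])
    } else {
      phenotypes <- match.arg(phenotypes, phenotype_levels(), several.ok = TRUE)
      n_cells <- length(phenotypes)
    }
    if (n_cells == 0) {
      empty_cells <- tibble(cell_id = integer(), well_id = character(),
                            site_index = integer(), y = double(), x = double(),
                            phenotype = character(), nucleus_fragmented = logical(),
                            fragment_count = integer())
      return(structure(list(cells = empty_cells,
                            nuclei = tibble(cell_id = integer(), y = double(),
                                            x = double(), ry = double(),
                                            rx = double(), theta = double()),
                            puncta = tibble(cell_id = integer(), channel = character(),
                                            y = double(), x = double(),
                                            diameter = double(), amplitude = double()),
                            well_id = well_id, site_index = site_index),
                       class = "momp_truth"))
    }

    centroids <- place_points(n_cells, lo_y = m, hi_y = h - m, lo_x = m,
                              hi_x = w - m, min_sep = config$min_cell_separation)
    n_placed <- nrow(centroids)
    if (n_placed < n_cells) {
      warn(sprintf("field %s/s%d: placed %d of %d requested cells (density limit)",
                   well_id, site_index, n_placed, n_cells))
      phenotypes <- phenotypes[seq_len(n_placed)]
      n_cells <- n_placed
    }

    apoptotic <- phenotypes %in% c("BAX_POSITIVE", "DOUBLE_POSITIVE")
    fragmented <- apoptotic & stats::runif(n_cells) < config$frag_prob_apoptotic

    nuclei <- vector("list", n_cells)
    puncta <- vector("list", n_cells)
    frag_n <- integer(n_cells)
    for (i in seq_len(n_cells)) {
      cy <- centroids$y[i]; cx <- centroids$x[i]
      if (fragmented[i]) {
        k <- sample(2:4, 1)
        frag_n[i] <- k
        pos <- place_points(k, lo_y = cy - config$fragment_spread,
                            hi_y = cy + config$fragment_spread,
                            lo_x = cx - config$fragment_spread,
                            hi_x = cx + config$fragment_spread, min_sep = 7.5)
        k <- nrow(pos)
        frag_n[i] <- k
        r <- stats::runif(k, config$fragment_radius_range[1],
                          config$fragment_radius_range[2])
        nuclei[[i]] <- tibble(cell_id = i, y = pos$y, x = pos$x,
                              ry = r, rx = r, theta = 0)
      } else {
        frag_n[i] <- 1L
        rr <- stats::runif(2, config$nucleus_radius_range[1],
                           config$nucleus_radius_range[2])
        nuclei[[i]] <- tibble(cell_id = i, y = cy, x = cx,
                              ry = max(rr), rx = min(rr),
                              theta = stats::runif(1, 0, pi))
      }
      pp <- draw_cell_puncta(phenotypes[i], cy, cx, config)
      if (nrow(pp) > 0) pp$cell_id <- i
      puncta[[i]] <- pp
    }

    cells <- tibble(cell_id = seq_len(n_cells), well_id = well_id,
                    site_index = as.integer(site_index),
                    y = centroids$y, x = centroids$x,
                    phenotype = phenotypes,
                    nucleus_fragmented = fragmented,
                    fragment_count = frag_n)
    structure(list(cells = cells, nuclei = list_rbind(nuclei),
                   puncta = list_rbind(puncta),
                   well_id = well_id, site_index = as.integer(site_index)),
              class = "momp_truth")
  })
}

# Rejection-sample n points in a box with a minimum pairwise separation.
place_points <- function(n, lo_y, hi_y, lo_x, hi_x, min_sep) {
  ys <- double(0); xs <- double(0)
  attempts <- 0L
  while (length(ys) < n && attempts < 400L * n) {
    attempts <- attempts + 1L
    y <- stats::runif(1, lo_y, hi_y); x <- stats::runif(1, lo_x, hi_x)
    if (length(ys) == 0 || min((ys - y)^2 + (xs - x)^2) >= min_sep^2) {
      ys <- c(ys, y); xs <- c(xs, x)
    }
  }
  tibble(y = ys, x = xs)
}

# Puncta for one cell: counts ~ 1 + Poisson(mean - 1) in each active channel,
# placed in a radial annulus around the centroid with same-channel and
# cross-channel separation constraints.
draw_cell_puncta <- function(phenotype, cy, cx, config) {
  chans <- switch(phenotype,
                  BAX_POSITIVE = "YFP",
                  INTACT = "TexasRed",
                  DOUBLE_POSITIVE = c("YFP", "TexasRed"),
                  NONDETERMINED = character(0))
  if (length(chans) == 0) {
    return(tibble(cell_id = integer(), channel = character(), y = double(),
                  x = double(), diameter = double(), amplitude = double()))
  }
  all_y <- double(0); all_x <- double(0); all_ch <- character(0)
  out <- vector("list", length(chans))
  for (ci in seq_along(chans)) {
    ch <- chans[ci]
    spec <- config$puncta[[ch]]
    n <- 1L + stats::rpois(1, max(spec$count_mean - 1, 0))
    py <- double(0); px <- double(0)
    tries <- 0L
    while (length(py) < n && tries < 80L * n) {
      tries <- tries + 1L
      r <- sqrt(stats::runif(1, config$puncta_zone[1]^2, config$puncta_zone[2]^2))
      a <- stats::runif(1, 0, 2 * pi)
      y <- cy + r * sin(a); x <- cx + r * cos(a)
      ok <- TRUE
      if (length(all_y) > 0) {
        d2 <- (all_y - y)^2 + (all_x - x)^2
        same <- all_ch == ch
        if (any(same) && min(d2[same]) < config$min_puncta_separation^2) ok <- FALSE
        if (ok && any(!same) && min(d2[!same]) < config$min_bax_omi_separation^2) ok <- FALSE
      }
      if (ok) {
        py <- c(py, y); px <- c(px, x)
        all_y <- c(all_y, y); all_x <- c(all_x, x); all_ch <- c(all_ch, ch)
      }
    }
    k <- length(py)
    out[[ci]] <- tibble(channel = ch, y = py, x = px,
                        diameter = stats::runif(k, spec$diameter_range[1],
                                                spec$diameter_range[2]),
                        amplitude = spec$amplitude * stats::runif(k, 0.8, 1.2))
  }
  res <- list_rbind(out)
  res$cell_id <- NA_integer_
  res
}

#' Render a field image from ground truth
#'
#' Paints nuclei (soft-edged ellipses; fragmented nuclei as several small
#' blobs), diffuse cytoplasmic reporter signal and puncta (2-D Gaussians with
#' FWHM equal to the true diameter) onto a constant background, then applies
#' Poisson shot noise and Gaussian read noise. With `noise_sigma = 0` in the
#' config the output is fully deterministic pixel arithmetic (no noise of
#' either kind). Intensities beyond the 16-bit range are clipped with a
#' warning.
#'
#' @param truth A `momp_truth` from [simulate_field_truth()].
#' @param config The same [sim_config()] used to build the truth.
#' @param seed Integer seed for the noise draws.
#' @return A list of class `momp_field`: `channels` (named list of integer
#'   matrices `DAPI`, `YFP`, `TexasRed`), `well_id`, `site_index`,
#'   `pixel_size`.
#' @export
render_field <- function(truth, config, seed = config$seed) {
  h <- config$image_shape[1]; w <- config$image_shape[2]
  bg <- config$background_level
  dapi <- matrix(0, h, w); yfp <- matrix(0, h, w); txr <- matrix(0, h, w)

  nb <- truth$nuclei
  for (i in seq_len(nrow(nb))) {
    p <- patch_at(ellipse_patch(nb$ry[i], nb$rx[i], nb$theta[i],
                                config$nucleus_amplitude, edge = 0.8),
                  nb$y[i], nb$x[i], h, w)
    dapi[p$idx] <- dapi[p$idx] + p$vals
  }
  cl <- truth$cells
  if (nrow(cl) > 0) {
    cyto <- disk_patch(config$cell_radius, 1, edge = 2)
    for (i in seq_len(nrow(cl))) {
      dif <- config$diffuse[[cl$phenotype[i]]]
      if (dif[["YFP"]] > 0 || dif[["TexasRed"]] > 0) {
        p <- patch_at(cyto, cl$y[i], cl$x[i], h, w)
        if (dif[["YFP"]] > 0) yfp[p$idx] <- yfp[p$idx] + p$vals * dif[["YFP"]]
        if (dif[["TexasRed"]] > 0) txr[p$idx] <- txr[p$idx] + p$vals * dif[["TexasRed"]]
      }
    }
  }
  pu <- truth$puncta
  for (i in seq_len(nrow(pu))) {
    p <- patch_at(gaussian_patch(pu$diameter[i] / 2.35482, pu$amplitude[i]),
                  pu$y[i], pu$x[i], h, w)
    if (pu$channel[i] == "YFP") yfp[p$idx] <- yfp[p$idx] + p$vals
    else txr[p$idx] <- txr[p$idx] + p$vals
  }

  chans <- list(DAPI = dapi + bg, YFP = yfp + bg, TexasRed = txr + bg)
  ig <- config$illumination_gradient %||% c(0, 0)
  if (any(ig != 0)) {
    shade <- 1 + outer((seq_len(h) / h - 0.5) * ig[1],
                       (seq_len(w) / w - 0.5) * ig[2], "+")
    chans <- lapply(chans, function(m) m * shade)
  }
  chans <- with_seed(seed, lapply(chans, apply_camera_noise, config = config))
  structure(list(channels = chans, well_id = truth$well_id,
                 site_index = truth$site_index, pixel_size = config$pixel_size),
            class = "momp_field")
}

apply_camera_noise <- function(img, config) {
  if (config$noise_sigma > 0) {
    n <- length(img)
    shot <- matrix(stats::rpois(n, pmax(img, 0) / config$gain) * config$gain,
                   nrow(img), ncol(img))
    img <- shot + stats::rnorm(n, 0, config$noise_sigma)
  }
  if (any(img > 65535)) {
    warn("rendered intensities exceed the 16-bit range; values clipped")
  }
  img <- round(clamp(img, 0, 65535))
  storage.mode(img) <- "integer"
  img
}

#' Simulate one field: ground truth plus rendered image
#'
#' @inheritParams simulate_field_truth
#' @return A list with elements `truth` (`momp_truth`) and `field`
#'   (`momp_field`). Truth and rendering use seeds derived from `seed` by
#'   counter-based splitting, so the pair is reproducible as a unit.
#' @export
simulate_field <- function(config, well_id = "B03", site_index = 1L,
                           seed = config$seed, n_cells = NULL,
                           phenotypes = NULL) {
  truth <- simulate_field_truth(config, well_id = well_id,
                                site_index = site_index,
                                seed = derive_seed(seed, well_id, site_index, "truth"),
                                n_cells = n_cells, phenotypes = phenotypes)
  field <- render_field(truth, config,
                        seed = derive_seed(seed, well_id, site_index, "render"))
  list(truth = truth, field = field)
}

#' @export
print.momp_field <- function(x, ...) {
  cat(sprintf("<momp_field> well %s site %d: %d x %d px, channels %s\n",
              x$well_id, x$site_index, nrow(x$channels[[1]]),
              ncol(x$channels[[1]]), paste(names(x$channels), collapse = "/")))
  invisible(x)
}

#' @export
print.momp_truth <- function(x, ...) {
  cat(sprintf("<momp_truth> well %s site %d: %d cells, %d puncta\n",
              x$well_id, x$site_index, nrow(x$cells), nrow(x$puncta)))
  invisible(x)
}
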