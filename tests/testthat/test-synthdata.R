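# Synthetic-data generator: layout arithmetic, determinism, ground-truth
# consistency, mixture realization, colony fraction control.

test_that("plate layout arithmetic: edge exclusion, capacity, plate count", {
  cfg <- sim_config()
  expect_equal(usable_wells(cfg), (16 - 4) * (24 - 4))  # 240

  genes <- sprintf("g%04d", 1:1318)
  layout <- generate_plate_layout(genes, cfg, replicates = 1)
  # 240 usable minus 8 control wells = 232 sample wells/plate -> 6 plates
  expect_equal(length(unique(layout$plate)), ceiling(1318 / 232))
  smp <- dplyr::filter(layout, role == "SAMPLE")
  expect_equal(sort(unique(smp$gene)), sort(genes))
  expect_equal(nrow(smp), 1318)

  # all edge-band wells are EMPTY_EDGE and untreated
  edge <- dplyr::filter(layout, row <= 2 | row >= 15 | column <= 2 | column >= 23)
  expect_true(all(edge$role == "EMPTY_EDGE"))
  expect_true(all(edge$treatment == "NONE"))
})

test_that("plate layout: replicate plates carry the same gene set", {
  layout <- generate_plate_layout(sprintf("g%02d", 1:50), sim_config(),
                                  replicates = 3)
  sets <- layout |>
    dplyr::filter(role == "SAMPLE") |>
    dplyr::group_by(replicate) |>
    dplyr::summarise(genes = list(sort(gene)))
  expect_equal(length(unique(sets$genes)), 1)
  # every plate has its control complement
  ctrl <- layout |>
    dplyr::filter(role %in% c("NEG_CONTROL", "POS_CONTROL")) |>
    dplyr::count(plate)
  expect_true(all(ctrl$n == 4))
})

test_that("empty gene list yields a controls-only layout", {
  layout <- generate_plate_layout(character(0), sim_config(), replicates = 1)
  expect_equal(sum(layout$role == "SAMPLE"), 0)
  expect_gt(sum(layout$role == "NEG_CONTROL"), 0)
  expect_true(all(layout$role %in% c("NEG_CONTROL", "POS_CONTROL", "TOX_MARKER",
                                     "UNTREATED", "EMPTY_EDGE")))
})

test_that("capacity overflow raises an informative error", {
  cfg <- sim_config(plate_format = c(8L, 8L), edge_margin = 2L)  # 16 usable
  expect_error(generate_plate_layout(sprintf("g%d", 1:9), cfg, replicates = 1,
                                     controls = c(NEG_CONTROL = 16L)),
               "capacity|control wells")
})

test_that("secondary layout separates a gene's siRNAs across plates", {
  cfg <- sim_config()
  genes <- sprintf("g%03d", 1:232)  # exactly one plate chunk per siRNA set
  layout <- generate_plate_layout(genes, cfg, replicates = 1, sirnas_per_gene = 4)
  per_gene <- layout |>
    dplyr::filter(role == "SAMPLE") |>
    dplyr::group_by(gene) |>
    dplyr::summarise(n_plates = dplyr::n_distinct(plate), n = dplyr::n())
  expect_true(all(per_gene$n == 4))
  expect_true(all(per_gene$n_plates == 4))
})

test_that("field truth: determinism, puncta in-bounds and in-range", {
  cfg <- small_config()
  t1 <- simulate_field_truth(cfg, seed = 11)
  t2 <- simulate_field_truth(cfg, seed = 11)
  expect_identical(t1, t2)

  expect_true(all(t1$puncta$y >= 1 & t1$puncta$y <= cfg$image_shape[1]))
  expect_true(all(t1$puncta$x >= 1 & t1$puncta$x <= cfg$image_shape[2]))
  for (ch in c("YFP", "TexasRed")) {
    dr <- cfg$puncta[[ch]]$diameter_range
    d <- t1$puncta$diameter[t1$puncta$channel == ch]
    expect_true(all(d >= dr[1] & d <= dr[2]))
  }
})

test_that("phenotype-channel contract of the ground truth", {
  cfg <- small_config()
  tr <- simulate_field_truth(cfg, seed = 3, n_cells = 30)
  by_cell <- split(tr$puncta$channel, tr$puncta$cell_id)
  for (i in seq_len(nrow(tr$cells))) {
    ph <- tr$cells$phenotype[i]
    chans <- unique(by_cell[[as.character(tr$cells$cell_id[i])]])
    switch(ph,
      BAX_POSITIVE = expect_identical(chans, "YFP"),
      INTACT = expect_identical(chans, "TexasRed"),
      DOUBLE_POSITIVE = expect_setequal(chans, c("YFP", "TexasRed")),
      NONDETERMINED = expect_null(chans))
  }
})

test_that("double-positive cells have non-colocalized BAX and OMI puncta", {
  cfg <- small_config()
  tr <- simulate_field_truth(cfg, seed = 5,
                             phenotypes = rep("DOUBLE_POSITIVE", 10))
  for (cid in tr$cells$cell_id) {
    p <- tr$puncta[tr$puncta$cell_id == cid, ]
    bax <- p[p$channel == "YFP", ]; omi <- p[p$channel == "TexasRed", ]
    expect_gte(nrow(bax), 1); expect_gte(nrow(omi), 1)
    d2 <- outer(bax$y, omi$y, "-")^2 + outer(bax$x, omi$x, "-")^2
    expect_gte(sqrt(min(d2)), cfg$min_bax_omi_separation)
  }
})

test_that("mixture realization matches the configured probabilities", {
  cfg <- sim_config()  # full-size field holds 100 cells comfortably
  mix <- cfg$phenotype_mixture
  labels <- character(0)
  for (s in 1:12) {
    tr <- simulate_field_truth(cfg, seed = 100 + s, n_cells = 100)
    labels <- c(labels, tr$cells$phenotype)
  }
  n <- length(labels)
  expect_gte(n, 1000)
  for (ph in names(mix)) {
    p_hat <- mean(labels == ph)
    se <- sqrt(mix[[ph]] * (1 - mix[[ph]]) / n)
    expect_lt(abs(p_hat - mix[[ph]]), 3 * se + 1e-12)
  }
})

test_that("rendering: empty noiseless field is uniformly the background", {
  cfg <- noiseless_config(background_level = 137)
  tr <- simulate_field_truth(cfg, seed = 1, n_cells = 0)
  f <- render_field(tr, cfg)
  for (ch in names(f$channels)) {
    expect_true(all(f$channels[[ch]] == 137))
  }
})

test_that("illumination gradient tilts the field as configured", {
  cfg <- noiseless_config(background_level = 1000,
                          illumination_gradient = c(0.2, 0))
  tr <- simulate_field_truth(cfg, seed = 1, n_cells = 0)
  f <- render_field(tr, cfg)
  img <- f$channels$DAPI
  top <- mean(img[1:10, ]); bottom <- mean(img[311:320, ])
  expect_gt(bottom, top)
  # the sampled bands are 310/320 of the field apart
  # integer rounding of pixel values leaves ~1e-4 slack
  expect_equal((bottom - top) / 1000, 0.2 * 310 / 320, tolerance = 1e-3)
})

test_that("rendering is bit-identical under a fixed seed", {
  cfg <- small_config()
  tr <- simulate_field_truth(cfg, seed = 9)
  f1 <- render_field(tr, cfg, seed = 7)
  f2 <- render_field(tr, cfg, seed = 7)
  expect_identical(f1$channels, f2$channels)
  f3 <- render_field(tr, cfg, seed = 8)
  expect_false(identical(f1$channels, f3$channels))
})

test_that("rendered puncta produce the right number of local maxima", {
  cfg <- noiseless_config()
  tr <- simulate_field_truth(cfg, seed = 21, phenotypes = "INTACT")
  f <- render_field(tr, cfg)
  img <- f$channels$TexasRed
  # oracle: peak detection at the generator's own coordinates
  n_peaks <- 0
  for (i in seq_len(nrow(tr$puncta))) {
    y <- round(tr$puncta$y[i]); x <- round(tr$puncta$x[i])
    win <- img[(y - 2):(y + 2), (x - 2):(x + 2)]
    if (max(win) > cfg$background_level + tr$puncta$amplitude[i] / 2) {
      n_peaks <- n_peaks + 1
    }
  }
  expect_equal(n_peaks, nrow(tr$puncta))
})

test_that("overflow beyond 16 bits clips with a warning", {
  cfg <- noiseless_config(background_level = 65000,
                          nucleus_amplitude = 20000)
  tr <- simulate_field_truth(cfg, seed = 2, n_cells = 3)
  w <- testthat::capture_warnings(f <- render_field(tr, cfg))
  expect_true(any(grepl("clipped", w)))
  expect_lte(max(f$channels$DAPI), 65535)
})

test_that("screen score simulation: zero noise reproduces the baseline", {
  sim <- simulate_screen_scores(100, replicates = 2, noise_sd = 0, seed = 4)
  smp <- dplyr::filter(sim$summaries, !grepl("^N", well))
  expect_true(all(smp$frac_bax_positive == sim$baseline[["pct_bax_positive"]] / 100))
  expect_true(all(smp$frac_double_positive == sim$baseline[["pct_double_positive"]] / 100))
})

test_that("screen score simulation: spikes rank on top and tables are reproducible", {
  spiked <- stats::setNames(rep(5, 20), sprintf("gene%04d", 1:20))
  s1 <- simulate_screen_scores(100, spiked, noise_cv = 0.05, seed = 8)
  s2 <- simulate_screen_scores(100, spiked, noise_cv = 0.05, seed = 8)
  expect_identical(s1$summaries, s2$summaries)
  ranks <- s1$summaries |>
    dplyr::inner_join(s1$plate_map, by = c("plate", "well")) |>
    dplyr::filter(role == "SAMPLE") |>
    dplyr::group_by(gene) |>
    dplyr::summarise(score = mean(frac_double_positive)) |>
    dplyr::arrange(dplyr::desc(score))
  expect_setequal(ranks$gene[1:20], names(spiked))
  expect_error(simulate_screen_scores(10, noise_sd = -1), "noise_sd")
})

test_that("colony wells realize the requested covered fraction", {
  expect_error(render_colony_well(-0.1), "\\[0, 1\\]")
  blank <- render_colony_well(0, seed = 1)
  expect_equal(blank$realized_fraction, 0)
  full <- render_colony_well(1, seed = 1)
  expect_equal(full$realized_fraction, 1)
  for (f in c(0.05, 0.30, 0.60, 0.95)) {
    cw <- render_colony_well(f, n_colonies = 50, seed = round(100 * f))
    expect_lt(abs(cw$realized_fraction - f), 0.01)
  }
  # determinism
  a <- render_colony_well(0.3, seed = 5); b <- render_colony_well(0.3, seed = 5)
  expect_identical(a$image, b$image)
})
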