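# Shared fixtures: a small field geometry keeps unit tests fast; acceptance
# tests use the full default configuration.

small_config <- function(...) {
  args <- utils::modifyList(list(image_shape = c(320L, 320L),
                                 cells_per_field = 18), list(...))
  do.call(sim_config, args)
}

# A noiseless configuration for pixel-exact contracts.
noiseless_config <- function(...) {
  args <- utils::modifyList(list(noise_sigma = 0), list(...))
  do.call(small_config, args)
}

# One analysed field plus its truth, memoised per (seed, config hash-free).
sim_and_analyze <- function(config = small_config(), seed = 7,
                            params = detection_params(), ...) {
  fs <- simulate_field(config, seed = seed, ...)
  an <- analyze_field(fs$field, params)
  c(fs, an)
}

# Hand-built cell-record rows for classification-rule tests.
record_row <- function(bax = 0L, omi = 0L, yfp = 100, txr = 100,
                       well = "P1:B03", frag = FALSE) {
  tibble::tibble(cell_id = 1L, well_id = well, site_index = 1L, y = 1, x = 1,
                 nucleus_area = 250, fragment_count = 1L,
                 nucleus_fragmented = frag,
                 bax_granule_count = as.integer(bax),
                 bax_granule_total_intensity = bax * 1e4,
                 omi_granule_count = as.integer(omi),
                 omi_granule_total_intensity = omi * 1e4,
                 mean_yfp_intensity = yfp, mean_txred_intensity = txr)
}
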