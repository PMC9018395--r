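#' Build and validate a run configuration
#'
#' One object drives an end-to-end screen run: simulation settings, detection
#' parameters, screen statistics settings and output paths. Configurations
#' round-trip through YAML via [read_run_config()].
#'
#' @param genes Character vector of gene identifiers (or a single integer n,
#'   expanded to `gene0001..`).
#' @param mode `"images"` runs the full image pipeline (simulate fields,
#'   detect, classify); `"summaries"` uses the imageless score generator.
#' @param replicates Replicate plates.
#' @param tail_fraction Hit-calling tail, in (0, 0.5).
#' @param category Hit category to call.
#' @param min_concordant Secondary-screen concordance threshold (1..4).
#' @param spiked_effects Optional spike table passed to the generator (see
#'   [simulate_screen_scores()]); in `"images"` mode, category III/I/II
#'   multipliers rescale the spiked gene's well mixture.
#' @param noise_cv,noise_sd Score noise for `"summaries"` mode.
#' @param sim Optional list of [sim_config()] overrides (e.g. smaller
#'   `image_shape`, `cells_per_field`, `sites_per_well` for quick runs).
#' @param detection Optional list of [detection_params()] overrides.
#' @param seed Master seed; every well/site derives its own stream from it.
#' @param outdir Output directory.
#' @param write_images Also write every simulated field as TIFFs.
#' @return A list of class `momp_run_config`.
#' @export
run_config <- function(genes = 96L, mode = c("summaries", "images"),
                       replicates = 3L, tail_fraction = 0.10,
                       category = "III", min_concordant = 3L,
                       spiked_effects = NULL, noise_cv = 0.2, noise_sd = 0,
                       sim = list(), detection = list(), seed = 1L,
                       outdir = tempfile("momp_run_"), write_images = FALSE) {
  mode <- match.arg(mode)
  if (is.numeric(genes) && length(genes) == 1) {
    genes <- sprintf("gene%04d", seq_len(genes))
  }
  if (!(tail_fraction > 0 && tail_fraction < 0.5)) {
    abort("`tail_fraction` must lie in (0, 0.5).")
  }
  if (!(min_concordant %in% 1:4)) abort("`min_concordant` must be in 1..4.")
  if (replicates < 1) abort("`replicates` must be >= 1.")
  cfg <- list(genes = genes, mode = mode, replicates = as.integer(replicates),
              tail_fraction = tail_fraction, category = category,
              min_concordant = as.integer(min_concordant),
              spiked_effects = spiked_effects,
              noise_cv = noise_cv, noise_sd = noise_sd,
              sim = sim, detection = detection, seed = as.integer(seed),
              outdir = outdir, write_images = isTRUE(write_images))
  # constructing the full objects validates the overrides now, not mid-run
  do.call(sim_config, cfg$sim)
  do.call(detection_params, cfg$detection)
  structure(cfg, class = "momp_run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys are [run_config()] arguments.
#' @return A validated `momp_run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  args <- yaml::read_yaml(path)
  if (!is.null(args$spiked_effects)) {
    args$spiked_effects <- as_tibble(args$spiked_effects)
  }
  do.call(run_config, args)
}

#' Run the screen pipeline end to end
#'
#' Executes simulate -> (detect -> phenotype) -> summarise -> score -> call
#' hits, writing `plate_map.csv`, `well_summaries.csv`, `gene_scores.csv`,
#' `primary_hits.csv`, a `run.log` and a `manifest.json` recording the config
#' hash, seed, per-stage row counts and an MD5 checksum of every output
#' file. Re-running with the same config and seed reproduces every output
#' byte-identically (the manifest carries no timestamps).
#'
#' @param config A `momp_run_config` (or path to its YAML).
#' @return Invisibly, a list with the key tables (`plate_map`, `summaries`,
#'   `gene_scores`, `hits`) and the `manifest`.
#' @export
run_screen <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "momp_run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$outdir, "run.log")
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }
  scfg <- do.call(sim_config, config$sim)
  dpar <- do.call(detection_params, config$detection)
  say("stage simulate: mode=%s, %d genes, %d replicates, seed=%d",
      config$mode, length(config$genes), config$replicates, config$seed)

  if (config$mode == "summaries") {
    sim <- simulate_screen_scores(
      n_genes = length(config$genes), spiked_effects = config$spiked_effects,
      replicates = config$replicates, noise_sd = config$noise_sd,
      noise_cv = config$noise_cv, seed = derive_seed(config$seed, "scores"))
    plate_map <- sim$plate_map
    summaries <- sim$summaries
  } else {
    plate_map <- generate_plate_layout(config$genes, scfg,
                                       replicates = config$replicates)
    wells <- plate_map |> filter(!(.data$role %in% c("EMPTY_EDGE", "TOX_MARKER")))
    spikes <- normalize_spikes(config$spiked_effects)
    res <- vector("list", nrow(wells))
    for (i in seq_len(nrow(wells))) {
      res[[i]] <- simulate_well_records(wells[i, ], scfg, dpar, spikes,
                                        config$seed,
                                        write_images = config$write_images,
                                        outdir = config$outdir)
    }
    records <- list_rbind(res)
    say("stage detect+phenotype: %d cells across %d wells", nrow(records),
        nrow(wells))
    summaries <- withCallingHandlers(
      summarize_wells(records, dpar,
                      wells = paste(wells$plate, wells$well, sep = ":")),
      warning = function(w) {
        log_lines <<- c(log_lines, conditionMessage(w))
        invokeRestart("muffleWarning")
      }) |>
      normalize_summary_keys()
  }
  say("stage summarise: %d well summaries (%d valid)", nrow(summaries),
      sum(summaries$valid))

  gene_scores <- score_genes(summaries, plate_map)
  say("stage score: %d genes scored", nrow(gene_scores))
  hits <- call_primary_hits(gene_scores, category = config$category,
                            tail_fraction = config$tail_fraction)
  say("stage call-hits: %d hits in category %s (tail %.2f)", nrow(hits),
      config$category, config$tail_fraction)

  files <- list(plate_map = plate_map, well_summaries = summaries,
                gene_scores = gene_scores, primary_hits = hits)
  paths <- imap(files, function(df, name) {
    p <- file.path(config$outdir, paste0(name, ".csv"))
    readr::write_csv(df, p)
    p
  })
  writeLines(log_lines, log_path)

  cfg_for_hash <- config
  cfg_for_hash$outdir <- NULL
  manifest <- list(
    package = "mompscreen",
    version = as.character(utils::packageVersion("mompscreen")),
    seed = config$seed,
    mode = config$mode,
    config_hash = config_hash(cfg_for_hash),
    stages = lapply(files, nrow),
    files = lapply(paths, function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(files, list(manifest = manifest, outdir = config$outdir)))
}

# Role- and spike-adjusted phenotype mixture for one well.
well_mixture <- function(wrow, scfg, spikes) {
  mix <- scfg$phenotype_mixture[phenotype_levels()]
  if (wrow$role == "POS_CONTROL") {
    # BAX pool: no puncta formation, reduced Venus fluorescence
    mix <- c(BAX_POSITIVE = 0.02, INTACT = 0.86, DOUBLE_POSITIVE = 0.02,
             NONDETERMINED = 0.10)
  } else if (wrow$role == "UNTREATED") {
    mix <- c(BAX_POSITIVE = 0.03, INTACT = 0.93, DOUBLE_POSITIVE = 0.01,
             NONDETERMINED = 0.03)
  } else if (wrow$role == "SAMPLE" && nrow(spikes) > 0 &&
             wrow$gene %in% spikes$gene) {
    sp <- spikes[spikes$gene == wrow$gene, ][1, ]
    if (sp$category == "III") {
      mix["DOUBLE_POSITIVE"] <- min(0.9, mix[["DOUBLE_POSITIVE"]] * sp$multiplier)
    } else {
      mix["BAX_POSITIVE"] <- min(0.9, mix[["BAX_POSITIVE"]] * sp$multiplier)
    }
    mix["INTACT"] <- max(0, 1 - sum(mix[c("BAX_POSITIVE", "DOUBLE_POSITIVE",
                                          "NONDETERMINED")]))
    mix <- mix / sum(mix)
  }
  mix
}

config_hash <- function(x) {
  ser <- yaml::as.yaml(unclass(strip_tibbles(x)))
  bytes <- utf8ToInt(ser)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

strip_tibbles <- function(x) {
  if (is.data.frame(x)) return(as.list(as.data.frame(x)))
  if (is.list(x)) return(lapply(x, strip_tibbles))
  x
}

# run_screen builds wells from the mixture chosen by well_mixture(); the
# sim_config mixture is only the SAMPLE/NEG_CONTROL baseline.
simulate_well_records <- function(wrow, scfg, dpar, spikes, master_seed,
                                  write_images = FALSE, outdir = NULL) {
  mix <- well_mixture(wrow, scfg, spikes)
  scfg$phenotype_mixture <- mix
  map_dfr(seq_len(scfg$sites_per_well), function(s) {
    fs <- simulate_field(scfg, well_id = wrow$well, site_index = s,
                         seed = derive_seed(master_seed, wrow$plate, wrow$well, s))
    if (write_images && !is.null(outdir)) {
      write_field_tiff(fs$field, file.path(outdir, "images"), plate = wrow$plate)
    }
    out <- analyze_field(fs$field, dpar)$records
    out$well_id <- paste(wrow$plate, wrow$well, sep = ":")
    out
  })
}
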