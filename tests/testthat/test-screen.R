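# Screen statistics: Z', gene scoring, hit calling, secondary concordance.

test_that("Z' closed form, degenerate and error cases", {
  expect_equal(compute_zprime(c(0.8, 0.8, 0.8), c(0.1, 0.1, 0.1)), 1)
  pos <- c(0.85, 0.9, 0.95); neg <- c(0.05, 0.1, 0.15)  # mu .9/.1, sd .05
  expect_equal(compute_zprime(pos, neg), 1 - 3 * (0.05 + 0.05) / 0.8)
  expect_error(compute_zprime(c(0.5, 0.6), c(0.55, 0.55)), "undefined")
  expect_error(compute_zprime(0.9, c(0.1, 0.2)), "at least 2")
})

test_that("Z' agrees with the closed form on randomized controls", {
  set.seed(42)
  for (i in 1:100) {
    pos <- rnorm(sample(3:12, 1), mean = runif(1, 0.5, 2), sd = runif(1, 0.01, 0.3))
    neg <- rnorm(sample(3:12, 1), mean = runif(1, -1, 0.4), sd = runif(1, 0.01, 0.3))
    if (mean(pos) == mean(neg)) next
    manual <- 1 - 3 * (sqrt(sum((pos - mean(pos))^2 / (length(pos) - 1))) +
                         sqrt(sum((neg - mean(neg))^2 / (length(neg) - 1)))) /
      abs(mean(pos) - mean(neg))
    expect_equal(compute_zprime(pos, neg), manual, tolerance = 1e-12)
    expect_lte(compute_zprime(pos, neg), 1)
  }
})

test_that("Z' decreases as control spread grows", {
  base <- compute_zprime(c(0.88, 0.9, 0.92), c(0.08, 0.1, 0.12))
  wider <- compute_zprime(c(0.8, 0.9, 1.0), c(0.08, 0.1, 0.12))
  expect_lt(wider, base)
})

test_that("gene scoring: triplicate mean and SEM match hand arithmetic", {
  sim <- simulate_screen_scores(3, replicates = 3, seed = 1)
  s <- sim$summaries
  # overwrite one gene's double-positive fractions with {4, 5, 6}%
  target <- "S0001"
  s$frac_double_positive[s$well == target] <- c(4, 5, 6) / 100
  gs <- score_genes(s, sim$plate_map)
  g1 <- gs[gs$gene == "gene0001", ]
  expect_equal(g1$pct_double_positive, 5)
  expect_equal(g1$sem_pct_double_positive, 1 / sqrt(3))
  expect_equal(g1$n_replicates, 3L)

  # fold-change: gene at 3x the plate's negative-control mean on every plate
  s2 <- sim$summaries
  neg_mean <- s2 |>
    dplyr::inner_join(sim$plate_map, by = c("plate", "well")) |>
    dplyr::filter(role == "NEG_CONTROL") |>
    dplyr::group_by(plate) |>
    dplyr::summarise(m = mean(frac_bax_positive))
  for (pl in neg_mean$plate) {
    s2$frac_bax_positive[s2$plate == pl & s2$well == target] <-
      3 * neg_mean$m[neg_mean$plate == pl]
  }
  gs2 <- score_genes(s2, sim$plate_map)
  expect_equal(gs2$fold_bax_positive[gs2$gene == "gene0001"], 3)
})

test_that("invalid wells are skipped and n_replicates decremented", {
  sim <- simulate_screen_scores(4, replicates = 3, seed = 2)
  s <- sim$summaries
  s$valid[s$plate == "P01_R2" & s$well == "S0002"] <- FALSE
  gs <- score_genes(s, sim$plate_map)
  expect_equal(gs$n_replicates[gs$gene == "gene0002"], 2L)
  expect_equal(gs$n_replicates[gs$gene == "gene0001"], 3L)
  # single surviving replicate reports SEM 0
  s$valid[s$plate %in% c("P01_R2", "P01_R3") & s$well == "S0003"] <- FALSE
  gs3 <- score_genes(s, sim$plate_map)
  expect_equal(gs3$n_replicates[gs3$gene == "gene0003"], 1L)
  expect_equal(gs3$sem_pct_double_positive[gs3$gene == "gene0003"], 0)
})

test_that("hit calling equals a brute-force sort oracle", {
  brute <- function(scores, stat, descending, tail) {
    ord <- order(if (descending) -scores[[stat]] else scores[[stat]],
                 scores$gene)
    scores$gene[ord][seq_len(floor(tail * nrow(scores)))]
  }
  set.seed(7)
  for (rep in 1:8) {
    n <- sample(c(10, 137, 1318, 10000), 1)
    scores <- tibble::tibble(
      gene = sprintf("g%05d", seq_len(n)),
      n_replicates = 3L,
      fold_bax_positive = round(stats::rlnorm(n, 0, 0.5), 3),
      sem_fold_bax_positive = 0.1,
      pct_double_positive = round(stats::runif(n, 0, 30), 2),
      sem_pct_double_positive = 0.2)
    tail <- sample(c(0.05, 0.10, 0.25), 1)
    for (cat in c("I", "II", "III")) {
      stat <- if (cat == "III") "pct_double_positive" else "fold_bax_positive"
      hits <- call_primary_hits(scores, cat, tail)
      expect_identical(hits$gene, brute(scores, stat, cat != "II", tail))
      expect_equal(hits$rank, seq_len(nrow(hits)))
    }
  }
})

test_that("1318 genes at the 10% tail yield 131 hits per category", {
  sim <- simulate_screen_scores(1318, noise_cv = 0.2, seed = 3)
  gs <- score_genes(sim$summaries, sim$plate_map)
  for (cat in c("I", "II", "III")) {
    expect_equal(nrow(call_primary_hits(gs, cat, 0.10)), 131)
  }
})

test_that("spiked genes are recovered exactly at low noise", {
  spiked <- stats::setNames(rep(5, 20), sprintf("gene%04d", sample(1:100, 20)))
  sim <- simulate_screen_scores(100, spiked, noise_cv = 0.02, seed = 11)
  gs <- score_genes(sim$summaries, sim$plate_map)
  hits <- call_primary_hits(gs, "III", 0.20)
  expect_setequal(hits$gene, names(spiked))
})

test_that("all-equal scores fall back to lexicographic order, flagged", {
  scores <- tibble::tibble(gene = sprintf("g%02d", 10:1), n_replicates = 3L,
                           fold_bax_positive = 1, sem_fold_bax_positive = 0,
                           pct_double_positive = 5,
                           sem_pct_double_positive = 0)
  hits <- call_primary_hits(scores, "III", 0.3)
  expect_equal(hits$gene, sort(scores$gene)[1:3])
  expect_true(all(hits$tie_degenerate))
})

test_that("tail_fraction is validated", {
  sim <- simulate_screen_scores(10, seed = 1)
  gs <- score_genes(sim$summaries, sim$plate_map)
  expect_error(call_primary_hits(gs, "III", 0.6), "tail_fraction")
  expect_error(call_primary_hits(gs, "III", 0), "tail_fraction")
})

test_that("secondary concordance implements the 3-of-4 rule", {
  tbl <- tibble::tibble(
    gene = rep(c("gA", "gB", "gC", "gD"), each = 4)[-16],  # gD has 3 siRNAs
    sirna_id = paste0("si", 1:15),
    hit = c(TRUE, TRUE, TRUE, FALSE,   # gA: 3/4 -> confirmed
            TRUE, TRUE, FALSE, FALSE,  # gB: 2/4 -> not confirmed
            TRUE, TRUE, TRUE, TRUE,    # gC: 4/4 -> confirmed
            TRUE, TRUE, TRUE))         # gD: 3 present, all hits -> confirmed
  res <- confirm_secondary(tbl)
  expect_equal(res$confirmed[res$gene == "gA"], TRUE)
  expect_equal(res$confirmed[res$gene == "gB"], FALSE)
  expect_equal(res$confirmed[res$gene == "gC"], TRUE)
  expect_equal(res$n_concordant[res$gene == "gC"], 4L)
  # missing fourth siRNA counts as non-concordant but 3 hits still confirm
  expect_equal(res$confirmed[res$gene == "gD"], TRUE)
})

test_that("secondary concordance from scores uses the primary threshold rule", {
  tbl <- tidyr::expand_grid(gene = c("gA", "gB"), sirna = 1:4) |>
    dplyr::mutate(sirna_id = paste0(gene, "_si", sirna),
                  score = c(12, 11, 10, 2, 12, 2, 3, 2))
  res <- confirm_secondary(tbl, threshold = 9, direction = "above")
  expect_true(res$confirmed[res$gene == "gA"])
  expect_false(res$confirmed[res$gene == "gB"])
  res2 <- confirm_secondary(tbl, threshold = 9, direction = "above",
                            min_concordant = 1)
  expect_true(all(res2$confirmed))
})
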