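# The synthetic-data generator: seeded determinism, structural guarantees,
# and distributional agreement with the configured laws.

test_that("generator configuration rejects invalid settings", {
  expect_error(sim_config(n_mirnas = 0), "positive integer")
  expect_error(sim_config(n_genes = 0), "positive integer")
  expect_error(sim_config(target_fraction = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(repression_delta = -1), ">= 0")
  expect_error(sim_config(utr_min_len = 5), "7 nt")
  expect_error(sim_config(adapter = "ACGT"), "8 nt")
})

test_that("mature miRNA generation is deterministic, arm-paired and bounded", {
  cfg <- small_cfg(n_mirnas = 4, rng_seed = 1)
  m1 <- generate_mirnas(cfg)
  m2 <- generate_mirnas(cfg)
  expect_identical(m1, m2)
  expect_equal(nrow(m1), 4L)
  expect_equal(m1$name,
               c("sim-miR-1-5p", "sim-miR-1-3p",
                 "sim-miR-2-5p", "sim-miR-2-3p"))
  big <- generate_mirnas(small_cfg(n_mirnas = 401, rng_seed = 7))
  expect_equal(nrow(big), 401L)
  expect_true(all(nchar(big$sequence) %in% 21:23))
  expect_true(all(grepl("^[ACGU]+$", big$sequence)))
  expect_identical(big$seed, substr(big$sequence, 2, 8))
})

test_that("UTR generation yields unique ids and reproducible sequences", {
  cfg <- small_cfg(n_genes = 100, rng_seed = 2)
  u1 <- generate_utrs(cfg)
  u2 <- generate_utrs(cfg)
  expect_identical(u1, u2)
  expect_equal(nrow(u1), 100L)
  expect_false(anyDuplicated(u1$gene_id) > 0)
  expect_false(anyDuplicated(u1$transcript_id) > 0)
  expect_true(all(u1$length >= cfg$utr_min_len))
  expect_identical(u1$length, nchar(u1$sequence))
})

test_that("UTR lengths follow the truncated log-normal law", {
  cfg <- small_cfg(n_genes = 10000, rng_seed = 11)
  u <- generate_utrs(cfg)
  # closed-form moments of the left-truncated log-normal
  mu <- cfg$utr_meanlog; s <- cfg$utr_sdlog; a <- cfg$utr_min_len
  za <- (log(a) - mu) / s
  tail_p <- pnorm(za, lower.tail = FALSE)
  m1 <- exp(mu + s^2 / 2) * pnorm(za - s, lower.tail = FALSE) / tail_p
  m2 <- exp(2 * mu + 2 * s^2) * pnorm(za - 2 * s, lower.tail = FALSE) / tail_p
  se <- sqrt((m2 - m1^2) / nrow(u))
  expect_lt(abs(mean(u$length) - m1), 3 * se)
})

test_that("site implantation respects the target fraction and length", {
  cfg <- small_cfg(n_genes = 1000, n_mirnas = 2, n_de_mirnas = 1,
                   target_fraction = 0.3, rng_seed = 3)
  mir <- generate_mirnas(cfg)
  utr <- generate_utrs(cfg)
  imp <- implant_sites(utr, mir, cfg)
  expect_equal(nrow(imp$truth), 300L)
  expect_identical(imp$utrs$length, utr$length)
  expect_true(all(imp$truth$gene_id %in% utr$gene_id))

  none <- implant_sites(utr, mir, small_cfg(n_genes = 1000, n_mirnas = 2,
                                            target_fraction = 0,
                                            rng_seed = 3))
  expect_identical(none$utrs, utr)
  expect_equal(nrow(none$truth), 0L)

  short <- utr
  short$sequence[1] <- "ACGT"
  short$length[1] <- 4L
  expect_error(implant_sites(short, mir, cfg), "at least 7 nt")
})

test_that("every implanted site is recovered by the predictor", {
  cfg <- small_cfg(n_genes = 10, n_mirnas = 2, n_de_mirnas = 1,
                   target_fraction = 1, rng_seed = 5)
  mir <- generate_mirnas(cfg)
  imp <- implant_sites(generate_utrs(cfg), mir, cfg)
  expect_equal(nrow(imp$truth), 10L)
  tp <- target_pairs(predict_targets(mir, imp$utrs))
  expect_true(all(
    paste(imp$truth$mirna, imp$truth$gene_id) %in%
      paste(tp$mirna, tp$gene_id)
  ))
})

test_that("replicate noise and the repression shift behave as configured", {
  # noise-free limit: replicates identical
  cfg0 <- small_cfg(n_genes = 50, replicate_cv = 0, rng_seed = 8)
  sim0 <- simulate_mirna_study(cfg0)
  wide <- tidyr::pivot_wider(sim0$expression, names_from = "replicate",
                             values_from = "tpm", names_prefix = "r")
  expect_equal(wide$r1, wide$r2)

  # Monte-Carlo oracle: with delta = 1 the raw (offset-free) mean log2 ratio
  # of targets sits about 1 unit below that of non-targets
  cfg1 <- small_cfg(n_genes = 10000, n_mirnas = 2, n_de_mirnas = 1,
                    repression_delta = 1, target_fraction = 0.3,
                    rng_seed = 9)
  sim1 <- simulate_mirna_study(cfg1)
  raw <- summarize_replicates(sim1$expression) |>
    tidyr::pivot_wider(names_from = "condition", values_from = "mean_tpm") |>
    dplyr::mutate(lfc = log2(mated / virgin))
  is_t <- raw$gene_id %in% sim1$truth$gene_id
  gap <- mean(raw$lfc[is_t]) - mean(raw$lfc[!is_t])
  se <- sqrt(var(raw$lfc[is_t]) / sum(is_t) +
               var(raw$lfc[!is_t]) / sum(!is_t))
  expect_lt(abs(gap - (-1)), 3 * se)
})

test_that("synthetic reads carry the adapter and map back to their miRNA", {
  cfg <- small_cfg(n_mirnas = 4, rng_seed = 10)
  mir <- generate_mirnas(cfg)
  reads <- generate_srna_reads(mir, c("sim-miR-1-5p" = 5L), cfg)
  expect_equal(nrow(reads), 5L)
  expect_true(all(grepl("TGGAATTC", reads$sequence, fixed = TRUE)))
  trimmed <- trim_adapter(reads, "TGGAATTC")
  mat <- chartr("U", "T", mir$sequence)
  for (ins in trimmed$insert) {
    hits <- which(vapply(mat, grepl, logical(1), pattern = ins, fixed = TRUE))
    expect_identical(mir$name[hits], "sim-miR-1-5p")
  }
  expect_equal(nrow(generate_srna_reads(mir, integer(0), cfg)), 0L)
})
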