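# Seed extraction, representative-UTR selection, and seed-site scanning
# against a brute-force sliding-window oracle.

test_that("seed extraction returns nucleotides 2-8 from the 5' end", {
  expect_equal(extract_seed("ACGGUUAAC"), "CGGUUAA")
  expect_equal(extract_seed("AAAAAAAA"), "AAAAAAA")
  expect_equal(extract_seed(c("ACGGUUAAC", "UGAGGUAGUAGG")),
               c("CGGUUAA", "GAGGUAG"))
  expect_error(extract_seed("ACGGUUA"), "at least 8 nt")
})

test_that("representative UTR selection takes the longest, ties at random", {
  cand <- tibble::tibble(
    gene_id = c("g1", "g1", "g2", "g2", "g3", "g3"),
    transcript_id = c("t1a", "t1b", "t2a", "t2b", "t3a", "t3b"),
    sequence = c(strrep("A", 100), strrep("C", 250), # g1: clear winner
                 strrep("G", 300), strrep("T", 300), # g2: tie
                 "", NA)                             # g3: no annotated UTR
  )
  sel <- select_representative_utr(cand, seed = 1)
  expect_equal(sel$gene_id, c("g1", "g2"))
  expect_equal(sel$transcript_id[sel$gene_id == "g1"], "t1b")
  expect_equal(sel$length, c(250L, 300L))
  # seeded tie-break is reproducible
  expect_identical(sel, select_representative_utr(cand, seed = 1))
  # both tied isoforms are reachable under different seeds
  picks <- vapply(1:20, function(s) {
    select_representative_utr(cand, seed = s)$transcript_id[2]
  }, character(1))
  expect_setequal(unique(picks), c("t2a", "t2b"))
})

test_that("site scanning reports exact reverse-complement seed matches", {
  h1 <- find_sites("CGGUUAA", "AAATTAACCGTT")
  expect_equal(h1$start, 3L)
  expect_equal(h1$end, 10L)
  expect_equal(h1$site_type, "7mer-m8")

  h2 <- find_sites("CGGUUAA", "TTAACCGATTAACCGA")
  expect_equal(h2$start, c(0L, 8L))
  expect_equal(h2$site_type, c("8mer", "8mer"))
  expect_equal(h2$end - h2$start, c(8L, 8L))

  expect_equal(nrow(find_sites("CGGUUAA", "ACGT")), 0L)
  expect_error(find_sites("CGGUUA", "ACGTACGT"), "exactly 7 nt")
})

test_that("overlapping occurrences each count", {
  # seed UUUUUUU -> site AAAAAAA; poly-A run of 9 holds 3 overlapping sites
  h <- find_sites("UUUUUUU", "CCAAAAAAAAACC")
  expect_equal(nrow(h), 3L)
  expect_equal(h$start, c(2L, 3L, 4L))
  # first two are followed by A (8mer), the last is followed by C
  expect_equal(h$site_type, c("8mer", "8mer", "7mer-m8"))
})

test_that("scanner agrees with the sliding-window oracle and is U/T robust", {
  set.seed(33)
  for (i in 1:300) {
    seed <- random_dna(7, c("A", "C", "G", "U"))
    utr <- random_dna(sample(20:300, 1))
    got <- find_sites(seed, utr)
    want <- oracle_sites(seed, utr)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$site_type, want$site_type)
    # T-alphabet seed gives identical hits
    got_t <- find_sites(chartr("U", "T", seed), utr)
    expect_identical(got, got_t)
  }
})

test_that("7mer-1A sites are reported only when enabled", {
  # seed CGGUUAA: m2-m7 reverse complement is TAACCG; 7mer-1A site TAACCGA
  # with a non-complementary base (not T) before it
  utr <- "GGTAACCGAGG"
  expect_equal(nrow(find_sites("CGGUUAA", utr)), 0L)
  h <- find_sites("CGGUUAA", utr, include_7mer_1a = TRUE)
  expect_equal(h$site_type, "7mer-1A")
  expect_equal(h$end - h$start, 7L)
  # the same site preceded by T completes the m8 pair: classed 8mer instead
  h8 <- find_sites("CGGUUAA", "GTTAACCGAGG", include_7mer_1a = TRUE)
  expect_equal(h8$site_type, "8mer")
})

test_that("predict_targets validates inputs and covers implanted truth", {
  cfg <- small_cfg(n_genes = 50, rng_seed = 13)
  sim <- simulate_mirna_study(cfg)
  tt <- predict_targets(sim$mirnas, sim$utrs)
  tp <- target_pairs(tt)
  expect_true(all(paste(sim$truth$mirna, sim$truth$gene_id) %in%
                    paste(tp$mirna, tp$gene_id)))
  expect_true(all(tp$gene_id %in% sim$utrs$gene_id))
  expect_error(predict_targets(sim$mirnas[0, ], sim$utrs), "nonempty")
  dup <- dplyr::bind_rows(sim$utrs, sim$utrs[1, ])
  expect_error(predict_targets(sim$mirnas, dup), "duplicate")
})

test_that("longer UTRs accumulate more chance sites", {
  cfg <- small_cfg(n_genes = 1000, n_mirnas = 10, target_fraction = 0,
                   rng_seed = 14)
  utrs <- generate_utrs(cfg)
  mir <- generate_mirnas(cfg)
  tt <- predict_targets(mir, utrs)
  counts <- utrs |>
    dplyr::left_join(dplyr::count(tibble::as_tibble(tt), gene_id),
                     by = "gene_id") |>
    dplyr::mutate(n = tidyr::replace_na(n, 0L))
  rho <- suppressWarnings(
    cor.test(counts$length, counts$n, method = "spearman")$estimate
  )
  expect_gt(rho, 0)
})
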