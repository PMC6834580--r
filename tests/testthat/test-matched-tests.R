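# Length binning, stratified matching, and the repeated matched tests.

test_that("bin edges start at 0 and close the final bin at the maximum", {
  expect_equal(make_bins(c(100, 450), 200), c(0, 200, 400, 450))
  expect_equal(make_bins(c(100, 400), 200), c(0, 200, 400))
  expect_equal(make_bins(c(50), 200), c(0, 50))
  expect_error(make_bins(c(100), 0), "> 0")
  expect_error(make_bins(numeric(0)), "nonempty")
  # the maximum itself falls in the last (right-closed) bin
  b <- make_bins(c(100, 400), 200)
  expect_equal(mirmatch:::assign_bins(400, b), 2L)
})

test_that("stratified matching equalises group sizes per bin", {
  b <- make_bins(c(100, 150, 120, 130, 140), 200)
  sm <- stratified_match(c(10, 20), c(1, 2, 3),
                         c(100, 150), c(120, 130, 140), b)
  expect_equal(sm$n_matched, 2)
  expect_length(sm$target, 2)
  expect_length(sm$nontarget, 2)

  # disjoint bins: nothing matched
  b2 <- make_bins(c(100, 500), 200)
  sm2 <- stratified_match(1, 2, 100, 500, b2)
  expect_equal(sm2$n_matched, 0)

  # equal groups pass through unchanged, order preserved
  sm3 <- stratified_match(c("a", "b", "c"), c("x", "y", "z"),
                          c(50, 250, 450), c(60, 260, 460),
                          make_bins(c(50, 460), 200))
  expect_equal(sm3$target, c("a", "b", "c"))
  expect_equal(sm3$nontarget, c("x", "y", "z"))
})

test_that("matched vectors always balance across random instances", {
  set.seed(51)
  for (i in 1:200) {
    nt <- sample(1:80, 1); nn <- sample(1:80, 1)
    tl <- sample(1:1500, nt, replace = TRUE)
    nl <- sample(1:1500, nn, replace = TRUE)
    b <- make_bins(c(tl, nl), 200)
    sm <- stratified_match(seq_len(nt), seq_len(nn), tl, nl, b)
    expect_length(sm$target, sm$n_matched)
    expect_length(sm$nontarget, sm$n_matched)
    # expected size: sum over bins of min counts
    bt <- table(mirmatch:::assign_bins(tl, b))
    bn <- table(mirmatch:::assign_bins(nl, b))
    common <- intersect(names(bt), names(bn))
    expect_equal(sm$n_matched,
                 sum(pmin(as.integer(bt[common]), as.integer(bn[common]))))
  }
})

test_that("the matched test is reproducible and direction-aware", {
  cfg <- small_cfg(n_genes = 400, n_mirnas = 2, n_de_mirnas = 1,
                   repression_delta = 1.5, rng_seed = 55)
  sim <- simulate_mirna_study(cfg)
  tt <- predict_targets(sim$mirnas, sim$utrs)
  fc <- prep_expression(sim$expression)
  tc <- matched_test_config(n_reps = 1, rng_seed = 9)
  r1 <- run_matched_test(fc, tt, sim$utrs, "sim-miR-1-5p", "up", "ks",
                         config = tc)
  r2 <- run_matched_test(fc, tt, sim$utrs, "sim-miR-1-5p", "up", "ks",
                         config = tc)
  expect_identical(r1, r2)
  expect_equal(r1$n_reps, 1L)
  expect_false(is.na(r1$mean_p))
  # repression of up-miRNA targets is detected
  expect_lt(r1$mean_p, 0.05)
  # testing the wrong direction finds nothing
  r3 <- run_matched_test(fc, tt, sim$utrs, "sim-miR-1-5p", "down", "ks",
                         config = matched_test_config(n_reps = 10,
                                                      rng_seed = 9))
  expect_gt(r3$mean_p, 0.5)
})

test_that("unmatched and degenerate cases yield NA rows, not errors", {
  fc <- tibble::tibble(gene_id = c("g1", "g2"), log2fc = c(0, 1))
  utrs <- tibble::tibble(gene_id = c("g1", "g2"), length = c(100L, 900L))
  tc <- matched_test_config(n_reps = 3, rng_seed = 1)
  # targets and non-targets live in disjoint length bins
  r <- run_matched_test(fc, "g1", utrs, "mirX", "up", "ks", config = tc)
  expect_true(is.na(r$mean_p))
  expect_match(r$na_reason, "no length bin")
  # no targets at all
  r2 <- run_matched_test(fc, character(0), utrs, "mirX", "up", "ks",
                         config = tc)
  expect_match(r2$na_reason, "no targets")
})

test_that("the Fisher variant samples identifiers and finds enrichment", {
  set.seed(61)
  n <- 400
  fc <- tibble::tibble(gene_id = sprintf("g%03d", 1:n), log2fc = rnorm(n))
  utrs <- tibble::tibble(gene_id = fc$gene_id,
                         length = sample(100:1000, n, replace = TRUE))
  targets <- sample(fc$gene_id, 120)
  # strong enrichment: most targets are DE in the opposite (down) direction
  de_genes <- tibble::tibble(
    gene_id = c(sample(targets, 80), sample(setdiff(fc$gene_id, targets), 20)),
    direction = "down"
  )
  tc <- matched_test_config(n_reps = 20, rng_seed = 5)
  r <- run_matched_test(fc, targets, utrs, "mirX", "up", "fisher",
                        de_genes = de_genes, config = tc)
  expect_lt(r$mean_p, 1e-6)
  expect_error(
    run_matched_test(fc, targets, utrs, "mirX", "up", "fisher", config = tc),
    "de_genes"
  )
})

test_that("pairwise combination tests cover same-direction pairs", {
  cfg <- small_cfg(n_genes = 500, n_mirnas = 6, n_de_mirnas = 3,
                   target_fraction = 0.4, repression_delta = 1,
                   rng_seed = 77)
  sim <- simulate_mirna_study(cfg)
  tt <- predict_targets(sim$mirnas, sim$utrs)
  fc <- prep_expression(sim$expression)
  tc <- matched_test_config(n_reps = 5, rng_seed = 3)
  pw <- pairwise_combination_tests(fc, tt, sim$utrs, sim$de_mirnas,
                                   config = tc)
  expect_equal(nrow(pw), choose(3, 2))
  expect_true(all(grepl("\\+", pw$test_id)))

  # fewer than two same-direction miRNAs: empty result
  one <- pairwise_combination_tests(fc, tt, sim$utrs, sim$de_mirnas[1, ],
                                    config = tc)
  expect_equal(nrow(one), 0)

  # disjoint target sets give an NA pair result
  fc2 <- tibble::tibble(gene_id = c("g1", "g2"), log2fc = c(0, 1))
  utr2 <- tibble::tibble(gene_id = c("g1", "g2"), length = c(100L, 150L))
  tt2 <- tibble::tibble(mirna = c("mA", "mB"), gene_id = c("g1", "g2"),
                        start = 0L, end = 7L, site_type = "7mer-m8")
  de2 <- tibble::tibble(mirna = c("mA", "mB"), direction = "up")
  pw2 <- pairwise_combination_tests(fc2, tt2, utr2, de2, config = tc)
  expect_equal(nrow(pw2), 1)
  expect_true(is.na(pw2$mean_p))
})

test_that("the full test battery carries BH q-values and tidiers work", {
  cfg <- small_cfg(n_genes = 400, n_mirnas = 4, n_de_mirnas = 2,
                   repression_delta = 1, rng_seed = 88)
  sim <- simulate_mirna_study(cfg)
  tt <- predict_targets(sim$mirnas, sim$utrs)
  fc <- prep_expression(sim$expression)
  res <- run_matched_tests(fc, tt, sim$utrs, sim$de_mirnas, sim$de_genes,
                           matched_test_config(n_reps = 10, rng_seed = 2))
  expect_s3_class(res, "mirmatch_results")
  expect_true("bh_q" %in% names(res))
  # q-values come from the mean p within each test type
  for (ttp in unique(res$test_type)) {
    sub <- res[res$test_type == ttp, ]
    expect_equal(sub$bh_q, bh_adjust(sub$mean_p))
  }
  td <- tidy(res)
  expect_equal(nrow(td), sum(res$n_reps))
  expect_equal(glance(res)$n_tests, nrow(res))
  expect_s3_class(autoplot(res), "ggplot")
})
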