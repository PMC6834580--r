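# The core procedure: 3'UTR-length-stratified subsampling that equalises
# predicted targets and non-targets within 200-nt length bins, followed by a
# one-sided KS test on fold changes (or a one-sided Fisher exact test on
# opposite-direction DE membership), repeated over fresh subsamples with the
# mean p-value taken as representative, and BH-FDR across tests.

#' Configuration of the matched resampling tests
#'
#' @param bin_width Histogram bin width for 3'UTR length stratification, nt.
#' @param n_reps Number of independent subsampling repetitions per test.
#' @param fdr_alpha Benjamini-Hochberg false discovery rate.
#' @param rng_seed Master seed; repetition `r` of each test draws from a
#'   sub-stream derived from it, so runs are reproducible and repetitions
#'   independent.
#' @return A `matched_test_config` list.
#' @export
matched_test_config <- function(bin_width = 200, n_reps = 100,
                                fdr_alpha = 0.05, rng_seed = 1) {
  if (bin_width <= 0) abort("`bin_width` must be > 0.")
  assert_count(n_reps, "n_reps")
  if (fdr_alpha <= 0 || fdr_alpha >= 1) abort("`fdr_alpha` must be in (0, 1).")
  structure(
    list(bin_width = bin_width, n_reps = as.integer(n_reps),
         fdr_alpha = fdr_alpha, rng_seed = as.integer(rng_seed)),
    class = "matched_test_config"
  )
}

#' Histogram bin edges for 3'UTR length stratification
#'
#' Bins start at 0 in `bin_width` increments: half-open `[0, w), [w, 2w), ...`
#' with the final bin closed on the right at the global maximum length of the
#' two groups combined.
#'
#' @param lengths Positive UTR lengths of both groups pooled.
#' @param bin_width Bin width, nt (default 200).
#' @return Numeric vector of bin edges.
#' @examples
#' make_bins(c(100, 450), 200) # 0 200 400 450
#' @export
make_bins <- function(lengths, bin_width = 200) {
  if (length(lengths) == 0) abort("`lengths` must be nonempty.")
  if (any(lengths <= 0)) abort("Lengths must be positive.")
  if (bin_width <= 0) abort("`bin_width` must be > 0.")
  mx <- max(lengths)
  k <- ceiling(mx / bin_width)
  c(seq(0, (k - 1) * bin_width, by = bin_width), mx)
}

# Bin index per length; the last bin is closed on the right.
assign_bins <- function(lengths, breaks) {
  findInterval(lengths, breaks, rightmost.closed = TRUE)
}

#' Length-matched subsample of targets and non-targets
#'
#' Within each length bin the larger group is subsampled without replacement
#' down to the smaller group's count; bins where either group is empty
#' contribute nothing; kept items are concatenated across bins. Kept indices
#' within a bin are returned in their original order, so equal groups pass
#' through unchanged.
#'
#' @param target_items,nontarget_items Vectors of the values to be compared
#'   (log2 fold changes for the KS test, gene identifiers for the Fisher
#'   test).
#' @param target_lengths,nontarget_lengths Matching 3'UTR lengths.
#' @param bins Bin edges from [make_bins()].
#' @return A list with `target`, `nontarget` (equal-length kept vectors),
#'   `target_idx`, `nontarget_idx`, and `n_matched` (per-group size; 0 means
#'   no bin held both groups, and the downstream test is reported `NA`).
#' @export
stratified_match <- function(target_items, nontarget_items,
                             target_lengths, nontarget_lengths, bins) {
  stopifnot(length(target_items) == length(target_lengths),
            length(nontarget_items) == length(nontarget_lengths))
  bt <- assign_bins(target_lengths, bins)
  bn <- assign_bins(nontarget_lengths, bins)
  sm <- stratified_match_idx(split(seq_along(bt), bt),
                             split(seq_along(bn), bn))
  list(
    target = target_items[sm$target_idx],
    nontarget = nontarget_items[sm$nontarget_idx],
    target_idx = sm$target_idx,
    nontarget_idx = sm$nontarget_idx,
    n_matched = length(sm$target_idx)
  )
}

# Fast core used per repetition: index lists pre-split by bin id.
stratified_match_idx <- function(split_t, split_n) {
  common <- intersect(names(split_t), names(split_n))
  ti <- ni <- vector("list", length(common))
  for (j in seq_along(common)) {
    it <- split_t[[common[j]]]
    in_ <- split_n[[common[j]]]
    k <- min(length(it), length(in_))
    if (length(it) > k) it <- sort(sample(it, k))
    if (length(in_) > k) in_ <- sort(sample(in_, k))
    ti[[j]] <- it; ni[[j]] <- in_
  }
  list(target_idx = unlist(ti) %||% integer(0),
       nontarget_idx = unlist(ni) %||% integer(0))
}

#' Matched resampling test for one miRNA (or one target set)
#'
#' Partitions the retained genes (those with both a fold change and a UTR
#' length) into predicted targets and non-targets of the given miRNA, then
#' repeats `n_reps` times: draw a fresh length-matched subsample
#' ([stratified_match()]) and apply the test. For the KS test the compared
#' values are log2 fold changes and the alternative follows the miRNA's
#' direction: `"greater"` for up-regulated miRNAs (targets expected
#' repressed, i.e. stochastically smaller fold changes) and `"less"` for
#' down-regulated miRNAs (targets expected de-repressed). For the Fisher
#' test gene identifiers are sampled instead and the table tests enrichment
#' of opposite-direction DE genes among matched targets, alternative always
#' `"greater"`.
#'
#' The mean of the repetition p-values is taken as the representative
#' p-value. The mean of p-values is not itself a valid p-value in general,
#' so the median p and the fraction of repetitions rejecting at
#' `fdr_alpha` are also reported as diagnostics.
#'
#' @param fc Fold-change tibble from [prep_expression()] (`gene_id`,
#'   `log2fc`).
#' @param targets Site-level tibble from [predict_targets()], or a character
#'   vector of predicted target gene ids.
#' @param utrs Representative UTR tibble (`gene_id`, `length`).
#' @param mirna miRNA name (used to subset `targets` and label the result).
#' @param direction `"up"` or `"down"`: the miRNA's differential-expression
#'   direction.
#' @param test_type `"ks"` or `"fisher"`.
#' @param de_genes Tibble `gene_id`, `direction` of differentially expressed
#'   genes (required for the Fisher test).
#' @param config A [matched_test_config()].
#' @param nontarget_genes Optional explicit non-target gene set (defaults to
#'   all retained genes that are not targets).
#' @return A one-row tibble: `test_id`, `test_type`, `direction`,
#'   `n_target`, `n_nontarget`, `n_matched`, `n_reps`, `n_na`, `mean_p`,
#'   `median_p`, `reject_frac`, `na_reason`, and the list column `p_reps`.
#' @export
run_matched_test <- function(fc, targets, utrs, mirna,
                             direction = c("up", "down"),
                             test_type = c("ks", "fisher"),
                             de_genes = NULL,
                             config = matched_test_config(),
                             nontarget_genes = NULL) {
  direction <- match.arg(direction)
  test_type <- match.arg(test_type)
  stopifnot(inherits(config, "matched_test_config"))
  if (test_type == "fisher" && is.null(de_genes)) {
    abort("The Fisher test needs `de_genes` direction labels.")
  }
  target_genes <- if (is.character(targets)) targets else {
    tp <- target_pairs(targets)
    tp$gene_id[tp$mirna == mirna]
  }
  retained <- inner_join(
    select(as_tibble(fc), "gene_id", "log2fc"),
    select(utrs, "gene_id", "length"),
    by = "gene_id"
  )
  tg <- retained |> filter(.data$gene_id %in% target_genes)
  ng <- if (is.null(nontarget_genes)) {
    retained |> filter(!.data$gene_id %in% target_genes)
  } else {
    retained |> filter(.data$gene_id %in% nontarget_genes)
  }
  na_row <- function(reason, n_matched = 0L) {
    tibble(
      test_id = mirna, test_type = test_type, direction = direction,
      n_target = nrow(tg), n_nontarget = nrow(ng),
      n_matched = n_matched, n_reps = config$n_reps,
      n_na = config$n_reps, mean_p = NA_real_, median_p = NA_real_,
      reject_frac = NA_real_, na_reason = reason,
      p_reps = list(rep(NA_real_, config$n_reps))
    )
  }
  if (nrow(tg) == 0) return(na_row("no targets among retained genes"))
  if (nrow(ng) == 0) return(na_row("no non-targets among retained genes"))

  breaks <- make_bins(c(tg$length, ng$length), config$bin_width)
  split_t <- split(seq_len(nrow(tg)), assign_bins(tg$length, breaks))
  split_n <- split(seq_len(nrow(ng)), assign_bins(ng$length, breaks))
  n_matched <- sum(vapply(
    intersect(names(split_t), names(split_n)),
    function(b) min(length(split_t[[b]]), length(split_n[[b]])), integer(1)
  ))
  if (n_matched == 0L) return(na_row("no length bin holds both groups"))

  alt <- if (direction == "up") "greater" else "less"
  opposite <- if (!is.null(de_genes)) {
    de_genes$gene_id[de_genes$direction ==
                       if (direction == "up") "down" else "up"]
  }
  ps <- withr::with_preserve_seed({
    vapply(seq_len(config$n_reps), function(r) {
      # counter-based sub-seed: repetition r is reproducible in isolation
      set.seed(derive_seed(config$rng_seed,
                           sprintf("%s|%s|rep%05d", mirna, test_type, r)))
      sm <- stratified_match_idx(split_t, split_n)
      if (test_type == "ks") {
        k <- ks_stat(tg$log2fc[sm$target_idx], ng$log2fc[sm$nontarget_idx],
                     alt)
        n1 <- length(sm$target_idx); n2 <- length(sm$nontarget_idx)
        min(1, exp(-2 * k^2 * n1 * n2 / (n1 + n2)))
      } else {
        a <- sum(tg$gene_id[sm$target_idx] %in% opposite)
        b <- length(sm$target_idx) - a
        cc <- sum(ng$gene_id[sm$nontarget_idx] %in% opposite)
        d <- length(sm$nontarget_idx) - cc
        fisher_one_sided(c(a, b, cc, d))
      }
    }, numeric(1))
  })

  tibble(
    test_id = mirna, test_type = test_type, direction = direction,
    n_target = nrow(tg), n_nontarget = nrow(ng),
    n_matched = n_matched, n_reps = config$n_reps,
    n_na = sum(is.na(ps)),
    mean_p = mean(ps, na.rm = TRUE),
    median_p = median(ps, na.rm = TRUE),
    reject_frac = mean(ps < config$fdr_alpha, na.rm = TRUE),
    na_reason = NA_character_,
    p_reps = list(ps)
  )
}

#' Matched resampling tests for all DE miRNAs, with pairwise combinations
#'
#' Runs [run_matched_test()] for every differentially expressed miRNA (KS
#' always; Fisher when `de_genes` is supplied), optionally adds pairwise
#' combination tests ([pairwise_combination_tests()]), and appends BH
#' q-values over the mean p-values, adjusted within each test type.
#'
#' @inheritParams run_matched_test
#' @param de_mirnas Tibble `mirna`, `direction` of DE miRNAs.
#' @param tests Character subset of `c("ks", "fisher")`.
#' @param pairwise Also test pairwise combinations of same-direction miRNAs.
#' @return A tibble of class `mirmatch_results`, one row per test, with a
#'   `bh_q` column.
#' @export
run_matched_tests <- function(fc, targets, utrs, de_mirnas, de_genes = NULL,
                              config = matched_test_config(),
                              tests = c("ks", "fisher"), pairwise = TRUE) {
  stopifnot(all(c("mirna", "direction") %in% names(de_mirnas)))
  tests <- match.arg(tests, several.ok = TRUE)
  if (is.null(de_genes)) tests <- setdiff(tests, "fisher")
  rows <- list()
  for (tt in tests) {
    for (i in seq_len(nrow(de_mirnas))) {
      rows[[length(rows) + 1L]] <- run_matched_test(
        fc, targets, utrs, de_mirnas$mirna[i], de_mirnas$direction[i],
        tt, de_genes, config
      )
    }
    if (pairwise) {
      rows[[length(rows) + 1L]] <- pairwise_combination_tests(
        fc, targets, utrs, de_mirnas, de_genes, config, tests = tt
      )
    }
  }
  out <- bind_rows(rows)
  out <- out |>
    group_by(.data$test_type) |>
    mutate(bh_q = bh_adjust(.data$mean_p)) |>
    ungroup()
  class(out) <- c("mirmatch_results", class(out))
  out
}

#' Pairwise combinatorial matched tests for same-direction miRNAs
#'
#' For each unordered pair of miRNAs differentially expressed in the same
#' direction, the target set is the intersection of the two predicted target
#' sets (genes targeted by both miRNAs) and the non-target set is the genes
#' predicted to be targeted by neither; the matched test then proceeds as for
#' a single miRNA. Fewer than two eligible miRNAs yields an empty result.
#'
#' @inheritParams run_matched_tests
#' @return A tibble of test rows (possibly zero rows), without BH adjustment.
#' @export
pairwise_combination_tests <- function(fc, targets, utrs, de_mirnas,
                                       de_genes = NULL,
                                       config = matched_test_config(),
                                       tests = "ks") {
  tests <- match.arg(tests, c("ks", "fisher"), several.ok = TRUE)
  if (is.null(de_genes)) tests <- setdiff(tests, "fisher")
  tp <- target_pairs(targets)
  rows <- list()
  for (dir in unique(de_mirnas$direction)) {
    mirs <- de_mirnas$mirna[de_mirnas$direction == dir]
    if (length(mirs) < 2) next
    prs <- combn(sort(mirs), 2)
    for (j in seq_len(ncol(prs))) {
      m1 <- prs[1, j]; m2 <- prs[2, j]
      set1 <- tp$gene_id[tp$mirna == m1]
      set2 <- tp$gene_id[tp$mirna == m2]
      both <- intersect(set1, set2)
      neither <- setdiff(unique(fc$gene_id), union(set1, set2))
      pair_id <- paste0(m1, "+", m2)
      for (tt in tests) {
        row <- run_matched_test(
          fc, both, utrs, mirna = pair_id, direction = dir, test_type = tt,
          de_genes = de_genes, config = config, nontarget_genes = neither
        )
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble(
      test_id = character(0), test_type = character(0),
      direction = character(0), n_target = integer(0),
      n_nontarget = integer(0), n_matched = integer(0), n_reps = integer(0),
      n_na = integer(0), mean_p = numeric(0), median_p = numeric(0),
      reject_frac = numeric(0), na_reason = character(0), p_reps = list()
    ))
  }
  bind_rows(rows)
}

#' @rdname run_matched_tests
#' @param x A `mirmatch_results` tibble.
#' @param ... Unused.
#' @export
tidy.mirmatch_results <- function(x, ...) {
  x |>
    as_tibble() |>
    select("test_id", "test_type", "direction", "p_reps") |>
    mutate(p_reps = purrr::map(.data$p_reps, ~ tibble(
      rep = seq_along(.x), p_value = .x
    ))) |>
    tidyr::unnest("p_reps")
}

#' @rdname run_matched_tests
#' @export
glance.mirmatch_results <- function(x, ...) {
  tibble(
    n_tests = nrow(x),
    n_na = sum(is.na(x$mean_p)),
    n_significant = sum(x$bh_q < 0.05, na.rm = TRUE),
    min_mean_p = suppressWarnings(min(x$mean_p, na.rm = TRUE))
  )
}

#' @rdname run_matched_tests
#' @param object A `mirmatch_results` tibble.
#' @export
autoplot.mirmatch_results <- function(object, ...) {
  d <- tidy(object) |> filter(!is.na(.data$p_value))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$test_id, y = .data$p_value,
                                  fill = .data$test_type)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::geom_hline(yintercept = 0.05, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Subsampling repetition p-value",
                  fill = "Test") +
    ggplot2::theme_minimal()
}
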