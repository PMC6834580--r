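# Diagnosis of 3'UTR-length confounding of target status: longer UTRs accrue
# more chance seed matches, so naive target-vs-nontarget comparisons are
# biased. A panel of random seeds (matching the size of the real miRNA
# complement) quantifies the chance-hit gradient.

#' Generate random miRNA-like seed sequences
#'
#' I.i.d. uniform nucleotides over the RNA alphabet, seeded-deterministic.
#' Used as a null seed panel: hits of random seeds carry no biology, so any
#' association of their counts with UTR length is pure length confounding.
#'
#' @param n Number of seeds (default 401, the size of a full fly mature
#'   miRNA complement).
#' @param length Seed length, nt (default 7).
#' @param seed Integer RNG seed; `NULL` uses the current RNG state.
#' @return Character vector of `n` seeds.
#' @export
random_seeds <- function(n = 401, length = 7, seed = NULL) {
  assert_count(n, "n")
  assert_count(length, "length")
  gen <- function() random_seqs(rep(length, n), RNA_ALPHABET)
  if (is.null(seed)) gen() else
    withr::with_seed(derive_seed(seed, "random-seeds"), gen())
}

#' Quantify the association between 3'UTR length and seed-site count
#'
#' Tallies per-gene total site counts over a seed panel (typically from
#' [random_seeds()] via [predict_targets()]), computes the Spearman rank
#' correlation between UTR length and site count, and exports stratified
#' empirical CDF curves of length and site count for plotting. Genes may be
#' classed `up` / `down` / `ns` via `de_genes` to mirror cumulative-plot
#' diagnostics stratified by differential expression.
#'
#' @param targets Site-level tibble from [predict_targets()] (any seed set).
#' @param utrs Representative UTR tibble (`gene_id`, `length`); every target
#'   gene must have a UTR record.
#' @param de_genes Optional tibble `gene_id`, `direction` (`"up"`/`"down"`);
#'   unlisted genes are classed `"ns"`.
#' @return An object of class `mirmatch_confound`: list with `per_gene`
#'   (gene_id, utr_length, site_count, fc_class), `rho`, `p_value`,
#'   `degenerate` (TRUE when all lengths are equal, where the correlation is
#'   undefined), and `ecdf` (long tibble of ECDF points per class and
#'   variable).
#' @export
site_length_association <- function(targets, utrs, de_genes = NULL) {
  targets <- as_tibble(targets)
  if (nrow(targets) == 0) abort("`targets` must contain at least one site.")
  if (!all(targets$gene_id %in% utrs$gene_id)) {
    abort("Every target gene needs a UTR record.")
  }
  if (nrow(utrs) < 2) abort("Need at least two genes for a correlation.")
  per_gene <- utrs |>
    select("gene_id", utr_length = "length") |>
    left_join(
      targets |> dplyr::count(.data$gene_id, name = "site_count"),
      by = "gene_id"
    ) |>
    mutate(site_count = tidyr::replace_na(.data$site_count, 0L))
  per_gene$fc_class <- "ns"
  if (!is.null(de_genes)) {
    m <- match(per_gene$gene_id, de_genes$gene_id)
    per_gene$fc_class[!is.na(m)] <- de_genes$direction[m[!is.na(m)]]
  }
  degenerate <- length(unique(per_gene$utr_length)) == 1L
  if (degenerate) {
    rho <- NA_real_; p <- NA_real_
  } else {
    ct <- suppressWarnings(
      cor.test(per_gene$utr_length, per_gene$site_count,
               method = "spearman", exact = FALSE)
    )
    rho <- unname(ct$estimate); p <- ct$p.value
  }
  ecdf_tbl <- bind_rows(lapply(split(per_gene, per_gene$fc_class), function(d) {
    bind_rows(
      ecdf_points(d$utr_length, "utr_length", d$fc_class[1]),
      ecdf_points(d$site_count, "site_count", d$fc_class[1])
    )
  }))
  structure(
    list(per_gene = per_gene, rho = rho, p_value = p,
         degenerate = degenerate, ecdf = ecdf_tbl),
    class = "mirmatch_confound"
  )
}

ecdf_points <- function(x, variable, fc_class) {
  xs <- sort(unique(x))
  tibble(variable = variable, fc_class = fc_class,
         value = xs, cum_fraction = ecdf(x)(xs))
}

#' @export
print.mirmatch_confound <- function(x, ...) {
  cat("<mirmatch_confound>\n")
  if (x$degenerate) {
    cat("  all UTR lengths equal: correlation undefined\n")
  } else {
    cat(sprintf("  Spearman rho(length, site count) = %.3f (p = %.3g)\n",
                x$rho, x$p_value))
  }
  cat(sprintf("  %d genes, %d site-bearing\n", nrow(x$per_gene),
              sum(x$per_gene$site_count > 0)))
  invisible(x)
}

#' @rdname site_length_association
#' @param x A `mirmatch_confound` object.
#' @param ... Unused.
#' @export
tidy.mirmatch_confound <- function(x, ...) as_tibble(x$per_gene)

#' @rdname site_length_association
#' @export
glance.mirmatch_confound <- function(x, ...) {
  tibble(rho = x$rho, p_value = x$p_value, n_genes = nrow(x$per_gene),
         degenerate = x$degenerate)
}

#' @rdname site_length_association
#' @param object A `mirmatch_confound` object.
#' @export
autoplot.mirmatch_confound <- function(object, ...) {
  ggplot2::ggplot(object$ecdf,
                  ggplot2::aes(x = .data$value, y = .data$cum_fraction,
                               colour = .data$fc_class)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~.data$variable, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "Cumulative fraction of genes",
                  colour = "DE class") +
    ggplot2::theme_minimal()
}
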