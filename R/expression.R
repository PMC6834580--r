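# Expression preprocessing: replicate averaging, zero filtering, and offset
# log2 fold change between two conditions of one comparison.

#' Average replicate TPM values per gene and condition
#'
#' @param tpm Long tibble with columns `gene_id`, `condition`, `replicate`,
#'   `tpm`. Every condition must carry the same gene set in every replicate
#'   (rectangular design).
#' @return A tibble `gene_id`, `condition`, `mean_tpm`.
#' @export
summarize_replicates <- function(tpm) {
  stopifnot(all(c("gene_id", "condition", "replicate", "tpm") %in% names(tpm)))
  if (any(tpm$tpm < 0, na.rm = TRUE)) abort("TPM values must be nonnegative.")
  per_rep <- tpm |>
    group_by(.data$condition, .data$replicate) |>
    summarise(genes = list(sort(unique(.data$gene_id))), .groups = "drop")
  if (length(unique(per_rep$genes)) != 1L) {
    abort("All replicates must share the same gene set (rectangular table).")
  }
  tpm |>
    group_by(.data$gene_id, .data$condition) |>
    summarise(mean_tpm = mean(.data$tpm), .groups = "drop")
}

#' Discard genes with zero mean abundance
#'
#' Two scopes are supported. `"per-comparison"` (default) removes a gene from
#' the comparison only when its mean TPM is zero in *both* conditions, which
#' keeps the gene sets of the two conditions identical so a paired fold
#' change is defined for every retained gene. `"per-condition"` removes the
#' gene from any single condition where its mean is zero, which can leave
#' asymmetric gene sets.
#'
#' @param means Tibble from [summarize_replicates()].
#' @param scope `"per-comparison"` or `"per-condition"`.
#' @return The filtered mean table.
#' @export
filter_zero <- function(means, scope = c("per-comparison", "per-condition")) {
  scope <- match.arg(scope)
  out <- if (scope == "per-condition") {
    filter(means, .data$mean_tpm > 0)
  } else {
    means |>
      group_by(.data$gene_id) |>
      filter(any(.data$mean_tpm > 0)) |>
      ungroup()
  }
  if (nrow(out) == 0) warn("All genes removed by the zero filter.")
  out
}

#' Offset log2 fold change
#'
#' `log2((b + pseudocount) / (a + pseudocount))`; by convention `a` is the
#' virgin (reference) mean and `b` the mated mean, so negative values mean
#' lower abundance after mating.
#'
#' @param mean_a,mean_b Nonnegative mean abundances (vectorised).
#' @param pseudocount Positive offset added to both means (default 1).
#' @return Numeric vector of log2 fold changes.
#' @examples
#' compute_log2fc(1, 3) # = 1
#' @export
compute_log2fc <- function(mean_a, mean_b, pseudocount = 1) {
  if (pseudocount <= 0) abort("`pseudocount` must be > 0.")
  if (any(mean_a < 0, na.rm = TRUE) || any(mean_b < 0, na.rm = TRUE)) {
    abort("Mean abundances must be nonnegative.")
  }
  log2((mean_b + pseudocount) / (mean_a + pseudocount))
}

#' Prepare a per-gene fold-change table for one comparison
#'
#' Averages replicates, applies the zero filter, and computes the offset
#' log2 fold change of `condition_b` over `condition_a`.
#'
#' @param tpm Long replicate-level TPM tibble (see [summarize_replicates()]).
#' @param condition_a,condition_b Reference and test condition labels
#'   (defaults `"virgin"` and `"mated"`).
#' @param pseudocount Offset for [compute_log2fc()].
#' @param scope Zero-filter scope, see [filter_zero()].
#' @return A tibble `gene_id`, `mean_a`, `mean_b`, `log2fc`, with attributes
#'   `comparison` and `pseudocount`.
#' @export
prep_expression <- function(tpm, condition_a = "virgin",
                            condition_b = "mated", pseudocount = 1,
                            scope = c("per-comparison", "per-condition")) {
  scope <- match.arg(scope)
  conds <- unique(tpm$condition)
  if (!all(c(condition_a, condition_b) %in% conds)) {
    abort("Both conditions must be present in `tpm`.")
  }
  means <- tpm |>
    filter(.data$condition %in% c(condition_a, condition_b)) |>
    summarize_replicates() |>
    filter_zero(scope = scope)
  if (nrow(means) == 0) {
    out <- tibble(gene_id = character(0), mean_a = numeric(0),
                  mean_b = numeric(0), log2fc = numeric(0))
    attr(out, "comparison") <- paste0(condition_b, "-over-", condition_a)
    attr(out, "pseudocount") <- pseudocount
    return(out)
  }
  wide <- means |>
    tidyr::pivot_wider(names_from = "condition", values_from = "mean_tpm")
  if (scope == "per-condition") {
    wide <- tidyr::drop_na(wide, dplyr::all_of(c(condition_a, condition_b)))
  }
  out <- wide |>
    mutate(
      mean_a = .data[[condition_a]],
      mean_b = .data[[condition_b]],
      log2fc = compute_log2fc(.data$mean_a, .data$mean_b, pseudocount)
    ) |>
    select("gene_id", "mean_a", "mean_b", "log2fc")
  attr(out, "comparison") <- paste0(condition_b, "-over-", condition_a)
  attr(out, "pseudocount") <- pseudocount
  out
}
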