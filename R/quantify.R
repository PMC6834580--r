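# Small-RNA read processing: adapter trimming by 8-base prefix recognition
# and exact (0-edit, 0-gap) quantification against mature miRNA sequences.

#' Trim the 3' sequencing adapter from small-RNA reads
#'
#' The adapter is recognised by its first 8 bases; the insert is everything
#' before the *first* occurrence of that 8-mer. Reads without an occurrence
#' are kept untrimmed with the full read as insert. Qualities play no role
#' (FASTQ is treated as FASTA).
#'
#' @param reads Tibble with columns `read_id`, `sequence` (DNA).
#' @param adapter_prefix The first 8 bases of the adapter (default
#'   `"TGGAATTC"`).
#' @return The input tibble with added columns `insert` and `trimmed`.
#' @examples
#' trim_adapter(tibble::tibble(read_id = "r1",
#'                             sequence = "ACGTACGTTGGAATTCCCCC"))
#' @export
trim_adapter <- function(reads, adapter_prefix = "TGGAATTC") {
  if (!is_string(adapter_prefix) || nchar(adapter_prefix) != 8L ||
      !grepl("^[ACGT]{8}$", adapter_prefix)) {
    abort("`adapter_prefix` must be an 8-nt DNA string.")
  }
  if (nrow(reads) > 0 && any(!nzchar(reads$sequence) | is.na(reads$sequence))) {
    abort("Empty read sequences are not allowed.")
  }
  pos <- as.integer(regexpr(adapter_prefix, reads$sequence, fixed = TRUE))
  reads |>
    mutate(
      trimmed = pos > 0L,
      insert = ifelse(pos > 0L, substr(.data$sequence, 1L, pos - 1L),
                      .data$sequence)
    )
}

#' Count small-RNA inserts against mature miRNA sequences
#'
#' An insert is counted for a miRNA iff it is an exact substring (no
#' mismatches, no gaps) of that miRNA's mature sequence and its length lies
#' within `length_window`. By default an insert matching several mature
#' sequences increments every one of them (`multi = "all"`);
#' `multi = "fractional"` splits one count evenly across the matches.
#'
#' @param reads Trimmed read tibble from [trim_adapter()] (columns `insert`;
#'   untrimmed full-length reads simply fail the length window).
#' @param mirnas Tibble with columns `name`, `sequence` (RNA or DNA; U and T
#'   are equivalent).
#' @param sample Sample name for the output column.
#' @param length_window Inclusive insert-length bounds, default `c(18, 26)`
#'   nt, excluding degradation products and the 30-nt 2S rRNA class.
#' @param multi Multi-mapping policy, `"all"` or `"fractional"`.
#' @return A tibble `mirna`, `sample`, `count` with one row per miRNA.
#' @export
quantify_reads <- function(reads, mirnas, sample = "sample1",
                           length_window = c(18L, 26L),
                           multi = c("all", "fractional")) {
  multi <- match.arg(multi)
  if (nrow(mirnas) == 0) abort("`mirnas` must be nonempty.")
  if (!"insert" %in% names(reads)) {
    abort("`reads` must carry an `insert` column; run `trim_adapter()` first.")
  }
  mat <- rna_to_dna(mirnas$sequence)
  counts <- setNames(numeric(nrow(mirnas)), mirnas$name)
  ins <- reads$insert
  keep <- nchar(ins) >= length_window[1] & nchar(ins) <= length_window[2]
  tab <- table(ins[keep])
  if (length(tab) > 0) {
    for (u in names(tab)) {
      hit <- which(vapply(mat, function(s) grepl(u, s, fixed = TRUE),
                          logical(1)))
      if (length(hit) == 0) next
      w <- if (multi == "all") 1 else 1 / length(hit)
      counts[hit] <- counts[hit] + as.numeric(tab[[u]]) * w
    }
  }
  tibble(mirna = mirnas$name, sample = sample, count = unname(counts))
}

#' Build a miRNA-by-sample count matrix from several samples
#'
#' @param ... Long count tibbles from [quantify_reads()].
#' @return A wide tibble, one row per miRNA, one column per sample.
#' @export
count_matrix <- function(...) {
  bind_rows(...) |>
    tidyr::pivot_wider(names_from = "sample", values_from = "count",
                       values_fill = 0)
}
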