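# Seed-based miRNA target prediction over representative 3'UTRs.
#
# The canonical criterion is an exact Watson-Crick reverse complement of the
# 7-nt seed (miRNA nucleotides 2-8 from the 5' end) in the UTR sense strand.
# Sites whose reverse-complement match is immediately followed (3' on the
# UTR, target position t1) by an adenosine are annotated as 8mer; matches to
# nucleotides 2-7 plus a t1 adenosine (7mer-1A) can be enabled but are off by
# default, so that any 2-8 seed match - and only such a match - makes a gene
# a predicted target.

#' Extract the canonical 7-nt seed from mature miRNA sequences
#'
#' The seed is nucleotides 2-8 of the mature miRNA, counted 1-based from the
#' 5' end; it is the primary determinant of target recognition.
#'
#' @param sequence Character vector of mature miRNA sequences (RNA or DNA
#'   alphabet), each at least 8 nt.
#' @return Character vector of 7-nt seeds in the input alphabet.
#' @examples
#' extract_seed("ACGGUUAAC")
#' @export
extract_seed <- function(sequence) {
  if (any(nchar(sequence) < 8L)) {
    abort("Mature sequences must be at least 8 nt to have a 2-8 seed.")
  }
  substr(sequence, 2L, 8L)
}

#' Select one representative 3'UTR per gene
#'
#' For each gene the transcript isoform with the longest annotated 3'UTR is
#' designated representative; ties on the maximum length are broken by a
#' seeded uniform random choice; genes whose isoforms all lack an annotated
#' UTR are dropped.
#'
#' @param candidates Tibble with columns `gene_id`, `transcript_id`,
#'   `sequence` (possibly empty string or `NA` for unannotated UTRs) and
#'   optionally `taxon_id`.
#' @param seed Integer seed governing the tie-break; `NULL` uses the current
#'   RNG state.
#' @return A tibble of one `UTRRecord` row per retained gene: `gene_id`,
#'   `transcript_id`, `taxon_id`, `sequence`, `length`.
#' @export
select_representative_utr <- function(candidates, seed = NULL) {
  stopifnot(all(c("gene_id", "transcript_id", "sequence") %in%
                  names(candidates)))
  cand <- candidates |>
    mutate(sequence = ifelse(is.na(.data$sequence), "", .data$sequence),
           length = nchar(.data$sequence)) |>
    filter(.data$length > 0L)
  if (!"taxon_id" %in% names(cand)) cand$taxon_id <- NA_integer_
  pick <- function() {
    cand |>
      group_by(.data$gene_id) |>
      filter(.data$length == max(.data$length)) |>
      dplyr::slice_sample(n = 1L) |>
      ungroup() |>
      select("gene_id", "transcript_id", "taxon_id", "sequence", "length") |>
      arrange(.data$gene_id)
  }
  if (is.null(seed)) pick() else
    withr::with_seed(derive_seed(seed, "utr-tiebreak"), pick())
}

# Core scanner: all seed-complementary sites of one seed across a character
# vector of UTR sequences. Returns 0-based half-open coordinates.
scan_seed_sites <- function(seed, seqs, ids, include_7mer_1a = FALSE) {
  seed_dna <- rna_to_dna(seed)
  pat_m8 <- revcomp_dna(seed_dna) # reverse complement of nt 2-8
  subject <- Biostrings::DNAStringSet(seqs)
  names(subject) <- ids
  u <- unlist(Biostrings::vmatchPattern(pat_m8, subject))
  if (length(u) > 0) {
    gene <- names(u)
    s1 <- Biostrings::start(u) # 1-based
    e1 <- Biostrings::end(u)
    nxt <- substr(seqs[match(gene, ids)], e1 + 1L, e1 + 1L)
    is8 <- nxt == "A"
    hits <- tibble(
      gene_id = gene,
      start = s1 - 1L,
      end = ifelse(is8, e1 + 1L, e1),
      site_type = ifelse(is8, "8mer", "7mer-m8")
    )
  } else {
    hits <- tibble(gene_id = character(0), start = integer(0),
                   end = integer(0), site_type = character(0))
  }
  if (include_7mer_1a) {
    # match to seed nt 2-7 (first 6 of the 7-nt seed) plus t1 adenosine,
    # excluding positions already covered by an m8 match
    pat_1a <- paste0(revcomp_dna(substr(seed_dna, 1L, 6L)), "A")
    m8_base <- chartr("ACGT", "TGCA", substr(seed_dna, 7L, 7L))
    u2 <- unlist(Biostrings::vmatchPattern(pat_1a, subject))
    if (length(u2) > 0) {
      gene <- names(u2)
      s1 <- Biostrings::start(u2)
      prev <- substr(seqs[match(gene, ids)], s1 - 1L, s1 - 1L)
      keep <- prev != m8_base # m8-paired occurrences are 8mers, not 7mer-1A
      if (any(keep)) {
        hits <- bind_rows(hits, tibble(
          gene_id = gene[keep],
          start = s1[keep] - 1L,
          end = s1[keep] + 6L,
          site_type = "7mer-1A"
        ))
      }
    }
  }
  arrange(hits, .data$gene_id, .data$start)
}

#' Find seed-complementary sites of one miRNA seed in one 3'UTR
#'
#' Scans the UTR sense strand for exact reverse complements of the seed
#' (U and T are equivalent); every occurrence is reported and overlapping
#' occurrences each count. Coordinates are 0-based half-open.
#'
#' @param seed 7-nt seed (RNA or DNA alphabet).
#' @param utr_sequence One UTR sequence (DNA alphabet).
#' @param include_7mer_1a Also report 7mer-1A sites (match to seed
#'   nucleotides 2-7 plus a t1 adenosine). Off by default: the canonical
#'   criterion is full 2-8 seed complementarity.
#' @return A tibble `start`, `end`, `site_type` (`7mer-m8`, `8mer`, or
#'   `7mer-1A`); empty if the UTR is shorter than 7 nt.
#' @examples
#' find_sites("CGGUUAA", "AAATTAACCGTT")
#' @export
find_sites <- function(seed, utr_sequence, include_7mer_1a = FALSE) {
  if (nchar(seed) != 7L) abort("`seed` must be exactly 7 nt.")
  if (nchar(utr_sequence) < 7L) {
    return(tibble(start = integer(0), end = integer(0),
                  site_type = character(0)))
  }
  scan_seed_sites(seed, utr_sequence, "utr", include_7mer_1a) |>
    select("start", "end", "site_type")
}

#' Predict miRNA targets across a representative 3'UTR set
#'
#' Applies [find_sites()] for every (miRNA, gene) pair. A gene is a predicted
#' target of a miRNA iff it has at least one site of an enabled type.
#'
#' @param mirnas Tibble with columns `name` and `seed` (or `sequence`, from
#'   which seeds are derived).
#' @param utrs Tibble of representative UTRs (`gene_id`, `sequence`), one row
#'   per gene.
#' @param include_7mer_1a Enable the 7mer-1A site class (see [find_sites()]).
#' @return A tibble of class `mirmatch_targets`: one row per site, columns
#'   `mirna`, `gene_id`, `start`, `end`, `site_type`.
#' @seealso [target_pairs()] for the distinct (miRNA, gene) predicate.
#' @export
predict_targets <- function(mirnas, utrs, include_7mer_1a = FALSE) {
  if (nrow(mirnas) == 0 || nrow(utrs) == 0) {
    abort("`mirnas` and `utrs` must be nonempty.")
  }
  if (anyDuplicated(utrs$gene_id)) {
    abort("`utrs` must have one row per gene (duplicate gene_id found).")
  }
  if (!"seed" %in% names(mirnas)) {
    mirnas$seed <- extract_seed(mirnas$sequence)
  }
  nm <- if ("name" %in% names(mirnas)) mirnas$name else mirnas$mirna
  hits <- purrr::map2(nm, mirnas$seed, function(m, s) {
    h <- scan_seed_sites(s, utrs$sequence, utrs$gene_id, include_7mer_1a)
    if (nrow(h) > 0) mutate(h, mirna = m) else NULL
  })
  out <- bind_rows(hits)
  if (nrow(out) == 0) {
    out <- tibble(mirna = character(0), gene_id = character(0),
                  start = integer(0), end = integer(0),
                  site_type = character(0))
  } else {
    out <- select(out, "mirna", "gene_id", "start", "end", "site_type")
  }
  class(out) <- c("mirmatch_targets", class(out))
  out
}

#' Distinct predicted (miRNA, gene) target pairs
#'
#' @param targets Site-level tibble from [predict_targets()].
#' @return A tibble `mirna`, `gene_id`, `n_sites`.
#' @export
target_pairs <- function(targets) {
  targets |>
    as_tibble() |>
    dplyr::count(.data$mirna, .data$gene_id, name = "n_sites")
}
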