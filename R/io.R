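# Readers and writers for the plain-text formats the pipeline exchanges:
# FASTA (mature miRNAs, 3'UTRs), FASTQ (small-RNA reads), and the
# three-column tab-delimited miRNA/UTR files used by seed-match predictors.

#' Read mature miRNA sequences from FASTA
#'
#' Headers are taken up to the first whitespace (miRBase-style `>name desc`).
#' Seeds (nucleotides 2-8) are derived on read.
#'
#' @param path FASTA file of mature miRNA sequences (RNA or DNA alphabet).
#' @return A tibble `name`, `sequence` (RNA), `seed`.
#' @export
read_mirna_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  seqs <- unname(dna_to_rna(as.character(x)))
  nm <- sub("\\s.*$", "", names(x))
  tibble(name = nm, sequence = seqs, seed = extract_seed(seqs))
}

#' Write named sequences to FASTA
#'
#' @param seqs Named character vector, or a tibble with `name`/`gene_id` and
#'   `sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.data.frame(seqs)) {
    nm <- if ("name" %in% names(seqs)) seqs$name else seqs$gene_id
    seqs <- setNames(seqs$sequence, nm)
  }
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read small-RNA reads from FASTQ
#'
#' Qualities are discarded (the downstream pipeline converts FASTQ to FASTA).
#'
#' @param path FASTQ file.
#' @return A tibble `read_id`, `sequence`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble(read_id = sub("\\s.*$", "", names(x)),
         sequence = unname(as.character(x)))
}

#' Write small-RNA reads to FASTQ (constant quality)
#'
#' @param reads Tibble `read_id`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  q <- Biostrings::BStringSet(strrep("I", nchar(reads$sequence)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Write the three-column tab-delimited miRNA file
#'
#' Columns: miRNA name, 7-nt seed (nucleotides 2-8), NCBI taxon id - the
#' input format expected by seed-match target predictors.
#'
#' @param mirnas Tibble with `name` and `seed` columns.
#' @param path Output path.
#' @param taxon_id NCBI taxon id (default 7227, *D. melanogaster*).
#' @return `path`, invisibly.
#' @export
write_mirna_tsv <- function(mirnas, path, taxon_id = 7227L) {
  readr::write_tsv(
    tibble(name = mirnas$name, seed = mirnas$seed, taxon_id = taxon_id),
    path, col_names = FALSE
  )
  invisible(path)
}

#' Write the three-column tab-delimited 3'UTR file
#'
#' Columns: identifier (`gene_id|transcript_id`), NCBI taxon id, UTR
#' sequence.
#'
#' @param utrs Representative UTR tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_utr_tsv <- function(utrs, path) {
  readr::write_tsv(
    tibble(
      id = paste(utrs$gene_id, utrs$transcript_id, sep = "|"),
      taxon_id = utrs$taxon_id,
      sequence = utrs$sequence
    ),
    path, col_names = FALSE
  )
  invisible(path)
}

#' Read the three-column tab-delimited 3'UTR file
#'
#' @param path Path written by [write_utr_tsv()].
#' @return A tibble `gene_id`, `transcript_id`, `taxon_id`, `sequence`,
#'   `length`.
#' @export
read_utr_tsv <- function(path) {
  d <- readr::read_tsv(path, col_names = c("id", "taxon_id", "sequence"),
                       col_types = "cic", progress = FALSE)
  parts <- stringr::str_split_fixed(d$id, stringr::fixed("|"), 2)
  tibble(
    gene_id = parts[, 1],
    transcript_id = parts[, 2],
    taxon_id = as.integer(d$taxon_id),
    sequence = toupper(d$sequence),
    length = nchar(d$sequence)
  )
}
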