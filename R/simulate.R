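# Synthetic-data generator: mature miRNAs, representative 3'UTRs, ground-truth
# target implantation, two-condition replicate expression, small-RNA reads.
# Every generator draws from a sub-stream derived from cfg$rng_seed, so the
# full study is byte-identical across reruns of the same configuration.

#' Generate a set of mature miRNAs
#'
#' Names carry `-5p`/`-3p` arm suffixes in pairs (the two single-stranded
#' products of one pre-miRNA hairpin); an odd count leaves the last hairpin
#' with only a 5p arm. Sequences are 21-23 nt over the RNA alphabet, and the
#' canonical 7-nt seed (nucleotides 2-8 from the 5' end) is precomputed.
#'
#' @param cfg A [sim_config()].
#' @return A tibble with columns `name`, `sequence` (RNA), `seed` (RNA, 7 nt).
#' @examples
#' generate_mirnas(sim_config(n_mirnas = 4, rng_seed = 1))
#' @export
generate_mirnas <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_mirnas
  hairpin <- rep(seq_len(ceiling(n / 2)), each = 2L)[seq_len(n)]
  arm <- rep(c("5p", "3p"), length.out = n)
  names <- sprintf("sim-miR-%d-%s", hairpin, arm)
  withr::with_seed(derive_seed(cfg$rng_seed, "mirnas"), {
    lens <- sample(21:23, n, replace = TRUE)
    seqs <- random_seqs(lens, RNA_ALPHABET)
  })
  tibble(
    name = names,
    sequence = seqs,
    seed = extract_seed(seqs)
  )
}

#' Generate representative 3'UTR records
#'
#' Lengths are drawn from a log-normal law truncated below at
#' `cfg$utr_min_len` (inverse-CDF truncation, so no rejection loop), rounded
#' to whole nucleotides; sequences are i.i.d. uniform DNA. One record per
#' gene, mirroring a per-gene representative-isoform UTR set.
#'
#' @param cfg A [sim_config()].
#' @return A tibble with columns `gene_id`, `transcript_id`, `taxon_id`,
#'   `sequence`, `length`.
#' @export
generate_utrs <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_genes
  withr::with_seed(derive_seed(cfg$rng_seed, "utrs"), {
    p_min <- plnorm(cfg$utr_min_len, cfg$utr_meanlog, cfg$utr_sdlog)
    u <- runif(n, p_min, 1)
    lens <- as.integer(round(qlnorm(u, cfg$utr_meanlog, cfg$utr_sdlog)))
    lens <- pmax(lens, cfg$utr_min_len)
    seqs <- random_seqs(lens, DNA_ALPHABET)
  })
  tibble(
    gene_id = sprintf("GENE%05d", seq_len(n)),
    transcript_id = sprintf("TX%05d.1", seq_len(n)),
    taxon_id = 7227L,
    sequence = seqs,
    length = lens
  )
}

#' Implant seed-complementary target sites into 3'UTRs
#'
#' For each designated miRNA, a `target_fraction` subset of genes receives one
#' exact reverse-complement seed match, spliced in place (7 nt overwritten at
#' a uniform random position) so UTR lengths are unchanged and downstream
#' length-matching is exercised honestly. Implants never overlap an earlier
#' implant in the same UTR. Background sequence can still harbour chance seed
#' matches; those are intentionally left in place.
#'
#' @param utrs UTR tibble from [generate_utrs()].
#' @param mirnas miRNA tibble from [generate_mirnas()].
#' @param cfg A [sim_config()].
#' @param designated Character vector of miRNA names to implant for; defaults
#'   to the first `cfg$n_de_mirnas` miRNAs.
#' @return A list with elements `utrs` (modified tibble) and `truth`
#'   (tibble `mirna`, `gene_id`: the implanted ground-truth target pairs).
#' @export
implant_sites <- function(utrs, mirnas, cfg, designated = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  designated <- designated %||% head(mirnas$name, cfg$n_de_mirnas)
  if (!all(designated %in% mirnas$name)) {
    abort("All designated miRNAs must be present in `mirnas`.")
  }
  if (any(utrs$length < 7L)) {
    abort("All UTRs must be at least 7 nt to accept a seed match.")
  }
  truth <- list()
  seqs <- utrs$sequence
  occupied <- vector("list", nrow(utrs)) # implanted [start,end] intervals
  n_take <- round(cfg$target_fraction * nrow(utrs))
  withr::with_seed(derive_seed(cfg$rng_seed, "implant"), {
    for (m in designated) {
      site <- revcomp_dna(rna_to_dna(mirnas$seed[mirnas$name == m]))
      idx <- sort(sample.int(nrow(utrs), n_take))
      placed <- logical(length(idx))
      for (j in seq_along(idx)) {
        i <- idx[j]
        L <- utrs$length[i]
        cand <- seq_len(L - 6L)
        if (length(occupied[[i]]) > 0) {
          for (iv in occupied[[i]]) {
            cand <- cand[cand > iv[2] | cand + 6L < iv[1]]
          }
        }
        if (length(cand) == 0L) next # UTR saturated; skip gene
        pos <- cand[sample.int(length(cand), 1L)]
        substr(seqs[i], pos, pos + 6L) <- site
        occupied[[i]] <- c(occupied[[i]], list(c(pos, pos + 6L)))
        placed[j] <- TRUE
      }
      truth[[m]] <- tibble(mirna = m, gene_id = utrs$gene_id[idx[placed]])
    }
  })
  utrs$sequence <- seqs
  truth <- if (length(truth) > 0) bind_rows(truth) else
    tibble(mirna = character(0), gene_id = character(0))
  list(utrs = utrs, truth = truth)
}

#' Simulate replicate-level expression for a two-condition design
#'
#' Baseline per-gene abundance is log-normal. In the mated condition the
#' expected abundance of true targets is shifted on the log2 scale:
#' `-repression_delta` for targets of up-regulated miRNAs (repression by the
#' more abundant miRNA), `+repression_delta` for targets of down-regulated
#' miRNAs (de-repression). Replicates receive independent multiplicative
#' log-normal noise with coefficient of variation `replicate_cv`, mean 1, so
#' `replicate_cv = 0` gives identical replicates.
#'
#' @param truth Ground-truth target tibble (`mirna`, `gene_id`) from
#'   [implant_sites()].
#' @param utrs UTR tibble (supplies the gene universe).
#' @param cfg A [sim_config()].
#' @param mirna_directions Tibble (`mirna`, `direction`) for the designated
#'   miRNAs; defaults to `cfg$de_direction` recycled over the truth miRNAs.
#' @return A tibble `gene_id`, `condition` (`"virgin"`/`"mated"`),
#'   `replicate`, `tpm`.
#' @export
generate_expression <- function(truth, utrs, cfg, mirna_directions = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!all(truth$gene_id %in% utrs$gene_id)) {
    abort("`truth` refers to genes absent from `utrs`.")
  }
  if (is.null(mirna_directions)) {
    mir <- unique(truth$mirna)
    mirna_directions <- tibble(
      mirna = mir,
      direction = rep(cfg$de_direction, length.out = length(mir))
    )
  }
  genes <- utrs$gene_id
  shift <- gene_shifts(truth, mirna_directions, genes, cfg$repression_delta)

  n <- length(genes)
  sdlog_rep <- sqrt(log(1 + cfg$replicate_cv^2))
  withr::with_seed(derive_seed(cfg$rng_seed, "expression"), {
    base <- rlnorm(n, cfg$tpm_meanlog, cfg$tpm_sdlog)
    out <- vector("list", 2L * cfg$n_replicates)
    k <- 0L
    for (cond in c("virgin", "mated")) {
      mu <- if (cond == "mated") base * 2^shift else base
      for (r in seq_len(cfg$n_replicates)) {
        noise <- if (cfg$replicate_cv == 0) rep(1, n) else
          rlnorm(n, -sdlog_rep^2 / 2, sdlog_rep)
        k <- k + 1L
        out[[k]] <- tibble(
          gene_id = genes, condition = cond, replicate = r,
          tpm = mu * noise
        )
      }
    }
  })
  bind_rows(out)
}

# Expected log2 shift per gene in the mated condition: -delta if targeted by
# any up-direction miRNA, +delta if by any down-direction miRNA, net 0 if both.
gene_shifts <- function(truth, mirna_directions, genes, delta) {
  shift <- setNames(numeric(length(genes)), genes)
  if (nrow(truth) == 0 || delta == 0) return(shift)
  tt <- left_join(truth, mirna_directions, by = "mirna")
  up_genes <- unique(tt$gene_id[tt$direction == "up"])
  down_genes <- unique(tt$gene_id[tt$direction == "down"])
  shift[up_genes] <- shift[up_genes] - delta
  shift[down_genes] <- shift[down_genes] + delta
  shift
}

#' Generate adapter-ligated small-RNA reads
#'
#' Each read is a 5'-anchored prefix of a mature miRNA (insert length drawn
#' from `cfg$insert_lengths`, capped at the mature length, so insert lengths
#' peak at 22-23 nt as in typical miRNA libraries), followed by the 3'
#' adapter, padded with the adapter sequence recycled and truncated to the
#' sequencer read length. Exactly `abundances[m]` reads are emitted per miRNA.
#'
#' @param mirnas miRNA tibble from [generate_mirnas()].
#' @param abundances Named integer vector of read counts per miRNA name.
#' @param cfg A [sim_config()].
#' @return A tibble `read_id`, `sequence` (DNA, `cfg$read_length` nt).
#' @export
generate_srna_reads <- function(mirnas, abundances, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(abundances) == 0) {
    return(tibble(read_id = character(0), sequence = character(0)))
  }
  if (is.null(names(abundances)) || !all(names(abundances) %in% mirnas$name)) {
    abort("`abundances` must be named by miRNA names present in `mirnas`.")
  }
  if (any(abundances < 0) || any(abundances != trunc(abundances))) {
    abort("`abundances` must be nonnegative integers.")
  }
  pad <- strrep(cfg$adapter, ceiling(cfg$read_length / nchar(cfg$adapter)) + 1L)
  withr::with_seed(derive_seed(cfg$rng_seed, "reads"), {
    out <- purrr::imap(abundances[abundances > 0], function(cnt, m) {
      mat <- rna_to_dna(mirnas$sequence[mirnas$name == m])
      ins_len <- pmin(sample(cfg$insert_lengths, cnt, replace = TRUE),
                      nchar(mat))
      inserts <- substring(mat, 1L, ins_len)
      tibble(
        mirna = m,
        sequence = substring(paste0(inserts, pad), 1L, cfg$read_length)
      )
    })
  })
  reads <- bind_rows(out)
  if (nrow(reads) == 0) {
    return(tibble(read_id = character(0), sequence = character(0)))
  }
  tibble(
    read_id = sprintf("read_%06d_%s", seq_len(nrow(reads)), reads$mirna),
    sequence = reads$sequence
  )
}

#' Simulate a complete synthetic miRNA study
#'
#' Runs all generators in order and assembles the study: mature miRNAs,
#' implanted representative 3'UTRs, ground-truth target table, direction
#' labels for the designated differentially expressed miRNAs, ground-truth
#' differential-expression labels for genes (derived from the implanted
#' shifts), and the replicate-level expression table.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `mirmatch_sim`: a list with elements `mirnas`,
#'   `utrs`, `truth`, `de_mirnas`, `de_genes`, `expression`, `config`.
#' @examples
#' sim <- simulate_mirna_study(sim_config(n_genes = 200, rng_seed = 1))
#' names(sim)
#' @export
simulate_mirna_study <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  mirnas <- generate_mirnas(cfg)
  utrs0 <- generate_utrs(cfg)
  imp <- implant_sites(utrs0, mirnas, cfg)
  de_mirnas <- tibble(
    mirna = head(mirnas$name, cfg$n_de_mirnas),
    direction = rep(cfg$de_direction, length.out = cfg$n_de_mirnas)
  )
  expr <- generate_expression(imp$truth, imp$utrs, cfg, de_mirnas)
  shift <- gene_shifts(imp$truth, de_mirnas, imp$utrs$gene_id,
                       cfg$repression_delta)
  de_genes <- tibble(
    gene_id = imp$utrs$gene_id,
    direction = dplyr::case_when(shift < 0 ~ "down",
                                 shift > 0 ~ "up",
                                 TRUE ~ "ns")
  ) |> filter(.data$direction != "ns")
  structure(
    list(
      mirnas = mirnas, utrs = imp$utrs, truth = imp$truth,
      de_mirnas = de_mirnas, de_genes = de_genes,
      expression = expr, config = cfg
    ),
    class = "mirmatch_sim"
  )
}

#' @export
print.mirmatch_sim <- function(x, ...) {
  cat(sprintf(
    "<mirmatch_sim> %d genes, %d miRNAs (%d DE), %d implanted target pairs\n",
    nrow(x$utrs), nrow(x$mirnas), nrow(x$de_mirnas), nrow(x$truth)
  ))
  invisible(x)
}
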