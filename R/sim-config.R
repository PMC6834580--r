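#' Configuration for the synthetic miRNA study generator
#'
#' Bundles every tunable of the simulator with validation. The defaults
#' emulate the structure of a mating-response small-RNA/mRNA study in
#' *Drosophila*: a heavy-tailed 3'UTR length distribution, a handful of
#' differentially expressed miRNAs whose targets are repressed in the mated
#' condition, two biological replicates per condition, and adapter-ligated
#' small-RNA reads with insert lengths peaking at 22-23 nt.
#'
#' @param n_genes Number of genes (one representative 3'UTR each).
#' @param n_mirnas Number of mature miRNAs; named in -5p/-3p pairs.
#' @param n_de_mirnas Number of designated differentially expressed miRNAs
#'   (the first `n_de_mirnas` miRNAs); these receive implanted target sites
#'   and a direction label.
#' @param de_direction Direction label(s) for the designated miRNAs,
#'   `"up"` or `"down"`, recycled to `n_de_mirnas`.
#' @param utr_meanlog,utr_sdlog Log-normal parameters of the 3'UTR length
#'   law (defaults: median 500 nt, sigma on the log scale 1).
#' @param utr_min_len Lower truncation of the UTR length law, nt.
#' @param target_fraction Fraction of genes implanted with at least one seed
#'   site per designated miRNA, in `[0, 1]`.
#' @param repression_delta Log2-fold-change shift (>= 0) applied in the mated
#'   condition to true targets: targets of "up" miRNAs are shifted by
#'   `-repression_delta` (repression), targets of "down" miRNAs by
#'   `+repression_delta` (de-repression).
#' @param tpm_meanlog,tpm_sdlog Log-normal parameters of baseline gene
#'   abundance (TPM-like units).
#' @param replicate_cv Coefficient of variation of the multiplicative
#'   replicate noise (0 = identical replicates).
#' @param n_replicates Biological replicates per condition.
#' @param adapter 3' sequencing adapter ligated to every small-RNA read.
#' @param read_length Sequencer read length, nt.
#' @param insert_lengths Candidate insert lengths for small-RNA reads;
#'   each read uses a prefix of the mature miRNA of one of these lengths
#'   (capped at the mature length).
#' @param rng_seed Integer master seed; every stochastic step derives its own
#'   sub-stream from it, so outputs are byte-identical across reruns.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [simulate_mirna_study()]
#' @examples
#' cfg <- sim_config(n_genes = 200, n_mirnas = 4, rng_seed = 1)
#' cfg$target_fraction
#' @export
sim_config <- function(n_genes = 2000,
                       n_mirnas = 10,
                       n_de_mirnas = 2,
                       de_direction = "up",
                       utr_meanlog = log(500),
                       utr_sdlog = 1,
                       utr_min_len = 30,
                       target_fraction = 0.3,
                       repression_delta = 1,
                       tpm_meanlog = 2,
                       tpm_sdlog = 1.5,
                       replicate_cv = 0.2,
                       n_replicates = 2,
                       adapter = "TGGAATTCTCGGGTGCCAAGG",
                       read_length = 50,
                       insert_lengths = c(22, 23),
                       rng_seed = 1) {
  assert_count(n_genes, "n_genes")
  assert_count(n_mirnas, "n_mirnas")
  assert_count(n_replicates, "n_replicates")
  assert_count(read_length, "read_length")
  if (!is.numeric(n_de_mirnas) || n_de_mirnas < 0 || n_de_mirnas > n_mirnas) {
    abort("`n_de_mirnas` must be between 0 and `n_mirnas`.")
  }
  de_direction <- match.arg(de_direction, c("up", "down"), several.ok = TRUE)
  if (!is.numeric(target_fraction) || target_fraction < 0 || target_fraction > 1) {
    abort("`target_fraction` must lie in [0, 1].")
  }
  if (!is.numeric(repression_delta) || repression_delta < 0) {
    abort("`repression_delta` must be >= 0.")
  }
  if (!is.numeric(replicate_cv) || replicate_cv < 0) {
    abort("`replicate_cv` must be >= 0.")
  }
  if (!is.numeric(utr_min_len) || utr_min_len < 7) {
    abort("`utr_min_len` must be at least the seed-match length (7 nt).")
  }
  if (!is_string(adapter) || nchar(adapter) < 8 ||
      !grepl("^[ACGT]+$", adapter)) {
    abort("`adapter` must be a DNA string of at least 8 nt.")
  }
  if (!is.numeric(insert_lengths) || any(insert_lengths < 1)) {
    abort("`insert_lengths` must be positive.")
  }
  assert_count(rng_seed %% 2147483647, "rng_seed")

  structure(
    list(
      n_genes = as.integer(n_genes),
      n_mirnas = as.integer(n_mirnas),
      n_de_mirnas = as.integer(n_de_mirnas),
      de_direction = de_direction,
      utr_meanlog = utr_meanlog,
      utr_sdlog = utr_sdlog,
      utr_min_len = as.integer(utr_min_len),
      target_fraction = target_fraction,
      repression_delta = repression_delta,
      tpm_meanlog = tpm_meanlog,
      tpm_sdlog = tpm_sdlog,
      replicate_cv = replicate_cv,
      n_replicates = as.integer(n_replicates),
      adapter = adapter,
      read_length = as.integer(read_length),
      insert_lengths = as.integer(insert_lengths),
      rng_seed = as.integer(rng_seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-17s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}

#' Read a simulator configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys fall back to [sim_config()]
#' defaults.
#'
#' @param path Path to a YAML file whose keys are `sim_config()` arguments.
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    abort(sprintf("Unknown sim_config keys in %s: %s",
                  path, paste(bad, collapse = ", ")))
  }
  do.call(sim_config, vals)
}
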