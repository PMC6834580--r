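# Independent oracles and small fixture builders shared across tests.

# Brute-force sliding-window seed-site scanner: the reference against which
# find_sites() is checked. 0-based half-open coordinates, like find_sites().
oracle_sites <- function(seed, utr) {
  seed_dna <- chartr("Uu", "TT", toupper(seed))
  comp <- chartr("ACGT", "TGCA", seed_dna)
  rc <- paste(rev(strsplit(comp, "")[[1]]), collapse = "")
  L <- nchar(utr)
  if (L < 7) {
    return(data.frame(start = integer(0), end = integer(0),
                      site_type = character(0)))
  }
  starts <- seq_len(L - 6)                       # every window, 1-based
  windows <- substring(utr, starts, starts + 6)
  p <- starts[windows == rc]
  if (length(p) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      site_type = character(0)))
  }
  is8 <- substring(utr, p + 7, p + 7) == "A"     # "" when past the end
  data.frame(
    start = p - 1L,
    end = ifelse(is8, p + 7L, p + 6L),
    site_type = ifelse(is8, "8mer", "7mer-m8")
  )
}

# Exhaustive hypergeometric tail: P(top-left >= a) over all 2x2 tables with
# the observed margins.
oracle_fisher <- function(a, b, cc, d) {
  r1 <- a + b; c1 <- a + cc; n <- a + b + cc + d
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x) {
    choose(c1, x) * choose(n - c1, r1 - x) / choose(n, r1)
  }, numeric(1))
  sum(probs[(lo:hi) >= a])
}

# Sup of one-sided ECDF difference on a fine grid of pooled points.
oracle_ks_d <- function(x, y, alternative) {
  pts <- sort(unique(c(x, y)))
  fx <- ecdf(x)(pts); fy <- ecdf(y)(pts)
  if (alternative == "greater") max(c(fx - fy, 0)) else max(c(fy - fx, 0))
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

small_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_genes = 200, n_mirnas = 4, n_de_mirnas = 2,
                   target_fraction = 0.3, rng_seed = 42)
  do.call(sim_config, utils::modifyList(defaults, args))
}
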