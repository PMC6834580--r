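# Internal helpers shared across the package: seeded sub-stream derivation,
# nucleotide alphabet conversions, random sequence generation.

DNA_ALPHABET <- c("A", "C", "G", "T")
RNA_ALPHABET <- c("A", "C", "G", "U")

#' Derive a reproducible sub-seed from a master seed and a string key
#'
#' Different pipeline stages (and different resampling repetitions) draw from
#' independent, reproducible RNG streams derived from one master seed, so the
#' result of any stage does not depend on how many random numbers an earlier
#' stage consumed. The derivation is a small multiplicative hash kept within
#' the 32-bit integer range that `set.seed()` accepts.
#'
#' @param seed Integer master seed.
#' @param key Character scalar naming the stream (e.g. `"utrs"`, `"rep007"`).
#' @return An integer in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key))
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- (as.double(seed) %% m)
  for (code in utf8ToInt(key)) {
    h <- (h * 48271 + code) %% m
  }
  as.integer(h)
}

# U -> T (case-insensitive input is uppercased first)
rna_to_dna <- function(x) chartr("Uu", "TT", toupper(x))

# T -> U
dna_to_rna <- function(x) chartr("Tt", "UU", toupper(x))

# Reverse complement of DNA strings (vectorised over character vector).
revcomp_dna <- function(x) {
  comp <- chartr("ACGT", "TGCA", toupper(x))
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

# n random nucleotide strings of the given lengths over the given alphabet.
random_seqs <- function(lengths, alphabet = DNA_ALPHABET) {
  total <- sum(lengths)
  if (total == 0L) return(character(0))
  codes <- utf8ToInt(paste(alphabet, collapse = ""))
  big <- intToUtf8(codes[sample.int(length(alphabet), total, replace = TRUE)])
  stops <- cumsum(lengths)
  starts <- c(1L, head(stops, -1L) + 1L)
  substring(big, starts, stops)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

assert_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != trunc(x)) {
    abort(sprintf("`%s` must be a single positive integer.", name))
  }
}
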