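#' @useDynLib soxyprof, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats sd rbinom runif chisq.test
#' @importFrom utils write.table read.delim head tail
NULL

# 20-letter amino-acid alphabet used throughout; code 21 is the neutral
# "unknown" slot (scores 0 against everything).
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Encode a protein string as integer residue codes
#'
#' Codes are indices into the package alphabet (`A`=1 ... `Y`=20); any other
#' character (including `X`) maps to the neutral code 21.
#' @param seq single protein string.
#' @return integer vector of codes.
#' @keywords internal
encode_seq <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  codes <- match(chars, AA_ALPHABET)
  codes[is.na(codes)] <- 21L
  codes
}

decode_seq <- function(codes) {
  paste(c(AA_ALPHABET, "X")[codes], collapse = "")
}

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so library calls never perturb
#' user-level streams.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

# Deterministic child seed derivation, kept below 2^31 (double arithmetic
# is exact here since seed * 1009 < 2^53).
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(k) * 97) %% 2147483587)
}

# BLOSUM62 padded with a neutral 21st row/column for unknown residues,
# ordered to match the package alphabet. Cached after first use.
.soxy_env <- new.env(parent = emptyenv())

blosum62_matrix <- function() {
  if (is.null(.soxy_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    b <- e$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
    out <- matrix(0, 21, 21)
    out[1:20, 1:20] <- b
    .soxy_env$blosum62 <- out
  }
  .soxy_env$blosum62
}

# Background amino-acid frequencies (uniform by default).
uniform_background <- function() {
  stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
}

#' Uniformly shuffle a protein sequence
#'
#' Fisher-Yates permutation of the residues: same length and composition,
#' positional signal destroyed. The standard decoy null for score
#' calibration.
#' @param seq protein string, length >= 1.
#' @param seed integer seed.
#' @return shuffled protein string.
#' @export
#' @examples
#' shuffle_sequence("MKVTIGGC", seed = 1)
shuffle_sequence <- function(seq, seed) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) >= 1L)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  with_seed(seed, paste(sample(chars), collapse = ""))
}

# Random protein from given background composition (i.i.d. residues).
random_protein <- function(len, background = uniform_background()) {
  paste(sample(AA_ALPHABET, len, replace = TRUE, prob = background),
        collapse = "")
}

# Stable TSV writers: fixed column order, "\n" line endings, no quoting of
# plain fields, so byte-identical reruns under a fixed seed.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
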