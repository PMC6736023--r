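# Shared constants and small helpers.

# The 20 standard amino acids, one-letter code, alphabetical.
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Ambiguity / non-standard letters excluded from hexamer matching.
AA_AMBIGUOUS <- c("B", "J", "O", "U", "X", "Z")

#' Background amino-acid composition
#'
#' Average residue frequencies of well-annotated protein sequence space
#' (UniProtKB/Swiss-Prot release statistics, rounded), normalized to sum to
#' one. Used as the default background for the Q-repeat log-odds fingerprint;
#' any strictly positive composition summing to one can be supplied instead.
#'
#' @return Named numeric vector over the 20 standard residues, summing to 1.
#' @export
#' @examples
#' sum(uniprot_background())
uniprot_background <- function() {
  f <- c(A = 8.25, C = 1.38, D = 5.46, E = 6.72, F = 3.86,
         G = 7.07, H = 2.27, I = 5.91, K = 5.80, L = 9.65,
         M = 2.41, N = 4.06, P = 4.74, Q = 3.93, R = 5.53,
         S = 6.64, T = 5.35, V = 6.86, W = 1.10, Y = 2.92)
  f / sum(f)
}

# Evaluate `expr` with a temporary RNG state seeded from `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# scalar character / numeric argument checks
assert_string <- function(x, name = deparse(substitute(x))) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single string", name), call. = FALSE)
  }
  x
}

assert_number <- function(x, name = deparse(substitute(x)),
                          lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      x < lower || x > upper) {
    stop(sprintf("'%s' must be a number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  x
}

# split a sequence string into a character vector of residues
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]
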