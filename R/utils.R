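# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement a nucleotide string
#'
#' Vectorised over its input; `N` maps to `N`.
#'
#' @param x character vector of sequences over `{A,C,G,T,N}`.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  .revcomp_cpp(as.character(x))
}

# Run `code` under a fixed RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# Draw one random sequence of length `n`.
random_seq <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# All k-mers of `seq` (character scalar), optionally strided.
seq_kmers <- function(seq, k, stride = 1L) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  starts <- seq.int(1L, n - k + 1L, by = stride)
  substring(seq, starts, starts + k - 1L)
}

# sample() without the length-1 surprise: always samples from `x` itself.
safe_sample <- function(x, size = length(x), replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

# stopifnot() with a formatted message.
abort_if <- function(cond, msg, ...) {
  if (cond) stop(sprintf(msg, ...), call. = FALSE)
  invisible(NULL)
}

# Deterministic text formatting for numeric artifact columns, so pipeline
# outputs are byte-stable across runs.
fmt_num <- function(x, digits = 6) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "g"))
}
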