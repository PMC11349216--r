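#' Reverse complement of a DNA string
#'
#' Vectorised over its input. The alphabet is restricted to \code{A, C, G, T,
#' N}; \code{N} complements to \code{N}. Sequences are plain character
#' strings throughout the package, always stored 5'->3' on the sense (top)
#' strand.
#'
#' @param seq character vector of DNA strings (may be empty strings).
#' @return character vector of the same length with each element reverse
#'   complemented.
#' @examples
#' reverse_complement("AGGGTCAGTAAGCACCCGCG")
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq))
  bad <- regexpr("[^ACGTN]", seq)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("non-DNA character '%s' at position %d of sequence %d",
                 substr(seq[i], bad[i], bad[i]), bad[i], i))
  }
  out <- chartr("ACGTN", "TGCAN", seq)
  vapply(out, function(s) {
    if (nchar(s) == 0L) return("")
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# Normalize an input sequence: uppercase, RNA U -> DNA T.
normalize_dna <- function(seq, allow_n = FALSE) {
  s <- chartr("u", "t", toupper(seq))
  s <- chartr("U", "T", s)
  pat <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  bad <- regexpr(pat, s)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("invalid character '%s' at position %d after U->T normalization",
                 substr(s[i], bad[i], bad[i]), bad[i]))
  }
  s
}

# Hamming distance between equal-length strings (no N special-casing).
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  if (nchar(a) == 0L) return(0L)
  sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
}

# Random DNA of given lengths using the session RNG.
random_dna <- function(n, len) {
  bases <- c("A", "C", "G", "T")
  vapply(seq_len(n), function(i) {
    paste(sample(bases, len, replace = TRUE), collapse = "")
  }, character(1L))
}

# Substring by 0-based half-open interval.
substr0 <- function(s, start, end) {
  if (end <= start) return("")
  substr(s, start + 1L, end)
}
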