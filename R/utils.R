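#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the `{A,C,G,T,N}` alphabet. `N`
#' complements to `N`.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
#' @examples
#' dna_revcomp("ACGTN")
dna_revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Complement (no reversal) of DNA strings
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @keywords internal
dna_comp <- function(x) chartr("ACGTN", "TGCAN", x)

# Normalise user-supplied sequence input: uppercase DNA, RNA U -> T.
norm_dna <- function(x) chartr("U", "T", toupper(x))

# Validate that sequences use only A/C/G/T/N; report first offender.
check_alphabet <- function(x, what = "sequence") {
  bad <- regexpr("[^ACGTN]", x)
  hit <- which(bad > 0L)
  if (length(hit)) {
    stop(sprintf("invalid character '%s' in %s %d at position %d",
                 substr(x[hit[1]], bad[hit[1]], bad[hit[1]]),
                 what, hit[1], bad[hit[1]]), call. = FALSE)
  }
  invisible(x)
}

# Stable utility: random DNA string(s) from the current RNG stream.
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}
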