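#' Residue alphabets
#'
#' `aa_alphabet()` returns the 20 canonical amino-acid one-letter codes;
#' `dna_alphabet()` the four nucleotide letters. Both are in fixed
#' lexicographic order so that vocabulary enumeration and tie-breaking are
#' deterministic.
#'
#' @return A character vector of single-letter symbols.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' @rdname aa_alphabet
#' @export
dna_alphabet <- function() c("A", "C", "G", "T")

# Conventional closest-canonical mapping for ambiguity/rare codes.
# X is intentionally absent: it has no nearest residue.
.noncanonical_map <- c(B = "D", Z = "E", J = "L", U = "C", O = "K")

#' Alphabet policy for n-gram counting
#'
#' Bundles the residue alphabet with the rule applied to symbols outside it.
#' The policy is applied at counting time, not at FASTA parsing time, so the
#' same parsed proteome can be recounted under different policies.
#'
#' @param alphabet Character vector of distinct single-character symbols
#'   (default: the 20 canonical amino acids).
#' @param noncanonical One of `"drop_ngram"` (default; any counting window
#'   containing an out-of-alphabet symbol is skipped), `"map_to_nearest"`
#'   (B>D, Z>E, J>L, U>C, O>K before counting; windows containing X or other
#'   unmappable symbols are still skipped), or `"keep"` (out-of-alphabet
#'   symbols participate in windows verbatim).
#'
#' @return An object of class `alphabet_policy`.
#' @export
alphabet_policy <- function(alphabet = aa_alphabet(),
                            noncanonical = c("drop_ngram", "map_to_nearest", "keep")) {
  noncanonical <- match.arg(noncanonical)
  alphabet <- as.character(alphabet)
  if (length(alphabet) < 2L || anyDuplicated(alphabet) ||
      any(nchar(alphabet) != 1L)) {
    plm_abort("`alphabet` must contain >= 2 distinct single-character symbols.",
              "plm_param_error")
  }
  structure(
    list(alphabet = sort(alphabet), noncanonical = noncanonical),
    class = "alphabet_policy"
  )
}

#' @export
print.alphabet_policy <- function(x, ...) {
  cat("<alphabet_policy> |A| =", length(x$alphabet),
      paste0("[", paste(x$alphabet, collapse = ""), "]"),
      "noncanonical =", x$noncanonical, "\n")
  invisible(x)
}

#' Number of possible distinct n-grams
#'
#' For an alphabet of size `|A|` there are `|A|^n` possible n-grams.
#'
#' @param policy An [alphabet_policy()].
#' @param n N-gram order (positive integer).
#' @return `|A|^n` as a double (exact for all practical sizes).
#' @export
vocabulary_size <- function(policy, n) {
  check_order(n)
  length(policy$alphabet)^n
}

check_order <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n != floor(n)) {
    plm_abort("`n` must be a single positive integer.", "plm_param_error")
  }
  invisible(as.integer(n))
}
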