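#' RNA sequences
#'
#' An `rna_sequence` is an identified RNA string over the alphabet
#' `A`, `C`, `G`, `U`, `N`, with 1-based positions.  `T`/`t` in the input is
#' transliterated to `U` and lowercase letters are uppercased, so DNA-style
#' FASTA records are accepted transparently.
#'
#' @param residues A single string of residues.
#' @param id Sequence identifier.
#' @return An object of class `rna_sequence` with fields `id`, `residues`
#'   and `length`.
#' @examples
#' x <- rna_sequence("GGGAAACCC", id = "hairpin9")
#' x$length
#' @export
rna_sequence <- function(residues, id = "seq") {
  if (!is.character(residues) || length(residues) != 1L || is.na(residues)) {
    abort("`residues` must be a single string.")
  }
  res <- chartr("acgutT", "ACGUUU", residues)
  bad <- regexpr("[^ACGUN]", res)
  if (bad > 0L) {
    abort(sprintf(
      "illegal residue '%s' at position %d in sequence '%s'",
      substr(res, bad, bad), bad, id
    ), class = "hybridfold_residue_error")
  }
  if (nchar(res) < 1L) abort("sequence must have length >= 1")
  structure(
    list(id = as.character(id), residues = res, length = nchar(res)),
    class = "rna_sequence"
  )
}

#' @export
print.rna_sequence <- function(x, ...) {
  cat(sprintf("<rna_sequence> %s (L = %d)\n", x$id, x$length))
  cat(x$residues, "\n")
  invisible(x)
}

#' @rdname rna_sequence
#' @param x Object to coerce (string or `rna_sequence`).
#' @export
as_rna_sequence <- function(x, id = "seq") {
  if (inherits(x, "rna_sequence")) return(x)
  rna_sequence(x, id = id)
}

# residues as integer codes 1..5 for A,C,G,U,N (internal; PAD never occurs
# at the R level, sequences are handled one at a time)
seq_codes <- function(x) {
  x <- as_rna_sequence(x)
  match(strsplit(x$residues, "", fixed = TRUE)[[1]], c("A", "C", "G", "U", "N"))
}

# canonical base-pair lookup: 6 pairs AU, UA, CG, GC, GU, UG
CANONICAL_PAIRS <- c("AU", "UA", "CG", "GC", "GU", "UG")

is_canonical <- function(a, b) paste0(a, b) %in% CANONICAL_PAIRS

residue_at <- function(x, i) substr(x$residues, i, i)
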