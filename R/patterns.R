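# IUPAC pattern utilities shared by every counting stage.
#
# Internally bases are coded A=1, C=2, G=3, T=4; code 5 stands for N (or any
# ambiguity letter in a *genome*, which matches nothing when counting).

.BASES <- c("A", "C", "G", "T")

# per-letter sets of concrete bases (subset of .BASES)
.IUPAC_SETS <- local({
  m <- strsplit(Biostrings::IUPAC_CODE_MAP, "")
  names(m) <- names(Biostrings::IUPAC_CODE_MAP)
  m
})

.IUPAC_LETTERS <- names(.IUPAC_SETS)

#' Validate an IUPAC oligomer pattern
#'
#' @param pattern Single character string over the IUPAC alphabet
#'   (`A C G T R Y S W K M B D H V N`).
#' @return The pattern, uppercased, invisibly usable downstream.
#' @keywords internal
check_pattern <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || is.na(pattern) ||
      nchar(pattern) == 0L) {
    stop("pattern must be a single non-empty character string", call. = FALSE)
  }
  pattern <- toupper(pattern)
  letters <- strsplit(pattern, "")[[1]]
  bad <- !(letters %in% .IUPAC_LETTERS)
  if (any(bad)) {
    stop(sprintf("invalid IUPAC letter '%s' at position %d of pattern '%s'",
                 letters[which(bad)[1]], which(bad)[1], pattern),
         call. = FALSE)
  }
  pattern
}

# list of integer code vectors (one per pattern position)
pattern_sets <- function(pattern) {
  pattern <- check_pattern(pattern)
  lapply(strsplit(pattern, "")[[1]], function(l) {
    match(.IUPAC_SETS[[l]], .BASES)
  })
}

#' Reverse complement of an IUPAC pattern
#'
#' Standard IUPAC complementation (R<->Y, K<->M, S, W and N map to
#' themselves), then reversal, so that degenerate patterns such as `RCCGGY`
#' are handled correctly.
#'
#' @param pattern IUPAC pattern string.
#' @return The reverse-complement pattern string.
#' @examples
#' reverse_complement("GCGATCGC")  # palindromic: unchanged
#' reverse_complement("CAGGCGCC")
#' @export
reverse_complement <- function(pattern) {
  pattern <- check_pattern(pattern)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(pattern)))
}

#' Expand a degenerate pattern into its concrete oligomers
#'
#' @param pattern IUPAC pattern string.
#' @return Character vector of all concrete `A/C/G/T` oligomers the pattern
#'   matches; its length is the product of the per-position code sizes.
#' @examples
#' expand_pattern("RCCGGY")  # 4 expansions
#' @export
expand_pattern <- function(pattern) {
  sets <- lapply(strsplit(check_pattern(pattern), "")[[1]],
                 function(l) .IUPAC_SETS[[l]])
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
  apply(grid[, rev(seq_along(sets)), drop = FALSE], 1L, paste0, collapse = "")
}

#' Degeneracy of a pattern
#'
#' @param pattern IUPAC pattern string.
#' @return Integer: number of concrete oligomers matched.
#' @export
pattern_degeneracy <- function(pattern) {
  sets <- pattern_sets(pattern)
  as.integer(prod(vapply(sets, length, 1L)))
}

#' Is a pattern a DNA palindrome?
#'
#' A pattern is palindromic when it equals its IUPAC reverse complement
#' (e.g. `GCGATCGC`, `RCCGGY`).
#'
#' @param pattern IUPAC pattern string.
#' @return Logical.
#' @export
is_palindromic <- function(pattern) {
  pattern <- check_pattern(pattern)
  identical(pattern, reverse_complement(pattern))
}

# complement of a single concrete base ("A" -> "T", ...)
complement_base <- function(base) {
  c(A = "T", C = "G", G = "C", T = "A")[[base]]
}
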