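#' IUPAC nucleotide ambiguity codes
#'
#' The 16-character alphabet accepted throughout the package: the four bases,
#' the eleven IUPAC ambiguity codes, and the gap character `"-"`. Ambiguity
#' codes typically encode electropherogram double peaks from direct
#' sequencing (e.g. co-amplified nuclear mitochondrial pseudogenes, or
#' incompletely homogenised multi-copy nuclear loci).
#'
#' @format A named list mapping each alphabet character to the character
#'   vector of bases it stands for; the gap maps to an empty vector.
#' @export
IUPAC_STATES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"),
  "-" = character(0)
)

# two-fold codes indexed by sorted base pair, used by the simulator
.TWOFOLD_CODE <- c(AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M")

.ALPHABET <- names(IUPAC_STATES)

#' Base states encoded by a single alignment character
#'
#' Expands one character of the IUPAC DNA alphabet to the set of bases it
#' may represent. Plain bases map to themselves, ambiguity codes to their
#' standard sets, `N` to all four bases, and the gap to the empty set
#' (a gap carries no character state).
#'
#' @param char A single character (case-insensitive; `"U"` is accepted and
#'   treated as `"T"`).
#' @return Character vector of bases, possibly empty (for the gap).
#' @examples
#' iupac_states("R")  # A G
#' iupac_states("-")  # character(0)
#' @export
iupac_states <- function(char) {
  if (!is.character(char) || length(char) != 1L || nchar(char) != 1L) {
    stop("`char` must be a single character", call. = FALSE)
  }
  ch <- toupper(char)
  if (ch == "U") ch <- "T"
  states <- IUPAC_STATES[[ch]]
  if (is.null(states)) {
    stop(sprintf("character '%s' is not in the IUPAC DNA alphabet", char),
         call. = FALSE)
  }
  states
}

# TRUE for characters that resolve to exactly one base
.is_determinate <- function(chars) chars %in% c("A", "C", "G", "T")

# uppercase + U->T normalisation for a character vector of residues
.normalise_chars <- function(chars) {
  chars <- toupper(chars)
  chars[chars == "U"] <- "T"
  chars
}
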