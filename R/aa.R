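# Amino-acid alphabet, physicochemical classes and the standard genetic code.

#' The 20-letter amino-acid alphabet
#'
#' One-letter codes for the 20 proteinogenic amino acids, in alphabetical
#' order. All protein contexts, predictor weights and composition analyses in
#' this package are restricted to this alphabet (no stop, no ambiguity codes).
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Physicochemical amino-acid classes
#'
#' Grouping of the 20 amino acids into hydrophobic, polar and charged
#' classes, as used to label slopes in [aa_composition_regression()].
#'
#' @format Named character vector mapping one-letter code to class
#'   (`"hydrophobic"`, `"polar"` or `"charged"`).
#' @export
AA_CLASSES <- c(
  G = "hydrophobic", A = "hydrophobic", P = "hydrophobic", V = "hydrophobic",
  L = "hydrophobic", I = "hydrophobic", M = "hydrophobic", W = "hydrophobic",
  F = "hydrophobic",
  S = "polar", T = "polar", Y = "polar", N = "polar", Q = "polar", C = "polar",
  K = "charged", R = "charged", H = "charged", D = "charged", E = "charged"
)

# DNA bases in the order conventionally used to lay out codon tables.
DNA_BASES <- c("T", "C", "A", "G")

# Standard genetic code, DNA-keyed (T, not U). The 64-character amino-acid
# string follows the conventional layout: first base slowest-varying, bases
# ordered T, C, A, G; "*" marks stop codons.
standard_genetic_code <- function() {
  aas <- strsplit(
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
    ""
  )[[1]]
  codons <- character(64)
  i <- 0L
  for (b1 in DNA_BASES) for (b2 in DNA_BASES) for (b3 in DNA_BASES) {
    i <- i + 1L
    codons[i] <- paste0(b1, b2, b3)
  }
  stats::setNames(aas, codons)
}

GENETIC_CODE_DNA <- standard_genetic_code()

# Validate a string as a (possibly empty) run of one-letter amino acids.
is_aa_string <- function(x) {
  length(x) == 1L && !is.na(x) &&
    (nchar(x) == 0L ||
       all(strsplit(x, "")[[1]] %in% AA_ALPHABET))
}
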