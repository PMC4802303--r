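#' @importFrom methods new validObject is setClass setGeneric setMethod
#'   setValidity representation
NULL

## 20 standard residues, then the terminal-gap symbol '-'.
## Index 22 is the catch-all bucket for nonstandard letters (B, Z, X, U, ...):
## it scores 0 against everything and is excluded from CKSAAP features.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
ALPHABET21 <- c(AA20, "-")
SYM_X <- 22L

.pkg_cache <- new.env(parent = emptyenv())

#' Convert peptides to an integer symbol matrix
#'
#' Each row is one peptide; entries index `ALPHABET21` (1..21), with
#' nonstandard letters mapped to the inert bucket 22.
#'
#' @param peptides character vector of equal-length peptides.
#' @return integer matrix, `length(peptides)` rows.
#' @keywords internal
peptideMatrix <- function(peptides) {
  if (length(peptides) == 0L) {
    return(matrix(integer(0), nrow = 0L, ncol = 0L))
  }
  lens <- nchar(peptides)
  if (length(unique(lens)) != 1L) {
    stop("peptides must all have the same length")
  }
  chars <- strsplit(toupper(peptides), "", fixed = TRUE)
  idx <- match(unlist(chars), ALPHABET21)
  idx[is.na(idx)] <- SYM_X
  matrix(as.integer(idx), nrow = length(peptides), ncol = lens[1L],
         byrow = TRUE)
}

indicesToPeptide <- function(idx) {
  paste0(c(ALPHABET21, "X")[idx], collapse = "")
}

#' The BLOSUM62 substitution table extended to the window alphabet
#'
#' A 22 x 22 integer matrix: the standard 20 x 20 BLOSUM62 block (taken from
#' \pkg{Biostrings}), with the terminal-gap symbol `-` and the nonstandard
#' bucket scoring 0 against everything.
#'
#' @return numeric matrix with dimnames `c(ALPHABET21, "X")`.
#' @examples
#' substitutionMatrix()["Y", "Y"]  # 7, the self-score of tyrosine
#' @export
substitutionMatrix <- function() {
  if (is.null(.pkg_cache$sub)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    b62 <- e$BLOSUM62
    m <- matrix(0, 22L, 22L, dimnames = list(c(ALPHABET21, "X"),
                                             c(ALPHABET21, "X")))
    m[AA20, AA20] <- b62[AA20, AA20]
    .pkg_cache$sub <- m
  }
  .pkg_cache$sub
}
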