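#' Extract a peptide window around a sequence position
#'
#' Returns the `2n + 1`-residue window covering positions `position - n`
#' to `position + n` of the protein, with positions falling outside the
#' sequence replaced by the terminal-gap symbol `-`.
#'
#' @param sequence amino-acid string (a single protein sequence).
#' @param position 1-based position of the candidate site.
#' @param n window half-width.
#' @param strict if `TRUE` (default) require a tyrosine at `position`;
#'   set `FALSE` when scanning arbitrary positions.
#' @return character window of length `2n + 1`.
#' @examples
#' extractWindow("MYACD", 2, 2)  # "-MYAC"
#' @export
extractWindow <- function(sequence, position, n, strict = TRUE) {
  sequence <- toupper(sequence)
  len <- nchar(sequence)
  position <- as.integer(position)
  if (position < 1L || position > len) {
    stop(sprintf("position %d out of range 1..%d", position, len))
  }
  ctr <- substr(sequence, position, position)
  if (strict && ctr != "Y") {
    stop(sprintf("residue at position %d is '%s', not the required 'Y'",
                 position, ctr))
  }
  lo <- position - n
  hi <- position + n
  body <- substr(sequence, max(lo, 1L), min(hi, len))
  paste0(strrep("-", max(0L, 1L - lo)), body, strrep("-", max(0L, hi - len)))
}

#' Pairwise sequence identity of two equal-length windows
#'
#' The fraction of positions at which the two windows carry the same
#' symbol; `-` aligned with `-` counts as a match, and the denominator is
#' always the full window length.
#'
#' @param a,b peptide windows of equal length.
#' @return identity fraction in `[0, 1]`.
#' @export
pairwiseIdentity <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    stop("windows must have equal length for identity computation")
  }
  ca <- strsplit(toupper(a), "", fixed = TRUE)[[1L]]
  cb <- strsplit(toupper(b), "", fixed = TRUE)[[1L]]
  mean(ca == cb)
}

#' Greedy redundancy reduction of a window set
#'
#' Removes windows so that every retained pair has identity below
#' `threshold`. Windows are visited in lexicographic `(protein_id,
#' position)` order (plain peptide order when no provenance columns are
#' given) and a window is dropped if it matches any already-retained
#' window at or above the threshold, making the reduction deterministic.
#'
#' @param windows data.frame with a `peptide` column (and optionally
#'   `protein_id`, `position`), or a character vector of peptides.
#' @param threshold identity threshold; retained pairs satisfy
#'   `identity < threshold`. Default 0.70.
#' @return same type as the input, reduced; input order of the survivors
#'   is not preserved (the documented visiting order is).
#' @export
redundancyReduce <- function(windows, threshold = 0.70) {
  asVector <- is.character(windows)
  df <- if (asVector) {
    data.frame(peptide = windows,
               protein_id = rep("", length(windows)),
               position = seq_along(windows))
  } else {
    windows
  }
  if (nrow(df) == 0L) return(windows[0L])
  if (!"protein_id" %in% names(df)) df$protein_id <- ""
  if (!"position" %in% names(df)) df$position <- seq_len(nrow(df))
  ord <- order(df$protein_id, df$position, df$peptide)
  df <- df[ord, , drop = FALSE]
  mat <- peptideMatrix(df$peptide)
  L <- ncol(mat)
  keep <- integer(0)
  for (i in seq_len(nrow(mat))) {
    if (length(keep) == 0L) {
      keep <- i
      next
    }
    kept <- mat[keep, , drop = FALSE]
    ident <- rowMeans(kept == matrix(mat[i, ], nrow(kept), L, byrow = TRUE))
    if (all(ident < threshold)) keep <- c(keep, i)
  }
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (asVector) out$peptide else out
}

#' Re-window stored peptides to a different length
#'
#' Symmetrically trims a wider window or pads a narrower one with `-` so
#' the center position is preserved. Used when model-specific peptide
#' lengths differ from the stored dataset width.
#'
#' @param peptides character vector of equal odd-length windows.
#' @param n target half-width.
#' @return character vector of `2n + 1`-length windows.
#' @export
rewindowPeptides <- function(peptides, n) {
  if (length(peptides) == 0L) return(peptides)
  L <- nchar(peptides[1L])
  stopifnot(L %% 2L == 1L)
  nOld <- (L - 1L) %/% 2L
  if (n == nOld) return(peptides)
  if (n < nOld) {
    substr(peptides, nOld + 1L - n, nOld + 1L + n)
  } else {
    pad <- strrep("-", n - nOld)
    paste0(pad, peptides, pad)
  }
}
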