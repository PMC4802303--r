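#' Per-position residue composition of a training set
#'
#' Counts, for every position offset (center tyrosine = 0) and every
#' symbol of the 21-letter alphabet (terminal gap `-` included), how many
#' positive and negative windows carry that symbol there.
#'
#' @param train a [SiteTrainingSet-class].
#' @return data.frame with columns `offset`, `residue`, `posCount`,
#'   `negCount`; per (offset, class) the counts sum to the class size.
#' @export
positionComposition <- function(train) {
  n <- halfWidth(train)
  offs <- (-n):n
  cnt <- function(pep) {
    M <- peptideMatrix(pep)
    vapply(seq_len(ncol(M)), function(j) {
      tabulate(M[, j], nbins = 21L)
    }, integer(21L))
  }
  posC <- cnt(positives(train))
  negC <- cnt(negatives(train))
  data.frame(offset = rep(offs, each = 21L),
             residue = rep(ALPHABET21, times = length(offs)),
             posCount = as.integer(posC),
             negCount = as.integer(negC))
}

#' Positional residue enrichment by Fisher's exact test
#'
#' For every (position offset, residue) pair, tests the 2 x 2 table of
#' residue presence/absence against class membership with a two-sided
#' Fisher's exact test, flags `p < alpha` (default 0.01, uncorrected, as
#' is conventional for positional logos), and assigns the direction from
#' the sample odds ratio (over-represented in positives when the
#' positive-class proportion exceeds the negative one).
#'
#' @param train a [SiteTrainingSet-class], or the output of
#'   [positionComposition()].
#' @param alpha significance threshold on the p-value (default 0.01).
#' @param correct `"none"` (default) or `"BH"` for Benjamini-Hochberg
#'   adjustment before flagging.
#' @return data.frame with `offset`, `residue`, the four table cells
#'   (`posWith`, `posWithout`, `negWith`, `negWithout`), `oddsRatio`,
#'   `p`, `direction` (`"over"`/`"under"`), `significant`.
#' @export
fisherEnrichment <- function(train, alpha = 0.01,
                             correct = c("none", "BH")) {
  correct <- match.arg(correct)
  comp <- if (is(train, "SiteTrainingSet")) positionComposition(train)
          else train
  nPos <- sum(comp$posCount[comp$offset == comp$offset[1L]])
  nNeg <- sum(comp$negCount[comp$offset == comp$offset[1L]])
  a <- comp$posCount
  b <- nPos - a
  c_ <- comp$negCount
  d <- nNeg - c_
  p <- numeric(nrow(comp))
  orat <- numeric(nrow(comp))
  for (i in seq_len(nrow(comp))) {
    tab <- matrix(c(a[i], b[i], c_[i], d[i]), 2L)
    if (sum(tab[1L, ]) == 0L || sum(tab[2L, ]) == 0L ||
        (a[i] + c_[i]) == 0L) {
      p[i] <- 1  # degenerate margin: no information
      orat[i] <- 1
    } else {
      p[i] <- stats::fisher.test(tab, alternative = "two.sided")$p.value
      orat[i] <- if (all(tab > 0L)) (a[i] * d[i]) / (b[i] * c_[i]) else
        ((a[i] + 0.5) * (d[i] + 0.5)) / ((b[i] + 0.5) * (c_[i] + 0.5))
    }
  }
  pAdj <- if (correct == "BH") stats::p.adjust(p, "BH") else p
  data.frame(offset = comp$offset, residue = comp$residue,
             posWith = a, posWithout = b, negWith = c_, negWithout = d,
             oddsRatio = orat, p = p,
             direction = ifelse(a / nPos >= c_ / nNeg, "over", "under"),
             significant = pAdj < alpha)
}

#' Write an enrichment report TSV
#'
#' @param enrichment output of [fisherEnrichment()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeEnrichmentReport <- function(enrichment, path) {
  utils::write.table(enrichment, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
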