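## Robinson-Robinson style background amino-acid frequencies.
BG_FREQ <- c(A = 0.078, C = 0.019, D = 0.054, E = 0.063, F = 0.039,
             G = 0.074, H = 0.022, I = 0.051, K = 0.057, L = 0.091,
             M = 0.022, N = 0.045, P = 0.052, Q = 0.043, R = 0.051,
             S = 0.071, T = 0.058, V = 0.064, W = 0.013, Y = 0.032)

#' Planted positional enrichment profiles of the three phosphatases
#'
#' Each profile lists the residues over-represented around the central
#' tyrosine of that enzyme's substrates (offset 0 = the site itself), the
#' target probability each enriched residue reaches at full motif
#' strength, and — for SHP-2, whose substrates cluster near the C
#' terminus — an elevated probability of a C-terminally truncated window.
#' Default class sizes mirror the curated datasets (about 1:14 imbalance).
#'
#' @param enzyme `"PTP1B"`, `"SHP-1"` or `"SHP-2"`.
#' @return list with elements `enzyme`, `enrich` (data.frame `offset`,
#'   `residue`, `prob`), `ctermTruncProb`, `nPos`, `nNeg`.
#' @export
enzymeProfile <- function(enzyme = ENZYMES) {
  enzyme <- match.arg(enzyme)
  tab <- switch(enzyme,
    "PTP1B" = data.frame(
      offset  = c(-7, -7, -2, -9, -5, -1, 1, -8),
      residue = c("D", "R", "P", "P", "E", "Y", "Y", "K"),
      prob    = c(0.20, 0.20, 0.35, 0.35, 0.35, 0.35, 0.35, 0.35)),
    "SHP-1" = data.frame(
      offset  = c(3, 9, 2, 3, -1, -2, -3, -4),
      residue = c("L", "P", "V", "V", "D", "D", "D", "E"),
      prob    = c(0.20, 0.35, 0.35, 0.20, 0.35, 0.35, 0.35, 0.35)),
    "SHP-2" = data.frame(
      offset  = c(2, 1, 3, -4, -1, -10),
      residue = c("D", "V", "P", "E", "E", "T"),
      prob    = c(0.35, 0.35, 0.35, 0.35, 0.35, 0.35)))
  sizes <- list("PTP1B" = c(63L, 898L), "SHP-1" = c(50L, 852L),
                "SHP-2" = c(51L, 718L))[[enzyme]]
  list(enzyme = enzyme, enrich = tab,
       ctermTruncProb = if (enzyme == "SHP-2") 0.30 else 0,
       nPos = sizes[1L], nNeg = sizes[2L])
}

.positionProbs <- function(n, enrich, strength) {
  offs <- (-n):n
  lapply(offs, function(o) {
    p <- BG_FREQ
    rows <- enrich[enrich$offset == o, , drop = FALSE]
    if (nrow(rows) > 0L && strength > 0) {
      tgt <- (1 - strength) * p[rows$residue] + strength * rows$prob
      rest <- setdiff(names(p), rows$residue)
      p[rest] <- p[rest] / sum(p[rest]) * (1 - sum(tgt))
      p[rows$residue] <- tgt
    }
    p / sum(p)
  })
}

.sampleWindows <- function(m, n, probs) {
  L <- 2L * n + 1L
  cols <- lapply(seq_len(L), function(j) {
    if (j == n + 1L) rep("Y", m)
    else sample(names(BG_FREQ), m, replace = TRUE, prob = probs[[j]])
  })
  do.call(paste0, cols)
}

.truncateWindows <- function(pep, n, baseProb, ctermProb) {
  m <- length(pep)
  out <- pep
  hit <- stats::runif(m) < baseProb
  side <- sample(c("L", "R"), m, replace = TRUE)
  padLen <- sample.int(n, m, replace = TRUE)
  cHit <- stats::runif(m) < ctermProb
  cLen <- if (n >= 4L) 3L + sample.int(n - 3L, m, replace = TRUE)
          else sample.int(n, m, replace = TRUE)
  for (i in seq_len(m)) {
    L <- 2L * n + 1L
    if (cHit[i]) {
      out[i] <- paste0(substr(pep[i], 1L, L - cLen[i]), strrep("-", cLen[i]))
    } else if (hit[i]) {
      if (side[i] == "L") {
        out[i] <- paste0(strrep("-", padLen[i]),
                         substr(pep[i], padLen[i] + 1L, L))
      } else {
        out[i] <- paste0(substr(pep[i], 1L, L - padLen[i]),
                         strrep("-", padLen[i]))
      }
    }
  }
  out
}

#' Generate a synthetic motif-enriched training set
#'
#' Emulates the structure of the curated datasets: positive windows carry
#' planted residue enrichments at enzyme-specific positions, negatives are
#' drawn from background residue frequencies, and a fraction of windows is
#' terminally truncated (padded with `-`). Identical seeds give identical
#' output.
#'
#' @param profile an [enzymeProfile()] list (or an enzyme name).
#' @param nPos,nNeg class sizes; defaults come from the profile
#'   (about 1:14 imbalance as in the curated data).
#' @param n window half-width (default 10, 21-mers).
#' @param motifStrength 0..1; 0 removes the planted motif entirely so
#'   positives and negatives are exchangeable (null model).
#' @param termProb probability that a window is terminally truncated.
#' @param seed integer RNG seed.
#' @param dir if non-`NULL`, also write `<enzyme>.fasta` and
#'   `<enzyme>_sites.tsv` fixture files (one synthetic protein per
#'   window) into this directory.
#' @return a [SiteTrainingSet-class]; when `dir` is given, the file paths
#'   are attached as `attr(x, "files")`.
#' @export
generateSynthetic <- function(profile = "PTP1B", nPos = NULL, nNeg = NULL,
                              n = 10L, motifStrength = 1, termProb = 0.10,
                              seed = 1L, dir = NULL) {
  if (is.character(profile)) profile <- enzymeProfile(profile)
  if (is.null(nPos)) nPos <- profile$nPos
  if (is.null(nNeg)) nNeg <- profile$nNeg
  stopifnot(nPos > 0L, nNeg > 0L)
  if (n < 1L) stop("window must be odd and >= 3")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)

  posProbs <- .positionProbs(n, profile$enrich, motifStrength)
  negProbs <- .positionProbs(n, profile$enrich, 0)
  pos <- .sampleWindows(nPos, n, posProbs)
  neg <- .sampleWindows(nNeg, n, negProbs)
  pos <- .truncateWindows(pos, n, termProb,
                          profile$ctermTruncProb * max(motifStrength, 0))
  neg <- .truncateWindows(neg, n, termProb, 0)

  tag <- gsub("-", "", profile$enzyme)
  mkRows <- function(pep, label, prefix) {
    leftPad <- nchar(sub("[^-].*$", "", pep))
    data.frame(peptide = pep, label = label,
               protein_id = sprintf("SYN%s_%s%04d", tag, prefix,
                                    seq_along(pep)),
               position = n + 1L - leftPad, stringsAsFactors = FALSE)
  }
  windows <- rbind(mkRows(pos, "positive", "P"), mkRows(neg, "negative", "N"))
  ts <- SiteTrainingSet(profile$enzyme, n, windows)

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    seqs <- gsub("-", "", windows$peptide)
    fa <- file.path(dir, paste0(tag, ".fasta"))
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(structure(seqs, names = windows$protein_id)),
      fa)
    sites <- data.frame(protein_id = windows$protein_id,
                        position = windows$position,
                        enzyme = profile$enzyme, label = windows$label)
    tsv <- file.path(dir, paste0(tag, "_sites.tsv"))
    con <- file(tsv, "w", encoding = "UTF-8")
    writeLines("# synthetic site annotations", con)
    utils::write.table(sites, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    attr(ts, "files") <- c(fasta = fa, sites = tsv)
  }
  ts
}
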