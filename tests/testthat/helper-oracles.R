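# Brute-force oracles, independent of the package's vectorized code paths.

# Build a SiteTrainingSet from plain peptide vectors.
toySet <- function(pos, neg, enzyme = "PTP1B") {
  n <- (nchar(pos[1L]) - 1L) %/% 2L
  SiteTrainingSet(enzyme, n, data.frame(
    peptide = c(pos, neg),
    label = rep(c("positive", "negative"), c(length(pos), length(neg))),
    protein_id = sprintf("T%03d", seq_len(length(pos) + length(neg))),
    position = rep(n + 1L, length(pos) + length(neg))))
}

# O(n^2) pairwise AUC with ties counting one half.
bruteAuc <- function(scores, labels) {
  pos <- scores[labels == "positive"]
  neg <- scores[labels == "negative"]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Raw BLOSUM62 lookup straight from the Biostrings table; gap and
# nonstandard symbols score 0.
.b62env <- new.env()
rawB62 <- function(a, b) {
  if (is.null(.b62env$m)) {
    data("BLOSUM62", package = "Biostrings", envir = .b62env)
    .b62env$m <- .b62env$BLOSUM62
  }
  aas <- rownames(.b62env$m)
  if (!(a %in% aas) || !(b %in% aas) || a %in% c("X", "*") ||
      b %in% c("X", "*")) return(0)
  as.numeric(.b62env$m[a, b])
}

# Positional MGPS similarity recomputed by explicit loops.
bruteMgpsSimilarity <- function(query, ref, w) {
  qa <- strsplit(query, "")[[1L]]
  ra <- strsplit(ref, "")[[1L]]
  ctr <- (length(qa) + 1L) %/% 2L
  s <- 0
  for (i in seq_along(qa)) {
    s <- s + w[i] * if (i == ctr) 1 else rawB62(qa[i], ra[i])
  }
  max(s, 0)
}

bruteMgpsScore <- function(query, refs, w) {
  mean(vapply(refs, function(r) bruteMgpsSimilarity(query, r, w),
              numeric(1)))
}

# Exhaustive kNN ranking: raw BLOSUM62 similarity (center included, no
# override), positive sims scaled by posWeight, stable sort with
# positives before negatives on ties, then pool order.
bruteKnnScore <- function(query, pool, labels, posWeight, k) {
  sims <- vapply(pool, function(p) {
    qa <- strsplit(query, "")[[1L]]
    pa <- strsplit(p, "")[[1L]]
    sum(vapply(seq_along(qa), function(i) rawB62(qa[i], pa[i]),
               numeric(1)))
  }, numeric(1))
  sims[labels == "positive"] <- sims[labels == "positive"] * posWeight
  ord <- order(-sims, ifelse(labels == "positive", 0L, 1L),
               seq_along(pool))
  sum(labels[ord[seq_len(k)]] == "positive") / k
}

# Two-sided Fisher p by full hypergeometric enumeration.
bruteFisherP <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; kk <- a + c_
  lo <- max(0L, kk - n); hi <- min(kk, m)
  probs <- dhyper(lo:hi, m, n, kk)
  p0 <- dhyper(a, m, n, kk)
  sum(probs[probs <= p0 * (1 + 1e-7)])
}
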