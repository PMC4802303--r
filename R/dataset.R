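#' Read a site-annotation table
#'
#' Tab-separated, UTF-8, `#` comment lines; columns `protein_id`,
#' `position`, `enzyme`, `label`.
#'
#' @param path file path.
#' @return data.frame of site annotations.
#' @export
readSitesTable <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("protein_id", "position", "enzyme", "label")
  if (!all(need %in% names(df))) {
    stop("sites table must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("sites table is empty")
  if (!all(df$label %in% SITE_LABELS)) {
    stop("site labels must be 'positive' or 'negative'")
  }
  df$position <- as.integer(df$position)
  dup <- duplicated(df[, c("protein_id", "position", "enzyme")])
  if (any(dup)) {
    stop("duplicate (protein, position) rows in sites table: ",
         paste(unique(df$protein_id[dup]), collapse = ", "))
  }
  df
}

.readFastaNamed <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- sub("\\s.*$", "", names(aa))  # id = first word of header
  seqs
}

#' Build a training set from FASTA substrates and a sites table
#'
#' Positive windows are the annotated dephosphorylation sites of the
#' requested enzyme. Negatives are the rows explicitly labelled
#' `negative` when the table carries any; otherwise every other tyrosine
#' of the substrate proteins is harvested as a negative (tyrosines not
#' experimentally shown to be dephosphorylated). Both classes then pass
#' through [redundancyReduce()] separately.
#'
#' @param fastaPath FASTA file of substrate sequences.
#' @param sitesPath site-annotation TSV (see [readSitesTable()]).
#' @param enzyme phosphatase to select.
#' @param n window half-width (default 10, 21-mers).
#' @param identityThreshold redundancy-reduction threshold (default 0.70).
#' @return a [SiteTrainingSet-class].
#' @export
loadDataset <- function(fastaPath, sitesPath, enzyme, n = 10L,
                        identityThreshold = 0.70) {
  seqs <- .readFastaNamed(fastaPath)
  sites <- readSitesTable(sitesPath)
  sites <- sites[sites$enzyme == enzyme, , drop = FALSE]
  if (nrow(sites) == 0L) {
    stop("no sites annotated for enzyme ", enzyme)
  }
  unknown <- setdiff(unique(sites$protein_id), names(seqs))
  if (length(unknown)) {
    stop("protein ids missing from FASTA: ", paste(unknown, collapse = ", "))
  }
  mkWindows <- function(tab, label) {
    if (nrow(tab) == 0L) {
      return(data.frame(peptide = character(0), label = character(0),
                        protein_id = character(0), position = integer(0)))
    }
    pep <- mapply(function(id, pos) extractWindow(seqs[[id]], pos, n),
                  tab$protein_id, tab$position, USE.NAMES = FALSE)
    data.frame(peptide = pep, label = label, protein_id = tab$protein_id,
               position = tab$position, stringsAsFactors = FALSE)
  }
  pos <- mkWindows(sites[sites$label == "positive", , drop = FALSE],
                   "positive")
  if (nrow(pos) == 0L) stop("no positive sites for enzyme ", enzyme)
  negAnnot <- sites[sites$label == "negative", , drop = FALSE]
  if (nrow(negAnnot) > 0L) {
    neg <- mkWindows(negAnnot, "negative")
  } else {
    # harvest all other tyrosines of the substrate proteins
    prot <- unique(pos$protein_id)
    posKey <- paste(pos$protein_id, pos$position)
    rows <- lapply(prot, function(id) {
      at <- which(strsplit(seqs[[id]], "", fixed = TRUE)[[1L]] == "Y")
      at <- at[!paste(id, at) %in% posKey]
      if (!length(at)) return(NULL)
      data.frame(protein_id = id, position = at, stringsAsFactors = FALSE)
    })
    rows <- do.call(rbind, rows)
    neg <- mkWindows(rows, "negative")
  }
  pos <- redundancyReduce(pos, identityThreshold)
  neg <- redundancyReduce(neg, identityThreshold)
  SiteTrainingSet(enzyme, n, rbind(pos, neg))
}

#' Write / read a training set as a TSV archive
#'
#' One TSV per enzyme, columns `peptide`, `label`, `protein_id`,
#' `position`.
#'
#' @param x a [SiteTrainingSet-class].
#' @param path output TSV path.
#' @return `writeTrainingSet` returns `path` invisibly; `readTrainingSet`
#'   returns a [SiteTrainingSet-class].
#' @export
writeTrainingSet <- function(x, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# enzyme=%s n=%d", enzyme(x), halfWidth(x)), con)
  utils::write.table(siteWindows(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrainingSet
#' @export
readTrainingSet <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec("enzyme=(\\S+) n=(\\d+)", hdr))[[1L]]
  if (length(m) != 3L) stop("missing '# enzyme=... n=...' header: ", path)
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  SiteTrainingSet(m[2L], as.integer(m[3L]), df)
}
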