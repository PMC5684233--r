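## Cosine-family spectrum-spectrum scoring and library search.
##
## All variants are normalized dot products over tolerance-matched peak
## pairs; they differ in the per-peak weight and in whether the alignment
## admits precursor-shifted matches:
##   cosine   w = intensity,                 unshifted
##   massbank w = mass^2 * sqrt(intensity),  unshifted
##   gnps     w = sqrt(intensity),           shifted alignment
## Weights are L2-normalized over the full peak list (not only matched
## peaks), so the self-score is exactly 1 and every score lies in [0, 1].

.peakWeights <- function(s, variant) {
  m <- peakMasses(s); i <- peakIntensities(s)
  switch(variant,
         cosine = i,
         massbank = m^2 * sqrt(i),
         gnps = sqrt(i),
         stop("unknown scoring variant '", variant, "'"))
}

#' Score a spectrum pair with a cosine-family similarity
#'
#' @param q,r [Spectrum-class] objects.
#' @param tolerancePpm peak-matching tolerance.
#' @param variant `"cosine"`, `"massbank"` or `"gnps"` (see the file-level
#'   weight table; `gnps` uses the precursor-shifted alignment).
#' @param origin hit origin recorded in the result (`"target"` or
#'   `"decoy"`).
#' @return one-row data.frame with `query_id`, `reference_id`, `score` in
#'   \[0, 1\], `n_matched` (aligned peak pairs) and `origin`.
#' @examples
#' s <- spectrum("a", 181.07, c(85, 127, 181), c(10, 40, 100))
#' cosineScore(s, s)$score   # exactly 1
#' @export
cosineScore <- function(q, r, tolerancePpm = 10,
                        variant = c("cosine", "massbank", "gnps"),
                        origin = "target") {
  variant <- match.arg(variant)
  if (!nPeaks(q) || !nPeaks(r))
    stop("cosineScore requires non-empty spectra", call. = FALSE)
  wq <- .peakWeights(q, variant); wr <- .peakWeights(r, variant)
  nq <- sqrt(sum(wq^2)); nr <- sqrt(sum(wr^2))
  if (nq == 0 || nr == 0) {
    score <- 0; nMatched <- 0L
  } else {
    al <- alignPeaks(q, r, tolerancePpm, shifted = (variant == "gnps"),
                     wq = wq / nq, wr = wr / nr)
    score <- min(1, max(0, al$weight))
    nMatched <- nrow(al$pairs)
  }
  data.frame(query_id = spectrumId(q), reference_id = spectrumId(r),
             score = score, n_matched = nMatched, origin = origin,
             stringsAsFactors = FALSE)
}

#' Search query spectra against a spectral library
#'
#' For each query, all references whose precursor mass lies within the
#' precursor window are scored; the best-scoring reference whose alignment
#' has at least `minMatchedPeaks` matched pairs is reported as the single
#' hit (ties broken towards the lexicographically smaller reference
#' identifier). Queries with no eligible reference yield no row.
#'
#' @param queries,lib [SpectralLibrary-class] objects.
#' @param origin origin label stored in the hits (`"target"` or
#'   `"decoy"`).
#' @param minMatchedPeaks minimum number of aligned peak pairs for a hit.
#' @param precursorWindowPpm precursor window, p.p.m.
#' @param variant,tolerancePpm passed to [cosineScore()].
#' @return data.frame of hits (`query_id`, `reference_id`, `score`,
#'   `n_matched`, `origin`), at most one row per query, in query order.
#' @export
searchLibrary <- function(queries, lib, origin = "target",
                          minMatchedPeaks = 6L, precursorWindowPpm = 10,
                          variant = "cosine", tolerancePpm = 10) {
  stopifnot(minMatchedPeaks >= 0L)
  refs <- librarySpectra(lib)
  refPrec <- vapply(refs, precursorMz, numeric(1))
  refIds <- libraryIds(lib)
  rows <- list()
  for (q in librarySpectra(queries)) {
    if (!nPeaks(q)) next
    cand <- which(abs(refPrec - precursorMz(q)) <=
                    ppmWindow(precursorMz(q), precursorWindowPpm))
    if (!length(cand)) next
    best <- NULL
    for (j in cand[order(refIds[cand])]) {
      if (!nPeaks(refs[[j]])) next
      hit <- cosineScore(q, refs[[j]], tolerancePpm, variant, origin)
      if (hit$n_matched < minMatchedPeaks) next
      if (is.null(best) || hit$score > best$score) best <- hit
    }
    if (!is.null(best)) rows[[length(rows) + 1L]] <- best
  }
  if (!length(rows))
    return(data.frame(query_id = character(0), reference_id = character(0),
                      score = numeric(0), n_matched = integer(0),
                      origin = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Read and write hit tables
#'
#' Hits are serialized as TSV with columns `query_id`, `reference_id`,
#' `score`, `n_matched`, `origin`.
#'
#' @param hits data.frame of hits as produced by [searchLibrary()].
#' @param path file path.
#' @return `writeHits`: `path` invisibly; `readHits`: the hits data.frame.
#' @export
writeHits <- function(hits, path) {
  write.table(hits, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeHits
#' @export
readHits <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
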