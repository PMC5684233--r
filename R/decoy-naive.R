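## Naive decoy construction: resample fragment masses from the whole
## library. The baseline the more structured decoys are judged against.

## flat multiset of all fragment-ion masses in a library
.poolMasses <- function(pool) {
  unlist(lapply(librarySpectra(pool), peakMasses), use.names = FALSE)
}

## assign the target's intensities to drawn masses in mass-rank order, so
## the intensity-vs-rank profile of the original spectrum is preserved and
## the intensity multiset is conserved exactly
.assignIntensities <- function(masses, target) {
  ord <- order(masses)
  sortedInt <- peakIntensities(target)  # target peaks already mass-sorted
  out <- numeric(length(masses))
  out[ord] <- sortedInt[seq_along(masses)]
  out
}

#' Naive decoy spectrum
#'
#' Draws fragment-ion masses uniformly from all fragment ions of the pool
#' library until the decoy has exactly as many peaks as the target
#' spectrum. Masses above the target's precursor mass, and masses within
#' `sepPpm` of an already drawn mass, are discarded and redrawn. The
#' target's intensities are assigned to the drawn masses in mass-rank
#' order, so the intensity multiset is conserved.
#'
#' @param target the [Spectrum-class] to mimic.
#' @param pool the [SpectralLibrary-class] supplying fragment masses, or a
#'   precomputed numeric vector of pool masses.
#' @param sepPpm minimum relative separation between decoy peaks.
#' @return a decoy [Spectrum-class] with `precursorMz(target)` and
#'   `nPeaks(target)` peaks.
#' @export
naiveDecoy <- function(target, pool, sepPpm = 5) {
  masses <- if (is.numeric(pool)) pool else .poolMasses(pool)
  if (!length(masses)) stop("decoy pool is empty", call. = FALSE)
  n <- nPeaks(target)
  prec <- precursorMz(target)
  drawn <- numeric(0)
  attempts <- 0L
  maxAttempts <- 400L * max(1L, n)
  while (length(drawn) < n) {
    attempts <- attempts + 1L
    if (attempts > maxAttempts)
      stop("pool exhausted while building naive decoy for spectrum '",
           spectrumId(target), "' (", length(drawn), "/", n, " peaks)",
           call. = FALSE)
    m <- masses[sample.int(length(masses), 1L)]
    if (m > prec) next
    if (length(drawn) && any(abs(drawn - m) <= ppmWindow(m, sepPpm))) next
    drawn <- c(drawn, m)
  }
  spectrum(spectrumId(target), prec, drawn,
           .assignIntensities(drawn, target), ionMode = ionMode(target))
}
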