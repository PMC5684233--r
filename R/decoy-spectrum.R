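## Spectrum-based decoy construction: fragment ions are added iteratively,
## conditional on the ions already in the decoy, so fragmentation cascades
## and co-occurrence structure of the library are mimicked. A two-step
## candidate process (draw five candidate ions from the spectra containing
## the last added ion, then draw the actual decoy ion from the candidate
## set) prevents fragment-rich spectra from dominating.

## sorted index over all pool fragment ions for fast 5 p.p.m. lookups
.poolIndex <- function(pool) {
  specs <- librarySpectra(pool)
  masses <- unlist(lapply(specs, peakMasses), use.names = FALSE)
  specIdx <- rep.int(seq_along(specs),
                     vapply(specs, nPeaks, integer(1)))
  ord <- order(masses)
  list(masses = masses[ord], specIdx = specIdx[ord],
       peaksBySpec = lapply(specs, peakMasses))
}

## indices of pool spectra containing a fragment ion within ppm of m
.spectraContaining <- function(index, m, ppm = 5) {
  tol <- ppmWindow(m, ppm)
  lo <- findInterval(m - tol, index$masses) + 1L
  hi <- findInterval(m + tol, index$masses)
  if (hi < lo) return(integer(0))
  unique(index$specIdx[lo:hi])
}

#' Spectrum-based decoy spectrum
#'
#' Starts from the target's precursor fragment ion (the peak nearest the
#' precursor m/z, or the selected-ion mass when no such peak exists). For
#' every ion added to the decoy, all pool spectra containing that ion
#' within `sepPpm` are located and five of their fragment ions (all, if
#' fewer) are drawn uniformly into a persistent candidate set; the next
#' decoy ion is drawn uniformly from that set. Ions above the precursor
#' mass or within `sepPpm` of an existing decoy ion are discarded. If the
#' candidate set empties before the target peak count is reached, the
#' remaining slots fall back to naive draws (recorded in the `"fallback"`
#' attribute).
#'
#' @param target the [Spectrum-class] to mimic.
#' @param pool the [SpectralLibrary-class] supplying fragment ions, or a
#'   prebuilt index from the internal pool indexer.
#' @param sepPpm matching/separation tolerance, p.p.m.
#' @param candidatesPerIon candidate ions drawn per matched-spectra set.
#' @return a decoy [Spectrum-class] with `nPeaks(target)` peaks; attribute
#'   `"fallback"` counts naive-filled slots.
#' @export
spectrumBasedDecoy <- function(target, pool, sepPpm = 5,
                               candidatesPerIon = 5L) {
  index <- if (is.list(pool) && !is.null(pool$peaksBySpec)) pool
           else .poolIndex(pool)
  if (!length(index$masses)) stop("decoy pool is empty", call. = FALSE)
  n <- nPeaks(target)
  prec <- precursorMz(target)
  ## seed ion: the precursor fragment ion, or the selected-ion mass
  pm <- peakMasses(target)
  nearPrec <- which(abs(pm - prec) <= ppmWindow(prec, sepPpm))
  seedMass <- if (length(nearPrec)) pm[nearPrec[length(nearPrec)]] else prec
  decoy <- seedMass
  candidates <- numeric(0)
  expand <- function(m) {
    hits <- .spectraContaining(index, m, sepPpm)
    if (!length(hits)) return(numeric(0))
    ions <- unlist(index$peaksBySpec[hits], use.names = FALSE)
    k <- min(candidatesPerIon, length(ions))
    ions[sample.int(length(ions), k)]
  }
  candidates <- c(candidates, expand(seedMass))
  fallback <- 0L
  guard <- 0L
  while (length(decoy) < n) {
    guard <- guard + 1L
    if (!length(candidates) || guard > 1000L * n) {
      ## no progress possible conditionally: fill the rest naively
      remaining <- n - length(decoy)
      fallback <- fallback + remaining
      att <- 0L
      while (length(decoy) < n) {
        att <- att + 1L
        if (att > 400L * n)
          stop("pool exhausted while building spectrum-based decoy for '",
               spectrumId(target), "'", call. = FALSE)
        m <- index$masses[sample.int(length(index$masses), 1L)]
        if (m > prec) next
        if (any(abs(decoy - m) <= ppmWindow(m, sepPpm))) next
        decoy <- c(decoy, m)
      }
      break
    }
    k <- sample.int(length(candidates), 1L)
    m <- candidates[k]
    candidates <- candidates[-k]
    if (m > prec) next
    if (any(abs(decoy - m) <= ppmWindow(m, sepPpm))) next
    decoy <- c(decoy, m)
    candidates <- c(candidates, expand(m))
  }
  out <- spectrum(spectrumId(target), prec, decoy,
                  .assignIntensities(decoy, target),
                  ionMode = ionMode(target))
  attr(out, "fallback") <- fallback
  out
}
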