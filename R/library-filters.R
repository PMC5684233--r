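## Library inclusion filters and collision-energy merging.
##
## A reference spectrum enters the search library only if it is measured in
## positive ion mode, its compound is below 1000 Da ("below" strict), and
## at least five of its peaks carry at least 2% of the base-peak intensity
## (so the spectrum is informative enough to match). A structure-derived
## compound mass, when present, must additionally agree with the precursor
## m/z to within 10 p.p.m. after removing the proton.

#' Library inclusion filters for reference spectra
#'
#' @param s a [Spectrum-class].
#' @param maxCompoundMass exclusive upper bound on the compound mass, Da.
#' @param minInformativePeaks minimum number of peaks at or above
#'   `relIntensity` of the base peak.
#' @param relIntensity relative-intensity floor (fraction of base peak).
#' @param massAgreementPpm maximum precursor-vs-structure mass deviation.
#' @return logical; attribute `"reason"` names the first failing rule
#'   (`"ion-mode"`, `"compound-mass"`, `"mass-agreement"`,
#'   `"min-informative-peaks"`) or `"pass"`.
#' @examples
#' s <- spectrum("x", 181.07, c(85, 127, 163, 181), c(50, 80, 100, 60),
#'               compoundMass = 180.063)
#' passesLibraryFilters(s)   # FALSE: only 4 informative peaks
#' @export
passesLibraryFilters <- function(s, maxCompoundMass = 1000,
                                 minInformativePeaks = 5L,
                                 relIntensity = 0.02,
                                 massAgreementPpm = 10) {
  fail <- function(reason) structure(FALSE, reason = reason)
  if (ionMode(s) != "positive") return(fail("ion-mode"))
  cm <- compoundMass(s)
  if (!is.na(cm)) {
    if (cm >= maxCompoundMass) return(fail("compound-mass"))
    ## structure-mass agreement: precursor is [M+H]+
    if (abs((precursorMz(s) - protonMass()) - cm) >
        ppmWindow(cm, massAgreementPpm))
      return(fail("mass-agreement"))
  } else {
    if (precursorMz(s) - protonMass() >= maxCompoundMass)
      return(fail("compound-mass"))
  }
  inten <- peakIntensities(s)
  if (!length(inten)) return(fail("min-informative-peaks"))
  nInformative <- sum(inten >= relIntensity * max(inten))
  if (nInformative < minInformativePeaks)
    return(fail("min-informative-peaks"))
  structure(TRUE, reason = "pass")
}

#' Apply the inclusion filters to a whole library
#'
#' @param lib a [SpectralLibrary-class].
#' @param ... passed to [passesLibraryFilters()].
#' @return the filtered [SpectralLibrary-class]; attribute `"reasons"`
#'   holds the per-entry decision table.
#' @export
filterLibrary <- function(lib, ...) {
  res <- lapply(librarySpectra(lib), passesLibraryFilters, ...)
  keep <- vapply(res, function(r) as.logical(r), logical(1))
  out <- spectralLibrary(librarySpectra(lib)[keep], name = libraryName(lib))
  attr(out, "reasons") <- data.frame(
    identifier = libraryIds(lib),
    pass = keep,
    reason = vapply(res, function(r) attr(r, "reason"), character(1)),
    stringsAsFactors = FALSE)
  out
}

#' Merge spectra of one compound recorded at different collision energies
#'
#' Pools the peaks of all input spectra and combines peaks that fall within
#' the matching tolerance max(`ppm` relative, `absDa` absolute) into one
#' peak, keeping the mass of the most intense member and the maximum
#' intensity. The maximum (rather than a sum) preserves the relative
#' intensity structure that the inclusion filters rely on.
#'
#' @param spectra list of [Spectrum-class] objects sharing a compound and a
#'   precursor mass (within `precursorPpm`).
#' @param ppm,absDa peak-combination tolerance.
#' @param precursorPpm maximum allowed precursor disagreement.
#' @return a single merged [Spectrum-class] (identifier of the first
#'   input).
#' @export
mergeCollisionEnergies <- function(spectra, ppm = 10, absDa = 0.002,
                                   precursorPpm = 10) {
  stopifnot(length(spectra) >= 1L)
  prec <- vapply(spectra, precursorMz, numeric(1))
  if (diff(range(prec)) > ppmWindow(mean(prec), precursorPpm))
    stop("precursor masses disagree beyond ", precursorPpm, " p.p.m.: ",
         paste(format(prec), collapse = ", "), call. = FALSE)
  ids <- vapply(spectra, function(s) compoundId(s), character(1))
  ids <- ids[!is.na(ids)]
  if (length(unique(ids)) > 1L)
    stop("spectra to merge must share a compound identity", call. = FALSE)
  mass <- unlist(lapply(spectra, peakMasses))
  inten <- unlist(lapply(spectra, peakIntensities))
  ord <- order(mass)
  mass <- mass[ord]; inten <- inten[ord]
  ## single-linkage clustering along the sorted mass axis: adjacent peaks
  ## within tolerance belong to one cluster
  if (length(mass) > 1L) {
    gapOk <- massMatches(mass[-1L], mass[-length(mass)], ppm, absDa)
    grp <- cumsum(c(1L, !gapOk))
  } else grp <- rep(1L, length(mass))
  outMass <- vapply(split(seq_along(mass), grp), function(ix) {
    mass[ix][which.max(inten[ix])]
  }, numeric(1))
  outInt <- vapply(split(inten, grp), max, numeric(1))
  s1 <- spectra[[1]]
  spectrum(spectrumId(s1), precursorMz(s1), outMass, outInt,
           ionMode = ionMode(s1), compoundMass = compoundMass(s1),
           compoundId = compoundId(s1))
}
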