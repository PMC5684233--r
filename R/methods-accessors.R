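#' Accessors for Spectrum objects
#'
#' @param x a [Spectrum-class] object.
#' @return `spectrumId`, `ionMode`, `compoundId`: character;
#'   `precursorMz`, `compoundMass`: numeric; `peakTable`: two-column
#'   matrix; `peakMasses`, `peakIntensities`: numeric vectors; `nPeaks`:
#'   integer.
#' @name Spectrum-accessors
NULL

#' @rdname Spectrum-accessors
#' @export
setMethod("spectrumId", "Spectrum", function(x) x@identifier)
#' @rdname Spectrum-accessors
#' @export
setMethod("precursorMz", "Spectrum", function(x) x@precursorMz)
#' @rdname Spectrum-accessors
#' @export
setMethod("ionMode", "Spectrum", function(x) x@ionMode)
#' @rdname Spectrum-accessors
#' @export
setMethod("peakTable", "Spectrum", function(x) x@peaks)
#' @rdname Spectrum-accessors
#' @export
setMethod("peakMasses", "Spectrum", function(x) unname(x@peaks[, "mass"]))
#' @rdname Spectrum-accessors
#' @export
setMethod("peakIntensities", "Spectrum",
          function(x) unname(x@peaks[, "intensity"]))
#' @rdname Spectrum-accessors
#' @export
setMethod("nPeaks", "Spectrum", function(x) nrow(x@peaks))
#' @rdname Spectrum-accessors
#' @export
setMethod("compoundMass", "Spectrum", function(x) x@compoundMass)
#' @rdname Spectrum-accessors
#' @export
setMethod("compoundId", "Spectrum", function(x) x@compoundId)

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum '%s' (%s mode)\n", object@identifier,
              object@ionMode))
  cat(sprintf("  precursor m/z: %.5f | peaks: %d", object@precursorMz,
              nrow(object@peaks)))
  if (!is.na(object@compoundId))
    cat(sprintf(" | compound: %s", object@compoundId))
  cat("\n")
})

#' Accessors for SpectralLibrary objects
#'
#' @param x a [SpectralLibrary-class] object.
#' @param i index or identifier.
#' @return `librarySpectra`: list of spectra; `libraryIds`: character
#'   vector; `libraryName`: string; `length`: number of entries.
#' @name SpectralLibrary-accessors
NULL

#' @rdname SpectralLibrary-accessors
#' @export
setMethod("libraryName", "SpectralLibrary", function(x) x@name)
#' @rdname SpectralLibrary-accessors
#' @export
setMethod("librarySpectra", "SpectralLibrary", function(x) x@entries)
#' @rdname SpectralLibrary-accessors
#' @export
setMethod("libraryIds", "SpectralLibrary", function(x)
  vapply(x@entries, function(s) s@identifier, character(1)))
#' @rdname SpectralLibrary-accessors
#' @export
setMethod("length", "SpectralLibrary", function(x) length(x@entries))

#' @rdname SpectralLibrary-accessors
#' @export
setMethod("[[", "SpectralLibrary", function(x, i) {
  if (is.character(i)) {
    k <- match(i, libraryIds(x))
    if (is.na(k)) stop("no spectrum with identifier '", i, "'")
    i <- k
  }
  x@entries[[i]]
})

setMethod("show", "SpectralLibrary", function(object) {
  cat(sprintf("%s '%s' with %d spectra\n", class(object), object@name,
              length(object@entries)))
  if (is(object, "DecoyLibrary"))
    cat(sprintf("  method: %s | source: %s | seed: %d\n", object@method,
                object@sourceLibrary, object@seed))
})

#' Accessors for FragmentationTree objects
#'
#' @param x a [FragmentationTree-class] object.
#' @return `nNodes`: integer; `rootFormula`: named integer count vector;
#'   `nodeMasses`: numeric vector of node ion m/z values.
#' @name FragmentationTree-accessors
NULL

#' @rdname FragmentationTree-accessors
#' @export
setMethod("nNodes", "FragmentationTree", function(x) length(x@parent))
#' @rdname FragmentationTree-accessors
#' @export
setMethod("rootFormula", "FragmentationTree", function(x) {
  r <- which(x@parent == 0L)
  setNames(x@formulas[r, ], formulaElements())
})
#' @rdname FragmentationTree-accessors
#' @export
setMethod("nodeMasses", "FragmentationTree", function(x) x@masses)

setMethod("show", "FragmentationTree", function(object) {
  cat(sprintf("FragmentationTree for spectrum '%s': %d nodes, root %s\n",
              object@spectrumId, nNodes(object),
              formulaToString(rootFormula(object))))
})

#' Accessors for MixtureModel objects
#'
#' @param x a [MixtureModel-class] object.
#' @return `pi0`: mixture weight of the false component (the PIT).
#' @name MixtureModel-accessors
NULL

#' @rdname MixtureModel-accessors
#' @export
setMethod("pi0", "MixtureModel", function(x) x@pi0)

setMethod("show", "MixtureModel", function(object) {
  cat(sprintf(
    "MixtureModel: pi0 = %.3f | false ~ Gamma(%.3g, %.3g) | true ~ mirrored %s\n",
    object@pi0, object@falseShape, object@falseScale, object@trueFamily))
  cat(sprintf("  logLik = %.3f after %d EM iteration(s)%s\n", object@logLik,
              object@nIter,
              if (object@converged) "" else " [not converged]"))
})
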