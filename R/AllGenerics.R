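#' @rdname Spectrum-accessors
#' @export
setGeneric("spectrumId", function(x) standardGeneric("spectrumId"))

#' @rdname Spectrum-accessors
#' @export
setGeneric("precursorMz", function(x) standardGeneric("precursorMz"))

#' @rdname Spectrum-accessors
#' @export
setGeneric("ionMode", function(x) standardGeneric("ionMode"))

#' @rdname Spectrum-accessors
#' @export
setGeneric("peakTable", function(x) standardGeneric("peakTable"))

#' @rdname Spectrum-accessors
#' @export
setGeneric("peakMasses", function(x) standardGeneric("peakMasses"))

#' @rdname Spectrum-accessors
#' @export
setGeneric("peakIntensities", function(x) standardGeneric("peakIntensities"))

#' @rdname Spectrum-accessors
#' @export
setGeneric("nPeaks", function(x) standardGeneric("nPeaks"))

#' @rdname Spectrum-accessors
#' @export
setGeneric("compoundMass", function(x) standardGeneric("compoundMass"))

#' @rdname Spectrum-accessors
#' @export
setGeneric("compoundId", function(x) standardGeneric("compoundId"))

#' @rdname SpectralLibrary-accessors
#' @export
setGeneric("libraryName", function(x) standardGeneric("libraryName"))

#' @rdname SpectralLibrary-accessors
#' @export
setGeneric("librarySpectra", function(x) standardGeneric("librarySpectra"))

#' @rdname SpectralLibrary-accessors
#' @export
setGeneric("libraryIds", function(x) standardGeneric("libraryIds"))

#' @rdname FragmentationTree-accessors
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname FragmentationTree-accessors
#' @export
setGeneric("rootFormula", function(x) standardGeneric("rootFormula"))

#' @rdname FragmentationTree-accessors
#' @export
setGeneric("nodeMasses", function(x) standardGeneric("nodeMasses"))

#' @rdname MixtureModel-accessors
#' @export
setGeneric("pi0", function(x) standardGeneric("pi0"))
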