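#' @import methods
NULL

#' Spectrum: a single MS/MS spectrum
#'
#' The unit of library search and decoy generation: an identifier, a
#' precursor m/z, an ion mode, and a peak list sorted strictly ascending in
#' mass. Optionally carries the structure-derived monoisotopic compound
#' mass (used by the library inclusion filters) and a ground-truth compound
#' identity (used only by the evaluation harness).
#'
#' @slot identifier unique record identifier (e.g. a MassBank accession).
#' @slot precursorMz precursor (or selected-ion) m/z in Da; positive.
#' @slot ionMode `"positive"` or `"negative"`.
#' @slot peaks two-column numeric matrix, columns `mass` (Da) and
#'   `intensity` (arbitrary units), rows sorted strictly ascending in mass.
#' @slot compoundMass structure-derived neutral monoisotopic mass in Da, or
#'   `NA_real_` when unknown.
#' @slot compoundId ground-truth compound identity, or `NA_character_`.
#' @exportClass Spectrum
setClass("Spectrum",
  representation(
    identifier = "character",
    precursorMz = "numeric",
    ionMode = "character",
    peaks = "matrix",
    compoundMass = "numeric",
    compoundId = "character"
  ),
  prototype(
    identifier = NA_character_,
    precursorMz = NA_real_,
    ionMode = "positive",
    peaks = matrix(numeric(0), ncol = 2,
                   dimnames = list(NULL, c("mass", "intensity"))),
    compoundMass = NA_real_,
    compoundId = NA_character_
  )
)

setValidity("Spectrum", function(object) {
  msg <- character(0)
  if (length(object@identifier) != 1L || is.na(object@identifier) ||
      !nzchar(object@identifier))
    msg <- c(msg, "identifier must be a single non-empty string")
  if (length(object@precursorMz) != 1L || is.na(object@precursorMz) ||
      object@precursorMz <= 0)
    msg <- c(msg, "precursorMz must be a single positive number")
  if (!(object@ionMode %in% c("positive", "negative")))
    msg <- c(msg, "ionMode must be 'positive' or 'negative'")
  p <- object@peaks
  if (ncol(p) != 2L || !identical(colnames(p), c("mass", "intensity")))
    msg <- c(msg, "peaks must have columns 'mass' and 'intensity'")
  else if (nrow(p)) {
    if (any(p[, "mass"] <= 0)) msg <- c(msg, "peak masses must be positive")
    if (any(p[, "intensity"] < 0))
      msg <- c(msg, "peak intensities must be non-negative")
    if (nrow(p) > 1L && any(diff(p[, "mass"]) <= 0))
      msg <- c(msg, "peak masses must be strictly ascending")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Spectrum
#'
#' Peaks are sorted by mass; exact duplicate masses within one record are
#' merged at construction time keeping the maximum intensity, so the peak
#' list is always strictly ascending.
#'
#' @param identifier record identifier.
#' @param precursorMz precursor (or selected-ion) m/z in Da.
#' @param mass,intensity numeric vectors of equal length.
#' @param ionMode `"positive"` (default) or `"negative"`.
#' @param compoundMass optional neutral monoisotopic mass in Da.
#' @param compoundId optional ground-truth compound identity.
#' @return a [Spectrum-class] object.
#' @examples
#' s <- spectrum("demo", 181.07, mass = c(85.03, 127.04, 181.07),
#'               intensity = c(10, 40, 100))
#' nPeaks(s)
#' @export
spectrum <- function(identifier, precursorMz, mass, intensity,
                     ionMode = "positive",
                     compoundMass = NA_real_, compoundId = NA_character_) {
  stopifnot(length(mass) == length(intensity))
  ord <- order(mass)
  mass <- as.numeric(mass[ord]); intensity <- as.numeric(intensity[ord])
  if (length(mass) > 1L) {
    keep <- !duplicated(mass)
    if (!all(keep)) {
      grp <- cumsum(keep)
      intensity <- as.numeric(tapply(intensity, grp, max))
      mass <- mass[keep]
    }
  }
  new("Spectrum",
      identifier = as.character(identifier),
      precursorMz = as.numeric(precursorMz),
      ionMode = ionMode,
      peaks = cbind(mass = mass, intensity = intensity),
      compoundMass = as.numeric(compoundMass),
      compoundId = as.character(compoundId))
}

#' SpectralLibrary: an ordered collection of spectra
#'
#' @slot entries list of [Spectrum-class] objects with unique identifiers.
#' @slot name library name.
#' @exportClass SpectralLibrary
setClass("SpectralLibrary",
  representation(entries = "list", name = "character"),
  prototype(entries = list(), name = "library")
)

setValidity("SpectralLibrary", function(object) {
  msg <- character(0)
  if (!all(vapply(object@entries, is, logical(1), "Spectrum")))
    msg <- c(msg, "all entries must be Spectrum objects")
  else {
    ids <- vapply(object@entries, function(s) s@identifier, character(1))
    if (anyDuplicated(ids))
      msg <- c(msg, "spectrum identifiers must be unique within a library")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SpectralLibrary
#'
#' @param entries list of [Spectrum-class] objects.
#' @param name library name.
#' @return a [SpectralLibrary-class] object.
#' @export
spectralLibrary <- function(entries = list(), name = "library") {
  new("SpectralLibrary", entries = entries, name = name)
}

#' DecoyLibrary: a decoy spectral library mirroring a target library
#'
#' Extends [SpectralLibrary-class]; records the generating method, the
#' source library and the RNG seed so decoy construction is reproducible.
#' Entry `i` mirrors source entry `i`: same precursor mass, same peak count
#' (tree-based: same as the noise-filtered source, minus logged drops) and
#' the same intensity multiset.
#'
#' @slot method one of `"naive"`, `"spectrum_based"`, `"tree_based"`.
#' @slot sourceLibrary name of the target library the decoys mirror.
#' @slot seed integer RNG seed used for generation.
#' @slot report per-spectrum generation status (data.frame).
#' @exportClass DecoyLibrary
setClass("DecoyLibrary",
  contains = "SpectralLibrary",
  representation(
    method = "character",
    sourceLibrary = "character",
    seed = "integer",
    report = "data.frame"
  ),
  prototype(method = "naive", sourceLibrary = NA_character_, seed = 0L,
            report = data.frame())
)

setValidity("DecoyLibrary", function(object) {
  if (!(object@method %in% c("naive", "spectrum_based", "tree_based")))
    "method must be one of naive, spectrum_based, tree_based"
  else TRUE
})

#' FragmentationTree: molecular-formula annotation of an MS/MS spectrum
#'
#' A rooted tree whose nodes are molecular formulas of (hypothetical)
#' fragment ions and whose edges carry neutral-loss formulas. For every
#' edge, child formula + loss formula equals the parent formula
#' element-wise; the root is the precursor ion formula. Stored as parallel
#' vectors over nodes: `parent[i]` is the parent index (0 for the root) and
#' row `i` of `losses` is the loss on the edge into node `i`.
#'
#' @slot formulas integer matrix, one row per node, columns
#'   `formulaElements()`.
#' @slot losses integer matrix, one row per node (row of zeros for the
#'   root), columns `formulaElements()`.
#' @slot parent integer vector of parent indices, 0 marks the root.
#' @slot masses numeric vector of node ion m/z values (\[M+H\]+).
#' @slot intensities numeric vector of matched peak intensities
#'   (`NA` where the node has no matched peak).
#' @slot spectrumId identifier of the spectrum the tree annotates.
#' @exportClass FragmentationTree
setClass("FragmentationTree",
  representation(
    formulas = "matrix",
    losses = "matrix",
    parent = "integer",
    masses = "numeric",
    intensities = "numeric",
    spectrumId = "character"
  )
)

setValidity("FragmentationTree", function(object) {
  msg <- character(0)
  n <- length(object@parent)
  if (n == 0L) return("tree must have at least one node")
  if (nrow(object@formulas) != n || nrow(object@losses) != n ||
      length(object@masses) != n || length(object@intensities) != n)
    return("node slots must have one entry per node")
  roots <- which(object@parent == 0L)
  if (length(roots) != 1L)
    msg <- c(msg, "tree must have exactly one root")
  if (any(object@parent < 0L | object@parent > n))
    msg <- c(msg, "parent indices out of range")
  ## connectivity/acyclicity: every node must reach the root by parents
  if (length(roots) == 1L) {
    for (i in seq_len(n)) {
      seen <- logical(n); j <- i
      while (j != 0L) {
        if (seen[j]) { msg <- c(msg, "cycle in parent pointers"); break }
        seen[j] <- TRUE
        j <- object@parent[j]
      }
    }
  }
  if (any(object@formulas < 0L))
    msg <- c(msg, "all node formulas must be valid (non-negative counts)")
  ## edge consistency: child + loss == parent
  for (i in seq_len(n)) {
    p <- object@parent[i]
    if (p == 0L) next
    if (!all(object@formulas[i, ] + object@losses[i, ] ==
             object@formulas[p, ]))
      msg <- c(msg, sprintf(
        "edge into node %d inconsistent: child + loss != parent", i))
  }
  if (length(msg)) unique(msg) else TRUE
})

#' MixtureModel: two-component empirical-Bayes model of search scores
#'
#' Scores of false hits are modeled with a Gamma distribution on the score
#' itself; scores of true hits with a "mirrored" Gamma, Gumbel or Weibull
#' distribution, i.e. the named distribution applied to (1 - score) so its
#' mode sits near high scores. The mixture weight `pi0` of the false
#' component is the percentage of incorrect targets (PIT).
#'
#' @slot pi0 mixture weight of the false component, in \[0, 1\].
#' @slot falseShape,falseScale Gamma parameters of the false component.
#' @slot trueFamily `"gamma"`, `"gumbel"` or `"weibull"`.
#' @slot truePar named numeric vector of true-component parameters on the
#'   mirrored axis (Gamma: shape/scale; Gumbel: loc/scale; Weibull:
#'   shape/scale).
#' @slot logLik final log-likelihood of the fit.
#' @slot logLikTrace per-iteration log-likelihood (non-decreasing).
#' @slot nIter number of EM iterations performed.
#' @slot converged whether the EM tolerance was reached.
#' @slot scoreMax upper bound of the score domain used for mirroring.
#' @exportClass MixtureModel
setClass("MixtureModel",
  representation(
    pi0 = "numeric",
    falseShape = "numeric",
    falseScale = "numeric",
    trueFamily = "character",
    truePar = "numeric",
    logLik = "numeric",
    logLikTrace = "numeric",
    nIter = "integer",
    converged = "logical",
    scoreMax = "numeric"
  )
)

setValidity("MixtureModel", function(object) {
  msg <- character(0)
  if (object@pi0 < 0 || object@pi0 > 1) msg <- c(msg, "pi0 must be in [0,1]")
  if (object@falseShape <= 0 || object@falseScale <= 0)
    msg <- c(msg, "false-component Gamma parameters must be positive")
  if (!(object@trueFamily %in% c("gamma", "gumbel", "weibull")))
    msg <- c(msg, "trueFamily must be gamma, gumbel or weibull")
  if (length(msg)) msg else TRUE
})
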