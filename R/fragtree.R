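## Fragmentation trees: rooted trees of molecular-formula nodes connected
## by neutral-loss edges. The root is the precursor-ion formula; every
## child formula is the parent formula minus the loss on the connecting
## edge. Trees drive noise filtering (only tree-annotated peaks are signal)
## and the re-rooting decoy construction.

#' Construct a FragmentationTree from parents, losses and a root formula
#'
#' Node formulas are derived by subtracting losses along the edges from the
#' root formula, then the full set of class invariants is checked.
#'
#' @param parent integer vector of parent indices (0 for the root).
#' @param losses list of loss formulas (strings or count vectors), one per
#'   node; the root entry is ignored and stored as the empty formula.
#' @param rootFormula formula of the precursor ion.
#' @param spectrumId identifier of the annotated spectrum.
#' @param intensities matched peak intensity per node (`NA` where absent).
#' @return a validated [FragmentationTree-class].
#' @examples
#' t <- fragmentationTree(parent = c(0L, 1L, 2L),
#'                        losses = list("0", "H2O", "CO"),
#'                        rootFormula = "C6H12O6", spectrumId = "demo")
#' nNodes(t)
#' @export
fragmentationTree <- function(parent, losses, rootFormula, spectrumId,
                              intensities = rep(NA_real_, length(parent))) {
  n <- length(parent)
  stopifnot(length(losses) == n, length(intensities) == n)
  el <- formulaElements()
  lossM <- matrix(0L, n, length(el), dimnames = list(NULL, el))
  for (i in seq_len(n))
    if (parent[i] != 0L) lossM[i, ] <- asFormula(losses[[i]])
  formM <- .propagateFormulas(as.integer(parent), lossM,
                              asFormula(rootFormula))
  masses <- apply(formM, 1L, function(f) ionMass(setNames(f, el)))
  new("FragmentationTree", formulas = formM, losses = lossM,
      parent = as.integer(parent), masses = as.numeric(masses),
      intensities = as.numeric(intensities),
      spectrumId = as.character(spectrumId))
}

## derive all node formulas from a root formula by subtracting losses along
## edges; works in topological (root-first) order and never clamps, so
## invalid (negative-count) formulas propagate and stay visible
.propagateFormulas <- function(parent, lossM, rootF) {
  n <- length(parent)
  el <- formulaElements()
  formM <- matrix(0L, n, length(el), dimnames = list(NULL, el))
  ord <- .topoOrder(parent)
  for (i in ord) {
    if (parent[i] == 0L) formM[i, ] <- rootF
    else formM[i, ] <- formM[parent[i], ] - lossM[i, ]
  }
  formM
}

## root-first traversal order for a parent-pointer tree
.topoOrder <- function(parent) {
  n <- length(parent)
  depth <- integer(n)
  for (i in seq_len(n)) {
    d <- 0L; j <- i
    while (parent[j] != 0L) { d <- d + 1L; j <- parent[j]
      if (d > n) stop("cycle in parent pointers", call. = FALSE) }
    depth[i] <- d
  }
  order(depth)
}

#' Standard neutral-loss alphabet
#'
#' A small alphabet of common small-molecule neutral losses, used by the
#' toy tree annotator and the synthetic benchmark generator.
#'
#' @return named character vector of loss formulas (names are the formula
#'   strings, values identical).
#' @export
lossAlphabet <- function() {
  x <- c("H2O", "NH3", "CO", "CH2O", "C2H4", "CO2", "CH4O",
         "C2H2O", "C3H6", "CH2O2", "C2H4O2", "C4H8")
  setNames(x, x)
}

#' Write a fragmentation tree in the DOT dialect
#'
#' One node line per fragment, `label="FORMULA\\nmass"` with an optional
#' `intensity` attribute; one edge line per loss with the loss formula as
#' edge label. Unknown attributes are ignored on reading.
#'
#' @param tree a [FragmentationTree-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @seealso [readDotTree()]
#' @export
writeDotTree <- function(tree, path) {
  el <- formulaElements()
  n <- nNodes(tree)
  lines <- c(sprintf("digraph \"%s\" {", tree@spectrumId))
  for (i in seq_len(n)) {
    f <- formulaToString(setNames(tree@formulas[i, ], el))
    attrs <- sprintf("label=\"%s\\n%.6f\"", f, tree@masses[i])
    if (!is.na(tree@intensities[i]))
      attrs <- paste0(attrs, sprintf(" intensity=\"%.6f\"",
                                     tree@intensities[i]))
    lines <- c(lines, sprintf("  v%d [%s];", i, attrs))
  }
  for (i in seq_len(n)) {
    p <- tree@parent[i]
    if (p == 0L) next
    loss <- formulaToString(setNames(tree@losses[i, ], el))
    lines <- c(lines, sprintf("  v%d -> v%d [label=\"%s\"];", p, i, loss))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

#' Read a fragmentation tree from the DOT dialect
#'
#' Structural problems (no or multiple roots, cycles) raise a structural
#' error; an edge whose loss formula does not equal parent minus child
#' raises a consistency error.
#'
#' @param path DOT file written by [writeDotTree()] (or compatible).
#' @param spectrumId spectrum identifier to attach; defaults to the
#'   digraph name.
#' @return a validated [FragmentationTree-class].
#' @export
readDotTree <- function(path, spectrumId = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  gname <- sub("^digraph\\s*\"?([^\"{]*)\"?\\s*\\{.*$", "\\1",
               grep("^digraph", lines, value = TRUE)[1])
  gname <- trimws(gname)
  if (is.null(spectrumId)) spectrumId <- if (nzchar(gname)) gname else "tree"
  edgePat <- "^\"?([A-Za-z0-9_]+)\"?\\s*->\\s*\"?([A-Za-z0-9_]+)\"?"
  nodePat <- "^\"?([A-Za-z0-9_]+)\"?\\s*\\[(.*)\\]"
  nodes <- list()       # id -> list(formula, mass, intensity)
  edges <- list()       # list(from, to, loss)
  for (ln in lines) {
    if (grepl("^(digraph|\\}|#|//)", ln) || !nzchar(ln)) next
    if (grepl("->", ln, fixed = TRUE)) {
      from <- sub(paste0(edgePat, ".*$"), "\\1", ln)
      to <- sub(paste0(edgePat, ".*$"), "\\2", ln)
      lab <- .dotAttr(ln, "label")
      if (is.na(lab))
        stop("edge without loss label: '", ln, "'", call. = FALSE)
      edges[[length(edges) + 1L]] <- list(from = from, to = to, loss = lab)
    } else if (grepl(nodePat, ln)) {
      id <- sub(paste0(nodePat, ".*$"), "\\1", ln)
      lab <- .dotAttr(ln, "label")
      if (is.na(lab))
        stop("node without label: '", ln, "'", call. = FALSE)
      parts <- strsplit(lab, "\\\\n")[[1]]
      inten <- suppressWarnings(as.numeric(.dotAttr(ln, "intensity")))
      nodes[[id]] <- list(formula = parseFormula(parts[1]),
                          mass = suppressWarnings(as.numeric(parts[2])),
                          intensity = inten)
    }
  }
  if (!length(nodes)) stop("no nodes in DOT file ", path, call. = FALSE)
  ids <- names(nodes)
  parent <- setNames(rep(0L, length(ids)), ids)
  lossOf <- setNames(vector("list", length(ids)), ids)
  for (e in edges) {
    if (!(e$from %in% ids) || !(e$to %in% ids))
      stop("edge references unknown node: ", e$from, " -> ", e$to,
           call. = FALSE)
    if (parent[e$to] != 0L)
      stop("structural error: node '", e$to, "' has multiple parents",
           call. = FALSE)
    parent[e$to] <- match(e$from, ids)
    lossOf[[e$to]] <- parseFormula(e$loss)
  }
  roots <- which(parent == 0L)
  if (length(roots) != 1L)
    stop("structural error: tree must have exactly one root (found ",
         length(roots), ")", call. = FALSE)
  ## consistency: declared child formula must equal parent - loss
  for (k in seq_along(ids)) {
    p <- parent[k]
    if (p == 0L) next
    expect <- nodes[[p]]$formula - lossOf[[k]]
    if (!all(expect == nodes[[k]]$formula))
      stop("consistency error: loss on edge into '", ids[k],
           "' does not equal parent minus child", call. = FALSE)
  }
  losses <- lapply(seq_along(ids), function(k)
    if (parent[k] == 0L) emptyFormula() else lossOf[[k]])
  inten <- vapply(nodes, function(nd)
    if (is.null(nd$intensity) || length(nd$intensity) == 0L) NA_real_
    else nd$intensity, numeric(1))
  fragmentationTree(parent = unname(parent), losses = losses,
                    rootFormula = nodes[[roots]]$formula,
                    spectrumId = spectrumId, intensities = unname(inten))
}

.dotAttr <- function(line, name) {
  pat <- paste0(name, "\\s*=\\s*\"([^\"]*)\"")
  m <- regmatches(line, regexpr(pat, line, perl = TRUE))
  if (!length(m)) return(NA_character_)
  sub(pat, "\\1", m, perl = TRUE)
}

#' Noise-filter a spectrum with its fragmentation tree
#'
#' Keeps only the peaks annotated by a tree node, i.e. peaks whose mass
#' matches some node ion mass within max(`ppm` relative, `absDa` absolute);
#' surviving intensities are unchanged. A result that is empty or consists
#' only of the precursor peak is flagged for discard via the `"discard"`
#' attribute — the caller decides.
#'
#' @param s a [Spectrum-class].
#' @param tree the [FragmentationTree-class] annotating `s`.
#' @param ppm,absDa matching tolerance.
#' @return the filtered [Spectrum-class] with attribute `"discard"`.
#' @export
noiseFilter <- function(s, tree, ppm = 10, absDa = 0.002) {
  if (!identical(tree@spectrumId, spectrumId(s)))
    stop("tree annotates spectrum '", tree@spectrumId, "', not '",
         spectrumId(s), "'", call. = FALSE)
  pm <- peakMasses(s)
  keep <- vapply(pm, function(m)
    any(massMatches(m, tree@masses, ppm, absDa)), logical(1))
  out <- spectrum(spectrumId(s), precursorMz(s), pm[keep],
                  peakIntensities(s)[keep], ionMode = ionMode(s),
                  compoundMass = compoundMass(s),
                  compoundId = compoundId(s))
  precOnly <- nPeaks(out) == 1L &&
    massMatches(peakMasses(out)[1], precursorMz(s), ppm, absDa)
  attr(out, "discard") <- nPeaks(out) == 0L || precOnly
  out
}

#' Toy fragmentation-tree annotator (fixture plumbing)
#'
#' A greedy stand-in for a real fragmentation-tree engine, used only to
#' build test fixtures and synthetic benchmarks: peaks are visited in
#' descending mass order and attached to the first already-annotated node
#' from which a single loss out of [lossAlphabet()] explains the peak mass
#' within tolerance with a valid resulting formula. Unexplainable peaks
#' are skipped; a spectrum with no explainable peak yields a single-node
#' (precursor-only) tree.
#'
#' @param s a [Spectrum-class].
#' @param precursorFormula formula of the precursor ion; its \[M+H\]+ mass
#'   must lie within `precursorPpm` of `precursorMz(s)`.
#' @param ppm,absDa peak-matching tolerance.
#' @param losses loss alphabet (character vector of formula strings).
#' @param precursorPpm allowed precursor-vs-formula deviation.
#' @return a validated [FragmentationTree-class].
#' @export
toyTreeAnnotator <- function(s, precursorFormula, ppm = 10, absDa = 0.002,
                             losses = lossAlphabet(), precursorPpm = 10) {
  rootF <- asFormula(precursorFormula)
  rootMz <- ionMass(rootF)
  if (abs(rootMz - precursorMz(s)) > ppmWindow(precursorMz(s), precursorPpm))
    stop("precursor formula mass ", format(rootMz),
         " not within ", precursorPpm, " p.p.m. of precursor m/z ",
         format(precursorMz(s)), call. = FALSE)
  lossF <- lapply(losses, parseFormula)
  lossMass <- vapply(lossF, formulaMass, numeric(1))
  pm <- peakMasses(s); pint <- peakIntensities(s)
  ord <- order(pm, decreasing = TRUE)
  ## node store grown greedily
  nodeF <- list(rootF)
  nodeMass <- rootMz
  nodeParent <- 0L
  nodeLoss <- list(emptyFormula())
  nodeInt <- NA_real_
  rootPeak <- which(massMatches(pm, rootMz, ppm, absDa))
  if (length(rootPeak)) nodeInt[1] <- pint[rootPeak[which.max(pint[rootPeak])]]
  for (k in ord) {
    if (any(massMatches(pm[k], nodeMass, ppm, absDa))) next  # already annotated
    attached <- FALSE
    for (j in seq_along(nodeF)) {
      if (attached) break
      for (li in seq_along(lossF)) {
        cand <- nodeMass[j] - lossMass[li]
        if (abs(pm[k] - cand) <= max(ppmWindow(cand, ppm), absDa)) {
          childF <- nodeF[[j]] - lossF[[li]]
          if (all(childF >= 0L)) {
            nodeF[[length(nodeF) + 1L]] <- childF
            nodeMass <- c(nodeMass, ionMass(childF))
            nodeParent <- c(nodeParent, j)
            nodeLoss[[length(nodeLoss) + 1L]] <- lossF[[li]]
            nodeInt <- c(nodeInt, pint[k])
            attached <- TRUE
            break
          }
        }
      }
    }
  }
  fragmentationTree(parent = nodeParent, losses = nodeLoss,
                    rootFormula = rootF, spectrumId = spectrumId(s),
                    intensities = nodeInt)
}
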