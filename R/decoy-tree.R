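## Fragmentation-tree re-rooting decoy: keep the tree's structure and all
## its losses, relocate the root, give the new root the precursor-ion
## formula, and recompute all fragment formulas by subtracting losses along
## the re-rooted edges. Subtrees that end up with chemically impossible
## formulas (negative element counts) are re-grafted onto uniformly chosen
## valid nodes. The new root is not drawn uniformly: node v is chosen with
## relative probability 1/(n_v + 1), where n_v is the number of edges that
## would need re-grafting if v became the root.

## reverse the parent pointers along the path from newRoot up to the old
## root; each reversed edge keeps its loss (stored child-side)
.reRootStructure <- function(parent, lossM, newRoot) {
  chain <- integer(0); j <- newRoot
  while (j != 0L) { chain <- c(chain, j); j <- parent[j] }
  newParent <- parent; newLoss <- lossM
  if (length(chain) > 1L) {
    for (k in seq_len(length(chain) - 1L)) {
      child <- chain[k]; par <- chain[k + 1L]
      newParent[par] <- child
      newLoss[par, ] <- lossM[child, ]   # edge loss travels with the edge
    }
  }
  newParent[newRoot] <- 0L
  newLoss[newRoot, ] <- 0L
  list(parent = newParent, lossM = newLoss)
}

## number of maximal invalid subtrees (edges requiring a re-graft) after
## re-rooting at v: simulate the formula propagation once and count edges
## whose child formula is invalid while the parent formula is valid
.nRegraft <- function(tree, v) {
  rr <- .reRootStructure(tree@parent, tree@losses, v)
  formM <- .propagateFormulas(rr$parent, rr$lossM, rootFormula(tree))
  valid <- rowSums(formM < 0L) == 0L
  sum(vapply(seq_along(rr$parent), function(i) {
    p <- rr$parent[i]
    p != 0L && !valid[i] && valid[p]
  }, logical(1)))
}

#' Re-rooting weights of a fragmentation tree
#'
#' For every candidate root — every node except the current root, since
#' the decoy must not reproduce the original (true) spectrum — the number
#' `n_regraft` of edges that would require re-grafting if that node became
#' the root, and the relative root-choice weight `1 / (n_regraft + 1)`.
#'
#' @param tree a [FragmentationTree-class].
#' @return data.frame with columns `node`, `n_regraft`, `weight`.
#' @export
reRootWeights <- function(tree) {
  cand <- setdiff(seq_len(nNodes(tree)), which(tree@parent == 0L))
  nre <- vapply(cand, function(v) .nRegraft(tree, v), numeric(1))
  data.frame(node = cand, n_regraft = as.integer(nre),
             weight = 1 / (nre + 1))
}

## all descendants of node v (including v) under parent pointers
.subtreeNodes <- function(parent, v) {
  n <- length(parent)
  inSub <- logical(n); inSub[v] <- TRUE
  repeat {
    add <- which(!inSub & parent != 0L & inSub[pmax(parent, 1L)])
    add <- add[parent[add] != 0L & inSub[parent[add]]]
    if (!length(add)) break
    inSub[add] <- TRUE
  }
  which(inSub)
}

#' Fragmentation-tree re-rooting decoy spectrum
#'
#' @param target the [Spectrum-class] the tree annotates (supplies the
#'   identifier, ion mode and precursor mass of the decoy).
#' @param tree a valid [FragmentationTree-class] for `target`.
#' @param maxRegraftAttempts uniform attachment attempts per invalid
#'   subtree before the subtree's peaks are dropped.
#' @return a decoy [Spectrum-class] whose peaks are the ion masses of the
#'   re-rooted tree's (valid) node formulas, carrying the original peak
#'   intensities. Attributes: `"rootChoice"` (index of the sampled new
#'   root), `"dropped"` (number of nodes dropped because no valid re-graft
#'   existed).
#' @export
treeBasedDecoy <- function(target, tree, maxRegraftAttempts = 100L) {
  n <- nNodes(tree)
  if (n == 1L) {
    ## precursor-only tree: no re-rooting possible; such spectra are
    ## normally discarded by noise filtering before decoy generation
    out <- spectrum(spectrumId(target), precursorMz(target),
                    nodeMasses(tree), tree@intensities,
                    ionMode = ionMode(target))
    attr(out, "rootChoice") <- 1L
    attr(out, "dropped") <- 0L
    return(out)
  }
  rw <- reRootWeights(tree)
  v <- rw$node[sample.int(nrow(rw), 1L, prob = rw$weight)]
  rr <- .reRootStructure(tree@parent, tree@losses, v)
  parent <- rr$parent; lossM <- rr$lossM
  rootF <- rootFormula(tree)        # new root takes the precursor formula
  keep <- rep(TRUE, n)
  dropped <- 0L
  repeat {
    formM <- .propagateFormulas(parent, lossM, rootF)
    valid <- rowSums(formM < 0L) == 0L
    ## a node needs re-grafting when its formula turned invalid under a
    ## valid parent, or when it duplicates another node's formula (two
    ## identical fragment ions cannot coexist in one spectrum)
    bad <- which(keep & !valid &
                   vapply(seq_len(n), function(i)
                     parent[i] != 0L && valid[parent[i]] && keep[parent[i]],
                     logical(1)))
    if (!length(bad)) {
      kept <- which(keep)
      keys <- apply(formM, 1L, paste, collapse = ",")
      bad <- kept[duplicated(keys[kept]) & kept != which(parent == 0L)]
      bad <- setdiff(bad, which(parent == 0L))
    }
    if (!length(bad)) break
    cNode <- bad[1L]
    sub <- .subtreeNodes(parent, cNode)
    cand <- setdiff(which(keep & valid), sub)
    success <- FALSE
    if (length(cand)) {
      for (a in seq_len(maxRegraftAttempts)) {
        parent[cNode] <- cand[sample.int(length(cand), 1L)]
        formM2 <- .propagateFormulas(parent, lossM, rootF)
        subOk <- all(rowSums(formM2[sub, , drop = FALSE] < 0L) == 0L)
        if (subOk) {
          ## the moved subtree must not collide with fragments outside it
          keys2 <- apply(formM2, 1L, paste, collapse = ",")
          outside <- setdiff(which(keep), sub)
          subOk <- !any(keys2[sub] %in% keys2[outside]) &&
            !anyDuplicated(keys2[sub])
        }
        if (subOk) { success <- TRUE; break }
      }
    }
    if (!success) {
      keep[sub] <- FALSE
      dropped <- dropped + length(sub)
      ## park the dropped subtree at the root so propagation stays finite
      parent[cNode] <- which(parent == 0L)[1L]
    }
  }
  formM <- .propagateFormulas(parent, lossM, rootF)
  el <- formulaElements()
  useNode <- keep & !is.na(tree@intensities)
  masses <- vapply(which(useNode), function(i)
    ionMass(setNames(formM[i, ], el)), numeric(1))
  intens <- tree@intensities[useNode]
  out <- spectrum(spectrumId(target), precursorMz(target), masses, intens,
                  ionMode = ionMode(target))
  attr(out, "rootChoice") <- v
  attr(out, "dropped") <- dropped
  out
}
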