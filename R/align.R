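## Tolerance-aware peak alignment.
##
## Candidate peak pairs are all (query, reference) pairs within the mass
## tolerance — optionally also pairs displaced by the precursor-mass
## difference (the "shifted" rule behind modified-cosine scoring). The
## returned matching maximizes the summed pair weights exactly: the
## candidate-pair graph is split into connected components and each
## component is solved by exhaustive search (components are tiny at
## realistic tolerances; a greedy fallback guards pathological ones).

#' Align the peaks of two spectra
#'
#' @param q,r [Spectrum-class] objects (query and reference).
#' @param tolerancePpm mass tolerance for a pair, in p.p.m. of the
#'   reference peak mass.
#' @param shifted if `TRUE`, a query peak may additionally match a
#'   reference peak displaced by `precursorMz(q) - precursorMz(r)`.
#' @param wq,wr optional per-peak weights (default: intensities); the
#'   matching maximizes the sum of `wq[i] * wr[j]` over matched pairs.
#' @return list with `pairs` (two-column matrix of query/reference peak
#'   indices, each index used at most once), `weight` (the maximized
#'   total), and `tolerancePpm`.
#' @export
alignPeaks <- function(q, r, tolerancePpm = 10, shifted = FALSE,
                       wq = NULL, wr = NULL) {
  stopifnot(tolerancePpm > 0)
  mq <- peakMasses(q); mr <- peakMasses(r)
  if (is.null(wq)) wq <- peakIntensities(q)
  if (is.null(wr)) wr <- peakIntensities(r)
  empty <- list(pairs = matrix(integer(0), ncol = 2,
                               dimnames = list(NULL, c("query", "reference"))),
                weight = 0, tolerancePpm = tolerancePpm)
  if (!length(mq) || !length(mr)) return(empty)
  shift <- if (shifted) precursorMz(q) - precursorMz(r) else 0
  qi <- integer(0); ri <- integer(0)
  for (j in seq_along(mr)) {
    tol <- ppmWindow(mr[j], tolerancePpm)
    hit <- which(abs(mq - mr[j]) <= tol)
    if (shifted && abs(shift) > tol)
      hit <- union(hit, which(abs(mq - (mr[j] + shift)) <= tol))
    if (length(hit)) { qi <- c(qi, hit); ri <- c(ri, rep(j, length(hit))) }
  }
  if (!length(qi)) return(empty)
  w <- wq[qi] * wr[ri]
  sel <- .maxWeightMatching(qi, ri, w)
  pairs <- cbind(query = qi[sel], reference = ri[sel])
  pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  list(pairs = pairs, weight = sum(w[sel]), tolerancePpm = tolerancePpm)
}

## exact maximum-weight bipartite matching on a sparse candidate edge list;
## returns indices of selected edges
.maxWeightMatching <- function(qi, ri, w) {
  nE <- length(qi)
  ## connected components of the bipartite graph via label propagation
  compQ <- setNames(rep(NA_integer_, length(unique(qi))), unique(qi))
  comp <- integer(nE); nxt <- 0L
  edgeQ <- match(qi, unique(qi))
  ## union-find over edges sharing a query or reference node
  parent <- seq_len(nE)
  findp <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  unite <- function(a, b) { ra <- findp(a); rb <- findp(b); if (ra != rb) parent[rb] <<- ra }
  byQ <- split(seq_len(nE), qi)
  for (g in byQ) if (length(g) > 1L) for (k in g[-1L]) unite(g[1L], k)
  byR <- split(seq_len(nE), ri)
  for (g in byR) if (length(g) > 1L) for (k in g[-1L]) unite(g[1L], k)
  roots <- vapply(seq_len(nE), findp, integer(1))
  sel <- integer(0)
  for (g in split(seq_len(nE), roots)) {
    if (length(g) == 1L) { sel <- c(sel, g); next }
    if (length(g) <= 22L) sel <- c(sel, g[.bruteMatch(qi[g], ri[g], w[g])])
    else sel <- c(sel, g[.greedyMatch(qi[g], ri[g], w[g])])
  }
  sel
}

## exhaustive search over matchings within one small component
.bruteMatch <- function(qi, ri, w) {
  qNodes <- unique(qi)
  best <- list(weight = -Inf, sel = integer(0))
  recurse <- function(k, usedR, sel, acc) {
    ## bound: remaining max possible
    if (k > length(qNodes)) {
      if (acc > best$weight) best <<- list(weight = acc, sel = sel)
      return()
    }
    cand <- which(qi == qNodes[k] & !(ri %in% usedR))
    ## option: leave this query peak unmatched
    recurse(k + 1L, usedR, sel, acc)
    for (e in cand)
      recurse(k + 1L, c(usedR, ri[e]), c(sel, e), acc + w[e])
  }
  recurse(1L, integer(0), integer(0), 0)
  best$sel
}

## greedy fallback for oversized components: take edges by descending
## weight, skipping conflicts
.greedyMatch <- function(qi, ri, w) {
  ord <- order(w, decreasing = TRUE)
  usedQ <- c(); usedR <- c(); sel <- integer(0)
  for (e in ord) {
    if (qi[e] %in% usedQ || ri[e] %in% usedR) next
    sel <- c(sel, e); usedQ <- c(usedQ, qi[e]); usedR <- c(usedR, ri[e])
  }
  sel
}
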