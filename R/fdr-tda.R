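## Separated target-decoy FDR estimation. Queries are searched separately
## against the target and the decoy library; hits are merged and sorted by
## score, and for any threshold the number of decoy hits above it estimates
## the number of false target hits above it, scaled by the percentage of
## incorrect targets (PIT):
##
##   FDR(t) = PIT * D(t) / T(t)
##
## The q-value of a hit is the minimal FDR at which the hit is still
## reported, i.e. the running minimum of FDR over all thresholds at or
## below the hit's score. With PIT = 1 this reduces to the classical
## separated target-decoy estimator D(t) / T(t).

#' Merge target and decoy hits into a score-sorted hit list
#'
#' At equal score a decoy hit sorts before a target hit (the conservative
#' convention: it maximizes the estimated FDR at that score).
#'
#' @param targets,decoys hit data.frames from [searchLibrary()].
#' @return merged data.frame sorted by descending score.
#' @export
mergeHitLists <- function(targets, decoys) {
  all <- rbind(targets, decoys)
  all[order(-all$score, all$origin != "decoy", all$reference_id), ,
      drop = FALSE]
}

#' Estimate FDR and q-values by separated target-decoy search
#'
#' @param targets data.frame of best target hits (one per query).
#' @param decoys data.frame of best decoy hits (same query set).
#' @param pit percentage of incorrect targets in \[0, 1\]; usually
#'   [estimatePit()] of a mixture model fitted to the target scores, or 1
#'   for the uncorrected estimator.
#' @return data.frame (one row per target hit, sorted by descending
#'   score): `query_id`, `reference_id`, `threshold` (the hit's score),
#'   `n_targets` and `n_decoys` at or above the threshold, `fdr`, and the
#'   monotonized `q`. Attribute `"pit"` stores the PIT used.
#' @examples
#' t <- data.frame(query_id = letters[1:4], reference_id = "r",
#'                 score = c(.9, .7, .5, .3), n_matched = 3L,
#'                 origin = "target")
#' d <- data.frame(query_id = letters[1:2], reference_id = "d",
#'                 score = c(.6, .4), n_matched = 3L, origin = "decoy")
#' estimateFdrTda(t, d, pit = 1)
#' @export
estimateFdrTda <- function(targets, decoys, pit = 1) {
  stopifnot(pit >= 0, pit <= 1)
  if (!nrow(targets)) {
    warning("empty target hit list; returning empty FDR curve")
    return(structure(data.frame(query_id = character(0),
                                reference_id = character(0),
                                threshold = numeric(0),
                                n_targets = integer(0),
                                n_decoys = integer(0),
                                fdr = numeric(0), q = numeric(0)),
                     pit = pit))
  }
  ts <- targets[order(-targets$score, targets$reference_id), , drop = FALSE]
  ds <- if (nrow(decoys)) decoys$score else numeric(0)
  thr <- ts$score
  nT <- seq_along(thr)   # targets with score >= thr (sorted descending)
  ## careful with ties: count all targets at or above the threshold value
  nT <- vapply(thr, function(t) sum(ts$score >= t), integer(1))
  nD <- vapply(thr, function(t) sum(ds >= t), integer(1))
  fdr <- pit * nD / nT
  q <- rev(cummin(rev(fdr)))
  structure(data.frame(query_id = ts$query_id,
                       reference_id = ts$reference_id,
                       threshold = thr, n_targets = nT, n_decoys = nD,
                       fdr = fdr, q = q, stringsAsFactors = FALSE),
            pit = pit)
}

#' Decoy-based p-value of a search score
#'
#' The estimated p-value is the ratio of decoy hits with score above the
#' given score (strictly greater, so a score above every decoy has
#' p = 0). The add-one (Laplace) variant returns
#' `(count + 1) / (n + 1)` for users who require strictly positive
#' p-values.
#'
#' @param score numeric vector of scores to evaluate.
#' @param decoys data.frame of decoy hits, or a numeric vector of decoy
#'   scores; must be non-empty.
#' @param laplace use the add-one variant.
#' @return numeric vector of p-values in \[0, 1\].
#' @export
estimatePValue <- function(score, decoys, laplace = FALSE) {
  ds <- if (is.data.frame(decoys)) decoys$score else as.numeric(decoys)
  if (!length(ds)) stop("empty decoy hit list", call. = FALSE)
  cnt <- vapply(score, function(s) sum(ds > s), numeric(1))
  if (laplace) (cnt + 1) / (length(ds) + 1) else cnt / length(ds)
}

#' Annotation counts at given FDR levels
#'
#' @param fdrCurve result of [estimateFdrTda()] or [fdrFromPep()].
#' @param levels FDR (q-value) levels.
#' @return data.frame with `fdr_level`, `score_threshold` (smallest score
#'   achieving the level; `NA` if unattainable) and `n_annotations`.
#' @export
annotationsAtFdr <- function(fdrCurve, levels = c(0.01, 0.05)) {
  out <- lapply(levels, function(lv) {
    ok <- which(fdrCurve$q <= lv)
    if (!length(ok))
      data.frame(fdr_level = lv, score_threshold = NA_real_,
                 n_annotations = 0L)
    else {
      k <- max(ok)  # deepest hit still within the level
      data.frame(fdr_level = lv,
                 score_threshold = fdrCurve$threshold[k],
                 n_annotations = k)
    }
  })
  do.call(rbind, out)
}
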