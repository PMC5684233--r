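## Synthetic benchmark: a self-contained evaluation world in which every
## query's true identity is known, so estimated q-values can be compared
## with exact ones. Compounds are random molecular formulas assembled from
## the standard neutral-loss alphabet (a small core plus a multiset of
## losses); their fragments are partial-loss subtractions, so distinct
## compounds share fragment ions exactly the way the decoy constructions
## assume. Three query classes emulate the evaluation setting: perturbed
## copies of library spectra (true hits), structurally similar isomers
## with partially shifted peaks (high-scoring wrong hits), and re-fragmented
## isomers with no library counterpart (null hits).

#' Specification of a synthetic benchmark
#'
#' @param nCompounds number of library compounds (>= 2).
#' @param nQueries number of query spectra.
#' @param peaksPerSpectrum integer range (min, max) of fragment peaks per
#'   library spectrum, precursor ion included.
#' @param isomerFraction fraction of queries given a structurally similar
#'   in-library isomer with overlapping peaks.
#' @param trueFraction fraction of queries that are perturbed copies of a
#'   library compound (correct identifications); the remainder after
#'   `isomerFraction` are null queries.
#' @param noisePeaks integer range of random noise peaks added to each
#'   spectrum.
#' @param jitterPpm query peak-mass jitter, p.p.m. (uniform in +/- this).
#' @param intensitySigma sdlog of the multiplicative lognormal intensity
#'   noise on query peaks.
#' @param dropout probability that a query peak is dropped.
#' @param seed RNG seed; the whole benchmark is deterministic given it.
#' @return a validated spec (list with class `"BenchmarkSpec"`).
#' @export
benchmarkSpec <- function(nCompounds = 200L, nQueries = 500L,
                          peaksPerSpectrum = c(6L, 12L),
                          isomerFraction = 0.1, trueFraction = 0.5,
                          noisePeaks = c(0L, 5L), jitterPpm = 5,
                          intensitySigma = 0.3, dropout = 0.1,
                          seed = 1L) {
  stopifnot(nCompounds >= 2L, nQueries >= 1L,
            length(peaksPerSpectrum) == 2L,
            peaksPerSpectrum[1] >= 3L,
            peaksPerSpectrum[2] >= peaksPerSpectrum[1],
            isomerFraction >= 0, isomerFraction <= 1,
            trueFraction >= 0, trueFraction + isomerFraction <= 1,
            length(noisePeaks) == 2L, noisePeaks[2] >= noisePeaks[1])
  structure(list(nCompounds = as.integer(nCompounds),
                 nQueries = as.integer(nQueries),
                 peaksPerSpectrum = as.integer(peaksPerSpectrum),
                 isomerFraction = isomerFraction,
                 trueFraction = trueFraction,
                 noisePeaks = as.integer(noisePeaks),
                 jitterPpm = jitterPpm,
                 intensitySigma = intensitySigma,
                 dropout = dropout, seed = as.integer(seed)),
            class = "BenchmarkSpec")
}

#' @export
print.BenchmarkSpec <- function(x, ...) {
  cat(sprintf(
    "BenchmarkSpec: %d compounds, %d queries (true %.0f%%, isomer %.0f%%), seed %d\n",
    x$nCompounds, x$nQueries, 100 * x$trueFraction,
    100 * x$isomerFraction, x$seed))
  invisible(x)
}

.CORES <- c("CH4", "C2H6", "C2H5N", "C3H8", "C2H6O", "C3H6O")

## attachment law for fragmentation cascades: with probability
## .CASCADE_P a fragment fragments further (parent = the most recently
## added node, extending a cascade), otherwise it branches off any
## existing fragment uniformly. This yields the chain-heavy, moderately
## branched trees typical of sequential fragmentation, rather than the
## star-like trees uniform attachment would produce.
.CASCADE_P <- 0.6
.attachParent <- function(nExisting) {
  if (nExisting == 1L || runif(1) < .CASCADE_P) nExisting
  else sample.int(nExisting, 1L)
}

## random compound: core + multiset of losses; the fragmentation tree is a
## random cascade-attachment tree over those losses, so every node formula
## is a partial-loss subtraction and automatically valid
.randomCompound <- function(k, losses = lossAlphabet()) {
  core <- parseFormula(sample(.CORES, 1L))
  picks <- sample(losses, k - 1L, replace = TRUE)
  lossF <- lapply(picks, parseFormula)
  rootF <- Reduce(`+`, lossF, core)
  parent <- integer(k); parent[1] <- 0L
  for (j in seq_len(k - 1L))
    parent[j + 1L] <- .attachParent(j)
  list(rootF = rootF, parent = parent,
       losses = c(list(emptyFormula()), lossF))
}

## clean spectrum of a compound: node ion masses with fresh intensities
.compoundSpectrum <- function(id, cmp, noiseRange) {
  el <- formulaElements()
  lossM <- do.call(rbind, lapply(cmp$losses, function(f) asFormula(f)))
  formM <- .propagateFormulas(cmp$parent, lossM, cmp$rootF)
  masses <- apply(formM, 1L, function(f) ionMass(setNames(f, el)))
  inten <- runif(length(masses), 5, 100)
  prec <- ionMass(cmp$rootF)
  nNoise <- sample(seq(noiseRange[1], noiseRange[2]), 1L)
  if (nNoise > 0L) {
    nm <- runif(nNoise, 50, max(51, prec - 1))
    masses <- c(masses, nm)
    inten <- c(inten, runif(nNoise, 3, 25))
  }
  spectrum(id, prec, masses, inten,
           compoundMass = formulaMass(cmp$rootF), compoundId = id)
}

## measurement noise: mass jitter, multiplicative intensity noise, peak
## dropout, extra noise peaks
.perturbSpectrum <- function(s, id, spec) {
  m <- peakMasses(s); i <- peakIntensities(s)
  m <- m * (1 + runif(length(m), -spec$jitterPpm, spec$jitterPpm) * 1e-6)
  i <- i * rlnorm(length(i), 0, spec$intensitySigma)
  keep <- runif(length(m)) > spec$dropout
  if (sum(keep) < 3L) keep[sample.int(length(keep), 3L)] <- TRUE
  m <- m[keep]; i <- i[keep]
  nNoise <- sample(seq(spec$noisePeaks[1], spec$noisePeaks[2]), 1L)
  if (nNoise > 0L) {
    prec <- precursorMz(s)
    m <- c(m, runif(nNoise, 50, max(51, prec - 1)))
    i <- c(i, runif(nNoise, 3, 25))
  }
  prec <- precursorMz(s) *
    (1 + runif(1, -spec$jitterPpm, spec$jitterPpm) * 1e-6)
  spectrum(id, prec, m, i)
}

## a different fragmentation of the same root formula: random losses drawn
## subject to validity, mirroring an isomeric compound absent from the
## library
.refragment <- function(rootF, k, losses = lossAlphabet()) {
  lossF <- lapply(losses, parseFormula)
  parent <- 0L
  forms <- list(rootF)
  lsUsed <- list(emptyFormula())
  guard <- 0L
  while (length(forms) < k && guard < 50L * k) {
    guard <- guard + 1L
    p <- .attachParent(length(forms))
    l <- lossF[[sample.int(length(lossF), 1L)]]
    child <- forms[[p]] - l
    if (any(child < 0L) || child[["C"]] < 1L) next
    forms[[length(forms) + 1L]] <- child
    parent <- c(parent, p)
    lsUsed[[length(lsUsed) + 1L]] <- l
  }
  list(rootF = rootF, parent = parent, losses = lsUsed)
}

#' Generate a synthetic benchmark
#'
#' @param spec a [benchmarkSpec()].
#' @return list with `target` (a [SpectralLibrary-class] of reference
#'   spectra, identifiers = compound identities), `trees` (named list of
#'   [FragmentationTree-class] built by [toyTreeAnnotator()]), `queries`
#'   (a [SpectralLibrary-class]) and `truth` (data.frame `query_id`,
#'   `true_id`, where `true_id` is `"absent"` for queries without a true
#'   library match). Deterministic given `spec$seed`.
#' @export
generateBenchmark <- function(spec) {
  stopifnot(inherits(spec, "BenchmarkSpec"))
  withSeed(spec$seed, {
    ## --- library compounds with unique root formulas ---
    n <- spec$nCompounds
    cmps <- vector("list", n)
    seen <- character(0)
    for (i in seq_len(n)) {
      for (try in seq_len(200L)) {
        k <- sample(seq(spec$peaksPerSpectrum[1], spec$peaksPerSpectrum[2]),
                    1L)
        cmp <- .randomCompound(k)
        key <- formulaToString(cmp$rootF)
        if (!(key %in% seen) && formulaMass(cmp$rootF) < 1000) break
      }
      seen <- c(seen, key)
      cmps[[i]] <- cmp
    }
    ids <- sprintf("CPD%04d", seq_len(n))
    targetSpecs <- lapply(seq_len(n), function(i)
      .compoundSpectrum(ids[i], cmps[[i]], spec$noisePeaks))
    target <- spectralLibrary(targetSpecs, name = "target")
    trees <- lapply(seq_len(n), function(i)
      toyTreeAnnotator(targetSpecs[[i]], cmps[[i]]$rootF))
    names(trees) <- ids
    ## --- queries ---
    nQ <- spec$nQueries
    nTrue <- round(spec$trueFraction * nQ)
    nIso <- round(spec$isomerFraction * nQ)
    nNull <- nQ - nTrue - nIso
    queries <- list(); truth <- character(0)
    lossMassTab <- vapply(lapply(lossAlphabet(), parseFormula),
                          formulaMass, numeric(1))
    ## each query is its own compound measurement: base compounds are drawn
    ## without replacement whenever the library is large enough, so queries
    ## are distinct compounds (as in a real cross-library evaluation) and
    ## do not share decoy counterparts
    drawBase <- function(count) sample.int(n, count, replace = count > n)
    baseTrue <- drawBase(nTrue)
    baseIso <- drawBase(nIso)
    baseNull <- drawBase(nNull)
    for (q in seq_len(nTrue)) {
      i <- baseTrue[q]
      qid <- sprintf("QTRU%04d", q)
      queries[[length(queries) + 1L]] <-
        .perturbSpectrum(targetSpecs[[i]], qid, spec)
      truth[qid] <- ids[i]
    }
    for (q in seq_len(nIso)) {
      i <- baseIso[q]
      qid <- sprintf("QISO%04d", q)
      s <- targetSpecs[[i]]
      m <- peakMasses(s); it <- peakIntensities(s)
      shiftable <- which(m < precursorMz(s) - 1)
      nShift <- max(1L, round(0.3 * length(shiftable)))
      sel <- sample(shiftable, min(nShift, length(shiftable)))
      for (k in sel) {
        delta <- lossMassTab[sample.int(length(lossMassTab), 1L)] *
          sample(c(-1, 1), 1L)
        cand <- m[k] + delta
        if (cand > 30 && cand < precursorMz(s)) m[k] <- cand
      }
      iso <- spectrum(qid, precursorMz(s), m, it)
      queries[[length(queries) + 1L]] <- .perturbSpectrum(iso, qid, spec)
      truth[qid] <- "absent"
    }
    for (q in seq_len(nNull)) {
      i <- baseNull[q]
      qid <- sprintf("QNUL%04d", q)
      cmp <- .refragment(cmps[[i]]$rootF, nPeaks(targetSpecs[[i]]))
      s <- .compoundSpectrum(qid, cmp, spec$noisePeaks)
      queries[[length(queries) + 1L]] <- .perturbSpectrum(s, qid, spec)
      truth[qid] <- "absent"
    }
    list(target = target, trees = trees,
         queries = spectralLibrary(queries, name = "queries"),
         truth = data.frame(query_id = names(truth), true_id = unname(truth),
                            stringsAsFactors = FALSE))
  })
}

#' True q-values from known query identities
#'
#' With ground truth available the true FDR at any score threshold is the
#' fraction of false hits among all hits at or above the threshold, and
#' the true q-value of a hit is the smallest FDR at which it is reported.
#'
#' @param hits data.frame of target hits ([searchLibrary()] output).
#' @param truth data.frame `query_id`, `true_id` covering all hit queries.
#' @return data.frame sorted by descending score: `query_id`,
#'   `reference_id`, `threshold`, `correct`, `true_fdr`, `true_q`.
#' @export
trueQValues <- function(hits, truth) {
  idx <- match(hits$query_id, truth$query_id)
  if (anyNA(idx))
    stop("queries missing from ground truth: ",
         paste(head(hits$query_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  correct <- truth$true_id[idx] == hits$reference_id
  ord <- order(-hits$score, hits$reference_id)
  h <- hits[ord, , drop = FALSE]; correct <- correct[ord]
  fdr <- vapply(h$score, function(t) {
    sel <- h$score >= t
    mean(!correct[sel])
  }, numeric(1))
  q <- rev(cummin(rev(fdr)))
  data.frame(query_id = h$query_id, reference_id = h$reference_id,
             threshold = h$score, correct = correct, true_fdr = fdr,
             true_q = q, stringsAsFactors = FALSE)
}

#' Calibration report: estimated vs true q-values and p-value uniformity
#'
#' @param estimated FDR curve from [estimateFdrTda()] or [fdrFromPep()]
#'   (needs `query_id` and `q`).
#' @param trueQ result of [trueQValues()] on the same hits.
#' @param pValues optional vector of p-values for the known-false hits;
#'   under the null these must be uniform.
#' @param band true-q interval over which the maximum |estimated - true|
#'   deviation is summarized.
#' @return list with `table` (per-hit estimated vs true q), `maxAbsDevInBand`,
#'   `smallQBias` (whether estimates undershoot below true q = 0.05, the
#'   documented isomer-driven bias region), `ks` (Kolmogorov-Smirnov test
#'   of the p-values against uniform, or `NULL`) and `qq` (p-value
#'   quantile table).
#' @export
calibrationReport <- function(estimated, trueQ, pValues = NULL,
                              band = c(0.05, 0.3)) {
  tab <- merge(estimated[, c("query_id", "q")],
               trueQ[, c("query_id", "true_q", "correct")],
               by = "query_id")
  names(tab)[names(tab) == "q"] <- "estimated_q"
  inBand <- tab$true_q >= band[1] & tab$true_q <= band[2]
  maxDev <- if (any(inBand))
    max(abs(tab$estimated_q[inBand] - tab$true_q[inBand])) else NA_real_
  small <- tab$true_q < 0.05
  smallQBias <- any(small) &&
    mean(tab$estimated_q[small] <= tab$true_q[small]) > 0.5
  ks <- NULL; qq <- NULL
  if (!is.null(pValues) && length(pValues)) {
    ks <- suppressWarnings(ks.test(pValues, "punif"))
    pr <- seq(0, 1, by = 0.1)
    qq <- data.frame(theoretical = pr,
                     observed = as.numeric(stats::quantile(pValues, pr)))
  }
  list(table = tab, maxAbsDevInBand = maxDev, smallQBias = smallQBias,
       ks = ks, qq = qq)
}

#' Sweep scoring parameters against an FDR level
#'
#' For each minimum-matched-peaks value, searches target and decoy
#' libraries, estimates q-values, and reports the smallest score threshold
#' at which the estimated FDR stays at or below `fdrLevel`, together with
#' the number of annotations retained there.
#'
#' @param queries,target,decoys [SpectralLibrary-class] objects.
#' @param minMatchedGrid integer vector of minimum matched peaks.
#' @param fdrLevel target FDR (q-value) level.
#' @param pit PIT passed to [estimateFdrTda()].
#' @param ... passed to [searchLibrary()] (variant, tolerances, window).
#' @return data.frame `min_matched_peaks`, `score_threshold`,
#'   `n_annotations`.
#' @export
parameterSweep <- function(queries, target, decoys, minMatchedGrid = 2:8,
                           fdrLevel = 0.01, pit = 1, ...) {
  stopifnot(length(minMatchedGrid) >= 1L)
  rows <- lapply(minMatchedGrid, function(mmp) {
    tHits <- searchLibrary(queries, target, "target",
                           minMatchedPeaks = mmp, ...)
    dHits <- searchLibrary(queries, decoys, "decoy",
                           minMatchedPeaks = mmp, ...)
    if (!nrow(tHits))
      return(data.frame(min_matched_peaks = mmp,
                        score_threshold = NA_real_, n_annotations = 0L))
    curve <- suppressWarnings(estimateFdrTda(tHits, dHits, pit))
    at <- annotationsAtFdr(curve, fdrLevel)
    data.frame(min_matched_peaks = mmp,
               score_threshold = at$score_threshold,
               n_annotations = at$n_annotations)
  })
  do.call(rbind, rows)
}

#' Noise-filter a benchmark target library with its trees
#'
#' Applies [noiseFilter()] entry-wise and discards spectra flagged as
#' empty or precursor-only, keeping library and tree sets in step.
#'
#' @param target a [SpectralLibrary-class].
#' @param trees named list of trees keyed by spectrum identifier.
#' @return list `target` (filtered library), `trees` (matching subset),
#'   `discarded` (identifiers of discarded spectra).
#' @export
noiseFilterLibrary <- function(target, trees) {
  kept <- list(); keptTrees <- list(); discarded <- character(0)
  for (s in librarySpectra(target)) {
    tr <- trees[[spectrumId(s)]]
    if (is.null(tr)) { discarded <- c(discarded, spectrumId(s)); next }
    f <- noiseFilter(s, tr)
    if (isTRUE(attr(f, "discard"))) {
      discarded <- c(discarded, spectrumId(s))
    } else {
      kept[[length(kept) + 1L]] <- f
      keptTrees[[spectrumId(s)]] <- tr
    }
  }
  list(target = spectralLibrary(kept, name = libraryName(target)),
       trees = keptTrees, discarded = discarded)
}

#' Run the full significance-estimation pipeline on a benchmark
#'
#' Generates (or takes) a benchmark, noise-filters the target library,
#' builds a decoy library, searches queries against both, estimates PIT by
#' the empirical-Bayes mixture, and returns target-decoy and
#' empirical-Bayes FDR curves together with the ground-truth q-values.
#'
#' @param bench output of [generateBenchmark()].
#' @param method decoy construction method.
#' @param decoySeed seed for the decoy build.
#' @param minMatchedPeaks minimum matched peaks for a hit.
#' @param variant scoring variant.
#' @param tolerancePpm peak-match tolerance.
#' @param precursorWindowPpm precursor window.
#' @param pit `"auto"` (empirical Bayes when >= 50 target hits, else 1) or
#'   a number in \[0, 1\].
#' @return list: `targetHits`, `decoyHits`, `tda` (FDR curve), `model`
#'   (mixture or NULL), `eb` (empirical-Bayes curve or NULL), `pit`,
#'   `trueQ`, `falsePValues` (decoy-based p-values of known-false hits),
#'   `filtered` (the noise-filtered target set).
#' @export
benchmarkPipeline <- function(bench, method = "tree_based", decoySeed = 1L,
                              minMatchedPeaks = 2L, variant = "cosine",
                              tolerancePpm = 15, precursorWindowPpm = 10,
                              pit = "auto") {
  flt <- noiseFilterLibrary(bench$target, bench$trees)
  decoys <- buildDecoyLibrary(flt$target, flt$trees, method = method,
                              seed = decoySeed)
  tHits <- searchLibrary(bench$queries, flt$target, "target",
                         minMatchedPeaks = minMatchedPeaks,
                         precursorWindowPpm = precursorWindowPpm,
                         variant = variant, tolerancePpm = tolerancePpm)
  dHits <- searchLibrary(bench$queries, decoys, "decoy",
                         minMatchedPeaks = minMatchedPeaks,
                         precursorWindowPpm = precursorWindowPpm,
                         variant = variant, tolerancePpm = tolerancePpm)
  model <- NULL
  pitVal <- if (identical(pit, "auto")) {
    if (nrow(tHits) >= 50L) {
      model <- fitMixtureEM(tHits$score)
      estimatePit(model)
    } else 1
  } else as.numeric(pit)
  if (is.null(model) && nrow(tHits) >= 50L)
    model <- tryCatch(fitMixtureEM(tHits$score), error = function(e) NULL)
  tda <- suppressWarnings(estimateFdrTda(tHits, dHits, pitVal))
  eb <- if (!is.null(model) && nrow(tHits)) fdrFromPep(model, tHits)
        else NULL
  trueQ <- trueQValues(tHits, bench$truth)
  falseScores <- trueQ$threshold[!trueQ$correct]
  falsePValues <- if (nrow(dHits) && length(falseScores))
    estimatePValue(falseScores, dHits) else numeric(0)
  list(targetHits = tHits, decoyHits = dHits, tda = tda, model = model,
       eb = eb, pit = pitVal, trueQ = trueQ, falsePValues = falsePValues,
       filtered = flt, decoys = decoys)
}

#' Write a benchmark bundle to a directory
#'
#' Emits `target.mgf`, `queries.mgf`, `trees/<id>.dot`, `truth.tsv` and
#' `spec.json`.
#'
#' @param bench output of [generateBenchmark()].
#' @param dir output directory (created if needed).
#' @param spec the [benchmarkSpec()] used (serialized for provenance).
#' @return `dir`, invisibly.
#' @export
writeBenchmark <- function(bench, dir, spec = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeMGF(bench$target, file.path(dir, "target.mgf"))
  writeMGF(bench$queries, file.path(dir, "queries.mgf"))
  treeDir <- file.path(dir, "trees")
  dir.create(treeDir, showWarnings = FALSE)
  for (id in names(bench$trees))
    writeDotTree(bench$trees[[id]], file.path(treeDir, paste0(id, ".dot")))
  write.table(bench$truth, file.path(dir, "truth.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  if (!is.null(spec))
    jsonlite::write_json(unclass(spec), file.path(dir, "spec.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
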