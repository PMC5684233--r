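test_that("benchmark generation is deterministic and well-formed", {
  spec <- benchmarkSpec(nCompounds = 25, nQueries = 30, seed = 7)
  a <- generateBenchmark(spec)
  b <- generateBenchmark(spec)
  expect_identical(lapply(librarySpectra(a$target), peakTable),
                   lapply(librarySpectra(b$target), peakTable))
  expect_identical(lapply(librarySpectra(a$queries), peakTable),
                   lapply(librarySpectra(b$queries), peakTable))
  expect_identical(a$truth, b$truth)
  # structure
  expect_equal(length(a$target), 25L)
  expect_equal(length(a$queries), 30L)
  expect_equal(nrow(a$truth), 30L)
  expect_setequal(names(a$trees), libraryIds(a$target))
  # every generated library spectrum passes the inclusion filters
  for (s in librarySpectra(a$target))
    expect_true(as.logical(passesLibraryFilters(s)))
  # all trees validate
  for (t in a$trees) expect_true(validObject(t))
  # truth covers every query, absent for isomer/null classes
  expect_true(all(grepl("^QTRU", a$truth$query_id[a$truth$true_id !=
                                                    "absent"])))
})

test_that("without isomers no query overlaps a wrong library entry by more than half", {
  bench <- generateBenchmark(benchmarkSpec(nCompounds = 40, nQueries = 40,
                                           isomerFraction = 0,
                                           trueFraction = 0.5, seed = 19))
  refs <- librarySpectra(bench$target)
  refPrec <- vapply(refs, precursorMz, numeric(1))
  for (q in librarySpectra(bench$queries)) {
    trueId <- bench$truth$true_id[bench$truth$query_id == spectrumId(q)]
    inWin <- which(abs(refPrec - precursorMz(q)) <= precursorMz(q) * 1e-5)
    for (j in inWin) {
      if (spectrumId(refs[[j]]) == trueId) next
      qm <- peakMasses(q)
      shared <- sum(vapply(qm, function(m)
        any(abs(peakMasses(refs[[j]]) - m) <=
              pmax(peakMasses(refs[[j]]) * 15e-6, 2e-3)), logical(1)))
      expect_lte(shared / length(qm), 0.5)
    }
  }
})

test_that("true q-values match labeled correctness and a brute-force sweep", {
  hits <- data.frame(query_id = sprintf("q%02d", 1:10),
                     reference_id = c(rep("good", 6), rep("bad", 4)),
                     score = seq(0.95, 0.5, length.out = 10),
                     n_matched = 3L, origin = "target")
  truth <- data.frame(query_id = hits$query_id,
                      true_id = c(rep("good", 6), rep("other", 4)))
  tq <- trueQValues(hits, truth)
  expect_equal(sum(tq$correct), 6L)
  # brute force: true FDR at each threshold, then running min from below
  ord <- order(-hits$score)
  correct <- (truth$true_id == hits$reference_id)[ord]
  fdrOracle <- vapply(seq_along(ord), function(i)
    mean(!correct[1:i]), numeric(1))
  qOracle <- rev(cummin(rev(fdrOracle)))
  expect_equal(tq$true_q, qOracle)

  # degenerate cases
  allGood <- truth; allGood$true_id <- hits$reference_id
  expect_true(all(trueQValues(hits, allGood)$true_q == 0))
  allBad <- truth; allBad$true_id <- "nope"
  expect_true(all(trueQValues(hits, allBad)$true_q == 1))
  expect_error(trueQValues(hits, truth[1:3, ]), "missing")
})

test_that("calibration report flags deviations and reproduces exactly calibrated input", {
  est <- data.frame(query_id = sprintf("q%d", 1:20),
                    q = seq(0, 0.38, by = 0.02))
  tq <- data.frame(query_id = est$query_id, true_q = est$q,
                   correct = rep(c(TRUE, FALSE), 10))
  rep1 <- calibrationReport(est, tq, pValues = runif(50))
  expect_equal(rep1$maxAbsDevInBand, 0)
  expect_false(is.null(rep1$ks))
  expect_equal(nrow(rep1$table), 20L)
})

test_that("parameter sweep reports the threshold reaching the FDR level", {
  bench <- generateBenchmark(benchmarkSpec(nCompounds = 60, nQueries = 80,
                                           seed = 3))
  flt <- noiseFilterLibrary(bench$target, bench$trees)
  dec <- buildDecoyLibrary(flt$target, flt$trees, "tree_based", seed = 1)
  sweep1 <- parameterSweep(bench$queries, flt$target, dec,
                           minMatchedGrid = c(2L, 4L), fdrLevel = 1.0,
                           tolerancePpm = 15)
  # degenerate level 1: the threshold is the lowest observed score
  for (i in seq_len(nrow(sweep1))) {
    tHits <- searchLibrary(bench$queries, flt$target, "target",
                           minMatchedPeaks = sweep1$min_matched_peaks[i],
                           tolerancePpm = 15)
    expect_equal(sweep1$score_threshold[i], min(tHits$score))
    expect_equal(sweep1$n_annotations[i], nrow(tHits))
  }
  # nested thresholds: more annotations at 5% than at 1%
  s5 <- parameterSweep(bench$queries, flt$target, dec,
                       minMatchedGrid = 2L, fdrLevel = 0.05,
                       tolerancePpm = 15)
  s1 <- parameterSweep(bench$queries, flt$target, dec,
                       minMatchedGrid = 2L, fdrLevel = 0.01,
                       tolerancePpm = 15)
  expect_gte(s5$n_annotations, s1$n_annotations)
})

test_that("noise filtering a library discards empty and precursor-only spectra", {
  bench <- generateBenchmark(benchmarkSpec(nCompounds = 10, nQueries = 1,
                                           seed = 5))
  # inject a precursor-only spectrum with a matching single-node tree
  lone <- spectrum("LONE", ionMass("C6H12O6"), ionMass("C6H12O6"), 100)
  loneTree <- toyTreeAnnotator(lone, "C6H12O6")
  lib <- spectralLibrary(c(librarySpectra(bench$target), list(lone)),
                         name = "t")
  trees <- c(bench$trees, list(LONE = loneTree))
  flt <- noiseFilterLibrary(lib, trees)
  expect_true("LONE" %in% flt$discarded)
  expect_equal(length(flt$target), 10L)
  expect_setequal(names(flt$trees), libraryIds(flt$target))
})

test_that("benchmark bundles round-trip through the on-disk formats", {
  bench <- generateBenchmark(benchmarkSpec(nCompounds = 8, nQueries = 6,
                                           seed = 2))
  dir <- withr::local_tempdir()
  writeBenchmark(bench, dir, spec = benchmarkSpec(nCompounds = 8,
                                                  nQueries = 6, seed = 2))
  expect_true(file.exists(file.path(dir, "target.mgf")))
  back <- readMGF(file.path(dir, "target.mgf"))
  expect_equal(libraryIds(back), libraryIds(bench$target))
  expect_equal(length(list.files(file.path(dir, "trees"), "\\.dot$")), 8L)
  tr <- readDotTree(file.path(dir, "trees", "CPD0001.dot"))
  expect_true(validObject(tr))
  truth <- read.table(file.path(dir, "truth.tsv"), header = TRUE,
                      sep = "\t")
  expect_equal(nrow(truth), 6L)
})
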