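test_that("tree construction derives formulas along losses and validates", {
  t <- fragmentationTree(parent = c(0L, 1L, 2L),
                         losses = list("0", "H2O", "CO"),
                         rootFormula = "C6H12O6", spectrumId = "chain")
  expect_equal(nNodes(t), 3L)
  expect_equal(formulaToString(rootFormula(t)), "C6H12O6")
  el <- formulaElements()
  expect_equal(formulaToString(setNames(t@formulas[3, ], el)), "C5H10O4")
  expect_equal(nodeMasses(t)[1], ionMass("C6H12O6"))

  # a loss larger than the parent formula is rejected by validity
  expect_error(fragmentationTree(parent = c(0L, 1L),
                                 losses = list("0", "C7H2"),
                                 rootFormula = "C6H12O6",
                                 spectrumId = "bad"),
               "valid")
})

test_that("DOT round trip preserves the tree", {
  t <- glucoseTree()
  path <- withr::local_tempfile(fileext = ".dot")
  writeDotTree(t, path)
  back <- readDotTree(path)
  expect_equal(nNodes(back), nNodes(t))
  expect_equal(back@parent, t@parent)
  expect_equal(back@formulas, t@formulas)
  expect_equal(back@losses, t@losses)
  expect_equal(back@masses, t@masses, tolerance = 1e-5)
  expect_equal(back@intensities, t@intensities, tolerance = 1e-5)
  expect_equal(back@spectrumId, "glc")
})

test_that("DOT reader rejects inconsistent and malformed trees", {
  path <- withr::local_tempfile(fileext = ".dot")
  # edge label H2O but child formula implies a CO loss
  writeLines(c("digraph \"x\" {",
               '  v1 [label="C6H12O6\\n181.070665"];',
               '  v2 [label="C6H10O4\\n147.065000"];',
               '  v1 -> v2 [label="H2O"];', "}"), path)
  expect_error(readDotTree(path), "consistency error")

  # two roots
  writeLines(c("digraph \"x\" {",
               '  v1 [label="C6H12O6\\n181.070665"];',
               '  v2 [label="C6H10O5\\n163.060100"];', "}"), path)
  expect_error(readDotTree(path), "structural error")

  # cycle / multiple parents
  writeLines(c("digraph \"x\" {",
               '  v1 [label="C6H12O6\\n181.070665"];',
               '  v2 [label="C6H10O5\\n163.060100"];',
               '  v1 -> v2 [label="H2O"];',
               '  v2 -> v1 [label="H2O"];', "}"), path)
  expect_error(readDotTree(path), "multiple parents|structural")
})

test_that("telescoping identity: losses along any root-leaf path sum to the formula difference", {
  set.seed(4)
  for (rep in 1:10) {
    k <- sample(4:9, 1)
    lossSet <- sample(lossAlphabet(), k - 1, replace = TRUE)
    rootF <- Reduce(formulaAdd, lapply(lossSet, parseFormula),
                    parseFormula("C2H6"))
    parent <- c(0L, vapply(seq_len(k - 1L),
                           function(j) sample.int(j, 1L), integer(1)))
    t <- fragmentationTree(parent, c(list("0"), as.list(lossSet)), rootF,
                           "rand")
    el <- formulaElements()
    for (i in seq_len(k)) {
      acc <- emptyFormula(); j <- i
      while (t@parent[j] != 0L) {
        acc <- acc + setNames(t@losses[j, ], el)
        j <- t@parent[j]
      }
      expect_equal(unname(rootFormula(t) - setNames(t@formulas[i, ], el)),
                   unname(acc))
    }
  }
})

test_that("noise filter keeps only tree-annotated peaks, intensities unchanged", {
  t <- glucoseTree()
  masses <- nodeMasses(t)
  s <- spectrum("glc", ionMass("C6H12O6"),
                mass = c(masses, 123.4567),  # one unannotated noise peak
                intensity = c(60, 100, 45, 20, 77))
  f <- noiseFilter(s, t)
  expect_equal(nPeaks(f), 4L)
  expect_false(any(abs(peakMasses(f) - 123.4567) < 0.01))
  expect_equal(sort(peakIntensities(f)), sort(c(60, 100, 45, 20)))
  expect_false(attr(f, "discard"))

  # identity when the tree annotates everything
  full <- spectrum("glc", ionMass("C6H12O6"), masses, c(60, 100, 45, 20))
  expect_equal(peakTable(noiseFilter(full, t)), peakTable(full))

  # idempotence
  expect_equal(peakTable(noiseFilter(f, t)), peakTable(f))

  # spectrum id mismatch is an error
  s2 <- spectrum("other", ionMass("C6H12O6"), masses, c(1, 1, 1, 1))
  expect_error(noiseFilter(s2, t), "annotates")
})

test_that("noise-filter tolerance is max(10 ppm, 2 mDa)", {
  t <- glucoseTree()
  m <- nodeMasses(t)[1]            # ~181 Da: 10 ppm = 1.8 mDa < 2 mDa
  inTol <- spectrum("glc", ionMass("C6H12O6"), m + 0.0019, 10)
  outTol <- spectrum("glc", ionMass("C6H12O6"), m + 0.0025, 10)
  expect_equal(nPeaks(noiseFilter(inTol, t)), 1L)   # inside 2 mDa absolute
  expect_equal(nPeaks(noiseFilter(outTol, t)), 0L)  # outside both rules
  expect_true(attr(noiseFilter(outTol, t), "discard"))

  # a precursor-only survivor is flagged for discard
  precOnly <- spectrum("glc", ionMass("C6H12O6"), ionMass("C6H12O6"), 10)
  expect_true(attr(noiseFilter(precOnly, t), "discard"))
})

test_that("toy annotator builds valid trees matching spectrum peaks", {
  s <- glucoseSpectrum()
  t <- toyTreeAnnotator(s, "C6H12O6")
  expect_true(validObject(t))
  expect_gte(nNodes(t), 2L)
  for (m in nodeMasses(t))
    expect_true(any(abs(peakMasses(s) - m) <= pmax(m * 1e-5, 0.002)))

  # precursor-only spectrum: single-node tree
  lone <- spectrum("x", ionMass("C6H12O6"), ionMass("C6H12O6"), 100)
  expect_equal(nNodes(toyTreeAnnotator(lone, "C6H12O6")), 1L)

  # the annotated tree round-trips through DOT and re-validates
  path <- withr::local_tempfile(fileext = ".dot")
  writeDotTree(t, path)
  expect_true(validObject(readDotTree(path)))

  # wrong precursor formula is rejected
  expect_error(toyTreeAnnotator(s, "C6H12O5"), "p.p.m")
})
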