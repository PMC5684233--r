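massbankRecord <- function(acc = "MB000001", nDecl = 3,
                           peaks = c("100.0500 200.0 999",
                                     "150.1000 50.0 250",
                                     "181.0707 100.0 500"),
                           precLine = "MS$FOCUSED_ION: PRECURSOR_M/Z 181.070700") {
  c(paste0("ACCESSION: ", acc),
    "AC$MASS_SPECTROMETRY: ION_MODE POSITIVE",
    precLine,
    paste0("PK$NUM_PEAK: ", nDecl),
    "PK$PEAK: m/z int. rel.int.",
    paste(" ", peaks),
    "//")
}

test_that("MassBank records parse with sorted peaks and raw intensities", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(massbankRecord(), path)
  lib <- readMassBank(path)
  expect_equal(length(lib), 1L)
  s <- lib[[1]]
  expect_equal(spectrumId(s), "MB000001")
  expect_equal(nPeaks(s), 3L)
  expect_equal(peakMasses(s), c(100.05, 150.10, 181.0707))
  # raw intensity column, not the rel.int. column
  expect_equal(peakIntensities(s), c(200, 50, 100))
  expect_equal(precursorMz(s), 181.0707)
})

test_that("MassBank write/read round-trips peak lists", {
  lib <- spectralLibrary(list(glucoseSpectrum("A1"), glucoseSpectrum("A2")),
                         name = "rt")
  path <- withr::local_tempfile(fileext = ".txt")
  writeMassBank(lib, path)
  back <- readMassBank(path)
  expect_equal(length(back), 2L)
  for (i in 1:2) {
    expect_equal(peakMasses(back[[i]]), peakMasses(lib[[i]]),
                 tolerance = 1e-6)
    expect_equal(peakIntensities(back[[i]]), peakIntensities(lib[[i]]),
                 tolerance = 1e-6)
    expect_equal(compoundMass(back[[i]]), compoundMass(lib[[i]]),
                 tolerance = 1e-6)
  }
})

test_that("malformed MassBank records raise record-level errors", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(massbankRecord(nDecl = 5), path)
  expect_error(readMassBank(path), "declares 5 peaks but 3")

  writeLines(massbankRecord(peaks = c("100.05 200.0", "oops line")), path)
  expect_error(readMassBank(path), "malformed peak line")

  # no precursor and no selected ion mass is fatal
  writeLines(massbankRecord(precLine = "CH$NAME: something", nDecl = 3),
             path)
  expect_error(readMassBank(path), "neither precursor")

  # selected-ion fallback is accepted
  writeLines(massbankRecord(precLine = "MS$FOCUSED_ION: ION 181.070700"),
             path)
  expect_equal(precursorMz(readMassBank(path)[[1]]), 181.0707)
})

test_that("MGF blocks parse, including negative mode and empty files", {
  path <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=one", "PEPMASS=181.0707", "CHARGE=1+",
               "100.05 200", "181.0707 100", "END IONS",
               "BEGIN IONS", "TITLE=two", "PEPMASS=120.0500", "CHARGE=1-",
               "60.02 10", "END IONS"), path)
  lib <- readMGF(path)
  expect_equal(length(lib), 2L)
  expect_equal(ionMode(lib[["two"]]), "negative")
  expect_equal(ionMode(lib[["one"]]), "positive")

  writeLines("BEGIN IONS\nTITLE=x\n100 1\nEND IONS", path)
  expect_error(readMGF(path), "PEPMASS")

  writeLines(character(0), path)
  expect_warning(empty <- readMGF(path), "no spectra")
  expect_equal(length(empty), 0L)
})

test_that("MGF write/read round-trips including ground-truth fields", {
  lib <- spectralLibrary(list(glucoseSpectrum("g1")), name = "rt")
  path <- withr::local_tempfile(fileext = ".mgf")
  writeMGF(lib, path)
  back <- readMGF(path)
  expect_equal(peakMasses(back[[1]]), peakMasses(lib[[1]]), tolerance = 1e-6)
  expect_equal(compoundId(back[[1]]), "g1")
  expect_equal(compoundMass(back[[1]]), formulaMass("C6H12O6"),
               tolerance = 1e-6)
})

test_that("library filters apply ion mode, mass bound and informative peaks", {
  ok <- spectrum("ok", 181.0707, c(85, 127, 163, 171, 181),
                 c(50, 80, 100, 30, 60), compoundMass = 180.063)
  r <- passesLibraryFilters(ok)
  expect_true(as.logical(r))
  expect_equal(attr(r, "reason"), "pass")

  neg <- spectrum("n", 181.0707, c(85, 127, 163, 171, 181),
                  c(50, 80, 100, 30, 60), ionMode = "negative")
  expect_equal(attr(passesLibraryFilters(neg), "reason"), "ion-mode")

  # 4 peaks above 2% of base, 30 below: informative-peak rule fails
  lowI <- spectrum("l", 500.1, c(seq(100, 129), 200, 210, 220, 230),
                   c(rep(0.5, 30), 100, 80, 60, 40))
  r2 <- passesLibraryFilters(lowI)
  expect_false(as.logical(r2))
  expect_equal(attr(r2, "reason"), "min-informative-peaks")

  # "below 1000 Da" is strict
  heavy <- spectrum("h", 1001.00728, c(100, 200, 300, 400, 500),
                    rep(100, 5), compoundMass = 1000.0)
  expect_equal(attr(passesLibraryFilters(heavy), "reason"), "compound-mass")

  # structure-mass agreement: precursor must match compound mass + proton
  off <- spectrum("o", 181.10, c(85, 127, 163, 171, 181),
                  rep(100, 5), compoundMass = 180.063)
  expect_equal(attr(passesLibraryFilters(off), "reason"), "mass-agreement")

  # purity: repeated evaluation gives the identical result
  expect_identical(passesLibraryFilters(ok), passesLibraryFilters(ok))
})

test_that("collision-energy merging pools, clusters and conserves base structure", {
  s <- glucoseSpectrum()
  # merging a spectrum with itself reproduces its peak list
  m <- mergeCollisionEnergies(list(s, s))
  expect_equal(peakMasses(m), peakMasses(s))
  expect_equal(peakIntensities(m), peakIntensities(s))

  # disjoint peak sets: union
  a <- spectrum("x", 300.1, c(100.0, 150.0), c(10, 20), compoundId = "c")
  b <- spectrum("x", 300.1, c(120.0, 170.0), c(5, 30), compoundId = "c")
  u <- mergeCollisionEnergies(list(a, b))
  expect_equal(peakMasses(u), c(100, 120, 150, 170))

  # peaks 5 p.p.m. apart merge into one, keeping the more intense mass;
  # oracle: brute-force single-linkage clustering at max(10 ppm, 2 mDa)
  c1 <- spectrum("x", 300.1, c(100.0000, 200.0), c(10, 5), compoundId = "c")
  c2 <- spectrum("x", 300.1, c(100.0005, 250.0), c(40, 5), compoundId = "c")
  mm <- mergeCollisionEnergies(list(c1, c2))
  expect_equal(nPeaks(mm), 3L)
  expect_equal(peakMasses(mm)[1], 100.0005)  # most intense member's mass
  expect_equal(peakIntensities(mm)[1], 40)

  # merged output never contains two peaks within the merge tolerance
  gaps <- diff(peakMasses(mm))
  expect_true(all(gaps > pmax(peakMasses(mm)[-1] * 1e-5, 0.002)))

  # precursor disagreement beyond tolerance is an error
  far <- spectrum("x", 300.2, c(100), c(1), compoundId = "c")
  expect_error(mergeCollisionEnergies(list(a, far)), "precursor masses")
})
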