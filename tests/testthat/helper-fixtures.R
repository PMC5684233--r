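# Shared fixtures, all built in code.

# glucose-like spectrum: [M+H]+ of C6H12O6 plus three fragment ions
glucoseSpectrum <- function(id = "glc") {
  forms <- c("C6H12O6", "C6H10O5", "C6H8O4", "C5H8O3")
  spectrum(id, ionMass("C6H12O6"),
           mass = vapply(forms, ionMass, numeric(1)),
           intensity = c(60, 100, 45, 20),
           compoundMass = formulaMass("C6H12O6"), compoundId = id)
}

# matching fragmentation tree (losses H2O, H2O, CH2O along a chain)
glucoseTree <- function(id = "glc") {
  fragmentationTree(parent = c(0L, 1L, 2L, 3L),
                    losses = list("0", "H2O", "H2O", "CH2O"),
                    rootFormula = "C6H12O6", spectrumId = id,
                    intensities = c(60, 100, 45, 20))
}

# star tree over an additively built root: every re-rooting is valid
starTree <- function(lossSet = c("H2O", "CO", "NH3", "C2H4"),
                     id = "star") {
  rootF <- Reduce(formulaAdd, lossSet, parseFormula("CH2"))
  fragmentationTree(parent = c(0L, rep(1L, length(lossSet))),
                    losses = c(list("0"), as.list(lossSet)),
                    rootFormula = rootF, spectrumId = id,
                    intensities = seq(100, by = -10,
                                      length.out = length(lossSet) + 1L))
}

treeSpectrum <- function(tree) {
  spectrum(tree@spectrumId, ionMass(rootFormula(tree)),
           nodeMasses(tree), tree@intensities)
}

# star with known non-trivial re-graft counts: losses C4H8/C3H6/H2O off
# glucose give n = 1, 1, 0 for the three leaves (derived by hand from the
# element-wise subtractions)
regraftStarTree <- function(id = "glc2") {
  fragmentationTree(parent = c(0L, 1L, 1L, 1L),
                    losses = list("0", "C4H8", "C3H6", "H2O"),
                    rootFormula = "C6H12O6", spectrumId = id,
                    intensities = c(100, 40, 30, 20))
}

randomHitList <- function(n, origin, prefix) {
  data.frame(query_id = sprintf("%s%03d", prefix, seq_len(n)),
             reference_id = sprintf("R%03d", sample.int(500, n)),
             score = round(runif(n), 3), n_matched = 3L,
             origin = origin, stringsAsFactors = FALSE)
}

# independent brute-force oracle for separated target-decoy q-values:
# sweep every distinct threshold (target and decoy scores), compute
# FDR(t) = pit * D(t)/T(t) where defined, and take, for each target hit,
# the minimum over all thresholds at or below its score
bruteForceQ <- function(targets, decoys, pit) {
  thr <- sort(unique(c(targets$score, decoys$score)))
  fdrAt <- vapply(thr, function(t) {
    T <- sum(targets$score >= t)
    if (T == 0L) return(NA_real_)
    pit * sum(decoys$score >= t) / T
  }, numeric(1))
  vapply(targets$score, function(s) {
    ok <- which(thr <= s & !is.na(fdrAt))
    min(fdrAt[ok])
  }, numeric(1))
}
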