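test_that("target-decoy FDR follows PIT * D/T and q-values monotonize", {
  # 100 targets above threshold 0.5, 10 decoys above: FDR = 0.8*10/100
  targets <- data.frame(query_id = sprintf("q%03d", 1:100),
                        reference_id = "r", score = seq(0.99, 0.5,
                                                        length.out = 100),
                        n_matched = 3L, origin = "target")
  decoys <- data.frame(query_id = sprintf("q%03d", 1:10),
                       reference_id = "d", score = seq(0.55, 0.5,
                                                       length.out = 10),
                       n_matched = 3L, origin = "decoy")
  curve <- estimateFdrTda(targets, decoys, pit = 0.8)
  bottom <- which.min(curve$threshold)
  expect_equal(curve$n_targets[bottom], 100L)
  expect_equal(curve$n_decoys[bottom], 10L)
  expect_equal(curve$fdr[bottom], 0.8 * 10 / 100)
  # q non-decreasing as score decreases
  expect_true(all(diff(curve$q) >= 0))
  # q of top hit is minimal
  expect_lte(curve$q[1], min(curve$q[-1]))

  # empty decoy list: FDR 0 everywhere
  c0 <- estimateFdrTda(targets, decoys[0, ], pit = 0.8)
  expect_true(all(c0$fdr == 0))

  # empty target list: warning and empty curve
  expect_warning(ce <- estimateFdrTda(targets[0, ], decoys, 1), "empty")
  expect_equal(nrow(ce), 0L)

  # pit = 1 reduces to the classical separated estimator D/T
  c1 <- estimateFdrTda(targets, decoys, pit = 1)
  expect_equal(c1$fdr, curve$n_decoys / curve$n_targets)
})

test_that("q-values equal brute-force threshold sweeps on random hit lists", {
  set.seed(42)
  for (rep in 1:20) {
    nT <- sample(3:20, 1); nD <- sample(0:20, 1)
    targets <- randomHitList(nT, "target", "t")
    decoys <- if (nD) randomHitList(nD, "decoy", "d") else
      randomHitList(1, "decoy", "d")[0, ]
    pit <- sample(c(0.5, 0.8, 1), 1)
    curve <- estimateFdrTda(targets, decoys, pit)
    oracle <- bruteForceQ(data.frame(score = curve$threshold), decoys, pit)
    expect_identical(curve$q, oracle)
  }
})

test_that("decoy p-values count strictly greater scores", {
  decoys <- data.frame(score = as.numeric(1:100), origin = "decoy")
  expect_equal(estimatePValue(150, decoys), 0)
  expect_equal(estimatePValue(0.5, decoys), 1)
  expect_equal(estimatePValue(95, decoys), 0.05)
  # step function, non-increasing in score
  grid <- seq(0, 110, by = 0.5)
  p <- estimatePValue(grid, decoys)
  expect_true(all(diff(p) <= 0))
  # Laplace variant never returns 0
  expect_equal(estimatePValue(150, decoys, laplace = TRUE), 1 / 101)
  expect_error(estimatePValue(0.5, decoys[0, ]), "empty")
})

test_that("EM recovers mixture parameters from simulated scores", {
  set.seed(31)
  n <- 2000; piTrue <- 0.7
  nf <- rbinom(1, n, piTrue)
  s <- c(rgamma(nf, shape = 2, scale = 0.05),
         1 - (0.15 - 0.05 * log(-log(runif(n - nf)))))  # mirrored Gumbel
  s <- pmin(pmax(s, 1e-4), 1)
  m <- fitMixtureEM(s, "gumbel")
  expect_s4_class(m, "MixtureModel")
  expect_lt(abs(pi0(m) - piTrue), 0.05)
  expect_true(all(diff(m@logLikTrace) >= -1e-8))
  expect_equal(estimatePit(m), pi0(m))

  # all-false sample: pi0 is driven towards 1
  sf <- pmin(pmax(rgamma(2000, shape = 2, scale = 0.05), 1e-4), 1)
  expect_gte(pi0(fitMixtureEM(sf)), 0.9)

  # tiny samples are refused with an actionable message
  expect_error(fitMixtureEM(runif(20)), "at least 50")
  expect_error(fitMixtureEM(c(runif(60), 2)), "lie in")
})

test_that("PEP behaves as a posterior and PIT equals the mixture weight", {
  # degenerate all-false model: PEP is identically 1
  allFalse <- new("MixtureModel", pi0 = 1, falseShape = 2, falseScale = 0.05,
                  trueFamily = "gumbel", truePar = c(loc = 0.15,
                                                     scale = 0.05),
                  logLik = 0, logLikTrace = 0, nIter = 1L,
                  converged = TRUE, scoreMax = 1)
  expect_true(all(posteriorErrorProbability(allFalse,
                                            seq(0.05, 0.95, 0.1)) == 1))

  # fitted fixture model: PEP non-increasing over a dense score grid
  set.seed(8)
  s <- c(rgamma(700, 2, scale = 0.05), 1 - rgamma(300, 3, scale = 0.04))
  s <- pmin(pmax(s, 1e-4), 1)
  m <- fitMixtureEM(s, "gamma")
  pep <- posteriorErrorProbability(m, seq(0.01, 0.99, by = 0.01))
  # non-increasing up to numerical noise where both densities vanish
  expect_true(all(diff(pep) <= 1e-4))
  expect_true(all(pep >= 0 & pep <= 1))
  expect_true(estimatePit(m) >= 0 && estimatePit(m) <= 1)
})

test_that("empirical-Bayes FDR is the running mean PEP, monotonized", {
  hits <- data.frame(query_id = sprintf("q%d", 1:60),
                     reference_id = "r",
                     score = seq(0.95, 0.05, length.out = 60),
                     n_matched = 3L, origin = "target")
  allFalse <- new("MixtureModel", pi0 = 1, falseShape = 2, falseScale = 0.05,
                  trueFamily = "gumbel", truePar = c(loc = 0.15,
                                                     scale = 0.05),
                  logLik = 0, logLikTrace = 0, nIter = 1L,
                  converged = TRUE, scoreMax = 1)
  curve <- fdrFromPep(allFalse, hits)
  # constant PEP c gives FDR = c at every threshold
  expect_true(all(curve$fdr == 1))
  expect_true(all(curve$q == 1))

  set.seed(3)
  s <- c(rgamma(500, 2, scale = 0.05), 1 - rgamma(500, 3, scale = 0.04))
  s <- pmin(pmax(s, 1e-4), 1)
  m <- fitMixtureEM(s, "gamma")
  hits2 <- data.frame(query_id = sprintf("q%d", seq_along(s)),
                      reference_id = "r", score = s, n_matched = 3L,
                      origin = "target")
  curve2 <- fdrFromPep(m, hits2)
  # FDR at the top hit equals that hit's own PEP
  expect_equal(curve2$fdr[1], curve2$pep[1])
  # the running mean from the top
  expect_equal(curve2$fdr, cumsum(curve2$pep) / seq_along(curve2$pep))
  expect_true(all(diff(curve2$q) >= 0))
})
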