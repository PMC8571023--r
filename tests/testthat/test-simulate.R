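test_that("simulateLibrary plants exactly the configured scaffold fraction", {
  lib <- simulateLibrary(simulationConfig(seed = 1, nMolecules = 20,
                                          fracScaffold = 0.3))
  expect_length(lib, 20)
  expect_length(lib@metadata$planted, 6)
  expect_setequal(compoundIds(scaffoldFilter(lib)),
                  lib@metadata$planted)
  # boundary fractions
  none <- simulateLibrary(simulationConfig(seed = 3, nMolecules = 10,
                                           fracScaffold = 0))
  expect_length(scaffoldFilter(none), 0)
  all_ <- simulateLibrary(simulationConfig(seed = 3, nMolecules = 10,
                                           fracScaffold = 1))
  expect_length(scaffoldFilter(all_), 10)
})

test_that("generators are byte-deterministic and leave the RNG untouched", {
  cfg <- simulationConfig(seed = 17, nMolecules = 15, fracScaffold = 0.4)
  a <- simulateLibrary(cfg)
  set.seed(999)
  before <- .Random.seed
  b <- simulateLibrary(cfg)
  expect_identical(compoundSmiles(a), compoundSmiles(b))
  expect_identical(a@metadata$planted, b@metadata$planted)
  expect_identical(.Random.seed, before)

  xy1 <- simulateRegressionData(simulationConfig(seed = 8))
  xy2 <- simulateRegressionData(simulationConfig(seed = 8))
  expect_identical(xy1, xy2)
  d1 <- simulateDecomposition(simulationConfig(seed = 8))
  d2 <- simulateDecomposition(simulationConfig(seed = 8))
  expect_identical(d1, d2)
  # different seeds give different draws
  expect_false(identical(xy1,
                         simulateRegressionData(simulationConfig(seed = 9))))
})

test_that("noise-free regression data is fit exactly; noisy data recovers
          the slope within sampling error", {
  clean <- simulateRegressionData(simulationConfig(seed = 4, slope = 0.3,
                                                   intercept = -1,
                                                   noiseSd = 0))
  fit <- pearsonRegression(clean$x, clean$y)
  expect_equal(fit@slope, 0.3, tolerance = 1e-10)
  expect_equal(fit@intercept, -1, tolerance = 1e-10)
  expect_equal(fit@r2, 1)

  noisy <- simulateRegressionData(simulationConfig(seed = 7, slope = 0.1,
                                                   intercept = 0.2,
                                                   noiseSd = 0.2,
                                                   nObs = 50))
  fit2 <- summary(lm(noisy$y ~ noisy$x))
  se <- fit2$coefficients[2, 2]
  expect_lt(abs(fit2$coefficients[2, 1] - 0.1), 3 * se)
})

test_that("null simulations reject at about the nominal 5% rate", {
  hits <- 0L
  nSeeds <- 500
  for (s in seq_len(nSeeds)) {
    xy <- simulateRegressionData(simulationConfig(seed = s, slope = 0,
                                                  intercept = 1,
                                                  noiseSd = 1,
                                                  nObs = 200))
    if (pearsonRegression(xy$x, xy$y)@p < 0.05) hits <- hits + 1L
  }
  rate <- hits / nSeeds
  tol <- 3 * sqrt(0.05 * 0.95 / nSeeds)
  expect_lt(abs(rate - 0.05), tol)
})

test_that("simulateDecomposition plants a recoverable hot-residue set", {
  d <- simulateDecomposition(simulationConfig(seed = 2, nResidues = 42,
                                              nHot = 3))
  hot <- hotResidues(d)
  expect_identical(nrow(hot), 3L)
  expect_setequal(paste0(hot$residue, "(", hot$chain, ")"),
                  attr(d, "planted"))
  # no hot residues
  d0 <- simulateDecomposition(simulationConfig(seed = 2, nHot = 0))
  expect_identical(nrow(hotResidues(d0)), 0L)
  # hotEffect = 0 puts planted residues exactly at the threshold, which
  # the <= semantics still includes
  dEdge <- simulateDecomposition(simulationConfig(seed = 6, nHot = 2,
                                                  hotEffect = 0))
  hotEdge <- hotResidues(dEdge)
  expect_identical(nrow(hotEdge), 2L)
  expect_true(all(pmin(hotEdge$dg_pb, hotEdge$dg_gb) == -3))
})

test_that("config validity constraints hold", {
  expect_error(simulationConfig(fracScaffold = 1.2), "fracScaffold")
  expect_error(simulationConfig(nHot = 50, nResidues = 10), "nHot")
  expect_error(simulationConfig(noiseSd = -1), "noiseSd")
})
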