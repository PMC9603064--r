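test_that("two-way generator is seed-reproducible and spec-validated", {
  s1 <- twoWaySimSpec(seed = 9L)
  a <- suppressWarnings(simulateExpression(s1))
  b <- suppressWarnings(simulateExpression(s1))
  expect_identical(exprData(a)$value, exprData(b)$value)
  c <- suppressWarnings(simulateExpression(twoWaySimSpec(seed = 10L)))
  expect_false(identical(exprData(a)$value, exprData(c)$value))
  # invalid specs rejected
  expect_error(twoWaySimSpec(geneEffects = c(1, 0, 0, 0)), "sum to zero")
  expect_error(twoWaySimSpec(lambda = c(1, 2)), "non-increasing")
  expect_error(twoWaySimSpec(sigma = -1), "sigma")
})

test_that("planted vectors are orthonormalized and expectations honored", {
  spec <- twoWaySimSpec(lambda = c(2, 1),
                        geneVectors = cbind(c(1, 2, 3, 4), c(1, 1, 2, 2)),
                        tissueVectors = matrix(rnorm(20, 1), 10, 2),
                        sigma = 0)
  gv <- spec@geneVectors
  expect_equal(crossprod(gv), diag(2), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(colSums(gv), c(0, 0), tolerance = 1e-12)
  x <- simulateExpression(spec)
  expect_equal(unclass(meansMatrix(cellMeans(x, "sim"))),
               expectedCellMeans(spec), tolerance = 1e-12)
})

test_that("empirical cell means converge to the spec expectation", {
  spec <- twoWaySimSpec(genes = c("g1", "g2"), tissues = c("e1", "e2"),
                        geneEffects = c(-0.2, 0.2), tissueEffects = c(-0.3, 0.3),
                        lambda = 0.5, geneVectors = matrix(c(-1, 1), 2),
                        tissueVectors = matrix(c(1, -1), 2),
                        sigma = 1, replicates = 10000L, seed = 3L)
  x <- suppressWarnings(simulateExpression(spec))
  m <- meansMatrix(cellMeans(x, "sim"))
  # s.e. of each cell mean is 0.01; 5 s.e. tolerance
  expect_lt(max(abs(m - expectedCellMeans(spec))), 0.05)
})

test_that("additive noise-free data have exactly zero interaction", {
  spec <- twoWaySimSpec(lambda = numeric(0),
                        geneVectors = matrix(numeric(0), 4, 0),
                        tissueVectors = matrix(numeric(0), 10, 0),
                        sigma = 0, replicates = 2L)
  x <- simulateExpression(spec)
  res <- ammiDecompose(x, "sim")
  expect_equal(anovaRow(res, "Interaction")$SS, 0, tolerance = 1e-18)
  expect_equal(max(singularValues(res)), 0, tolerance = 1e-10)
})

test_that("AMMI recovers a planted rank-1 interaction exactly at sigma = 0", {
  spec <- twoWaySimSpec(lambda = 5, geneVectors = matrix(c(3, -1, 2, 0), 4),
                        tissueVectors = matrix(rnorm(10, 2), 10),
                        sigma = 0, replicates = 2L)
  x <- suppressWarnings(simulateExpression(spec))
  res <- ammiDecompose(x, "sim", nAxes = 1L)
  lam <- singularValues(res)
  expect_equal(lam[1], 5, tolerance = 1e-8)
  expect_lt(max(lam[-1]), 1e-8)
})

test_that("gene scores correlate > 0.99 with the planted vector at sigma = 0.1", {
  spec <- twoWaySimSpec(lambda = c(4, 2), sigma = 0.1, replicates = 3L,
                        seed = 20260901L)
  x <- suppressWarnings(simulateExpression(spec))
  res <- ammiDecompose(x, "sim")
  expect_gt(abs(cor(geneScores(res)[, 1], spec@geneVectors[, 1])), 0.99)
})

test_that("ssp generator places noise at the correct strata", {
  # pure main-plot noise: E[main-plot error MS] = s * g * sigmaF^2
  sigmaF <- 0.5
  zero <- function(n) rep(0, n)
  ms <- vapply(1:200, function(i) {
    spec <- sspSimSpec(temperatures = paste0("T", 1:3),
                       tissues = paste0("S", 1:2), genes = paste0("G", 1:2),
                       blocks = 3L, tempEffects = zero(3),
                       tissueEffects = zero(2), geneEffects = zero(2),
                       tempTissue = matrix(0, 3, 2), tempGene = matrix(0, 3, 2),
                       tissueGene = matrix(0, 2, 2),
                       tempTissueGene = array(0, c(3, 2, 2)),
                       sigmaF = sigmaF, sigmaG = 0, sigmaE = 0, seed = i)
    fit <- fitSspAnova(suppressWarnings(simulateExpression(spec)))
    anovaRow(fit, "Main-plot error")$MS
  }, numeric(1))
  expected <- 2 * 2 * sigmaF^2
  expect_lt(abs(mean(ms) - expected) / expected, 0.15)
  # with sigmaG = sigmaE = 0, the lower strata carry no variation at all
  spec <- sspSimSpec(tempEffects = zero(5) , tissueEffects = zero(10),
                     geneEffects = zero(4), tempTissue = matrix(0, 5, 10),
                     tempGene = matrix(0, 5, 4), tissueGene = matrix(0, 10, 4),
                     tempTissueGene = array(0, c(5, 10, 4)),
                     sigmaF = 1, sigmaG = 0, sigmaE = 0, seed = 4L)
  fit <- fitSspAnova(suppressWarnings(simulateExpression(spec)))
  tab <- anovaTable(fit)
  lower <- tab$SS[tab$source %in% c("Tissue", "Gene", "Split-plot error",
                                    "Split-split-plot error")]
  expect_lt(max(lower), 1e-16)
})

test_that("ssp generator: zero sigmas and zero effects give an all-zero ANOVA", {
  zero <- function(n) rep(0, n)
  spec <- sspSimSpec(tempEffects = zero(5), tissueEffects = zero(10),
                     geneEffects = zero(4), tempTissue = matrix(0, 5, 10),
                     tempGene = matrix(0, 5, 4), tissueGene = matrix(0, 10, 4),
                     tempTissueGene = array(0, c(5, 10, 4)),
                     sigmaF = 0, sigmaG = 0, sigmaE = 0, seed = 1L)
  fit <- fitSspAnova(simulateExpression(spec))
  expect_lt(max(anovaTable(fit)$SS), 1e-20)
  # determinism of the full table
  a <- suppressWarnings(simulateExpression(sspSimSpec(seed = 77L)))
  b <- suppressWarnings(simulateExpression(sspSimSpec(seed = 77L)))
  expect_identical(exprData(a), exprData(b))
})

test_that("lognormal noise keeps values positive", {
  spec <- twoWaySimSpec(noise = "lognormal", mu = 0.3, sigma = 0.4,
                        seed = 2L)
  x <- simulateExpression(spec)
  expect_true(all(exprData(x)$value > 0))
})

test_that("sim specs round-trip through config files", {
  spec <- twoWaySimSpec(lambda = c(1.5, 0.5), sigma = 0.2, seed = 31L)
  path <- withr::local_tempfile(fileext = ".json")
  writeSimSpec(spec, path)
  spec2 <- readSimSpec(path)
  expect_equal(spec2@geneVectors, spec@geneVectors, tolerance = 1e-12)
  expect_equal(spec2@lambda, spec@lambda)
  expect_equal(exprData(suppressWarnings(simulateExpression(spec2)))$value,
               exprData(suppressWarnings(simulateExpression(spec)))$value,
               tolerance = 1e-12)
})
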