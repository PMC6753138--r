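test_that("penetrance calibration is exact and degenerates to the null", {
  mod <- PathwayEpistasis:::pairModel(0.25, 2, 0.05, "dominant", 1)
  expect_equal(sum(mod$prior * mod$penetrance), 0.05, tolerance = 1e-12)
  ## no interaction effect: baseline penetrance equals the prevalence
  mod0 <- PathwayEpistasis:::pairModel(0.25, 1, 0.05, "dominant", 1)
  expect_equal(mod0$f0, 0.05, tolerance = 1e-12)
  expect_equal(mod0$pCase, mod0$prior, tolerance = 1e-12)
  ## infeasible calibration is refused
  expect_error(simulateCohort(simulationSpec(10, 10, maf = 0.05,
                                             relativeRisk = 5,
                                             prevalence = 0.3,
                                             diseaseModel = "recessive",
                                             nBackgroundSnps = 0,
                                             nEmbeddedPairs = 1)),
               "calibration")
})

test_that("cohort simulation is bit-reproducible and label-faithful", {
  spec <- simulationSpec(50, 60, nBackgroundSnps = 30, maf = 0.2,
                         nEmbeddedPairs = 5, relativeRisk = 3, seed = 111)
  a <- simulateCohort(spec); b <- simulateCohort(spec)
  expect_identical(genotypes(a$ds), genotypes(b$ds))
  expect_equal(sum(phenotype(a$ds) == "case"), 50)
  expect_equal(sum(phenotype(a$ds) == "control"), 60)
  expect_equal(nrow(a$ds), 5 * 2 + 30)
})

test_that("embedded pairs carry the analytic class-conditional signal", {
  spec <- simulationSpec(5000, 5000, nBackgroundSnps = 0, maf = 0.25,
                         nEmbeddedPairs = 100, relativeRisk = 5,
                         seed = 112)
  co <- simulateCohort(spec)
  g <- genotypes(co$ds)
  case <- phenotype(co$ds) == "case"
  D <- codeGenotypes(g, "dominant")
  both <- D[, co$truth$idx_a] & D[, co$truth$idx_b]
  fCase <- colMeans(both[case, ]); fCtrl <- colMeans(both[!case, ])
  ## joint-carrier frequency higher in cases for (nearly) every pair
  expect_gte(mean(fCase > fCtrl), 0.99)
  ## frequencies match the closed-form class-conditional model
  mod <- co$model
  cc <- as.vector(outer(c(0, 1, 1), c(0, 1, 1)))
  expect_equal(mean(fCase), sum(mod$pCase[cc == 1]), tolerance = 0.01)
  expect_equal(mean(fCtrl), sum(mod$pControl[cc == 1]), tolerance = 0.01)
  ## single-SNP carrier rates: weak marginal signal when PR1 = 1
  m1Case <- colMeans(D[case, co$truth$idx_a])
  m1Ctrl <- colMeans(D[!case, co$truth$idx_a])
  carrier1 <- as.vector(outer(c(0, 1, 1), c(1, 1, 1)))
  expect_equal(mean(m1Case), sum(mod$pCase[carrier1 == 1]),
               tolerance = 0.01)
  expect_lt(mean(m1Case) - mean(m1Ctrl),
            mean(fCase) - mean(fCtrl))
  ## null effect: case and control MAF agree at embedded loci
  spec0 <- simulationSpec(3000, 3000, nBackgroundSnps = 0, maf = 0.25,
                          nEmbeddedPairs = 50, relativeRisk = 1,
                          seed = 113)
  co0 <- simulateCohort(spec0)
  g0 <- genotypes(co0$ds)
  case0 <- phenotype(co0$ds) == "case"
  expect_equal(mean(g0[case0, ]) / 2, mean(g0[!case0, ]) / 2,
               tolerance = 0.01)
})

test_that("network simulation preserves degrees while embedding blocks", {
  base <- simulateNetwork(400, 0.02, seed = 114)
  expect_equal(Matrix::nnzero(base$adj) / 2,
               round(0.02 * 400 * 399 / 2))
  sim <- simulateNetwork(400, 0.02,
                         blocks = list(list(sizeA = 30, sizeB = 30,
                                            density = 0.15)),
                         seed = 114)
  ## same seed: identical background before embedding, so the degree
  ## multiset must be preserved exactly by the rewiring
  expect_equal(sort(sim$degrees), sort(base$degrees))
  expect_equal(Matrix::nnzero(sim$adj), Matrix::nnzero(base$adj))
  b <- sim$blocks[[1]]
  expect_gte(b$achievedDensity, 0.15)
  expect_lt(b$achievedDensity, 0.15 * 1.05 + 2 / (30 * 30))
  obs <- sum(sim$adj[b$setA, b$setB]) / (30 * 30)
  expect_equal(obs, b$achievedDensity)
  ## a block at background density needs no rewiring
  plain <- simulateNetwork(200, 0.05,
                           blocks = list(list(sizeA = 20, sizeB = 20,
                                              density = 0.05)),
                           seed = 115)
  expect_equal(sort(plain$degrees),
               sort(simulateNetwork(200, 0.05, seed = 115)$degrees))
  ## a degree template is matched exactly
  tpl <- sim$degrees
  matched <- simulateNetwork(400, degreeTemplate = tpl, seed = 116)
  expect_equal(sort(matched$degrees), sort(tpl))
})

test_that("pair sensitivity is near chance with no effect and grows with n", {
  co0 <- simulateCohort(simulationSpec(250, 250, nBackgroundSnps = 300,
                                       maf = 0.25, nEmbeddedPairs = 100,
                                       relativeRisk = 1, seed = 117))
  s0 <- measurePairSensitivity(co0, density = 0.01, model = "DD")
  expect_lt(s0, 0.06)
  sens <- vapply(c(500, 2000), function(n) {
    co <- simulateCohort(simulationSpec(n / 2, n / 2,
                                        nBackgroundSnps = 300,
                                        maf = 0.25, nEmbeddedPairs = 100,
                                        relativeRisk = 2,
                                        seed = 118))
    measurePairSensitivity(co, density = 0.01, model = "DD")
  }, 0)
  expect_gt(sens[2], sens[1] - 0.05)
  expect_gt(sens[2], 0.3)
})

test_that("the power-curve selection logic is monotone in s and size", {
  ## miniature two-stage run
  pc <- powerCurve(mafs = 0.25, relativeRisk = 2, sizes = c(10L, 40L),
                   s = 0.05, pThreshold = 0.002,
                   sampleGrid = c(200L, 500L, 1000L),
                   nBackgroundSnps = 200L, nEmbeddedPairs = 50L,
                   netSnps = 300L, netDensity = 0.01, NP = 1000L,
                   seed = 119)
  ## larger blocks need lower density and never more samples
  expect_lte(pc$requiredDensity[pc$size == 40],
             pc$requiredDensity[pc$size == 10])
  if (!any(is.na(pc$minN)))
    expect_lte(pc$minN[pc$size == 40], pc$minN[pc$size == 10])
  ## doubling s can only lower the minimum n (re-derived from the cached
  ## sensitivities, which the selection is a pure function of)
  sens <- attr(pc, "sensitivities")
  minAt <- function(s, req) {
    ok <- sens$sensitivity * s >= req
    if (any(ok)) min(sens$n[ok]) else NA_integer_
  }
  for (i in seq_len(nrow(pc))) {
    m1 <- minAt(0.05, pc$requiredDensity[i])
    m2 <- minAt(0.10, pc$requiredDensity[i])
    expect_true(is.na(m1) || (!is.na(m2) && m2 <= m1))
  }
})
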