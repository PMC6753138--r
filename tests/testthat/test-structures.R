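test_that("between-pathway density counts match a brute-force double loop", {
  adj <- randomAdjacency(300, 0.05, seed = 51)
  withr::with_seed(51, {
    a <- sample(300, 40); b <- sample(setdiff(1:300, a), 30)
    d <- bpmDensity(adj, a, b)
    brute <- sum(vapply(a, function(i) sum(adj[i, b]), 0))
    expect_equal(d$edges, brute)
    expect_equal(d$possible, 40 * 30)
  })
  ## empty adjacency and complete block
  z <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                            dims = c(10, 10))
  expect_equal(bpmDensity(z, 1:3, 4:6)$density, 0)
  full <- Matrix::sparseMatrix(i = rep(1:3, each = 3),
                               j = rep(4:6, 3), x = 1, dims = c(10, 10),
                               symmetric = FALSE)
  full <- full + Matrix::t(full)
  expect_equal(bpmDensity(full, 1:3, 4:6)$density, 1)
  ## shared SNPs are removed before counting
  expect_null(bpmDensity(full, 1:3, 1:3))
})

test_that("chi-square statistics match textbook oracles", {
  ## observed at or below expectation scores zero (one-sided)
  expect_equal(chi2Global(50, 1000, 0.05, 1e5), 0)
  expect_equal(chi2Global(30, 1000, 0.05, 1e5), 0)
  expect_equal(chi2Local(60, 1000, 0.06), 0)
  withr::with_seed(52, {
    for (k in 1:40) {
      tot <- 20000; poss <- sample(200:2000, 1)
      dens <- runif(1, 0.02, 0.2)
      e <- rbinom(1, poss, dens * 2)
      te <- round(dens * tot)
      dens2 <- te / tot              # density consistent with the margins
      if (e > te || e / poss <= dens2) next
      tab <- matrix(c(e, te - e, poss - e, (tot - poss) - (te - e)), 2)
      want <- suppressWarnings(chisq.test(tab, correct = FALSE)$statistic)
      expect_equal(chi2Global(e, poss, dens2, tot), unname(want),
                   tolerance = 1e-10)
      ## local goodness of fit vs a direct two-cell computation
      m1 <- runif(1, 0.02, 0.1); m2 <- runif(1, 0.02, 0.1)
      exp1 <- poss * max(m1, m2)
      if (e > exp1) {
        gof <- (e - exp1)^2 / exp1 +
          ((poss - e) - (poss - exp1))^2 / (poss - exp1)
        expect_equal(chi2Local(e, poss, m1, m2), gof, tolerance = 1e-10)
      }
    }
  })
  ## realistic marginal regime: 1.2x enrichment over the larger marginal
  e <- round(1.2 * 0.065 * 5000)
  stat <- chi2Local(e, 5000, 0.059, 0.065)
  exp1 <- 5000 * 0.065
  gof <- (e - exp1)^2 / exp1 + ((5000 - e) - (5000 - exp1))^2 /
    (5000 - exp1)
  expect_equal(stat, gof, tolerance = 1e-10)
  expect_gt(stat, 0)
  ## approximate extensivity: doubling possible doubles the statistic
  s1 <- chi2Local(1.2 * 0.065 * 5000, 5000, 0.059, 0.065)
  s2 <- chi2Local(1.2 * 0.065 * 10000, 10000, 0.059, 0.065)
  expect_equal(s2 / s1, 2, tolerance = 0.01)
})

test_that("permutation p-values follow the pseudocount formula", {
  expect_equal(permPValue(10, NULL, matrix(c(11, 12, 13, 14, 15, rep(0, 995)))),
               (5 + 1) / 1000)
  ## all permutations exceed: capped at 1
  expect_equal(permPValue(0, NULL, matrix(rep(5, 100))), 1)
  ## joint condition: both statistics must be reached
  ng <- matrix(c(5, 5, 1, 1)); nl <- matrix(c(5, 1, 5, 1))
  expect_equal(permPValue(2, 2, ng, nl), (1 + 1) / 4)
})

test_that("the membership permutation preserves sizes and the identity", {
  adj <- randomAdjacency(120, 0.06, seed = 53)
  map <- snpPathwayMap(list(A = 1:20, B = 21:45, C = 40:60),
                       as.character(1:120))
  obs <- scoreStructures(adj, map)
  idPerm <- matrix(rep(1:120, 3), 120, 3)
  null <- snpPermutationNull(adj, map, NP = 3, perms = idPerm)
  cs <- obs$kind %in% c("BPM", "WPM")
  for (k in 1:3) {
    expect_equal(null$chi2g[k, cs], obs$chi2_global[cs], tolerance = 1e-9)
    expect_equal(null$chi2l[k, cs], obs$chi2_local[cs], tolerance = 1e-9)
    expect_equal(null$ustat[k, !cs], obs$u_stat[!cs], tolerance = 1e-9)
  }
  ## overlapping pathways: the B<->C pair is scored on disjoint remainders
  expect_true(all(obs$kind[cs][obs$pathway_a[cs] == "B" &
                                 obs$pathway_b[cs] == "C"] == "BPM"))
  ## no self-interaction structure is ever emitted
  expect_false(any(obs$pathway_a == obs$pathway_b & obs$kind == "BPM"))
})

test_that("null chi-square quantiles are uniform on a random network", {
  ## randomized-tiebreak quantiles of the observed statistic within its
  ## own permutation null are exactly uniform; KS checks the machinery
  adj <- randomAdjacency(250, 0.05, seed = 54)
  withr::with_seed(54, {
    sets <- split(sample(250, 240), rep(1:12, each = 20))
    names(sets) <- sprintf("P%d", 1:12)
    map <- snpPathwayMap(sets, as.character(1:250))
    obs <- scoreStructures(adj, map, kinds = "BPM")
    null <- snpPermutationNull(adj, map, NP = 400, seed = 99,
                               kinds = "BPM")
    u <- vapply(seq_len(nrow(obs)), function(i) {
      nd <- null$chi2g[, i]
      (sum(nd < obs$chi2_global[i]) +
         runif(1) * (1 + sum(nd == obs$chi2_global[i]))) / 401
    }, 0)
    expect_gt(ks.test(u, "punif")$p.value, 0.01)
  })
})

test_that("within-pathway scoring matches direct counts", {
  adj <- randomAdjacency(100, 0.08, seed = 55)
  map <- snpPathwayMap(list(W = 5:24), as.character(1:100))
  res <- scoreStructures(adj, map, kinds = "WPM")
  brute <- sum(as.matrix(adj)[5:24, 5:24]) / 2
  expect_equal(res$n_supporting_edges, brute)
  expect_equal(res$possible, 20 * 19 / 2)
  ## clique has density 1; empty block density 0 and chi2 0
  cl <- Matrix::sparseMatrix(i = rep(1:5, each = 5), j = rep(1:5, 5),
                             x = 1, dims = c(30, 30))
  diag(cl) <- 0
  cl <- Matrix::drop0(cl)
  mp <- snpPathwayMap(list(W = 1:5, E = 20:26), as.character(1:30))
  r2 <- scoreStructures(cl, mp, kinds = "WPM")
  expect_equal(r2$observed_density, c(1, 0))
  expect_equal(r2$chi2_global[2], 0)
})

test_that("pathway hub rank-sum matches exact enumeration", {
  ## brute-force: all subsets of size nx of the pooled sample
  enumP <- function(x, y) {
    pool <- c(x, y); W <- sum(rank(pool)[seq_along(x)])
    cs <- combn(length(pool), length(x))
    ws <- apply(cs, 2, function(i) sum(rank(pool)[i]))
    mean(ws >= W)
  }
  withr::with_seed(56, {
    for (k in 1:10) {
      x <- runif(sample(3:8, 1)); y <- runif(sample(5:8, 1))
      got <- rankSumTest(x, y)$p
      expect_equal(got, enumP(x, y), tolerance = 1e-10)
    }
  })
  ## pathway with all-zero degrees against connected rest: wrong tail
  adj <- randomAdjacency(60, 0.2, seed = 57)
  adj[1:10, ] <- 0; adj[, 1:10] <- 0
  adj <- Matrix::drop0(adj)
  mp <- snpPathwayMap(list(Z = 1:10), as.character(1:60))
  res <- scoreStructures(adj, mp, kinds = "PATH")
  expect_lt(res$u_path_neglog_p, 0.1)
  ## identical degree distributions: p about 1/2 on average
  withr::with_seed(58, {
    ps <- replicate(60, rankSumTest(runif(12), runif(12))$p)
    expect_lt(abs(mean(ps) - 0.5), 0.12)
  })
})

test_that("p_perm is monotone in the observed statistics", {
  null <- snpPermutationNull(randomAdjacency(100, 0.05, seed = 59),
                             snpPathwayMap(list(A = 1:15, B = 16:30),
                                           as.character(1:100)),
                             NP = 200, seed = 60, kinds = "BPM")
  g <- seq(0, 20, by = 2)
  p <- vapply(g, function(x) permPValue(x, x, null$chi2g, null$chi2l), 0)
  expect_true(all(diff(p) <= 0))
})

test_that("single-locus pathway enrichment finds a planted risk pathway", {
  co <- simulateCohort(simulationSpec(300, 300, nBackgroundSnps = 80,
                                      maf = 0.3, nEmbeddedPairs = 10,
                                      relativeRisk = 4, singleSnpRR = 3,
                                      seed = 61))
  ids <- snpInfo(co$ds)$snp_id
  map <- snpPathwayMap(list(hot = 1:20, cold1 = 21:50, cold2 = 51:80),
                       ids)
  enr <- univariatePathwayEnrichment(co$ds, map, model = "dominant",
                                     nPerm = 100, seed = 62)
  risk <- enr[enr$channel == "risk", ]
  expect_equal(risk$pathway[which.min(risk$p_ranksum)], "hot")
  expect_lt(risk$fdr[risk$pathway == "hot"],
            min(risk$fdr[risk$pathway != "hot"]) + 1e-9)
})
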