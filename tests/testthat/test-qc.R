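test_that("minor allele frequency is folded and excludes missing", {
  expect_equal(computeMAF(c(0, 0, 0, 0)), 0)
  expect_equal(computeMAF(c(2, 2, 2, 2)), 0)
  expect_equal(computeMAF(c(0, 1, 1, 2)), 0.5)
  expect_equal(computeMAF(c(0, 1, NA, NA)), 0.25)
  expect_error(computeMAF(c(NA_integer_, NA_integer_)), "missing")
  ## allele-fold symmetry on random columns
  withr::with_seed(1, {
    for (k in 1:20) {
      col <- rbinom(50, 2, runif(1, 0.05, 0.95))
      expect_equal(computeMAF(col), computeMAF(2L - col))
    }
  })
})

test_that("Hardy-Weinberg chi-square matches a direct 2x3-table oracle", {
  ## exact HW proportions -> chi2 = 0, p = 1
  expect_equal(hweTest(rep(c(0, 1, 2), c(25, 50, 25))), 1)
  expect_equal(hweTest(rep(0L, 30)), 1)
  ## all-homozygote split at f = 0.5 fails the 1e-6 filter
  expect_lt(hweTest(rep(c(0, 2), c(50, 50))), 1e-6)
  oracle <- function(n0, n1, n2) {
    n <- n0 + n1 + n2
    p <- (n1 + 2 * n2) / (2 * n)
    e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    obs <- c(n0, n1, n2)
    stat <- sum((obs[e > 0] - e[e > 0])^2 / e[e > 0])
    pchisq(stat, 1, lower.tail = FALSE)
  }
  withr::with_seed(7, {
    for (k in 1:50) {
      cnt <- rmultinom(1, 80, c(runif(1), runif(1), runif(1)))
      col <- rep(c(0L, 1L, 2L), cnt)
      expect_equal(hweTest(col), oracle(cnt[1], cnt[2], cnt[3]),
                   tolerance = 1e-10)
    }
  })
})

test_that("QC filters remove exactly the planted violations and are idempotent", {
  withr::with_seed(3, {
    g <- hweGenotypes(200, 60, maf = 0.3, seed = 3)
    ## planted violations; each carrier sample stays under the 2% sample
    ## missingness threshold (1 of 60 SNPs) except the planted one
    g[, 5] <- rbinom(200, 2, 0.01)            # low MAF
    g[2:13, 9] <- NA                          # SNP missingness 6% > 2%
    g[, 14] <- rep(c(0L, 0L, 2L, 2L), 50)     # HWE failure in controls too
    g[1, sample(15:60, 3)] <- NA              # sample missingness 5% > 2%
    ds <- genotypeData(g, rep(c("case", "control"), 100))
    out <- applyQcFilters(ds, qcConfig())
    kept <- snpInfo(out)$snp_id
    expect_false(any(c("s5", "s9", "s14") %in% kept))
    expect_equal(nrow(out), 57)
    expect_equal(ncol(out), 199)
    ## idempotence
    again <- applyQcFilters(out, qcConfig())
    expect_identical(genotypes(again), genotypes(out))
    ## a clean dataset passes untouched
    clean <- genotypeData(hweGenotypes(100, 10, 0.3, seed = 4),
                          rep(c("case", "control"), 50))
    expect_identical(genotypes(applyQcFilters(clean)), genotypes(clean))
  })
})

test_that("relatedness filter removes duplicates but spares independents", {
  g <- hweGenotypes(30, 2000, maf = 0.3, seed = 5)
  g[2, ] <- g[1, ]                            # duplicated sample
  g[20, ] <- g[19, ]
  ds <- genotypeData(g, rep(c("case", "control"), 15))
  pi <- estimateRelatedness(ds)
  expect_gt(pi[1, 2], 0.9)
  out <- relatednessFilter(ds, threshold = 0.2, seed = 1)
  expect_equal(ncol(out), 28)
  ## unreachable threshold removes nothing
  expect_equal(ncol(relatednessFilter(ds, threshold = 1.01)), 30)
  ## independent HWE samples: no estimate above 0.2 at many SNPs
  ds2 <- genotypeData(hweGenotypes(40, 5000, 0.3, seed = 6),
                      rep(c("case", "control"), 20))
  pi2 <- estimateRelatedness(ds2)
  expect_lt(max(pi2, na.rm = TRUE), 0.2)
})

test_that("case-control matching balances counts and respects structure", {
  ## 10 cases, 3 controls -> exactly 3 pairs
  g <- hweGenotypes(13, 50, 0.3, seed = 8)
  ds <- genotypeData(g, rep(c("case", "control"), c(10, 3)))
  out <- matchCasesControls(ds)
  expect_equal(ncol(out), 6)
  expect_equal(sum(phenotype(out) == "case"), 3)
  expect_true(all(table(pairId(out)) == 2))
  ## two separated subpopulations: pairs never cross them
  withr::with_seed(9, {
    n <- 60
    pop <- rep(c(1, 2), each = n / 2)
    maf <- ifelse(pop == 1, 0.1, 0.45)
    g2 <- t(vapply(maf, function(m) rbinom(80, 2, m), integer(80)))
    ph <- rep(c("case", "control"), n / 2)  # both classes in both pops
    ds2 <- genotypeData(g2, ph)
    out2 <- matchCasesControls(ds2, nComponents = 2)
    pidx <- split(seq_len(ncol(out2)), pairId(out2))
    origPop <- pop[match(
      SummarizedExperiment::colData(out2)$sample_id,
      sprintf("sample_%d", seq_len(n)))]
    crossing <- vapply(pidx, function(i) length(unique(origPop[i])) > 1,
                       TRUE)
    expect_false(any(crossing))
  })
})

test_that("LD pruning enforces the r-squared bound within windows", {
  g <- hweGenotypes(300, 40, 0.3, seed = 10)
  g[, 11] <- g[, 10]                          # identical adjacent SNPs
  ds <- genotypeData(g, rep(c("case", "control"), 150))
  cfg <- qcConfig(ldWindow = 10, ldStep = 3, ldR2Max = 0.1)
  out <- ldPrune(ds, cfg)
  kept <- snpInfo(out)$snp_id
  expect_false(all(c("s10", "s11") %in% kept))
  ## postcondition: max within-window r2 of retained SNPs below threshold
  gk <- genotypes(out)
  nk <- ncol(gk)
  for (start in seq(1, max(1, nk - 9), by = 3)) {
    win <- start:min(start + 9, nk)
    if (length(win) < 2) next
    r2 <- suppressWarnings(cor(gk[, win]))^2
    diag(r2) <- 0
    expect_lt(max(r2, na.rm = TRUE), 0.1)
  }
  ## independent SNPs at n = 500: near-zero removals
  ds2 <- genotypeData(hweGenotypes(500, 60, 0.3, seed = 11),
                      rep(c("case", "control"), 250))
  out2 <- ldPrune(ds2, cfg)
  expect_gte(ncol(out2), 59)
})

test_that("TSV and PLINK bed round trips preserve genotypes", {
  ds <- nullCohort(30, 8, seed = 12)
  tmp <- tempfile(fileext = ".tsv")
  writeGenotypeTsv(ds, tmp)
  back <- readGenotypeTsv(tmp)
  expect_equal(unname(genotypes(back)), unname(genotypes(ds)))
  expect_equal(phenotype(back), phenotype(ds))
  ## hand-built PLINK fileset: 5 samples, 2 SNPs
  prefix <- tempfile()
  writeLines(c("f1 i1 0 0 1 1", "f2 i2 0 0 1 2", "f3 i3 0 0 1 2",
               "f4 i4 0 0 1 1", "f5 i5 0 0 1 2"),
             paste0(prefix, ".fam"))
  writeLines(c("1\trs1\t0\t1000\tA\tG", "2\trs2\t0\t2000\tC\tT"),
             paste0(prefix, ".bim"))
  ## rs1: genotypes 2,1,0,NA,2 ; rs2: 0,0,1,1,2
  ## 2-bit codes (00=2, 10=1, 11=0, 01=NA), little-endian within byte
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pack <- function(codes) {
    codes <- c(codes, rep(0L, 4 * ceiling(length(codes) / 4) -
                            length(codes)))
    bytes <- vapply(seq(1, length(codes), by = 4), function(s)
      sum(codes[s:(s + 3)] * c(1L, 4L, 16L, 64L)), 0)
    as.raw(bytes)
  }
  writeBin(pack(c(0L, 2L, 3L, 1L, 0L)), con)   # 2,1,0,NA,2
  writeBin(pack(c(3L, 3L, 2L, 2L, 0L)), con)   # 0,0,1,1,2
  close(con)
  plink <- readPlink(prefix)
  expect_equal(unname(genotypes(plink)[, "rs1"]), c(2L, 1L, 0L, NA, 2L))
  expect_equal(unname(genotypes(plink)[, "rs2"]), c(0L, 0L, 1L, 1L, 2L))
  expect_equal(phenotype(plink), c("control", "case", "case", "control",
                                   "case"))
})
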