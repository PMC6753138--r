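## Shared fixture builders. Everything is generated in code under fixed
## seeds; no data files.

## HWE genotype matrix, samples x SNPs
hweGenotypes <- function(nSamples, nSnps, maf = 0.3, seed = 1) {
  withr::with_seed(seed, {
    m <- rep_len(maf, nSnps)
    matrix(stats::rbinom(nSamples * nSnps, 2, rep(m, each = nSamples)),
           nSamples, nSnps,
           dimnames = list(NULL, sprintf("s%d", seq_len(nSnps))))
  })
}

## Balanced null cohort with no disease signal
nullCohort <- function(nSamples = 100, nSnps = 20, maf = 0.3, seed = 1) {
  g <- hweGenotypes(nSamples, nSnps, maf, seed)
  genotypeData(g, rep(c("case", "control"), length.out = nSamples))
}

## Small planted-BPM cohort: pathways P_A / P_B of `size` SNPs whose
## aligned pairs are epistatic, plus null pathways and background SNPs.
plantedBpmCohort <- function(n = 800, size = 30, nNullPathways = 3,
                             nExtraBg = 60, maf = 0.25, rr = 3,
                             seed = 1) {
  spec <- simulationSpec(nCases = n / 2, nControls = n / 2,
                         nBackgroundSnps = nNullPathways * size + nExtraBg,
                         maf = maf, nEmbeddedPairs = size,
                         relativeRisk = rr, seed = seed)
  co <- simulateCohort(spec)
  ids <- snpInfo(co$ds)$snp_id
  paths <- list(P_A = co$truth$idx_a, P_B = co$truth$idx_b)
  for (k in seq_len(nNullPathways))
    paths[[sprintf("N%d", k)]] <- 2 * size + (k - 1) * size + seq_len(size)
  list(cohort = co, map = snpPathwayMap(paths, ids))
}

## Exact upper-tail hypergeometric by direct enumeration with choose()
hygeOracle <- function(M, N, K, X) {
  f <- X:min(K, N)
  sum(choose(N, f) * choose(M - N, K - f)) / choose(M, K)
}

## hygeSSI recomputed from first principles for one coded pair
hygeSsiOracle <- function(sx, sy, C, alpha = 0.05) {
  M <- length(sx); N <- sum(C)
  pv <- function(pat) hygeOracle(M, N, sum(pat), sum(pat & C))
  p11 <- pv(sx & sy); p10 <- pv(sx & !sy)
  p01 <- pv(!sx & sy); p00 <- pv(!sx & !sy)
  p1 <- pv(sx == 1); p2 <- pv(sy == 1)
  if (p11 <= alpha && p10 > alpha && p01 > alpha && p00 > alpha)
    max(0, -log10(p11 / min(p10, p01, p00, p1, p2)))
  else 0
}

## Random sparse symmetric adjacency at a given density
randomAdjacency <- function(n, density = 0.05, seed = 1) {
  withr::with_seed(seed, {
    ut <- which(upper.tri(matrix(0, n, n)))
    keep <- sample(ut, round(density * length(ut)))
    j <- ((keep - 1L) %/% n) + 1L
    i <- keep - (j - 1L) * n
    Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1, dims = c(n, n))
  })
}
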