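#' Quality-control configuration
#'
#' Bundles the genotype QC thresholds: the standard GWAS inclusion filters
#' (per-sample and per-SNP missingness, minor allele frequency,
#' Hardy-Weinberg equilibrium in controls), the relatedness cutoff, and the
#' LD pruning parameters with PLINK \code{--indep-pairwise} semantics.
#'
#' @param maxMissingRate maximal missing genotyping rate per sample/SNP.
#' @param minMaf minimum minor allele frequency.
#' @param hwePFloor Hardy-Weinberg equilibrium p-value cutoff (tested in
#'   controls; SNPs below are removed).
#' @param ibdThreshold proportion-IBD above which one member of a sample
#'   pair is removed.
#' @param ldWindow,ldStep,ldR2Max LD pruning: sliding window size (SNPs),
#'   step (SNPs), and maximal pairwise r-squared retained.
#' @return a list with class \code{"QcConfig"}.
#' @export
qcConfig <- function(maxMissingRate = 0.02, minMaf = 0.05,
                     hwePFloor = 1e-6, ibdThreshold = 0.2,
                     ldWindow = 50L, ldStep = 5L, ldR2Max = 0.1) {
  stopifnot(maxMissingRate >= 0, maxMissingRate <= 1,
            minMaf >= 0, minMaf <= 0.5, hwePFloor >= 0, hwePFloor <= 1,
            ldWindow >= ldStep, ldStep >= 1)
  structure(list(maxMissingRate = maxMissingRate, minMaf = minMaf,
                 hwePFloor = hwePFloor, ibdThreshold = ibdThreshold,
                 ldWindow = as.integer(ldWindow), ldStep = as.integer(ldStep),
                 ldR2Max = ldR2Max), class = "QcConfig")
}

#' Minor allele frequency of one genotype column
#'
#' Missing entries are excluded; the frequency is folded so the result is
#' always in [0, 0.5] regardless of which allele was labelled minor.
#'
#' @param col vector of minor-allele counts (0/1/2, NA = missing).
#' @return folded allele frequency \code{min(f, 1 - f)}.
#' @examples
#' computeMAF(c(0, 1, 1, 2))  # 0.5
#' @export
computeMAF <- function(col) {
  ok <- !is.na(col)
  if (!any(ok)) stop("all genotypes missing: unusable SNP")
  f <- sum(col[ok]) / (2 * sum(ok))
  min(f, 1 - f)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom Pearson chi-square of the observed genotype counts
#' against the Hardy-Weinberg expectation derived from the sample allele
#' frequency; upper-tail p-value. Monomorphic columns return 1.
#'
#' @param col vector of minor-allele counts (0/1/2, NA = missing).
#' @return p-value in (0, 1].
#' @export
hweTest <- function(col) {
  col <- col[!is.na(col)]
  n <- length(col)
  if (n == 0L || length(unique(col)) < 2L) return(1)
  n2 <- sum(col == 2L); n1 <- sum(col == 1L); n0 <- n - n1 - n2
  p <- (n1 + 2 * n2) / (2 * n)
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  obs <- c(n0, n1, n2)
  keep <- e > 0
  stat <- sum((obs[keep] - e[keep])^2 / e[keep])
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Apply the standard SNP/sample quality-control filters
#'
#' Iteratively removes (i) samples with missing rate above
#' \code{cfg$maxMissingRate}, (ii) SNPs with missing rate above the same
#' threshold, (iii) SNPs with folded MAF below \code{cfg$minMaf}, and (iv)
#' SNPs failing Hardy-Weinberg equilibrium in controls at
#' \code{cfg$hwePFloor}, until no further removals occur. Counts removed per
#' rule are appended to the dataset's QC log.
#'
#' @param ds a \linkS4class{GenotypeData}.
#' @param cfg a [qcConfig()].
#' @return the filtered \linkS4class{GenotypeData}.
#' @export
applyQcFilters <- function(ds, cfg = qcConfig()) {
  repeat {
    g <- genotypes(ds)                      # samples x SNPs
    sampMiss <- rowMeans(is.na(g))
    dropSamp <- sampMiss > cfg$maxMissingRate
    if (any(dropSamp)) {
      ds <- subsetGenotypeData(ds, sampleKeep = !dropSamp)
      ds <- appendQcLog(ds, "sample_missing_rate", sum(dropSamp))
      g <- genotypes(ds)
    }
    snpMiss <- colMeans(is.na(g))
    dropMiss <- snpMiss > cfg$maxMissingRate
    nObs <- colSums(!is.na(g))
    if (any(nObs == 0))
      dropMiss <- dropMiss | nObs == 0
    maf <- ifelse(nObs > 0,
                  pmin(1, colSums(g, na.rm = TRUE) / pmax(1, 2 * nObs)),
                  0)
    maf <- pmin(maf, 1 - maf)
    dropMaf <- !dropMiss & maf < cfg$minMaf
    ctrl <- phenotype(ds) == "control"
    hwe <- apply(g[ctrl, , drop = FALSE], 2, function(col) {
      if (all(is.na(col))) 1 else hweTest(col)
    })
    dropHwe <- !dropMiss & !dropMaf & hwe < cfg$hwePFloor
    anyDrop <- dropMiss | dropMaf | dropHwe
    if (any(dropMiss)) ds <- appendQcLog(ds, "snp_missing_rate", sum(dropMiss))
    if (any(dropMaf)) ds <- appendQcLog(ds, "snp_maf", sum(dropMaf))
    if (any(dropHwe)) ds <- appendQcLog(ds, "snp_hwe_controls", sum(dropHwe))
    if (any(anyDrop)) ds <- subsetGenotypeData(ds, snpKeep = !anyDrop)
    if (!any(anyDrop) && !any(dropSamp)) break
    if (nrow(ds) == 0L || ncol(ds) == 0L)
      stop("quality control removed every SNP or sample")
  }
  ds
}

#' Pairwise proportion-IBD relatedness estimates
#'
#' Method-of-moments estimator of the proportion of alleles shared identical
#' by descent (PI_HAT semantics): the identity-by-state distribution of each
#' sample pair is compared against its expectation under unrelatedness given
#' per-SNP allele frequencies, and the IBD state probabilities Z0, Z1, Z2
#' are solved for and combined as \code{Z1/2 + Z2}.
#'
#' @param ds a \linkS4class{GenotypeData}.
#' @return symmetric matrix of PI_HAT estimates (NA diagonal).
#' @export
estimateRelatedness <- function(ds) {
  g <- genotypes(ds)
  n <- nrow(g)
  obs <- !is.na(g)
  g0 <- g; g0[!obs] <- 0L
  p <- colSums(g0) / pmax(1, 2 * colSums(obs))   # A1 allele frequency
  q <- 1 - p
  ## per-SNP expected IBS-state probabilities under IBD state 0 / 1
  e0.ibs0 <- 2 * p^2 * q^2
  e0.ibs1 <- 4 * p^3 * q + 4 * p * q^3
  e0.ibs2 <- p^4 + q^4 + 4 * p^2 * q^2
  e1.ibs1 <- 2 * p^2 * q + 2 * p * q^2
  e1.ibs2 <- p^3 + q^3 + p^2 * q + p * q^2
  I0 <- matrix(as.numeric(obs & g == 0L), n)
  I1 <- matrix(as.numeric(obs & g == 1L), n)
  I2 <- matrix(as.numeric(obs & g == 2L), n)
  ibs0 <- tcrossprod(I0, I2); ibs0 <- ibs0 + t(ibs0)
  het <- tcrossprod(I1, I0 + I2)
  ibs1 <- het + t(het)
  ibs2 <- tcrossprod(I0) + tcrossprod(I1) + tcrossprod(I2)
  O <- matrix(as.numeric(obs), n)
  wt <- function(w) tcrossprod(O * rep(w, each = n), O)
  E0.0 <- wt(e0.ibs0); E0.1 <- wt(e0.ibs1); E0.2 <- wt(e0.ibs2)
  E1.1 <- wt(e1.ibs1); E1.2 <- wt(e1.ibs2)
  z0 <- ibs0 / pmax(E0.0, .Machine$double.eps)
  z1 <- (ibs1 - z0 * E0.1) / pmax(E1.1, .Machine$double.eps)
  z2 <- (ibs2 - z0 * E0.2 - z1 * E1.2) /
    pmax(tcrossprod(O) - 0, .Machine$double.eps)
  z0 <- pmin(pmax(z0, 0), 1); z1 <- pmin(pmax(z1, 0), 1)
  z2 <- pmin(pmax(z2, 0), 1)
  tot <- z0 + z1 + z2
  piHat <- (z1 / 2 + z2) / tot
  diag(piHat) <- NA_real_
  dimnames(piHat) <- list(colnames(ds), colnames(ds))
  piHat
}

#' Remove one member of each related sample pair
#'
#' Pairs with estimated proportion IBD above \code{threshold} are resolved
#' by removing one randomly chosen member (seeded RNG); removals cascade so
#' that no retained pair exceeds the threshold.
#'
#' @param ds a \linkS4class{GenotypeData} with at least 2 samples.
#' @param threshold proportion-IBD cutoff (default 0.2).
#' @param seed integer seed for the removal choice.
#' @return the filtered \linkS4class{GenotypeData}.
#' @export
relatednessFilter <- function(ds, threshold = 0.2, seed = 1L) {
  stopifnot(ncol(ds) >= 2)
  piHat <- estimateRelatedness(ds)
  drop <- logical(ncol(ds))
  rng <- seededRng(seed)
  repeat {
    live <- which(!drop)
    sub <- piHat[live, live, drop = FALSE]
    hits <- which(sub > threshold & upper.tri(sub), arr.ind = TRUE)
    if (!nrow(hits)) break
    pair <- live[hits[1L, ]]
    victim <- pair[1L + (rng() < 0.5)]
    drop[victim] <- TRUE
  }
  if (any(drop)) {
    ds <- subsetGenotypeData(ds, sampleKeep = !drop)
    ds <- appendQcLog(ds, "relatedness_pi_hat", sum(drop))
  }
  ds
}

#' Match cases to controls in principal-component space
#'
#' Projects all samples onto the top principal axes of the standardized
#' genotype matrix and greedily pairs each case with its nearest unmatched
#' control (1:1, without replacement). Unmatched samples are dropped, so the
#' result has balanced case/control counts and \code{pair_id} filled;
#' matched-pair structure is what the sample-permutation FDR preserves.
#'
#' @param ds a \linkS4class{GenotypeData} with at least one case and one
#'   control.
#' @param nComponents number of principal components used (default 4).
#' @return a \linkS4class{GenotypeData} of matched pairs.
#' @export
matchCasesControls <- function(ds, nComponents = 4L) {
  ph <- phenotype(ds)
  cases <- which(ph == "case"); ctrls <- which(ph == "control")
  if (!length(cases) || !length(ctrls))
    stop("need at least one case and one control")
  g <- genotypes(ds)
  mu <- colMeans(g, na.rm = TRUE)
  idx <- which(is.na(g), arr.ind = TRUE)
  if (nrow(idx)) g[idx] <- mu[idx[, 2]]
  sd <- apply(g, 2, stats::sd)
  keep <- sd > 0
  z <- scale(g[, keep, drop = FALSE])
  k <- min(nComponents, ncol(z), nrow(z) - 1L)
  pc <- stats::prcomp(z, rank. = k)$x
  d2 <- outer(rowSums(pc[cases, , drop = FALSE]^2),
              rowSums(pc[ctrls, , drop = FALSE]^2), "+") -
    2 * tcrossprod(pc[cases, , drop = FALSE], pc[ctrls, , drop = FALSE])
  nPairs <- min(length(cases), length(ctrls))
  pairCase <- integer(nPairs); pairCtrl <- integer(nPairs)
  for (i in seq_len(nPairs)) {
    m <- arrayInd(which.min(d2), dim(d2))
    pairCase[i] <- cases[m[1]]; pairCtrl[i] <- ctrls[m[2]]
    d2[m[1], ] <- Inf; d2[, m[2]] <- Inf
  }
  keepSamp <- c(rbind(pairCase, pairCtrl))
  ids <- rep(sprintf("pair_%d", seq_len(nPairs)), each = 2)
  dropped <- ncol(ds) - length(keepSamp)
  ds <- subsetGenotypeData(ds, sampleKeep = keepSamp)
  colData(ds)$pair_id <- ids
  if (dropped > 0) ds <- appendQcLog(ds, "unmatched_samples", dropped)
  ds
}

#' Prune SNPs in linkage disequilibrium
#'
#' Sliding-window LD pruning with PLINK \code{--indep-pairwise} semantics:
#' windows of \code{ldWindow} SNPs advanced by \code{ldStep}; within each
#' window, while any retained pair has squared Pearson correlation of
#' genotype codes at or above \code{ldR2Max}, one SNP of the worst pair is
#' removed (deterministic tie-break: lower MAF, then lower position).
#' Correlations use pairwise-complete samples. SNPs must be sorted by
#' (chromosome, position).
#'
#' @param ds a \linkS4class{GenotypeData}.
#' @param cfg a [qcConfig()] supplying \code{ldWindow}, \code{ldStep},
#'   \code{ldR2Max}.
#' @return the pruned \linkS4class{GenotypeData}.
#' @export
ldPrune <- function(ds, cfg = qcConfig()) {
  info <- snpInfo(ds)
  ord <- order(info$chrom, info$pos)
  if (any(ord != seq_along(ord)))
    stop("SNPs must be sorted by (chromosome, position)")
  g <- genotypes(ds)
  maf <- apply(g, 2, computeMAF)
  removed <- logical(ncol(g))
  for (chr in unique(info$chrom)) {
    snpIdx <- which(info$chrom == chr)
    start <- 1L
    repeat {
      win <- snpIdx[seq(start, min(start + cfg$ldWindow - 1L,
                                   length(snpIdx)))]
      live <- win[!removed[win]]
      if (length(live) >= 2L) {
        r2 <- suppressWarnings(
          stats::cor(g[, live, drop = FALSE],
                     use = "pairwise.complete.obs"))^2
        r2[is.na(r2)] <- 0
        diag(r2) <- 0
        while (max(r2) >= cfg$ldR2Max) {
          m <- arrayInd(which.max(r2), dim(r2))
          a <- live[m[1]]; b <- live[m[2]]
          victim <- if (maf[a] < maf[b]) a
            else if (maf[b] < maf[a]) b
            else if (info$pos[a] < info$pos[b]) a else b
          removed[victim] <- TRUE
          vi <- match(victim, live)
          r2[vi, ] <- 0; r2[, vi] <- 0
        }
      }
      if (start + cfg$ldWindow - 1L >= length(snpIdx)) break
      start <- start + cfg$ldStep
    }
  }
  if (any(removed)) {
    ds <- subsetGenotypeData(ds, snpKeep = !removed)
    ds <- appendQcLog(ds, "ld_prune", sum(removed))
  }
  ds
}
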