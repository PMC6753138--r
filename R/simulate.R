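#' Specification of a synthetic epistatic case-control cohort
#'
#' Describes the generative model used by [simulateCohort()]: biallelic
#' SNPs in Hardy-Weinberg equilibrium, a set of embedded SNP pairs whose
#' joint carrier genotype multiplies the baseline penetrance, and
#' unassociated background SNPs. The two-locus penetrance is
#' \code{f0 * d(g1, g2)} with relative risk \code{d} for double carriers
#' (the four double-carrier genotype cells share one relative risk),
#' \code{singleSnpRR} for single carriers and 1 otherwise; \code{f0} is
#' calibrated analytically so the population prevalence matches
#' \code{prevalence}.
#'
#' @param nCases,nControls cohort composition.
#' @param nBackgroundSnps unassociated SNPs (default 2000).
#' @param maf minor allele frequency of the embedded SNPs.
#' @param backgroundMaf per-SNP MAFs for the background, or NULL to draw
#'   them uniformly from [0.05, 0.5].
#' @param nEmbeddedPairs number of embedded interacting pairs
#'   (non-overlapping in SNPs; default 100).
#' @param relativeRisk shared double-carrier relative risk d
#'   (d11 = d12 = d21 = d22).
#' @param prevalence population disease prevalence (default 0.05).
#' @param diseaseModel \code{"dominant"} (carrier = at least one minor
#'   allele) or \code{"recessive"} (carrier = minor homozygote).
#' @param singleSnpRR relative risk of single-carrier combinations
#'   (default 1: all excess risk is epistatic).
#' @param seed integer seed.
#' @return a list with class \code{"SimulationSpec"}.
#' @export
simulationSpec <- function(nCases, nControls, nBackgroundSnps = 2000L,
                           maf = 0.25, backgroundMaf = NULL,
                           nEmbeddedPairs = 100L, relativeRisk = 2,
                           prevalence = 0.05,
                           diseaseModel = c("dominant", "recessive"),
                           singleSnpRR = 1, seed = 1L) {
  diseaseModel <- match.arg(diseaseModel)
  stopifnot(prevalence > 0, prevalence < 1, relativeRisk >= 1,
            singleSnpRR >= 1, maf > 0, maf <= 0.5, nCases >= 1,
            nControls >= 1)
  structure(list(nCases = as.integer(nCases),
                 nControls = as.integer(nControls),
                 nBackgroundSnps = as.integer(nBackgroundSnps),
                 maf = maf, backgroundMaf = backgroundMaf,
                 nEmbeddedPairs = as.integer(nEmbeddedPairs),
                 relativeRisk = relativeRisk, prevalence = prevalence,
                 diseaseModel = diseaseModel, singleSnpRR = singleSnpRR,
                 seed = as.integer(seed)),
            class = "SimulationSpec")
}

## Two-locus genotype model for one embedded pair: HWE prior over the 9
## genotype cells, penetrance f0 * d(g), and the class-conditional cell
## probabilities. Cells are ordered g1-major: (g1, g2) = (0,0), (1,0), ...
pairModel <- function(maf, relativeRisk, prevalence, diseaseModel,
                      singleSnpRR) {
  pg <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  carrier <- if (diseaseModel == "dominant") c(0, 1, 1) else c(0, 0, 1)
  prior <- as.vector(outer(pg, pg))
  cc <- as.vector(outer(carrier, carrier))        # both-carrier indicator
  sc <- as.vector(outer(carrier, 1 - carrier) + outer(1 - carrier, carrier))
  d <- ifelse(cc == 1, relativeRisk, ifelse(sc == 1, singleSnpRR, 1))
  f0 <- prevalence / sum(prior * d)
  if (f0 * max(d) > 1)
    stop(sprintf(
      "penetrance calibration failed: f0 * max relative risk = %.3f > 1",
      f0 * max(d)))
  pen <- f0 * d
  g1 <- rep(0:2, times = 3); g2 <- rep(0:2, each = 3)
  list(prior = prior, penetrance = pen, f0 = f0,
       pCase = prior * pen / sum(prior * pen),
       pControl = prior * (1 - pen) / sum(prior * (1 - pen)),
       g1 = g1, g2 = g2)
}

#' Simulate an epistatic case-control cohort
#'
#' Case/control labels are fixed at the requested counts; each embedded
#' pair's two-locus genotype is drawn from its class-conditional
#' distribution (Bayes inversion of the calibrated penetrance model
#' against the HWE prior), and background SNPs are drawn from
#' Hardy-Weinberg equilibrium independently of status. Embedded pairs do
#' not share SNPs. Bit-reproducible given \code{spec$seed}.
#'
#' @param spec a [simulationSpec()].
#' @return list: \code{ds} (a \linkS4class{GenotypeData}; embedded SNPs
#'   come first, named \code{pair<k>_a/_b}), \code{truth} (data.frame of
#'   embedded pair SNP ids and indices), \code{model} (the calibrated
#'   penetrance model).
#' @export
simulateCohort <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  mod <- pairModel(spec$maf, spec$relativeRisk, spec$prevalence,
                   spec$diseaseModel, spec$singleSnpRR)
  n <- spec$nCases + spec$nControls
  nP <- spec$nEmbeddedPairs
  nB <- spec$nBackgroundSnps
  withSeed(spec$seed, {
    ## embedded pairs: one class-conditional cell draw per sample x pair
    cells <- matrix(0L, n, nP)
    if (nP > 0) {
      cells[seq_len(spec$nCases), ] <-
        sample.int(9L, spec$nCases * nP, replace = TRUE,
                   prob = mod$pCase)
      cells[spec$nCases + seq_len(spec$nControls), ] <-
        sample.int(9L, spec$nControls * nP, replace = TRUE,
                   prob = mod$pControl)
    }
    g <- matrix(0L, n, 2L * nP + nB)
    if (nP > 0) {
      g[, 2 * seq_len(nP) - 1L] <- mod$g1[cells]
      g[, 2 * seq_len(nP)] <- mod$g2[cells]
    }
    if (nB > 0) {
      bm <- if (is.null(spec$backgroundMaf))
        stats::runif(nB, 0.05, 0.5) else rep_len(spec$backgroundMaf, nB)
      g[, 2 * nP + seq_len(nB)] <-
        stats::rbinom(n * nB, 2L, rep(bm, each = n))
    }
    ids <- c(if (nP > 0) as.vector(rbind(sprintf("pair%d_a", seq_len(nP)),
                                         sprintf("pair%d_b", seq_len(nP)))),
             if (nB > 0) sprintf("bg%d", seq_len(nB)))
    colnames(g) <- ids
    ds <- genotypeData(g, phenotype = rep(c("case", "control"),
                                          c(spec$nCases, spec$nControls)))
    truth <- if (nP > 0)
      data.frame(pair = seq_len(nP),
                 snp_a = sprintf("pair%d_a", seq_len(nP)),
                 snp_b = sprintf("pair%d_b", seq_len(nP)),
                 idx_a = 2 * seq_len(nP) - 1L, idx_b = 2 * seq_len(nP))
    else data.frame()
    list(ds = ds, truth = truth, model = mod)
  })
}

#' Sensitivity of pairwise interaction detection on a simulated cohort
#'
#' Builds the interaction network for the cohort, binarizes it at the
#' requested density, and returns the fraction of embedded pairs present
#' as edges (either channel).
#'
#' @param cohort output of [simulateCohort()].
#' @param density binarization density (default 0.01).
#' @param model disease model for [buildNetwork()] (default \code{"DD"}).
#' @param alpha,prefilter scoring parameters.
#' @param seed seed for binarization tie-breaks.
#' @return sensitivity in [0, 1].
#' @export
measurePairSensitivity <- function(cohort, density = 0.01, model = "DD",
                                   alpha = 0.05, prefilter = 0.2,
                                   seed = 1L) {
  net <- buildNetwork(cohort$ds, model = model, alpha = alpha,
                      prefilter = prefilter)
  net <- binarizeNetwork(net, density, seed = seed)
  adj <- adjacency(net, "both")
  if (!nrow(cohort$truth)) return(NA_real_)
  mean(adj[cbind(cohort$truth$idx_a, cohort$truth$idx_b)] > 0)
}

## ---------------------------------------------------------------------------
## Synthetic interaction networks with embedded BPM blocks

#' Simulate a binary SNP-SNP network with embedded between-pathway blocks
#'
#' Generates a background network (matching a supplied degree sequence by
#' the configuration model with simple-graph repair, or Erdos-Renyi at
#' \code{backgroundDensity}), then raises each requested block (a pair of
#' disjoint node sets) to its target density by degree-preserving edge
#' swaps: an edge leaving the block's A side and one leaving its B side
#' are rewired into an A-B edge plus an outside edge, so every node degree
#' and the global density are unchanged.
#'
#' @param nSnps number of nodes.
#' @param backgroundDensity background edge density.
#' @param blocks list of blocks, each
#'   \code{list(sizeA =, sizeB =, density =)}.
#' @param degreeTemplate optional integer degree sequence to match.
#' @param seed integer seed.
#' @param maxAttemptsFactor bound on rewiring attempts per needed edge.
#' @return list: \code{adj} (sparse symmetric), \code{blocks} (registry
#'   with node sets and achieved densities), \code{degrees}.
#' @export
simulateNetwork <- function(nSnps, backgroundDensity = 0.01,
                            blocks = list(), degreeTemplate = NULL,
                            seed = 1L, maxAttemptsFactor = 200L) {
  withSeed(seed, {
    if (!is.null(degreeTemplate)) {
      stopifnot(length(degreeTemplate) == nSnps)
      gr <- igraph::sample_degseq(degreeTemplate, method = "fast.heur.simple")
    } else {
      m <- round(backgroundDensity * nSnps * (nSnps - 1) / 2)
      gr <- igraph::sample_gnm(nSnps, m)
    }
    el <- igraph::as_edgelist(gr, names = FALSE)
    A <- matrix(FALSE, nSnps, nSnps)
    A[el] <- TRUE; A[el[, c(2, 1)]] <- TRUE
    ## disjoint node sets for all blocks
    needed <- sum(vapply(blocks, function(b) b$sizeA + b$sizeB, 0))
    stopifnot(needed <= nSnps)
    pool <- sample.int(nSnps, needed)
    offset <- 0L
    registry <- list()
    for (bi in seq_along(blocks)) {
      b <- blocks[[bi]]
      setA <- pool[offset + seq_len(b$sizeA)]; offset <- offset + b$sizeA
      setB <- pool[offset + seq_len(b$sizeB)]; offset <- offset + b$sizeB
      inA <- logical(nSnps); inA[setA] <- TRUE
      inB <- logical(nSnps); inB[setB] <- TRUE
      target <- ceiling(b$density * b$sizeA * b$sizeB)
      current <- sum(A[setA, setB])
      attempts <- 0L
      maxAttempts <- maxAttemptsFactor * max(1L, target - current)
      while (current < target && attempts < maxAttempts) {
        attempts <- attempts + 1L
        a <- setA[sample.int(b$sizeA, 1L)]
        nbrA <- which(A[a, ] & !inB)
        if (!length(nbrA)) next
        x <- nbrA[sample.int(length(nbrA), 1L)]
        bb <- setB[sample.int(b$sizeB, 1L)]
        nbrB <- which(A[bb, ] & !inA)
        if (!length(nbrB)) next
        y <- nbrB[sample.int(length(nbrB), 1L)]
        if (x == y || x == bb || y == a) next
        if (A[a, bb] || A[x, y]) next
        A[a, x] <- A[x, a] <- FALSE
        A[bb, y] <- A[y, bb] <- FALSE
        A[a, bb] <- A[bb, a] <- TRUE
        A[x, y] <- A[y, x] <- TRUE
        ## the rewired-in outside edge may itself land in the block
        current <- current + 1L + (inA[x] && inB[y]) + (inB[x] && inA[y])
      }
      achieved <- current / (b$sizeA * b$sizeB)
      if (current < target)
        stop(sprintf(
          "block %d: rewiring stalled at density %.4g (target %.4g)",
          bi, achieved, b$density))
      registry[[bi]] <- list(setA = setA, setB = setB,
                             targetDensity = b$density,
                             achievedDensity = achieved, edges = current)
    }
    ut <- which(upper.tri(A) & A, arr.ind = TRUE)
    adj <- Matrix::sparseMatrix(i = c(ut[, 1], ut[, 2]),
                                j = c(ut[, 2], ut[, 1]), x = 1,
                                dims = c(nSnps, nSnps))
    list(adj = adj, blocks = registry, degrees = Matrix::rowSums(adj))
  })
}

## Internal: permutation p-value of one embedded block on one network.
blockPermP <- function(adj, setA, setB, NP, seed) {
  n <- nrow(adj)
  map <- snpPathwayMap(list(A = setA, B = setB),
                       snpIds = as.character(seq_len(n)))
  res <- discoverStructures(adj, map, NP = NP, seed = seed, kinds = "BPM")
  res$p_perm[1]
}

#' Smallest detectable block density at a permutation threshold
#'
#' Finds, by expanding search plus bisection over the embedded edge count,
#' the smallest between-pathway block density whose SNP-permutation
#' p-value on a simulated background network reaches \code{pThreshold}
#' (both chi-square statistics jointly, \code{NP} membership
#' permutations).
#'
#' @param sizeA,sizeB block side sizes.
#' @param nSnps,backgroundDensity background network geometry.
#' @param NP SNP permutations; \code{ceiling(1/pThreshold)} or more is
#'   needed for the threshold to be reachable.
#' @param pThreshold target permutation p-value (default 3e-5).
#' @param seed integer seed.
#' @return list: \code{density} (the required block density),
#'   \code{edges}, \code{possible}, \code{pPerm}.
#' @export
requiredBlockDensity <- function(sizeA, sizeB, nSnps = 2000L,
                                 backgroundDensity = 0.01, NP = 33334L,
                                 pThreshold = 3.0e-5, seed = 1L) {
  if ((1 / NP) > pThreshold)
    stop("NP too small to resolve pThreshold")
  possible <- sizeA * sizeB
  evalEdges <- function(e, k) {
    d <- min(1, e / possible)
    sim <- simulateNetwork(nSnps, backgroundDensity,
                           blocks = list(list(sizeA = sizeA, sizeB = sizeB,
                                              density = d)),
                           seed = deriveSeed(seed, k))
    blockPermP(sim$adj, sim$blocks[[1]]$setA, sim$blocks[[1]]$setB,
               NP = NP, seed = deriveSeed(seed, 1000 + k))
  }
  e0 <- ceiling(backgroundDensity * possible)
  step <- max(2L, ceiling(4 * sqrt(possible * backgroundDensity)))
  lo <- e0; hi <- e0 + step; k <- 0L
  repeat {
    k <- k + 1L
    pHi <- evalEdges(hi, k)
    if (pHi <= pThreshold || hi >= possible) break
    lo <- hi
    hi <- min(possible, hi + step)
    step <- step * 2L
  }
  if (pHi > pThreshold)
    stop("block cannot reach the permutation threshold even when complete")
  pAt <- pHi
  while (hi - lo > 1L) {
    k <- k + 1L
    mid <- (lo + hi) %/% 2L
    pMid <- evalEdges(mid, k)
    if (pMid <= pThreshold) { hi <- mid; pAt <- pMid } else lo <- mid
  }
  list(density = hi / possible, edges = hi, possible = possible,
       pPerm = pAt)
}

## ---------------------------------------------------------------------------
## Two-stage power analysis

#' Two-stage power analysis: minimum cohort size per scenario
#'
#' Stage 1 simulates cohorts with embedded interacting SNP pairs at each
#' grid sample size and measures the sensitivity of pairwise interaction
#' detection at the given network density. Stage 2 determines, for each
#' block size, the smallest embedded between-pathway density whose
#' SNP-permutation p-value on a simulated background network reaches
#' \code{pThreshold}. A scenario's minimum cohort size is the smallest
#' grid size whose sensitivity, scaled by the assumed biological
#' interaction density \code{s}, covers the required block density:
#' \code{sensitivity x s >= requiredDensity}. Sensitivities are computed
#' lazily (ascending sample size) and cached across block sizes.
#'
#' @param mafs embedded-pair minor allele frequencies to evaluate.
#' @param relativeRisk shared double-carrier relative risk.
#' @param sizes block side sizes (one square block per entry).
#' @param s scaling parameter: assumed fraction of functionally
#'   interacting SNP pairs across two truly interacting pathways
#'   (default 0.05).
#' @param pThreshold permutation significance threshold (default 3e-5).
#' @param sampleGrid candidate cohort sizes (cases + controls).
#' @param nBackgroundSnps,nEmbeddedPairs stage-1 cohort geometry.
#' @param netSnps,netDensity stage-2 network geometry.
#' @param NP stage-2 SNP permutations (default 33334, resolving 3e-5).
#' @param diseaseModel penetrance model for the cohort simulation.
#' @param networkModel disease model for the stage-1 interaction network.
#' @param seed master seed.
#' @return data.frame with one row per (maf, size): \code{requiredDensity},
#'   \code{minN} (NA when no grid size suffices), \code{sensAtMinN}; the
#'   stage-1 sensitivity table is attached as attribute
#'   \code{"sensitivities"}.
#' @export
powerCurve <- function(mafs, relativeRisk = 2, sizes = c(25L, 300L),
                       s = 0.05, pThreshold = 3.0e-5,
                       sampleGrid = c(200L, 500L, 1000L, 2000L, 5000L,
                                      10000L),
                       nBackgroundSnps = 2000L, nEmbeddedPairs = 100L,
                       netSnps = 2000L, netDensity = 0.01, NP = 33334L,
                       diseaseModel = "dominant", networkModel = "DD",
                       seed = 1L) {
  stage2 <- lapply(seq_along(sizes), function(i)
    requiredBlockDensity(sizes[i], sizes[i], nSnps = netSnps,
                         backgroundDensity = netDensity, NP = NP,
                         pThreshold = pThreshold,
                         seed = deriveSeed(seed, 7000 + i)))
  reqDens <- vapply(stage2, `[[`, 0, "density")
  sensTab <- data.frame(maf = numeric(), n = integer(),
                        sensitivity = numeric())
  out <- data.frame()
  for (mi in seq_along(mafs)) {
    maf <- mafs[mi]
    sens <- rep(NA_real_, length(sampleGrid))
    minN <- rep(NA_integer_, length(sizes))
    sensAt <- rep(NA_real_, length(sizes))
    for (ni in seq_along(sampleGrid)) {
      if (all(!is.na(minN))) break
      n <- sampleGrid[ni]
      spec <- simulationSpec(
        nCases = n %/% 2L, nControls = n - n %/% 2L,
        nBackgroundSnps = nBackgroundSnps, maf = maf,
        nEmbeddedPairs = nEmbeddedPairs, relativeRisk = relativeRisk,
        diseaseModel = diseaseModel,
        seed = deriveSeed(seed, 100 * mi + ni))
      cohort <- simulateCohort(spec)
      sens[ni] <- measurePairSensitivity(cohort, density = netDensity,
                                         model = networkModel,
                                         seed = deriveSeed(seed, ni))
      sensTab <- rbind(sensTab, data.frame(maf = maf, n = n,
                                           sensitivity = sens[ni]))
      hit <- is.na(minN) & (sens[ni] * s >= reqDens)
      minN[hit] <- n
      sensAt[hit] <- sens[ni]
    }
    out <- rbind(out, data.frame(maf = maf, size = sizes,
                                 requiredDensity = reqDens, minN = minN,
                                 sensAtMinN = sensAt))
  }
  attr(out, "sensitivities") <- sensTab
  attr(out, "stage2") <- stage2
  out
}
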