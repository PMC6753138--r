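#' Validate discovered structures in an independent cohort
#'
#' Recomputes, for each discovered structure, the global and local
#' chi-square statistics (converted to one-sided 1-df chi-square p-values)
#' and the SNP-permutation p-value on the validation network, which must
#' share the discovery run's SNP universe, disease model and density. A
#' structure replicates when all three p-values are at most
#' \code{threshold}. Structures whose pathway SNPs are absent from the
#' validation universe are marked untestable.
#'
#' @param results data.frame of discovered structures (BPM/WPM rows).
#' @param valAdj binarized validation adjacency (one channel).
#' @param map the shared \linkS4class{SnpPathwayMap}.
#' @param NP SNP permutations for the validation p_perm.
#' @param threshold significance level per criterion (default 0.05).
#' @param seed integer seed.
#' @return \code{results} with columns \code{val_p_global},
#'   \code{val_p_local}, \code{val_p_perm}, \code{testable}, \code{pass}.
#' @export
validateStructure <- function(results, valAdj, map, NP = 1000L,
                              threshold = 0.05, seed = 1L) {
  kinds <- unique(results$kind)
  stopifnot(all(kinds %in% c("BPM", "WPM")))
  val <- discoverStructures(valAdj, map, NP = NP, seed = seed,
                            kinds = kinds)
  key <- function(d) paste(d$kind, d$pathway_a, d$pathway_b)
  idx <- match(key(results), key(val))
  testable <- !is.na(idx)
  pg <- pl <- pp <- rep(NA_real_, nrow(results))
  pg[testable] <- stats::pchisq(val$chi2_global[idx[testable]], df = 1,
                                lower.tail = FALSE)
  pl[testable] <- stats::pchisq(val$chi2_local[idx[testable]], df = 1,
                                lower.tail = FALSE)
  pp[testable] <- val$p_perm[idx[testable]]
  results$val_p_global <- pg
  results$val_p_local <- pl
  results$val_p_perm <- pp
  results$testable <- testable
  results$pass <- testable & pg <= threshold & pl <= threshold &
    pp <= threshold
  results
}

#' Fold enrichment of replication over sample-permuted expectation
#'
#' Ratio of the number of discovered structures passing the validation
#' criteria in the real validation cohort to the average number passing in
#' sample-label-permuted validation cohorts. Significance is assessed by
#' bootstrap: structure sets of the same size are resampled from the
#' candidate pool and their folds form the null distribution.
#'
#' @param passReal logical vector: validation pass/fail of the discovered
#'   set (untestable structures excluded beforehand).
#' @param nullPass logical matrix (NPs runs x discovered structures):
#'   pass/fail of the same structures in each permuted validation cohort.
#' @param poolPass,poolNullPass same two objects for the full candidate
#'   pool the bootstrap resamples from (defaults: the discovered set).
#' @param nBoot bootstrap replicates (default 10000).
#' @param seed integer seed.
#' @return list: \code{fold}, \code{pBoot}, \code{nPass},
#'   \code{nullMean}, and \code{degenerate} (TRUE when the permuted
#'   expectation was zero and the fold was reported against 1/NPs).
#' @export
foldEnrichment <- function(passReal, nullPass, poolPass = passReal,
                           poolNullPass = nullPass, nBoot = 10000L,
                           seed = 1L) {
  stopifnot(length(passReal) >= 1)
  nullPass <- as.matrix(nullPass)
  NPs <- nrow(nullPass)
  num <- sum(passReal)
  den <- mean(rowSums(nullPass))
  degenerate <- FALSE
  fold <- if (den > 0) num / den
    else if (num == 0) 0
    else { degenerate <- TRUE; num / (1 / NPs) }
  k <- length(passReal)
  poolNullPass <- as.matrix(poolNullPass)
  boots <- withSeed(seed, vapply(seq_len(nBoot), function(b) {
    idx <- sample.int(length(poolPass), k, replace = TRUE)
    nb <- sum(poolPass[idx])
    db <- mean(rowSums(poolNullPass[, idx, drop = FALSE]))
    if (db > 0) nb / db else if (nb == 0) 0 else nb * NPs
  }, 0))
  pBoot <- (sum(boots >= fold) + 1) / (nBoot + 1)
  list(fold = fold, pBoot = pBoot, nPass = num, nullMean = den,
       degenerate = degenerate)
}

#' Hypergeometric overlap of supporting SNP pairs across cohorts
#'
#' Within one structure's possible SNP pairs, tests whether the supporting
#' edges found in the discovery network and those found in the validation
#' network overlap more than expected: upper-tail hypergeometric with the
#' block's possible pairs as population, discovery edges as successes and
#' validation edges as draws. Also returns the overlap coefficient
#' (intersection over the smaller edge set).
#'
#' @param adjDiscovery,adjValidation binarized adjacencies on the same SNP
#'   universe.
#' @param setA,setB SNP index sets of the structure (\code{setB = NULL}
#'   for a WPM).
#' @return list: \code{p}, \code{coefficient}, \code{nDiscovery},
#'   \code{nValidation}, \code{nShared}, \code{possible}.
#' @export
snpPairOverlapTest <- function(adjDiscovery, adjValidation, setA,
                               setB = NULL) {
  kd <- supportingPairKeys(adjDiscovery, setA, setB)
  kv <- supportingPairKeys(adjValidation, setA, setB)
  possible <- if (is.null(setB)) length(setA) * (length(setA) - 1) / 2
    else length(setA) * length(setB)
  nd <- length(kd); nv <- length(kv)
  shared <- length(intersect(kd, kv))
  if (nd == 0 || nv == 0)
    return(list(p = 1, coefficient = 0, nDiscovery = nd, nValidation = nv,
                nShared = 0, possible = possible))
  p <- hygePvalue(possible, nd, nv, shared)
  list(p = p, coefficient = shared / min(nd, nv), nDiscovery = nd,
       nValidation = nv, nShared = shared, possible = possible)
}

#' Full replication analysis of discovered structures
#'
#' Builds the validation network at the discovery model/density, validates
#' every discovered structure, estimates the fold enrichment over
#' \code{NPs} sample-permuted validation cohorts with bootstrap
#' significance, and compares supporting SNP-pair overlap of replicated
#' structures against the permuted cohorts by a one-tailed rank-sum test.
#'
#' @param results discovered structures (one kind, one channel; rows to
#'   validate).
#' @param dsValidation validation cohort (same SNP universe as discovery).
#' @param map the shared \linkS4class{SnpPathwayMap}.
#' @param model,density,channel,alpha,prefilter discovery settings reused.
#' @param adjDiscovery the discovery adjacency (for the overlap test).
#' @param NPs sample permutations of the validation cohort (default 10).
#' @param NP SNP permutations per validation run.
#' @param nBoot bootstrap replicates for the fold p-value.
#' @param seed master seed.
#' @return list: \code{validated} (results + validation columns +
#'   per-structure overlap test), \code{fold} (from [foldEnrichment()]),
#'   \code{overlapRankSumP}.
#' @export
replicateStructures <- function(results, dsValidation, map, model, density,
                                channel = "risk", adjDiscovery = NULL,
                                alpha = 0.05, prefilter = 0.2, NPs = 10L,
                                NP = 1000L, nBoot = 10000L, seed = 1L) {
  net <- buildNetwork(dsValidation, model = model, alpha = alpha,
                      prefilter = prefilter)
  net <- binarizeNetwork(net, density, seed = seed)
  valAdj <- adjacency(net, channel)
  validated <- validateStructure(results, valAdj, map, NP = NP,
                                 seed = deriveSeed(seed, 1))
  ## permuted validation cohorts
  nullPass <- matrix(FALSE, NPs, nrow(results))
  nullCoef <- matrix(NA_real_, NPs, nrow(results))
  sets <- pathwaySnps(map); nm <- pathwayNames(map)
  structSets <- lapply(seq_len(nrow(results)), function(i) {
    a <- sets[[match(results$pathway_a[i], nm)]]
    if (results$kind[i] == "BPM") {
      b <- sets[[match(results$pathway_b[i], nm)]]
      list(a = setdiff(a, b), b = setdiff(b, a))
    } else list(a = sets[[match(results$pathway_a[i], nm)]], b = NULL)
  })
  for (k in seq_len(NPs)) {
    sk <- deriveSeed(seed, 100 + k)
    dsk <- shuffleLabels(dsValidation, seed = sk)
    nk <- buildNetwork(dsk, model = model, alpha = alpha,
                       prefilter = prefilter)
    nk <- binarizeNetwork(nk, density, seed = sk)
    ak <- adjacency(nk, channel)
    vk <- validateStructure(results, ak, map, NP = NP,
                            seed = deriveSeed(sk, 1))
    nullPass[k, ] <- vk$pass
    if (!is.null(adjDiscovery))
      nullCoef[k, ] <- vapply(structSets, function(s)
        snpPairOverlapTest(adjDiscovery, ak, s$a, s$b)$coefficient, 0)
  }
  testable <- validated$testable
  fold <- foldEnrichment(validated$pass[testable],
                         nullPass[, testable, drop = FALSE],
                         nBoot = nBoot, seed = deriveSeed(seed, 2))
  overlapRankSumP <- NA_real_
  if (!is.null(adjDiscovery)) {
    ov <- lapply(structSets, function(s)
      snpPairOverlapTest(adjDiscovery, valAdj, s$a, s$b))
    validated$overlap_p <- vapply(ov, `[[`, 0, "p")
    validated$overlap_coefficient <- vapply(ov, `[[`, 0, "coefficient")
    reps <- which(validated$pass)
    if (length(reps))
      overlapRankSumP <- rankSumTest(
        validated$overlap_coefficient[reps],
        as.vector(nullCoef[, reps, drop = FALSE]))$p
  }
  list(validated = validated, fold = fold,
       overlapRankSumP = overlapRankSumP)
}
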