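#' SNP-SNP interaction density between two pathways
#'
#' Counts binarized interactions across \code{setA x setB} after removing
#' the SNPs shared by the two sets (a between-pathway structure is only
#' evaluated on the disjoint remainders, so self-interactions of the
#' overlap never inflate it).
#'
#' @param adj symmetric sparse adjacency matrix.
#' @param setA,setB integer SNP index vectors.
#' @return list with \code{edges}, \code{possible} (\code{|A| * |B|}) and
#'   \code{density}; \code{NULL} if either set is empty after overlap
#'   removal (the structure is skipped upstream).
#' @export
bpmDensity <- function(adj, setA, setB) {
  shared <- intersect(setA, setB)
  a <- setdiff(setA, shared); b <- setdiff(setB, shared)
  if (!length(a) || !length(b)) return(NULL)
  edges <- sum(adj[a, b, drop = FALSE])
  possible <- length(a) * length(b)
  list(edges = edges, possible = possible, density = edges / possible)
}

#' Chi-square enrichment of a block against the global network density
#'
#' One-sided 1-df Pearson chi-square of the 2x2 table contrasting edge
#' counts inside the block against the rest of the network. Blocks at or
#' below the expected density score 0 (enrichment only). When
#' \code{totalPairs} is not supplied, the binomial goodness-of-fit form
#' against \code{possible * globalDensity} is used instead of the 2x2
#' table.
#'
#' @param edges observed edge count(s) in the block.
#' @param possible number of SNP pairs in the block.
#' @param globalDensity overall network density (0 < d < 1).
#' @param totalPairs total number of SNP pairs in the network.
#' @return chi-square statistic(s) >= 0. Vectorized over
#'   \code{edges}/\code{possible}.
#' @export
chi2Global <- function(edges, possible, globalDensity, totalPairs = NULL) {
  ## degenerate networks: nothing can be enriched against an empty or
  ## complete network unless edges appear where none are expected
  if (globalDensity <= 0)
    return(ifelse(edges > 0, Inf, 0) * (edges * 0 + 1))
  if (globalDensity >= 1)
    return(edges * 0)
  if (is.null(totalPairs)) {
    stat <- chi2Gof(edges, possible, globalDensity)
  } else {
    totalEdges <- globalDensity * totalPairs
    a <- edges; b <- possible - edges
    c <- totalEdges - edges; d <- (totalPairs - possible) - c
    num <- (totalPairs) * (a * d - b * c)^2
    den <- (a + b) * (c + d) * (a + c) * (b + d)
    stat <- ifelse(den > 0, num / den, 0)
    stat[edges / possible <= globalDensity] <- 0
  }
  stat
}

## 1-df goodness-of-fit chi-square of an edge count vs expected density,
## one-sided (0 unless enriched); expected density 0 gives 0 for an empty
## block and +Inf otherwise.
chi2Gof <- function(edges, possible, expDensity) {
  z <- edges * 0                     # broadcast template (edges' shape)
  exp1 <- possible * expDensity + z
  exp0 <- possible - possible * expDensity + z
  stat <- (edges - exp1)^2 / pmax(exp1, .Machine$double.xmin) +
    (edges - exp1)^2 / pmax(exp0, .Machine$double.xmin)
  zeroExp <- exp1 <= 0
  stat[zeroExp] <- ifelse(edges[zeroExp] > 0, Inf, 0)
  stat[exp0 <= 0 & !zeroExp] <- 0    # expected density >= 1: no enrichment
  stat[edges <= exp1] <- 0
  stat
}

#' Chi-square enrichment of a block against the pathways' marginal density
#'
#' The expected local density is the larger of the two pathways' marginal
#' densities (a pathway's marginal density is its interaction density with
#' all other SNPs in the network); the statistic is the one-sided 1-df
#' goodness-of-fit chi-square of the observed edge count against
#' \code{possible * max(marginalA, marginalB)}.
#'
#' @param edges,possible as in [chi2Global()].
#' @param marginalA,marginalB marginal densities in [0, 1).
#' @return chi-square statistic(s) >= 0 (\code{Inf} if the expected density
#'   is zero but edges were observed).
#' @export
chi2Local <- function(edges, possible, marginalA, marginalB = marginalA) {
  expDens <- pmax(marginalA, marginalB)
  chi2Gof(edges, possible, expDens)
}

#' One-tailed rank-sum test (pathway degrees greater)
#'
#' Wilcoxon rank-sum comparing \code{x} against \code{y}, alternative
#' "x stochastically greater". Exact when there are no ties and both sizes
#' are at most \code{exactLimit}; otherwise the normal approximation with
#' tie correction and continuity correction is used.
#'
#' @param x,y numeric vectors (both non-empty).
#' @param exactLimit maximal group size for the exact distribution.
#' @return list with \code{W} (sum of ranks of \code{x} minus its minimum,
#'   i.e. the Mann-Whitney U), \code{p}, and \code{negLog10P}.
#' @export
rankSumTest <- function(x, y, exactLimit = 100L) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx > 0, ny > 0)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)])
  U <- W - nx * (nx + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (!ties && nx <= exactLimit && ny <= exactLimit) {
    ## exact upper tail: P(U >= u) = P(U <= nx*ny - u) by symmetry
    p <- stats::pwilcox(nx * ny - U, nx, ny)
  } else {
    p <- rankSumPNormal(W, nx, ny, r)
  }
  p <- min(max(p, .Machine$double.xmin), 1)
  list(W = W, p = p, negLog10P = -log10(p))
}

## Normal approximation (tie-corrected, continuity-corrected) for the
## one-tailed rank-sum p given the rank vector of the pooled sample.
rankSumPNormal <- function(W, nx, ny, r) {
  n <- nx + ny
  mu <- nx * (n + 1) / 2
  tieTab <- table(r)
  tieAdj <- sum(tieTab^3 - tieTab)
  sigma2 <- nx * ny / 12 * ((n + 1) - tieAdj / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  stats::pnorm((W - mu - 0.5) / sqrt(sigma2), lower.tail = FALSE)
}

#' Empirical permutation p-value with pseudocount
#'
#' \code{p = (# permutations whose null statistics jointly reach the
#' observed ones + 1) / NP}, capped at 1. For chi-square structures both
#' the global and local statistics must be reached jointly; for PATH
#' structures the single rank-sum statistic is used.
#'
#' @param obsG,obsL observed statistics (vectors over structures;
#'   \code{obsL = NULL} for a single-statistic comparison).
#' @param nullG,nullL permutation null matrices (NP x structures).
#' @return p-values in (0, 1].
#' @examples
#' permPValue(5, NULL, matrix(c(rep(10, 0), rep(0, 150000))))  # 6.7e-6
#' @export
permPValue <- function(obsG, obsL, nullG, nullL = NULL) {
  nullG <- as.matrix(nullG)
  NP <- nrow(nullG)
  S <- length(obsG)
  exceed <- nullG >= matrix(obsG, NP, S, byrow = TRUE)
  if (!is.null(obsL)) {
    nullL <- as.matrix(nullL)
    exceed <- exceed & (nullL >= matrix(obsL, NP, S, byrow = TRUE))
  }
  pmin(1, (colSums(exceed) + 1) / NP)
}

## ---------------------------------------------------------------------------
## Structure enumeration and observed scoring

## Internal: the fixed list of structures evaluated on a map.
## BPMs on disjoint remainders; structures whose remainders are empty or
## singleton sets are skipped (logged via attribute).
enumerateStructures <- function(map, kinds = c("BPM", "WPM", "PATH")) {
  sets <- pathwaySnps(map)
  nm <- pathwayNames(map)
  P <- length(sets)
  out <- list()
  skipped <- character()
  if ("BPM" %in% kinds && P >= 2) {
    for (p in seq_len(P - 1)) for (q in (p + 1):P) {
      a <- setdiff(sets[[p]], sets[[q]])
      b <- setdiff(sets[[q]], sets[[p]])
      if (!length(a) || !length(b)) {
        skipped <- c(skipped, paste0(nm[p], "<->", nm[q]))
        next
      }
      out[[length(out) + 1L]] <- list(kind = "BPM", a = a, b = b,
                                      pa = nm[p], pb = nm[q])
    }
  }
  if ("WPM" %in% kinds) for (p in seq_len(P)) {
    if (length(sets[[p]]) >= 2)
      out[[length(out) + 1L]] <- list(kind = "WPM", a = sets[[p]], b = NULL,
                                      pa = nm[p], pb = "")
  }
  if ("PATH" %in% kinds) for (p in seq_len(P))
    out[[length(out) + 1L]] <- list(kind = "PATH", a = sets[[p]], b = NULL,
                                    pa = nm[p], pb = "")
  attr(out, "skipped") <- skipped
  out
}

## Internal: statistics of every structure on one adjacency matrix.
## Returns a data.frame in the fixed enumeration order.
structureStats <- function(adj, structures, deg = NULL, ranks = NULL) {
  n <- nrow(adj)
  totalPairs <- n * (n - 1) / 2
  if (is.null(deg)) deg <- Matrix::rowSums(adj)
  totalEdges <- sum(deg) / 2
  globalDensity <- totalEdges / totalPairs
  if (is.null(ranks)) ranks <- rank(deg)
  rows <- lapply(structures, function(s) {
    if (s$kind == "BPM") {
      a <- s$a; b <- s$b
      e <- sum(adj[a, b, drop = FALSE])
      possible <- length(a) * length(b)
      wA <- sum(adj[a, a, drop = FALSE]) / 2
      wB <- sum(adj[b, b, drop = FALSE]) / 2
      mA <- (sum(deg[a]) - 2 * wA) / (length(a) * (n - length(a)))
      mB <- (sum(deg[b]) - 2 * wB) / (length(b) * (n - length(b)))
      c2g <- chi2Global(e, possible, globalDensity, totalPairs)
      c2l <- chi2Local(e, possible, mA, mB)
      data.frame(kind = "BPM", pathway_a = s$pa, pathway_b = s$pb,
                 n_supporting_edges = e, possible = possible,
                 observed_density = e / possible,
                 expected_global = globalDensity,
                 expected_local = max(mA, mB),
                 chi2_global = c2g, chi2_local = c2l,
                 u_stat = NA_real_, u_path_neglog_p = NA_real_)
    } else if (s$kind == "WPM") {
      a <- s$a
      e <- sum(adj[a, a, drop = FALSE]) / 2
      possible <- length(a) * (length(a) - 1) / 2
      mA <- (sum(deg[a]) - 2 * e) / (length(a) * (n - length(a)))
      c2g <- chi2Global(e, possible, globalDensity, totalPairs)
      c2l <- chi2Local(e, possible, mA)
      data.frame(kind = "WPM", pathway_a = s$pa, pathway_b = "",
                 n_supporting_edges = e, possible = possible,
                 observed_density = e / possible,
                 expected_global = globalDensity, expected_local = mA,
                 chi2_global = c2g, chi2_local = c2l,
                 u_stat = NA_real_, u_path_neglog_p = NA_real_)
    } else {
      a <- s$a
      W <- sum(ranks[a])
      rt <- if (length(unique(deg)) == 1L)
        list(W = W, p = 1, negLog10P = 0)
      else rankSumTest(deg[a], deg[-a])
      data.frame(kind = "PATH", pathway_a = s$pa, pathway_b = "",
                 n_supporting_edges = sum(deg[a]), possible = NA_real_,
                 observed_density = NA_real_,
                 expected_global = globalDensity,
                 expected_local = NA_real_,
                 chi2_global = NA_real_, chi2_local = NA_real_,
                 u_stat = W, u_path_neglog_p = rt$negLog10P)
    }
  })
  do.call(rbind, rows)
}

#' Score BPM, WPM and PATH structures on a binarized network
#'
#' Computes for every pathway pair (BPM: disjoint remainders after shared
#' SNP removal), pathway (WPM) and pathway hub candidate (PATH) the
#' observed interaction density, the global and local chi-square
#' enrichment statistics (BPM/WPM), and the one-tailed degree rank-sum
#' statistic (PATH), on one adjacency matrix (one channel).
#'
#' @param adj symmetric sparse adjacency (one channel of a binarized
#'   network, see [adjacency()]).
#' @param map a \linkS4class{SnpPathwayMap} on the same SNP universe.
#' @param kinds subset of \code{c("BPM", "WPM", "PATH")}.
#' @return a data.frame, one row per structure.
#' @export
scoreStructures <- function(adj, map, kinds = c("BPM", "WPM", "PATH")) {
  structures <- enumerateStructures(map, kinds)
  if (!length(structures)) stop("no scoreable structure")
  res <- structureStats(adj, structures)
  skipped <- attr(structures, "skipped")
  if (length(skipped))
    attr(res, "skipped") <- skipped
  res
}

## ---------------------------------------------------------------------------
## SNP-pathway membership permutation null

#' SNP-permutation null distributions for pathway structures
#'
#' Each permutation applies one global random relabeling of SNP identities
#' to the pathway map while keeping the network fixed: pathway sizes and
#' overlaps, network topology and degree sequence are all preserved, only
#' membership is shuffled. For every structure the global and local
#' chi-square statistics (BPM/WPM) or the degree rank-sum statistic (PATH)
#' are recomputed. Deterministic given \code{seed}.
#'
#' @param adj symmetric sparse adjacency matrix.
#' @param map a \linkS4class{SnpPathwayMap}.
#' @param NP number of permutations (>= 1).
#' @param seed integer seed.
#' @param kinds structure kinds to evaluate.
#' @param perms optional n x NP integer matrix of explicit permutations
#'   (column k is the relabeling used in iteration k); overrides the RNG.
#' @param chunkSize permutations evaluated per sparse-matrix block.
#' @return list with elements \code{chi2g}, \code{chi2l} (NP x structures
#'   matrices, NA columns for PATH), \code{ustat} (NP x structures, NA for
#'   chi-square structures), \code{structures} (the enumeration), and
#'   \code{NP}, \code{seed}.
#' @export
snpPermutationNull <- function(adj, map, NP, seed = 1L,
                               kinds = c("BPM", "WPM", "PATH"),
                               perms = NULL, chunkSize = NULL) {
  stopifnot(NP >= 1)
  structures <- enumerateStructures(map, kinds)
  S <- length(structures)
  n <- nrow(adj)
  totalPairs <- n * (n - 1) / 2
  deg <- Matrix::rowSums(adj)
  totalEdges <- sum(deg) / 2
  globalDensity <- totalEdges / totalPairs
  ranks <- rank(deg)
  sizesA <- vapply(structures, function(s) length(s$a), 0L)
  isBpm <- vapply(structures, function(s) s$kind == "BPM", TRUE)
  isWpm <- vapply(structures, function(s) s$kind == "WPM", TRUE)
  isPath <- vapply(structures, function(s) s$kind == "PATH", TRUE)
  sizesB <- vapply(structures, function(s)
    if (is.null(s$b)) 0L else length(s$b), 0L)
  ## triplet skeletons: (row = original SNP index, col = structure)
  triA <- cbind(unlist(lapply(structures, `[[`, "a")),
                rep.int(seq_len(S), sizesA))
  triB <- if (any(isBpm))
    cbind(unlist(lapply(structures[isBpm], `[[`, "b")),
          rep.int(which(isBpm), sizesB[isBpm]))
  else cbind(integer(), integer())
  chi2g <- matrix(NA_real_, NP, S)
  chi2l <- matrix(NA_real_, NP, S)
  ustat <- matrix(NA_real_, NP, S)
  if (is.null(chunkSize)) {
    ## cap both the sparse triplet count and the dense workspace
    nnzPerPerm <- nrow(triA) + nrow(triB)
    chunkSize <- max(1L, min(NP, as.integer(2e6 / max(1, nnzPerPerm)),
                             as.integer(4e6 / max(1, n * S))))
  }
  colSumAt <- function(dense, rows, cols) {
    ## sum dense[rows, cols] entries grouped by column, over all S*B columns
    v <- rowsum(dense[cbind(rows, cols)], cols)
    out <- numeric(ncol(dense))
    out[as.integer(rownames(v))] <- v
    out
  }
  withSeed(seed, {
    done <- 0L
    while (done < NP) {
      B <- min(chunkSize, NP - done)
      pm <- if (is.null(perms)) {
        vapply(seq_len(B), function(k) sample.int(n), integer(n))
      } else {
        perms[, done + seq_len(B), drop = FALSE]
      }
      iA <- as.vector(pm[triA[, 1], ])
      jA <- rep.int(triA[, 2], B) + rep((seq_len(B) - 1L) * S,
                                        each = nrow(triA))
      bigU <- Matrix::sparseMatrix(i = iA, j = jA, x = 1,
                                   dims = c(n, S * B))
      TU <- as.matrix(adj %*% bigU)
      withinA <- colSumAt(TU, iA, jA) / 2
      degSumA <- as.vector(Matrix::crossprod(bigU, deg))
      if (nrow(triB)) {
        iB <- as.vector(pm[triB[, 1], ])
        jB <- rep.int(triB[, 2], B) + rep((seq_len(B) - 1L) * S,
                                          each = nrow(triB))
        bigV <- Matrix::sparseMatrix(i = iB, j = jB, x = 1,
                                     dims = c(n, S * B))
        edgesAB <- colSumAt(TU, iB, jB)
        TV <- as.matrix(adj %*% bigV)
        withinB <- colSumAt(TV, iB, jB) / 2
        degSumB <- as.vector(Matrix::crossprod(bigV, deg))
      }
      uW <- as.vector(Matrix::crossprod(bigU, ranks))
      ## reshape the per-(structure, permutation) vectors to S x B and
      ## compute all statistics of the chunk at once
      rows <- done + seq_len(B)
      mWithinA <- matrix(withinA, S, B)
      mDegA <- matrix(degSumA, S, B)
      if (any(isBpm)) {
        sb <- which(isBpm)
        aN <- sizesA[sb]; bN <- sizesB[sb]
        e <- matrix(edgesAB, S, B)[sb, , drop = FALSE]
        possible <- aN * bN
        mA <- (mDegA[sb, , drop = FALSE] -
                 2 * mWithinA[sb, , drop = FALSE]) / (aN * (n - aN))
        mWB <- matrix(withinB, S, B)[sb, , drop = FALSE]
        mDB <- matrix(degSumB, S, B)[sb, , drop = FALSE]
        mB <- (mDB - 2 * mWB) / (bN * (n - bN))
        chi2g[rows, sb] <- t(chi2Global(e, possible, globalDensity,
                                        totalPairs))
        chi2l[rows, sb] <- t(chi2Local(e, possible, mA, mB))
      }
      if (any(isWpm)) {
        sw <- which(isWpm)
        aN <- sizesA[sw]
        e <- mWithinA[sw, , drop = FALSE]
        possible <- aN * (aN - 1) / 2
        mA <- (mDegA[sw, , drop = FALSE] - 2 * e) / (aN * (n - aN))
        chi2g[rows, sw] <- t(chi2Global(e, possible, globalDensity,
                                        totalPairs))
        chi2l[rows, sw] <- t(chi2Local(e, possible, mA))
      }
      if (any(isPath)) {
        sp <- which(isPath)
        ustat[rows, sp] <- t(matrix(uW, S, B)[sp, , drop = FALSE])
      }
      done <- done + B
    }
  })
  list(chi2g = chi2g, chi2l = chi2l, ustat = ustat,
       structures = structures, NP = NP, seed = seed)
}

#' Score structures and attach SNP-permutation p-values
#'
#' Convenience wrapper: [scoreStructures()] plus [snpPermutationNull()]
#' plus [permPValue()]. For BPM/WPM structures the permutation p-value
#' requires the null to reach both chi-square statistics jointly; for PATH
#' structures the null must reach the observed degree rank-sum.
#'
#' @inheritParams snpPermutationNull
#' @return data.frame of structures with a \code{p_perm} column; the null
#'   is attached as attribute \code{"null"} for FDR reuse.
#' @export
discoverStructures <- function(adj, map, NP, seed = 1L,
                               kinds = c("BPM", "WPM", "PATH"),
                               chunkSize = NULL) {
  res <- scoreStructures(adj, map, kinds)
  null <- snpPermutationNull(adj, map, NP, seed = seed, kinds = kinds,
                             chunkSize = chunkSize)
  p <- rep(NA_real_, nrow(res))
  cs <- res$kind %in% c("BPM", "WPM")
  if (any(cs))
    p[cs] <- permPValue(res$chi2_global[cs], res$chi2_local[cs],
                        null$chi2g[, cs, drop = FALSE],
                        null$chi2l[, cs, drop = FALSE])
  if (any(!cs))
    p[!cs] <- permPValue(res$u_stat[!cs], NULL,
                         null$ustat[, !cs, drop = FALSE])
  res$p_perm <- p
  attr(res, "null") <- null
  res
}

## ---------------------------------------------------------------------------
## Univariate (single-locus) pathway enrichment

#' Pathway enrichment of single-locus disease associations
#'
#' Scores every SNP by the upper-tail hypergeometric association of its
#' carrier pattern with the class (risk: cases; protective: controls) under
#' a recessive, dominant, or combined (per-SNP best of the two) coding, and
#' tests each pathway for enrichment of high-scoring SNPs with a one-tailed
#' rank-sum test against all SNPs. FDR is estimated from sample-label
#' permutations using the permutation FDR machinery.
#'
#' @param ds a QC'd \linkS4class{GenotypeData}.
#' @param map a \linkS4class{SnpPathwayMap}.
#' @param model \code{"combined"}, \code{"dominant"} or \code{"recessive"}.
#' @param nPerm number of sample permutations for the FDR (default 1000).
#' @param seed integer seed.
#' @return data.frame with one row per (pathway, channel): rank-sum p,
#'   \code{fdr}.
#' @export
univariatePathwayEnrichment <- function(ds, map,
                                        model = c("combined", "dominant",
                                                  "recessive"),
                                        nPerm = 1000L, seed = 1L) {
  model <- match.arg(model)
  g <- genotypes(ds)
  isCase <- phenotype(ds) == "case"
  codings <- switch(model,
    dominant = list(codeGenotypes(g, "dominant")),
    recessive = list(codeGenotypes(g, "recessive")),
    combined = list(codeGenotypes(g, "recessive"),
                    codeGenotypes(g, "dominant")))
  snpScore <- function(labels) {
    out <- list(risk = rep(0, ncol(g)), protective = rep(0, ncol(g)))
    N <- sum(labels)
    M <- nrow(g)
    for (X in codings) {
      K <- colSums(X, na.rm = TRUE)
      Xc <- colSums(X * labels, na.rm = TRUE)
      pr <- -log10(hygePvalue(M, N, K, Xc))
      pp <- -log10(hygePvalue(M, M - N, K, K - Xc))
      out$risk <- pmax(out$risk, pr)
      out$protective <- pmax(out$protective, pp)
    }
    out
  }
  obs <- snpScore(isCase)
  sets <- pathwaySnps(map)
  testOne <- function(scores) vapply(sets, function(s)
    rankSumTest(scores[s], scores[-s])$p, 0)
  obsP <- list(risk = testOne(obs$risk), protective = testOne(obs$protective))
  nullP <- withSeed(seed, {
    lapply(seq_len(nPerm), function(k) {
      lab <- sample(isCase)
      sc <- snpScore(lab)
      list(risk = testOne(sc$risk), protective = testOne(sc$protective))
    })
  })
  out <- do.call(rbind, lapply(c("risk", "protective"), function(ch) {
    po <- obsP[[ch]]
    nullMat <- vapply(nullP, `[[`, po, ch)   # pathways x nPerm
    fdr <- vapply(seq_along(po), function(i) {
      better <- sum(nullMat < po[i]) / nPerm
      atLeast <- sum(po <= po[i])
      min(1, better / atLeast)
    }, 0)
    ord <- order(po)
    fdr[ord] <- cummax(fdr[ord])
    data.frame(pathway = pathwayNames(map), channel = ch,
               p_ranksum = po, fdr = fdr, row.names = NULL)
  }))
  out
}
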