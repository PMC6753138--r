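#' Pair-preserving shuffle of case/control labels
#'
#' When matched pairs are annotated, each pair swaps its case/control
#' labels with probability 1/2, preserving the matched population
#' structure; otherwise labels are permuted freely.
#'
#' @param ds a \linkS4class{GenotypeData}.
#' @param seed integer seed.
#' @return \code{ds} with shuffled phenotype.
#' @export
shuffleLabels <- function(ds, seed = 1L) {
  ph <- phenotype(ds)
  pid <- pairId(ds)
  newPh <- withSeed(seed, {
    if (!any(is.na(pid)) && length(unique(pid)) < length(pid)) {
      out <- ph
      for (p in unique(pid)) {
        idx <- which(pid == p)
        if (stats::runif(1) < 0.5) out[idx] <- rev(out[idx])
      }
      out
    } else sample(ph)
  })
  colData(ds)$phenotype <- newPh
  ds
}

#' Sample-permutation null runs for the hybrid FDR
#'
#' Reruns the complete discovery pipeline (network construction,
#' binarization at the same target density, structure scoring and
#' SNP-permutation p-values) on case/control labels shuffled while
#' preserving matched pairs. The pooled null structure statistics feed
#' [estimateFdr()].
#'
#' @param ds a QC'd \linkS4class{GenotypeData}.
#' @param map a \linkS4class{SnpPathwayMap}.
#' @param model disease model for [buildNetwork()].
#' @param density binarization density (must equal the real run's).
#' @param NPs number of sample permutations (default 10).
#' @param NP number of SNP permutations per run (must equal the real
#'   run's).
#' @param channel \code{"risk"} or \code{"protective"}.
#' @param kinds structure kinds.
#' @param alpha,prefilter scoring parameters.
#' @param seed master seed; run k uses a derived seed.
#' @return data.frame of pooled null structures (with \code{run} column),
#'   with attribute \code{NPs}.
#' @export
samplePermutationNull <- function(ds, map, model, density, NPs = 10L,
                                  NP = 1000L,
                                  channel = c("risk", "protective"),
                                  kinds = c("BPM", "WPM", "PATH"),
                                  alpha = 0.05, prefilter = 0.2,
                                  seed = 1L) {
  channel <- match.arg(channel)
  runs <- lapply(seq_len(NPs), function(k) {
    sk <- deriveSeed(seed, k)
    dsk <- shuffleLabels(ds, seed = sk)
    net <- buildNetwork(dsk, model = model, alpha = alpha,
                        prefilter = prefilter)
    net <- binarizeNetwork(net, density = density, seed = sk)
    res <- discoverStructures(adjacency(net, channel), map, NP = NP,
                              seed = deriveSeed(sk, 1), kinds = kinds)
    res$run <- k
    attr(res, "null") <- NULL
    res
  })
  out <- do.call(rbind, runs)
  attr(out, "NPs") <- NPs
  out
}

#' Permutation-based false discovery rate for discovered structures
#'
#' For structure i, \code{FDR(i)} is the average number of null structures
#' (from the sample-permutation runs) strictly better than i on all
#' criteria, divided by the number of real structures at least as good as
#' i on all criteria. For chi-square structures (BPM/WPM) the criteria are
#' (chi2_global, chi2_local, p_perm); for PATH structures
#' (u_path_neglog_p, p_perm). Values are clipped to [0, 1] and monotonized
#' non-decreasing down the significance-ranked list. BPM, WPM and PATH
#' structures are corrected separately, as are channels: pass in one
#' family at a time.
#'
#' @param real data.frame from [discoverStructures()] (one kind, one
#'   channel).
#' @param nullRuns pooled null structures from [samplePermutationNull()],
#'   same kind/channel.
#' @param NPs number of sample-permutation runs behind \code{nullRuns}
#'   (defaults to its \code{NPs} attribute).
#' @return \code{real} with an \code{fdr} column.
#' @export
estimateFdr <- function(real, nullRuns, NPs = attr(nullRuns, "NPs")) {
  if (is.null(NPs)) stop("NPs not supplied")
  stopifnot(length(unique(real$kind)) == 1L)
  usePath <- real$kind[1] == "PATH"
  if (usePath) {
    g <- real$u_path_neglog_p; l <- NULL
    ng <- nullRuns$u_path_neglog_p; nl <- NULL
  } else {
    g <- real$chi2_global; l <- real$chi2_local
    ng <- nullRuns$chi2_global; nl <- nullRuns$chi2_local
  }
  p <- real$p_perm; np <- nullRuns$p_perm
  fdr <- vapply(seq_len(nrow(real)), function(i) {
    better <- ng > g[i] & np < p[i]
    atLeast <- g >= g[i] & p <= p[i]
    if (!usePath) {
      better <- better & nl > l[i]
      atLeast <- atLeast & l >= l[i]
    }
    min(1, (sum(better) / NPs) / sum(atLeast))
  }, 0)
  ord <- order(p, -g, if (usePath) integer(nrow(real)) else -l)
  fdr[ord] <- cummax(fdr[ord])
  real$fdr <- fdr
  real
}

#' Pilot selection of disease model and network density
#'
#' Runs a reduced discovery (fewer SNP permutations, SNP-permutation-based
#' FDR surrogate instead of sample permutations) for every combination of
#' candidate disease model and binarization density, and returns the
#' combination minimizing the estimated FDR of the top-most significant
#' structure. Ties favor the larger density, then the model listed first.
#'
#' @param ds a QC'd \linkS4class{GenotypeData}.
#' @param map a \linkS4class{SnpPathwayMap}.
#' @param models candidate disease models (order = tie-break preference).
#' @param densities candidate densities
#'   (default \code{c(0.005, 0.01, 0.025, 0.05, 0.1)}).
#' @param NPpilot SNP permutations per combination (default 10000).
#' @param channel,kinds,alpha,prefilter,seed as elsewhere.
#' @return list: \code{model}, \code{density}, and a \code{grid}
#'   data.frame of top-structure FDRs per combination.
#' @export
pilotSelect <- function(ds, map, models = c("RR", "DD", "combined", "AA"),
                        densities = c(0.005, 0.01, 0.025, 0.05, 0.1),
                        NPpilot = 10000L, channel = "risk",
                        kinds = "BPM", alpha = 0.05, prefilter = 0.2,
                        seed = 1L) {
  stopifnot(length(densities) >= 1)
  grid <- expand.grid(model = models, density = densities,
                      stringsAsFactors = FALSE)
  grid$topFdr <- NA_real_
  for (mi in seq_along(models)) {
    net <- buildNetwork(ds, model = models[mi], alpha = alpha,
                        prefilter = prefilter)
    for (di in seq_along(densities)) {
      row <- which(grid$model == models[mi] & grid$density == densities[di])
      bn <- binarizeNetwork(net, densities[di], seed = deriveSeed(seed, row))
      res <- discoverStructures(adjacency(bn, channel), map, NP = NPpilot,
                                seed = deriveSeed(seed, 1000 + row),
                                kinds = kinds)
      null <- attr(res, "null")
      top <- order(res$p_perm, -res$chi2_global)[1]
      ## SNP-permutation FDR surrogate for the top structure: average count
      ## of per-permutation structures beating it on both chi-squares,
      ## over the count of real structures at least as good.
      better <- mean(rowSums(
        null$chi2g > res$chi2_global[top] &
        null$chi2l > res$chi2_local[top], na.rm = TRUE))
      atLeast <- sum(res$chi2_global >= res$chi2_global[top] &
                     res$chi2_local >= res$chi2_local[top])
      grid$topFdr[row] <- min(1, better / atLeast)
    }
  }
  modelRank <- match(grid$model, models)
  best <- order(grid$topFdr, -grid$density, modelRank)[1]
  list(model = grid$model[best], density = grid$density[best], grid = grid)
}

## ---------------------------------------------------------------------------
## BPM redundancy

## Internal: canonical keys of the supporting edges of a block (setA x
## setB nonzero entries of adj), as i*n + j with i < j.
supportingPairKeys <- function(adj, setA, setB = NULL) {
  n <- nrow(adj)
  sub <- if (is.null(setB)) adj[setA, setA, drop = FALSE]
    else adj[setA, setB, drop = FALSE]
  sub <- as(sub, "TsparseMatrix")
  if (!length(sub@i)) return(numeric())
  i <- setA[sub@i + 1L]
  j <- if (is.null(setB)) setA[sub@j + 1L] else setB[sub@j + 1L]
  lo <- pmin(i, j); hi <- pmax(i, j)
  unique(as.numeric(lo) * n + hi)
}

#' Overlap coefficient between two structures' supporting SNP pairs
#'
#' Number of supporting SNP pairs shared by the two structures divided by
#' the number of possible SNP pairs in the smaller structure.
#'
#' @param adj the binarized adjacency both structures were scored on.
#' @param setA1,setB1 SNP index sets of the first structure (\code{setB1 =
#'   NULL} for a WPM).
#' @param setA2,setB2 the second structure.
#' @return overlap coefficient in [0, 1].
#' @export
overlapCoefficient <- function(adj, setA1, setB1, setA2, setB2) {
  poss <- function(a, b) if (is.null(b)) length(a) * (length(a) - 1) / 2
    else length(a) * length(b)
  p1 <- poss(setA1, setB1); p2 <- poss(setA2, setB2)
  if (min(p1, p2) == 0) stop("structure with zero possible pairs")
  k1 <- supportingPairKeys(adj, setA1, setB1)
  k2 <- supportingPairKeys(adj, setA2, setB2)
  length(intersect(k1, k2)) / min(p1, p2)
}

#' Collapse redundant structures into connected components
#'
#' Builds a graph over discovered structures with an edge wherever the
#' supporting-pair overlap coefficient exceeds \code{maxOverlap}; the
#' number of unique discoveries is the number of connected components, and
#' each component is represented by its lowest-FDR member (ties:
#' replicated structures first if a \code{replicated} column is present,
#' then lexicographic pathway ids).
#'
#' @param results data.frame of discovered structures (needs
#'   \code{pathway_a}, \code{pathway_b}, \code{fdr}).
#' @param map the \linkS4class{SnpPathwayMap} used for discovery.
#' @param adj the binarized adjacency used for discovery.
#' @param maxOverlap similarity cutoff (default 0.25).
#' @return \code{results} with \code{component} and \code{representative}
#'   columns; the component count as attribute \code{"nComponents"}.
#' @export
collapseRedundant <- function(results, map, adj, maxOverlap = 0.25) {
  sets <- pathwaySnps(map)
  nm <- pathwayNames(map)
  getSets <- function(i) {
    a <- sets[[match(results$pathway_a[i], nm)]]
    if (results$kind[i] == "BPM") {
      b <- sets[[match(results$pathway_b[i], nm)]]
      list(a = setdiff(a, b), b = setdiff(b, a))
    } else list(a = a, b = NULL)
  }
  k <- nrow(results)
  edges <- matrix(integer(), ncol = 2)
  if (k >= 2) {
    pairs <- utils::combn(k, 2)
    hit <- apply(pairs, 2, function(pq) {
      s1 <- getSets(pq[1]); s2 <- getSets(pq[2])
      overlapCoefficient(adj, s1$a, s1$b, s2$a, s2$b) > maxOverlap
    })
    edges <- t(pairs[, hit, drop = FALSE])
  }
  gr <- igraph::graph_from_edgelist(edges, directed = FALSE)
  gr <- igraph::add_vertices(gr, max(0, k - igraph::vcount(gr)))
  comp <- igraph::components(gr)$membership
  results$component <- comp
  rep <- logical(k)
  for (cc in unique(comp)) {
    idx <- which(comp == cc)
    repCol <- if ("replicated" %in% colnames(results))
      !results$replicated[idx] else rep(0L, length(idx))
    ord <- order(results$fdr[idx], repCol,
                 results$pathway_a[idx], results$pathway_b[idx])
    rep[idx[ord[1]]] <- TRUE
  }
  results$representative <- rep
  attr(results, "nComponents") <- max(comp)
  results
}
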