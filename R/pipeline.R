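#' Configuration for an end-to-end discovery run
#'
#' Collects all pipeline parameters plus the master seed; every stochastic
#' step derives its own seed from it, so a run is fully determined by its
#' configuration.
#'
#' @param model disease model (\code{"combined"}, \code{"DD"}, \code{"RR"},
#'   \code{"RD"}, \code{"DR"}, \code{"AA"}).
#' @param density binarization density.
#' @param channels channels analysed (each end-to-end independently).
#' @param kinds structure kinds scored.
#' @param npSnp SNP-pathway membership permutations.
#' @param npSample sample-label permutations for the FDR (default 10).
#' @param alpha,prefilter hygeSSI parameters.
#' @param seed master seed.
#' @return a list with class \code{"RunConfig"}.
#' @export
runConfig <- function(model = "combined", density = 0.05,
                      channels = c("risk", "protective"),
                      kinds = c("BPM", "WPM", "PATH"),
                      npSnp = 10000L, npSample = 10L, alpha = 0.05,
                      prefilter = 0.2, seed = 1L) {
  structure(list(model = model, density = density, channels = channels,
                 kinds = kinds, npSnp = as.integer(npSnp),
                 npSample = as.integer(npSample), alpha = alpha,
                 prefilter = prefilter, seed = as.integer(seed)),
            class = "RunConfig")
}

#' Run the discovery pipeline end to end
#'
#' Executes, on an already QC'd dataset: interaction network construction
#' under the configured disease model; density binarization; BPM/WPM/PATH
#' scoring with SNP-permutation p-values per channel; and the hybrid
#' sample-permutation FDR (each sample permutation reruns the full
#' network + scoring + SNP-permutation pipeline). Deterministic given the
#' configuration.
#'
#' @param ds a QC'd (and ideally matched) \linkS4class{GenotypeData}.
#' @param map a \linkS4class{SnpPathwayMap} on the dataset's SNPs.
#' @param config a [runConfig()].
#' @return list: \code{results} (data.frame over channels and kinds with
#'   \code{p_perm} and \code{fdr}), \code{network} (the binarized
#'   \linkS4class{InteractionNetwork}), \code{nullRuns} (pooled
#'   sample-permutation statistics per channel), \code{config}.
#' @export
runDiscovery <- function(ds, map, config = runConfig()) {
  stopifnot(inherits(config, "RunConfig"))
  if (!identical(snpUniverse(map), snpInfo(ds)$snp_id))
    stop("pathway map SNP universe does not match the dataset")
  net <- buildNetwork(ds, model = config$model, alpha = config$alpha,
                      prefilter = config$prefilter)
  net <- binarizeNetwork(net, config$density,
                         seed = deriveSeed(config$seed, 1))
  chunks <- list()
  nullRuns <- list()
  for (ch in config$channels) {
    adj <- adjacency(net, ch)
    res <- discoverStructures(adj, map, NP = config$npSnp,
                              seed = deriveSeed(config$seed, 2),
                              kinds = config$kinds)
    attr(res, "null") <- NULL
    res$channel <- ch
    null <- samplePermutationNull(
      ds, map, model = config$model, density = config$density,
      NPs = config$npSample, NP = config$npSnp, channel = ch,
      kinds = config$kinds, alpha = config$alpha,
      prefilter = config$prefilter,
      seed = deriveSeed(config$seed, 3))
    res <- do.call(rbind, lapply(split(res, res$kind), function(part) {
      estimateFdr(part, null[null$kind == part$kind[1], , drop = FALSE],
                  NPs = config$npSample)
    }))
    rownames(res) <- NULL
    chunks[[ch]] <- res
    nullRuns[[ch]] <- null
  }
  results <- do.call(rbind, chunks)
  results <- results[order(results$fdr, results$p_perm), ]
  rownames(results) <- NULL
  list(results = results, network = net, nullRuns = nullRuns,
       config = config)
}
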