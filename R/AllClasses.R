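#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData rowData<- colData<-
NULL

#' GenotypeData: case-control genotypes with SNP and sample annotation
#'
#' Container for a biallelic genotype matrix (minor-allele counts in
#' \{0, 1, 2\}, \code{NA} = missing) with per-SNP metadata (chromosome,
#' 1-based position, alleles) and per-sample metadata (phenotype, optional
#' matched-pair identifier). Extends
#' \linkS4class{SummarizedExperiment}: SNPs are rows, samples are columns,
#' the single assay is named \code{"genotype"}.
#'
#' @slot qcLog a data.frame logging filter actions (rule, items removed).
#' @seealso [genotypeData()] for construction, [genotypes()], [phenotype()],
#'   [pairId()], [snpInfo()] for access.
#' @export
setClass("GenotypeData",
  contains = "SummarizedExperiment",
  representation(qcLog = "data.frame"),
  prototype(qcLog = data.frame(rule = character(), removed = integer()))
)

setValidity("GenotypeData", function(object) {
  msg <- character()
  if (!"genotype" %in% names(assays(object)))
    msg <- c(msg, "assay 'genotype' is required")
  else {
    g <- assay(object, "genotype")
    bad <- !is.na(g) & !(g %in% 0:2)
    if (any(bad))
      msg <- c(msg, "genotype values must be 0, 1, 2 or NA")
  }
  rd <- rowData(object)
  need <- c("chrom", "pos")
  if (!all(need %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'chrom' and 'pos'")
  else if (nrow(rd) && any(is.na(rd$pos) | rd$pos < 1))
    msg <- c(msg, "SNP positions must be strictly positive")
  cd <- colData(object)
  if (!"phenotype" %in% colnames(cd))
    msg <- c(msg, "colData must contain 'phenotype'")
  else if (ncol(object) &&
           !all(cd$phenotype %in% c("case", "control")))
    msg <- c(msg, "phenotype must be 'case' or 'control' for every sample")
  if (length(msg)) msg else TRUE
})

#' SnpPathwayMap: pathway to SNP membership after gene-window mapping
#'
#' Maps pathway identifiers to sets of SNP indices (into a fixed SNP
#' universe) after SNP-to-gene window mapping, gene-to-pathway annotation,
#' and pathway size filtering. Each SNP appears at most once per pathway.
#'
#' @slot pathways named list of sorted integer vectors (indices into
#'   \code{snpIds}).
#' @slot snpIds character vector, the SNP universe the indices refer to.
#' @slot snpToGenes named list mapping SNP id to the gene symbols it was
#'   assigned to (possibly empty).
#' @export
setClass("SnpPathwayMap",
  representation(pathways = "list", snpIds = "character",
                 snpToGenes = "list"))

setValidity("SnpPathwayMap", function(object) {
  msg <- character()
  n <- length(object@snpIds)
  for (p in object@pathways) {
    if (anyDuplicated(p)) { msg <- c(msg, "duplicated SNP in a pathway"); break }
    if (length(p) && (min(p) < 1L || max(p) > n)) {
      msg <- c(msg, "pathway SNP index outside the SNP universe"); break
    }
  }
  if (is.null(names(object@pathways)) && length(object@pathways))
    msg <- c(msg, "pathways must be named")
  if (length(msg)) msg else TRUE
})

#' InteractionNetwork: SNP-SNP interaction scores and binarized adjacency
#'
#' Symmetric SNP x SNP interaction score matrix for one disease model
#' (\code{"RR"}, \code{"DD"}, \code{"RD"}, \code{"DR"}, \code{"combined"}
#' hygeSSI, or \code{"AA"} additive -log10 LRT p), the per-edge channel
#' (risk/protective), and - after [binarizeNetwork()] - sparse risk and
#' protective adjacency matrices at a target network density.
#'
#' @slot model disease model label.
#' @slot scores symmetric numeric matrix, zero diagonal, nonnegative.
#' @slot channel integer matrix: 1 = risk, 2 = protective, 0 = no edge.
#' @slot adjacencyRisk,adjacencyProtective symmetric sparse pattern
#'   matrices (filled by [binarizeNetwork()]).
#' @slot density target edge density; \code{achievedDensity} the realized one.
#' @slot alpha,prefilter scoring parameters used.
#' @slot snpIds SNP identifiers for rows/columns.
#' @export
setClass("InteractionNetwork",
  representation(model = "character", scores = "matrix",
                 channel = "matrix", adjacencyRisk = "ANY",
                 adjacencyProtective = "ANY", density = "numeric",
                 achievedDensity = "numeric", alpha = "numeric",
                 prefilter = "numeric", snpIds = "character"),
  prototype(adjacencyRisk = NULL, adjacencyProtective = NULL,
            density = NA_real_, achievedDensity = NA_real_,
            alpha = 0.05, prefilter = 0.2))

setValidity("InteractionNetwork", function(object) {
  msg <- character()
  s <- object@scores
  if (nrow(s) != ncol(s)) msg <- c(msg, "score matrix must be square")
  if (nrow(s) && any(diag(s) != 0)) msg <- c(msg, "diagonal must be zero")
  if (nrow(s) && any(s < 0)) msg <- c(msg, "scores must be nonnegative")
  if (!object@model %in% c("RR", "DD", "RD", "DR", "combined", "AA"))
    msg <- c(msg, "unknown disease model")
  if (length(object@snpIds) != nrow(s))
    msg <- c(msg, "snpIds length must match score matrix")
  if (length(msg)) msg else TRUE
})
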