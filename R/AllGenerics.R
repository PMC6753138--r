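#' @rdname GenotypeData-class
#' @param x a \linkS4class{GenotypeData} object.
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname GenotypeData-class
#' @export
setGeneric("phenotype", function(x) standardGeneric("phenotype"))

#' @rdname GenotypeData-class
#' @export
setGeneric("pairId", function(x) standardGeneric("pairId"))

#' @rdname GenotypeData-class
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' @rdname GenotypeData-class
#' @export
setGeneric("qcLog", function(x) standardGeneric("qcLog"))

#' @rdname SnpPathwayMap-class
#' @param x a \linkS4class{SnpPathwayMap}.
#' @export
setGeneric("pathwaySnps", function(x) standardGeneric("pathwaySnps"))

#' @rdname SnpPathwayMap-class
#' @export
setGeneric("pathwayNames", function(x) standardGeneric("pathwayNames"))

#' @rdname SnpPathwayMap-class
#' @export
setGeneric("snpUniverse", function(x) standardGeneric("snpUniverse"))

#' @rdname InteractionNetwork-class
#' @param x an \linkS4class{InteractionNetwork}.
#' @export
setGeneric("interactionScores", function(x) standardGeneric("interactionScores"))

#' @rdname InteractionNetwork-class
#' @export
setGeneric("adjacency", function(x, channel = c("both", "risk", "protective"))
  standardGeneric("adjacency"))

#' @rdname InteractionNetwork-class
#' @export
setGeneric("networkDensity", function(x) standardGeneric("networkDensity"))
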