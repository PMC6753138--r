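#' Read / write gene-set collections in GMT format
#'
#' GMT is tab-separated: pathway id, description, then gene symbols. Gene
#' lists are deduplicated on read; empty gene lists are rejected.
#'
#' @param file path to a .gmt file.
#' @return named list of pathways, each a list with elements \code{name},
#'   \code{description} and \code{genes}.
#' @export
readGmt <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("GMT line with no genes: ", f[1])
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("GMT pathway with empty gene list: ", f[1])
    list(name = f[1], description = f[2], genes = genes)
  })
  names(out) <- vapply(out, `[[`, "", "name")
  if (anyDuplicated(names(out))) stop("duplicated pathway ids in GMT")
  out
}

#' @rdname readGmt
#' @param gsc a gene-set collection as returned by [readGmt()].
#' @export
writeGmt <- function(gsc, file) {
  lines <- vapply(gsc, function(p)
    paste(c(p$name, p$description, p$genes), collapse = "\t"), "")
  writeLines(lines, file)
  invisible(file)
}

#' Read a gene coordinate table
#'
#' Tab-separated columns \code{symbol}, \code{chrom}, \code{start},
#' \code{end}. Coordinates may be 0-based half-open (BED convention) or
#' 1-based closed; internally the 1-based closed convention is used.
#'
#' @param file path to the TSV.
#' @param zeroBased if TRUE, \code{start} is shifted by +1 on read.
#' @return data.frame with 1-based closed gene intervals.
#' @export
readGeneTable <- function(file, zeroBased = FALSE) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  stopifnot(all(c("symbol", "chrom", "start", "end") %in% colnames(tab)))
  if (zeroBased) tab$start <- tab$start + 1L
  if (any(tab$start > tab$end)) stop("gene interval with start > end")
  tab
}

#' Map SNPs to genes by a symmetric window
#'
#' A SNP maps to every gene whose body overlaps a window of
#' \code{windowBp} base pairs on each side of the SNP position
#' (closed intervals, same chromosome).
#'
#' @param snps data.frame with \code{snp_id}, \code{chrom}, \code{pos}.
#' @param genes data.frame with \code{symbol}, \code{chrom}, \code{start},
#'   \code{end} (1-based closed intervals).
#' @param windowBp window half-width in bp (default 50 kb).
#' @return named list: SNP id -> character vector of gene symbols (possibly
#'   empty).
#' @export
mapSnpsToGenes <- function(snps, genes, windowBp = 50000L) {
  if (any(genes$start > genes$end)) stop("invalid gene interval")
  snpGr <- GenomicRanges::GRanges(
    seqnames = as.character(snps$chrom),
    ranges = IRanges::IRanges(start = pmax(1L, snps$pos - windowBp),
                              end = snps$pos + windowBp))
  geneGr <- GenomicRanges::GRanges(
    seqnames = as.character(genes$chrom),
    ranges = IRanges::IRanges(start = genes$start, end = genes$end))
  ## chromosomes present on only one side are simply non-overlapping
  hits <- suppressWarnings(GenomicRanges::findOverlaps(snpGr, geneGr))
  out <- rep(list(character()), nrow(snps))
  names(out) <- snps$snp_id
  if (length(hits)) {
    sp <- split(genes$symbol[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits))
    out[as.integer(names(sp))] <- lapply(sp, unique)
  }
  out
}

#' Build the pathway -> SNP membership map
#'
#' Combines the SNP-to-gene assignment with a gene-set collection. A
#' pathway is retained iff the number of its genes represented by at least
#' one SNP in the dataset and the number of distinct SNPs mapping to it both
#' fall in \code{[minSize, maxSize]}. Each SNP is associated at most once
#' with each pathway even when it maps to several member genes.
#'
#' @param snpToGenes named list from [mapSnpsToGenes()]; names define the
#'   SNP universe (and its index order).
#' @param gsc gene-set collection from [readGmt()] (or a named list of
#'   character gene vectors).
#' @param minSize,maxSize pathway size bounds applied to both gene and SNP
#'   counts (defaults 10 and 300).
#' @return a \linkS4class{SnpPathwayMap}.
#' @export
buildSnpPathwayMap <- function(snpToGenes, gsc, minSize = 10L,
                               maxSize = 300L) {
  snpIds <- names(snpToGenes)
  if (is.null(snpIds)) stop("snpToGenes must be named by SNP id")
  gene2snp <- new.env(parent = emptyenv())
  for (i in seq_along(snpToGenes))
    for (gene in snpToGenes[[i]])
      assign(gene, c(get0(gene, envir = gene2snp, ifnotfound = integer()),
                     i), envir = gene2snp)
  geneLists <- lapply(gsc, function(p)
    if (is.list(p)) p$genes else as.character(p))
  pathways <- list()
  for (pid in names(geneLists)) {
    genes <- unique(geneLists[[pid]])
    hit <- genes[vapply(genes, function(g)
      !is.null(get0(g, envir = gene2snp)), TRUE)]
    snps <- sort(unique(unlist(lapply(hit, get, envir = gene2snp),
                               use.names = FALSE)))
    if (length(hit) >= minSize && length(hit) <= maxSize &&
        length(snps) >= minSize && length(snps) <= maxSize)
      pathways[[pid]] <- as.integer(snps)
  }
  if (!length(pathways))
    stop("no pathway passed the size filter")
  new("SnpPathwayMap", pathways = pathways, snpIds = snpIds,
      snpToGenes = snpToGenes)
}

#' Construct a SnpPathwayMap directly from membership lists
#'
#' Convenience constructor used by the simulators and tests: pathway
#' membership is given explicitly as indices (or SNP ids) into a SNP
#' universe, bypassing gene annotation.
#'
#' @param pathways named list of integer index vectors (or character SNP id
#'   vectors) giving each pathway's SNPs.
#' @param snpIds the SNP universe.
#' @return a \linkS4class{SnpPathwayMap}.
#' @export
snpPathwayMap <- function(pathways, snpIds) {
  pathways <- lapply(pathways, function(p) {
    if (is.character(p)) p <- match(p, snpIds)
    sort(unique(as.integer(p)))
  })
  new("SnpPathwayMap", pathways = pathways, snpIds = snpIds,
      snpToGenes = list())
}

#' @rdname SnpPathwayMap-class
#' @export
setMethod("pathwaySnps", "SnpPathwayMap", function(x) x@pathways)

#' @rdname SnpPathwayMap-class
#' @export
setMethod("pathwayNames", "SnpPathwayMap", function(x) names(x@pathways))

#' @rdname SnpPathwayMap-class
#' @export
setMethod("snpUniverse", "SnpPathwayMap", function(x) x@snpIds)

setMethod("show", "SnpPathwayMap", function(object) {
  sizes <- lengths(object@pathways)
  cat(sprintf("SnpPathwayMap: %d pathways over %d SNPs (sizes %d-%d)\n",
              length(sizes), length(object@snpIds),
              if (length(sizes)) min(sizes) else 0L,
              if (length(sizes)) max(sizes) else 0L))
})

#' Write a pathway-SNP map as TSV (pathway_id, snp_id)
#'
#' @param map a \linkS4class{SnpPathwayMap}.
#' @param file output path.
#' @export
writeSnpPathwayMap <- function(map, file) {
  rows <- do.call(rbind, lapply(pathwayNames(map), function(p)
    data.frame(pathway_id = p, snp_id = map@snpIds[map@pathways[[p]]],
               stringsAsFactors = FALSE)))
  utils::write.table(rows, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
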