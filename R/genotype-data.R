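#' Construct a GenotypeData object
#'
#' @param genotypes integer matrix of minor-allele counts. Orientation is
#'   samples x SNPs (the natural orientation of most genotype tables); it is
#'   stored internally SNPs x samples following the
#'   \linkS4class{SummarizedExperiment} convention.
#' @param phenotype character/factor of \code{"case"}/\code{"control"}, one
#'   per sample, or a numeric vector using the PLINK convention
#'   (1 = control, 2 = case).
#' @param snps data.frame with columns \code{snp_id}, \code{chrom},
#'   \code{pos} (1-based bp) and optionally \code{allele_minor},
#'   \code{allele_major}. Defaults to placeholder annotation on one
#'   chromosome at 1 Mb spacing (positions are only consulted by LD pruning
#'   and gene mapping).
#' @param sampleIds character vector of sample identifiers.
#' @param pairId optional matched-pair identifier per sample.
#' @return a \linkS4class{GenotypeData}.
#' @examples
#' g <- matrix(rbinom(40, 2, 0.3), nrow = 10,
#'             dimnames = list(NULL, paste0("rs", 1:4)))
#' gd <- genotypeData(g, rep(c("case", "control"), 5))
#' gd
#' @export
genotypeData <- function(genotypes, phenotype, snps = NULL,
                         sampleIds = NULL, pairId = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  nSamp <- nrow(genotypes)
  nSnp <- ncol(genotypes)
  if (is.numeric(phenotype))
    phenotype <- c("control", "case")[match(phenotype, c(1, 2))]
  phenotype <- as.character(phenotype)
  if (length(phenotype) != nSamp)
    stop("phenotype must have one entry per sample")
  if (is.null(sampleIds))
    sampleIds <- sprintf("sample_%d", seq_len(nSamp))
  if (is.null(snps)) {
    ids <- colnames(genotypes)
    if (is.null(ids)) ids <- sprintf("snp_%d", seq_len(nSnp))
    snps <- data.frame(snp_id = ids, chrom = "1",
                       pos = seq_len(nSnp) * 1e6,
                       allele_minor = "A", allele_major = "G",
                       stringsAsFactors = FALSE)
  }
  stopifnot(nrow(snps) == nSnp)
  if (is.null(snps$allele_minor)) snps$allele_minor <- "A"
  if (is.null(snps$allele_major)) snps$allele_major <- "G"
  cd <- DataFrame(sample_id = sampleIds, phenotype = phenotype)
  cd$pair_id <- if (is.null(pairId)) NA_character_ else as.character(pairId)
  se <- SummarizedExperiment(
    assays = SimpleList(genotype = t(genotypes)),
    rowData = DataFrame(snps), colData = cd)
  rownames(se) <- snps$snp_id
  colnames(se) <- sampleIds
  new("GenotypeData", se)
}

#' @rdname GenotypeData-class
#' @aliases genotypes,GenotypeData-method
#' @export
setMethod("genotypes", "GenotypeData", function(x)
  t(assay(x, "genotype")))

#' @rdname GenotypeData-class
#' @export
setMethod("phenotype", "GenotypeData", function(x)
  as.character(colData(x)$phenotype))

#' @rdname GenotypeData-class
#' @export
setMethod("pairId", "GenotypeData", function(x)
  as.character(colData(x)$pair_id))

#' @rdname GenotypeData-class
#' @export
setMethod("snpInfo", "GenotypeData", function(x)
  as.data.frame(rowData(x)))

#' @rdname GenotypeData-class
#' @export
setMethod("qcLog", "GenotypeData", function(x) x@qcLog)

setMethod("show", "GenotypeData", function(object) {
  ph <- phenotype(object)
  cat(sprintf(
    "GenotypeData: %d SNPs x %d samples (%d cases, %d controls)\n",
    nrow(object), ncol(object), sum(ph == "case"), sum(ph == "control")))
  g <- assay(object, "genotype")
  cat(sprintf("  missing rate: %.4f\n", mean(is.na(g))))
  if (nrow(object@qcLog))
    cat(sprintf("  QC log: %d entries (see qcLog())\n", nrow(object@qcLog)))
})

appendQcLog <- function(ds, rule, removed) {
  ds@qcLog <- rbind(ds@qcLog,
                    data.frame(rule = rule, removed = as.integer(removed)))
  ds
}

subsetGenotypeData <- function(ds, snpKeep = NULL, sampleKeep = NULL) {
  log <- ds@qcLog
  if (!is.null(snpKeep)) ds <- ds[snpKeep, ]
  if (!is.null(sampleKeep)) ds <- ds[, sampleKeep]
  ds <- as(ds, "GenotypeData")
  ds@qcLog <- log
  ds
}

## ---------------------------------------------------------------------------
## Readers / writers

#' Read a genotype matrix in the package's TSV dialect
#'
#' The dialect is one row per sample: a \code{sample_id} column, a
#' \code{phenotype} column (1 = control, 2 = case, PLINK convention) and one
#' integer column of minor-allele counts per SNP (NA = missing), with SNP
#' identifiers as the header. SNP coordinates may be supplied separately.
#'
#' @param file path to the TSV file.
#' @param snps optional SNP annotation data.frame (see [genotypeData()]).
#' @return a \linkS4class{GenotypeData}.
#' @export
readGenotypeTsv <- function(file, snps = NULL) {
  tab <- utils::read.delim(file, check.names = FALSE,
                           stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "phenotype") %in% colnames(tab)))
  meta <- c("sample_id", "phenotype")
  g <- as.matrix(tab[, setdiff(colnames(tab), meta), drop = FALSE])
  genotypeData(g, phenotype = as.numeric(tab$phenotype), snps = snps,
               sampleIds = as.character(tab$sample_id))
}

#' Write a GenotypeData object in the TSV dialect
#'
#' @param ds a \linkS4class{GenotypeData}.
#' @param file output path.
#' @export
writeGenotypeTsv <- function(ds, file) {
  tab <- data.frame(sample_id = colData(ds)$sample_id,
                    phenotype = ifelse(phenotype(ds) == "case", 2L, 1L),
                    check.names = FALSE)
  tab <- cbind(tab, as.data.frame(genotypes(ds)))
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a PLINK .bed/.bim/.fam fileset
#'
#' Reads the binary SNP-major PLINK 1 format. Genotypes are returned as
#' counts of the A1 allele (PLINK's minor allele by convention):
#' \code{00 -> 2}, \code{10 -> 1}, \code{11 -> 0}, \code{01 -> NA}.
#' Phenotype uses the PLINK coding 1 = control, 2 = case.
#'
#' @param prefix path prefix; \code{<prefix>.bed/.bim/.fam} must exist.
#' @return a \linkS4class{GenotypeData}.
#' @export
readPlink <- function(prefix) {
  fam <- utils::read.table(paste0(prefix, ".fam"),
                           stringsAsFactors = FALSE)
  bim <- utils::read.table(paste0(prefix, ".bim"),
                           stringsAsFactors = FALSE)
  colnames(bim) <- c("chrom", "snp_id", "cm", "pos", "a1", "a2")
  nSamp <- nrow(fam)
  nSnp <- nrow(bim)
  bytesPerSnp <- ceiling(nSamp / 4)
  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L)))
    stop("not a SNP-major PLINK .bed file")
  raw <- readBin(con, "raw", bytesPerSnp * nSnp)
  if (length(raw) < bytesPerSnp * nSnp)
    stop("truncated .bed file")
  ## 2-bit decode via a 256 x 4 lookup: 00=2 copies of A1, 10=1, 11=0, 01=NA
  codes <- c(2L, NA_integer_, 1L, 0L)
  byte <- as.integer(raw)
  lut <- cbind(codes[bitwAnd(0:255, 3L) + 1L],
               codes[bitwAnd(bitwShiftR(0:255, 2L), 3L) + 1L],
               codes[bitwAnd(bitwShiftR(0:255, 4L), 3L) + 1L],
               codes[bitwAnd(bitwShiftR(0:255, 6L), 3L) + 1L])
  dec <- matrix(t(lut[byte + 1L, , drop = FALSE]), nrow = bytesPerSnp * 4)
  g <- dec[seq_len(nSamp), , drop = FALSE]     # samples x SNPs
  colnames(g) <- bim$snp_id
  snps <- data.frame(snp_id = bim$snp_id, chrom = as.character(bim$chrom),
                     pos = bim$pos, allele_minor = bim$a1,
                     allele_major = bim$a2, stringsAsFactors = FALSE)
  genotypeData(g, phenotype = as.numeric(fam[[6]]), snps = snps,
               sampleIds = as.character(fam[[2]]))
}

#' Write the QC report accumulated on a dataset
#'
#' @param ds a \linkS4class{GenotypeData}.
#' @param file output TSV path (columns: rule, items_removed).
#' @export
writeQcReport <- function(ds, file) {
  log <- qcLog(ds)
  colnames(log) <- c("rule", "items_removed")
  utils::write.table(log, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
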