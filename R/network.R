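## Vectorized hygeSSI over all SNP pairs.
##
## For binary codings A (role x) and B (role y), all pattern counts reduce
## to cross-products of indicator matrices, so a full SNP x SNP score matrix
## costs two (no missing data) or eight (with missing data) matrix products
## plus elementwise hypergeometric tails.

hygeClassScores <- function(K11, X11, K10, X10, K01, X01, K00, X00,
                            Kx, Xx, Ky, Xy, M, N, alpha) {
  P11 <- stats::phyper(X11 - 1, N, M - N, K11, lower.tail = FALSE)
  P10 <- stats::phyper(X10 - 1, N, M - N, K10, lower.tail = FALSE)
  P01 <- stats::phyper(X01 - 1, N, M - N, K01, lower.tail = FALSE)
  P00 <- stats::phyper(X00 - 1, N, M - N, K00, lower.tail = FALSE)
  Px <- stats::phyper(Xx - 1, N, M - N, Kx, lower.tail = FALSE)
  Py <- stats::phyper(Xy - 1, N, M - N, Ky, lower.tail = FALSE)
  P11 <- pmax(P11, .Machine$double.xmin)
  den <- pmin(P10, P01, P00, Px, Py)
  gate <- (P11 <= alpha) & (P10 > alpha) & (P01 > alpha) & (P00 > alpha)
  sc <- log10(den) - log10(P11)
  sc[!gate] <- 0
  sc[sc < 0] <- 0
  sc
}

## Risk (class = cases) and protective (class = controls) score matrices
## for codings A, B (samples x SNPs integer 0/1, NA = missing).
hygeSsiMatrix <- function(A, B, isCase, alpha = 0.05) {
  M0 <- nrow(A)
  isCase <- as.integer(as.logical(isCase))
  cs <- isCase == 1L
  anyNA <- anyNA(A) || anyNA(B)
  if (!anyNA) {
    K11 <- crossprod(A, B)
    X11 <- crossprod(A[cs, , drop = FALSE], B[cs, , drop = FALSE])
    k1x <- colSums(A); k1y <- colSums(B)
    x1x <- colSums(A[cs, , drop = FALSE])
    x1y <- colSums(B[cs, , drop = FALSE])
    nx <- ncol(A); ny <- ncol(B)
    Kx <- matrix(k1x, nx, ny); Ky <- matrix(k1y, nx, ny, byrow = TRUE)
    K10 <- Kx - K11; K01 <- Ky - K11; K00 <- M0 - Kx - Ky + K11
    M <- matrix(M0, nx, ny)
    N <- sum(isCase)
    Xxc <- matrix(x1x, nx, ny); Xyc <- matrix(x1y, nx, ny, byrow = TRUE)
    X10 <- Xxc - X11; X01 <- Xyc - X11; X00 <- N - Xxc - Xyc + X11
    risk <- hygeClassScores(K11, X11, K10, X10, K01, X01, K00, X00,
                            Kx, Xxc, Ky, Xyc, M0, N, alpha)
    prot <- hygeClassScores(K11, K11 - X11, K10, K10 - X10,
                            K01, K01 - X01, K00, K00 - X00,
                            Kx, Kx - Xxc, Ky, Ky - Xyc,
                            M0, M0 - N, alpha)
  } else {
    OA <- !is.na(A); OB <- !is.na(B)
    A0 <- A; A0[!OA] <- 0L; B0 <- B; B0[!OB] <- 0L
    storage.mode(OA) <- "integer"; storage.mode(OB) <- "integer"
    Mp <- crossprod(OA, OB)
    Np <- crossprod(OA * isCase, OB * isCase)
    K11 <- crossprod(A0, B0)
    X11 <- crossprod(A0 * isCase, B0 * isCase)
    K10 <- crossprod(A0, (1L - B0) * OB)
    X10 <- crossprod(A0 * isCase, ((1L - B0) * OB) * isCase)
    K01 <- crossprod((1L - A0) * OA, B0)
    X01 <- crossprod(((1L - A0) * OA) * isCase, B0 * isCase)
    K00 <- Mp - K11 - K10 - K01
    X00 <- Np - X11 - X10 - X01
    Kx <- crossprod(A0, OB); Xx <- crossprod(A0 * isCase, OB * isCase)
    Ky <- crossprod(OA, B0); Xy <- crossprod(OA * isCase, B0 * isCase)
    risk <- hygeClassScores(K11, X11, K10, X10, K01, X01, K00, X00,
                            Kx, Xx, Ky, Xy, Mp, Np, alpha)
    prot <- hygeClassScores(K11, K11 - X11, K10, K10 - X10,
                            K01, K01 - X01, K00, K00 - X00,
                            Kx, Kx - Xx, Ky, Ky - Xy,
                            Mp, Mp - Np, alpha)
  }
  list(risk = risk, protective = prot)
}

#' Build a SNP-SNP interaction network
#'
#' Scores every SNP pair under a disease model. For the hypergeometric
#' models the pair is scored twice, once against the cases (risk channel)
#' and once against the controls (protective channel); the reported score
#' is the larger of the two and the channel records which (ties go to
#' risk). \code{"combined"} takes the elementwise maximum over the RR, DD,
#' RD and DR codings, deciding (score, channel) jointly. \code{"AA"} scores
#' pairs by the additive logistic-regression likelihood-ratio test
#' (single channel, labelled by the sign of the interaction coefficient).
#'
#' @param ds a QC'd \linkS4class{GenotypeData}.
#' @param model one of \code{"combined"}, \code{"DD"}, \code{"RR"},
#'   \code{"RD"}, \code{"DR"}, \code{"AA"}.
#' @param alpha nominal threshold for the hygeSSI gates (default 0.05).
#' @param prefilter minimum hygeSSI retained at binarization (stored on the
#'   network; not applied to AA scores).
#' @return an \linkS4class{InteractionNetwork} with scores and channel
#'   filled (adjacency empty until [binarizeNetwork()]).
#' @export
buildNetwork <- function(ds, model = c("combined", "DD", "RR", "RD", "DR",
                                       "AA"),
                         alpha = 0.05, prefilter = 0.2) {
  model <- match.arg(model)
  g <- genotypes(ds)
  isCase <- as.integer(phenotype(ds) == "case")
  snpIds <- snpInfo(ds)$snp_id
  n <- ncol(g)
  if (model == "AA") {
    risk <- matrix(0, n, n)
    chan <- matrix(0L, n, n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      s <- suppressWarnings(additiveLrt(g[, i], g[, j], isCase))
      risk[i, j] <- risk[j, i] <- s
      if (s > 0) {
        ok <- !is.na(g[, i]) & !is.na(g[, j])
        b <- tryCatch(stats::coef(stats::glm(
          isCase[ok] ~ g[ok, i] + g[ok, j] + I(g[ok, i] * g[ok, j]),
          family = stats::binomial()))[["I(g[ok, i] * g[ok, j])"]],
          error = function(e) 0)
        chan[i, j] <- chan[j, i] <- if (!is.na(b) && b < 0) 2L else 1L
      }
    }
    net <- new("InteractionNetwork", model = model, scores = risk,
               channel = chan, alpha = alpha, prefilter = 0,
               snpIds = snpIds)
    return(net)
  }
  D <- codeGenotypes(g, "dominant")
  R <- codeGenotypes(g, "recessive")
  comp <- switch(model,
    DD = list(list(D, D)),
    RR = list(list(R, R)),
    RD = list(list(R, D)),
    DR = list(list(D, R)),
    combined = list(list(R, R), list(D, D), list(R, D)))
  risk <- matrix(0, n, n); prot <- matrix(0, n, n)
  for (ab in comp) {
    sc <- hygeSsiMatrix(ab[[1]], ab[[2]], isCase, alpha)
    symmetric <- identical(ab[[1]], ab[[2]])
    risk <- pmax(risk, sc$risk); prot <- pmax(prot, sc$protective)
    if (model == "combined" && !symmetric) {
      ## asymmetric coding contributes both orientations (RD and DR)
      risk <- pmax(risk, t(sc$risk)); prot <- pmax(prot, t(sc$protective))
    }
  }
  diag(risk) <- 0; diag(prot) <- 0
  scores <- pmax(risk, prot)
  chan <- matrix(0L, n, n)
  chan[scores > 0] <- ifelse(risk[scores > 0] >= prot[scores > 0], 1L, 2L)
  new("InteractionNetwork", model = model, scores = scores,
      channel = chan, alpha = alpha, prefilter = prefilter,
      snpIds = snpIds)
}

#' Binarize an interaction network at a target density
#'
#' Among pairs with score at or above the pre-filter, the top
#' \code{floor(density * nPairsTotal)} pairs by score are kept (ties at the
#' cutoff broken by a seeded, recorded shuffle); the kept edges are split
#' into risk and protective adjacency matrices according to each edge's
#' channel, against the same global ranking. If fewer pairs are eligible
#' than requested, all are kept and the achieved density recorded.
#'
#' @param net an \linkS4class{InteractionNetwork} with scores.
#' @param density target fraction of all SNP pairs retained (0 < d < 1).
#' @param prefilter minimum score for eligibility (defaults to the value
#'   stored on the network; 0.2 for hygeSSI models, none for AA).
#' @param seed seed for the tie-breaking shuffle.
#' @return the network with \code{adjacencyRisk}/\code{adjacencyProtective}
#'   and \code{achievedDensity} filled.
#' @export
binarizeNetwork <- function(net, density, prefilter = net@prefilter,
                            seed = 1L) {
  stopifnot(density > 0, density < 1)
  n <- length(net@snpIds)
  pairs <- upperPairs(n)
  sc <- net@scores[upper.tri(net@scores)]
  eligible <- which(sc >= max(prefilter, .Machine$double.xmin))
  m <- floor(density * nrow(pairs))
  tie <- withSeed(seed, sample.int(length(sc)))
  if (length(eligible) > m) {
    ord <- eligible[order(-sc[eligible], tie[eligible])]
    keep <- ord[seq_len(m)]
  } else {
    keep <- eligible
  }
  chanFlat <- net@channel[upper.tri(net@channel)]
  mk <- function(sel) {
    Matrix::sparseMatrix(
      i = c(pairs[sel, 1], pairs[sel, 2]),
      j = c(pairs[sel, 2], pairs[sel, 1]),
      x = 1, dims = c(n, n), dimnames = list(net@snpIds, net@snpIds))
  }
  net@adjacencyRisk <- mk(keep[chanFlat[keep] == 1L])
  net@adjacencyProtective <- mk(keep[chanFlat[keep] == 2L])
  net@density <- density
  net@achievedDensity <- length(keep) / nrow(pairs)
  net
}

#' @rdname InteractionNetwork-class
#' @export
setMethod("interactionScores", "InteractionNetwork", function(x) x@scores)

#' @rdname InteractionNetwork-class
#' @param channel which adjacency to return; \code{"both"} returns the
#'   union of risk and protective edges.
#' @export
setMethod("adjacency", "InteractionNetwork", function(x, channel = c(
    "both", "risk", "protective")) {
  channel <- match.arg(channel)
  if (is.null(x@adjacencyRisk))
    stop("network has not been binarized; call binarizeNetwork()")
  switch(channel,
         risk = x@adjacencyRisk,
         protective = x@adjacencyProtective,
         both = {
           a <- x@adjacencyRisk + x@adjacencyProtective
           a@x[a@x > 1] <- 1
           a
         })
})

#' @rdname InteractionNetwork-class
#' @export
setMethod("networkDensity", "InteractionNetwork", function(x)
  x@achievedDensity)

setMethod("show", "InteractionNetwork", function(object) {
  n <- length(object@snpIds)
  cat(sprintf("InteractionNetwork (%s model): %d SNPs\n", object@model, n))
  cat(sprintf("  positive scores: %d pairs\n",
              sum(object@scores[upper.tri(object@scores)] > 0)))
  if (!is.null(object@adjacencyRisk))
    cat(sprintf("  binarized at density %.4g (achieved %.4g): %d risk, %d protective edges\n",
                object@density, object@achievedDensity,
                Matrix::nnzero(object@adjacencyRisk) / 2,
                Matrix::nnzero(object@adjacencyProtective) / 2))
})

#' Export the binarized network as a TSV edge list
#'
#' Columns: snp_i, snp_j, model, score, channel.
#'
#' @param net a binarized \linkS4class{InteractionNetwork}.
#' @param file output path.
#' @export
writeEdgeList <- function(net, file) {
  n <- length(net@snpIds)
  a <- adjacency(net, "both")
  ut <- which(upper.tri(a) & (as.matrix(a) > 0), arr.ind = TRUE)
  df <- data.frame(
    snp_i = net@snpIds[ut[, 1]], snp_j = net@snpIds[ut[, 2]],
    model = net@model,
    score = net@scores[ut],
    channel = c("none", "risk", "protective")[net@channel[ut] + 1L])
  df <- df[order(-df$score), ]
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
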