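#' Upper-tail hypergeometric p-value
#'
#' Probability of observing at least \code{X} samples with a genotype
#' pattern inside a class, when \code{K} samples carry the pattern overall,
#' the class holds \code{N} of the \code{M} samples, and carriers are
#' exchangeable: \code{P(count >= X)} under the hypergeometric law. Exact
#' (no normal approximation).
#'
#' @param M total samples. @param N samples in the class.
#' @param K samples carrying the pattern. @param X pattern carriers in the
#'   class. All arguments may be vectors/matrices of equal shape.
#' @return p-value(s) in (0, 1].
#' @examples
#' hygePvalue(8, 4, 4, 4)   # 1/70
#' hygePvalue(10, 5, 2, 0)  # 1: upper tail from zero
#' @export
hygePvalue <- function(M, N, K, X) {
  bad <- X < 0 | X > pmin(K, N) | N > M | K > M
  if (any(bad, na.rm = TRUE))
    stop("hypergeometric inputs must satisfy 0 <= X <= min(K, N) <= M")
  p <- stats::phyper(X - 1, N, M - N, K, lower.tail = FALSE)
  ## guard against p = 0 from degenerate rounding; p is in (0, 1] by theory
  pmax(p, .Machine$double.xmin)
}

#' Binary genotype codings for the dominant and recessive disease models
#'
#' Dominant: carriers of at least one minor allele are coded 1
#' (\code{mm = Mm = 1}, \code{MM = 0}). Recessive: only minor-allele
#' homozygotes are coded 1 (\code{mm = 1}, \code{Mm = MM = 0}). Missing
#' genotypes stay missing.
#'
#' @param g vector or matrix of minor-allele counts.
#' @param model \code{"dominant"} or \code{"recessive"}.
#' @return binary coding of the same shape.
#' @export
codeGenotypes <- function(g, model = c("dominant", "recessive")) {
  model <- match.arg(model)
  out <- if (model == "dominant") (g >= 1L) else (g == 2L)
  storage.mode(out) <- "integer"
  out
}

#' hygeSSI: hypergeometric SNP-SNP interaction score for one pair
#'
#' Compares the class association of the joint carrier pattern
#' (\code{sx = 1 & sy = 1}, p-value P11) against the most associated of the
#' alternative patterns (P10, P01, P00) and the two single-SNP main effects
#' (P1., P.1), all measured by [hygePvalue()] against class \code{C}. The
#' score is \code{-log10(P11 / min(P10, P01, P00, P1., P.1))} when the
#' joint pattern is significant (\code{P11 <= alpha}) and none of the
#' alternative patterns is (\code{P10, P01, P00 > alpha}); otherwise 0.
#' Negative log-ratios are floored at 0. Samples missing either SNP are
#' excluded pairwise.
#'
#' @param sx,sy binary-coded genotype vectors (see [codeGenotypes()]).
#' @param C logical or 0/1 vector marking the class (e.g. cases).
#' @param alpha nominal significance threshold (default 0.05).
#' @return nonnegative score (0 = no interaction under the gates).
#' @export
hygeSsiScore <- function(sx, sy, C, alpha = 0.05) {
  ok <- !is.na(sx) & !is.na(sy)
  sx <- sx[ok]; sy <- sy[ok]; C <- as.logical(C[ok])
  M <- length(sx)
  if (M == 0L) return(0)
  if (all(sx == sx[1]) || all(sy == sy[1])) {
    warning("degenerate coded vector (constant); score set to 0")
    return(0)
  }
  N <- sum(C)
  cnt <- function(pat) c(K = sum(pat), X = sum(pat & C))
  p11 <- cnt(sx == 1L & sy == 1L)
  p10 <- cnt(sx == 1L & sy == 0L)
  p01 <- cnt(sx == 0L & sy == 1L)
  p00 <- cnt(sx == 0L & sy == 0L)
  m1 <- cnt(sx == 1L)
  m2 <- cnt(sy == 1L)
  pv <- vapply(list(p11, p10, p01, p00, m1, m2), function(k)
    hygePvalue(M, N, k["K"], k["X"]), 0)
  if (pv[1] <= alpha && all(pv[2:4] > alpha))
    max(0, -log10(pv[1] / min(pv[2:6])))
  else 0
}

#' Additive-model interaction score by logistic-regression LRT
#'
#' Fits logistic models \code{C ~ g1 + g2} and \code{C ~ g1 + g2 + g1:g2}
#' on 0/1/2 allele-count codings and returns \code{-log10} of the 1-df
#' likelihood-ratio chi-square p-value. Non-convergence or separation
#' yields a score of 0 with a warning; a constant interaction column gives
#' p = 1 (score 0).
#'
#' @param g1,g2 minor-allele-count vectors (0/1/2, NA excluded pairwise).
#' @param C class labels (logical or 0/1), non-constant.
#' @return \code{-log10} LRT p-value (>= 0).
#' @export
additiveLrt <- function(g1, g2, C) {
  ok <- !is.na(g1) & !is.na(g2) & !is.na(C)
  g1 <- as.numeric(g1[ok]); g2 <- as.numeric(g2[ok])
  C <- as.numeric(as.logical(C[ok]))
  if (length(unique(C)) < 2L) stop("class labels are constant")
  gg <- g1 * g2
  if (length(unique(gg)) < 2L) return(0)
  fit <- tryCatch({
    m0 <- stats::glm(C ~ g1 + g2, family = stats::binomial())
    m1 <- stats::glm(C ~ g1 + g2 + gg, family = stats::binomial())
    list(m0 = m0, m1 = m1)
  }, warning = function(w) NULL, error = function(e) NULL)
  if (is.null(fit)) {
    warning("logistic fit did not converge (possible separation); score 0")
    return(0)
  }
  stat <- max(0, fit$m0$deviance - fit$m1$deviance)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  -log10(max(p, .Machine$double.xmin))
}
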