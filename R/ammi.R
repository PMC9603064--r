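## AMMI: additive two-way ANOVA plus SVD of the doubly-centered interaction
## residuals, per temperature. Sums of squares are kept on the
## replicate-observation scale (means-based SS times r) so that the Error
## row (pooled within-cell SS, df g*e*(r-1)) balances the Total.

#' Gollob degrees of freedom for an IPCA axis
#'
#' The n-th interaction principal component axis of a g x e two-way table
#' is assigned g + e - 1 - 2n degrees of freedom for its F test against the
#' pooled error. The Gollob test is known to be liberal; it is implemented
#' here as the field's conventional default.
#'
#' @param g number of genotypes (genes)
#' @param e number of environments (tissues)
#' @param n axis index, 1 <= n <= min(g, e) - 1
#' @return integer degrees of freedom
#' @examples
#' gollobDf(4, 10, 1)  # 11
#' @export
gollobDf <- function(g, e, n) {
  stopifnot(g >= 2, e >= 2)
  if (any(n < 1) || any(n > min(g, e) - 1))
    stop(sprintf("axis index must lie in 1..%d", min(g, e) - 1))
  as.integer(g + e - 1 - 2 * n)
}

#' @describeIn AmmiResult-class AMMI decomposition of one temperature's
#'   gene x tissue x replicate data.
#'
#' Cell means are computed per gene x tissue; gene and tissue main effects
#' are the marginal means minus the grand mean; the interaction residual
#' matrix z_ge = mean_ge - gene mean - tissue mean + grand mean is
#' decomposed by SVD. SS_IPCAn = r * lambda_n^2; axes beyond `nAxes` are
#' pooled into a Residual row. Every tested row is F-tested against the
#' pooled within-cell Error MS; IPCA axes carry Gollob df. Axis signs follow
#' the convention that the largest-magnitude tissue score on each axis is
#' positive.
#'
#' @param x an [ExpressionTable-class] with >= 2 replicate blocks at the
#'   requested temperature
#' @param temperature temperature label to analyze
#' @param nAxes number of IPCA axes to retain (default 2)
#' @param ... unused
#' @return an [AmmiResult-class]
#' @export
setMethod("ammiDecompose", "ExpressionTable",
          function(x, temperature, nAxes = 2L, ...) {
  d <- .subsetTemperature(x, temperature)
  r <- attr(d, "replicates")
  if (r < 2L)
    stop("AMMI needs >= 2 replicate blocks to form the Error stratum; ",
         "supply replicated data")
  g <- nlevels(d$gene); e <- nlevels(d$tissue)
  K <- min(g, e) - 1L
  nAxes <- as.integer(nAxes)
  if (nAxes < 1L || nAxes > K)
    stop(sprintf("nAxes must lie in 1..%d", K))

  m <- tapply(d$value, list(d$gene, d$tissue), mean)   # g x e cell means
  gm <- mean(m)
  alpha <- rowMeans(m) - gm
  beta <- colMeans(m) - gm
  z <- sweep(sweep(m, 1, rowMeans(m)), 2, colMeans(m)) + gm
  sv <- svd(z)
  lambda <- sv$d[seq_len(K)]
  u <- sv$u[, seq_len(K), drop = FALSE]
  v <- sv$v[, seq_len(K), drop = FALSE]
  # orient: largest-|.| tissue score positive per axis; null axes zeroed
  for (j in seq_len(K)) {
    if (lambda[j] <= 1e-12 * max(sv$d[1], 1)) { u[, j] <- 0; v[, j] <- 0; next }
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) { v[, j] <- -v[, j]; u[, j] <- -u[, j] }
  }
  dimnames(u) <- list(levels(d$gene), paste0("IPCA", seq_len(K)))
  dimnames(v) <- list(levels(d$tissue), paste0("IPCA", seq_len(K)))

  ssGene <- r * e * sum(alpha^2)
  ssTissue <- r * g * sum(beta^2)
  ssInt <- r * sum(z^2)
  ssTrt <- r * sum((m - gm)^2)
  ssTotal <- sum((d$value - mean(d$value))^2)
  ssError <- ssTotal - ssTrt
  ssAxes <- r * lambda^2
  retained <- seq_len(nAxes)
  ssResid <- ssInt - sum(ssAxes[retained])

  dfAxes <- gollobDf(g, e, retained)
  dfInt <- (g - 1L) * (e - 1L)
  dfResid <- dfInt - sum(dfAxes)
  dfError <- g * e * (r - 1L)
  src <- c("Total", "Treatment", "Gene", "Tissue", "Interaction",
           paste0("IPCA", retained), "Residual", "Error")
  df <- c(g * e * r - 1L, g * e - 1L, g - 1L, e - 1L, dfInt, dfAxes,
          dfResid, dfError)
  SS <- c(ssTotal, ssTrt, ssGene, ssTissue, ssInt, ssAxes[retained],
          max(ssResid, 0), ssError)
  MS <- ifelse(df > 0, SS / df, NA_real_)
  msErr <- ssError / dfError
  tested <- c(FALSE, TRUE, TRUE, TRUE, TRUE, rep(TRUE, nAxes), FALSE, FALSE)
  F <- ifelse(tested, MS / msErr, NA_real_)
  p <- ifelse(tested, stats::pf(F, df, dfError, lower.tail = FALSE), NA_real_)
  pctTotal <- c(NA, NA, ssGene, ssTissue, ssInt, rep(NA, nAxes), NA, NA) /
    ssTotal * 100
  pctInt <- c(rep(NA, 5), ssAxes[retained], max(ssResid, 0), NA) / ssInt * 100
  tab <- data.frame(source = src, df = as.integer(df), SS = SS, MS = MS,
                    F = F, p = p, pctTotal = pctTotal,
                    pctInteraction = pctInt, stringsAsFactors = FALSE)
  new("AmmiResult", anova = tab, singularValues = lambda, geneScores = u,
      tissueScores = v, nAxes = nAxes, replicates = as.integer(r),
      temperature = as.character(temperature), grandMean = gm,
      geneEffects = alpha, tissueEffects = beta)
})

#' @describeIn AmmiResult-class unit-norm gene singular vectors (columns
#'   IPCA1..IPCAK); multiply by `singularValues(x)^f` for display scalings.
#' @export
setMethod("geneScores", "AmmiResult", function(x, ...) x@geneScores)

#' @describeIn AmmiResult-class unit-norm tissue singular vectors
#' @export
setMethod("tissueScores", "AmmiResult", function(x, ...) x@tissueScores)

#' Effect-contribution profile across temperatures
#'
#' Collects, per temperature, the percentage of the total sum of squares
#' attributable to the genotype (gene) effect, the tissue effect, and the
#' genotype x tissue interaction — the series behind the contribution-trend
#' view of a multi-temperature AMMI analysis.
#'
#' @param results a single [AmmiResult-class] or a list of them
#' @return data.frame with columns temperature, genotypePct, tissuePct,
#'   interactionPct, ordered as supplied
#' @export
contributionProfile <- function(results) {
  if (is(results, "AmmiResult")) results <- list(results)
  stopifnot(length(results) >= 1,
            all(vapply(results, is, logical(1), "AmmiResult")))
  rows <- lapply(results, function(r) {
    a <- r@anova
    data.frame(temperature = r@temperature,
               genotypePct = a$pctTotal[a$source == "Gene"],
               tissuePct = a$pctTotal[a$source == "Tissue"],
               interactionPct = a$pctTotal[a$source == "Interaction"],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
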