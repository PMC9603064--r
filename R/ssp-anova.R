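## Classical closed-form balanced split-split-plot decomposition.
## Temperature is the main-plot factor, tissue the subplot factor, gene the
## sub-subplot factor; block x treatment interactions beyond the defined
## strata are pooled into those strata (standard SSP convention), giving
## exactly three error rows.

#' @describeIn SspAnovaTable-class fit the split-split-plot analysis of
#'   variance to a balanced replicate-level table.
#'
#' F ratios use the stratum-correct denominators: Temperature is tested
#' against the Main-plot error; Tissue and Temperature x Tissue against the
#' Split-plot error; Gene and every gene-bearing interaction against the
#' Split-split-plot error. Blocks are reported without an F test.
#' p-values are exact upper-tail F probabilities at full precision
#' (the display formatter floors them at 1e-7).
#'
#' @param x an [ExpressionTable-class], balanced, with >= 2 blocks and >= 2
#'   levels of each treatment factor
#' @param ... unused
#' @return an [SspAnovaTable-class]
#' @export
setMethod("fitSspAnova", "ExpressionTable", function(x, ...) {
  b <- isBalanced(x)
  if (!isTRUE(b)) stop("split-split-plot ANOVA requires a balanced design")
  d <- x@data
  k <- attr(b, "replicates")
  t <- nlevels(d$temperature); s <- nlevels(d$tissue); g <- nlevels(d$gene)
  if (k < 2L) stop("at least 2 replicate blocks required")
  dfs <- c(k - 1, t - 1, (k - 1) * (t - 1), s - 1, (t - 1) * (s - 1),
           t * (k - 1) * (s - 1), g - 1, (t - 1) * (g - 1),
           (s - 1) * (g - 1), (t - 1) * (s - 1) * (g - 1),
           t * s * (k - 1) * (g - 1))
  if (any(dfs == 0))
    stop("a variance stratum has zero degrees of freedom; ",
         "need >= 2 levels of every factor and >= 2 blocks")

  y <- d$value
  gm <- mean(y)
  m1 <- function(f1) tapply(y, d[[f1]], mean) - gm
  m2 <- function(f1, f2) {
    m <- tapply(y, list(d[[f1]], d[[f2]]), mean)
    sweep(sweep(m, 1, tapply(y, d[[f1]], mean)), 2,
          tapply(y, d[[f2]], mean)) + gm
  }
  ssB  <- t * s * g * sum(m1("block")^2)
  ssT  <- k * s * g * sum(m1("temperature")^2)
  ssMPE <- s * g * sum(m2("temperature", "block")^2)
  ssS  <- k * t * g * sum(m1("tissue")^2)
  ssTS <- k * g * sum(m2("temperature", "tissue")^2)
  # split-plot error: block x tissue variation within each temperature,
  # pooled over temperatures (absorbs block:tissue and block:temp:tissue)
  mIHK <- tapply(y, list(d$temperature, d$tissue, d$block), mean)
  mIH <- tapply(y, list(d$temperature, d$tissue), mean)
  mIK <- tapply(y, list(d$temperature, d$block), mean)
  mI <- tapply(y, d$temperature, mean)
  devSPE <- sweep(sweep(mIHK, c(1, 2), mIH), c(1, 3), mIK) +
    array(mI, dim(mIHK))
  ssSPE <- g * sum(devSPE^2)
  ssG  <- k * t * s * sum(m1("gene")^2)
  ssTG <- k * s * sum(m2("temperature", "gene")^2)
  ssSG <- k * t * sum(m2("tissue", "gene")^2)
  mIHJ <- tapply(y, list(d$temperature, d$tissue, d$gene), mean)
  mIJ <- tapply(y, list(d$temperature, d$gene), mean)
  mHJ <- tapply(y, list(d$tissue, d$gene), mean)
  mH <- tapply(y, d$tissue, mean)
  mJ <- tapply(y, d$gene, mean)
  devTSG <- mIHJ -
    array(rep(mIH, times = g), c(t, s, g)) -
    aperm(array(rep(mIJ, times = s), c(t, g, s)), c(1, 3, 2)) -
    aperm(array(rep(mHJ, times = t), c(s, g, t)), c(3, 1, 2)) +
    array(mI, c(t, s, g)) +
    aperm(array(rep(mH, times = t * g), c(s, t, g)), c(2, 1, 3)) +
    aperm(array(rep(mJ, times = t * s), c(g, t, s)), c(2, 3, 1)) - gm
  ssTSG <- k * sum(devTSG^2)
  ssTotal <- sum((y - gm)^2)
  ssSSPE <- ssTotal - (ssB + ssT + ssMPE + ssS + ssTS + ssSPE +
                       ssG + ssTG + ssSG + ssTSG)
  ssSSPE <- max(ssSSPE, 0)

  src <- c("Blocks", "Temperature", "Main-plot error", "Tissue",
           "Temperature x Tissue", "Split-plot error", "Gene",
           "Temperature x Gene", "Tissue x Gene",
           "Temperature x Tissue x Gene", "Split-split-plot error")
  SS <- c(ssB, ssT, ssMPE, ssS, ssTS, ssSPE, ssG, ssTG, ssSG, ssTSG, ssSSPE)
  MS <- SS / dfs
  # denominator stratum per row (NA = not tested)
  den <- c(NA, 3, NA, 6, 6, NA, 11, 11, 11, 11, NA)
  F <- ifelse(is.na(den), NA_real_, MS / MS[den])
  p <- ifelse(is.na(F), NA_real_, stats::pf(F, dfs, dfs[den], lower.tail = FALSE))
  tab <- data.frame(source = src, df = as.integer(dfs), SS = SS, MS = MS,
                    F = F, p = p, stringsAsFactors = FALSE)
  new("SspAnovaTable", table = tab, nObs = length(y))
})
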