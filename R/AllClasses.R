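## Central S4 containers. Replicate-level observations stay in long format
## (temperature, tissue, gene, block, value); wide gene x tissue matrices are
## always derived, never primary, so balance can be checked unambiguously.

.EXPR_COLS <- c("temperature", "tissue", "gene", "block", "value")

#' ExpressionTable: replicate-level relative expression observations
#'
#' Long-format container for a balanced (or to-be-checked) factorial of
#' relative expression values: one row per temperature x tissue x gene x
#' replicate block. Values are dimensionless relative-expression units
#' (e.g. 2^-ddCt output); the unit label is carried as metadata only.
#'
#' @slot data data.frame with columns temperature, tissue, gene, block, value.
#'   The first three are factors whose level order is the display order.
#' @slot unit single character, the expression unit label (metadata only).
#' @export
setClass("ExpressionTable",
  representation(data = "data.frame", unit = "character"))

setValidity("ExpressionTable", function(object) {
  d <- object@data
  msg <- character()
  if (!all(.EXPR_COLS %in% names(d)))
    msg <- c(msg, paste("data must have columns",
                        paste(.EXPR_COLS, collapse = ", ")))
  else {
    if (!is.numeric(d$value))
      msg <- c(msg, "value column must be numeric")
    else if (any(!is.finite(d$value)))
      msg <- c(msg, "all expression values must be finite")
    key <- interaction(d$temperature, d$tissue, d$gene, d$block, drop = TRUE)
    if (anyDuplicated(key))
      msg <- c(msg, sprintf("duplicated design cell at row %d",
                            which(duplicated(key))[1L]))
  }
  if (length(object@unit) != 1L)
    msg <- c(msg, "unit must be a single string")
  if (length(msg)) msg else TRUE
})

#' TwoWayMeans: gene x tissue cell-mean matrix at one temperature
#'
#' @slot means numeric matrix, genes in rows, tissues in columns.
#' @slot replicates integer, number of replicate blocks averaged per cell.
#' @slot temperature character, the temperature label the means belong to.
#' @slot unit character, expression unit label.
#' @export
setClass("TwoWayMeans",
  representation(means = "matrix", replicates = "integer",
                 temperature = "character", unit = "character"))

setValidity("TwoWayMeans", function(object) {
  m <- object@means
  msg <- character()
  if (!is.numeric(m) || any(!is.finite(m)))
    msg <- c(msg, "means must be a finite numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "means must carry gene rownames and tissue colnames")
  if (length(object@replicates) != 1L || object@replicates < 1L)
    msg <- c(msg, "replicates must be a single positive integer")
  if (length(msg)) msg else TRUE
})

#' SspAnovaTable: split-split-plot analysis of variance
#'
#' Ordered rows of the classical balanced split-split-plot decomposition:
#' Blocks, Temperature, Main-plot error, Tissue, Temperature x Tissue,
#' Split-plot error, Gene, the three gene-bearing interactions, and the
#' Split-split-plot error. F ratios use the stratum-correct denominators.
#'
#' @slot table data.frame with columns source, df, SS, MS, F, p.
#' @slot nObs integer, number of observations the fit used.
#' @export
setClass("SspAnovaTable",
  representation(table = "data.frame", nObs = "integer"))

setValidity("SspAnovaTable", function(object) {
  t <- object@table
  msg <- character()
  need <- c("source", "df", "SS", "MS", "F", "p")
  if (!all(need %in% names(t)))
    msg <- c(msg, "table must have columns source, df, SS, MS, F, p")
  else {
    if (any(t$SS < -1e-8)) msg <- c(msg, "sums of squares must be non-negative")
    if (sum(t$df) != object@nObs - 1L)
      msg <- c(msg, "degrees of freedom must sum to N - 1")
  }
  if (length(msg)) msg else TRUE
})

#' AmmiResult: additive main effects + multiplicative interaction decomposition
#'
#' Holds the per-temperature AMMI analysis: the additive ANOVA rows
#' (Total, Treatment, Gene, Tissue, Interaction, IPCA axes, Residual, Error),
#' the singular values of the doubly-centered interaction matrix, and
#' unit-norm gene/tissue singular vectors per axis. Sums of squares are on
#' the replicate-observation scale (means-based SS times r), so the Error
#' row with df g*e*(r-1) balances the Total.
#'
#' @slot anova data.frame with columns source, df, SS, MS, F, p,
#'   pctTotal, pctInteraction.
#' @slot singularValues all min(g,e)-1 singular values of the interaction
#'   matrix of cell means.
#' @slot geneScores g x K matrix of unit-norm gene singular vectors.
#' @slot tissueScores e x K matrix of unit-norm tissue singular vectors.
#' @slot nAxes integer, number of IPCA axes retained (rest pooled as Residual).
#' @slot replicates integer, replicate blocks per cell.
#' @slot temperature character label.
#' @slot grandMean numeric, grand mean of cell means.
#' @slot geneEffects named numeric, gene main-effect deviations.
#' @slot tissueEffects named numeric, tissue main-effect deviations.
#' @export
setClass("AmmiResult",
  representation(anova = "data.frame", singularValues = "numeric",
                 geneScores = "matrix", tissueScores = "matrix",
                 nAxes = "integer", replicates = "integer",
                 temperature = "character", grandMean = "numeric",
                 geneEffects = "numeric", tissueEffects = "numeric"))

setValidity("AmmiResult", function(object) {
  msg <- character()
  sv <- object@singularValues
  if (length(sv) > 1L && any(diff(sv) > 1e-8 * max(1, sv[1L])))
    msg <- c(msg, "singular values must be non-increasing")
  K <- length(sv)
  if (ncol(object@geneScores) != K || ncol(object@tissueScores) != K)
    msg <- c(msg, "score matrices must have one column per singular value")
  tol <- 1e-6 * max(1, max(abs(object@geneScores)))
  if (K && any(abs(colSums(object@geneScores)) > tol))
    msg <- c(msg, "gene scores must sum to zero on every axis")
  if (K && any(abs(colSums(object@tissueScores)) > tol))
    msg <- c(msg, "tissue scores must sum to zero on every axis")
  if (length(msg)) msg else TRUE
})

#' GgeResult: environment-centered SVD for GGE biplot geometry
#'
#' Tissue-(environment-)centered SVD of a gene x tissue cell-mean matrix,
#' with up to three retained axes and a singular-value partition applied:
#' gene scores are lambda^f * gamma, tissue scores lambda^(1-f) * delta,
#' with f = 0.5 (symmetric), 1 (genotype-focused) or 0 (environment-focused).
#' All planar biplot geometry uses the first two axes; distances from the
#' biplot origin use all retained axes.
#'
#' @slot singularValues retained singular values (NA when the object was
#'   built from externally supplied scores).
#' @slot geneScores g x k matrix of partitioned gene scores.
#' @slot tissueScores e x k matrix of partitioned tissue scores.
#' @slot partition "symmetric", "genotype" or "environment".
#' @slot varianceExplained fraction of centered sum of squares per retained
#'   axis.
#' @slot columnMeans tissue means removed by centering (mu + beta_e).
#' @slot temperature character label.
#' @export
setClass("GgeResult",
  representation(singularValues = "numeric", geneScores = "matrix",
                 tissueScores = "matrix", partition = "character",
                 varianceExplained = "numeric", columnMeans = "numeric",
                 temperature = "character"))

setValidity("GgeResult", function(object) {
  msg <- character()
  g <- object@geneScores
  if (ncol(g) != ncol(object@tissueScores))
    msg <- c(msg, "gene and tissue score matrices must agree in axis count")
  sv <- object@singularValues
  if (!all(is.na(sv)) && any(diff(sv) > 1e-8))
    msg <- c(msg, "singular values must be non-increasing")
  if (length(msg)) msg else TRUE
})

#' SectorAssignment: which-won-where geometry of a GGE biplot
#'
#' @slot vertices convex-hull genes in angular order.
#' @slot rayAngles angles (radians) of the sector boundary rays from the
#'   biplot origin, perpendicular to the hull edges.
#' @slot assignment data.frame (tissue, winner): the hull-vertex gene with
#'   the highest projection for each tissue.
#' @slot degenerate TRUE when the gene scores are collinear and the plane
#'   collapses to two half-plane sectors.
#' @export
setClass("SectorAssignment",
  representation(vertices = "character", rayAngles = "numeric",
                 assignment = "data.frame", degenerate = "logical"))

#' TwoWaySimSpec: generator spec for one-temperature gene x tissue data
#'
#' Parameterizes cell expectations mu + alpha_g + beta_e +
#' sum_n lambda_n gamma_gn delta_en with i.i.d. Gaussian (or lognormal)
#' replicate noise. Planted singular vectors are orthonormalized internally
#' (Gram-Schmidt against the constant vector and each other).
#'
#' @slot mu grand mean.
#' @slot geneEffects named, sum-to-zero gene deviations alpha_g.
#' @slot tissueEffects named, sum-to-zero tissue deviations beta_e.
#' @slot lambda non-increasing, non-negative singular values of the planted
#'   interaction.
#' @slot geneVectors g x n matrix of planted gene vectors (orthonormalized).
#' @slot tissueVectors e x n matrix of planted tissue vectors.
#' @slot sigma residual s.d. of replicate noise.
#' @slot replicates blocks per cell.
#' @slot noise "gaussian" or "lognormal" (lognormal exponentiates the linear
#'   predictor plus noise; ANOVA expectations then hold on the log scale).
#' @slot temperature label attached to the generated records.
#' @slot seed integer RNG seed.
#' @export
setClass("TwoWaySimSpec",
  representation(mu = "numeric", geneEffects = "numeric",
                 tissueEffects = "numeric", lambda = "numeric",
                 geneVectors = "matrix", tissueVectors = "matrix",
                 sigma = "numeric", replicates = "integer",
                 noise = "character", temperature = "character",
                 seed = "integer"))

.zeroSumOk <- function(v, tol = 1e-10) abs(sum(v)) <= tol * max(1, max(abs(v)))

setValidity("TwoWaySimSpec", function(object) {
  msg <- character()
  if (!.zeroSumOk(object@geneEffects))
    msg <- c(msg, "gene effects must sum to zero (tolerance 1e-10)")
  if (!.zeroSumOk(object@tissueEffects))
    msg <- c(msg, "tissue effects must sum to zero (tolerance 1e-10)")
  if (any(object@lambda < 0)) msg <- c(msg, "lambda must be non-negative")
  if (is.unsorted(rev(object@lambda)))
    msg <- c(msg, "lambda must be non-increasing")
  if (length(object@lambda) != ncol(object@geneVectors) ||
      length(object@lambda) != ncol(object@tissueVectors))
    msg <- c(msg, "one gene and tissue vector per lambda required")
  if (object@sigma < 0) msg <- c(msg, "sigma must be non-negative")
  if (object@replicates < 1L) msg <- c(msg, "replicates must be >= 1")
  if (!object@noise %in% c("gaussian", "lognormal"))
    msg <- c(msg, "noise must be 'gaussian' or 'lognormal'")
  if (length(msg)) msg else TRUE
})

#' SspSimSpec: generator spec for a split-split-plot experiment
#'
#' Fixed treatment effects (all sum-to-zero over every index) plus three
#' independent random error strata: a main-plot error shared within block x
#' temperature, a subplot error shared within block x temperature x tissue,
#' and a per-observation sub-subplot error.
#'
#' @slot mu grand mean.
#' @slot blocks number of complete replicate blocks.
#' @slot tempEffects,tissueEffects,geneEffects named sum-to-zero main effects.
#' @slot tempTissue,tempGene,tissueGene two-way interaction matrices,
#'   sum-to-zero over each index.
#' @slot tempTissueGene three-way interaction array (t x s x g), sum-to-zero
#'   over each index.
#' @slot sigmaF main-plot error s.d.
#' @slot sigmaG subplot error s.d.
#' @slot sigmaE sub-subplot (residual) error s.d.
#' @slot seed integer RNG seed.
#' @export
setClass("SspSimSpec",
  representation(mu = "numeric", blocks = "integer",
                 tempEffects = "numeric", tissueEffects = "numeric",
                 geneEffects = "numeric", tempTissue = "matrix",
                 tempGene = "matrix", tissueGene = "matrix",
                 tempTissueGene = "array", sigmaF = "numeric",
                 sigmaG = "numeric", sigmaE = "numeric", seed = "integer"))

.marginZeroOk <- function(a, tol = 1e-10) {
  sc <- max(1, max(abs(a)))
  nd <- length(dim(a))
  if (nd == 0L) return(abs(sum(a)) <= tol * sc)
  all(vapply(seq_len(nd), function(k) {
    other <- setdiff(seq_len(nd), k)
    m <- apply(a, other, sum)
    all(abs(m) <= tol * sc)
  }, logical(1)))
}

setValidity("SspSimSpec", function(object) {
  msg <- character()
  t <- length(object@tempEffects); s <- length(object@tissueEffects)
  g <- length(object@geneEffects)
  if (!.zeroSumOk(object@tempEffects) || !.zeroSumOk(object@tissueEffects) ||
      !.zeroSumOk(object@geneEffects))
    msg <- c(msg, "main effects must sum to zero (tolerance 1e-10)")
  if (!identical(dim(object@tempTissue), c(t, s)) ||
      !identical(dim(object@tempGene), c(t, g)) ||
      !identical(dim(object@tissueGene), c(s, g)) ||
      !identical(dim(object@tempTissueGene), c(t, s, g)))
    msg <- c(msg, "interaction array dimensions must match factor levels")
  else if (!.marginZeroOk(object@tempTissue) ||
           !.marginZeroOk(object@tempGene) ||
           !.marginZeroOk(object@tissueGene) ||
           !.marginZeroOk(object@tempTissueGene))
    msg <- c(msg, "interaction arrays must sum to zero over every index")
  if (object@blocks < 2L) msg <- c(msg, "at least 2 blocks required")
  if (any(c(object@sigmaF, object@sigmaG, object@sigmaE) < 0))
    msg <- c(msg, "error s.d. values must be non-negative")
  if (length(msg)) msg else TRUE
})

## ---- accessors ----

#' @describeIn ExpressionTable-class the long-format data.frame
#' @export
setMethod("exprData", "ExpressionTable", function(x) x@data)

#' @export
setMethod("exprUnit", "ExpressionTable", function(x) x@unit)

#' @export
setMethod("geneNames", "ExpressionTable", function(x) levels(x@data$gene))

#' @export
setMethod("tissueNames", "ExpressionTable", function(x) levels(x@data$tissue))

#' @export
setMethod("temperatureNames", "ExpressionTable",
          function(x) levels(x@data$temperature))

#' @export
setMethod("geneNames", "TwoWayMeans", function(x) rownames(x@means))

#' @export
setMethod("tissueNames", "TwoWayMeans", function(x) colnames(x@means))

#' @export
setMethod("anovaTable", "SspAnovaTable", function(x) x@table)

#' @export
setMethod("anovaTable", "AmmiResult", function(x) x@anova)

#' @export
setMethod("singularValues", "AmmiResult", function(x) x@singularValues)

#' @export
setMethod("singularValues", "GgeResult", function(x) x@singularValues)

#' @export
setMethod("varianceExplained", "GgeResult", function(x) x@varianceExplained)

#' Cell-mean matrix of a TwoWayMeans object
#'
#' @param object a TwoWayMeans
#' @return numeric gene x tissue matrix
#' @export
meansMatrix <- function(object) {
  stopifnot(is(object, "TwoWayMeans"))
  object@means
}

#' Replicate count behind a TwoWayMeans object
#' @param object a TwoWayMeans
#' @export
replicateCount <- function(object) {
  stopifnot(is(object, "TwoWayMeans"))
  object@replicates
}

## ---- show methods ----

setMethod("show", "ExpressionTable", function(object) {
  d <- object@data
  cat(sprintf("ExpressionTable: %d observations [unit: %s]\n",
              nrow(d), object@unit))
  cat(sprintf("  %d temperature(s) x %d tissue(s) x %d gene(s)\n",
              nlevels(d$temperature), nlevels(d$tissue), nlevels(d$gene)))
  b <- isBalanced(object)
  cat(if (isTRUE(b)) sprintf("  balanced, %d replicate block(s) per cell\n",
                             attr(b, "replicates"))
      else "  NOT balanced\n")
})

setMethod("show", "TwoWayMeans", function(object) {
  cat(sprintf("TwoWayMeans at %s: %d gene(s) x %d tissue(s), r = %d\n",
              object@temperature, nrow(object@means), ncol(object@means),
              object@replicates))
  print(round(object@means, 4))
})

setMethod("show", "SspAnovaTable", function(object) {
  cat("Split-split-plot analysis of variance\n")
  print(formatAnova(object@table), row.names = FALSE)
})

setMethod("show", "AmmiResult", function(object) {
  cat(sprintf("AMMI decomposition at %s (%d IPCA axes retained)\n",
              object@temperature, object@nAxes))
  print(formatAnova(object@anova), row.names = FALSE)
})

setMethod("show", "GgeResult", function(object) {
  cat(sprintf("GGE decomposition at %s [%s partition]\n",
              object@temperature, object@partition))
  ve <- object@varianceExplained
  if (length(ve) && !all(is.na(ve)))
    cat(sprintf("  variance explained: %s\n",
                paste(sprintf("PC%d %.1f%%", seq_along(ve), 100 * ve),
                      collapse = ", ")))
  cat(sprintf("  %d gene(s), %d tissue(s), %d axes\n",
              nrow(object@geneScores), nrow(object@tissueScores),
              ncol(object@geneScores)))
})

setMethod("show", "SectorAssignment", function(object) {
  if (object@degenerate)
    cat("Which-won-where (degenerate: collinear gene scores, two half-planes)\n")
  else
    cat(sprintf("Which-won-where: hull vertices %s\n",
                paste(object@vertices, collapse = ", ")))
  print(object@assignment, row.names = FALSE)
})
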