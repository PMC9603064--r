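## Synthetic expression generators with known ground truth: additive main
## effects, planted low-rank multiplicative interaction, and (for the
## split-split-plot layout) three independent error strata.

.PPAR_GENES <- c("PPARa1", "PPARa2", "PPARb", "PPARg")
.TISSUES <- c("intestine", "liver", "gill", "heart", "kidney",
              "brain", "muscle", "spleen", "skin", "stomach")
.TEMPERATURES <- c("14", "20", "23", "25", "28")

## zero-sum, unit-norm columns orthogonal to 1 and to each other
.gramSchmidt <- function(v, tol = 1e-12) {
  n <- nrow(v)
  basis <- matrix(rep(1 / sqrt(n), n), ncol = 1)  # project out the mean
  out <- matrix(0, n, ncol(v))
  for (j in seq_len(ncol(v))) {
    w <- v[, j]
    for (k in seq_len(ncol(basis))) w <- w - sum(w * basis[, k]) * basis[, k]
    nw <- sqrt(sum(w^2))
    if (nw < tol)
      stop("planted vectors are collinear after centering; cannot orthonormalize")
    w <- w / nw
    basis <- cbind(basis, w)
    out[, j] <- w
  }
  out
}

## deterministic zero-sum orthonormal default vectors (Helmert contrasts)
.helmertVectors <- function(n, k) {
  h <- stats::contr.helmert(n)[, seq_len(k), drop = FALSE]
  apply(h, 2, function(v) v / sqrt(sum(v^2)))
}

.centeredSeq <- function(n, scale) {
  v <- seq_len(n) - (n + 1) / 2
  scale * v / max(abs(v))
}

#' Simulation spec for a one-temperature gene x tissue table
#'
#' Defaults emulate the study design this package targets: 4 PPAR genes x
#' 10 tissues x 3 replicate blocks, a grand mean of 1.5 relative units,
#' modest sum-to-zero main effects, and a rank-2 planted interaction
#' (lambda = 0.8, 0.4) on deterministic orthonormal contrast vectors.
#'
#' @param genes,tissues factor labels
#' @param mu grand mean (relative expression units)
#' @param geneEffects,tissueEffects sum-to-zero deviations; defaults are
#'   centered linear ramps of half-amplitude 0.4 (genes) and 0.6 (tissues)
#' @param lambda planted interaction singular values, non-increasing
#' @param geneVectors,tissueVectors planted singular vectors, one column per
#'   lambda; orthonormalized internally
#' @param sigma replicate noise s.d. (default 0.35)
#' @param replicates blocks per cell (default 3)
#' @param noise "gaussian" (default) or "lognormal"
#' @param temperature label attached to the generated rows
#' @param seed RNG seed
#' @return a [TwoWaySimSpec-class]
#' @export
twoWaySimSpec <- function(genes = .PPAR_GENES, tissues = .TISSUES,
                          mu = 1.5,
                          geneEffects = .centeredSeq(length(genes), 0.4),
                          tissueEffects = .centeredSeq(length(tissues), 0.6),
                          lambda = c(0.8, 0.4),
                          geneVectors = .helmertVectors(length(genes),
                                                        length(lambda)),
                          tissueVectors = .helmertVectors(length(tissues),
                                                          length(lambda)),
                          sigma = 0.35, replicates = 3L,
                          noise = "gaussian", temperature = "sim",
                          seed = 1L) {
  names(geneEffects) <- genes
  names(tissueEffects) <- tissues
  geneVectors <- as.matrix(geneVectors)
  tissueVectors <- as.matrix(tissueVectors)
  if (length(lambda)) {
    geneVectors <- .gramSchmidt(geneVectors)
    tissueVectors <- .gramSchmidt(tissueVectors)
  }
  rownames(geneVectors) <- genes
  rownames(tissueVectors) <- tissues
  new("TwoWaySimSpec", mu = mu, geneEffects = geneEffects,
      tissueEffects = tissueEffects, lambda = as.numeric(lambda),
      geneVectors = geneVectors, tissueVectors = tissueVectors,
      sigma = sigma, replicates = as.integer(replicates), noise = noise,
      temperature = temperature, seed = as.integer(seed))
}

#' Expected cell means of a two-way simulation spec
#' @param spec a [TwoWaySimSpec-class]
#' @return gene x tissue matrix of expectations
#' @export
expectedCellMeans <- function(spec) {
  stopifnot(is(spec, "TwoWaySimSpec"))
  g <- length(spec@geneEffects); e <- length(spec@tissueEffects)
  m <- matrix(spec@mu, g, e) + outer(spec@geneEffects, spec@tissueEffects, "+")
  if (length(spec@lambda))
    m <- m + spec@geneVectors %*% diag(spec@lambda, length(spec@lambda)) %*%
      t(spec@tissueVectors)
  dimnames(m) <- list(names(spec@geneEffects), names(spec@tissueEffects))
  m
}

#' @describeIn twoWaySimSpec generate the replicate-level table
#' @param spec a [TwoWaySimSpec-class] or [SspSimSpec-class]
#' @param ... unused
#' @export
setMethod("simulateExpression", "TwoWaySimSpec", function(spec, ...) {
  validObject(spec)
  mu <- expectedCellMeans(spec)
  genes <- rownames(mu); tissues <- colnames(mu)
  r <- spec@replicates
  d <- expand.grid(block = seq_len(r), gene = genes, tissue = tissues,
                   temperature = spec@temperature, stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  eta <- mu[cbind(match(d$gene, genes), match(d$tissue, tissues))]
  set.seed(spec@seed)
  eps <- stats::rnorm(nrow(d), 0, spec@sigma)
  d$value <- if (spec@noise == "lognormal") exp(eta + eps) else eta + eps
  d$gene <- factor(d$gene, levels = genes)
  d$tissue <- factor(d$tissue, levels = tissues)
  if (any(d$value < 0))
    warning("generator produced negative expression values")
  ExpressionTable(d)
})

#' Simulation spec for a split-split-plot experiment
#'
#' Defaults emulate the full study layout: 3 blocks x 5 temperatures x
#' 10 tissues x 4 genes with deterministic sum-to-zero effect patterns and
#' stratified noise of realistic replicated-qPCR magnitude
#' (sigmaF = 0.12, sigmaG = 0.1, sigmaE = 0.5).
#'
#' Interaction arrays default to separable products of the main-effect
#' patterns (scaled), which satisfy the every-index zero-sum constraint by
#' construction.
#'
#' @param temperatures,tissues,genes factor labels
#' @param blocks number of complete replicate blocks (>= 2)
#' @param mu grand mean
#' @param tempEffects,tissueEffects,geneEffects sum-to-zero main effects
#' @param tempTissue,tempGene,tissueGene,tempTissueGene interaction arrays,
#'   sum-to-zero over every index
#' @param sigmaF,sigmaG,sigmaE main-plot, subplot and sub-subplot error s.d.
#' @param seed RNG seed
#' @return an [SspSimSpec-class]
#' @export
sspSimSpec <- function(temperatures = .TEMPERATURES, tissues = .TISSUES,
                       genes = .PPAR_GENES, blocks = 3L, mu = 1.6,
                       tempEffects = .centeredSeq(length(temperatures), 0.35),
                       tissueEffects = .centeredSeq(length(tissues), 0.7),
                       geneEffects = .centeredSeq(length(genes), 0.5),
                       tempTissue = 0.8 * outer(tempEffects, tissueEffects),
                       tempGene = 0.9 * outer(tempEffects, geneEffects),
                       tissueGene = 0.7 * outer(tissueEffects, geneEffects),
                       tempTissueGene = 0.5 * outer(outer(tempEffects,
                                                          tissueEffects),
                                                    geneEffects),
                       sigmaF = 0.12, sigmaG = 0.1, sigmaE = 0.5,
                       seed = 1L) {
  names(tempEffects) <- temperatures
  names(tissueEffects) <- tissues
  names(geneEffects) <- genes
  new("SspSimSpec", mu = mu, blocks = as.integer(blocks),
      tempEffects = tempEffects, tissueEffects = tissueEffects,
      geneEffects = geneEffects, tempTissue = as.matrix(tempTissue),
      tempGene = as.matrix(tempGene), tissueGene = as.matrix(tissueGene),
      tempTissueGene = tempTissueGene, sigmaF = sigmaF, sigmaG = sigmaG,
      sigmaE = sigmaE, seed = as.integer(seed))
}

#' @describeIn sspSimSpec generate the replicate-level table with the three
#'   error draws placed at the correct strata: the main-plot error is shared
#'   within block x temperature, the subplot error within block x
#'   temperature x tissue, and the sub-subplot error is per observation.
#' @export
setMethod("simulateExpression", "SspSimSpec", function(spec, ...) {
  validObject(spec)
  temps <- names(spec@tempEffects); tissues <- names(spec@tissueEffects)
  genes <- names(spec@geneEffects)
  t <- length(temps); s <- length(tissues); g <- length(genes)
  k <- spec@blocks
  d <- expand.grid(block = seq_len(k), gene = genes, tissue = tissues,
                   temperature = temps, stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  ti <- match(d$temperature, temps); si <- match(d$tissue, tissues)
  gi <- match(d$gene, genes)
  eta <- spec@mu + spec@tempEffects[ti] + spec@tissueEffects[si] +
    spec@geneEffects[gi] + spec@tempTissue[cbind(ti, si)] +
    spec@tempGene[cbind(ti, gi)] + spec@tissueGene[cbind(si, gi)] +
    spec@tempTissueGene[cbind(ti, si, gi)]
  set.seed(spec@seed)
  f <- matrix(stats::rnorm(t * k, 0, spec@sigmaF), t, k)
  gErr <- array(stats::rnorm(t * s * k, 0, spec@sigmaG), c(t, s, k))
  e <- stats::rnorm(nrow(d), 0, spec@sigmaE)
  d$value <- as.numeric(eta) + f[cbind(ti, d$block)] +
    gErr[cbind(ti, si, d$block)] + e
  d$temperature <- factor(d$temperature, levels = temps)
  d$tissue <- factor(d$tissue, levels = tissues)
  d$gene <- factor(d$gene, levels = genes)
  if (any(d$value < 0))
    warning("generator produced negative expression values")
  ExpressionTable(d)
})

#' Write a simulation spec as a config file
#'
#' Serializes the spec as JSON (or YAML when the yaml package is available
#' and the path ends in .yml/.yaml) so runs can be reproduced from disk.
#'
#' @param spec a [TwoWaySimSpec-class] or [SspSimSpec-class]
#' @param file output path
#' @return `file`, invisibly
#' @export
writeSimSpec <- function(spec, file) {
  slots <- slotNames(class(spec))
  lst <- lapply(slots, function(s) slot(spec, s))
  names(lst) <- slots
  lst$class <- as.character(class(spec))
  # factor labels stored explicitly (JSON/YAML round-trips drop names)
  if (is(spec, "TwoWaySimSpec")) {
    lst$genes <- names(spec@geneEffects)
    lst$tissues <- names(spec@tissueEffects)
  } else {
    lst$temperatures <- names(spec@tempEffects)
    lst$tissues <- names(spec@tissueEffects)
    lst$genes <- names(spec@geneEffects)
  }
  if (grepl("\\.ya?ml$", file)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML output; use a .json path")
    writeLines(yaml::as.yaml(lapply(lst, .stripDim)), file)
  } else {
    jsonlite::write_json(lapply(lst, .stripDim), file, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(file)
}

.stripDim <- function(x) {
  if (is.array(x) && length(dim(x)) >= 2)
    list(values = as.numeric(x), dim_ = dim(x))
  else x
}

#' Read a simulation spec config file written by [writeSimSpec()]
#' @param file path to a .json/.yml spec file
#' @return the reconstructed spec object
#' @export
readSimSpec <- function(file) {
  lst <- if (grepl("\\.ya?ml$", file)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required to read YAML specs")
    yaml::read_yaml(file)
  } else jsonlite::read_json(file, simplifyVector = TRUE)
  cls <- lst$class
  lst$class <- NULL
  restore <- function(x) {
    if (is.list(x) && !is.null(x$dim_))
      array(as.numeric(unlist(x$values)), dim = as.integer(x$dim_))
    else x
  }
  lst <- lapply(lst, restore)
  if (cls == "TwoWaySimSpec") {
    twoWaySimSpec(
      genes = unlist(lst$genes), tissues = unlist(lst$tissues),
      mu = lst$mu, geneEffects = unlist(lst$geneEffects),
      tissueEffects = unlist(lst$tissueEffects),
      lambda = as.numeric(unlist(lst$lambda)),
      geneVectors = .asMatrix(lst$geneVectors, length(lst$genes)),
      tissueVectors = .asMatrix(lst$tissueVectors, length(lst$tissues)),
      sigma = lst$sigma, replicates = lst$replicates, noise = lst$noise,
      temperature = lst$temperature, seed = lst$seed)
  } else if (cls == "SspSimSpec") {
    t <- length(lst$temperatures); s <- length(lst$tissues)
    g <- length(lst$genes)
    sspSimSpec(
      temperatures = unlist(lst$temperatures), tissues = unlist(lst$tissues),
      genes = unlist(lst$genes), blocks = lst$blocks, mu = lst$mu,
      tempEffects = unlist(lst$tempEffects),
      tissueEffects = unlist(lst$tissueEffects),
      geneEffects = unlist(lst$geneEffects),
      tempTissue = .asMatrix(lst$tempTissue, t),
      tempGene = .asMatrix(lst$tempGene, t),
      tissueGene = .asMatrix(lst$tissueGene, s),
      tempTissueGene = array(unlist(lst$tempTissueGene), c(t, s, g)),
      sigmaF = lst$sigmaF, sigmaG = lst$sigmaG, sigmaE = lst$sigmaE,
      seed = lst$seed)
  } else stop("unknown spec class in file: ", cls)
}

.asMatrix <- function(x, nrow) {
  if (is.matrix(x)) return(x)
  matrix(unlist(x), nrow = nrow)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
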