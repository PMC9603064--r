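## GGE biplot analysis: environment-centered SVD of the gene x tissue
## cell-mean matrix (centering removes mu + beta_e, leaving G + GE), three
## retained axes for distances, planar (PC1-PC2) biplot geometry.

.PARTITION_F <- c(symmetric = 0.5, genotype = 1, environment = 0)

#' @describeIn GgeResult-class environment-centered SVD of a cell-mean
#'   matrix
#'
#' Each tissue column is centered by its mean; the SVD of the centered
#' matrix is computed and up to three axes are retained. The singular-value
#' partition exponent f scales gene scores by lambda^f and tissue scores by
#' lambda^(1-f) (f = 0.5 symmetric default, 1 genotype-focused,
#' 0 environment-focused); gene-score x tissue-score inner products are
#' independent of f. Axis signs follow the convention that the
#' largest-magnitude tissue score per axis is positive. An all-equal matrix
#' is not an error: all singular values (and scores) are zero.
#'
#' @param x a [TwoWayMeans-class] or a numeric gene x tissue matrix with
#'   dimnames
#' @param partition "symmetric", "genotype" or "environment"
#' @param ... unused
#' @return a [GgeResult-class]
#' @export
setMethod("ggeDecompose", "TwoWayMeans", function(x, partition = "symmetric",
                                                  ...) {
  res <- ggeDecompose(x@means, partition = partition)
  res@temperature <- x@temperature
  res
})

#' @describeIn GgeResult-class method for a plain gene x tissue matrix
#' @export
setMethod("ggeDecompose", "matrix", function(x, partition = "symmetric",
                                             ...) {
  partition <- match.arg(partition, names(.PARTITION_F))
  f <- .PARTITION_F[[partition]]
  stopifnot(nrow(x) >= 2, ncol(x) >= 2, all(is.finite(x)))
  cm <- colMeans(x)
  z <- sweep(x, 2, cm)
  k <- min(3L, nrow(x) - 1L, ncol(x))
  sv <- svd(z)
  lambda <- sv$d[seq_len(k)]
  u <- sv$u[, seq_len(k), drop = FALSE]
  v <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (lambda[j] <= 1e-12 * max(sv$d[1], 1)) { # null axis: zero the scores
      u[, j] <- 0; v[, j] <- 0; next
    }
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) { v[, j] <- -v[, j]; u[, j] <- -u[, j] }
  }
  gs <- sweep(u, 2, lambda^f, "*")
  ts <- sweep(v, 2, lambda^(1 - f), "*")
  ax <- paste0("PC", seq_len(k))
  dimnames(gs) <- list(rownames(x), ax)
  dimnames(ts) <- list(colnames(x), ax)
  tot <- sum(sv$d^2)
  ve <- if (tot > 0) lambda^2 / tot else rep(0, k)
  new("GgeResult", singularValues = lambda, geneScores = gs,
      tissueScores = ts, partition = partition, varianceExplained = ve,
      columnMeans = cm, temperature = "unspecified")
})

#' Assemble a GgeResult from externally supplied scores
#'
#' Builds the geometry object directly from partitioned gene and tissue
#' scores (for example scores printed in a published table, whose
#' singular-value partition may be unknown). All rank-based outputs
#' (which-won-where, mean-versus-stability, ideal-point rankings, distances)
#' are computable from the scores alone.
#'
#' @param geneScores g x k numeric matrix (k <= 3), genes in rownames
#' @param tissueScores e x k numeric matrix, tissues in rownames
#' @param temperature optional label
#' @return a [GgeResult-class] with NA singular values
#' @export
ggeFromScores <- function(geneScores, tissueScores,
                          temperature = "unspecified") {
  geneScores <- as.matrix(geneScores)
  tissueScores <- as.matrix(tissueScores)
  stopifnot(ncol(geneScores) == ncol(tissueScores),
            all(is.finite(geneScores)), all(is.finite(tissueScores)))
  new("GgeResult", singularValues = rep(NA_real_, ncol(geneScores)),
      geneScores = geneScores, tissueScores = tissueScores,
      partition = "external", varianceExplained = rep(NA_real_,
                                                      ncol(geneScores)),
      columnMeans = numeric(), temperature = as.character(temperature))
}

#' @describeIn GgeResult-class partitioned gene scores
#' @param x a GgeResult
#' @param ... unused
#' @export
setMethod("geneScores", "GgeResult", function(x, ...) x@geneScores)

#' @describeIn GgeResult-class partitioned tissue scores
#' @export
setMethod("tissueScores", "GgeResult", function(x, ...) x@tissueScores)

#' Euclidean distance from the biplot center
#'
#' @param scores numeric vector of axis scores, or a matrix with one row
#'   per entry (up to three axes)
#' @return per-entry Euclidean norm sqrt(s1^2 + s2^2 + s3^2)
#' @examples
#' distanceFromCenter(c(2.7550, -0.2784, 0.0241))
#' @export
distanceFromCenter <- function(scores) {
  if (is.null(dim(scores))) return(sqrt(sum(scores^2)))
  sqrt(rowSums(scores^2))
}

.planar <- function(m) m[, seq_len(min(2L, ncol(m))), drop = FALSE]

#' @describeIn GgeResult-class pairwise tissue-vector geometry on the
#'   PC1-PC2 plane: the cosine of the angle between two tissue vectors
#'   approximates the correlation of gene-expression rankings in those
#'   tissues, and the vector length measures the tissue's ability to
#'   discriminate among genes. Zero-length vectors are flagged (`degenerate`)
#'   and their angles set to NA rather than throwing.
#' @return for `tissueRelationships`: list with `cosine` and `angle`
#'   (degrees) matrices, `length` per tissue, and `degenerate` logical
#' @export
setMethod("tissueRelationships", "GgeResult", function(x) {
  s <- .planar(x@tissueScores)
  len <- sqrt(rowSums(s^2))
  degenerate <- len <= 1e-12 * max(len, 1)
  n <- nrow(s)
  cosine <- matrix(NA_real_, n, n, dimnames = list(rownames(s), rownames(s)))
  ok <- !degenerate
  if (any(ok)) {
    u <- s[ok, , drop = FALSE] / len[ok]
    cc <- tcrossprod(u)
    cc <- pmin(pmax(cc, -1), 1)
    cosine[ok, ok] <- cc
  }
  list(cosine = cosine, angle = acos(cosine) * 180 / pi, length = len,
       degenerate = degenerate)
})

## angular which-won-where machinery -----------------------------------------

#' @describeIn SectorAssignment-class which-won-where sector geometry
#'
#' Computes the convex hull of the gene PC1-PC2 scores; sector boundaries
#' are the rays from the origin perpendicular to the hull edges; each
#' tissue's winning gene is the hull vertex whose projection onto the
#' tissue vector is maximal (ties broken by gene label order, an arbitrary
#' documented convention). When all gene scores are collinear the plane
#' degenerates into two half-plane sectors split by the perpendicular of
#' the common direction.
#'
#' @param x a [GgeResult-class]
#' @param ... unused
#' @return a [SectorAssignment-class]
#' @export
setMethod("whichWonWhere", "GgeResult", function(x, ...) {
  gs <- .planar(x@geneScores)
  ts <- .planar(x@tissueScores)
  if (ncol(gs) < 2) {  # single axis: trivially collinear
    gs <- cbind(gs, 0); ts <- cbind(ts, 0)
  }
  genes <- rownames(gs); tissues <- rownames(ts)
  ctr <- sweep(gs, 2, colMeans(gs))
  collinear <- nrow(gs) < 3 ||
    svd(ctr)$d[2] <= 1e-9 * max(svd(ctr)$d[1], 1)
  if (collinear) {
    # two half-planes along the dominant direction
    dir <- svd(ctr)$v[, 1]
    proj <- as.numeric(gs %*% dir)
    lo <- genes[which.min(proj)]; hi <- genes[which.max(proj)]
    tProj <- as.numeric(ts %*% dir)
    winner <- ifelse(tProj >= 0, hi, lo)
    return(new("SectorAssignment", vertices = c(hi, lo),
               rayAngles = atan2(-dir[1], dir[2]) + c(0, pi),
               assignment = data.frame(tissue = tissues, winner = winner,
                                       stringsAsFactors = FALSE),
               degenerate = TRUE))
  }
  hull <- rev(grDevices::chull(gs[, 1], gs[, 2]))   # counterclockwise
  vertices <- genes[hull]
  hs <- gs[hull, , drop = FALSE]
  nh <- nrow(hs)
  # boundary ray between adjacent vertices A, B: direction d with
  # d.(A - B) = 0, oriented toward the dominance boundary (max d.(A + B))
  rayAngles <- vapply(seq_len(nh), function(i) {
    a <- hs[i, ]; b <- hs[i %% nh + 1, ]
    edge <- a - b
    d1 <- c(-edge[2], edge[1]); d2 <- -d1
    d <- if (sum(d1 * (a + b)) >= sum(d2 * (a + b))) d1 else d2
    atan2(d[2], d[1])
  }, numeric(1))
  proj <- ts %*% t(hs)             # tissues x hull vertices
  winner <- apply(proj, 1, function(p) {
    cand <- vertices[p >= max(p) - 1e-12]
    sort(cand)[1]                  # ties broken by gene label order
  })
  new("SectorAssignment", vertices = vertices, rayAngles = rayAngles,
      assignment = data.frame(tissue = tissues, winner = winner,
                              stringsAsFactors = FALSE),
      degenerate = FALSE)
})

#' @describeIn SectorAssignment-class per-sector winning genes
#' @param object a SectorAssignment
#' @export
sectorWinners <- function(object) {
  stopifnot(is(object, "SectorAssignment"))
  sp <- split(object@assignment$tissue, object@assignment$winner)
  data.frame(winner = names(sp),
             tissues = vapply(sp, paste, character(1), collapse = ", "),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @describeIn GgeResult-class mean performance versus stability
#'
#' The average-environment axis is the unit vector along the mean of the
#' tissue PC1-PC2 scores. A gene's projection onto it approximates its mean
#' expression across tissues; the magnitude of the orthogonal component
#' measures instability of its expression across tissues. Genes are ranked
#' by descending projection (high expression) and ascending instability
#' (stable expression).
#'
#' @return for `meanVsStability`: list with `axis` (unit vector), `table`
#'   (gene, meanProjection, instability), `highExpression` and `stability`
#'   ranked gene vectors
#' @export
setMethod("meanVsStability", "GgeResult", function(x) {
  gs <- .planar(x@geneScores)
  ts <- .planar(x@tissueScores)
  if (ncol(gs) < 2) { gs <- cbind(gs, 0); ts <- cbind(ts, 0) }
  a <- colMeans(ts)
  na <- sqrt(sum(a^2))
  if (na <= 1e-12)
    stop("average-environment axis undefined: mean tissue vector is zero")
  a <- a / na
  proj <- as.numeric(gs %*% a)
  orth <- gs - outer(proj, a)
  instab <- sqrt(rowSums(orth^2))
  genes <- rownames(gs)
  tab <- data.frame(gene = genes, meanProjection = proj, instability = instab,
                    stringsAsFactors = FALSE, row.names = NULL)
  list(axis = a, table = tab,
       highExpression = genes[order(-proj, genes)],
       stability = genes[order(instab, genes)])
})

#' @describeIn GgeResult-class comprehensive (ideal-point) ranking
#'
#' The ideal point sits on the average-environment axis at the maximum gene
#' projection with zero instability; genes are ranked by ascending planar
#' distance to it, jointly rewarding high and stable expression (the
#' concentric-circles view).
#'
#' @return for `idealPointRanking`: list with `idealPoint` (PC1-PC2
#'   coordinates), `table` (gene, distance), `comprehensive` ranked genes
#' @export
setMethod("idealPointRanking", "GgeResult", function(x) {
  mvs <- meanVsStability(x)
  gs <- .planar(x@geneScores)
  if (ncol(gs) < 2) gs <- cbind(gs, 0)
  ideal <- max(mvs$table$meanProjection) * mvs$axis
  dist <- sqrt(rowSums(sweep(gs, 2, ideal)^2))
  genes <- rownames(gs)
  list(idealPoint = ideal,
       table = data.frame(gene = genes, distance = dist,
                          stringsAsFactors = FALSE, row.names = NULL),
       comprehensive = genes[order(dist, genes)])
})

#' @describeIn GgeResult-class the three gene rankings as one table
#' @return for `ggeRankings`: data.frame with columns rank, highExpression,
#'   stableExpression, comprehensive
#' @export
setMethod("ggeRankings", "GgeResult", function(x) {
  mvs <- meanVsStability(x)
  ipr <- idealPointRanking(x)
  data.frame(rank = seq_along(mvs$highExpression),
             highExpression = mvs$highExpression,
             stableExpression = mvs$stability,
             comprehensive = ipr$comprehensive,
             stringsAsFactors = FALSE)
})

#' Render GGE biplot views as SVG
#'
#' Optional rendering of the four standard views; the geometry objects, not
#' the images, are the tested surface of the package.
#'
#' @param x a [GgeResult-class]
#' @param file output SVG path
#' @param view one of "relationships", "which-won-where", "mean-stability",
#'   "concentric"
#' @return `file`, invisibly
#' @export
plotBiplot <- function(x, file,
                       view = c("relationships", "which-won-where",
                                "mean-stability", "concentric")) {
  view <- match.arg(view)
  gs <- .planar(geneScores(x)); ts <- .planar(tissueScores(x))
  grDevices::svg(file)
  on.exit(grDevices::dev.off())
  lim <- range(c(gs, ts, 0)) * 1.15
  plot(NA, xlim = lim, ylim = lim, asp = 1, xlab = "PC1", ylab = "PC2",
       main = paste("GGE biplot:", view))
  abline(h = 0, v = 0, col = "grey80")
  if (view == "relationships")
    segments(0, 0, ts[, 1], ts[, 2], col = "steelblue")
  if (view == "which-won-where") {
    www <- whichWonWhere(x)
    if (!www@degenerate) {
      hullIdx <- match(www@vertices, rownames(gs))
      polygon(gs[hullIdx, 1], gs[hullIdx, 2], border = "grey40")
      rr <- max(abs(lim))
      segments(0, 0, rr * cos(www@rayAngles), rr * sin(www@rayAngles),
               lty = 2, col = "grey40")
    }
  }
  if (view %in% c("mean-stability", "concentric")) {
    a <- meanVsStability(x)$axis
    rr <- max(abs(lim))
    segments(-rr * a[1], -rr * a[2], rr * a[1], rr * a[2], col = "grey40")
    if (view == "concentric") {
      ip <- idealPointRanking(x)$idealPoint
      symbols(rep(ip[1], 4), rep(ip[2], 4),
              circles = max(abs(lim)) * (1:4) / 8,
              add = TRUE, inches = FALSE, fg = "grey70")
    }
  }
  points(ts, pch = 4, col = "steelblue")
  text(ts, labels = rownames(ts), pos = 3, cex = 0.7, col = "steelblue")
  points(gs, pch = 19, col = "firebrick")
  text(gs, labels = rownames(gs), pos = 3, cex = 0.8, col = "firebrick")
  invisible(file)
}
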