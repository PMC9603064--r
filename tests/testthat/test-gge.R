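# deterministic rank-2 gene x tissue mean matrix with known G+GE structure
plantedMeans <- function(seed = 1, g = 4, e = 10, rank = 2) {
  set.seed(seed)
  gs <- scale(matrix(rnorm(g * rank), g, rank), scale = FALSE)  # zero-sum
  ts <- matrix(rnorm(e * rank), e, rank)
  beta <- rnorm(e)
  m <- sweep(1.5 + gs %*% t(ts), 2, beta, "+")
  dimnames(m) <- list(paste0("G", seq_len(g)), paste0("E", seq_len(e)))
  list(m = m, centered = gs %*% t(ts))
}

test_that("environment-centered SVD reconstructs and matches an eigen oracle", {
  set.seed(33)
  m <- matrix(rnorm(40, 2), 4, 10,
              dimnames = list(paste0("G", 1:4), paste0("E", 1:10)))
  res <- ggeDecompose(m)
  z <- sweep(m, 2, colMeans(m))
  gs <- geneScores(res); ts <- tissueScores(res)
  # 3 axes are complete for 4 genes: inner products rebuild the centered matrix
  expect_lt(norm(z - gs %*% t(ts), "F") / norm(z, "F"), 1e-10)
  # axis variance shares against a brute-force eigendecomposition of z'z
  ev <- sort(eigen(crossprod(z), symmetric = TRUE)$values, decreasing = TRUE)
  expect_equal(varianceExplained(res), (ev / sum(ev))[1:3], tolerance = 1e-8)
  # gene scores zero-sum per axis (environment centering)
  expect_lt(max(abs(colSums(gs))), 1e-10)
  expect_true(all(diff(singularValues(res)) <= 1e-10))
})

test_that("degenerate matrices behave: equal columns center to zero", {
  # columns differ only by their means: centering leaves nothing
  dn <- list(paste0("G", 1:4), paste0("E", 1:6))
  m0 <- sweep(matrix(0, 4, 6, dimnames = dn), 2, 1:6, "+")
  res0 <- ggeDecompose(m0)
  expect_equal(max(singularValues(res0)), 0, tolerance = 1e-10)
  expect_equal(max(abs(geneScores(res0))), 0, tolerance = 1e-10)
  # rank-1 G+GE: PC1 explains all of it
  p <- plantedMeans(seed = 5, rank = 1)
  res1 <- ggeDecompose(p$m)
  expect_equal(varianceExplained(res1)[1], 1, tolerance = 1e-10)
})

test_that("partition choices rescale scores but not their inner products", {
  p <- plantedMeans(seed = 9)
  grids <- lapply(c("symmetric", "genotype", "environment"),
                  function(pt) ggeDecompose(p$m, partition = pt))
  prods <- lapply(grids, function(r) geneScores(r) %*% t(tissueScores(r)))
  expect_equal(prods[[1]], prods[[2]], tolerance = 1e-10)
  expect_equal(prods[[1]], prods[[3]], tolerance = 1e-10)
  expect_equal(prods[[1]], p$centered, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("distance from center is the Euclidean norm of the PC scores", {
  expect_equal(distanceFromCenter(c(0, 0, 0)), 0)
  expect_equal(distanceFromCenter(c(2.7550, -0.2784, 0.0241)), 2.7691,
               tolerance = 2e-4)
  expect_equal(distanceFromCenter(c(0.7094, 0.4912, -0.3105)), 0.9171,
               tolerance = 6e-4)
})

test_that("published score table is internally consistent with its distances", {
  sc <- turbotGgeScores()
  di <- distanceFromCenter(as.matrix(sc[, c("PCA1", "PCA2", "PCA3")]))
  expect_lt(max(abs(di - sc$Di)), 5e-4)
  # gene scores sum to ~0 per axis at every temperature (print rounding)
  for (tmp in unique(sc$temperature)) {
    gs <- sc[sc$temperature == tmp & sc$type == "gene", ]
    expect_lt(max(abs(colSums(gs[, c("PCA1", "PCA2", "PCA3")]))), 5e-3)
  }
})

test_that("tissue relationship angles and lengths behave geometrically", {
  gs <- matrix(c(1, -1, 0.5, -0.5), 2, 2,
               dimnames = list(c("A", "B"), c("PC1", "PC2")))
  ts <- rbind(e1 = c(1, 0), e2 = c(2, 0), e3 = c(0, 1), e4 = c(-1, 0),
              e5 = c(0, 0))
  colnames(ts) <- c("PC1", "PC2")
  r <- ggeFromScores(gs, ts)
  rel <- tissueRelationships(r)
  expect_equal(rel$angle["e1", "e2"], 0)           # identical direction
  expect_equal(rel$cosine["e1", "e2"], 1)
  expect_equal(rel$angle["e1", "e3"], 90)          # orthogonal: unrelated
  expect_equal(rel$angle["e1", "e4"], 180)
  expect_equal(rel$length[["e2"]], 2)
  expect_true(rel$degenerate[["e5"]])
  expect_true(all(is.na(rel$cosine["e5", ])))
  # random grid: symmetric with unit diagonal
  set.seed(2)
  rr <- tissueRelationships(ggeDecompose(plantedMeans(3)$m))
  expect_equal(rr$cosine, t(rr$cosine))
  expect_equal(unname(diag(rr$cosine)), rep(1, ncol(plantedMeans(3)$m)))
})

test_that("which-won-where winners equal the centered-mean argmax on rank-2 data", {
  p <- plantedMeans(seed = 17)
  res <- ggeDecompose(p$m)
  www <- whichWonWhere(res)
  expect_false(www@degenerate)
  # winner of every tissue is the gene with the largest centered mean there
  oracle <- rownames(p$m)[apply(p$centered, 2, which.max)]
  expect_equal(www@assignment$winner, oracle)
  # each winner is a hull vertex
  expect_true(all(www@assignment$winner %in% www@vertices))
  # sector boundary rays separate consecutive hull vertices' dominance
  expect_equal(length(www@rayAngles), length(www@vertices))
})

test_that("which-won-where handles rank-1 (collinear) score degeneracy", {
  gs <- cbind(PC1 = c(G1 = 2, G2 = 1, G3 = -1, G4 = -2), PC2 = 0)
  ts <- cbind(PC1 = c(e1 = 1, e2 = 0.5, e3 = -0.25), PC2 = 0)
  www <- whichWonWhere(ggeFromScores(gs, ts))
  expect_true(www@degenerate)
  expect_equal(www@assignment$winner, c("G1", "G1", "G4"))
})

test_that("mean-vs-stability projections match a trigonometric recomputation", {
  p <- plantedMeans(seed = 23)
  res <- ggeDecompose(p$m)
  mvs <- meanVsStability(res)
  gs <- geneScores(res)[, 1:2]
  ts <- tissueScores(res)[, 1:2]
  a <- colMeans(ts); a <- a / sqrt(sum(a^2))
  ang <- atan2(gs[, 2], gs[, 1]) - atan2(a[2], a[1])
  len <- sqrt(rowSums(gs^2))
  expect_equal(mvs$table$meanProjection, unname(len * cos(ang)),
               tolerance = 1e-10)
  expect_equal(mvs$table$instability, unname(abs(len * sin(ang))),
               tolerance = 1e-10)
  # symmetric two-gene case: equal and opposite
  g2 <- rbind(A = c(1, 0.5), B = c(-1, -0.5))
  t2 <- rbind(e1 = c(1, 0), e2 = c(0.8, 0.1))
  colnames(g2) <- colnames(t2) <- c("PC1", "PC2")
  sym <- meanVsStability(ggeFromScores(g2, t2))
  expect_equal(sum(sym$table$meanProjection), 0, tolerance = 1e-12)
  expect_equal(diff(sym$table$instability), 0, tolerance = 1e-12)
  # zero mean-tissue vector: axis undefined
  tz <- rbind(e1 = c(1, 0), e2 = c(-1, 0))
  colnames(tz) <- c("PC1", "PC2")
  expect_error(meanVsStability(ggeFromScores(g2, tz)), "undefined")
})

test_that("ideal-point ranking puts an ideal gene first and is rotation/flip invariant", {
  gs <- rbind(best = c(2, 0), mid = c(1, 0.5), worst = c(-3, 0.5))
  ts <- rbind(e1 = c(1, 0.1), e2 = c(0.9, -0.1))
  colnames(gs) <- colnames(ts) <- c("PC1", "PC2")
  # place 'best' exactly at the ideal point
  r0 <- ggeFromScores(gs, ts)
  a <- meanVsStability(r0)$axis
  gs["best", ] <- max(geneScores(r0) %*% a) * a
  r1 <- ggeFromScores(gs, ts)
  ipr <- idealPointRanking(r1)
  expect_equal(ipr$comprehensive[1], "best")
  expect_equal(ipr$table$distance[ipr$table$gene == "best"], 0,
               tolerance = 1e-10)
  # rigid rotation of all planar scores leaves every ranking unchanged
  p <- plantedMeans(seed = 29)
  res <- ggeDecompose(p$m)
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- ggeFromScores(geneScores(res)[, 1:2] %*% R,
                       tissueScores(res)[, 1:2] %*% R)
  expect_identical(ggeRankings(rot), ggeRankings(ggeFromScores(
    geneScores(res)[, 1:2], tissueScores(res)[, 1:2])))
  # axis sign flips leave rankings unchanged
  flip <- diag(c(1, -1))
  flipped <- ggeFromScores(geneScores(res)[, 1:2] %*% flip,
                           tissueScores(res)[, 1:2] %*% flip)
  expect_identical(ggeRankings(flipped), ggeRankings(ggeFromScores(
    geneScores(res)[, 1:2], tissueScores(res)[, 1:2])))
})

test_that("rankings from the published scores match the published order at 14 degC", {
  res <- turbotGgeResults("14")[["14"]]
  rk <- ggeRankings(res)
  expect_equal(rk$comprehensive, c("PPARg", "PPARa1", "PPARa2", "PPARb"))
  www <- whichWonWhere(res)
  w <- www@assignment
  expect_equal(w$winner[w$tissue %in% c("spleen", "skin", "gill", "stomach")],
               rep("PPARg", 4))
  expect_equal(w$winner[w$tissue == "kidney"], "PPARa1")
})
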