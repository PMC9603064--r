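# Brute-force oracles and fixture builders, kept deliberately naive and
# independent of the package's matrix implementations.

# balanced random replicate table, one temperature
randomTwoWayTable <- function(seed, g = 3, e = 4, r = 2, temperature = "T") {
  set.seed(seed)
  d <- expand.grid(block = seq_len(r), gene = paste0("G", seq_len(g)),
                   tissue = paste0("E", seq_len(e)),
                   temperature = temperature, stringsAsFactors = FALSE)
  d$value <- rnorm(nrow(d), 2, 1)
  ExpressionTable(d)
}

# balanced random split-split-plot table
randomSspTable <- function(seed, t = 2, s = 3, g = 2, k = 2) {
  set.seed(seed)
  d <- expand.grid(block = seq_len(k), gene = paste0("G", seq_len(g)),
                   tissue = paste0("S", seq_len(s)),
                   temperature = paste0("T", seq_len(t)),
                   stringsAsFactors = FALSE)
  d$value <- rnorm(nrow(d), 5, 2)
  ExpressionTable(d)
}

# per-cell means by explicit looping
naiveCellMeans <- function(x, temperature) {
  d <- exprData(x)
  d <- d[as.character(d$temperature) == temperature, ]
  genes <- unique(as.character(d$gene)); tissues <- unique(as.character(d$tissue))
  m <- matrix(NA_real_, length(genes), length(tissues),
              dimnames = list(genes, tissues))
  for (g in genes) for (e in tissues)
    m[g, e] <- mean(d$value[d$gene == g & d$tissue == e])
  m
}

# AMMI SS by explicit nested loops over the definitions
naiveAmmiSS <- function(x, temperature) {
  d <- exprData(x)
  d <- d[as.character(d$temperature) == temperature, ]
  genes <- unique(as.character(d$gene)); tissues <- unique(as.character(d$tissue))
  r <- nrow(d) / (length(genes) * length(tissues))
  m <- naiveCellMeans(x, temperature)
  gm <- mean(d$value)
  ssGene <- 0
  for (g in genes) ssGene <- ssGene + r * length(tissues) * (mean(m[g, ]) - gm)^2
  ssTissue <- 0
  for (e in tissues) ssTissue <- ssTissue + r * length(genes) * (mean(m[, e]) - gm)^2
  ssInt <- 0
  for (g in genes) for (e in tissues)
    ssInt <- ssInt + r * (m[g, e] - mean(m[g, ]) - mean(m[, e]) + gm)^2
  ssErr <- 0
  for (g in genes) for (e in tissues) {
    v <- d$value[d$gene == g & d$tissue == e]
    ssErr <- ssErr + sum((v - mean(v))^2)
  }
  list(gene = ssGene, tissue = ssTissue, interaction = ssInt, error = ssErr,
       total = sum((d$value - gm)^2))
}

# split-split-plot SS by explicit summation over factor-level means
naiveSspSS <- function(x) {
  d <- exprData(x)
  y <- d$value; gm <- mean(y)
  lev <- function(f) unique(as.character(d[[f]]))
  mt <- function(...) {
    sel <- Reduce(`&`, list(...))
    mean(y[sel])
  }
  temps <- lev("temperature"); tiss <- lev("tissue"); genes <- lev("gene")
  blocks <- unique(d$block)
  t <- length(temps); s <- length(tiss); g <- length(genes); k <- length(blocks)
  ssB <- 0
  for (b in blocks) ssB <- ssB + t * s * g * (mt(d$block == b) - gm)^2
  ssT <- 0
  for (i in temps) ssT <- ssT + k * s * g * (mt(d$temperature == i) - gm)^2
  ssMPE <- 0
  for (i in temps) for (b in blocks)
    ssMPE <- ssMPE + s * g * (mt(d$temperature == i, d$block == b) -
      mt(d$temperature == i) - mt(d$block == b) + gm)^2
  ssS <- 0
  for (h in tiss) ssS <- ssS + k * t * g * (mt(d$tissue == h) - gm)^2
  ssTS <- 0
  for (i in temps) for (h in tiss)
    ssTS <- ssTS + k * g * (mt(d$temperature == i, d$tissue == h) -
      mt(d$temperature == i) - mt(d$tissue == h) + gm)^2
  ssSPE <- 0
  for (i in temps) for (h in tiss) for (b in blocks)
    ssSPE <- ssSPE + g * (mt(d$temperature == i, d$tissue == h, d$block == b) -
      mt(d$temperature == i, d$tissue == h) -
      mt(d$temperature == i, d$block == b) + mt(d$temperature == i))^2
  ssG <- 0
  for (j in genes) ssG <- ssG + k * t * s * (mt(d$gene == j) - gm)^2
  ssTG <- 0
  for (i in temps) for (j in genes)
    ssTG <- ssTG + k * s * (mt(d$temperature == i, d$gene == j) -
      mt(d$temperature == i) - mt(d$gene == j) + gm)^2
  ssSG <- 0
  for (h in tiss) for (j in genes)
    ssSG <- ssSG + k * t * (mt(d$tissue == h, d$gene == j) -
      mt(d$tissue == h) - mt(d$gene == j) + gm)^2
  ssTSG <- 0
  for (i in temps) for (h in tiss) for (j in genes)
    ssTSG <- ssTSG + k * (mt(d$temperature == i, d$tissue == h, d$gene == j) -
      mt(d$temperature == i, d$tissue == h) -
      mt(d$temperature == i, d$gene == j) -
      mt(d$tissue == h, d$gene == j) +
      mt(d$temperature == i) + mt(d$tissue == h) + mt(d$gene == j) - gm)^2
  ssTotal <- sum((y - gm)^2)
  ssSSPE <- ssTotal - (ssB + ssT + ssMPE + ssS + ssTS + ssSPE +
                       ssG + ssTG + ssSG + ssTSG)
  c(Blocks = ssB, Temperature = ssT, `Main-plot error` = ssMPE,
    Tissue = ssS, `Temperature x Tissue` = ssTS, `Split-plot error` = ssSPE,
    Gene = ssG, `Temperature x Gene` = ssTG, `Tissue x Gene` = ssSG,
    `Temperature x Tissue x Gene` = ssTSG, `Split-split-plot error` = ssSSPE)
}

anovaRow <- function(fit, source) {
  tab <- anovaTable(fit)
  tab[tab$source == source, , drop = FALSE]
}
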