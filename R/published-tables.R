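## Loaders for the published summary tables of the turbot PPAR temperature
## study that this package's methods target: the split-split-plot ANOVA,
## the per-temperature AMMI ANOVA, the GGE scores with distances, and the
## gene rankings. Shipped as plain TSV under inst/extdata; useful both as
## worked examples and as arithmetic cross-checks of the implementation.

.extdata <- function(name) {
  path <- system.file("extdata", name, package = "tissueGxE")
  if (!nzchar(path)) stop("installed fixture not found: ", name)
  path
}

#' Published split-split-plot ANOVA summary (turbot PPAR study)
#'
#' The 11-row ANOVA (Blocks through Split-split-plot error) of PPAR relative
#' expression in turbot: 4 genes x 10 tissues x 5 temperatures x 3 blocks.
#'
#' @return data.frame with columns source, df, SS, MS, F, p (F and p NA for
#'   untested rows)
#' @export
turbotSspAnova <- function() {
  utils::read.delim(.extdata("turbot_ppar_ssp_anova.tsv"))
}

#' Published per-temperature AMMI ANOVA summary (turbot PPAR study)
#'
#' @return data.frame with columns temperature, source, df, SS, MS, F, p,
#'   pct. The `pct` column is percent of total SS on the Gene, Tissue and
#'   Interaction rows and percent of interaction SS on the IPCA rows, as in
#'   the published layout.
#' @export
turbotAmmiAnova <- function() {
  d <- utils::read.delim(.extdata("turbot_ppar_ammi_anova.tsv"),
                         colClasses = c(temperature = "character"))
  d
}

#' Published GGE scores and center distances (turbot PPAR study)
#'
#' Per temperature: three PC scores and the distance from the biplot center
#' for each of the 4 genes and 10 tissues. The singular-value partition
#' behind the printed scores is not documented by the source software, so
#' only partition-invariant quantities (inner products, distances, rank
#' outputs) should be compared against them.
#'
#' @return data.frame with columns temperature, type, name, PCA1, PCA2,
#'   PCA3, Di
#' @export
turbotGgeScores <- function() {
  utils::read.delim(.extdata("turbot_ppar_gge_scores.tsv"),
                    colClasses = c(temperature = "character"))
}

#' Published gene rankings (turbot PPAR study)
#'
#' High-expression, stable-expression and comprehensive (high-and-stable)
#' gene orderings per temperature.
#'
#' @return data.frame with columns temperature, rank, highExpression,
#'   stableExpression, comprehensive
#' @export
turbotRankings <- function() {
  utils::read.delim(.extdata("turbot_ppar_rankings.tsv"),
                    colClasses = c(temperature = "character"))
}

#' GGE geometry objects from the published score table
#'
#' Convenience wrapper building one [GgeResult-class] per temperature from
#' [turbotGgeScores()] via [ggeFromScores()].
#'
#' @param temperature temperature label(s); default all five
#' @return a named list of [GgeResult-class] objects
#' @export
turbotGgeResults <- function(temperature = c("14", "20", "23", "25", "28")) {
  sc <- turbotGgeScores()
  out <- lapply(temperature, function(tmp) {
    d <- sc[sc$temperature == tmp, ]
    if (!nrow(d)) stop("no published scores at temperature ", tmp)
    gs <- as.matrix(d[d$type == "gene", c("PCA1", "PCA2", "PCA3")])
    rownames(gs) <- d$name[d$type == "gene"]
    ts <- as.matrix(d[d$type == "tissue", c("PCA1", "PCA2", "PCA3")])
    rownames(ts) <- d$name[d$type == "tissue"]
    ggeFromScores(gs, ts, temperature = tmp)
  })
  names(out) <- temperature
  out
}
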