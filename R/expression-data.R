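## Reading/writing replicate-level expression tables and the ddCt step.

#' Construct an ExpressionTable from a long-format data.frame
#'
#' @param data data.frame with columns temperature, tissue, gene, block,
#'   value. temperature, tissue and gene become factors whose level order is
#'   the order of first appearance (preserved through all downstream tables).
#' @param unit expression unit label carried as metadata (default
#'   "relative units").
#' @return an [ExpressionTable-class] object
#' @examples
#' d <- expand.grid(block = 1:2, gene = c("g1", "g2"), tissue = c("t1", "t2"),
#'                  temperature = "20")
#' d$value <- rnorm(nrow(d), 1.5, 0.2)
#' ExpressionTable(d)
#' @export
ExpressionTable <- function(data, unit = "relative units") {
  stopifnot(is.data.frame(data))
  missing <- setdiff(.EXPR_COLS, names(data))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  d <- data[, .EXPR_COLS]
  for (col in c("temperature", "tissue", "gene"))
    if (!is.factor(d[[col]]))
      d[[col]] <- factor(d[[col]], levels = unique(as.character(d[[col]])))
  d$block <- as.integer(d$block)
  d$value <- as.numeric(d$value)
  rownames(d) <- NULL
  new("ExpressionTable", data = d, unit = unit)
}

#' Read an expression table from delimited text
#'
#' Expects a header row naming the five canonical columns
#' `temperature,tissue,gene,block,value` (any order, extra columns ignored).
#'
#' @param file path to a delimited text file
#' @param sep field delimiter; `","` (default) or `"\t"` etc.
#' @param unit unit label to attach
#' @return an [ExpressionTable-class]
#' @export
readExpressionTable <- function(file, sep = ",", unit = "relative units") {
  d <- utils::read.table(file, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(.EXPR_COLS, names(d))
  if (length(missing))
    stop(sprintf("'%s' lacks required column(s): %s", file,
                 paste(missing, collapse = ", ")))
  suppressWarnings(v <- as.numeric(d$value))
  if (any(is.na(v) & !is.na(d$value)))
    stop(sprintf("non-numeric value at data row %d of '%s'",
                 which(is.na(v) & !is.na(d$value))[1L], file))
  if (any(is.na(v)))
    stop(sprintf("missing value at data row %d of '%s'",
                 which(is.na(v))[1L], file))
  d$value <- v
  key <- interaction(d$temperature, d$tissue, d$gene, d$block, drop = TRUE)
  if (anyDuplicated(key))
    stop(sprintf("duplicated design cell at data row %d of '%s'",
                 which(duplicated(key))[1L], file))
  ExpressionTable(d, unit = unit)
}

#' Write an expression table as delimited text
#'
#' Values are printed with 17 significant digits so that
#' `readExpressionTable(writeExpressionTable(x))` round-trips doubles
#' bit-identically.
#'
#' @param x an [ExpressionTable-class]
#' @param file output path
#' @param sep field delimiter
#' @return `file`, invisibly
#' @export
writeExpressionTable <- function(x, file, sep = ",") {
  stopifnot(is(x, "ExpressionTable"))
  d <- x@data
  d$value <- sprintf("%.17g", d$value)
  utils::write.table(d, file, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Relative expression by the ddCt (2^-ddCt) method
#'
#' Computes 2^-[(Ct_target - Ct_reference)_sample -
#' (Ct_target - Ct_reference)_calibrator]: the fold change of the target
#' gene relative to the internal reference gene, normalized to a calibrator
#' sample. Vectorized over samples.
#'
#' @param ctTarget,ctReference sample cycle thresholds of target and
#'   reference gene (cycles)
#' @param calCtTarget,calCtReference calibrator cycle thresholds
#' @return strictly positive relative expression (dimensionless)
#' @examples
#' relativeExpression(24, 18, 24, 18)  # same dCt as calibrator -> 1
#' relativeExpression(25, 18, 24, 18)  # one cycle later -> 0.5
#' @export
relativeExpression <- function(ctTarget, ctReference, calCtTarget,
                               calCtReference) {
  ct <- c(ctTarget, ctReference, calCtTarget, calCtReference)
  if (!is.numeric(ct) || any(!is.finite(ct)) || any(ct <= 0))
    stop("all Ct values must be finite and positive")
  ddct <- (ctTarget - ctReference) - (calCtTarget - calCtReference)
  2^(-ddct)
}

#' Relative expression for a whole Ct table
#'
#' Applies the ddCt method per gene, using the row(s) flagged
#' `is_calibrator` as the calibrator for their gene (mean dCt if several).
#'
#' @param ct data.frame with columns sample, gene, ct_target, ct_reference,
#'   is_calibrator
#' @return the input with an added `value` column of relative expression
#' @export
ddctTable <- function(ct) {
  need <- c("sample", "gene", "ct_target", "ct_reference", "is_calibrator")
  missing <- setdiff(need, names(ct))
  if (length(missing))
    stop("Ct table lacks column(s): ", paste(missing, collapse = ", "))
  if (any(!is.finite(ct$ct_target)) || any(!is.finite(ct$ct_reference)))
    stop("all Ct values must be finite")
  dct <- ct$ct_target - ct$ct_reference
  out <- ct
  out$value <- NA_real_
  for (g in unique(ct$gene)) {
    sel <- ct$gene == g
    cal <- sel & as.logical(ct$is_calibrator)
    if (!any(cal)) stop(sprintf("no calibrator sample for gene '%s'", g))
    out$value[sel] <- 2^(-(dct[sel] - mean(dct[cal])))
  }
  out
}

#' @describeIn ExpressionTable-class check design balance; returns TRUE with
#'   attribute `replicates` when every temperature x tissue x gene cell has
#'   the same complete set of blocks, FALSE otherwise.
#' @param x an ExpressionTable
#' @param temperature optional temperature label to restrict the check to
#' @export
setMethod("isBalanced", "ExpressionTable", function(x, temperature = NULL) {
  d <- x@data
  if (!is.null(temperature)) {
    d <- d[d$temperature == temperature, , drop = FALSE]
    if (!nrow(d)) stop(sprintf("unknown temperature '%s'", temperature))
    d <- droplevels(d)
  }
  counts <- table(d$temperature, d$tissue, d$gene)
  r <- counts[1L]
  if (any(counts != r)) return(FALSE)
  # every cell must see the same block set, exactly once each
  blocks <- sort(unique(d$block))
  if (length(blocks) != r) return(FALSE)
  structure(TRUE, replicates = as.integer(r))
})

.subsetTemperature <- function(x, temperature) {
  d <- x@data
  if (!temperature %in% levels(d$temperature))
    stop(sprintf("unknown temperature '%s'", temperature))
  b <- isBalanced(x, temperature)
  if (!isTRUE(b))
    stop(sprintf("design is not balanced at temperature '%s'", temperature))
  d <- droplevels(d[d$temperature == temperature, , drop = FALSE])
  attr(d, "replicates") <- attr(b, "replicates")
  d
}

#' @describeIn ExpressionTable-class gene x tissue cell means at one
#'   temperature (mean over replicate blocks)
#' @param temperature temperature label to aggregate at
#' @export
setMethod("cellMeans", "ExpressionTable", function(x, temperature, ...) {
  d <- .subsetTemperature(x, temperature)
  m <- tapply(d$value, list(d$gene, d$tissue), mean)
  new("TwoWayMeans", means = unclass(m), replicates = attr(d, "replicates"),
      temperature = as.character(temperature), unit = x@unit)
})

#' @describeIn ExpressionTable-class mean expression over all gene x tissue
#'   x block observations at one temperature
#' @export
setMethod("temperatureGrandMean", "ExpressionTable",
          function(x, temperature) {
  d <- .subsetTemperature(x, temperature)
  mean(d$value)
})
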