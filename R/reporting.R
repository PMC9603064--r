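## Report writers: TSV tables mirroring the standard SSP / AMMI / GGE
## layouts, with significance stars, 4-decimal display, and a full-precision
## machine-readable JSON sidecar.

#' Significance stars at the conventional table thresholds
#' @param p numeric p-values
#' @return "**" for p < 0.01, "*" for p < 0.05, "" otherwise (NA -> "")
#' @export
significanceStars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

.fmtNum <- function(x, digits = 4) {
  ifelse(is.na(x), "", formatC(x, format = "f", digits = digits))
}

.fmtP <- function(p) {
  # display floor at 1e-7, mirroring the published table convention
  ifelse(is.na(p), "",
         ifelse(p < 1e-7, "1e-07", formatC(p, format = "g", digits = 4)))
}

#' Format an ANOVA data.frame for display
#'
#' Rounds SS/MS/F to 4 decimals, floors displayed p-values at 1e-7 and
#' appends significance stars (** p < 0.01, * p < 0.05). Locale-independent:
#' every printed number re-parses with `as.numeric`.
#'
#' @param tab data.frame with columns source, df, SS, MS and optionally F,
#'   p, pctTotal, pctInteraction
#' @return data.frame of character columns ready for printing/writing
#' @export
formatAnova <- function(tab) {
  out <- data.frame(source = tab$source, df = tab$df,
                    SS = .fmtNum(tab$SS), MS = .fmtNum(tab$MS),
                    stringsAsFactors = FALSE)
  if ("F" %in% names(tab))
    out$F <- paste0(.fmtNum(tab$F), significanceStars(tab$p))
  if ("p" %in% names(tab)) out$p <- .fmtP(tab$p)
  if ("pctTotal" %in% names(tab)) out$pctTotal <- .fmtNum(tab$pctTotal)
  if ("pctInteraction" %in% names(tab))
    out$pctInteraction <- .fmtNum(tab$pctInteraction)
  out
}

.writeTsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline and write a report bundle
#'
#' Reads (or takes) a replicate-level expression table, runs the requested
#' analyses and writes TSV reports mirroring the standard table layouts:
#' the 11-row split-split-plot ANOVA, per-temperature AMMI ANOVA and score
#' tables, per-temperature GGE scores/sectors/rankings, and the
#' effect-contribution profile across temperatures. A `run_log.txt` records
#' package version, seed and options; `results.json` holds every table at
#' full precision. On any error, partial outputs are removed.
#'
#' @param input an [ExpressionTable-class] or path to a delimited file with
#'   the canonical columns
#' @param outputDir directory to create/write into
#' @param analyses subset of c("ssp", "ammi", "gge")
#' @param temperature temperature label(s) for AMMI/GGE; default all in the
#'   table
#' @param nAxes retained AMMI axes
#' @param partition GGE singular-value partition
#' @param sep input field delimiter when `input` is a path
#' @param seed optional integer; recorded in the log and set before any
#'   analysis for end-to-end reproducibility
#' @param verbose log progress to stderr
#' @return invisibly, the character vector of files written
#' @export
runReport <- function(input, outputDir, analyses = c("ssp", "ammi", "gge"),
                      temperature = NULL, nAxes = 2L,
                      partition = "symmetric", sep = ",", seed = NULL,
                      verbose = TRUE) {
  analyses <- match.arg(analyses, c("ssp", "ammi", "gge"),
                        several.ok = TRUE)
  say <- function(...) if (verbose) message(...)
  written <- character()
  ok <- FALSE
  on.exit(if (!ok && length(written)) {
    unlink(written)
    say("error: removed partial outputs")
  })

  x <- if (is(input, "ExpressionTable")) input
       else readExpressionTable(input, sep = sep)
  if (!isTRUE(isBalanced(x)))
    stop("input design is unbalanced; analyses require balance")
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (!dir.exists(outputDir))
    dir.create(outputDir, recursive = TRUE)
  temps <- if (is.null(temperature)) temperatureNames(x)
           else as.character(temperature)

  sidecar <- list()
  emit <- function(name, display, full) {
    path <- file.path(outputDir, paste0(name, ".tsv"))
    .writeTsv(display, path)
    written <<- c(written, path)
    sidecar[[name]] <<- full
    say("wrote ", path)
  }

  if ("ssp" %in% analyses) {
    fit <- fitSspAnova(x)
    emit("ssp_anova", formatAnova(anovaTable(fit)), anovaTable(fit))
  }
  ammiResults <- list()
  if ("ammi" %in% analyses) {
    for (tmp in temps) {
      res <- ammiDecompose(x, tmp, nAxes = nAxes)
      ammiResults[[tmp]] <- res
      emit(paste0("ammi_", tmp), formatAnova(anovaTable(res)),
           anovaTable(res))
      sc <- data.frame(name = c(rownames(geneScores(res)),
                                rownames(tissueScores(res))),
                       type = rep(c("gene", "tissue"),
                                  c(nrow(geneScores(res)),
                                    nrow(tissueScores(res)))),
                       rbind(geneScores(res), tissueScores(res)),
                       row.names = NULL, check.names = FALSE)
      emit(paste0("ammi_scores_", tmp),
           cbind(sc[1:2], lapply(sc[-(1:2)], .fmtNum)), sc)
    }
    prof <- contributionProfile(unname(ammiResults))
    emit("contribution_profile",
         cbind(prof[1], lapply(prof[-1], .fmtNum)), prof)
  }
  if ("gge" %in% analyses) {
    for (tmp in temps) {
      res <- ggeDecompose(cellMeans(x, tmp), partition = partition)
      gs <- geneScores(res); ts <- tissueScores(res)
      sc <- data.frame(name = c(rownames(gs), rownames(ts)),
                       type = rep(c("gene", "tissue"),
                                  c(nrow(gs), nrow(ts))),
                       rbind(gs, ts),
                       Di = c(distanceFromCenter(gs),
                              distanceFromCenter(ts)),
                       row.names = NULL, check.names = FALSE)
      emit(paste0("gge_scores_", tmp),
           cbind(sc[1:2], lapply(sc[-(1:2)], .fmtNum)), sc)
      www <- whichWonWhere(res)
      emit(paste0("gge_sectors_", tmp), www@assignment, www@assignment)
      rk <- ggeRankings(res)
      rk <- cbind(temperature = tmp, rk)
      emit(paste0("gge_rankings_", tmp), rk, rk)
    }
  }

  jsonPath <- file.path(outputDir, "results.json")
  jsonlite::write_json(sidecar, jsonPath, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  written <- c(written, jsonPath)
  logPath <- file.path(outputDir, "run_log.txt")
  writeLines(c(
    paste0("tissueGxE version: ",
           as.character(utils::packageVersion("tissueGxE"))),
    paste0("R version: ", R.version.string),
    paste0("seed: ", if (is.null(seed)) "none" else seed),
    paste0("analyses: ", paste(analyses, collapse = ",")),
    paste0("temperatures: ", paste(temps, collapse = ",")),
    paste0("nAxes: ", nAxes),
    paste0("partition: ", partition)), logPath)
  written <- c(written, logPath)
  ok <- TRUE
  invisible(written)
}
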