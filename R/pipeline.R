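#' Run the end-to-end imprinting-defect analysis
#'
#' Chains the stages on file inputs: read and validate the methylation
#' table; score every sample (per-DMR deviations, 14q-index, defect call);
#' summarize classification per group; compare locus-specific versus LINE-1
#' demethylation when a LINE-1 locus is present; correlate the H19 defect
#' extent with the index when H19 is present; and, when a survival table is
#' supplied, stratify it by defect call and run Kaplan-Meier plus log-rank.
#' Outputs are written to \code{outdir} together with a provenance manifest
#' (package version, seed, configuration hash, input hashes) whose content
#' is byte-identical across reruns on identical inputs.
#'
#' @param methFile Path to the long methylation table.
#' @param outdir Output directory (created if needed).
#' @param survivalFile Optional path to a survival table; if the file is
#'   missing the survival stage is skipped with a message.
#' @param normalGroup Normal-group label (default "normal").
#' @param locus Scored locus (default "14q32").
#' @param expectedLevel Expected imprinted level (default 50).
#' @param threshold Index positivity threshold (default 8.5).
#' @param comparatorLocus Genome-wide surrogate locus for the demethylation
#'   comparison (default "LINE1").
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed is provenance for upstream simulation).
#' @param verbose Emit stage-tagged progress messages (default TRUE).
#' @return Invisibly, a list: scores, classification, demethylation, h19
#'   correlation, survival results, manifest, and the output paths.
#' @export
runPipeline <- function(methFile, outdir, survivalFile = NULL,
                        normalGroup = "normal", locus = "14q32",
                        expectedLevel = 50, threshold = 8.5,
                        comparatorLocus = "LINE1", seed = 1,
                        verbose = TRUE) {
  say <- function(stage, ...) if (verbose)
    message("[", stage, "] ", ...)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  say("read", "reading ", methFile)
  meth <- readMethylationTable(methFile)

  say("score", "scoring ", length(unique(meth$sample_id)), " samples")
  scores <- tryCatch(
    scoreSamples(meth, locus = locus, expectedLevel = expectedLevel,
                 threshold = threshold),
    error = function(e) stop("stage 'score' failed on ", methFile, ": ",
                             conditionMessage(e), call. = FALSE))
  scoresPath <- file.path(outdir, "scores.tsv")
  writeTsv(scores, scoresPath)

  say("compare", "classification summary and cohort tests")
  classification <- classificationSummary(scores$call, scores$group)
  writeTsv(classification, file.path(outdir, "classification.tsv"))

  demeth <- NULL
  if (comparatorLocus %in% meth$locus && normalGroup %in% meth$group) {
    demeth <- demethylationExtent(meth, normalGroup = normalGroup,
                                  locus = locus,
                                  comparatorLocus = comparatorLocus)
    writeTsv(demeth$groupMeans, file.path(outdir, "demethylation.tsv"))
  }

  h19 <- NULL
  if ("H19" %in% meth$locus) {
    h19sub <- meth[meth$locus == "H19", c("sample_id", "methylation_pct")]
    merged <- merge(scores[, c("sample_id", "fourteen_q_index")], h19sub,
                    by = "sample_id")
    if (nrow(merged) >= 3L)
      h19 <- pearsonCorrelation(merged$fourteen_q_index,
                                dmrDeviation(merged$methylation_pct,
                                             expectedLevel))
  }

  survivalRes <- NULL
  if (!is.null(survivalFile)) {
    if (!file.exists(survivalFile)) {
      say("survive", "survival table ", survivalFile,
          " not found; stage skipped")
    } else {
      say("survive", "Kaplan-Meier and log-rank by defect call")
      surv <- readSurvivalTable(survivalFile)
      strat <- stratifyByIndex(scores, surv, mode = "call")
      survivalRes <- tryCatch(survivalByStratum(strat),
                              error = function(e) {
                                say("survive", "skipped: ",
                                    conditionMessage(e))
                                NULL
                              })
      if (!is.null(survivalRes)) {
        kmTab <- do.call(rbind, lapply(names(survivalRes$curves),
          function(s) cbind(stratum = s, survivalRes$curves[[s]]$table)))
        writeTsv(kmTab, file.path(outdir, "km.tsv"))
      }
    }
  }

  cfg <- list(normalGroup = normalGroup, locus = locus,
              expectedLevel = expectedLevel, threshold = threshold,
              comparatorLocus = comparatorLocus, seed = seed)
  manifest <- list(
    package = "imprintscore",
    version = as.character(utils::packageVersion("imprintscore")),
    seed = seed,
    config = cfg,
    config_hash = contentHash(paste(names(cfg), unlist(cfg),
                                  sep = "=", collapse = ";")),
    input_hashes = c(
      methylation = contentHash(readLines(methFile)),
      survival = if (!is.null(survivalFile) && file.exists(survivalFile))
        contentHash(readLines(survivalFile)) else NA_character_))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  say("done", "outputs in ", outdir)
  invisible(list(scores = scores, classification = classification,
                 demethylation = demeth, h19Correlation = h19,
                 survival = survivalRes, manifest = manifest,
                 outdir = outdir))
}
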