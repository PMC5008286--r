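#' Call per-CpG methylation from one bisulfite-converted clone sequence
#'
#' Compares a gapless, pre-trimmed clone sequence against the reference
#' amplicon. At each CpG cytosine a retained C is called methylated (bisulfite
#' leaves 5mC intact), a T unmethylated (unmethylated C deaminates and reads
#' as T), anything else missing. Non-CpG cytosines are unmethylated in
#' mammalian somatic DNA, so the fraction of them reading as T estimates the
#' clone's bisulfite conversion rate.
#'
#' Alignment is out of scope: clones must be the same length as the
#' reference. Sequences needing alignment should be handled upstream.
#'
#' @param reference A [ReferenceAmplicon-class].
#' @param cloneSequence Character scalar or [Biostrings::DNAString]; same
#'   length as the reference, alphabet {A, C, G, T, N}.
#' @return A list with elements \code{calls} (integer vector over CpG sites:
#'   1 methylated, 0 unmethylated, NA missing, named by 1-based CpG position)
#'   and \code{conversionRate} (fraction of readable non-CpG cytosines that
#'   converted; NA if none readable).
#' @examples
#' amp <- referenceAmplicon("ACGTCTA")
#' callMethylation(amp, "ACGTTTA")  # CpG methylated, conversion 1.0
#' callMethylation(amp, "ATGTCTA")  # CpG unmethylated, conversion 0.0
#' @export
callMethylation <- function(reference, cloneSequence) {
  stopifnot(methods::is(reference, "ReferenceAmplicon"))
  cloneSequence <- toupper(as.character(cloneSequence))
  if (!nzchar(cloneSequence))
    stop("empty clone sequence", call. = FALSE)
  if (nchar(cloneSequence) != nchar(reference@sequence))
    stop("clone length (", nchar(cloneSequence), ") differs from reference (",
         nchar(reference@sequence), "); alignment is required upstream",
         call. = FALSE)
  chars <- strsplit(cloneSequence, "")[[1]]
  if (!all(chars %in% c("A", "C", "G", "T", "N")))
    stop("clone sequence must be over {A,C,G,T,N}", call. = FALSE)

  cpgBase <- chars[reference@cpgPositions]
  calls <- ifelse(cpgBase == "C", 1L, ifelse(cpgBase == "T", 0L, NA_integer_))
  names(calls) <- as.character(reference@cpgPositions)

  qcBase <- chars[reference@nonCpgCPositions]
  readable <- sum(qcBase %in% c("C", "T"))
  conversionRate <- if (readable > 0) sum(qcBase == "T") / readable
                    else NA_real_
  list(calls = calls, conversionRate = conversionRate)
}

#' Call a clone set against a reference amplicon
#'
#' Applies [callMethylation()] to every clone and assembles a
#' [CloneMatrix-class].
#'
#' @param reference A [ReferenceAmplicon-class].
#' @param clones A [Biostrings::DNAStringSet], named character vector, or
#'   path handled by [callClonesFasta()].
#' @return A [CloneMatrix-class] (clones x CpG sites).
#' @export
callClones <- function(reference, clones) {
  ids <- names(clones)
  cloneChars <- as.character(clones)
  if (length(cloneChars) < 1L) stop("no clone sequences", call. = FALSE)
  ids <- ids %||% paste0("clone_", seq_along(cloneChars))
  res <- lapply(cloneChars, function(s) callMethylation(reference, s))
  calls <- do.call(rbind, lapply(res, `[[`, "calls"))
  rownames(calls) <- ids
  colnames(calls) <- paste0("CpG_", reference@cpgPositions)
  methods::new("CloneMatrix",
               calls = calls,
               conversionRates = vapply(res, `[[`, numeric(1),
                                        "conversionRate"))
}

#' @rdname callClones
#' @param referencePath,clonesPath FASTA paths for the reference amplicon and
#'   the clone sequences.
#' @export
callClonesFasta <- function(referencePath, clonesPath) {
  ref <- readReferenceAmplicon(referencePath)
  clones <- Biostrings::readDNAStringSet(clonesPath)
  callClones(ref, as.character(clones))
}

#' Accessors for CloneMatrix objects
#'
#' @param x A [CloneMatrix-class].
#' @param minConversion Conversion-rate threshold below which a clone is
#'   flagged as incompletely converted (default 0.95, the usual QC
#'   convention).
#' @return \code{cloneCalls}: the integer call matrix; \code{conversionRates}:
#'   per-clone conversion rates; \code{cloneIds}: clone identifiers;
#'   \code{flaggedClones}: logical vector, TRUE for clones failing
#'   conversion QC.
#' @name CloneMatrix-accessors
NULL

#' @rdname CloneMatrix-accessors
#' @export
setMethod("cloneCalls", "CloneMatrix", function(x) x@calls)

#' @rdname CloneMatrix-accessors
#' @export
setMethod("conversionRates", "CloneMatrix", function(x) x@conversionRates)

#' @rdname CloneMatrix-accessors
#' @export
setMethod("cloneIds", "CloneMatrix", function(x) rownames(x@calls))

#' @rdname CloneMatrix-accessors
#' @export
setMethod("flaggedClones", "CloneMatrix", function(x, minConversion = 0.95) {
  flagged <- !is.na(x@conversionRates) & x@conversionRates < minConversion
  names(flagged) <- rownames(x@calls)
  flagged
})

setMethod("show", "CloneMatrix", function(object) {
  m <- object@calls
  cat("CloneMatrix:", nrow(m), "clones x", ncol(m), "CpG sites\n")
  ov <- tryCatch(summarizeCloneMatrix(object, excludeFlagged = FALSE)$overall,
                 error = function(e) NA_real_)
  cat(sprintf("  overall methylation: %.1f%%\n", ov))
  cat(sprintf("  median conversion rate: %.3f (%d clone(s) < 0.95)\n",
              stats::median(object@conversionRates, na.rm = TRUE),
              sum(flaggedClones(object))))
})

#' Summarize a clone matrix into per-site, per-clone and overall methylation
#'
#' The overall level is the mean of per-clone methylation fractions (i.e. the
#' average over sequenced clones), the standard summary for bisulfite
#' TA-cloning data. Clones with no informative calls are excluded; clones
#' failing conversion QC are excluded by default.
#'
#' @param x A [CloneMatrix-class].
#' @param minConversion Conversion threshold for QC exclusion (default 0.95).
#' @param excludeFlagged Drop clones below \code{minConversion}? Default TRUE.
#' @return A list: \code{perSite} (% methylation per CpG), \code{perClone}
#'   (% per clone), \code{overall} (% overall), \code{nClonesUsed},
#'   \code{excluded} (ids of excluded clones).
#' @examples
#' amp <- referenceAmplicon("TACGTTACGTT")
#' cm <- callClones(amp, c(a = "TATGTTATGTT", b = "TACGTTACGTT"))
#' summarizeCloneMatrix(cm, excludeFlagged = FALSE)$overall  # 50
#' @export
summarizeCloneMatrix <- function(x, minConversion = 0.95,
                                 excludeFlagged = TRUE) {
  stopifnot(methods::is(x, "CloneMatrix"))
  m <- x@calls
  drop <- rowSums(!is.na(m)) == 0L
  if (excludeFlagged) drop <- drop | flaggedClones(x, minConversion)
  excluded <- rownames(m)[drop]
  m <- m[!drop, , drop = FALSE]
  if (nrow(m) == 0L || all(is.na(m)))
    stop("no informative clones after exclusions", call. = FALSE)
  perClone <- 100 * rowMeans(m, na.rm = TRUE)
  perSite <- 100 * colMeans(m, na.rm = TRUE)
  list(perSite = perSite,
       perClone = perClone,
       overall = mean(perClone),
       nClonesUsed = nrow(m),
       excluded = excluded)
}

#' Classify the allele-level methylation pattern of a clone matrix
#'
#' Imprinted regions show a diagnostic dichotomy: one parental allele densely
#' methylated, the other essentially free of methylation, with ~50% bulk
#' methylation. This classifier labels clones as dense
#' (per-clone methylation >= \code{denseCutoff}) or sparse
#' (<= \code{sparseCutoff}) and calls the matrix:
#' \itemize{
#'   \item \code{imprinted} if both clone classes reach frequency
#'     \code{balanceMin} and the overall level falls in \code{imprintedBand};
#'   \item \code{hypermethylated} if the overall level >= \code{hyperCutoff}
#'     (both alleles densely methylated, as at CpG-island flanks);
#'   \item \code{hypomethylated} if the overall level <= \code{hypoCutoff};
#'   \item \code{mixed} otherwise.
#' }
#'
#' @param x A [CloneMatrix-class].
#' @param denseCutoff,sparseCutoff Per-clone fractions bounding the dense and
#'   sparse classes (defaults 0.7 and 0.3).
#' @param balanceMin Minimum frequency of each class for an imprinted call
#'   (default 0.2).
#' @param imprintedBand Overall-% window for an imprinted call
#'   (default c(40, 60)).
#' @param hyperCutoff,hypoCutoff Overall-% cutoffs for fully methylated /
#'   fully unmethylated calls (defaults 80 and 20).
#' @param minConversion,excludeFlagged Conversion QC, as in
#'   [summarizeCloneMatrix()].
#' @return Character scalar: one of "imprinted", "hypermethylated",
#'   "hypomethylated", "mixed".
#' @export
detectImprintingPattern <- function(x, denseCutoff = 0.7, sparseCutoff = 0.3,
                                    balanceMin = 0.2,
                                    imprintedBand = c(40, 60),
                                    hyperCutoff = 80, hypoCutoff = 20,
                                    minConversion = 0.95,
                                    excludeFlagged = TRUE) {
  s <- summarizeCloneMatrix(x, minConversion = minConversion,
                            excludeFlagged = excludeFlagged)
  if (s$nClonesUsed < 4L)
    stop("at least 4 informative clones are required (have ",
         s$nClonesUsed, ")", call. = FALSE)
  frac <- s$perClone / 100
  fDense <- mean(frac >= denseCutoff)
  fSparse <- mean(frac <= sparseCutoff)
  if (fDense >= balanceMin && fSparse >= balanceMin &&
      s$overall >= imprintedBand[1] && s$overall <= imprintedBand[2])
    return("imprinted")
  if (s$overall >= hyperCutoff) return("hypermethylated")
  if (s$overall <= hypoCutoff) return("hypomethylated")
  "mixed"
}

#' Write per-site / per-clone / overall clone summaries to TSV files
#'
#' @param x A [CloneMatrix-class].
#' @param prefix Output path prefix; writes \code{<prefix>_per_site.tsv},
#'   \code{<prefix>_per_clone.tsv} and \code{<prefix>_overall.tsv}.
#' @inheritParams summarizeCloneMatrix
#' @return Invisibly, the paths written.
#' @export
writeCloneSummary <- function(x, prefix, minConversion = 0.95,
                              excludeFlagged = TRUE) {
  s <- summarizeCloneMatrix(x, minConversion, excludeFlagged)
  paths <- paste0(prefix, c("_per_site.tsv", "_per_clone.tsv",
                            "_overall.tsv"))
  utils::write.table(
    data.frame(site = names(s$perSite), methylation_pct = s$perSite),
    paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(clone_id = names(s$perClone), methylation_pct = s$perClone,
               conversion_rate = conversionRates(x)[names(s$perClone)]),
    paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(overall_methylation_pct = s$overall,
               n_clones_used = s$nClonesUsed,
               pattern = tryCatch(
                 detectImprintingPattern(x, minConversion = minConversion,
                                         excludeFlagged = excludeFlagged),
                 error = function(e) NA_character_)),
    paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
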