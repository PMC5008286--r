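#' Relative expression by the delta-delta-Ct method
#'
#' Classic qPCR relative quantification with perfect-doubling efficiency:
#' \deqn{\Delta Ct = Ct_{gene} - Ct_{ref}}
#' \deqn{\Delta\Delta Ct = \Delta Ct_{sample} - \overline{\Delta Ct}_{calibrator}}
#' \deqn{fold = 2^{-\Delta\Delta Ct}}
#' The calibrator baseline is the arithmetic mean of calibrator-sample
#' delta-Ct per gene (equivalently, the geometric mean of their fold changes
#' is exactly 1). Samples lacking a reference-gene Ct are skipped with a
#' warning.
#'
#' @param ct Long data.frame: sample_id, gene, ct (cycles, > 0); an optional
#'   group column enables \code{calibratorGroup}.
#' @param referenceGene Housekeeping gene used as internal control
#'   (default "GAPDH").
#' @param calibratorGroup Group label defining calibrator samples
#'   (default "normal"); ignored when \code{calibratorSamples} is given.
#' @param calibratorSamples Explicit calibrator sample ids.
#' @return data.frame: sample_id (plus group if present), gene, delta_ct,
#'   delta_delta_ct, fold_change; reference-gene rows are omitted.
#' @export
relativeExpression <- function(ct, referenceGene = "GAPDH",
                               calibratorGroup = "normal",
                               calibratorSamples = NULL) {
  stopifnot(all(c("sample_id", "gene", "ct") %in% names(ct)))
  if (any(ct$ct <= 0, na.rm = TRUE))
    stop("Ct values must be positive", call. = FALSE)
  refCt <- ct[ct$gene == referenceGene, c("sample_id", "ct")]
  if (nrow(refCt) == 0L)
    stop("reference gene '", referenceGene, "' absent", call. = FALSE)
  names(refCt)[2] <- "ref_ct"
  x <- ct[ct$gene != referenceGene, , drop = FALSE]
  x <- merge(x, refCt, by = "sample_id", all.x = TRUE, sort = FALSE)
  noRef <- unique(x$sample_id[is.na(x$ref_ct)])
  if (length(noRef)) {
    warning("skipping sample(s) without reference Ct: ",
            paste(noRef, collapse = ", "), call. = FALSE)
    x <- x[!is.na(x$ref_ct), , drop = FALSE]
  }
  x$delta_ct <- x$ct - x$ref_ct
  if (is.null(calibratorSamples)) {
    if (!"group" %in% names(x))
      stop("supply calibratorSamples or a group column", call. = FALSE)
    calibratorSamples <- unique(x$sample_id[x$group == calibratorGroup])
  }
  if (length(calibratorSamples) == 0L)
    stop("calibrator set is empty", call. = FALSE)
  cal <- x[x$sample_id %in% calibratorSamples, , drop = FALSE]
  calMean <- tapply(cal$delta_ct, cal$gene, mean, na.rm = TRUE)
  if (any(!unique(x$gene) %in% names(calMean)))
    stop("calibrator lacks measurements for gene(s): ",
         paste(setdiff(unique(x$gene), names(calMean)), collapse = ", "),
         call. = FALSE)
  x$delta_delta_ct <- x$delta_ct - as.numeric(calMean[x$gene])
  x$fold_change <- 2^(-x$delta_delta_ct)
  keep <- intersect(c("sample_id", "group", "gene", "delta_ct",
                      "delta_delta_ct", "fold_change"), names(x))
  x[, keep, drop = FALSE]
}

#' ChIP-qPCR enrichment under the common normalization schemes
#'
#' \describe{
#'   \item{fold_over_igg}{mark / IgG — enrichment over the nonspecific
#'     antibody background.}
#'   \item{percent_input}{100 * mark / input — recovery relative to input
#'     chromatin.}
#'   \item{h3_normalized}{(mark / input) / (H3 / input) — histone-mark signal
#'     corrected for local nucleosome occupancy via total H3.}
#' }
#'
#' @param signal Long data.frame: region, mark, signal. Control rows use
#'   marks "input", "IgG" and "H3" (matched case-insensitively).
#' @param mode One of "fold_over_igg", "percent_input", "h3_normalized".
#' @return data.frame: region, mark, enrichment, mode — control rows omitted.
#' @export
chipEnrichment <- function(signal,
                           mode = c("fold_over_igg", "percent_input",
                                    "h3_normalized")) {
  mode <- match.arg(mode)
  stopifnot(all(c("region", "mark", "signal") %in% names(signal)))
  ctrlNeeded <- switch(mode,
                       fold_over_igg = "IgG",
                       percent_input = "input",
                       h3_normalized = c("input", "H3"))
  getCtrl <- function(region, name) {
    v <- signal$signal[signal$region == region &
                         tolower(signal$mark) == tolower(name)]
    if (length(v) != 1L || is.na(v) || v <= 0)
      stop("control '", name, "' missing or non-positive for region ",
           region, call. = FALSE)
    v
  }
  ctrlMarks <- c("input", "igg", "h3")
  out <- signal[!tolower(signal$mark) %in% ctrlMarks, , drop = FALSE]
  enr <- numeric(nrow(out))
  for (i in seq_len(nrow(out))) {
    reg <- out$region[i]; v <- out$signal[i]
    enr[i] <- switch(mode,
      fold_over_igg = v / getCtrl(reg, "IgG"),
      percent_input = 100 * v / getCtrl(reg, "input"),
      h3_normalized = (v / getCtrl(reg, "input")) /
        (getCtrl(reg, "H3") / getCtrl(reg, "input")))
  }
  # silence R CMD check note; ctrlNeeded documents the requirement
  invisible(ctrlNeeded)
  data.frame(region = out$region, mark = out$mark, enrichment = enr,
             mode = mode, row.names = NULL)
}

#' Log2-transform and row-center an expression matrix
#'
#' Per feature (row): take log2 and subtract the feature mean, so every row
#' sums to zero — the standard preprocessing before expression clustering.
#'
#' @param mat Numeric matrix, features x samples; values must be positive
#'   unless a pseudocount is supplied.
#' @param pseudocount Added to every value before log2 (default 0).
#' @return The transformed matrix.
#' @examples
#' log2MeanCenter(matrix(c(1, 2, 4), nrow = 1))  # -1 0 1
#' @export
log2MeanCenter <- function(mat, pseudocount = 0) {
  mat <- as.matrix(mat)
  if (any(mat + pseudocount <= 0, na.rm = TRUE))
    stop("non-positive values; supply a pseudocount", call. = FALSE)
  lg <- log2(mat + pseudocount)
  lg - rowMeans(lg, na.rm = TRUE)
}

#' Association of gene expression with the 14q-index
#'
#' Correlates per-gene log2 fold change with the per-sample 14q-index and
#' summarizes group means across normal, defect-negative and defect-positive
#' samples, reporting whether the means decrease monotonically with defect
#' status (the signature of imprinted-gene silencing by loss of imprinting).
#'
#' @param folds Output of [relativeExpression()] (sample_id, gene,
#'   fold_change).
#' @param scores Output of [scoreSamples()] (sample_id, group,
#'   fourteen_q_index, call).
#' @param normalGroup Label of the normal group in \code{scores}.
#' @return List: \code{correlations} (gene, r, r.squared, n) and
#'   \code{groupMeans} (gene x status mean log2 fold, with a
#'   \code{monotone_decreasing} flag).
#' @export
expressionIndexAssociation <- function(folds, scores,
                                       normalGroup = "normal") {
  stopifnot(all(c("sample_id", "gene", "fold_change") %in% names(folds)),
            all(c("sample_id", "fourteen_q_index", "call") %in%
                  names(scores)))
  x <- merge(folds,
             scores[, c("sample_id", "group", "fourteen_q_index",
                        "call")[c("sample_id", "group", "fourteen_q_index",
                                  "call") %in% names(scores)]],
             by = "sample_id", sort = FALSE)
  if (nrow(x) == 0L) stop("no samples shared by folds and scores",
                          call. = FALSE)
  x$log2_fold <- log2(x$fold_change)
  cors <- do.call(rbind, lapply(split(x, x$gene), function(g) {
    pc <- pearsonCorrelation(g$log2_fold, g$fourteen_q_index)
    data.frame(gene = g$gene[1], r = pc$r, r.squared = pc$r.squared,
               n = pc$n)
  }))
  rownames(cors) <- NULL
  gm <- NULL
  if ("group" %in% names(x)) {
    x$status <- ifelse(x$group == normalGroup, "normal",
                       ifelse(x$call == "positive", "14q-I(+)", "14q-I(-)"))
    x$status <- factor(x$status, c("normal", "14q-I(-)", "14q-I(+)"))
    gm <- do.call(rbind, lapply(split(x, x$gene), function(g) {
      m <- tapply(g$log2_fold, g$status, mean)
      data.frame(gene = g$gene[1],
                 mean_normal = unname(m["normal"]),
                 mean_negative = unname(m["14q-I(-)"]),
                 mean_positive = unname(m["14q-I(+)"]),
                 monotone_decreasing =
                   !anyNA(m) && all(diff(as.numeric(m)) < 0))
    }))
    rownames(gm) <- NULL
  }
  list(correlations = cors, groupMeans = gm)
}
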