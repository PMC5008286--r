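#' Deviation of a DMR methylation value from the imprinted level
#'
#' In normal tissue an imprinted DMR is methylated on exactly one parental
#' allele, so bulk methylation sits near 50%. Both gain and loss of
#' methylation disturb imprinting, so the defect extent is the absolute
#' deviation from the expected level.
#'
#' @param methylation Numeric vector of % methylation in [0, 100].
#' @param expectedLevel Expected imprinted level in % (default 50; tissues
#'   with age-shifted baselines, e.g. buccal epithelium, may override).
#' @return \code{|methylation - expectedLevel|}, in %.
#' @examples
#' dmrDeviation(c(50, 31, 69))  # 0 19 19
#' @export
dmrDeviation <- function(methylation, expectedLevel = 50) {
  assertPct(methylation, "methylation")
  assertPct(expectedLevel, "expectedLevel")
  abs(methylation - expectedLevel)
}

#' The 14q-index: mean absolute deviation of the three 14q32 DMRs from 50%
#'
#' \deqn{index = (|m_1 - 50| + |m_2 - 50| + |m_3 - 50|) / 3}
#'
#' where \eqn{m_1, m_2, m_3} are the % methylation of DMR-1, DMR-2 (the two
#' intergenic DMRs between DLK1 and MEG3) and DMR-3 (the MEG3 promoter DMR).
#' Missing DMRs are tolerated: the index is then the mean over the available
#' DMRs and the \code{"complete"} attribute marks affected samples (single-DMR
#' designs, e.g. a mouse IG-DMR assay, use the same machinery).
#'
#' @param m1,m2,m3 Numeric vectors of % methylation (NA = missing);
#'   vectorized over samples.
#' @param expectedLevel Expected imprinted level (default 50).
#' @return Numeric vector of index values, with attributes \code{complete}
#'   (logical: all three DMRs present) and \code{nDmrs} (count used).
#' @examples
#' fourteenQIndex(50, 50, 50)   # 0
#' fourteenQIndex(31, 35, 45)   # 13
#' @export
fourteenQIndex <- function(m1, m2, m3, expectedLevel = 50) {
  d <- cbind(dmrDeviation(m1, expectedLevel),
             dmrDeviation(m2, expectedLevel),
             dmrDeviation(m3, expectedLevel))
  n <- rowSums(!is.na(d))
  if (any(n == 0L))
    stop("all three DMR values missing for sample(s): ",
         paste(utils::head(which(n == 0L), 5L), collapse = ", "),
         call. = FALSE)
  idx <- rowMeans(d, na.rm = TRUE)
  attr(idx, "complete") <- n == 3L
  attr(idx, "nDmrs") <- n
  idx
}

#' Normal reference range per DMR
#'
#' Builds per-DMR normal statistics from normal-tissue methylation values,
#' in one of two modes:
#' \describe{
#'   \item{mean_ci}{t-based confidence interval for the mean:
#'     mean +/- t(1 - alpha/2, n - 1) * sd / sqrt(n). This is how narrow
#'     published normal bands (e.g. 51-55% around a 53% buccal DMR-1 mean)
#'     arise at modest n.}
#'   \item{reference_interval}{mean +/- z(1 - alpha/2) * sd, covering the
#'     stated fraction of individual normal values.}
#' }
#'
#' @param values Named list of numeric vectors (one per DMR), a single
#'   numeric vector (treated as one DMR), or a data.frame with columns
#'   \code{dmr} and \code{methylation_pct}.
#' @param ciLevel Confidence/coverage level (default 0.95).
#' @param mode "mean_ci" (default) or "reference_interval".
#' @param indexThreshold 14q-index threshold recorded alongside the ranges
#'   (default 8.5).
#' @return A [ReferenceRange-class].
#' @examples
#' rr <- referenceRange(list(`DMR-1` = c(51, 53, 55)))
#' rangeTable(rr)  # mean 53, interval approx [48.0, 58.0]
#' @export
referenceRange <- function(values, ciLevel = 0.95,
                           mode = c("mean_ci", "reference_interval"),
                           indexThreshold = 8.5) {
  mode <- match.arg(mode)
  if (ciLevel <= 0 || ciLevel >= 1)
    stop("ciLevel must lie strictly between 0 and 1", call. = FALSE)
  if (is.data.frame(values)) {
    stopifnot(all(c("dmr", "methylation_pct") %in% names(values)))
    values <- split(values$methylation_pct, values$dmr)
  }
  if (is.numeric(values)) values <- list(DMR = values)
  stats <- lapply(names(values), function(d) {
    v <- values[[d]][!is.na(values[[d]])]
    assertPct(v, paste0("normal values (", d, ")"))
    n <- length(v)
    if (n < 3L)
      stop("need at least 3 normal samples for ", d, " (have ", n, ")",
           call. = FALSE)
    m <- mean(v)
    s <- stats::sd(v)
    if (s == 0) {
      warning("zero variance for ", d, "; degenerate range [mean, mean]",
              call. = FALSE)
      hw <- 0
    } else {
      hw <- switch(mode,
        mean_ci = stats::qt(1 - (1 - ciLevel) / 2, df = n - 1) * s / sqrt(n),
        reference_interval = stats::qnorm(1 - (1 - ciLevel) / 2) * s)
    }
    data.frame(dmr = d, mean = m, lower = m - hw, upper = m + hw, n = n)
  })
  methods::new("ReferenceRange",
               ranges = do.call(rbind, stats),
               indexThreshold = indexThreshold,
               ciLevel = ciLevel,
               mode = mode)
}

#' @rdname referenceRange
#' @param x A \code{ReferenceRange}.
#' @export
setMethod("rangeTable", "ReferenceRange", function(x) x@ranges)

#' @rdname referenceRange
#' @export
setMethod("indexThreshold", "ReferenceRange", function(x) x@indexThreshold)

setMethod("show", "ReferenceRange", function(object) {
  cat(sprintf("ReferenceRange (%s, %.0f%% level), index threshold %.2f\n",
              object@mode, 100 * object@ciLevel, object@indexThreshold))
  print(object@ranges, row.names = FALSE)
})

#' Classify a sample as defect-positive or -negative from its 14q-index
#'
#' A sample is called positive when its index strictly exceeds the threshold
#' (default 8.5); an index exactly at the threshold is negative. The
#' comparator is configurable for sensitivity analyses.
#'
#' @param index Numeric vector of 14q-index values.
#' @param threshold Positivity threshold (default 8.5).
#' @param strict Use strict inequality (default TRUE).
#' @return Character vector, "positive" or "negative".
#' @examples
#' classifySample(c(0, 8.5, 18.6))  # negative negative positive
#' @export
classifySample <- function(index, threshold = 8.5, strict = TRUE) {
  if (any(!is.finite(index)))
    stop("index values must be finite", call. = FALSE)
  pos <- if (strict) index > threshold else index >= threshold
  ifelse(pos, "positive", "negative")
}

#' Direction of a methylation defect relative to a normal range
#'
#' @param methylation Numeric vector of % methylation.
#' @param range A [ReferenceRange-class] (with \code{dmr} naming the row to
#'   use) or a numeric vector c(lower, upper).
#' @param dmr DMR identifier to select from a multi-DMR range (unneeded for
#'   single-DMR ranges or numeric bounds).
#' @return Character vector: "hypo" (below the lower bound), "hyper" (above
#'   the upper bound) or "normal".
#' @examples
#' defectDirection(c(60, 74, 80), c(72, 76))  # hypo normal hyper
#' @export
defectDirection <- function(methylation, range, dmr = NULL) {
  if (methods::is(range, "ReferenceRange")) {
    tab <- rangeTable(range)
    row <- if (is.null(dmr)) {
      if (nrow(tab) != 1L)
        stop("range covers several DMRs; supply `dmr`", call. = FALSE)
      tab
    } else {
      hit <- tab[tab$dmr == dmr, , drop = FALSE]
      if (nrow(hit) != 1L) stop("no range for DMR ", dmr, call. = FALSE)
      hit
    }
    bounds <- c(row$lower, row$upper)
  } else {
    stopifnot(is.numeric(range), length(range) == 2L, range[1] <= range[2])
    bounds <- range
  }
  ifelse(methylation < bounds[1], "hypo",
         ifelse(methylation > bounds[2], "hyper", "normal"))
}

#' Score every sample of a long methylation table
#'
#' Computes per-DMR deviation extents, the 14q-index and the defect call for
#' each sample of a long-format methylation table (as produced by
#' [simulateCohort()] or read by [readMethylationTable()]).
#'
#' @param meth data.frame with columns sample_id, group, locus, dmr,
#'   methylation_pct (age_class optional).
#' @param locus Locus whose DMRs enter the index (default "14q32").
#' @param expectedLevel Expected imprinted level (default 50); a named vector
#'   gives per-DMR overrides (e.g. c(`DMR-1` = 53, `DMR-2` = 64) for buccal
#'   tissue).
#' @param threshold Index positivity threshold (default 8.5).
#' @param range Optional [ReferenceRange-class]; adds per-DMR defect
#'   directions.
#' @return data.frame: sample_id, group, one deviation column per DMR,
#'   fourteen_q_index, n_dmrs, complete, call (and direction columns when a
#'   range is given).
#' @export
scoreSamples <- function(meth, locus = "14q32", expectedLevel = 50,
                         threshold = 8.5, range = NULL) {
  stopifnot(all(c("sample_id", "locus", "dmr", "methylation_pct") %in%
                  names(meth)))
  sub <- meth[meth$locus == locus, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("no rows for locus ", locus, call. = FALSE)
  dmrs <- sort(unique(sub$dmr))
  wide <- stats::reshape(
    sub[, c("sample_id", "dmr", "methylation_pct")],
    idvar = "sample_id", timevar = "dmr", direction = "wide")
  names(wide) <- sub("^methylation_pct\\.", "", names(wide))
  expected <- if (length(expectedLevel) == 1L && is.null(names(expectedLevel)))
    stats::setNames(rep(expectedLevel, length(dmrs)), dmrs)
  else {
    lev <- stats::setNames(rep(50, length(dmrs)), dmrs)
    lev[names(expectedLevel)[names(expectedLevel) %in% dmrs]] <-
      expectedLevel[names(expectedLevel) %in% dmrs]
    lev
  }
  dev <- sapply(dmrs, function(d)
    dmrDeviation(wide[[d]], expected[[d]]))
  dev <- matrix(dev, nrow = nrow(wide),
                dimnames = list(NULL, paste0("deviation.", dmrs)))
  nDmrs <- rowSums(!is.na(dev))
  if (any(nDmrs == 0L))
    stop("sample(s) with no DMR values at ", locus, call. = FALSE)
  idx <- rowMeans(dev, na.rm = TRUE)
  out <- data.frame(sample_id = wide$sample_id, dev,
                    fourteen_q_index = idx,
                    n_dmrs = nDmrs,
                    complete = nDmrs == length(dmrs),
                    call = classifySample(idx, threshold),
                    check.names = FALSE)
  if (!is.null(range)) {
    tab <- rangeTable(range)
    for (d in intersect(dmrs, tab$dmr))
      out[[paste0("direction.", d)]] <-
        defectDirection(wide[[d]], range, dmr = d)
  }
  extra <- unique(meth[, intersect(c("sample_id", "group", "age_class"),
                                   names(meth)), drop = FALSE])
  merge(extra, out, by = "sample_id", sort = FALSE)
}
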