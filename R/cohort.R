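#' Product-moment correlation with R-squared
#'
#' Textbook Pearson correlation, computed from sums of centered
#' cross-products, on pairwise-complete observations. Implemented directly so
#' downstream reports control their own NA policy and error behaviour;
#' \code{stats::cor} serves as an independent cross-check in the test suite.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with \code{r}, \code{r.squared} and \code{n} (complete pairs
#'   used).
#' @examples
#' pearsonCorrelation(1:10, 2 * (1:10))$r  # 1
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L)
    stop("need at least 3 complete pairs (have ", n, ")", call. = FALSE)
  dx <- x - mean(x); dy <- y - mean(y)
  sxx <- sum(dx^2); syy <- sum(dy^2)
  if (sxx == 0 || syy == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  r <- sum(dx * dy) / sqrt(sxx * syy)
  list(r = r, r.squared = r^2, n = n)
}

twoSidedT <- function(t, df) 2 * stats::pt(-abs(t), df)

welchTTest <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("each group needs n >= 2", call. = FALSE)
  v1 <- stats::var(x); v2 <- stats::var(y)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(statistic = t, df = df, p.value = twoSidedT(t, df))
}

pooledTTest <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("each group needs n >= 2", call. = FALSE)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
    (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(statistic = t, df = df, p.value = twoSidedT(t, df))
}

onewayAnova <- function(values, group) {
  groups <- split(values, group)
  k <- length(groups)
  ns <- lengths(groups)
  N <- sum(ns)
  grand <- mean(values)
  ssb <- sum(ns * (vapply(groups, mean, numeric(1)) - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1L; df2 <- N - k
  f <- (ssb / df1) / (ssw / df2)
  list(statistic = f, df = c(df1, df2),
       p.value = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Compare grouped values: two-sample t test or one-way ANOVA
#'
#' Two groups are compared by a two-sided t test (Welch unequal-variance by
#' default; classical pooled Student t on request); three or more groups by a
#' one-way ANOVA F test. All statistics use the exact textbook formulas, with
#' p-values from the t / F distributions.
#'
#' @param values Numeric vector of observations.
#' @param group Grouping vector (coerced to factor), same length.
#' @param varEqual For two groups, use the pooled Student t (default FALSE =
#'   Welch).
#' @return An object of class \code{"htest"}: statistic (t or F), parameter
#'   (degrees of freedom), p.value, method, and a \code{groupSummary}
#'   data.frame (n, mean, sd per group).
#' @examples
#' groupTests(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3),
#'            varEqual = TRUE)
#' @export
groupTests <- function(values, group, varEqual = FALSE) {
  group <- factor(group)
  group <- droplevels(group)
  stopifnot(length(values) == length(group))
  ok <- !is.na(values) & !is.na(group)
  values <- values[ok]; group <- droplevels(group[ok])
  groups <- split(values, group)
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(lengths(groups) < 2L))
    stop("every group needs n >= 2; offending group(s): ",
         paste(names(groups)[lengths(groups) < 2L], collapse = ", "),
         call. = FALSE)
  summ <- data.frame(group = names(groups),
                     n = lengths(groups),
                     mean = vapply(groups, mean, numeric(1)),
                     sd = vapply(groups, stats::sd, numeric(1)),
                     row.names = NULL)
  if (length(groups) == 2L) {
    res <- if (varEqual) pooledTTest(groups[[1]], groups[[2]])
           else welchTTest(groups[[1]], groups[[2]])
    method <- if (varEqual) "Two-sample Student t test (pooled variance)"
              else "Welch two-sample t test"
    stat <- c(t = res$statistic)
    par <- c(df = res$df)
  } else {
    res <- onewayAnova(values, group)
    method <- "One-way ANOVA"
    stat <- c(F = res$statistic)
    par <- c(df1 = res$df[1], df2 = res$df[2])
  }
  structure(
    list(statistic = stat, parameter = par, p.value = res$p.value,
         method = method, data.name = "values by group",
         estimate = stats::setNames(summ$mean, paste("mean", summ$group)),
         groupSummary = summ),
    class = "htest")
}

#' Demethylation extent relative to the normal group, locus versus LINE-1
#'
#' For every record, the demethylation delta is normal-group mean minus the
#' observed value (positive = demethylation). Per-sample locus deltas
#' (averaging a locus's DMRs within a sample) are compared between a target
#' locus (default the 14q32 imprinted DMRs) and a genome-wide surrogate
#' (default LINE-1 repeat methylation) with a two-sided Welch t test: this is
#' the test of whether locus-specific demethylation exceeds what global
#' demethylation alone would produce.
#'
#' @param meth Long methylation data.frame (sample_id, group, locus, dmr,
#'   methylation_pct).
#' @param normalGroup Label of the normal group (default "normal").
#' @param locus Target locus (default "14q32").
#' @param comparatorLocus Genome-wide surrogate locus (default "LINE1").
#' @param groups Optional subset of (tumor) groups to compare; default: all
#'   non-normal groups.
#' @param varEqual Use the pooled t instead of Welch (default FALSE).
#' @return List: \code{deltas} (per-record deltas), \code{sampleDeltas}
#'   (per-sample per-locus means), \code{groupMeans} (group x locus mean
#'   deltas), \code{test} (htest comparing target vs comparator locus).
#' @export
demethylationExtent <- function(meth, normalGroup = "normal",
                                locus = "14q32", comparatorLocus = "LINE1",
                                groups = NULL, varEqual = FALSE) {
  stopifnot(all(c("sample_id", "group", "locus", "dmr", "methylation_pct")
                %in% names(meth)))
  normals <- meth[meth$group == normalGroup, , drop = FALSE]
  if (nrow(normals) == 0L)
    stop("no rows for normal group '", normalGroup, "'", call. = FALSE)
  key <- function(d) paste(d$locus, d$dmr, sep = "\r")
  normalMean <- tapply(normals$methylation_pct, key(normals), mean)
  missing <- setdiff(unique(key(meth)), names(normalMean))
  if (length(missing))
    stop("no normal mean available for: ",
         paste(gsub("\r", "/", missing), collapse = ", "), call. = FALSE)
  deltas <- meth
  deltas$delta <- as.numeric(normalMean[key(meth)]) - meth$methylation_pct

  if (is.null(groups)) groups <- setdiff(unique(meth$group), normalGroup)
  tum <- deltas[deltas$group %in% groups, , drop = FALSE]
  agg <- stats::aggregate(delta ~ sample_id + group + locus, data = tum,
                          FUN = mean)
  groupMeans <- stats::aggregate(delta ~ group + locus, data = agg,
                                 FUN = mean)
  both <- agg[agg$locus %in% c(locus, comparatorLocus), , drop = FALSE]
  test <- if (all(c(locus, comparatorLocus) %in% both$locus))
    groupTests(both$delta, factor(both$locus, c(locus, comparatorLocus)),
               varEqual = varEqual)
  else NULL
  list(deltas = deltas, sampleDeltas = agg, groupMeans = groupMeans,
       test = test)
}

#' Per-group counts and percent of defect-positive samples
#'
#' @param calls Character vector of "positive"/"negative" calls.
#' @param group Grouping vector, same length.
#' @param digits Decimal places for the displayed percent (default 0,
#'   i.e. nearest integer; use 1 for one-decimal reporting). Full precision
#'   is kept in \code{percent_positive_exact}.
#' @return data.frame: group, n_total, n_positive, percent_positive (rounded),
#'   percent_positive_exact.
#' @examples
#' classificationSummary(rep(c("positive", "negative"), c(20, 3)),
#'                       rep("early", 23))$percent_positive  # 87
#' @export
classificationSummary <- function(calls, group, digits = 0) {
  stopifnot(length(calls) == length(group))
  bad <- setdiff(unique(calls), c("positive", "negative"))
  if (length(bad))
    stop("calls must be 'positive' or 'negative'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (!is.factor(group)) group <- factor(group)
  empty <- levels(group)[!levels(group) %in% unique(as.character(group))]
  if (length(empty))
    warning("empty group(s) omitted: ", paste(empty, collapse = ", "),
            call. = FALSE)
  group <- droplevels(group)
  nTotal <- as.integer(table(group))
  nPos <- as.integer(tapply(calls == "positive", group, sum))
  pct <- 100 * nPos / nTotal
  data.frame(group = levels(group),
             n_total = nTotal,
             n_positive = nPos,
             percent_positive = round(pct, digits),
             percent_positive_exact = pct,
             row.names = NULL)
}

#' Parent-child methylation correlations in family triads
#'
#' Pearson correlation between the affected child's DMR methylation and each
#' parent's, per DMR. Incomplete triads (any missing member/value for that
#' DMR) are excluded pairwise and counted.
#'
#' @param triads Long data.frame: triad_id, member (child/mother/father),
#'   dmr, methylation_pct.
#' @return data.frame: dmr, parent, r, r.squared, n_triads, n_excluded.
#' @export
triadCorrelation <- function(triads) {
  stopifnot(all(c("triad_id", "member", "dmr", "methylation_pct") %in%
                  names(triads)))
  out <- list()
  for (d in sort(unique(triads$dmr))) {
    sub <- triads[triads$dmr == d, , drop = FALSE]
    wide <- stats::reshape(sub[, c("triad_id", "member", "methylation_pct")],
                           idvar = "triad_id", timevar = "member",
                           direction = "wide")
    names(wide) <- sub("^methylation_pct\\.", "", names(wide))
    for (parent in c("father", "mother")) {
      if (!all(c("child", parent) %in% names(wide))) next
      ok <- stats::complete.cases(wide$child, wide[[parent]])
      if (sum(ok) < 3L)
        stop("fewer than 3 complete child-", parent, " pairs at ", d,
             call. = FALSE)
      pc <- pearsonCorrelation(wide$child[ok], wide[[parent]][ok])
      out[[length(out) + 1L]] <-
        data.frame(dmr = d, parent = parent, r = pc$r,
                   r.squared = pc$r.squared, n_triads = pc$n,
                   n_excluded = sum(!ok))
    }
  }
  do.call(rbind, out)
}
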