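sniffDelimiter <- function(path) {
  first <- readLines(path, n = 1L)
  if (lengths(regmatches(first, gregexpr("\t", first))) > 0) "\t"
  else if (grepl(",", first)) ","
  else "\t"
}

#' Read and validate a long-format methylation table
#'
#' Accepts TSV or CSV (delimiter sniffed from the header line) with columns
#' sample_id, group, locus, dmr, methylation_pct (age_class and age
#' optional). Non-numeric or out-of-range methylation values and duplicated
#' (sample, locus, dmr) records are hard errors naming the offending rows —
#' silent coercion of malformed cohort data is never acceptable.
#'
#' @param path File path.
#' @return Validated data.frame.
#' @export
readMethylationTable <- function(path) {
  sep <- sniffDelimiter(path)
  x <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, colClasses = NA,
                         check.names = FALSE)
  need <- c("sample_id", "group", "locus", "dmr", "methylation_pct")
  absent <- setdiff(need, names(x))
  if (length(absent))
    stop("missing required column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  meth <- suppressWarnings(as.numeric(x$methylation_pct))
  badNum <- which(is.na(meth) & !is.na(x$methylation_pct))
  if (length(badNum))
    stop("non-numeric methylation_pct at data row(s): ",
         paste(utils::head(badNum, 5L), collapse = ", "), call. = FALSE)
  badRange <- which(!is.na(meth) & (meth < 0 | meth > 100))
  if (length(badRange))
    stop("methylation_pct outside [0, 100] at data row(s): ",
         paste(utils::head(badRange, 5L), collapse = ", "), call. = FALSE)
  x$methylation_pct <- meth
  key <- paste(x$sample_id, x$locus, x$dmr, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicated (sample, locus, dmr) at data row(s): ",
         paste(utils::head(dup, 5L), collapse = ", "), call. = FALSE)
  x
}

#' Read and validate a survival table
#'
#' Requires columns sample_id, time (> 0) and event (0/1).
#' @param path File path (TSV/CSV, delimiter sniffed).
#' @return Validated data.frame.
#' @export
readSurvivalTable <- function(path) {
  sep <- sniffDelimiter(path)
  x <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  absent <- setdiff(need, names(x))
  if (length(absent))
    stop("missing required column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(x$time)) || any(x$time <= 0))
    stop("time must be positive at data row(s): ",
         paste(utils::head(which(!(x$time > 0)), 5L), collapse = ", "),
         call. = FALSE)
  if (!all(x$event %in% c(0, 1)))
    stop("event must be 0 or 1", call. = FALSE)
  x
}

#' Write a data.frame as TSV
#'
#' Numeric columns are rounded to \code{digits} decimals (default 6, which
#' makes write/read round trips lossless at 6 decimal places; use 2 for
#' compact human-facing output).
#'
#' @param x data.frame.
#' @param path Output path.
#' @param digits Decimal places for numeric columns (NA = full precision).
#' @return Invisibly, \code{path}.
#' @export
writeTsv <- function(x, path, digits = 6) {
  if (!is.na(digits)) {
    num <- vapply(x, is.numeric, logical(1))
    x[num] <- lapply(x[num], round, digits = digits)
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
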