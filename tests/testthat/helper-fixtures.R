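# Small in-code fixtures shared across test files.

# Build a CloneMatrix directly from a 0/1/NA matrix (conversion rates
# default to fully converted).
makeCloneMatrix <- function(calls, conversionRates = rep(1, nrow(calls))) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls)))
    rownames(calls) <- paste0("clone_", seq_len(nrow(calls)))
  if (is.null(colnames(calls)))
    colnames(calls) <- paste0("CpG_", seq_len(ncol(calls)))
  methods::new("CloneMatrix", calls = calls,
               conversionRates = conversionRates)
}

# Long methylation table for a handful of samples at the 14q32 DMRs
# (+ optional extra loci), one row per (sample, dmr).
makeMethTable <- function(values, group = "tumor") {
  # values: named list sample_id -> numeric c(DMR-1, DMR-2, DMR-3)
  do.call(rbind, lapply(names(values), function(id) {
    data.frame(sample_id = id, group = group, locus = "14q32",
               dmr = c("DMR-1", "DMR-2", "DMR-3"),
               methylation_pct = values[[id]])
  }))
}

# Construct y with an exact sample Pearson correlation r against x,
# by combining standardized x with an orthogonalized noise vector.
vectorWithExactR <- function(x, r, seed = 1) {
  set.seed(seed)
  e <- stats::rnorm(length(x))
  e <- stats::residuals(stats::lm(e ~ x))
  xs <- (x - mean(x)) / stats::sd(x)
  es <- (e - mean(e)) / stats::sd(e)
  r * xs + sqrt(1 - r^2) * es
}
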