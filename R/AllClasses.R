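#' ReferenceAmplicon: a bisulfite PCR amplicon with annotated cytosine context
#'
#' Holds the (unconverted, top-strand) reference sequence of a bisulfite
#' amplicon together with the positions of CpG cytosines and of cytosines
#' outside CpG context. CpG positions are where methylation is read;
#' non-CpG cytosines should always read as T after complete conversion and
#' therefore measure per-clone conversion efficiency. All coordinates are
#' 1-based, following R convention.
#'
#' @slot sequence Character scalar, uppercase DNA over {A, C, G, T}.
#' @slot cpgPositions Integer vector, 1-based offsets of the C of each CpG.
#' @slot nonCpgCPositions Integer vector, 1-based offsets of cytosines not
#'   followed by G.
#'
#' @seealso [referenceAmplicon()] for the user-facing constructor, which
#'   derives both position sets from the sequence.
#' @exportClass ReferenceAmplicon
setClass("ReferenceAmplicon",
  representation(
    sequence = "character",
    cpgPositions = "integer",
    nonCpgCPositions = "integer"
  )
)

setValidity("ReferenceAmplicon", function(object) {
  msg <- character()
  seq <- object@sequence
  if (length(seq) != 1L || is.na(seq) || nchar(seq) == 0L)
    msg <- c(msg, "sequence must be a single non-empty string")
  else {
    chars <- strsplit(seq, "")[[1]]
    if (!all(chars %in% c("A", "C", "G", "T")))
      msg <- c(msg, "sequence must be uppercase DNA over {A,C,G,T}")
    p <- object@cpgPositions
    if (any(p < 1L) || any(p >= nchar(seq)))
      msg <- c(msg, "cpgPositions out of bounds")
    else if (!all(chars[p] == "C" & chars[p + 1L] == "G"))
      msg <- c(msg, "every cpgPosition must point at the C of a CpG")
    q <- object@nonCpgCPositions
    if (any(q < 1L) || any(q > nchar(seq)))
      msg <- c(msg, "nonCpgCPositions out of bounds")
    else if (!all(chars[q] == "C"))
      msg <- c(msg, "every nonCpgCPosition must point at a C")
    if (length(intersect(p, q)))
      msg <- c(msg, "CpG and non-CpG position sets must be disjoint")
  }
  if (length(msg)) msg else TRUE
})

#' CloneMatrix: per-clone, per-CpG methylation calls with conversion QC
#'
#' A clones x CpG-sites matrix of binary methylation calls (1 = methylated,
#' 0 = unmethylated, NA = missing/ambiguous) as read from bisulfite-converted
#' clone sequences, together with the per-clone bisulfite conversion rate
#' estimated from non-CpG cytosines.
#'
#' @slot calls Integer matrix, clones in rows (rownames = clone ids), CpG
#'   sites in columns; entries in {0L, 1L, NA}.
#' @slot conversionRates Numeric vector, one per clone, in [0, 1]; NA when no
#'   non-CpG cytosine was readable for that clone.
#'
#' @seealso [callClones()], [summarizeCloneMatrix()],
#'   [detectImprintingPattern()]
#' @exportClass CloneMatrix
setClass("CloneMatrix",
  representation(
    calls = "matrix",
    conversionRates = "numeric"
  )
)

setValidity("CloneMatrix", function(object) {
  msg <- character()
  m <- object@calls
  if (!is.matrix(m) || nrow(m) < 1L || ncol(m) < 1L)
    msg <- c(msg, "calls must be a non-empty matrix")
  else {
    vals <- m[!is.na(m)]
    if (length(vals) && !all(vals %in% c(0L, 1L)))
      msg <- c(msg, "calls must be 0, 1 or NA")
    if (length(object@conversionRates) != nrow(m))
      msg <- c(msg, "one conversion rate per clone required")
    cr <- object@conversionRates
    if (any(!is.na(cr) & (cr < 0 | cr > 1)))
      msg <- c(msg, "conversion rates must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' ReferenceRange: per-DMR normal methylation ranges and an index threshold
#'
#' Normal-tissue reference statistics per DMR (mean and interval bounds, with
#' the number of normals they are based on) plus the 14q-index threshold used
#' for defect-positive calls.
#'
#' @slot ranges data.frame with columns dmr, mean, lower, upper, n.
#' @slot indexThreshold Numeric scalar; samples with index strictly above it
#'   are called defect-positive.
#' @slot ciLevel Confidence/coverage level used to build the interval.
#' @slot mode Either "mean_ci" (t-interval for the mean) or
#'   "reference_interval" (mean +/- z * sd).
#'
#' @seealso [referenceRange()], [defectDirection()]
#' @exportClass ReferenceRange
setClass("ReferenceRange",
  representation(
    ranges = "data.frame",
    indexThreshold = "numeric",
    ciLevel = "numeric",
    mode = "character"
  )
)

setValidity("ReferenceRange", function(object) {
  msg <- character()
  r <- object@ranges
  need <- c("dmr", "mean", "lower", "upper", "n")
  if (!all(need %in% names(r)))
    msg <- c(msg, paste("ranges must have columns", paste(need, collapse = ", ")))
  else if (nrow(r)) {
    if (any(r$lower > r$mean | r$mean > r$upper))
      msg <- c(msg, "each range must satisfy lower <= mean <= upper")
    if (anyDuplicated(r$dmr))
      msg <- c(msg, "dmr identifiers must be unique")
  }
  if (length(object@indexThreshold) != 1L || !is.finite(object@indexThreshold))
    msg <- c(msg, "indexThreshold must be a finite scalar")
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: parameters of the synthetic methylation study generator
#'
#' Bundles every tunable of the synthetic-data module: cohort sizes, baseline
#' methylation and its spread, the group-specific hypomethylation shifts at
#' the 14q32 DMRs and at LINE-1, the coupling of the H19 defect extent to the
#' 14q-index, parent-child correlation targets, bisulfite-clone parameters,
#' the expression decay rate and survival hazard parameters, and the global
#' seed from which all component substreams are derived.
#'
#' Percentage parameters are on the 0-100 scale. Defaults encode the study
#' conditions the generator emulates: imprinted DMRs centred at 50%
#' methylation, a ~19% mean DMR hypomethylation in early-onset tumors versus
#' ~5% at LINE-1, ~6% in late-onset tumors, an H19-to-index defect coupling
#' of r = 0.78, and parent-child correlations of 0.5 (father, DMR-1) and
#' 0.63 (mother, DMR-2). The baseline DMR standard deviation of 8.8 is a
#' calibration chosen so the expected 14q-index of normal samples is ~7
#' (E|N(0, sigma)| = sigma * sqrt(2/pi)).
#'
#' @seealso [SimulationConfig()] for the constructor documenting each field.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    nPerGroup = "integer",
    groups = "character",
    dmrBaselineMean = "numeric",
    dmrBaselineSd = "numeric",
    shift14qEarly = "numeric",
    shift14qLate = "numeric",
    shiftLine1 = "numeric",
    line1Baseline = "numeric",
    line1Sd = "numeric",
    h19CouplingR = "numeric",
    triadRFatherDmr1 = "numeric",
    triadRMotherDmr2 = "numeric",
    triadMeanDmr1 = "numeric",
    triadMeanDmr2 = "numeric",
    triadSdDmr1 = "numeric",
    triadSdDmr2 = "numeric",
    nClones = "integer",
    nCpg = "integer",
    pMethDense = "numeric",
    pMethSparse = "numeric",
    conversionEfficiency = "numeric",
    alleleAssignment = "character",
    expressionGamma = "numeric",
    hazardH0 = "numeric",
    hazardBeta = "numeric",
    censoringMax = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nPerGroup < 2L)
    msg <- c(msg, "nPerGroup must be at least 2")
  if (!all(c("normal", "early_onset", "late_onset") %in% object@groups))
    msg <- c(msg, "groups must include normal, early_onset and late_onset")
  for (s in c("dmrBaselineSd", "line1Sd", "triadSdDmr1", "triadSdDmr2"))
    if (slot(object, s) <= 0)
      msg <- c(msg, paste(s, "must be positive"))
  for (s in c("dmrBaselineMean", "line1Baseline"))
    if (slot(object, s) < 0 || slot(object, s) > 100)
      msg <- c(msg, paste(s, "must lie in [0, 100]"))
  for (s in c("h19CouplingR", "triadRFatherDmr1", "triadRMotherDmr2"))
    if (abs(slot(object, s)) >= 1)
      msg <- c(msg, paste(s, "must lie strictly inside (-1, 1)"))
  for (s in c("pMethDense", "pMethSparse", "conversionEfficiency"))
    if (slot(object, s) < 0 || slot(object, s) > 1)
      msg <- c(msg, paste(s, "must lie in [0, 1]"))
  if (object@nClones < 2L) msg <- c(msg, "nClones must be at least 2")
  if (object@nCpg < 1L) msg <- c(msg, "nCpg must be at least 1")
  if (!object@alleleAssignment %in% c("balanced", "random"))
    msg <- c(msg, "alleleAssignment must be 'balanced' or 'random'")
  if (object@expressionGamma < 0)
    msg <- c(msg, "expressionGamma must be non-negative")
  if (object@hazardH0 <= 0) msg <- c(msg, "hazardH0 must be positive")
  if (object@censoringMax <= 0) msg <- c(msg, "censoringMax must be positive")
  if (length(msg)) msg else TRUE
})
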