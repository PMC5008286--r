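#' Construct a SimulationConfig
#'
#' All tunables of the synthetic methylation study generator with their
#' default study conditions. Percentages are on the 0-100 scale; shifts are
#' additive in percentage points (negative = hypomethylation).
#'
#' @param nPerGroup Samples per cohort group (default 50).
#' @param groups Cohort group labels.
#' @param dmrBaselineMean Normal imprinted-DMR methylation (%), default 50.
#' @param dmrBaselineSd Between-sample SD of DMR methylation (%), default
#'   8.8 — calibrated so the expected 14q-index of normal samples is about 7
#'   (E|N(0, sigma)| = sigma * sqrt(2 / pi)).
#' @param shift14qEarly Mean shift of the 14q32 DMRs in early-onset tumors
#'   (default -19).
#' @param shift14qLate Same for late-onset tumors (default -6).
#' @param shiftLine1 Mean LINE-1 shift in tumors of either onset
#'   (default -5).
#' @param line1Baseline Normal LINE-1 methylation (%), default 70.
#' @param line1Sd SD of LINE-1 methylation (%), default 3 (repeat-element
#'   pyrosequencing is tight).
#' @param h19CouplingR Target correlation between the 14q-index and the H19
#'   defect extent (default 0.78).
#' @param triadRFatherDmr1 Target child-father correlation at DMR-1
#'   (default 0.5).
#' @param triadRMotherDmr2 Target child-mother correlation at DMR-2
#'   (default 0.63).
#' @param triadMeanDmr1,triadMeanDmr2 Family buccal DMR means (%), defaults
#'   58 and 70 — above the unrelated-normal buccal means (53 and 64),
#'   reflecting the hypermethylation seen in patients and parents.
#' @param triadSdDmr1,triadSdDmr2 Family buccal SDs (%), defaults 3 and 4.5.
#' @param nClones,nCpg Bisulfite clone count and CpG sites per amplicon
#'   (defaults 10 and 20).
#' @param pMethDense,pMethSparse Per-CpG methylation probability on the dense
#'   (paternal-type) and sparse (maternal-type) allele (defaults 0.9, 0.1).
#' @param conversionEfficiency Probability an unmethylated C converts
#'   (default 1).
#' @param alleleAssignment "balanced" (default): clones split equally between
#'   the two alleles, emulating the clone-selection step of TA cloning;
#'   "random": iid Bernoulli(0.5) allele per clone.
#' @param expressionGamma Exponential decay rate of imprinted-gene expression
#'   per 10 index units (default 1).
#' @param hazardH0 Baseline hazard per month at index 8.5
#'   (default log(2)/60: median survival 60 months).
#' @param hazardBeta Log-hazard slope per 10 index units (default 1).
#' @param censoringMax Upper bound of uniform censoring times, months
#'   (default 120).
#' @param seed Global seed; every component draws from a substream derived
#'   deterministically from it.
#' @return A validated [SimulationConfig-class].
#' @export
SimulationConfig <- function(nPerGroup = 50,
                             groups = c("normal", "early_onset",
                                        "late_onset"),
                             dmrBaselineMean = 50, dmrBaselineSd = 8.8,
                             shift14qEarly = -19, shift14qLate = -6,
                             shiftLine1 = -5, line1Baseline = 70,
                             line1Sd = 3, h19CouplingR = 0.78,
                             triadRFatherDmr1 = 0.5,
                             triadRMotherDmr2 = 0.63,
                             triadMeanDmr1 = 58, triadMeanDmr2 = 70,
                             triadSdDmr1 = 3, triadSdDmr2 = 4.5,
                             nClones = 10, nCpg = 20,
                             pMethDense = 0.9, pMethSparse = 0.1,
                             conversionEfficiency = 1,
                             alleleAssignment = c("balanced", "random"),
                             expressionGamma = 1,
                             hazardH0 = log(2) / 60, hazardBeta = 1,
                             censoringMax = 120, seed = 1) {
  alleleAssignment <- match.arg(alleleAssignment)
  methods::new("SimulationConfig",
    nPerGroup = as.integer(nPerGroup), groups = groups,
    dmrBaselineMean = dmrBaselineMean, dmrBaselineSd = dmrBaselineSd,
    shift14qEarly = shift14qEarly, shift14qLate = shift14qLate,
    shiftLine1 = shiftLine1, line1Baseline = line1Baseline,
    line1Sd = line1Sd, h19CouplingR = h19CouplingR,
    triadRFatherDmr1 = triadRFatherDmr1,
    triadRMotherDmr2 = triadRMotherDmr2,
    triadMeanDmr1 = triadMeanDmr1, triadMeanDmr2 = triadMeanDmr2,
    triadSdDmr1 = triadSdDmr1, triadSdDmr2 = triadSdDmr2,
    nClones = as.integer(nClones), nCpg = as.integer(nCpg),
    pMethDense = pMethDense, pMethSparse = pMethSparse,
    conversionEfficiency = conversionEfficiency,
    alleleAssignment = alleleAssignment,
    expressionGamma = expressionGamma,
    hazardH0 = hazardH0, hazardBeta = hazardBeta,
    censoringMax = censoringMax, seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nPerGroup, "samples/group, groups:",
      paste(object@groups, collapse = ", "), "\n")
  cat(sprintf("  DMR baseline %.1f%% (sd %.1f); shifts early %.1f, late %.1f, LINE-1 %.1f\n",
              object@dmrBaselineMean, object@dmrBaselineSd,
              object@shift14qEarly, object@shift14qLate, object@shiftLine1))
  cat(sprintf("  H19 coupling r %.2f; triad r father/DMR-1 %.2f, mother/DMR-2 %.2f\n",
              object@h19CouplingR, object@triadRFatherDmr1,
              object@triadRMotherDmr2))
  cat(sprintf("  clones: %d x %d CpG (dense %.2f / sparse %.2f, conversion %.2f, %s alleles)\n",
              object@nClones, object@nCpg, object@pMethDense,
              object@pMethSparse, object@conversionEfficiency,
              object@alleleAssignment))
  cat(sprintf("  expression gamma %.2f; hazard h0 %.4f, beta %.2f; seed %d\n",
              object@expressionGamma, object@hazardH0, object@hazardBeta,
              object@seed))
})

#' Convert a SimulationConfig to / from a plain list
#'
#' Round-trippable representation used for JSON/YAML config files.
#' @param config A [SimulationConfig-class].
#' @return \code{configToList}: named list; \code{configFromList}: a
#'   [SimulationConfig-class].
#' @export
configToList <- function(config) {
  stopifnot(methods::is(config, "SimulationConfig"))
  nm <- methods::slotNames("SimulationConfig")
  stats::setNames(lapply(nm, function(s) methods::slot(config, s)), nm)
}

#' @rdname configToList
#' @param x Named list of SimulationConfig fields (missing fields keep their
#'   defaults).
#' @export
configFromList <- function(x) {
  do.call(SimulationConfig, x[names(x) %in%
                                names(formals(SimulationConfig))])
}

#' Simulate a methylation cohort
#'
#' Draws per-sample % methylation for the three 14q32 DMRs, the H19, MEST and
#' PEG3 DMRs and LINE-1, for a normal group and early-/late-onset tumor
#' groups. Normal imprinted DMRs are centred at the 50% monoallelic level;
#' tumor groups are shifted at the 14q32 DMRs only (about -19 points
#' early-onset, -6 late-onset) while LINE-1, the genome-wide surrogate, drops
#' about 5 points in both tumor groups. Noise is Gaussian and values are
#' clamped to [0, 100]. MEST and PEG3 stay at baseline in all groups. The
#' H19 defect extent is generated from the sample's realized 14q32 defect
#' extent (a latent severity shared across loci) plus calibrated noise so the
#' population correlation with the 14q-index equals \code{h19CouplingR};
#' the defect's sign (gain vs loss of methylation) is random, matching the
#' mixed hyper-/hypomethylation seen at H19.
#'
#' @param config A [SimulationConfig-class].
#' @return Long data.frame: sample_id, group, age_class, age, locus, dmr,
#'   methylation_pct. 14q32 rows carry dmr DMR-1/2/3; single-DMR loci use
#'   "<locus>-DMR" (LINE-1: "LINE1").
#' @export
simulateCohort <- function(config = SimulationConfig()) {
  methods::validObject(config)
  set.seed(substreamSeed(config@seed, 1L))
  n <- config@nPerGroup
  base <- config@dmrBaselineMean
  sd <- config@dmrBaselineSd

  rows <- list()
  perSample <- list()
  for (g in config@groups) {
    shift <- switch(g, early_onset = config@shift14qEarly,
                    late_onset = config@shift14qLate, 0)
    l1shift <- if (g == "normal") 0 else config@shiftLine1
    ageClass <- switch(g, early_onset = "early", late_onset = "late",
                       "normal")
    age <- switch(g,
                  early_onset = sample(12:29, n, replace = TRUE),
                  late_onset = sample(31:70, n, replace = TRUE),
                  sample(15:60, n, replace = TRUE))
    ids <- sprintf("%s_%03d", g, seq_len(n))
    m14 <- matrix(clampPct(base + shift + stats::rnorm(3 * n, 0, sd)),
                  nrow = n, ncol = 3)
    mest <- clampPct(base + stats::rnorm(n, 0, sd))
    peg3 <- clampPct(base + stats::rnorm(n, 0, sd))
    line1 <- clampPct(config@line1Baseline + l1shift +
                        stats::rnorm(n, 0, config@line1Sd))
    perSample[[g]] <- data.frame(
      sample_id = ids, group = g, age_class = ageClass, age = age,
      m14_1 = m14[, 1], m14_2 = m14[, 2], m14_3 = m14[, 3],
      mest = mest, peg3 = peg3, line1 = line1)
  }
  ps <- do.call(rbind, perSample)

  # H19: extent coupled to the realized 14q32 defect extent across the cohort
  extent14 <- rowMeans(abs(ps[, c("m14_1", "m14_2", "m14_3")] - base))
  r <- config@h19CouplingR
  sdX <- stats::sd(extent14)
  h19Extent <- if (r == 0 || sdX == 0) {
    mean(extent14) + stats::rnorm(nrow(ps), 0, max(sdX, sd / 2))
  } else {
    noiseSd <- sdX * sqrt(1 / r^2 - 1)
    5 + sign(r) * extent14 + stats::rnorm(nrow(ps), 0, noiseSd)
  }
  h19Sign <- sample(c(-1, 1), nrow(ps), replace = TRUE)
  ps$h19 <- clampPct(base + h19Sign * pmax(h19Extent, 0))

  loci <- c("14q32", "14q32", "14q32", "H19", "MEST", "PEG3", "LINE1")
  dmrs <- c("DMR-1", "DMR-2", "DMR-3", "H19-DMR", "MEST-DMR", "PEG3-DMR",
            "LINE1")
  vals <- list(ps$m14_1, ps$m14_2, ps$m14_3, ps$h19, ps$mest, ps$peg3,
               ps$line1)
  long <- data.frame(
    sample_id = rep(ps$sample_id, times = length(loci)),
    group = rep(ps$group, times = length(loci)),
    age_class = rep(ps$age_class, times = length(loci)),
    age = rep(ps$age, times = length(loci)),
    locus = rep(loci, each = nrow(ps)),
    dmr = rep(dmrs, each = nrow(ps)),
    methylation_pct = unlist(vals))
  rownames(long) <- NULL
  long[order(long$sample_id, long$locus, long$dmr), ]
}

#' Build a synthetic reference amplicon
#'
#' Concatenates one "TACGTT" block per CpG plus an "ACT"-repeat tail
#' providing non-CpG cytosines for conversion QC. Deterministic.
#'
#' @param nCpg Number of CpG sites (>= 1).
#' @param nNonCpgC Number of non-CpG cytosines (>= 5).
#' @return A [ReferenceAmplicon-class].
#' @export
makeReferenceAmplicon <- function(nCpg, nNonCpgC = 8) {
  if (nCpg < 1L) stop("nCpg must be at least 1", call. = FALSE)
  if (nNonCpgC < 5L)
    stop("need at least 5 non-CpG cytosines for conversion QC",
         call. = FALSE)
  seq <- paste0("GGATT",
                paste(rep("TACGTT", nCpg), collapse = ""),
                paste(rep("ACT", nNonCpgC), collapse = ""), "AA")
  referenceAmplicon(seq)
}

#' Simulate bisulfite TA-cloning data for an imprinted amplicon
#'
#' Each clone derives from one of two alleles — a densely methylated
#' (paternal-type) and a sparsely methylated (maternal-type) allele — with
#' per-CpG methylation Bernoulli(\code{pDense}) or Bernoulli(\code{pSparse}).
#' With \code{alleleAssignment = "balanced"} (the default) clones are split
#' equally between alleles, mirroring the selection of sequenced clones to
#' represent both alleles; \code{"random"} assigns each clone an allele with
#' probability 0.5. Incomplete bisulfite conversion leaves any unmethylated
#' cytosine (CpG or not) reading as C with probability
#' \code{1 - conversionEfficiency}, identically at CpG and QC positions, so
#' the conversion-QC machinery can detect it. Sequences are emitted on the
#' bisulfite-converted top strand only.
#'
#' @param pDense,pSparse Per-CpG methylation probabilities of the two
#'   alleles.
#' @param nClones Number of clones (>= 2).
#' @param nCpg CpG sites per amplicon (>= 1).
#' @param conversionEfficiency Probability an unmethylated C converts to T.
#' @param seed Integer seed.
#' @param alleleAssignment "balanced" or "random".
#' @return List: \code{reference} ([ReferenceAmplicon-class]),
#'   \code{sequences} (named character vector of clone sequences),
#'   \code{cloneMatrix} (apparent calls, i.e. what a caller should recover,
#'   as a [CloneMatrix-class]), \code{trueMethylation} (pre-artifact binary
#'   matrix), \code{alleles} (per-clone "dense"/"sparse").
#' @export
simulateClones <- function(pDense, pSparse, nClones, nCpg,
                           conversionEfficiency = 1, seed = 1,
                           alleleAssignment = c("balanced", "random")) {
  alleleAssignment <- match.arg(alleleAssignment)
  for (p in c(pDense, pSparse, conversionEfficiency))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]",
                             call. = FALSE)
  if (nCpg < 1L) stop("nCpg must be at least 1", call. = FALSE)
  if (nClones < 2L) stop("nClones must be at least 2", call. = FALSE)
  set.seed(substreamSeed(seed, 2L))
  ref <- makeReferenceAmplicon(nCpg)
  cpg <- cpgPositions(ref)
  qc <- nonCpgCPositions(ref)

  alleles <- if (alleleAssignment == "balanced") {
    sample(rep(c("dense", "sparse"), length.out = nClones))
  } else {
    sample(c("dense", "sparse"), nClones, replace = TRUE)
  }
  pAllele <- ifelse(alleles == "dense", pDense, pSparse)
  trueMeth <- matrix(stats::rbinom(nClones * nCpg, 1,
                                   rep(pAllele, times = nCpg)),
                     nrow = nClones, ncol = nCpg)
  # incomplete conversion: unmethylated C fails to convert with prob 1 - eff
  failCpg <- matrix(stats::rbinom(nClones * nCpg, 1,
                                  1 - conversionEfficiency),
                    nrow = nClones, ncol = nCpg)
  apparent <- pmax(trueMeth, (1 - trueMeth) * failCpg)
  failQc <- matrix(stats::rbinom(nClones * length(qc), 1,
                                 1 - conversionEfficiency),
                   nrow = nClones, ncol = length(qc))

  refChars <- strsplit(ampliconSequence(ref), "")[[1]]
  ids <- sprintf("clone_%03d", seq_len(nClones))
  seqs <- vapply(seq_len(nClones), function(i) {
    chars <- refChars
    chars[cpg] <- ifelse(apparent[i, ] == 1, "C", "T")
    chars[qc] <- ifelse(failQc[i, ] == 1, "C", "T")
    paste(chars, collapse = "")
  }, character(1))
  names(seqs) <- ids

  calls <- apparent
  storage.mode(calls) <- "integer"
  rownames(calls) <- ids
  colnames(calls) <- paste0("CpG_", cpg)
  rownames(trueMeth) <- ids
  cm <- methods::new("CloneMatrix", calls = calls,
                     conversionRates = 1 - rowMeans(failQc))
  list(reference = ref, sequences = seqs, cloneMatrix = cm,
       trueMethylation = trueMeth,
       alleles = stats::setNames(alleles, ids))
}

#' Simulate parent-child buccal methylation triads
#'
#' Child DMR methylation is a correlation-weighted combination of the
#' matching parent's standardized value and independent noise:
#' child = mu + sigma * (r * z_parent + sqrt(1 - r^2) * e), which yields a
#' population child-parent correlation of exactly r before clamping. DMR-1
#' couples the child to the father, DMR-2 to the mother; the other parent is
#' independent at that DMR.
#'
#' @param nTriads Number of triads (>= 3).
#' @param config A [SimulationConfig-class] (uses the triad* fields and
#'   seed).
#' @return Long data.frame: triad_id, member (child/mother/father), dmr
#'   (DMR-1/DMR-2), methylation_pct.
#' @export
simulateTriads <- function(nTriads, config = SimulationConfig()) {
  methods::validObject(config)
  if (nTriads < 3L) stop("nTriads must be at least 3", call. = FALSE)
  set.seed(substreamSeed(config@seed, 3L))
  draw <- function(mu, sigma, r, parentZ) {
    z <- r * parentZ + sqrt(1 - r^2) * stats::rnorm(nTriads)
    clampPct(mu + sigma * z)
  }
  zF1 <- stats::rnorm(nTriads); zM1 <- stats::rnorm(nTriads)
  zF2 <- stats::rnorm(nTriads); zM2 <- stats::rnorm(nTriads)
  m1 <- config@triadMeanDmr1; s1 <- config@triadSdDmr1
  m2 <- config@triadMeanDmr2; s2 <- config@triadSdDmr2
  father1 <- clampPct(m1 + s1 * zF1); mother1 <- clampPct(m1 + s1 * zM1)
  father2 <- clampPct(m2 + s2 * zF2); mother2 <- clampPct(m2 + s2 * zM2)
  child1 <- draw(m1, s1, config@triadRFatherDmr1, zF1)
  child2 <- draw(m2, s2, config@triadRMotherDmr2, zM2)
  ids <- sprintf("triad_%03d", seq_len(nTriads))
  long <- rbind(
    data.frame(triad_id = ids, member = "child", dmr = "DMR-1",
               methylation_pct = child1),
    data.frame(triad_id = ids, member = "father", dmr = "DMR-1",
               methylation_pct = father1),
    data.frame(triad_id = ids, member = "mother", dmr = "DMR-1",
               methylation_pct = mother1),
    data.frame(triad_id = ids, member = "child", dmr = "DMR-2",
               methylation_pct = child2),
    data.frame(triad_id = ids, member = "father", dmr = "DMR-2",
               methylation_pct = father2),
    data.frame(triad_id = ids, member = "mother", dmr = "DMR-2",
               methylation_pct = mother2))
  rownames(long) <- NULL
  long[order(long$triad_id, long$dmr, long$member), ]
}

#' Simulate expression and survival outcomes driven by the 14q-index
#'
#' Imprinted-gene expression decays exponentially with the index
#' (expression = base * exp(-gamma * index / 10) * lognormal noise), emitted
#' as a qPCR Ct table with a constant housekeeping gene (GAPDH) so the
#' delta-delta-Ct machinery applies directly. Survival times are exponential
#' with hazard h0 * exp(beta * (index - 8.5) / 10) under independent uniform
#' censoring on (0, censoringMax].
#'
#' @param indexValues Named numeric vector of per-sample 14q-index values
#'   (names = sample ids).
#' @param config A [SimulationConfig-class].
#' @param genes Imprinted genes to emit (defaults: DLK1-DIO3 cluster
#'   members).
#' @return List: \code{expression} (data.frame sample_id, gene, ct) and
#'   \code{survival} (data.frame sample_id, time, event).
#' @export
simulateOutcomes <- function(indexValues, config = SimulationConfig(),
                             genes = c("DLK1", "MEG3", "RTL1", "DIO3")) {
  methods::validObject(config)
  if (length(indexValues) == 0L || any(!is.finite(indexValues)))
    stop("indexValues must be non-empty and finite", call. = FALSE)
  set.seed(substreamSeed(config@seed, 4L))
  ids <- names(indexValues) %||% sprintf("sample_%03d",
                                         seq_along(indexValues))
  n <- length(indexValues)
  gamma <- config@expressionGamma

  refCt <- 16 + stats::rnorm(n, 0, 0.15)
  exprRows <- lapply(seq_along(genes), function(k) {
    # Ct rises as expression falls: Ct = Ct0 + gamma*index/(10*ln 2) - log2(noise)
    ct <- 22 + k + gamma * indexValues / (10 * log(2)) +
      stats::rnorm(n, 0, 0.3)
    data.frame(sample_id = ids, gene = genes[k], ct = ct)
  })
  expression <- rbind(do.call(rbind, exprRows),
                      data.frame(sample_id = ids, gene = "GAPDH",
                                 ct = refCt))
  rownames(expression) <- NULL

  hazard <- config@hazardH0 *
    exp(config@hazardBeta * (indexValues - 8.5) / 10)
  eventTime <- stats::rexp(n, rate = hazard)
  censTime <- stats::runif(n, 0, config@censoringMax)
  surv <- data.frame(sample_id = ids,
                     time = pmin(eventTime, censTime),
                     event = as.integer(eventTime <= censTime))
  list(expression = expression, survival = surv)
}

#' Write a full synthetic study to disk
#'
#' Generates and writes every table downstream stages consume: the cohort
#' methylation table, triads, bisulfite clone FASTA plus reference amplicon,
#' expression Ct table, survival table, and a JSON mirror of the
#' configuration.
#'
#' @param config A [SimulationConfig-class].
#' @param outdir Output directory (created if needed).
#' @param nTriads Number of triads (default 10).
#' @return Invisibly, a named character vector of the files written.
#' @export
simulateStudy <- function(config = SimulationConfig(), outdir,
                          nTriads = 10) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  meth <- simulateCohort(config)
  triads <- simulateTriads(nTriads, config)
  clones <- simulateClones(config@pMethDense, config@pMethSparse,
                           config@nClones, config@nCpg,
                           config@conversionEfficiency,
                           seed = config@seed,
                           alleleAssignment = config@alleleAssignment)
  scores <- scoreSamples(meth)
  idx <- stats::setNames(scores$fourteen_q_index, scores$sample_id)
  outcomes <- simulateOutcomes(idx, config)

  paths <- c(
    methylation = file.path(outdir, "methylation.tsv"),
    triads = file.path(outdir, "triads.tsv"),
    reference = file.path(outdir, "reference.fa"),
    clones = file.path(outdir, "clones.fa"),
    expression = file.path(outdir, "expression_ct.tsv"),
    survival = file.path(outdir, "survival.tsv"),
    config = file.path(outdir, "config.json"))
  writeTsv(meth, paths["methylation"])
  writeTsv(triads, paths["triads"])
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(
      ampliconSequence(clones$reference), "reference_amplicon")),
    paths["reference"])
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(clones$sequences),
                              paths["clones"])
  writeTsv(outcomes$expression, paths["expression"])
  writeTsv(outcomes$survival, paths["survival"])
  jsonlite::write_json(configToList(config), paths["config"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
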