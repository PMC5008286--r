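test_that("SimulationConfig validates its parameters", {
  expect_s4_class(SimulationConfig(), "SimulationConfig")
  expect_error(SimulationConfig(nPerGroup = 1), "nPerGroup")
  expect_error(SimulationConfig(dmrBaselineSd = 0), "positive")
  expect_error(SimulationConfig(h19CouplingR = 1), "strictly inside")
  expect_error(SimulationConfig(triadRFatherDmr1 = -1.2), "strictly inside")
  expect_error(SimulationConfig(hazardH0 = 0), "positive")
  expect_error(SimulationConfig(pMethDense = 1.5), "\\[0, 1\\]")
})

test_that("identical config and seed give identical outputs", {
  cfg <- SimulationConfig(nPerGroup = 20, seed = 123)
  expect_identical(simulateCohort(cfg), simulateCohort(cfg))
  expect_identical(simulateTriads(10, cfg), simulateTriads(10, cfg))
  expect_identical(simulateClones(0.9, 0.1, 10, 10, 0.97, seed = 123),
                   simulateClones(0.9, 0.1, 10, 10, 0.97, seed = 123))
  idx <- c(a = 3, b = 12, c = 20)
  expect_identical(simulateOutcomes(idx, cfg), simulateOutcomes(idx, cfg))
  # different seed, different tables
  cfg2 <- SimulationConfig(nPerGroup = 20, seed = 124)
  expect_false(identical(simulateCohort(cfg), simulateCohort(cfg2)))
})

test_that("cohort values stay in [0, 100] and cover every locus", {
  cfg <- SimulationConfig(nPerGroup = 30, seed = 2,
                          dmrBaselineSd = 30, line1Sd = 25)
  meth <- simulateCohort(cfg)
  expect_true(all(meth$methylation_pct >= 0 & meth$methylation_pct <= 100))
  expect_false(anyNA(meth$methylation_pct))
  expect_setequal(unique(meth$locus),
                  c("14q32", "H19", "MEST", "PEG3", "LINE1"))
  # every sample carries all 7 DMR records
  expect_true(all(table(meth$sample_id) == 7))
})

test_that("a noise-free, shift-free cohort sits at the imprinted level", {
  cfg <- SimulationConfig(nPerGroup = 10, seed = 1, dmrBaselineSd = 1e-9,
                          shift14qEarly = 0, shift14qLate = 0,
                          shiftLine1 = 0)
  meth <- simulateCohort(cfg)
  m14 <- meth$methylation_pct[meth$locus == "14q32"]
  expect_true(all(abs(m14 - 50) < 1e-6))
})

test_that("group-mean shifts are recovered within 3 standard errors", {
  cfg <- SimulationConfig(nPerGroup = 1000, seed = 11)
  meth <- simulateCohort(cfg)
  m14 <- meth[meth$locus == "14q32", ]
  byGroup <- tapply(m14$methylation_pct, m14$group, mean)
  se <- 8.8 / sqrt(3 * 1000)
  expect_lt(abs((byGroup[["early_onset"]] - byGroup[["normal"]]) - (-19)),
            3 * sqrt(2) * se)
  expect_lt(abs((byGroup[["late_onset"]] - byGroup[["normal"]]) - (-6)),
            3 * sqrt(2) * se)
  l1 <- meth[meth$locus == "LINE1", ]
  l1g <- tapply(l1$methylation_pct, l1$group, mean)
  seL1 <- 3 / sqrt(1000)
  expect_lt(abs((l1g[["early_onset"]] - l1g[["normal"]]) - (-5)),
            3 * sqrt(2) * seL1)
})

test_that("H19 defect extent is coupled to the 14q-index as configured", {
  cfg <- SimulationConfig(nPerGroup = 1000, seed = 21)
  meth <- simulateCohort(cfg)
  sc <- scoreSamples(meth)
  h19 <- meth[meth$locus == "H19", c("sample_id", "methylation_pct")]
  m <- merge(sc[, c("sample_id", "fourteen_q_index")], h19)
  r <- pearsonCorrelation(m$fourteen_q_index,
                          dmrDeviation(m$methylation_pct))$r
  expect_lt(abs(r - 0.78), 0.05)
  # MEST and PEG3 remain uncoupled
  for (loc in c("MEST", "PEG3")) {
    other <- meth[meth$locus == loc, c("sample_id", "methylation_pct")]
    m2 <- merge(sc[, c("sample_id", "fourteen_q_index")], other)
    r2 <- pearsonCorrelation(m2$fourteen_q_index,
                             dmrDeviation(m2$methylation_pct))$r
    expect_lt(abs(r2), 0.07)
  }
})

test_that("triad correlations hit their targets, parent-specifically", {
  cfg <- SimulationConfig(seed = 31)
  tc <- triadCorrelation(simulateTriads(5000, cfg))
  get <- function(d, p) tc$r[tc$dmr == d & tc$parent == p]
  expect_lt(abs(get("DMR-1", "father") - 0.5), 0.03)
  expect_lt(abs(get("DMR-2", "mother") - 0.63), 0.03)
  expect_lt(abs(get("DMR-1", "mother")), 0.05)
  expect_lt(abs(get("DMR-2", "father")), 0.05)
})

test_that("triad edge cases: independence and degenerate config", {
  cfg0 <- SimulationConfig(seed = 5, triadRFatherDmr1 = 0,
                           triadRMotherDmr2 = 0)
  tc <- triadCorrelation(simulateTriads(5000, cfg0))
  expect_true(all(abs(tc$r) < 0.05))
  expect_error(simulateTriads(2, SimulationConfig()), "at least 3")
})

test_that("clone simulation honours its probability contracts", {
  # symmetric alleles: expectation 0.5 * 0.9 + 0.5 * 0.1 = 0.5
  sim <- simulateClones(0.9, 0.1, nClones = 10000, nCpg = 20, seed = 8)
  ov <- summarizeCloneMatrix(sim$cloneMatrix)$overall
  expect_lt(abs(ov - 50), 1)
  expect_error(simulateClones(1.5, 0, 10, 10), "\\[0, 1\\]")
  expect_error(simulateClones(0.9, 0.1, 10, 0), "nCpg")
  expect_error(simulateClones(0.9, 0.1, 1, 10), "nClones")
})

test_that("expression decays with index and survival hazard rises", {
  cfg <- SimulationConfig(seed = 41, expressionGamma = 1, hazardBeta = 1)
  idx <- setNames(seq(0, 30, length.out = 400),
                  sprintf("s%03d", 1:400))
  out <- simulateOutcomes(idx, cfg)
  # Ct of imprinted genes rises with index (expression falls)
  dlk1 <- out$expression[out$expression$gene == "DLK1", ]
  r <- pearsonCorrelation(dlk1$ct, idx[dlk1$sample_id])$r
  expect_gt(r, 0.9)
  # housekeeping gene is flat
  gapdh <- out$expression[out$expression$gene == "GAPDH", ]
  rg <- pearsonCorrelation(gapdh$ct, idx[gapdh$sample_id])$r
  expect_lt(abs(rg), 0.15)
  expect_true(all(out$survival$time > 0))
  expect_true(all(out$survival$event %in% 0:1))
})

test_that("null outcome model is flat in index", {
  cfg <- SimulationConfig(seed = 43, expressionGamma = 0, hazardBeta = 0)
  set.seed(43)
  idx <- setNames(runif(400, 0, 30), sprintf("s%03d", 1:400))
  out <- simulateOutcomes(idx, cfg)
  dlk1 <- out$expression[out$expression$gene == "DLK1", ]
  expect_lt(abs(pearsonCorrelation(dlk1$ct, idx[dlk1$sample_id])$r), 0.15)
  strat <- data.frame(time = out$survival$time,
                      event = out$survival$event,
                      stratum = ifelse(idx > 15, "high", "low"))
  lr <- logrankTest(strat$time, strat$event, strat$stratum)
  expect_gt(lr$p.value, 0.001)
})

test_that("high-index stratum dies sooner under a positive hazard slope", {
  cfg <- SimulationConfig(seed = 47, hazardBeta = 1)
  set.seed(47)
  idx <- setNames(c(runif(1000, 0, 7), runif(1000, 15, 30)),
                  sprintf("s%04d", 1:2000))
  out <- simulateOutcomes(idx, cfg)
  hi <- idx[out$survival$sample_id] > 8.5
  kmHi <- kmEstimate(out$survival$time[hi], out$survival$event[hi])
  kmLo <- kmEstimate(out$survival$time[!hi], out$survival$event[!hi])
  expect_true(is.na(kmLo$median) || kmHi$median < kmLo$median)
  expect_false(is.na(kmHi$median))
})

test_that("simulateStudy writes a complete, reproducible bundle", {
  cfg <- SimulationConfig(nPerGroup = 5, seed = 99)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- simulateStudy(cfg, d1, nTriads = 4)
  p2 <- simulateStudy(cfg, d2, nTriads = 4)
  expect_true(all(file.exists(p1)))
  for (f in names(p1))
    expect_identical(readLines(p1[[f]], warn = FALSE),
                     readLines(p2[[f]], warn = FALSE))
  # config round trip
  cfg2 <- configFromList(jsonlite::read_json(p1[["config"]],
                                             simplifyVector = TRUE))
  expect_identical(simulateCohort(cfg2), simulateCohort(cfg))
})
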