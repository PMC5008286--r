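makeCtTable <- function() {
  # two calibrator (normal) samples and two tumors, one gene + GAPDH
  rbind(
    data.frame(sample_id = c("n1", "n2", "t1", "t2"),
               group = c("normal", "normal", "tumor", "tumor"),
               gene = "DLK1", ct = c(23.0, 24.0, 26.0, 23.5)),
    data.frame(sample_id = c("n1", "n2", "t1", "t2"),
               group = c("normal", "normal", "tumor", "tumor"),
               gene = "GAPDH", ct = c(19.5, 20.5, 20.0, 20.0)))
}

test_that("relativeExpression implements 2^-ddCt", {
  fe <- relativeExpression(makeCtTable())
  # calibrator mean dCt = ((23-19.5) + (24-20.5)) / 2 = 3.5
  t1 <- fe[fe$sample_id == "t1", ]
  expect_equal(t1$delta_ct, 6.0)
  expect_equal(t1$delta_delta_ct, 2.5)
  expect_equal(t1$fold_change, 2^-2.5)   # 0.1768
  t2 <- fe[fe$sample_id == "t2", ]
  expect_equal(t2$fold_change, 1)        # dCt equals the calibrator mean
  # one-cycle shift halves the fold change
  ct <- makeCtTable()
  ct$ct[ct$sample_id == "t2" & ct$gene == "DLK1"] <- 24.5  # ddCt becomes 1
  fe2 <- relativeExpression(ct)
  expect_equal(fe2$fold_change[fe2$sample_id == "t2"], 0.5)
})

test_that("calibrator fold changes have geometric mean exactly 1", {
  set.seed(7)
  ct <- rbind(
    data.frame(sample_id = rep(paste0("n", 1:5), each = 2),
               group = "normal",
               gene = rep(c("MEG3", "GAPDH"), 5),
               ct = 20 + rnorm(10)),
    data.frame(sample_id = rep(paste0("t", 1:4), each = 2),
               group = "tumor",
               gene = rep(c("MEG3", "GAPDH"), 4),
               ct = 22 + rnorm(8)))
  fe <- relativeExpression(ct)
  cal <- fe$fold_change[fe$group == "normal"]
  expect_equal(exp(mean(log(cal))), 1, tolerance = 1e-12)
})

test_that("relativeExpression skips samples without a reference Ct", {
  ct <- makeCtTable()
  ct <- ct[!(ct$sample_id == "t1" & ct$gene == "GAPDH"), ]
  expect_warning(fe <- relativeExpression(ct), "t1")
  expect_false("t1" %in% fe$sample_id)
  expect_error(relativeExpression(makeCtTable(), referenceGene = "ACTB"),
               "ACTB")
  bad <- makeCtTable(); bad$ct[1] <- -1
  expect_error(relativeExpression(bad), "positive")
})

test_that("chipEnrichment implements the three normalization modes", {
  sig <- data.frame(region = "IG-DMR",
                    mark = c("H3K4me3", "IgG", "input", "H3"),
                    signal = c(2.4, 0.03, 8.0, 4.0))
  fo <- chipEnrichment(sig, "fold_over_igg")
  expect_equal(fo$enrichment, 2.4 / 0.03)  # 80-fold over IgG
  pi <- chipEnrichment(sig, "percent_input")
  expect_equal(pi$enrichment, 100 * 2.4 / 8)
  h3 <- chipEnrichment(sig, "h3_normalized")
  expect_equal(h3$enrichment, (2.4 / 8) / (4 / 8))
  # mark equal to IgG gives fold 1
  sig1 <- sig; sig1$signal[1] <- 0.03
  expect_equal(chipEnrichment(sig1, "fold_over_igg")$enrichment, 1)
})

test_that("chip modes satisfy the ratio identity and name missing controls", {
  set.seed(13)
  sig <- expand.grid(region = c("r1", "r2"),
                     mark = c("H3K27me3", "IgG", "input", "H3"))
  sig$signal <- runif(nrow(sig), 0.5, 10)
  h3 <- chipEnrichment(sig, "h3_normalized")
  piMark <- chipEnrichment(sig, "percent_input")
  for (reg in c("r1", "r2")) {
    piH3 <- 100 * sig$signal[sig$region == reg & sig$mark == "H3"] /
      sig$signal[sig$region == reg & sig$mark == "input"]
    expect_lt(abs(h3$enrichment[h3$region == reg] -
                    piMark$enrichment[piMark$region == reg] / piH3), 1e-12)
  }
  noInput <- sig[sig$mark != "input", ]
  expect_error(chipEnrichment(noInput, "percent_input"), "input")
  zeroIgg <- sig; zeroIgg$signal[zeroIgg$mark == "IgG"] <- 0
  expect_error(chipEnrichment(zeroIgg, "fold_over_igg"), "IgG")
})

test_that("log2MeanCenter centers rows and is idempotent", {
  expect_equal(log2MeanCenter(matrix(c(1, 2, 4), nrow = 1)),
               matrix(c(-1, 0, 1), nrow = 1))
  expect_equal(log2MeanCenter(matrix(5, 1, 4)), matrix(0, 1, 4))
  expect_equal(log2MeanCenter(matrix(c(0, 1), nrow = 1), pseudocount = 1),
               matrix(c(-0.5, 0.5), nrow = 1))
  expect_error(log2MeanCenter(matrix(c(0, 1), nrow = 1)), "pseudocount")
  set.seed(19)
  m <- matrix(rexp(40) + 0.1, 4)
  centered <- log2MeanCenter(m)
  expect_true(all(abs(rowSums(centered)) < 1e-12))
  # re-centering already centered log data changes nothing
  expect_lt(max(abs((centered - rowMeans(centered)) - centered)), 1e-12)
})

test_that("expression decreases with index for imprinted genes only", {
  cfg <- SimulationConfig(nPerGroup = 100, seed = 51, expressionGamma = 1)
  meth <- simulateCohort(cfg)
  sc <- scoreSamples(meth)
  idx <- setNames(sc$fourteen_q_index, sc$sample_id)
  out <- simulateOutcomes(idx, cfg)
  ct <- merge(out$expression,
              unique(sc[, c("sample_id", "group")]), by = "sample_id")
  fe <- relativeExpression(ct, calibratorGroup = "normal")
  assoc <- expressionIndexAssociation(fe, sc)
  expect_true(all(assoc$correlations$r < -0.5))
  gm <- assoc$groupMeans
  expect_true(all(gm$monotone_decreasing))
  # null decay rate: no association
  cfg0 <- SimulationConfig(nPerGroup = 100, seed = 51,
                           expressionGamma = 0)
  out0 <- simulateOutcomes(idx, cfg0)
  ct0 <- merge(out0$expression,
               unique(sc[, c("sample_id", "group")]), by = "sample_id")
  fe0 <- relativeExpression(ct0, calibratorGroup = "normal")
  assoc0 <- expressionIndexAssociation(fe0, sc)
  expect_true(all(abs(assoc0$correlations$r) < 0.2))
})
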