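test_that("pearsonCorrelation matches stats::cor and handles edge cases", {
  set.seed(17)
  for (i in 1:20) {
    x <- rnorm(50); y <- rnorm(50)
    expect_lt(abs(pearsonCorrelation(x, y)$r - cor(x, y)), 1e-12)
  }
  x <- 1:10
  expect_equal(pearsonCorrelation(x, 2 * x)$r, 1)
  expect_equal(pearsonCorrelation(x, -x)$r, -1)
  expect_equal(pearsonCorrelation(x, -x)$r.squared, 1)
  expect_error(pearsonCorrelation(x, rep(3, 10)), "zero variance")
  expect_error(pearsonCorrelation(1:2, 1:2), "at least 3")
  expect_error(pearsonCorrelation(1:4, 1:5), "equal length")
  # pairwise-complete policy, with n reported
  r <- pearsonCorrelation(c(1, 2, 3, 4, NA), c(2, 4, 6, NA, 10))
  expect_equal(r$n, 3)
  expect_equal(r$r, 1)
})

test_that("squared correlation is reported alongside r", {
  x <- rnorm(100)
  y <- vectorWithExactR(x, 0.78)
  pc <- pearsonCorrelation(x, y)
  expect_equal(pc$r, 0.78, tolerance = 1e-12)
  expect_equal(round(pc$r.squared, 2), 0.61)
})

test_that("two-sample tests reproduce textbook arithmetic", {
  res <- groupTests(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3),
                    varEqual = TRUE)
  expect_equal(unname(res$statistic), -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(round(unname(res$statistic), 3), -3.674)
  expect_equal(unname(res$parameter), 4)
  # identical groups -> t = 0, p = 1
  res0 <- groupTests(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(unname(res0$statistic), 0)
  expect_equal(res0$p.value, 1)
})

test_that("Welch, pooled t and ANOVA agree with the stats-package oracles", {
  set.seed(23)
  for (i in 1:10) {
    x <- rnorm(12, sd = 1); y <- rnorm(20, mean = 0.5, sd = 2)
    g <- rep(c("x", "y"), c(12, 20))
    w <- groupTests(c(x, y), g)
    o <- t.test(x, y)
    expect_equal(unname(w$statistic), unname(o$statistic),
                 tolerance = 1e-9)
    expect_equal(w$p.value, o$p.value, tolerance = 1e-6)
    p <- groupTests(c(x, y), g, varEqual = TRUE)
    op <- t.test(x, y, var.equal = TRUE)
    expect_equal(p$p.value, op$p.value, tolerance = 1e-6)
  }
  v <- rnorm(60); g3 <- rep(c("a", "b", "c"), each = 20)
  a <- groupTests(v, g3)
  oa <- summary(aov(v ~ g3))[[1]]
  expect_equal(unname(a$statistic), oa$`F value`[1], tolerance = 1e-9)
  expect_equal(a$p.value, oa$`Pr(>F)`[1], tolerance = 1e-6)
})

test_that("one-way ANOVA on two equal-variance groups equals pooled t squared", {
  set.seed(29)
  x <- rnorm(15); y <- rnorm(15, 1)
  tt <- groupTests(c(x, y), rep(c("a", "b"), each = 15), varEqual = TRUE)
  ff <- imprintscore:::onewayAnova(c(x, y), rep(c("a", "b"), each = 15))
  expect_lt(abs(ff$statistic - unname(tt$statistic)^2), 1e-9)
})

test_that("groupTests rejects undersized groups", {
  expect_error(groupTests(1:3, c("a", "a", "b")), "n >= 2")
  expect_error(groupTests(1:3, rep("a", 3)), "at least 2 groups")
})

test_that("classificationSummary reproduces count-to-percent conversions", {
  calls <- rep(c("positive", "negative"), c(20, 3))
  s <- classificationSummary(calls, rep("early", 23))
  expect_equal(s$n_positive, 20L)
  expect_equal(s$percent_positive, 87)
  s2 <- classificationSummary(rep(c("positive", "negative"), c(5, 4)),
                              rep("late", 9))
  expect_equal(s2$percent_positive, 56)
  s3 <- classificationSummary(rep(c("positive", "negative"), c(13, 2)),
                              rep("biopsy", 15), digits = 1)
  expect_equal(s3$percent_positive, 86.7)
  s0 <- classificationSummary(rep("negative", 7), rep("g", 7))
  expect_equal(s0$percent_positive, 0)
  expect_error(classificationSummary("maybe", "g"), "positive")
  expect_warning(
    classificationSummary(rep("positive", 2),
                          factor(rep("a", 2), levels = c("a", "b"))),
    "empty group")
})

test_that("rounded percents stay within their rounding half-width", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(3:40, 1); k <- sample(0:n, 1)
    s <- classificationSummary(rep(c("positive", "negative"), c(k, n - k)),
                               rep("g", n))
    expect_lte(abs(s$percent_positive - 100 * k / n), 0.5)
  }
})

test_that("demethylationExtent computes deltas against the normal mean", {
  meth <- rbind(
    data.frame(sample_id = paste0("n", 1:3), group = "normal",
               locus = "IG", dmr = "IG-DMR",
               methylation_pct = c(62, 64, 66)),
    data.frame(sample_id = "t1", group = "tumor", locus = "IG",
               dmr = "IG-DMR", methylation_pct = 45),
    data.frame(sample_id = "t2", group = "tumor", locus = "IG",
               dmr = "IG-DMR", methylation_pct = 64))
  de <- demethylationExtent(meth, locus = "IG")
  expect_null(de$test)  # no genome-wide surrogate locus in this table
  d <- de$deltas
  expect_equal(d$delta[d$sample_id == "t1"], 19)  # 64 - 45
  expect_equal(d$delta[d$sample_id == "t2"], 0)   # at the normal mean
  # antisymmetry: swapping normal mean and value negates the delta
  expect_equal(64 - 45, -(45 - 64))
})

test_that("demethylationExtent tests locus against the genome-wide surrogate", {
  cfg <- SimulationConfig(nPerGroup = 200, seed = 3)
  meth <- simulateCohort(cfg)
  de <- demethylationExtent(meth, groups = "early_onset")
  gm <- de$groupMeans
  d14 <- gm$delta[gm$locus == "14q32"]
  dl1 <- gm$delta[gm$locus == "LINE1"]
  expect_gt(d14, dl1)
  expect_lt(de$test$p.value, 0.01)
  expect_match(de$test$method, "Welch")
  # missing normal mean for a compared locus is a hard error
  expect_error(
    demethylationExtent(meth[!(meth$group == "normal" &
                                 meth$locus == "LINE1"), ]),
    "no normal mean")
})

test_that("triadCorrelation is exact on degenerate family structures", {
  ids <- sprintf("t%02d", 1:10)
  child <- seq(50, 68, 2)
  tri <- rbind(
    data.frame(triad_id = ids, member = "child", dmr = "DMR-1",
               methylation_pct = child),
    data.frame(triad_id = ids, member = "father", dmr = "DMR-1",
               methylation_pct = child),  # child copies the father
    data.frame(triad_id = ids, member = "mother", dmr = "DMR-1",
               methylation_pct = rev(child)))
  tc <- triadCorrelation(tri)
  expect_equal(tc$r[tc$parent == "father"], 1)
  expect_equal(tc$r[tc$parent == "mother"], -1)
  # incomplete triads are excluded and counted
  tri2 <- tri[!(tri$triad_id == "t01" & tri$member == "father"), ]
  tc2 <- triadCorrelation(tri2)
  expect_equal(tc2$n_triads[tc2$parent == "father"], 9)
  expect_equal(tc2$n_excluded[tc2$parent == "father"], 1)
})
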