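# Independent oracles for the rank statistics, used to freeze expected
# values: Kruskal-Wallis H from first principles and the exact median-test
# p-value by exhausting group assignments.

handKruskalH <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  groups <- as.character(groups)
  h <- 12 / (n * (n + 1)) *
    sum(vapply(split(r, groups), function(ri)
      length(ri) * (mean(ri) - (n + 1) / 2)^2, numeric(1)))
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

exactMedianP <- function(values, groups) {
  # probability, over all equally likely assignments of the observed values
  # into groups of the observed sizes, of a 2x2 median table at least as
  # extreme (Fisher-style, summing tables with probability <= observed)
  gm <- median(values)
  below <- sum(values <= gm)
  g1 <- sum(groups == unique(groups)[1])
  n <- length(values)
  obs <- sum(values[groups == unique(groups)[1]] <= gm)
  probs <- dhyper(0:min(g1, below), below, n - below, g1)
  sum(probs[probs <= dhyper(obs, below, n - below, g1) + 1e-12])
}

test_that("assumption checks are calibrated on their null and alternative", {
  pNorm <- vapply(1:100, function(s) {
    withr::local_seed(1000 + s)
    assumptionChecks(rnorm(50), rep("a", 50))$ks$a$p
  }, numeric(1))
  expect_gte(mean(pNorm > 0.05), 0.90)

  pExp <- vapply(1:100, function(s) {
    withr::local_seed(2000 + s)
    assumptionChecks(rexp(200), rep("a", 200))$ks$a$p
  }, numeric(1))
  expect_gte(mean(pExp < 0.05), 0.90)

  # equal values in both groups: Levene statistic 0, normality flagged
  ac <- assumptionChecks(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(ac$levene$statistic, 0)
  acConst <- assumptionChecks(c(1, 1, 1, 2, 3, 4),
                              rep(c("a", "b"), each = 3))
  expect_true(acConst$ks$a$normalityUndefined)
  expect_false(acConst$ks$b$normalityUndefined)
})

test_that("pooled t-test: identity, symmetry, and summary-statistic form", {
  coh <- data.frame(group = rep(c("A", "B"), each = 4),
                    v = c(1, 2, 3, 4, 1, 2, 3, 4))
  r <- groupTTest("v", coh)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)

  withr::local_seed(5)
  coh2 <- data.frame(group = rep(c("A", "B"), each = 6), v = rnorm(12))
  r1 <- groupTTest("v", coh2)
  coh2$group <- ifelse(coh2$group == "A", "B", "A")
  r2 <- groupTTest("v", coh2)
  expect_equal(r2$statistic, -r1$statistic)
  expect_equal(r2$p, r1$p)

  # group body-mass summaries 64.0 +- 11.5 vs 71.2 +- 11.8, n = 10 + 10
  rs <- groupTTest(means = c(64.0, 71.2), sds = c(11.5, 11.8), ns = c(10, 10))
  expect_equal(rs$df, 18)
  expect_equal(rs$statistic, -1.3817, tolerance = 1e-4)
  expect_equal(rs$p, 0.1840, tolerance = 1e-3)
  expect_gt(rs$p, 0.05)

  # summary form matches the subject-level computation
  rl <- groupTTest("v", coh2)
  agg <- split(coh2$v, coh2$group)
  rs2 <- groupTTest(means = sapply(agg, mean), sds = sapply(agg, sd),
                    ns = lengths(agg))
  expect_equal(rs2$statistic, rl$statistic, tolerance = 1e-12)
  expect_equal(rs2$p, rl$p, tolerance = 1e-12)
})

test_that("two-way ANOVA reproduces the hand SS decomposition", {
  # 2x2 one observation per cell, additive values 1..4:
  # SS_A = 4, SS_B = 1, residual = 0
  d <- data.frame(gmfcs = c("I", "I", "II", "II"),
                  muscle = c("MG", "LG", "MG", "LG"),
                  intramf = c(1, 2, 3, 4))
  a <- suppressWarnings(anovaIntramf(d))  # zero-residual toy: Tukey is NaN
  expect_equal(a$effects$gmfcs$sumsq, 4)
  expect_equal(a$effects$muscle$sumsq, 1)
  expect_equal(a$effects$gmfcs$sumsqResid, 0, tolerance = 1e-12)
  # adding a constant changes nothing
  d2 <- d; d2$intramf <- d2$intramf + 100
  a2 <- suppressWarnings(anovaIntramf(d2))
  expect_equal(a2$effects$gmfcs$sumsq, a$effects$gmfcs$sumsq)
  expect_equal(a2$effects$muscle$sumsq, a$effects$muscle$sumsq)
  expect_error(anovaIntramf(d[d$gmfcs == "I", ]), ">= 2 GMFCS levels")
})

test_that("type II sums of squares agree with car::Anova when defined", {
  withr::local_seed(64)
  # unbalanced two-way layout with noise
  d <- data.frame(gmfcs = sample(c("I", "II", "III"), 40, TRUE,
                                 prob = c(0.2, 0.5, 0.3)),
                  muscle = sample(muscleNames(), 40, TRUE),
                  intramf = rnorm(40, 10, 2))
  a <- anovaIntramf(d)
  ref <- car::Anova(stats::lm(intramf ~ gmfcs + muscle, data = d), type = 2)
  for (tm in c("gmfcs", "muscle")) {
    expect_equal(a$effects[[tm]]$sumsq, ref[tm, "Sum Sq"], tolerance = 1e-10)
    expect_equal(a$effects[[tm]]$statistic, ref[tm, "F value"],
                 tolerance = 1e-10)
    expect_equal(a$effects[[tm]]$p, ref[tm, "Pr(>F)"], tolerance = 1e-10)
  }
})

test_that("two-way ANOVA type-I error is nominal under the null", {
  rej <- vapply(1:100, function(s) {
    withr::local_seed(3000 + s)
    d <- data.frame(gmfcs = rep(c("I", "II", "III"), each = 10),
                    muscle = rep(rep(c("MG", "LG"), each = 5), 3),
                    intramf = rnorm(30))
    anovaIntramf(d)$effects$gmfcs$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.06)
})

test_that("Tukey post-hoc table covers the GMFCS level pairs", {
  withr::local_seed(8)
  d <- data.frame(gmfcs = rep(c("I", "II", "III"), each = 10),
                  muscle = rep(muscleNames(), 6),
                  intramf = rnorm(30) + rep(c(0, 0, 3), each = 10))
  a <- anovaIntramf(d)
  expect_setequal(a$tukey$comparison, c("II-I", "III-I", "III-II"))
  expect_lt(a$tukey[a$tukey$comparison == "III-I", "p adj"], 0.01)
})

test_that("median test matches the exact enumeration oracle", {
  # (1,2,3) vs (4,5,6): only one table on each side is as extreme
  v <- c(1, 2, 3, 4, 5, 6)
  g <- rep(c("a", "b"), each = 3)
  r <- medianTest(v, g)
  expect_equal(r$p, 0.1)
  expect_equal(r$p, exactMedianP(v, g))
  expect_equal(unname(r$table["a", "le_median"]), 3L)

  # identical interleaved groups: p = 1
  r1 <- medianTest(c(1, 2, 3, 4), c("a", "b", "a", "b"))
  expect_equal(r1$p, 1)

  # invariance under a monotone transform
  withr::local_seed(9)
  v2 <- rnorm(14); g2 <- rep(c("a", "b"), 7)
  expect_equal(medianTest(exp(v2), g2)$p, medianTest(v2, g2)$p)

  # random cases agree with the enumeration oracle
  for (s in 1:20) {
    withr::local_seed(4000 + s)
    vv <- sample(1:50, 12)  # distinct values, no median ties
    gg <- rep(c("a", "b"), each = 6)
    expect_equal(medianTest(vv, gg)$p, exactMedianP(vv, gg),
                 tolerance = 1e-10)
  }

  rAll <- medianTest(rep(2, 8), rep(c("a", "b"), 4))
  expect_true(rAll$undefined)
})

test_that("Kruskal-Wallis H matches hand rank computation", {
  v <- 1:6
  g <- rep(c("a", "b", "c"), each = 2)
  r <- kruskalWallis(v, g)
  expect_equal(r$statistic, 32 / 7, tolerance = 1e-12)
  expect_equal(r$statistic, handKruskalH(v, g), tolerance = 1e-12)
  # permuting values within groups changes nothing
  r2 <- kruskalWallis(c(2, 1, 4, 3, 6, 5), g)
  expect_equal(r2$statistic, r$statistic)
  # exhaustive check at n = 6: H is maximised when the largest ranks sit
  # together in one group
  combs <- combn(6, 2)
  hmax <- -Inf
  for (i in seq_len(ncol(combs))) {
    rest <- setdiff(1:6, combs[, i])
    inner <- combn(rest, 2)
    for (j in seq_len(ncol(inner))) {
      gg <- character(6)
      gg[combs[, i]] <- "a"
      gg[inner[, j]] <- "b"
      gg[gg == ""] <- "c"
      hmax <- max(hmax, handKruskalH(1:6, gg))
    }
  }
  expect_equal(r$statistic, hmax, tolerance = 1e-12)
  # ties flagged
  expect_true(kruskalWallis(rep(1, 6), g)$undefined)
})

test_that("Pearson correlations: exact cases and null calibration", {
  coh <- data.frame(group = "TD", x = c(1, 2, 3), y = c(2, 4, 6),
                    z = c(3, 2, 1))
  cm <- correlationMatrix(coh, c("x", "y", "z"))
  expect_equal(cm$r[cm$var1 == "x" & cm$var2 == "y"], 1)
  expect_equal(cm$r[cm$var1 == "x" & cm$var2 == "z"], -1)

  withr::local_seed(11)
  crit <- qt(0.975, 8) / sqrt(8 + qt(0.975, 8)^2)  # |r| cutoff at n = 10
  expect_equal(crit, 0.632, tolerance = 1e-3)
  hits <- vapply(1:1000, function(s) {
    abs(cor(rnorm(10), rnorm(10))) >= crit
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.05), 0.02)

  cz <- data.frame(group = "TD", x = rep(1, 5), y = rnorm(5))
  r0 <- correlationMatrix(cz, c("x", "y"))
  expect_true(r0$undefined)
})

test_that("the full battery is quiet on a null cohort and structured", {
  spec <- deskCohortSpec(muscleFFShiftBSCP = 0,
                         gmfcsShift = c(I = 0, II = 0, III = 0),
                         sfThicknessMeanMm = c(TD = 7, BSCP = 7),
                         sfThicknessSDMm = c(TD = 2, BSCP = 2),
                         ageMean = c(TD = 22.8, BSCP = 22.8),
                         massMean = c(TD = 70, BSCP = 70),
                         heightMean = c(TD = 1.72, BSCP = 1.72),
                         heightSD = c(TD = 0.1, BSCP = 0.1))
  ps <- c()
  for (s in 1:8) {
    coh <- quantifyCohort(simulateCohort(spec, seed = 500 + s))
    rpt <- runStatsBattery(coh)
    ps <- c(ps,
            vapply(rpt$physical, function(x) x$ttest$p, numeric(1)),
            rpt$medianTests$sf_m$p, rpt$medianTests$imat$p,
            rpt$anovaTwoWay$effects$gmfcs$p)
    expect_record(rpt$anovaTwoWay$effects$gmfcs)
    expect_record(rpt$kruskalGmfcs$imat)
  }
  expect_true(all(ps >= 0 & ps <= 1))
  # two groups drawn from one population: no systematic rejections
  expect_lt(mean(ps < 0.05), 0.18)
})

test_that("battery results are invariant to row order", {
  coh <- quantifyCohort(simulateCohort(deskCohortSpec(), seed = 77))
  rep1 <- runStatsBattery(coh)
  coh2 <- coh[rev(seq_len(nrow(coh))), ]
  rep2 <- runStatsBattery(coh2)
  expect_equal(rep2$anovaTwoWay$effects$gmfcs$statistic,
               rep1$anovaTwoWay$effects$gmfcs$statistic)
  expect_equal(rep2$medianTests$imat$p, rep1$medianTests$imat$p)
  expect_equal(abs(rep2$physical$mass_kg$ttest$statistic),
               abs(rep1$physical$mass_kg$ttest$statistic))
})
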