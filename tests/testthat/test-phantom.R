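test_that("phantom fat-fraction field honours the configured composition", {
  # zero everywhere
  truth0 <- makeLegPhantom(uniformPhantomSpec(0))
  for (m in muscleNames())
    expect_equal(max(ffMap(truth0)[muscleMasks(phantomLabels(truth0))[[m]]]), 0)

  # per-muscle mask-wise means equal the configured base values exactly
  ffs <- c(MG = 0.12, LG = 0.07, SOL = 0.21, TA = 0.04, TP = 0.09)
  truth <- makeLegPhantom(smallPhantomSpec(muscleFF = ffs))
  for (m in muscleNames()) {
    mask <- muscleMasks(phantomLabels(truth))[[m]]
    expect_gt(sum(mask), 0)
    expect_equal(mean(ffMap(truth)[mask]), unname(ffs[[m]]))
  }
  expect_true(all(ffMap(truth) >= 0 & ffMap(truth) <= 1))
})

test_that("phantom generation is deterministic and masks validate", {
  a <- makeLegPhantom(smallPhantomSpec(), seed = 3L)
  b <- makeLegPhantom(smallPhantomSpec(), seed = 3L)
  expect_identical(ffMap(a), ffMap(b))
  expect_identical(s0Map(a), s0Map(b))
  expect_true(validateMasks(phantomLabels(a)))
})

test_that("impossible muscle layouts fail naming the muscle", {
  expect_error(
    makeLegPhantom(smallPhantomSpec(muscleInnerMm = 40)),
    "muscle annulus")
  # a sector squeezed to nothing by its seams
  expect_error(
    makeLegPhantom(smallPhantomSpec(
      muscleStartDeg = c(MG = 0, LG = 70.2, SOL = 144, TA = 216, TP = 288),
      muscleEndDeg = c(MG = 70.2, LG = 70.4, SOL = 216, TA = 288, TP = 360),
      seamWidthMm = 12)),
    "LG")
})

test_that("noiseless rendering conserves signal and recovers ff exactly", {
  truth <- makeLegPhantom(smallPhantomSpec())
  vol <- renderWaterFat(truth)
  expect_equal(waterImage(vol) + fatImage(vol), s0Map(truth))
  # uniform-ff ROI round trip: fatFraction == 100 * ff
  u <- makeLegPhantom(uniformPhantomSpec(0.25))
  vu <- renderWaterFat(u)
  expect_equal(fatFraction(vu, compartmentMask(phantomLabels(u))), 25)
  expect_equal(fatFraction(vu, compartmentMask(phantomLabels(u)),
                           mode = "voxel_mean"),
               25, ignore_attr = TRUE)
})

test_that("analytic render values match the signal model", {
  u <- makeLegPhantom(uniformPhantomSpec(0.25))
  v <- renderWaterFat(u)
  inside <- s0Map(u) > 0
  expect_equal(unique(waterImage(v)[inside]), 75)
  expect_equal(unique(fatImage(v)[inside]), 25)
})

test_that("T1 bias strictly increases every ROI fat fraction", {
  truth <- makeLegPhantom(smallPhantomSpec())
  masks <- phantomLabels(truth)
  rois <- c(muscleMasks(masks), list(compartment = compartmentMask(masks),
                                     sf = sfMask(masks)))
  betas <- c(1, 1.2, 1.5)
  ffs <- sapply(betas, function(b) {
    v <- renderWaterFat(truth, acq = acquisitionSpec(t1Bias = b))
    vapply(rois, function(m) fatFraction(v, m), numeric(1))
  })
  for (i in seq_len(nrow(ffs)))
    expect_true(all(diff(ffs[i, ]) > 0),
                info = paste("ROI", rownames(ffs)[i]))
})

test_that("Rician noise yields positive apparent fat in signal-free air", {
  truth <- makeLegPhantom(smallPhantomSpec())
  air <- s0Map(truth) == 0
  v <- renderWaterFat(truth, noiseSpec("rician", sigma = 2, seed = 42))
  expect_gt(fatFraction(v, air), 0)
})

test_that("echo rendering matches the closed-form signal model", {
  acq <- acquisitionSpec()
  # pure water voxel: all echoes equal W and real
  w <- makeLegPhantom(uniformPhantomSpec(0))
  ech <- renderEchoes(w, acq, fieldmapHz = 0)
  inside <- s0Map(w) > 0
  for (n in 1:4) {
    sl <- ech@signal[, , , n]
    expect_equal(Re(sl)[inside], s0Map(w)[inside])
    expect_equal(max(abs(Im(sl)[inside])), 0)
  }
  # ff = 0.3, s0 = 1: |S_n| = |W + F e^{i phi_n}| in closed form
  u <- makeLegPhantom(uniformPhantomSpec(0.3, s0 = 1))
  e0 <- renderEchoes(u, acq, fieldmapHz = 0)
  dfcs <- acq@fatShiftPpm * 42.577478518 * acq@fieldT
  te <- echoTimesMs(acq) / 1000
  vox <- which(s0Map(u) == 1)[1]
  for (n in 1:4) {
    phin <- 2 * pi * dfcs * te[n]
    expected <- Mod(0.7 + 0.3 * exp(1i * phin))
    expect_equal(Mod(e0@signal[, , , n][vox]), expected, tolerance = 1e-12)
  }
  # off-resonance is a pure phase factor: |S_n| unchanged
  e50 <- renderEchoes(u, acq, fieldmapHz = 50)
  expect_equal(Mod(e50@signal), Mod(e0@signal), tolerance = 1e-12)
})

test_that("repeat simulation honours the noise contract", {
  truth <- makeLegPhantom(smallPhantomSpec(nSlices = 2L))
  expect_error(simulateRepeats(truth, 1), "at least 2")
  clean <- simulateRepeats(truth, 5)
  for (k in 2:5)
    expect_identical(waterImage(clean[[k]]), waterImage(clean[[1]]))
  noisy1 <- simulateRepeats(truth, 3, noiseSpec("gaussian", 2, seed = 9))
  noisy2 <- simulateRepeats(truth, 3, noiseSpec("gaussian", 2, seed = 9))
  for (k in 1:3)
    expect_identical(waterImage(noisy1[[k]]), waterImage(noisy2[[k]]))
  expect_false(identical(waterImage(noisy1[[1]]), waterImage(noisy1[[2]])))
  expect_false(identical(waterImage(noisy1[[2]]), waterImage(noisy1[[3]])))
})

test_that("cohort simulation produces valid subjects and metadata", {
  spec <- deskCohortSpec()
  sim <- simulateCohort(spec, seed = 21)
  expect_length(sim$subjects, 20)
  expect_equal(sum(sim$cohort$group == "BSCP"), 10)
  expect_equal(as.integer(table(sim$cohort$gmfcs)[c("I", "II", "III")]),
               c(2L, 5L, 3L))
  expect_true(all(is.na(sim$cohort$gmfcs[sim$cohort$group == "TD"])))
  expect_equal(sim$cohort$bmi,
               sim$cohort$mass_kg / sim$cohort$height_m^2)
  for (s in sim$subjects) expect_true(validateMasks(s$masks))
  # bit-reproducible under the same seed
  sim2 <- simulateCohort(spec, seed = 21)
  expect_identical(sim$cohort, sim2$cohort)
  expect_identical(waterImage(sim$subjects[[5]]$volume),
                   waterImage(sim2$subjects[[5]]$volume))
})

test_that("BSCP fat-fraction shift propagates to the group means", {
  # noiseless, so quantified IntraMF equals the drawn truth; the group
  # difference estimates the configured +10 pp shift up to sampling error
  spec <- deskCohortSpec(noiseModel = "none", noiseSigma = 0,
                         gmfcsShift = c(I = 0, II = 0, III = 0))
  diffs <- vapply(1:6, function(s) {
    coh <- quantifyCohort(simulateCohort(spec, seed = 100 + s))
    mean(coh$intramf_mean[coh$group == "BSCP"]) -
      mean(coh$intramf_mean[coh$group == "TD"])
  }, numeric(1))
  # SE of one cohort-mean difference ~ 3/sqrt(5)/sqrt(10)*sqrt(2) ~ 0.6 pp
  expect_lt(abs(mean(diffs) - 10), 1)
})
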