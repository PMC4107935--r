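test_that("fat fraction reproduces hand-computed values", {
  shp <- c(4, 1, 1)
  all4 <- array(TRUE, shp)
  # pure water
  v0 <- fatWaterVolume(array(c(80, 60, 90, 70), shp), array(0, shp))
  expect_equal(fatFraction(v0, all4), 0)
  # I_fat = I_water everywhere: 50% in both modes
  veq <- fatWaterVolume(array(c(5, 9, 2, 7), shp), array(c(5, 9, 2, 7), shp))
  expect_equal(fatFraction(veq, all4), 50)
  expect_equal(fatFraction(veq, all4, mode = "voxel_mean"), 50,
               ignore_attr = TRUE)
  # summed mode: 100 * 100 / 400 = 25
  v <- fatWaterVolume(array(c(80, 60, 90, 70), shp),
                      array(c(20, 40, 10, 30), shp))
  expect_equal(fatFraction(v, all4), 25)
  # contract failures
  expect_error(fatFraction(v, array(FALSE, shp)), "empty mask")
  vz <- fatWaterVolume(array(0, shp), array(0, shp))
  expect_error(fatFraction(vz, all4), "no signal")
})

test_that("modes agree under uniform proton density, diverge otherwise", {
  shp <- c(3, 1, 1)
  mask <- array(TRUE, shp)
  # uniform s0 = 100, varying ff
  ff <- c(0.1, 0.3, 0.5)
  vu <- fatWaterVolume(array(100 * (1 - ff), shp), array(100 * ff, shp))
  expect_equal(fatFraction(vu, mask),
               fatFraction(vu, mask, mode = "voxel_mean"),
               ignore_attr = TRUE)
  # non-uniform s0: summed is signal-weighted, voxel_mean is not
  s0 <- c(10, 100, 1000)
  vn <- fatWaterVolume(array(s0 * (1 - ff), shp), array(s0 * ff, shp))
  expect_gt(abs(fatFraction(vn, mask) -
                fatFraction(vn, mask, mode = "voxel_mean")), 1)
  # zero-signal voxels are excluded and counted in voxel_mean mode
  vz <- fatWaterVolume(array(c(50, 0, 50), shp), array(c(50, 0, 50), shp))
  got <- fatFraction(vz, mask, mode = "voxel_mean")
  expect_equal(as.numeric(got), 50)
  expect_equal(attr(got, "excludedVoxels"), 1L)
})

test_that("adding fat signal strictly increases the summed fat fraction", {
  withr::local_seed(12)
  shp <- c(5, 5, 1)
  v <- fatWaterVolume(array(runif(25, 10, 100), shp),
                      array(runif(25, 0, 50), shp))
  mask <- array(runif(25) < 0.6, shp)
  base <- fatFraction(v, mask)
  vox <- which(mask)[3]
  fat2 <- fatImage(v); fat2[vox] <- fat2[vox] + 5
  expect_gt(fatFraction(fatWaterVolume(waterImage(v), fat2), mask), base)
})

test_that("uniform phantoms quantify to the exact configured percentage", {
  truth <- makeLegPhantom(uniformPhantomSpec(0.2))
  q <- quantifySubject(renderWaterFat(truth), phantomLabels(truth))
  expect_equal(unname(intramfPct(q)), rep(20, 5))
  expect_equal(imatPct(q), 20)
  expect_true(all(q@erodedVoxelCounts > 0))
  expect_equal(q@provenance$erosion$radiusPx, 2L)
})

test_that("fatty seams raise IMAT above every muscle's IntraMF", {
  truth <- makeLegPhantom(smallPhantomSpec(seamFF = 0.9))
  q <- quantifySubject(renderWaterFat(truth), phantomLabels(truth))
  expect_gt(imatPct(q), max(intramfPct(q)))
})

test_that("SF/M matches the analytic ring-to-disc ratio of the geometry", {
  spec <- smallPhantomSpec()
  truth <- makeLegPhantom(spec)
  q <- quantifySubject(renderWaterFat(truth), phantomLabels(truth))
  R <- spec@outerRadiusMm
  rIn <- R - spec@sfThicknessMm
  ringArea <- pi * (R^2 - rIn^2)
  compArea <- pi * rIn^2 - pi * spec@boneRadiiMm[1]^2
  expect_equal(sfMRatio(q), ringArea / compArea, tolerance = 0.02)
  expect_equal(q@sfVolumeCm3 / q@muscleVolumeCm3, sfMRatio(q))
})

test_that("reproducibility metric matches hand arithmetic and invariances", {
  mk <- function(vals) {
    new("FatQuantResult",
        intramfPct = setNames(vals, muscleNames()), imatPct = 10,
        sfVolumeCm3 = 10, muscleVolumeCm3 = 20, sfMRatio = 0.5,
        erodedVoxelCounts = setNames(rep(5L, 6),
                                     c(muscleNames(), "compartment")),
        provenance = list(erosion = list(), mode = "summed"))
  }
  # identical repeats
  same <- list(mk(c(5, 6, 7, 8, 9)), mk(c(5, 6, 7, 8, 9)))
  expect_equal(as.numeric(reproducibility(same)), 0)
  # one muscle varying (10, 11, 12): SD 1, average over 5 muscles = 0.2
  reps <- list(mk(c(10, 4, 4, 4, 4)), mk(c(11, 4, 4, 4, 4)),
               mk(c(12, 4, 4, 4, 4)))
  expect_equal(as.numeric(reproducibility(reps)), 0.2)
  # constant offset to every repeat leaves the metric unchanged
  shifted <- lapply(reps, function(r) {
    r@intramfPct <- r@intramfPct + 3; r
  })
  expect_equal(as.numeric(reproducibility(shifted)),
               as.numeric(reproducibility(reps)))
  # muscle order within results is irrelevant (accessed by name)
  perm <- lapply(reps, function(r) {
    r@intramfPct <- r@intramfPct[c("TP", "SOL", "MG", "TA", "LG")]
    r
  })
  expect_equal(as.numeric(reproducibility(perm)),
               as.numeric(reproducibility(reps)))
  expect_error(reproducibility(reps[1]), "at least 2")
})

test_that("noiseless repeats give exactly zero reproducibility SD", {
  truth <- makeLegPhantom(smallPhantomSpec(nSlices = 2L))
  reps <- simulateRepeats(truth, 5)
  q <- lapply(reps, function(v) quantifySubject(v, phantomLabels(truth)))
  expect_equal(as.numeric(reproducibility(q)), 0)
})
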