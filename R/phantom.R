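## Synthetic leg phantoms: stylised cross-sectional anatomy (subcutaneous fat
## ring, five angular-sector muscles with intermuscular seams, bone excluded),
## extruded along z, plus renderers for water/fat volumes and multi-echo
## complex signals with controllable noise and T1-bias confounders.

GYROMAGNETIC_MHZ_PER_T <- 42.577478518

## Fat--water chemical-shift frequency in Hz for a given acquisition.
chemicalShiftHz <- function(acq) {
  acq@fatShiftPpm * GYROMAGNETIC_MHZ_PER_T * acq@fieldT
}

#' Echo times of an acquisition
#' @param acq an [AcquisitionSpec-class].
#' @return Echo times in ms: te0 + (0:(n-1)) * deltaTe.
#' @export
echoTimesMs <- function(acq) {
  acq@te0Ms + (seq_len(acq@nEchoes) - 1L) * acq@deltaTeMs
}

## 2-D cross-section template: per-pixel region assignment on the (x, y)
## grid.  Everything is z-invariant, so the 3-D phantom is an extrusion.
crossSection <- function(spec) {
  nx <- spec@gridShape[1]; ny <- spec@gridShape[2]
  dx <- spec@voxelMm[1]; dy <- spec@voxelMm[2]
  xs <- (seq_len(nx) - (nx + 1) / 2) * dx
  ys <- (seq_len(ny) - (ny + 1) / 2) * dy
  X <- matrix(xs, nx, ny)
  Y <- matrix(ys, nx, ny, byrow = TRUE)
  R <- sqrt(X^2 + Y^2)
  theta <- (atan2(Y, X) * 180 / pi) %% 360

  innerR <- spec@outerRadiusMm - spec@sfThicknessMm
  leg <- R <= spec@outerRadiusMm
  sf <- leg & R > innerR

  bone <- matrix(FALSE, nx, ny)
  boneClear <- matrix(FALSE, nx, ny)
  for (k in seq_along(spec@boneRadiiMm)) {
    D <- sqrt((X - spec@boneCentersMm[k, 1])^2 + (Y - spec@boneCentersMm[k, 2])^2)
    bone <- bone | D <= spec@boneRadiiMm[k]
    boneClear <- boneClear | D <= spec@boneRadiiMm[k] + spec@boneClearanceMm
  }
  compartment <- R <= innerR & !bone

  ## seam zones: within seamWidth/2 of any sector boundary ray
  boundaries <- unique(spec@muscleStartDeg %% 360)
  seamZone <- matrix(FALSE, nx, ny)
  for (b in boundaries) {
    dAng <- abs(((theta - b + 180) %% 360) - 180)
    distToRay <- ifelse(dAng < 90, R * sin(dAng * pi / 180), Inf)
    seamZone <- seamZone | distToRay < spec@seamWidthMm / 2
  }

  rOuterMuscle <- innerR - spec@muscleMarginMm
  if (rOuterMuscle <= spec@muscleInnerMm)
    stop("muscle annulus is empty: compartment radius ", round(innerR, 1),
         " mm minus margin leaves no room beyond muscleInnerMm")

  muscles <- vector("list", length(MUSCLE_NAMES))
  names(muscles) <- MUSCLE_NAMES
  for (m in MUSCLE_NAMES) {
    a0 <- spec@muscleStartDeg[[m]] %% 360
    a1 <- spec@muscleEndDeg[[m]]
    span <- (a1 - spec@muscleStartDeg[[m]]) %% 360
    if (span == 0) span <- 360
    dFromStart <- (theta - a0) %% 360
    sector <- dFromStart < span
    msk <- sector & compartment & !seamZone & !boneClear &
      R >= spec@muscleInnerMm & R <= rOuterMuscle
    if (!any(msk))
      stop("muscle ", m, " has no voxels: sector [", round(a0, 1), ", ",
           round(a0 + span, 1), ") deg does not fit inside the compartment")
    muscles[[m]] <- msk
  }

  list(leg = leg, sf = sf, compartment = compartment, muscles = muscles,
       bone = bone)
}

extrude <- function(m2d, nz) {
  array(m2d, c(dim(m2d), nz))
}

#' Generate a synthetic leg phantom with known ground truth
#'
#' Builds the label masks and the true per-voxel fat-fraction and
#' proton-density fields for a stylised leg: muscle voxels carry their
#' muscle's base fat fraction, intermuscular seams and all compartment tissue
#' outside the muscle sectors carry the seam fat fraction, the subcutaneous
#' ring carries its (near-1) fat fraction, and bone and background carry zero
#' signal.  Anatomy is deterministic given the spec; the seed is accepted for
#' interface symmetry with the stochastic simulators and reserved for future
#' anatomical jitter.
#'
#' @param spec a [PhantomSpec-class].
#' @param seed integer seed (currently unused: the anatomy is deterministic).
#' @return A [PhantomTruth-class].
#' @examples
#' truth <- makeLegPhantom(phantomSpec(gridShape = c(32, 32, 4),
#'                                     outerRadiusMm = 28, sfThicknessMm = 5,
#'                                     boneRadiiMm = 4))
#' truth
#' @export
makeLegPhantom <- function(spec, seed = 1L) {
  validObject(spec)
  cs <- crossSection(spec)
  nz <- spec@gridShape[3]

  ff2d <- matrix(0, spec@gridShape[1], spec@gridShape[2])
  ff2d[cs$compartment] <- spec@seamFF
  for (m in MUSCLE_NAMES) ff2d[cs$muscles[[m]]] <- spec@muscleFF[[m]]
  ff2d[cs$sf] <- spec@sfFatFraction

  s02d <- matrix(0, spec@gridShape[1], spec@gridShape[2])
  s02d[cs$leg & !cs$bone] <- spec@s0

  labels <- labelMaskSet(
    sf = extrude(cs$sf, nz),
    compartment = extrude(cs$compartment, nz),
    muscles = lapply(cs$muscles, extrude, nz = nz))
  validObject(labels)

  new("PhantomTruth",
      ffMap = extrude(ff2d, nz), s0Map = extrude(s02d, nz),
      labels = labels, spec = spec)
}

## One channel of magnitude noise.  Gaussian: additive real noise clipped at
## zero (intensities are magnitudes); Rician: magnitude of the
## complex-Gaussian-noised signal, the distribution of magnitude MR images.
noiseChannel <- function(clean, noise) {
  if (noise@model == "none" || noise@sigma == 0) return(clean)
  n <- length(clean)
  if (noise@model == "gaussian") {
    out <- clean + stats::rnorm(n, 0, noise@sigma)
    out[out < 0] <- 0
  } else {
    out <- sqrt((clean + stats::rnorm(n, 0, noise@sigma))^2 +
                  stats::rnorm(n, 0, noise@sigma)^2)
  }
  array(out, dim(clean))
}

#' Render water and fat magnitude volumes from a phantom
#'
#' Noiseless with no T1 bias, each voxel gets water \eqn{(1-f)\,s_0} and fat
#' \eqn{f\,s_0}.  A T1-bias factor \eqn{\beta > 1} multiplies the fat channel
#' before noise, emulating the fat-signal overestimation of a T1-weighted
#' Dixon sequence.  Noise is drawn per channel using the seed in
#' \code{noise}, so renders are bit-reproducible.
#'
#' @param truth a [PhantomTruth-class].
#' @param noise a [NoiseSpec-class]; default none.
#' @param acq an [AcquisitionSpec-class]; only its \code{t1Bias} is used here.
#' @return A [FatWaterVolume-class].
#' @export
renderWaterFat <- function(truth, noise = noiseSpec("none"),
                           acq = acquisitionSpec()) {
  validObject(truth)
  water <- (1 - truth@ffMap) * truth@s0Map
  fat <- acq@t1Bias * truth@ffMap * truth@s0Map
  if (noise@model != "none" && noise@sigma > 0) {
    withr::local_seed(noise@seed)
    water <- noiseChannel(water, noise)
    fat <- noiseChannel(fat, noise)
  }
  fatWaterVolume(water, fat, voxelMm = truth@spec@voxelMm)
}

#' Render a complex multi-echo signal series
#'
#' Synthesises the single-peak chemical-shift signal model: at echo time
#' \eqn{t_n} the complex signal is
#' \deqn{S_n = (W + F e^{i\phi_n})\, e^{i 2\pi \psi t_n},}
#' with \eqn{W = (1-f)s_0}, \eqn{F = \beta f s_0}, \eqn{\phi_n = 2\pi
#' \Delta f_{cs} t_n} from the fat chemical shift, and \eqn{\psi} the
#' per-voxel off-resonance field offset in Hz.  Optional complex Gaussian
#' noise is added independently to real and imaginary parts of every echo.
#'
#' @param truth a [PhantomTruth-class].
#' @param acq an [AcquisitionSpec-class].
#' @param fieldmapHz scalar or array of per-voxel off-resonance (Hz).
#' @param noise a [NoiseSpec-class]; "gaussian" and "rician" both add complex
#'   Gaussian noise (the signal is complex here, so no magnitude is taken).
#' @return An [EchoSeries-class].
#' @export
renderEchoes <- function(truth, acq = acquisitionSpec(), fieldmapHz = 0,
                         noise = noiseSpec("none")) {
  validObject(truth); validObject(acq)
  shp <- dim(truth@ffMap)
  W <- (1 - truth@ffMap) * truth@s0Map
  F <- acq@t1Bias * truth@ffMap * truth@s0Map
  if (length(fieldmapHz) == 1L) fieldmapHz <- array(fieldmapHz, shp)
  stopifnot(identical(dim(fieldmapHz), shp))
  te <- echoTimesMs(acq)
  dfcs <- chemicalShiftHz(acq)
  sig <- array(complex(real = 0), c(shp, acq@nEchoes))
  addNoise <- noise@model != "none" && noise@sigma > 0
  if (addNoise) withr::local_seed(noise@seed)
  nvox <- prod(shp)
  for (n in seq_along(te)) {
    tSec <- te[n] / 1000
    phi <- 2 * pi * dfcs * tSec
    s <- (W + F * exp(1i * phi)) * exp(1i * 2 * pi * fieldmapHz * tSec)
    if (addNoise)
      s <- s + complex(real = stats::rnorm(nvox, 0, noise@sigma),
                       imaginary = stats::rnorm(nvox, 0, noise@sigma))
    sig[, , , n] <- s
  }
  new("EchoSeries", signal = sig, echoTimesMs = te, acq = acq)
}

#' Simulate repeat acquisitions of one phantom
#'
#' Renders the same anatomy \code{nRepeats} times with independent noise
#' draws (seed offset by the repeat index); the input substrate for the
#' scan--rescan reproducibility metric.
#'
#' @param truth a [PhantomTruth-class].
#' @param nRepeats number of repeats, >= 2.
#' @param noise a [NoiseSpec-class]; its seed is the base seed.
#' @param acq an [AcquisitionSpec-class].
#' @return List of [FatWaterVolume-class] of length \code{nRepeats}.
#' @export
simulateRepeats <- function(truth, nRepeats, noise = noiseSpec("none"),
                            acq = acquisitionSpec()) {
  if (nRepeats < 2)
    stop("reproducibility needs at least 2 repeats, got ", nRepeats)
  lapply(seq_len(nRepeats), function(i) {
    ni <- noiseSpec(noise@model, noise@sigma, seed = noise@seed + i - 1L)
    renderWaterFat(truth, noise = ni, acq = acq)
  })
}

## ---- cohort simulation -----------------------------------------------------

#' Describe a two-group synthetic cohort
#'
#' Study-condition defaults emulate the cohort the pipeline targets: 10
#' subjects with bilateral spastic cerebral palsy (BSCP, GMFCS levels I/II/III
#' in counts 2/5/3) and 10 typically developing (TD) subjects, per-muscle fat
#' fractions drawn from truncated normals, a +10-percentage-point BSCP shift
#' with 3-point between-subject SD, a GMFCS gradient (level III highest), a
#' thicker subcutaneous ring in the BSCP group (SF/M ratio about 1.9x the TD
#' value in expectation), and anthropometrics matching the target study's
#' group summaries (age about 22.5 vs 22.8 y, mass 64.0 vs 71.2 kg, height
#' 1.69 vs 1.76 m).
#'
#' @param nBSCP,nTD group sizes (each >= 2).
#' @param muscleFFMeanTD named per-muscle mean true fat fraction, TD group.
#' @param muscleFFShiftBSCP additive shift of the BSCP means (fraction units;
#'   0.10 = 10 percentage points).
#' @param muscleFFSD between-subject SD of the per-muscle fat fraction.
#' @param gmfcsCounts named counts of BSCP subjects at GMFCS I, II, III.
#' @param gmfcsShift named additive fat-fraction shift per GMFCS level.
#' @param sfThicknessMeanMm,sfThicknessSDMm per-group subcutaneous ring
#'   thickness distributions, names TD and BSCP.
#' @param ageMean,ageSD,massMean,massSD,heightMean,heightSD per-group
#'   anthropometric distributions, names TD and BSCP.
#' @param nMale number of male subjects per group, names TD and BSCP.
#' @param noiseModel,noiseSigma acquisition noise for the rendered volumes.
#' @param gridShape,voxelMm,outerRadiusMm phantom geometry shared by all
#'   subjects (subcutaneous thickness varies per subject).
#' @param seamFF intermuscular seam fat fraction.
#' @return A list of class \code{cohortSpec}.
#' @seealso [simulateCohort()]
#' @export
cohortSpec <- function(nBSCP = 10L, nTD = 10L,
                       muscleFFMeanTD = c(MG = 0.05, LG = 0.05, SOL = 0.05,
                                          TA = 0.04, TP = 0.04),
                       muscleFFShiftBSCP = 0.10,
                       muscleFFSD = 0.03,
                       gmfcsCounts = c(I = 2L, II = 5L, III = 3L),
                       gmfcsShift = c(I = -0.02, II = 0, III = 0.03),
                       sfThicknessMeanMm = c(TD = 8, BSCP = 13),
                       sfThicknessSDMm = c(TD = 2, BSCP = 4),
                       ageMean = c(TD = 22.8, BSCP = 22.5),
                       ageSD = c(TD = 3.0, BSCP = 2.9),
                       massMean = c(TD = 71.2, BSCP = 64.0),
                       massSD = c(TD = 11.8, BSCP = 11.5),
                       heightMean = c(TD = 1.76, BSCP = 1.69),
                       heightSD = c(TD = 0.12, BSCP = 0.08),
                       nMale = c(TD = 6L, BSCP = 7L),
                       noiseModel = "rician", noiseSigma = 2,
                       gridShape = c(64L, 64L, 27L),
                       voxelMm = c(2, 2, 4),
                       outerRadiusMm = 55,
                       seamFF = 0.8) {
  if (nBSCP < 2 || nTD < 2)
    stop("each group needs at least 2 subjects")
  if (sum(gmfcsCounts) != nBSCP)
    stop("GMFCS counts must sum to the BSCP group size")
  structure(as.list(environment()), class = "cohortSpec")
}

## Truncated-normal draws on [lo, hi] via inverse-CDF sampling.
rtruncnorm <- function(n, mean, sd, lo = 0, hi = 1) {
  if (sd == 0) return(rep(pmin(hi, pmax(lo, mean)), n))
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Simulate a full two-group cohort with rendered volumes
#'
#' Draws per-subject true fat fractions, subcutaneous ring thickness, and
#' metadata from the distributions in the [cohortSpec()], builds one phantom
#' per subject, and renders its water/fat volumes with the configured noise.
#' All randomness descends from \code{seed}, so the cohort is
#' bit-reproducible.
#'
#' @param spec a [cohortSpec()].
#' @param seed integer seed.
#' @return List with elements \code{subjects} (per subject: \code{id},
#'   \code{truth}, \code{volume}, \code{masks}, \code{trueFF}) and
#'   \code{cohort}, a data.frame with columns subject_id, group, gmfcs, age,
#'   sex, mass_kg, height_m, bmi.
#' @export
simulateCohort <- function(spec = cohortSpec(), seed = 1L) {
  stopifnot(inherits(spec, "cohortSpec"))
  withr::local_seed(seed)
  groups <- c(rep("BSCP", spec$nBSCP), rep("TD", spec$nTD))
  gmfcs <- c(rep(names(spec$gmfcsCounts), spec$gmfcsCounts),
             rep(NA_character_, spec$nTD))
  n <- length(groups)
  noiseSeeds <- sample.int(.Machine$integer.max - 64L, n)

  subjects <- vector("list", n)
  meta <- vector("list", n)
  for (i in seq_len(n)) {
    g <- groups[i]
    ffMean <- spec$muscleFFMeanTD
    if (g == "BSCP")
      ffMean <- ffMean + spec$muscleFFShiftBSCP + spec$gmfcsShift[[gmfcs[i]]]
    ff <- vapply(MUSCLE_NAMES, function(m)
      rtruncnorm(1, ffMean[[m]], spec$muscleFFSD), numeric(1))
    sfT <- rtruncnorm(1, spec$sfThicknessMeanMm[[g]], spec$sfThicknessSDMm[[g]],
                      lo = 3, hi = spec$outerRadiusMm / 2)
    pspec <- phantomSpec(gridShape = spec$gridShape, voxelMm = spec$voxelMm,
                         outerRadiusMm = spec$outerRadiusMm,
                         sfThicknessMm = sfT, muscleFF = ff,
                         seamFF = spec$seamFF)
    truth <- makeLegPhantom(pspec)
    noise <- noiseSpec(spec$noiseModel, spec$noiseSigma, seed = noiseSeeds[i])
    vol <- renderWaterFat(truth, noise = noise)

    age <- stats::rnorm(1, spec$ageMean[[g]], spec$ageSD[[g]])
    mass <- rtruncnorm(1, spec$massMean[[g]], spec$massSD[[g]], 35, 150)
    height <- rtruncnorm(1, spec$heightMean[[g]], spec$heightSD[[g]], 1.4, 2.1)
    nGrp <- if (g == "BSCP") spec$nBSCP else spec$nTD
    idxInGrp <- if (g == "BSCP") i else i - spec$nBSCP
    sex <- if (idxInGrp <= spec$nMale[[g]]) "m" else "f"

    id <- sprintf("%s%02d", tolower(g), idxInGrp)
    subjects[[i]] <- list(id = id, truth = truth, volume = vol,
                          masks = truth@labels, trueFF = ff)
    meta[[i]] <- data.frame(subject_id = id, group = g, gmfcs = gmfcs[i],
                            age = age, sex = sex, mass_kg = mass,
                            height_m = height, bmi = mass / height^2,
                            stringsAsFactors = FALSE)
  }
  cohort <- do.call(rbind, meta)
  rownames(cohort) <- NULL
  list(subjects = subjects, cohort = cohort)
}
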