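#' Create a paired water/fat volume
#'
#' @param water,fat 3-D numeric arrays of the same shape, nonnegative.
#' @param voxelMm voxel edge lengths in mm (x, y, z).
#' @return A [FatWaterVolume-class].
#' @examples
#' v <- fatWaterVolume(array(75, c(4, 4, 2)), array(25, c(4, 4, 2)))
#' fatFraction(v, array(TRUE, c(4, 4, 2)))  # 25
#' @export
fatWaterVolume <- function(water, fat, voxelMm = c(2, 2, 4)) {
  new("FatWaterVolume", water = water, fat = fat, voxelMm = as.numeric(voxelMm))
}

#' Create a label mask set
#'
#' @param sf,compartment logical 3-D arrays.
#' @param muscles named list of five logical arrays (MG, LG, SOL, TA, TP).
#' @return A validated [LabelMaskSet-class].
#' @export
labelMaskSet <- function(sf, compartment, muscles) {
  new("LabelMaskSet", sf = sf, compartment = compartment,
      muscles = muscles[MUSCLE_NAMES])
}

#' Describe a synthetic leg phantom
#'
#' Builds a [PhantomSpec-class] with defaults emulating a calf acquisition:
#' 64 x 64 x 27 grid at 2.0 x 2.0 x 4.0 mm (10.8 cm axial coverage), a 55 mm
#' leg radius with an 8 mm subcutaneous fat ring, five 72-degree muscle
#' sectors separated by 4 mm intermuscular seams, and a single bone circle
#' excluded from all ROIs.
#'
#' @param gridShape voxel counts (x, y, z).
#' @param voxelMm voxel size in mm.
#' @param outerRadiusMm leg outer radius (mm).
#' @param sfThicknessMm subcutaneous ring thickness (mm).
#' @param sfFatFraction fat fraction of subcutaneous voxels (default 0.9).
#' @param muscleFF named per-muscle base fat fraction in [0, 1].
#' @param muscleStartDeg,muscleEndDeg named sector angles (degrees).
#' @param muscleInnerMm inner radial limit of muscle sectors (mm).
#' @param muscleMarginMm margin between muscles and the compartment edge (mm).
#' @param seamFF fat fraction of the intermuscular seams.
#' @param seamWidthMm full seam width (mm).
#' @param boneCentersMm k x 2 matrix of bone centres (mm from the leg axis).
#' @param boneRadiiMm bone circle radii (mm).
#' @param boneClearanceMm muscle-free clearance around bone (mm).
#' @param s0 proton-density scale (arbitrary units).
#' @return A validated [PhantomSpec-class].
#' @examples
#' spec <- phantomSpec(muscleFF = c(MG = 0.2, LG = 0.2, SOL = 0.2,
#'                                  TA = 0.2, TP = 0.2), seamFF = 0.2)
#' @export
phantomSpec <- function(gridShape = c(64L, 64L, 27L),
                        voxelMm = c(2, 2, 4),
                        outerRadiusMm = 55,
                        sfThicknessMm = 8,
                        sfFatFraction = 0.9,
                        muscleFF = c(MG = 0.05, LG = 0.05, SOL = 0.05,
                                     TA = 0.04, TP = 0.04),
                        muscleStartDeg = c(MG = 0, LG = 72, SOL = 144,
                                           TA = 216, TP = 288),
                        muscleEndDeg = c(MG = 72, LG = 144, SOL = 216,
                                         TA = 288, TP = 360),
                        muscleInnerMm = 8,
                        muscleMarginMm = 3,
                        seamFF = 0.8,
                        seamWidthMm = 4,
                        boneCentersMm = matrix(c(0, 0), 1, 2),
                        boneRadiiMm = 8,
                        boneClearanceMm = 2,
                        s0 = 100) {
  new("PhantomSpec",
      gridShape = as.integer(gridShape), voxelMm = as.numeric(voxelMm),
      outerRadiusMm = outerRadiusMm, sfThicknessMm = sfThicknessMm,
      sfFatFraction = sfFatFraction,
      muscleFF = muscleFF[MUSCLE_NAMES],
      muscleStartDeg = muscleStartDeg[MUSCLE_NAMES],
      muscleEndDeg = muscleEndDeg[MUSCLE_NAMES],
      muscleInnerMm = muscleInnerMm, muscleMarginMm = muscleMarginMm,
      seamFF = seamFF, seamWidthMm = seamWidthMm,
      boneCentersMm = boneCentersMm, boneRadiiMm = as.numeric(boneRadiiMm),
      boneClearanceMm = boneClearanceMm, s0 = s0)
}

#' Describe a noise model
#'
#' @param model "none", "gaussian" or "rician".
#' @param sigma noise SD in the units of the proton-density scale s0.
#' @param seed integer base seed for the draw.
#' @return A [NoiseSpec-class].
#' @export
noiseSpec <- function(model = c("none", "gaussian", "rician"),
                      sigma = 0, seed = 1L) {
  model <- match.arg(model)
  if (model == "none") sigma <- 0
  new("NoiseSpec", model = model, sigma = sigma, seed = as.integer(seed))
}

#' Describe a multi-echo acquisition
#'
#' @param nEchoes number of echoes (default 4).
#' @param te0Ms first echo time in ms (default 2.3).
#' @param deltaTeMs echo spacing in ms (default 1.0).
#' @param fieldT field strength in tesla (default 3.0).
#' @param fatShiftPpm water--fat chemical shift in ppm (default 3.4).
#' @param t1Bias fat-signal multiplier beta >= 1 (default 1 = no T1 bias).
#' @return An [AcquisitionSpec-class].
#' @export
acquisitionSpec <- function(nEchoes = 4L, te0Ms = 2.3, deltaTeMs = 1.0,
                            fieldT = 3.0, fatShiftPpm = 3.4, t1Bias = 1.0) {
  new("AcquisitionSpec", nEchoes = as.integer(nEchoes), te0Ms = te0Ms,
      deltaTeMs = deltaTeMs, fieldT = fieldT, fatShiftPpm = fatShiftPpm,
      t1Bias = t1Bias)
}

#' Describe the edge-effect erosion
#'
#' @param radiusPx erosion radius in pixels (default 2, i.e. 4.0 mm at
#'   2.0 mm in-plane resolution).
#' @param elementShape "disk" or "square".
#' @param mode "per_slice_2d" (each axial slice eroded independently) or
#'   "full_3d".
#' @return An [ErosionParams-class].
#' @export
erosionParams <- function(radiusPx = 2L,
                          elementShape = c("disk", "square"),
                          mode = c("per_slice_2d", "full_3d")) {
  new("ErosionParams", radiusPx = as.integer(radiusPx),
      elementShape = match.arg(elementShape), mode = match.arg(mode))
}

## ---- accessors -------------------------------------------------------------

#' @describeIn fatWaterVolume Water channel of a volume.
#' @param x object to access.
#' @export
waterImage <- function(x) x@water

#' @describeIn fatWaterVolume Fat channel of a volume.
#' @export
fatImage <- function(x) x@fat

#' Voxel dimensions in mm
#' @param x a FatWaterVolume, PhantomTruth or PhantomSpec.
#' @export
voxelSize <- function(x) {
  if (is(x, "FatWaterVolume")) x@voxelMm
  else if (is(x, "PhantomTruth")) x@spec@voxelMm
  else if (is(x, "PhantomSpec")) x@voxelMm
  else stop("no voxel size for class ", class(x))
}

#' Muscle names used throughout the package
#' @return Character vector: MG, LG, SOL, TA, TP.
#' @export
muscleNames <- function() MUSCLE_NAMES

#' @describeIn labelMaskSet Named list of the five muscle masks.
#' @param x a LabelMaskSet.
#' @export
muscleMasks <- function(x) x@muscles

#' @describeIn labelMaskSet Subcutaneous fat mask.
#' @export
sfMask <- function(x) x@sf

#' @describeIn labelMaskSet Muscle compartment mask.
#' @export
compartmentMask <- function(x) x@compartment

#' @describeIn makeLegPhantom True fat-fraction field of a phantom.
#' @param x a PhantomTruth.
#' @export
ffMap <- function(x) x@ffMap

#' @describeIn makeLegPhantom Proton-density field of a phantom.
#' @export
s0Map <- function(x) x@s0Map

#' @describeIn makeLegPhantom Label masks of a phantom.
#' @export
phantomLabels <- function(x) x@labels

#' @describeIn quantifySubject Per-muscle IntraMF (%) of a result.
#' @param x a FatQuantResult.
#' @export
intramfPct <- function(x) x@intramfPct

#' @describeIn quantifySubject IMAT (%) of a result.
#' @export
imatPct <- function(x) x@imatPct

#' @describeIn quantifySubject Subcutaneous-fat-to-muscle volume ratio.
#' @export
sfMRatio <- function(x) x@sfMRatio

## ---- show methods ----------------------------------------------------------

setMethod("show", "FatWaterVolume", function(object) {
  d <- dim(object@water)
  cat(sprintf("FatWaterVolume: %d x %d x %d voxels at %.1f x %.1f x %.1f mm\n",
              d[1], d[2], d[3],
              object@voxelMm[1], object@voxelMm[2], object@voxelMm[3]))
  tot <- object@water + object@fat
  inb <- tot > 0
  if (any(inb))
    cat(sprintf("  whole-grid fat fraction (nonzero voxels): %.2f%%\n",
                100 * sum(object@fat[inb]) / sum(tot[inb])))
})

setMethod("show", "LabelMaskSet", function(object) {
  d <- dim(object@sf)
  cat(sprintf("LabelMaskSet on a %d x %d x %d grid\n", d[1], d[2], d[3]))
  cat(sprintf("  SF: %d voxels; compartment: %d voxels\n",
              sum(object@sf), sum(object@compartment)))
  for (m in MUSCLE_NAMES)
    cat(sprintf("  %-3s: %d voxels\n", m, sum(object@muscles[[m]])))
})

setMethod("show", "PhantomTruth", function(object) {
  d <- dim(object@ffMap)
  cat(sprintf("PhantomTruth: %d x %d x %d grid, s0 scale %.3g\n",
              d[1], d[2], d[3], object@spec@s0))
  for (m in MUSCLE_NAMES) {
    mm <- object@labels@muscles[[m]]
    cat(sprintf("  %-3s: %6d voxels, true FF %.3f\n",
                m, sum(mm), mean(object@ffMap[mm])))
  }
})

setMethod("show", "FatQuantResult", function(object) {
  cat("FatQuantResult\n")
  for (m in MUSCLE_NAMES)
    cat(sprintf("  IntraMF %-3s: %6.2f%%\n", m, object@intramfPct[[m]]))
  cat(sprintf("  IMAT       : %6.2f%%\n", object@imatPct))
  cat(sprintf("  SF volume  : %.1f cm^3; muscle volume: %.1f cm^3; SF/M = %.3f\n",
              object@sfVolumeCm3, object@muscleVolumeCm3, object@sfMRatio))
  cat(sprintf("  (erosion radius %d px, %s, %s; Eq. mode '%s')\n",
              object@provenance$erosion$radiusPx,
              object@provenance$erosion$elementShape,
              object@provenance$erosion$mode,
              object@provenance$mode))
})

setMethod("show", "EchoSeries", function(object) {
  d <- dim(object@signal)
  cat(sprintf("EchoSeries: %d echoes on a %d x %d x %d grid, TE = %s ms\n",
              d[4], d[1], d[2], d[3],
              paste(format(object@echoTimesMs), collapse = ", ")))
})
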