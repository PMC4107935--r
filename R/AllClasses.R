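#' @import methods
NULL

MUSCLE_NAMES <- c("MG", "LG", "SOL", "TA", "TP")

#' Paired water/fat intensity volumes
#'
#' Container for co-registered water and fat 3-D intensity grids sharing one
#' voxel geometry, as produced by a Dixon water--fat reconstruction.  All
#' intensities are nonnegative and in arbitrary scanner units; the fat
#' fraction of a region is \code{100 * fat / (fat + water)}.
#'
#' @slot water 3-D numeric array of water-signal intensities.
#' @slot fat 3-D numeric array of fat-signal intensities, same shape.
#' @slot voxelMm numeric length 3, voxel edge lengths in mm (x, y, z).
#' @seealso [fatWaterVolume()], [fatFraction()], [readFatWater()]
#' @export
setClass("FatWaterVolume",
  representation(water = "array", fat = "array", voxelMm = "numeric"))

setValidity("FatWaterVolume", function(object) {
  msg <- character()
  if (length(dim(object@water)) != 3L)
    msg <- c(msg, "'water' must be a 3-D array")
  if (!identical(dim(object@water), dim(object@fat)))
    msg <- c(msg, "'water' and 'fat' must share the same grid shape")
  if (length(object@voxelMm) != 3L || any(!is.finite(object@voxelMm)) ||
      any(object@voxelMm <= 0))
    msg <- c(msg, "'voxelMm' must be 3 positive voxel dimensions (mm)")
  if (anyNA(object@water) || anyNA(object@fat))
    msg <- c(msg, "intensities must not contain NA")
  else if (min(object@water) < 0 || min(object@fat) < 0)
    msg <- c(msg, "intensities must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Subcutaneous-fat, compartment and muscle label masks
#'
#' Binary masks for the subcutaneous fat ring, the whole muscle compartment
#' (everything inside the fascia, bone excluded) and the five calf muscles
#' (medial/lateral gastrocnemius, soleus, tibialis anterior/posterior).
#' The mask hierarchy is enforced by the validity method: muscle masks are
#' pairwise disjoint, every muscle voxel lies inside the compartment, and the
#' subcutaneous mask never overlaps the compartment.
#'
#' @slot sf logical 3-D array, subcutaneous fat.
#' @slot compartment logical 3-D array, muscle compartment.
#' @slot muscles named list of five logical 3-D arrays (MG, LG, SOL, TA, TP).
#' @seealso [labelMaskSet()], [readMasks()], [validateMasks()]
#' @export
setClass("LabelMaskSet",
  representation(sf = "array", compartment = "array", muscles = "list"))

setValidity("LabelMaskSet", function(object) {
  violations <- maskViolations(object)
  if (length(violations)) violations else TRUE
})

## Shared by the validity method and readMasks(), which reports voxel counts.
maskViolations <- function(object) {
  msg <- character()
  shp <- dim(object@sf)
  if (!is.logical(object@sf) || !is.logical(object@compartment))
    return("masks must be logical arrays")
  if (!identical(dim(object@compartment), shp))
    return("'sf' and 'compartment' must share the same grid shape")
  if (!identical(sort(names(object@muscles)), sort(MUSCLE_NAMES)))
    return(sprintf("muscle masks must be named %s",
                   paste(MUSCLE_NAMES, collapse = ", ")))
  for (m in MUSCLE_NAMES) {
    mm <- object@muscles[[m]]
    if (!is.logical(mm) || !identical(dim(mm), shp))
      return(sprintf("muscle mask '%s' must be a logical array of the volume shape", m))
  }
  pairs <- utils::combn(MUSCLE_NAMES, 2)
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    n <- sum(object@muscles[[a]] & object@muscles[[b]])
    if (n > 0)
      msg <- c(msg, sprintf("muscles %s and %s overlap in %d voxel(s)", a, b, n))
  }
  for (m in MUSCLE_NAMES) {
    n <- sum(object@muscles[[m]] & !object@compartment)
    if (n > 0)
      msg <- c(msg, sprintf("muscle %s has %d voxel(s) outside the compartment", m, n))
  }
  n <- sum(object@sf & object@compartment)
  if (n > 0)
    msg <- c(msg, sprintf("subcutaneous and compartment masks overlap in %d voxel(s)", n))
  msg
}

#' Geometric and compositional description of a synthetic leg
#'
#' Parameters of the stylised leg phantom: an elliptical cross-section with a
#' subcutaneous fat ring, a muscle compartment containing five angular-sector
#' muscles separated by intermuscular fat seams, and circular bone regions
#' excluded from all ROIs.  The anatomy is constant along z (an extruded
#' cross-section), which matches the short axial stack the analysis targets.
#'
#' Defaults emulate a calf acquisition: 2.0 x 2.0 mm in-plane voxels, 4.0 mm
#' slices, 27 slices (10.8 cm coverage).
#'
#' @slot gridShape integer length 3, voxel counts (x, y, z).
#' @slot voxelMm numeric length 3, voxel size in mm.
#' @slot outerRadiusMm leg outer radius (mm).
#' @slot sfThicknessMm thickness of the subcutaneous fat ring (mm).
#' @slot sfFatFraction fat fraction assigned to subcutaneous fat voxels.
#' @slot muscleFF named numeric length 5, base fat fraction per muscle in [0,1].
#' @slot muscleStartDeg named numeric length 5, sector start angle per muscle.
#' @slot muscleEndDeg named numeric length 5, sector end angle per muscle.
#' @slot muscleInnerMm inner radial limit of the muscle sectors (mm).
#' @slot muscleMarginMm gap between muscle sectors and the compartment edge (mm).
#' @slot seamFF fat fraction of intermuscular seams.
#' @slot seamWidthMm full width of the seams between muscle sectors (mm).
#' @slot boneCentersMm k x 2 matrix of bone circle centres (mm, relative to axis).
#' @slot boneRadiiMm numeric length k, bone circle radii (mm).
#' @slot boneClearanceMm clearance ring kept free of muscle around bone (mm).
#' @slot s0 proton-density scale (arbitrary units).
#' @seealso [phantomSpec()], [makeLegPhantom()]
#' @export
setClass("PhantomSpec",
  representation(gridShape = "integer", voxelMm = "numeric",
                 outerRadiusMm = "numeric", sfThicknessMm = "numeric",
                 sfFatFraction = "numeric",
                 muscleFF = "numeric",
                 muscleStartDeg = "numeric", muscleEndDeg = "numeric",
                 muscleInnerMm = "numeric", muscleMarginMm = "numeric",
                 seamFF = "numeric", seamWidthMm = "numeric",
                 boneCentersMm = "matrix", boneRadiiMm = "numeric",
                 boneClearanceMm = "numeric", s0 = "numeric"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@gridShape) != 3L || any(object@gridShape[1:2] < 4L) ||
      object@gridShape[3] < 1L)
    msg <- c(msg, "'gridShape' must be 3 voxel counts (in-plane >= 4, slices >= 1)")
  if (length(object@voxelMm) != 3L || any(object@voxelMm <= 0))
    msg <- c(msg, "'voxelMm' must be 3 positive lengths")
  for (s in c("outerRadiusMm", "sfThicknessMm", "muscleMarginMm",
              "seamWidthMm", "boneClearanceMm", "s0")) {
    if (slot(object, s) <= 0)
      msg <- c(msg, sprintf("'%s' must be > 0", s))
  }
  ffs <- c(object@muscleFF, object@seamFF, object@sfFatFraction)
  if (any(ffs < 0 | ffs > 1))
    msg <- c(msg, "all fat fractions must lie in [0, 1]")
  if (!identical(names(object@muscleFF), MUSCLE_NAMES))
    msg <- c(msg, "'muscleFF' must be named MG, LG, SOL, TA, TP")
  if (object@sfThicknessMm >= object@outerRadiusMm)
    msg <- c(msg, "'sfThicknessMm' must be smaller than 'outerRadiusMm'")
  if (nrow(object@boneCentersMm) != length(object@boneRadiiMm))
    msg <- c(msg, "'boneCentersMm' rows must match 'boneRadiiMm'")
  if (length(object@boneRadiiMm) && any(object@boneRadiiMm <= 0))
    msg <- c(msg, "bone radii must be > 0")
  if (length(msg)) msg else TRUE
})

#' Ground truth for a simulated leg
#'
#' Per-voxel true fat-fraction and proton-density fields together with the
#' label masks and the generating [PhantomSpec-class].  This is what rendered
#' volumes and downstream estimates are validated against.
#'
#' @slot ffMap 3-D numeric array, true fat fraction in [0, 1].
#' @slot s0Map 3-D numeric array, proton density (0 outside tissue).
#' @slot labels a [LabelMaskSet-class].
#' @slot spec the generating [PhantomSpec-class].
#' @seealso [makeLegPhantom()], [renderWaterFat()]
#' @export
setClass("PhantomTruth",
  representation(ffMap = "array", s0Map = "array",
                 labels = "LabelMaskSet", spec = "PhantomSpec"))

setValidity("PhantomTruth", function(object) {
  msg <- character()
  if (!identical(dim(object@ffMap), dim(object@s0Map)))
    msg <- c(msg, "'ffMap' and 's0Map' must share the same grid shape")
  if (min(object@ffMap) < 0 || max(object@ffMap) > 1)
    msg <- c(msg, "'ffMap' must lie in [0, 1] everywhere")
  if (min(object@s0Map) < 0)
    msg <- c(msg, "'s0Map' must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Noise model for rendered volumes
#'
#' Gaussian noise adds independent zero-mean noise to each channel; Rician
#' noise takes the magnitude of the complex-noised signal per channel, the
#' distribution of magnitude MR images.  Rician noise biases fat fractions of
#' low-signal regions upward, one of the known confounders of Dixon fat
#' quantification.
#'
#' @slot model one of "none", "gaussian", "rician".
#' @slot sigma noise standard deviation, same units as the proton density s0.
#' @slot seed integer base seed for the noise draw.
#' @seealso [noiseSpec()], [renderWaterFat()]
#' @export
setClass("NoiseSpec",
  representation(model = "character", sigma = "numeric", seed = "integer"))

setValidity("NoiseSpec", function(object) {
  msg <- character()
  if (!object@model %in% c("none", "gaussian", "rician"))
    msg <- c(msg, "'model' must be one of none, gaussian, rician")
  if (object@sigma < 0) msg <- c(msg, "'sigma' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Multi-echo gradient-echo acquisition parameters
#'
#' Parameters of the chemical-shift acquisition used both to synthesise echo
#' trains and to separate them: echo count and spacing, field strength, the
#' (single-peak) water--fat chemical shift, and an optional multiplicative T1
#' bias applied to the fat channel.  Defaults follow a four-point gradient
#' echo protocol at 3 T with first echo 2.3 ms and 1.0 ms echo spacing.
#'
#' @slot nEchoes number of echoes (>= 3 when the field map must be estimated).
#' @slot te0Ms first echo time (ms).
#' @slot deltaTeMs echo spacing (ms).
#' @slot fieldT main field strength (tesla).
#' @slot fatShiftPpm water--fat chemical shift (ppm, single fat peak).
#' @slot t1Bias factor beta >= 1 multiplying the fat signal; 1 disables the
#'   T1-weighting confounder.
#' @seealso [acquisitionSpec()], [renderEchoes()], [separateDixon()]
#' @export
setClass("AcquisitionSpec",
  representation(nEchoes = "integer", te0Ms = "numeric", deltaTeMs = "numeric",
                 fieldT = "numeric", fatShiftPpm = "numeric", t1Bias = "numeric"))

setValidity("AcquisitionSpec", function(object) {
  msg <- character()
  if (object@nEchoes < 2L) msg <- c(msg, "'nEchoes' must be >= 2")
  if (object@te0Ms <= 0) msg <- c(msg, "'te0Ms' must be > 0")
  if (object@deltaTeMs <= 0) msg <- c(msg, "'deltaTeMs' must be > 0")
  if (object@fieldT <= 0) msg <- c(msg, "'fieldT' must be > 0")
  if (object@t1Bias < 1) msg <- c(msg, "'t1Bias' must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Complex multi-echo signal series
#'
#' The complex gradient-echo signal at each echo time, stored as a 4-D array
#' (x, y, z, echo), with its echo times and generating acquisition parameters.
#'
#' @slot signal complex 4-D array, last dimension indexing echoes.
#' @slot echoTimesMs numeric, strictly increasing echo times (ms).
#' @slot acq the [AcquisitionSpec-class].
#' @seealso [renderEchoes()], [separateDixon()]
#' @export
setClass("EchoSeries",
  representation(signal = "array", echoTimesMs = "numeric",
                 acq = "AcquisitionSpec"))

setValidity("EchoSeries", function(object) {
  msg <- character()
  d <- dim(object@signal)
  if (length(d) != 4L)
    msg <- c(msg, "'signal' must be a 4-D (x, y, z, echo) array")
  else if (d[4] != length(object@echoTimesMs))
    msg <- c(msg, "echo count must match 'echoTimesMs'")
  if (d[4] != object@acq@nEchoes)
    msg <- c(msg, "echo count must match the acquisition spec")
  if (is.unsorted(object@echoTimesMs, strictly = TRUE))
    msg <- c(msg, "'echoTimesMs' must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Morphological erosion parameters
#'
#' The edge-effect erosion applied to musculature ROIs before intensity
#' ratios are formed: a structuring element of radius \code{radiusPx} pixels
#' (default 2, i.e. 4.0 mm at 2.0 mm in-plane resolution), disk or square
#' shaped, applied per axial slice (default) or in full 3-D.
#'
#' @slot radiusPx integer erosion radius in pixels, >= 0.
#' @slot elementShape "disk" (offsets with dx^2 + dy^2 <= r^2) or "square".
#' @slot mode "per_slice_2d" or "full_3d".
#' @seealso [erosionParams()], [erodeMask()]
#' @export
setClass("ErosionParams",
  representation(radiusPx = "integer", elementShape = "character",
                 mode = "character"))

setValidity("ErosionParams", function(object) {
  msg <- character()
  if (object@radiusPx < 0L) msg <- c(msg, "'radiusPx' must be >= 0")
  if (!object@elementShape %in% c("disk", "square"))
    msg <- c(msg, "'elementShape' must be 'disk' or 'square'")
  if (!object@mode %in% c("per_slice_2d", "full_3d"))
    msg <- c(msg, "'mode' must be 'per_slice_2d' or 'full_3d'")
  if (length(msg)) msg else TRUE
})

#' Per-subject fat quantification results
#'
#' The outputs of the quantification stage for one subject: intramuscular fat
#' fraction (IntraMF, %) per muscle, intermuscular fat fraction of the whole
#' compartment (IMAT, %), subcutaneous fat and muscle compartment volumes
#' (cm^3) and their ratio (SF/M), the eroded voxel counts behind every
#' reported percentage, and provenance (erosion and aggregation settings).
#'
#' @slot intramfPct named numeric length 5, IntraMF per muscle (%).
#' @slot imatPct IMAT of the eroded compartment (%).
#' @slot sfVolumeCm3 subcutaneous fat volume (cm^3).
#' @slot muscleVolumeCm3 un-eroded muscle compartment volume (cm^3).
#' @slot sfMRatio sfVolumeCm3 / muscleVolumeCm3 (dimensionless).
#' @slot erodedVoxelCounts named integer, voxels surviving erosion per ROI.
#' @slot provenance list recording erosion parameters and aggregation mode.
#' @seealso [quantifySubject()], [reproducibility()]
#' @export
setClass("FatQuantResult",
  representation(intramfPct = "numeric", imatPct = "numeric",
                 sfVolumeCm3 = "numeric", muscleVolumeCm3 = "numeric",
                 sfMRatio = "numeric", erodedVoxelCounts = "integer",
                 provenance = "list"))

setValidity("FatQuantResult", function(object) {
  msg <- character()
  pct <- c(object@intramfPct, object@imatPct)
  if (any(pct < 0 | pct > 100))
    msg <- c(msg, "percentages must lie in [0, 100]")
  if (!identical(names(object@intramfPct), MUSCLE_NAMES))
    msg <- c(msg, "'intramfPct' must be named MG, LG, SOL, TA, TP")
  if (object@muscleVolumeCm3 > 0 &&
      abs(object@sfMRatio - object@sfVolumeCm3 / object@muscleVolumeCm3) >
        1e-8 * max(1, object@sfMRatio))
    msg <- c(msg, "'sfMRatio' must equal sfVolumeCm3 / muscleVolumeCm3")
  if (any(object@erodedVoxelCounts <= 0L))
    msg <- c(msg, "every reported percentage needs a positive voxel count")
  if (length(msg)) msg else TRUE
})
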