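## NIfTI volume / label-mask / cohort-table I/O.  All geometric and label
## consistency is enforced at load time, before any computation: the validity
## of every downstream quantity depends on the mask hierarchy.

## Label scheme for single-volume masks: 1 = subcutaneous fat,
## 2 = compartment-only tissue (seams etc.), 3..7 = MG, LG, SOL, TA, TP.
## The compartment is the union of labels 2..7.
LABEL_SCHEME <- c(SF = 1L, COMPARTMENT = 2L, MG = 3L, LG = 4L, SOL = 5L,
                  TA = 6L, TP = 7L)

niftiVoxelMm <- function(img) {
  pd <- RNifti::pixdim(img)
  as.numeric(pd[seq_len(3)])
}

writeVolumeNifti <- function(arr, path, voxelMm) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- voxelMm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a co-registered water/fat volume pair
#'
#' Both files must be NIfTI volumes on the same grid with the same voxel
#' size; any mismatch fails naming both files.
#'
#' @param waterPath,fatPath paths to the water and fat NIfTI files.
#' @return A [FatWaterVolume-class] with voxel size from the header.
#' @export
readFatWater <- function(waterPath, fatPath) {
  w <- RNifti::readNifti(waterPath)
  f <- RNifti::readNifti(fatPath)
  if (!identical(dim(w), dim(f)))
    stop("grid shapes differ between '", waterPath, "' (",
         paste(dim(w), collapse = "x"), ") and '", fatPath, "' (",
         paste(dim(f), collapse = "x"), ")")
  vw <- niftiVoxelMm(w); vf <- niftiVoxelMm(f)
  if (max(abs(vw - vf)) > 1e-5)
    stop("voxel sizes differ between '", waterPath, "' and '", fatPath, "'")
  fatWaterVolume(array(as.numeric(w), dim(w)), array(as.numeric(f), dim(f)),
                 voxelMm = vw)
}

#' Write a water/fat volume pair as NIfTI
#'
#' @param vol a [FatWaterVolume-class].
#' @param waterPath,fatPath output paths (.nii or .nii.gz).
#' @return Invisibly, the two paths.
#' @export
writeFatWater <- function(vol, waterPath, fatPath) {
  writeVolumeNifti(vol@water, waterPath, vol@voxelMm)
  writeVolumeNifti(vol@fat, fatPath, vol@voxelMm)
  invisible(c(waterPath, fatPath))
}

#' Validate a label mask set
#'
#' Checks the mask hierarchy — muscles pairwise disjoint, muscles inside the
#' compartment, subcutaneous fat disjoint from the compartment — and fails
#' listing every violated invariant with its voxel count.
#'
#' @param masks a [LabelMaskSet-class].
#' @return Invisibly \code{TRUE}; errors on violation.
#' @export
validateMasks <- function(masks) {
  violations <- maskViolations(masks)
  if (length(violations))
    stop("invalid label masks:\n  ", paste(violations, collapse = "\n  "))
  invisible(TRUE)
}

#' Read ROI masks from NIfTI
#'
#' Accepts either one integer-labelled volume (1 = SF, 2 = compartment-only,
#' 3--7 = MG, LG, SOL, TA, TP; the compartment is the union of labels 2--7)
#' or a named list of seven binary-mask paths (\code{sf},
#' \code{compartment}, and the five muscle names).  The resulting set is
#' validated before it is returned.
#'
#' @param paths a single path (multi-label volume) or a named list/vector of
#'   paths to binary masks.
#' @return A validated [LabelMaskSet-class].
#' @export
readMasks <- function(paths) {
  if (length(paths) == 1L && is.character(paths)) {
    lab <- RNifti::readNifti(paths)
    arr <- array(as.numeric(lab), dim(lab))
    if (max(abs(arr - round(arr))) > 0)
      stop("'", paths, "' is not integer-valued; expected a label volume")
    arr <- round(arr)
    muscles <- lapply(MUSCLE_NAMES, function(m) arr == LABEL_SCHEME[[m]])
    names(muscles) <- MUSCLE_NAMES
    masks <- labelMaskSet(sf = arr == LABEL_SCHEME[["SF"]],
                          compartment = arr >= LABEL_SCHEME[["COMPARTMENT"]] &
                                        arr <= max(LABEL_SCHEME),
                          muscles = muscles)
  } else {
    paths <- as.list(paths)
    need <- c("sf", "compartment", MUSCLE_NAMES)
    if (!all(need %in% names(paths)))
      stop("mask paths must be named: ", paste(need, collapse = ", "))
    rd <- function(p) {
      img <- RNifti::readNifti(p)
      arr <- array(as.numeric(img), dim(img))
      if (!all(arr %in% c(0, 1)))
        stop("'", p, "' is not a binary mask")
      arr > 0
    }
    muscles <- lapply(MUSCLE_NAMES, function(m) rd(paths[[m]]))
    names(muscles) <- MUSCLE_NAMES
    masks <- labelMaskSet(sf = rd(paths$sf), compartment = rd(paths$compartment),
                          muscles = muscles)
  }
  validateMasks(masks)
  masks
}

#' Write a label mask set as one multi-label NIfTI volume
#'
#' Inverse of the single-volume form of [readMasks()]: voxels carry label 1
#' for subcutaneous fat, 3--7 for the five muscles, 2 for compartment tissue
#' in no muscle, 0 elsewhere.
#'
#' @param masks a [LabelMaskSet-class].
#' @param path output path.
#' @param voxelMm voxel size to record in the header.
#' @return Invisibly, the path.
#' @export
writeMasks <- function(masks, path, voxelMm = c(2, 2, 4)) {
  arr <- array(0L, dim(masks@sf))
  arr[masks@compartment] <- LABEL_SCHEME[["COMPARTMENT"]]
  for (m in MUSCLE_NAMES) arr[masks@muscles[[m]]] <- LABEL_SCHEME[[m]]
  arr[masks@sf] <- LABEL_SCHEME[["SF"]]
  writeVolumeNifti(arr, path, voxelMm)
}

#' Read and validate a cohort table
#'
#' CSV with one row per subject and columns subject_id, group (BSCP or TD),
#' gmfcs (I/II/III, empty for TD), age, sex, mass_kg, height_m and
#' optionally bmi plus quantification columns.  Validation: groups limited
#' to BSCP/TD, GMFCS present exactly for BSCP rows, and bmi (when present
#' alongside mass and height) within 1% of mass/height^2.
#'
#' @param path CSV path.
#' @return A data.frame.
#' @export
readCohortTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "gmfcs", "age", "sex", "mass_kg", "height_m")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("cohort table '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "))
  if (!all(tab$group %in% c("BSCP", "TD")))
    stop("group must be BSCP or TD")
  tab$gmfcs[!is.na(tab$gmfcs) & tab$gmfcs == ""] <- NA_character_
  if (any(is.na(tab$gmfcs) & tab$group == "BSCP") ||
      any(!is.na(tab$gmfcs) & tab$group == "TD"))
    stop("GMFCS level must be present exactly for BSCP subjects")
  if (!all(is.na(tab$gmfcs) | tab$gmfcs %in% c("I", "II", "III")))
    stop("GMFCS level must be I, II or III")
  if ("bmi" %in% names(tab)) {
    expect <- tab$mass_kg / tab$height_m^2
    off <- abs(tab$bmi - expect) > 0.01 * expect
    if (any(off, na.rm = TRUE))
      stop("bmi inconsistent with mass/height^2 for subject(s): ",
           paste(tab$subject_id[which(off)], collapse = ", "))
  }
  tab
}

#' Write a cohort table as CSV
#'
#' @param cohort data.frame as produced by [simulateCohort()] or
#'   [quantifyCohort()].
#' @param path output CSV path.
#' @return Invisibly, the path.
#' @export
writeCohortTable <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}
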