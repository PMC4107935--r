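## Mask geometry: the edge-effect erosion applied to musculature ROIs before
## intensity ratios are formed, and voxel-count volumetry.

## Structuring-element offsets.  disk: dx^2 + dy^2 (+ dz^2) <= r^2;
## square: Chebyshev ball.  Returned as an integer matrix, one offset per row.
elementOffsets <- function(radius, shape, ndim) {
  r <- as.integer(radius)
  g <- -r:r
  offs <- as.matrix(do.call(expand.grid, rep(list(g), ndim)))
  keep <- if (shape == "disk") rowSums(offs^2) <= r^2
          else rep(TRUE, nrow(offs))
  offs[keep, , drop = FALSE]
}

## Erosion by intersection of shifted masks: a voxel survives iff every
## offset of the structuring element lands on a TRUE voxel.  Shifting the
## whole array once per offset keeps this vectorised over the volume.
shiftAndErode2D <- function(mask, offs) {
  nx <- dim(mask)[1]; ny <- dim(mask)[2]
  out <- mask
  for (k in seq_len(nrow(offs))) {
    dx <- offs[k, 1]; dy <- offs[k, 2]
    if (dx == 0 && dy == 0) next
    shifted <- array(FALSE, dim(mask))
    xs <- seq_len(nx) + dx
    ys <- seq_len(ny) + dy
    okx <- xs >= 1 & xs <= nx
    oky <- ys >= 1 & ys <= ny
    if (length(dim(mask)) == 3L)
      shifted[okx, oky, ] <- mask[xs[okx], ys[oky], , drop = FALSE]
    else
      shifted[okx, oky] <- mask[xs[okx], ys[oky], drop = FALSE]
    out <- out & shifted
  }
  out
}

shiftAndErode3D <- function(mask, offs) {
  nx <- dim(mask)[1]; ny <- dim(mask)[2]; nz <- dim(mask)[3]
  out <- mask
  for (k in seq_len(nrow(offs))) {
    d <- offs[k, ]
    if (all(d == 0)) next
    shifted <- array(FALSE, dim(mask))
    xs <- seq_len(nx) + d[1]; ys <- seq_len(ny) + d[2]; zs <- seq_len(nz) + d[3]
    okx <- xs >= 1 & xs <= nx; oky <- ys >= 1 & ys <= ny; okz <- zs >= 1 & zs <= nz
    shifted[okx, oky, okz] <- mask[xs[okx], ys[oky], zs[okz], drop = FALSE]
    out <- out & shifted
  }
  out
}

#' Erode a binary mask
#'
#' Morphological erosion with a disk- or square-shaped structuring element.
#' In the default \code{per_slice_2d} mode each axial (z) slice is eroded
#' independently, matching an in-plane "2 pixels" element on anisotropic
#' voxels; \code{full_3d} erodes with the 3-D ball instead.  Erosion is
#' anti-extensive (the result is a subset of the input) and the identity at
#' radius 0.
#'
#' A non-empty input slice whose eroded result is empty triggers a warning
#' naming the slice; a fully empty result is an error, because an intensity
#' ratio over it would be undefined.
#'
#' @param mask logical array (2-D or 3-D).
#' @param params an [ErosionParams-class]; default radius 2 disk, per slice.
#' @return Logical array of the same shape.
#' @examples
#' m <- array(TRUE, c(10, 10, 1))
#' sum(erodeMask(m, erosionParams(radiusPx = 2)))  # 36: a 6 x 6 core survives
#' @export
erodeMask <- function(mask, params = erosionParams()) {
  validObject(params)
  stopifnot(is.logical(mask))
  nd <- length(dim(mask))
  stopifnot(nd %in% c(2L, 3L))
  if (params@radiusPx == 0L || !any(mask)) return(mask)

  if (params@mode == "full_3d" && nd == 3L) {
    offs <- elementOffsets(params@radiusPx, params@elementShape, 3L)
    out <- shiftAndErode3D(mask, offs)
  } else {
    offs <- elementOffsets(params@radiusPx, params@elementShape, 2L)
    out <- shiftAndErode2D(mask, offs)
  }

  if (nd == 3L) {
    inSlice <- apply(mask, 3, any)
    outSlice <- apply(out, 3, any)
    lost <- which(inSlice & !outSlice)
    if (length(lost) && any(outSlice))
      warning("erosion emptied slice(s) ", paste(lost, collapse = ", "),
              " of a non-empty mask")
  }
  if (!any(out))
    stop("erosion with radius ", params@radiusPx,
         " emptied the mask entirely; the ROI is too thin for fat quantification")
  out
}

#' Volume of a binary mask in cm^3
#'
#' Voxel count times voxel volume, converted from mm^3.
#'
#' @param mask logical array.
#' @param voxelMm voxel edge lengths in mm (x, y, z).
#' @return Volume in cm^3.
#' @examples
#' maskVolume(array(TRUE, c(10, 10, 10)), c(2, 2, 4))  # 16 cm^3
#' @export
maskVolume <- function(mask, voxelMm = c(2, 2, 4)) {
  stopifnot(is.logical(mask), length(voxelMm) == 3L, all(voxelMm > 0))
  sum(mask) * prod(voxelMm) / 1000
}
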