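## Four-point water--fat separation from multi-echo complex signals under the
## single-peak chemical-shift model
##   S_n = (W + F e^{i phi_n}) e^{i 2 pi psi t_n},
## with W, F real and nonnegative and psi the per-voxel off-resonance (Hz).
## With psi known the fit is linear in (W, F); with psi unknown it is found
## by a bounded 1-D search per voxel, spatially median-smoothed to suppress
## isolated water--fat swaps, then refined and solved linearly.

## Real-valued stacked design for the linear (W, F) fit at echo phases phi:
## rows are the real then imaginary parts of [1, e^{i phi_n}].
dixonDesign <- function(phi) {
  rbind(cbind(1, cos(phi)), cbind(0, sin(phi)))
}

## Demodulated signal stack: for candidate field psi, b = S_n e^{-i2pi psi t},
## stacked (Re, Im) as a (2n x nvox) matrix.  sigMat is (nvox x n) complex.
demodStack <- function(sigMat, tSec, psi) {
  if (length(psi) == 1L) {
    dem <- sigMat * exp(-1i * 2 * pi * psi * matrix(tSec, nrow(sigMat),
                                                    length(tSec), byrow = TRUE))
  } else {
    dem <- sigMat * exp(-1i * 2 * pi * outer(psi, tSec))
  }
  t(cbind(Re(dem), Im(dem)))
}

medianSmooth3x3 <- function(psi) {
  d <- dim(psi)
  out <- psi
  for (z in seq_len(d[3])) {
    sl <- psi[, , z]
    sm <- sl
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      ii <- max(1, i - 1):min(d[1], i + 1)
      jj <- max(1, j - 1):min(d[2], j + 1)
      sm[i, j] <- stats::median(sl[ii, jj])
    }
    out[, , z] <- sm
  }
  out
}

#' Separate water and fat from a multi-echo series
#'
#' Per-voxel least-squares inversion of the single-peak chemical-shift
#' signal model.  With a supplied field map the model is linear in (W, F)
#' and solved in one shot for all voxels.  With \code{fieldmap =
#' "estimate"}, the off-resonance is found per voxel by a grid search over
#' \eqn{\pm 1/(2\Delta TE)} (the unaliased range), median-smoothed over 3x3
#' in-plane neighbourhoods to break ties between swap-equivalent minima
#' toward the smoother solution, refined by a bounded 1-D optimisation, and
#' the linear solve repeated.  Outputs are magnitudes |W|, |F|, mirroring
#' scanner magnitude images.
#'
#' @param echoes an [EchoSeries-class] (>= 3 echoes to estimate the field
#'   map, >= 2 when it is given).
#' @param fieldmap "estimate", a scalar, or a per-voxel array of Hz.
#' @param gridStepHz spacing of the field-map search grid (default 4 Hz).
#' @param refineHz half-width of the final per-voxel refinement bracket
#'   around the smoothed field (default 25 Hz).  Must exceed the field
#'   variation the 3x3 median can introduce at map edges while staying well
#'   below the water--fat chemical shift, so the refinement cannot jump to
#'   the swapped minimum.
#' @param voxelMm voxel size attached to the output volume (the echo series
#'   itself carries no geometry).
#' @return List with \code{volume} (a [FatWaterVolume-class]) and
#'   \code{fieldmapHz} (array).
#' @export
separateDixon <- function(echoes, fieldmap = "estimate", gridStepHz = 4,
                          refineHz = 25, voxelMm = c(2, 2, 4)) {
  validObject(echoes)
  shp <- dim(echoes@signal)[1:3]
  nEcho <- dim(echoes@signal)[4]
  tSec <- echoes@echoTimesMs / 1000
  phi <- 2 * pi * chemicalShiftHz(echoes@acq) * tSec

  A <- dixonDesign(phi)
  AtA <- crossprod(A)
  if (rcond(AtA) < 1e-10)
    stop("degenerate echo spacing: fat phases ",
         paste(round(phi %% (2 * pi), 4), collapse = ", "),
         " rad make water and fat indistinguishable")
  P <- solve(AtA, t(A))  # coef = P %*% b

  nvox <- prod(shp)
  sigMat <- matrix(echoes@signal, nvox, nEcho)

  estimate <- is.character(fieldmap) && identical(fieldmap, "estimate")
  if (estimate) {
    if (nEcho < 3L)
      stop("field-map estimation needs at least 3 echoes")
    dTe <- tSec[2] - tSec[1]
    bound <- 1 / (2 * dTe)
    cand <- seq(-bound, bound, by = gridStepHz)
    rss <- matrix(Inf, nvox, length(cand))
    for (k in seq_along(cand)) {
      B <- demodStack(sigMat, tSec, cand[k])
      R <- B - A %*% (P %*% B)
      rss[, k] <- colSums(R^2)
    }
    rssAt <- function(p, b) {
      B <- demodStack(matrix(b, 1), tSec, p)
      sum((B - A %*% (P %*% B))^2)
    }
    refine <- function(p0, b, half = gridStepHz) {
      stats::optimize(function(p) rssAt(p, b),
                      lower = max(-bound, p0 - half),
                      upper = min(bound, p0 + half), tol = 1e-8)
    }
    ## the single-peak model admits a swap-equivalent residual minimum about
    ## one chemical shift away from the true field; refine the two
    ## best-separated coarse minima per voxel and, when their fits are
    ## indistinguishable, prefer the smaller |psi| (field offsets are small
    ## relative to the chemical shift)
    psiV <- numeric(nvox)
    for (v in seq_len(nvox)) {
      b <- sigMat[v, , drop = FALSE]
      energy <- sum(Mod(b)^2)
      if (energy == 0) { psiV[v] <- 0; next }
      k1 <- which.min(rss[v, ])
      far <- abs(cand - cand[k1]) > bound / 4
      o1 <- refine(cand[k1], b)
      if (any(far)) {
        k2 <- which(far)[which.min(rss[v, far])]
        o2 <- refine(cand[k2], b)
        tol <- 1e-6 * energy
        psiV[v] <- if (abs(o1$objective - o2$objective) <= tol) {
          if (abs(o1$minimum) <= abs(o2$minimum)) o1$minimum else o2$minimum
        } else if (o1$objective <= o2$objective) o1$minimum else o2$minimum
      } else psiV[v] <- o1$minimum
    }
    psi <- medianSmooth3x3(array(psiV, shp))
    ## final per-voxel refinement around the smoothed field
    psiV <- as.numeric(psi)
    for (v in seq_len(nvox)) {
      b <- sigMat[v, , drop = FALSE]
      if (sum(Mod(b)) == 0) next
      psiV[v] <- refine(psiV[v], b, half = refineHz)$minimum
    }
    psi <- array(psiV, shp)
  } else {
    if (nEcho < 2L) stop("separation needs at least 2 echoes")
    psi <- if (length(fieldmap) == 1L) array(as.numeric(fieldmap), shp)
           else { stopifnot(identical(dim(fieldmap), shp)); fieldmap }
  }

  B <- demodStack(sigMat, tSec, as.numeric(psi))
  coef <- P %*% B
  water <- array(abs(coef[1, ]), shp)
  fat <- array(abs(coef[2, ]), shp)
  list(volume = fatWaterVolume(water, fat, voxelMm = voxelMm),
       fieldmapHz = psi)
}

#' Write a complex echo series as paired real/imaginary NIfTI volumes
#'
#' @param echoes an [EchoSeries-class].
#' @param realPath,imagPath output paths for 4-D real and imaginary parts.
#' @param voxelMm voxel size recorded in both headers.
#' @return Invisibly, the two paths.
#' @export
writeEchoes <- function(echoes, realPath, imagPath, voxelMm = c(2, 2, 4)) {
  writeVolumeNifti(Re(echoes@signal), realPath, voxelMm)
  writeVolumeNifti(Im(echoes@signal), imagPath, voxelMm)
  invisible(c(realPath, imagPath))
}

#' Read a complex echo series from paired real/imaginary NIfTI volumes
#'
#' @param realPath,imagPath paths written by [writeEchoes()].
#' @param acq the [AcquisitionSpec-class] describing the echoes.
#' @return An [EchoSeries-class].
#' @export
readEchoes <- function(realPath, imagPath, acq = acquisitionSpec()) {
  re <- RNifti::readNifti(realPath)
  im <- RNifti::readNifti(imagPath)
  if (!identical(dim(re), dim(im)))
    stop("real and imaginary grids differ between '", realPath, "' and '",
         imagPath, "'")
  sig <- array(complex(real = as.numeric(re), imaginary = as.numeric(im)),
               dim(re))
  new("EchoSeries", signal = sig, echoTimesMs = echoTimesMs(acq), acq = acq)
}
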