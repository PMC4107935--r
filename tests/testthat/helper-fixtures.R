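# Shared fixtures: small phantoms, a desk-scale cohort spec, and the
# brute-force erosion oracle used to validate the morphology code.

smallPhantomSpec <- function(muscleFF = c(MG = 0.05, LG = 0.05, SOL = 0.05,
                                          TA = 0.04, TP = 0.04),
                             seamFF = 0.8, nSlices = 4L, ...) {
  phantomSpec(gridShape = c(48L, 48L, nSlices), outerRadiusMm = 40,
              sfThicknessMm = 6, muscleFF = muscleFF, seamFF = seamFF,
              boneRadiiMm = 6, ...)
}

uniformPhantomSpec <- function(ff, ...) {
  smallPhantomSpec(muscleFF = c(MG = ff, LG = ff, SOL = ff, TA = ff, TP = ff),
                   seamFF = ff, sfFatFraction = ff, ...)
}

# Reduced-geometry cohort used for Monte-Carlo calibration runs; study
# conditions (group sizes, FF shift and SD, GMFCS mix) stay at the defaults.
deskCohortSpec <- function(...) {
  args <- list(gridShape = c(48L, 48L, 8L), outerRadiusMm = 40,
               sfThicknessMeanMm = c(TD = 6, BSCP = 9),
               sfThicknessSDMm = c(TD = 1.5, BSCP = 2.5))
  do.call(cohortSpec, utils::modifyList(args, list(...)))
}

# Brute-force min-filter erosion oracle: a pixel survives iff every offset
# of the structuring element lies inside the mask (outside the image counts
# as background).  Deliberately written as an explicit per-pixel loop,
# independent of the shift-AND implementation.
bruteErode2D <- function(mask, radius, shape = "disk") {
  r <- as.integer(radius)
  offs <- expand.grid(dx = -r:r, dy = -r:r)
  if (shape == "disk") offs <- offs[offs$dx^2 + offs$dy^2 <= r^2, ]
  nx <- nrow(mask); ny <- ncol(mask)
  out <- matrix(FALSE, nx, ny)
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    if (!mask[i, j]) next
    keep <- TRUE
    for (k in seq_len(nrow(offs))) {
      ii <- i + offs$dx[k]; jj <- j + offs$dy[k]
      if (ii < 1 || ii > nx || jj < 1 || jj > ny || !mask[ii, jj]) {
        keep <- FALSE
        break
      }
    }
    out[i, j] <- keep
  }
  out
}

expect_record <- function(rec) {
  expect_true(is.list(rec))
  expect_true(all(c("test", "p", "n") %in% names(rec)))
  if (!is.na(rec$p)) expect_true(rec$p >= 0 && rec$p <= 1)
}
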