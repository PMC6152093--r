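#' Mass-weighted optimal (Kabsch) superposition
#'
#' Finds the proper rotation and translation minimising the weighted squared
#' deviation between two conformations and reports the minimised weighted
#' RMSD. Row-vector convention: the aligned mobile is
#' `sweep(mobile, 2, xc) %*% rotation` offset by `translation + xc %*% rotation`,
#' i.e. `transformCoords()` applies the fit.
#'
#' @param mobile numeric N x 3 matrix (or [Structure-class]).
#' @param reference numeric N x 3 matrix (or [Structure-class]) with the same
#'   atom count.
#' @param weights positive per-atom weights (masses); defaults to equal
#'   weights, or to the structure masses when `mobile` is a `Structure`.
#' @return a [SuperpositionResult-class].
#' @export
#' @examples
#' x <- matrix(rnorm(12), 4, 3)
#' superpose(x, x)@rmsd  # 0
superpose <- function(mobile, reference, weights = NULL) {
  if (is(mobile, "Structure")) {
    if (is.null(weights)) weights <- masses(mobile)
    mobile <- coords(mobile)
  }
  if (is(reference, "Structure")) reference <- coords(reference)
  n <- nrow(mobile)
  if (n != nrow(reference)) stop("atom counts differ")
  if (n < 3L) stop("superposition needs at least 3 atoms")
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights <= 0)) stop("weights must be positive")
  wsum <- sum(weights)
  xc <- colSums(mobile * weights) / wsum
  yc <- colSums(reference * weights) / wsum
  Xc <- sweep(mobile, 2, xc)
  Yc <- sweep(reference, 2, yc)
  # collinearity check on both point sets
  for (M in list(Xc, Yc)) {
    s <- svd(M * sqrt(weights), nu = 0, nv = 0)$d
    if (s[2] <= 1e-10 * max(s[1], 1e-300))
      stop("ill-conditioned superposition: points are (near-)collinear")
  }
  C <- crossprod(Xc * weights, Yc)
  sv <- svd(C)
  d <- sign(det(sv$u) * det(sv$v))
  sgn <- c(1, 1, d)
  R <- sv$u %*% diag(sgn) %*% t(sv$v)
  # residual-based RMSD: the trace formula suffers catastrophic cancellation
  # when the motion is (near-)exactly rigid
  D <- Xc %*% R - Yc
  rmsd <- sqrt(sum(weights * rowSums(D^2)) / wsum)
  new("SuperpositionResult", rotation = R,
      translation = as.numeric(yc - xc %*% R), rmsd = rmsd)
}

#' Apply a superposition to coordinates
#'
#' @param x numeric N x 3 matrix.
#' @param fit a [SuperpositionResult-class] from [superpose()].
#' @return the transformed N x 3 matrix.
#' @export
transformCoords <- function(x, fit) {
  sweep(x %*% fit@rotation, 2, fit@translation, "+")
}

# Extract the cube (n_sel x 3 x F) of a selection from a trajectory.
.selCube <- function(traj, selection) {
  traj@coords[selection@indices, , , drop = FALSE]
}

# Align every slice of a cube to the time-mean structure: first align to the
# first slice, take the mean, then realign everything to that mean.
.alignToMean <- function(cube, w) {
  a1 <- alignFramesCpp(cube, cube[, , 1], w)
  m <- rowMeans(a1, dims = 2)
  a2 <- alignFramesCpp(cube, m, w)
  list(cube = a2, mean = rowMeans(a2, dims = 2))
}

#' Per-frame RMSD series against a reference structure
#'
#' For every frame, superposes the fit selection onto the reference
#' (mass-weighted Kabsch) and reports the mass-weighted RMSD over the report
#' selection, preserving frame order.
#'
#' @param traj a [Trajectory-class].
#' @param reference a [Structure-class] (or N x 3 matrix over the full
#'   topology) to compare against.
#' @param fitSelection [Selection-class] used for the superposition
#'   (default: all atoms).
#' @param reportSelection [Selection-class] the RMSD is reported over
#'   (default: the fit selection).
#' @param massWeighted logical; use atomic masses as weights (default TRUE).
#' @return an [RmsdSeries-class].
#' @export
rmsdSeries <- function(traj, reference, fitSelection = NULL,
                       reportSelection = NULL, massWeighted = TRUE) {
  top <- topology(traj)
  if (is.null(fitSelection)) fitSelection <- allAtoms(top)
  if (is.null(reportSelection)) reportSelection <- fitSelection
  refLabel <- "reference"
  if (is(reference, "Structure")) reference <- coords(reference)
  if (nrow(reference) != nAtoms(top))
    stop("reference must cover the full topology")
  w <- if (massWeighted) masses(top) else rep(1, nAtoms(top))
  vals <- rmsdSeriesCpp(traj@coords, reference,
                        fitSelection@indices, reportSelection@indices,
                        w[fitSelection@indices], w[reportSelection@indices])
  new("RmsdSeries", values = as.numeric(vals), times = traj@times,
      referenceLabel = refLabel, selectionLabel = reportSelection@label)
}

#' Per-residue RMSF profile
#'
#' Aligns all frames (mass-weighted Kabsch on the selection), computes the
#' per-atom root mean square fluctuation about the chosen reference (the
#' post-alignment time-mean structure by default, or the first frame) and
#' aggregates to residues as the mass-weighted mean of the residue's selected
#' atoms.
#'
#' @param traj a [Trajectory-class] with at least two frames.
#' @param selection a [Selection-class] (default: backbone if present,
#'   otherwise all atoms).
#' @param alignTo `"mean-structure"` (default) or `"first-frame"`.
#' @param massWeighted logical.
#' @return an [RmsfProfile-class].
#' @export
rmsfPerResidue <- function(traj, selection = NULL,
                           alignTo = c("mean-structure", "first-frame"),
                           massWeighted = TRUE) {
  alignTo <- match.arg(alignTo)
  if (nFrames(traj) < 2L)
    stop("RMSF needs at least two frames (fluctuation undefined)")
  top <- topology(traj)
  if (is.null(selection)) selection <- allAtoms(top)
  idx <- selection@indices
  w <- if (massWeighted) masses(top)[idx] else rep(1, length(idx))
  cube <- .selCube(traj, selection)
  if (alignTo == "mean-structure") {
    al <- .alignToMean(cube, w)
    ref <- al$mean; cube <- al$cube
  } else {
    ref <- cube[, , 1]
    cube <- alignFramesCpp(cube, ref, w)
  }
  dev2 <- (cube - as.vector(ref))^2
  # per-atom mean squared fluctuation: sum over xyz, mean over frames
  msf <- rowSums(rowSums(dev2, dims = 2)) / dim(cube)[3]
  rmsfAtom <- sqrt(msf)
  key <- paste(top@chainIds[idx], top@residueIds[idx])
  ord <- !duplicated(key)
  resVals <- vapply(unique(key), function(k) {
    j <- key == k
    weighted.mean(rmsfAtom[j], w[j])
  }, 0)
  new("RmsfProfile", residueIds = top@residueIds[idx][ord],
      values = as.numeric(resVals), label = selection@label)
}

#' Detect the equilibration point of an RMSD series
#'
#' Slides a window of `window` frames along the series and returns the first
#' frame (1-based) from which every window mean stays within `tolerance` of
#' the final-window mean. If only the final window itself satisfies this (the
#' series never plateaus earlier), the final window's start frame is returned
#' with a warning.
#'
#' @param series an [RmsdSeries-class] or numeric vector.
#' @param window window length in frames (default 5% of the series length,
#'   at least 2).
#' @param tolerance plateau tolerance in Angstrom (default 0.3).
#' @return integer frame index (1-based).
#' @export
detectEquilibration <- function(series, window = NULL, tolerance = 0.3) {
  vals <- if (is(series, "RmsdSeries")) series@values else as.numeric(series)
  F <- length(vals)
  if (is.null(window)) window <- max(2L, floor(0.05 * F))
  if (tolerance <= 0) stop("tolerance must be positive")
  if (window >= F) stop("window must be shorter than the series")
  cs <- cumsum(c(0, vals))
  starts <- seq_len(F - window + 1L)
  wm <- (cs[starts + window] - cs[starts]) / window
  finalMean <- wm[length(wm)]
  ok <- abs(wm - finalMean) <= tolerance
  # first start from which all later window means stay within tolerance
  lastBad <- if (any(!ok)) max(which(!ok)) else 0L
  t0 <- lastBad + 1L
  if (t0 >= length(ok))
    warning("series never plateaus before the final window; ",
            "returning its start frame")
  as.integer(min(t0, length(ok)))
}
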