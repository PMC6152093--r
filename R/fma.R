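# Flatten an n x 3 coordinate matrix to (x1, y1, z1, x2, ...).
.flatten <- function(m) as.vector(t(m))
.unflatten <- function(v) matrix(v, ncol = 3, byrow = TRUE)

# Aligned, weighted, centered frame matrix (F x 3n) for a cube and mean.
.weightedDisplacements <- function(cube, mn, w) {
  n <- dim(cube)[1]; F <- dim(cube)[3]
  flat <- t(matrix(aperm(cube, c(2, 1, 3)), 3 * n, F))
  wc <- sqrt(rep(w, each = 3))
  sweep(flat, 2, .flatten(mn)) * rep(wc, each = F)
}

#' Principal component analysis of positional fluctuations
#'
#' Aligns all frames of the selection to their time-mean structure
#' (mass-weighted Kabsch), builds mass-weight-scaled centered coordinate
#' vectors and diagonalises their covariance. Modes come out in descending
#' eigenvalue order; at most `min(3n, F - 1)` eigenvalues are non-zero.
#'
#' @param traj a [Trajectory-class] with F >= 2 frames.
#' @param selection a [Selection-class] (default: all atoms).
#' @param massWeighted logical; scale displacements by sqrt(mass)
#'   (default TRUE).
#' @return a [PCAModel-class].
#' @export
fitPCA <- function(traj, selection = NULL, massWeighted = TRUE) {
  if (nFrames(traj) < 2L) stop("PCA needs at least two frames")
  top <- topology(traj)
  if (is.null(selection)) selection <- allAtoms(top)
  w <- if (massWeighted) masses(top)[selection@indices]
       else rep(1, length(selection@indices))
  al <- .alignToMean(.selCube(traj, selection), w)
  Y <- .weightedDisplacements(al$cube, al$mean, w)
  C <- crossprod(Y) / (nrow(Y) - 1)
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  new("PCAModel", mean = al$mean, vectors = e$vectors, values = vals,
      weights = w, selection = selection, massWeighted = massWeighted)
}

#' Project trajectory frames onto PCA modes
#'
#' Each frame's selection coordinates are aligned to the model's mean
#' structure, centered, weight-scaled and projected onto the requested
#' eigenvectors.
#'
#' @param traj a [Trajectory-class] (same topology the model was fitted on).
#' @param model a [PCAModel-class].
#' @param modes integer mode indices (default: all).
#' @return numeric F x length(modes) matrix of projections.
#' @export
projectFrames <- function(traj, model, modes = NULL) {
  if (is.null(modes)) modes <- seq_along(model@values)
  if (any(modes < 1L | modes > ncol(model@vectors)))
    stop("mode index out of range")
  cube <- alignFramesCpp(.selCube(traj, model@selection), model@mean,
                         model@weights)
  Y <- .weightedDisplacements(cube, model@mean, model@weights)
  Y %*% model@vectors[, modes, drop = FALSE]
}

#' Functional quantity: RMSD of a sub-region after global superposition
#'
#' The per-frame RMSD of `subselection` measured after superposing the whole
#' `fitSelection` on the reference -- the scalar regressed in functional mode
#' analysis (e.g. the RMSD of a binding loop after a global backbone fit).
#'
#' @param traj a [Trajectory-class].
#' @param subselection a [Selection-class], the region of interest.
#' @param reference a [Structure-class] or full-topology coordinate matrix.
#' @param fitSelection selection for the global superposition (default: all
#'   atoms).
#' @param massWeighted logical.
#' @return an [RmsdSeries-class] (the functional series).
#' @export
functionalRmsd <- function(traj, subselection, reference,
                           fitSelection = NULL, massWeighted = TRUE) {
  if (is.null(fitSelection)) fitSelection <- allAtoms(topology(traj))
  rmsdSeries(traj, reference, fitSelection = fitSelection,
             reportSelection = subselection, massWeighted = massWeighted)
}

#' Functional mode analysis
#'
#' Ordinary least squares of a scalar functional quantity on the projections
#' of the leading PCA modes, fitted on a training split and validated on the
#' held-out remainder (for a linear model, maximising the Pearson correlation
#' and least squares coincide). The maximally correlated motion (MCM) is the
#' normalised coefficient-weighted mode combination `sum(beta_i e_i)`; the
#' ensemble-weighted variant (ewMCM) additionally weights by the eigenvalues,
#' `sum(beta_i lambda_i e_i)`, emphasising how the motion is realised in the
#' sampled ensemble.
#'
#' @param model a [PCAModel-class].
#' @param projections F x m projection matrix from [projectFrames()] (columns
#'   must correspond to modes 1..m of `model`).
#' @param f numeric functional series of length F (or an [RmsdSeries-class]).
#' @param nComponents retained mode count; default: the smallest count
#'   explaining 90% of the total variance.
#' @param splitFraction fraction of frames (from the start) used for
#'   training; the rest validates (default 0.5).
#' @return an [FMAResult-class].
#' @export
fitFMA <- function(model, projections, f, nComponents = NULL,
                   splitFraction = 0.5) {
  if (is(f, "RmsdSeries")) f <- f@values
  f <- as.numeric(f)
  F <- nrow(projections)
  if (length(f) != F) stop("functional series length must match frame count")
  nzero <- sum(model@values > max(model@values) * 1e-12)
  if (is.null(nComponents)) {
    frac <- cumsum(model@values) / sum(model@values)
    nComponents <- which(frac >= 0.9)[1]
  }
  if (nComponents > nzero || nComponents > ncol(projections))
    stop("nComponents exceeds the available non-zero modes")
  train <- seq_len(max(2L, floor(splitFraction * F)))
  test <- setdiff(seq_len(F), train)
  if (var(f[train]) == 0) stop("functional quantity is constant on the training split")
  X <- cbind(1, projections[, seq_len(nComponents), drop = FALSE])
  fit <- lm.fit(X[train, , drop = FALSE], f[train])
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  pred <- as.numeric(X %*% cf)
  safeCor <- function(a, b) if (sd(a) == 0 || sd(b) == 0) 0 else cor(a, b)
  betas <- cf[-1]
  V <- model@vectors[, seq_len(nComponents), drop = FALSE]
  mcm <- as.numeric(V %*% betas)
  ewmcm <- as.numeric(V %*% (betas * model@values[seq_len(nComponents)]))
  norm2 <- function(v) sqrt(sum(v^2))
  if (norm2(mcm) == 0) stop("degenerate regression: all coefficients zero")
  new("FMAResult", betas = unname(betas), intercept = unname(cf[1]),
      mcm = mcm / norm2(mcm), ewmcm = ewmcm / norm2(ewmcm),
      rTrain = safeCor(f[train], pred[train]),
      rCv = if (length(test)) safeCor(f[test], pred[test]) else NA_real_,
      nComponents = as.integer(nComponents),
      splitFraction = splitFraction)
}

#' Filter a trajectory onto a single collective mode
#'
#' Replaces each frame by the model mean plus that frame's projection onto
#' `mode`, back-transformed to coordinate space -- all variance orthogonal to
#' the mode is removed. The returned trajectory covers the model's selection
#' atoms.
#'
#' @param traj a [Trajectory-class].
#' @param model a [PCAModel-class].
#' @param mode unit 3n-vector in the model's (weighted) mode space, e.g.
#'   `fma@ewmcm`.
#' @return a [Trajectory-class] over the selection atoms.
#' @export
filterOnMode <- function(traj, model, mode) {
  mode <- as.numeric(mode)
  if (abs(sqrt(sum(mode^2)) - 1) > 1e-8) stop("mode must be a unit vector")
  cube <- alignFramesCpp(.selCube(traj, model@selection), model@mean,
                         model@weights)
  Y <- .weightedDisplacements(cube, model@mean, model@weights)
  p <- as.numeric(Y %*% mode)
  wc <- sqrt(rep(model@weights, each = 3))
  flatMean <- .flatten(model@mean)
  n <- nrow(model@mean); F <- length(p)
  out <- array(0, dim = c(n, 3, F))
  for (t in seq_len(F))
    out[, , t] <- .unflatten(flatMean + p[t] * mode / wc)
  top <- subsetStructure(topology(traj), model@selection)
  Trajectory(out, top, times = traj@times)
}

#' RMSF profile of a mode-filtered trajectory
#'
#' Convenience wrapper: per-residue RMSF of the trajectory filtered on a
#' collective mode, which localises the residues participating in that mode.
#'
#' @param filtered a [Trajectory-class] from [filterOnMode()].
#' @param selection optional [Selection-class] on the filtered topology.
#' @param massWeighted logical.
#' @return an [RmsfProfile-class].
#' @export
modeRmsf <- function(filtered, selection = NULL, massWeighted = TRUE) {
  rmsfPerResidue(filtered, selection, alignTo = "mean-structure",
                 massWeighted = massWeighted)
}
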