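# Shared fixture builders and independent oracles. The superposition oracle
# uses Horn's quaternion method -- a different algorithm from the SVD-based
# Kabsch in the package -- so the two never share a code path.

# Compact random structure: residues of `atomsPerRes` atoms placed uniformly
# in a sphere, optionally with equal masses.
blobStructure <- function(nRes = 10, atomsPerRes = 4, radius = 10,
                          seed = 1, equalMass = FALSE) {
  set.seed(seed)
  n <- nRes * atomsPerRes
  pts <- matrix(0, 0, 3)
  while (nrow(pts) < n) {
    p <- runif(3, -radius, radius)
    if (sum(p^2) <= radius^2) pts <- rbind(pts, p)
  }
  nm <- rep(c("N", "CA", "C", "O")[seq_len(min(4, atomsPerRes))],
            length.out = n)
  s <- Structure(nm, rep(seq_len(nRes), each = atomsPerRes),
                 coords = pts,
                 masses = if (equalMass) rep(12, n) else NULL)
  s
}

# Uniform-ish random proper rotation.
randomRotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rigidTransform <- function(x, R, t) sweep(x %*% R, 2, t, "+")

# Horn quaternion superposition: returns the minimised weighted RMSD of
# mobile X onto reference Y (both N x 3 row-vector matrices).
hornRmsd <- function(X, Y, w = rep(1, nrow(X))) {
  wsum <- sum(w)
  xc <- colSums(X * w) / wsum
  yc <- colSums(Y * w) / wsum
  Xc <- sweep(X, 2, xc); Yc <- sweep(Y, 2, yc)
  S <- crossprod(Xc * w, Yc)   # S[a,b] = sum w x_a y_b
  N <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2], S[3,1]-S[1,3], S[1,2]-S[2,1],
    S[2,3]-S[3,2], S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1], S[3,1]+S[1,3],
    S[3,1]-S[1,3], S[1,2]+S[2,1], -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1], S[3,1]+S[1,3], S[2,3]+S[3,2], -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  q0 <- q[1]; q1 <- q[2]; q2 <- q[3]; q3 <- q[4]
  R <- matrix(c(
    q0^2+q1^2-q2^2-q3^2, 2*(q1*q2-q0*q3), 2*(q1*q3+q0*q2),
    2*(q1*q2+q0*q3), q0^2-q1^2+q2^2-q3^2, 2*(q2*q3-q0*q1),
    2*(q1*q3-q0*q2), 2*(q2*q3+q0*q1), q0^2-q1^2-q2^2+q3^2),
    3, 3, byrow = TRUE)
  D <- Xc %*% t(R) - Yc
  sqrt(sum(w * rowSums(D^2)) / wsum)
}

# Align a trajectory cube the same way the package does (first frame, mean,
# realign) but through the Horn oracle, for metric brute-force checks.
hornAlignToMean <- function(frames, w) {
  alignAll <- function(frames, ref) {
    lapply(frames, function(X) {
      wsum <- sum(w)
      xc <- colSums(X * w) / wsum
      yc <- colSums(ref * w) / wsum
      Xc <- sweep(X, 2, xc); Yc <- sweep(ref, 2, yc)
      S <- crossprod(Xc * w, Yc)
      N <- matrix(c(
        S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2], S[3,1]-S[1,3], S[1,2]-S[2,1],
        S[2,3]-S[3,2], S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1], S[3,1]+S[1,3],
        S[3,1]-S[1,3], S[1,2]+S[2,1], -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
        S[1,2]-S[2,1], S[3,1]+S[1,3], S[2,3]+S[3,2], -S[1,1]-S[2,2]+S[3,3]),
        4, 4, byrow = TRUE)
      q <- eigen(N, symmetric = TRUE)$vectors[, 1]
      q0 <- q[1]; q1 <- q[2]; q2 <- q[3]; q3 <- q[4]
      R <- matrix(c(
        q0^2+q1^2-q2^2-q3^2, 2*(q1*q2-q0*q3), 2*(q1*q3+q0*q2),
        2*(q1*q2+q0*q3), q0^2-q1^2+q2^2-q3^2, 2*(q2*q3-q0*q1),
        2*(q1*q3-q0*q2), 2*(q2*q3+q0*q1), q0^2-q1^2-q2^2+q3^2),
        3, 3, byrow = TRUE)
      sweep(Xc %*% t(R), 2, yc, "+")
    })
  }
  f1 <- alignAll(frames, frames[[1]])
  m <- Reduce(`+`, f1) / length(f1)
  f2 <- alignAll(frames, m)
  list(frames = f2, mean = Reduce(`+`, f2) / length(f2))
}

# Trajectory of explicit rigid motions of a structure (zero true RMSD).
rigidMotionTrajectory <- function(structure, nFrames = 6, seed = 1) {
  set.seed(seed)
  x <- coords(structure)
  frames <- lapply(seq_len(nFrames), function(t)
    rigidTransform(x, randomRotation(), rnorm(3, 0, 5)))
  Trajectory(frames, structure)
}

cosineSim <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))

# Complete pipeline fixture: a multi-state complex trajectory with energy
# parameters, written to files, plus a matching flat config.
pipelineFixture <- function(dir, seed = 1, occupancies = c(0.6, 0.4)) {
  tc <- generateToyComplex("helix-pair", receptorAtoms = 3, ligandAtoms = 3,
                           separation = 5, nFrames = 2, seed = seed)
  s <- tc$structure
  ms <- generateMultistateTrajectory(s, occupancies = occupancies,
                                     withinStateSd = 0.15, nFrames = 60,
                                     seed = seed, separation = 4)
  trajFile <- file.path(dir, "traj.pdb")
  parFile <- file.path(dir, "params.csv")
  writeTrajectory(ms$trajectory, trajFile, "pdb")
  writeParameters(tc$parameters, parFile)
  list(
    trajectory = trajFile,
    parameters = parFile,
    fit_selection = "backbone",
    functional_selection = "resid 2-3",
    receptor = "chain A",
    ligand = "chain B",
    seed = seed,
    clustering = list(k_min = 2, k_max = 6, stride = 1),
    energy = list(sphere_points = 240, stride = 10, start = 1),
    output = file.path(dir, "out"))
}

# Independent brute-force cluster metrics on an explicitly aligned frame
# matrix (F' x 3n weighted coordinates), written with plain loops.
bruteMetrics <- function(Y, labels, scale) {
  ks <- sort(unique(labels))
  K <- length(ks)
  Fp <- nrow(Y)
  g <- colMeans(Y)
  sst <- 0
  for (t in seq_len(Fp)) sst <- sst + sum((Y[t, ] - g)^2)
  cm <- matrix(0, K, ncol(Y))
  S <- numeric(K)
  sse <- 0
  for (i in seq_len(K)) {
    rows <- which(labels == ks[i])
    cm[i, ] <- colMeans(Y[rows, , drop = FALSE])
    dists <- numeric(length(rows))
    for (r in seq_along(rows)) {
      dv <- Y[rows[r], ] - cm[i, ]
      sse <- sse + sum(dv^2)
      dists[r] <- sqrt(sum(dv^2)) / scale
    }
    S[i] <- mean(dists)
  }
  ssr <- sst - sse
  dbi <- 0
  for (i in seq_len(K)) {
    worst <- -Inf
    for (j in seq_len(K)) {
      if (i == j) next
      m <- sqrt(sum((cm[i, ] - cm[j, ])^2)) / scale
      worst <- max(worst, (S[i] + S[j]) / m)
    }
    dbi <- dbi + worst
  }
  list(dbi = dbi / K, psf = (ssr / (K - 1)) / (sse / (Fp - K)),
       ssr_sst = ssr / sst)
}
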