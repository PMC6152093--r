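#' Pairwise frame-to-frame RMSD matrix
#'
#' Superposition-minimised mass-weighted RMSD between every pair of strided
#' frames, stored condensed (as \code{stats::dist}). Each pair is superposed
#' independently, so the triangle inequality is not assumed downstream.
#'
#' @param traj a [Trajectory-class].
#' @param selection a [Selection-class] (default: all atoms).
#' @param stride keep every `stride`-th frame (default 1).
#' @param massWeighted logical.
#' @return a [DistanceMatrix-class].
#' @export
rmsdMatrix <- function(traj, selection = NULL, stride = 1L,
                       massWeighted = TRUE) {
  top <- topology(traj)
  if (is.null(selection)) selection <- allAtoms(top)
  stride <- as.integer(stride)
  if (stride < 1L) stop("stride must be >= 1")
  keep <- seq(1L, nFrames(traj), by = stride)
  if (length(keep) < 2L) stop("need at least two strided frames")
  w <- if (massWeighted) masses(top)[selection@indices]
       else rep(1, length(selection@indices))
  cube <- traj@coords[selection@indices, , keep, drop = FALSE]
  v <- pairwiseRmsdCpp(cube, w)
  d <- structure(as.numeric(v), Size = length(keep), Diag = FALSE,
                 Upper = FALSE, method = "rmsd", class = "dist")
  new("DistanceMatrix", values = d, frameIndices = as.integer(keep),
      stride = stride, selectionLabel = selection@label)
}

#' Agglomerative clustering of a frame RMSD matrix
#'
#' Hierarchical (bottom-up) merging under the named linkage criterion;
#' cutting the merge tree yields a deterministic frame-to-cluster map for
#' each candidate count K. Centroid linkage follows the Lance-Williams
#' update on squared dissimilarities.
#'
#' @param dmat a [DistanceMatrix-class].
#' @param linkage `"average"` (default), `"complete"` or `"centroid"`.
#' @param kRange integer candidate cluster counts (default `2:10`, capped at
#'   the frame count).
#' @return integer matrix of labels, one row per strided frame, one column
#'   per K (column names are the counts).
#' @export
hierarchicalCluster <- function(dmat, linkage = c("average", "complete",
                                                  "centroid"),
                                kRange = NULL) {
  linkage <- match.arg(linkage)
  Fp <- attr(dmat@values, "Size")
  if (is.null(kRange)) kRange <- seq(2L, min(10L, Fp))
  kRange <- as.integer(kRange)
  if (any(kRange < 1L | kRange > Fp))
    stop("kRange must lie within [1, ", Fp, "]")
  tree <- if (linkage == "centroid") hclust(dmat@values^2, method = "centroid")
          else hclust(dmat@values, method = linkage)
  labs <- vapply(kRange, function(k) cutree(tree, k = k), integer(Fp))
  labs <- matrix(labs, nrow = Fp,
                 dimnames = list(NULL, as.character(kRange)))
  labs
}

# Aligned weighted frame matrix (F' x 3n) in a single common reference frame,
# plus the RMSD-like scale (sqrt total weight): a variance decomposition
# (SSR + SSE = SST) is only exact in one fixed frame.
.clusterSpace <- function(traj, selection, frameIndices, massWeighted = TRUE) {
  top <- topology(traj)
  if (is.null(selection)) selection <- allAtoms(top)
  w <- if (massWeighted) masses(top)[selection@indices]
       else rep(1, length(selection@indices))
  cube <- traj@coords[selection@indices, , frameIndices, drop = FALSE]
  al <- .alignToMean(cube, w)
  Y <- .weightedDisplacements(al$cube, al$mean, w)
  list(Y = Y, scale = sqrt(sum(w)))
}

#' Cluster-quality metrics: DBI, pseudo-F and SSR/SST
#'
#' Frames are superposed to a single common mean structure and the
#' ANOVA-style decomposition is computed in that fixed mass-weighted
#' coordinate space: SST is the total squared deviation from the global mean,
#' SSE the within-cluster deviation from cluster means, SSR = SST - SSE.
#' pSF = (SSR/(K-1))/(SSE/(F'-K)) (reported as `Inf` when SSE = 0). The
#' Davies-Bouldin index uses the mean member distance to the cluster mean
#' (S_i) and the distance between cluster means (M_ij), distances on the
#' mass-weighted RMSD scale.
#'
#' @param traj a [Trajectory-class].
#' @param labels integer cluster labels for the strided frames.
#' @param selection a [Selection-class] (must match the one used to build the
#'   distance matrix).
#' @param frameIndices original frame indices of the strided frames (default:
#'   all frames).
#' @param massWeighted logical.
#' @return a list with `dbi`, `psf`, `ssr_sst` (and `sst`, `sse`, `ssr`).
#' @export
clusterMetrics <- function(traj, labels, selection = NULL,
                           frameIndices = NULL, massWeighted = TRUE) {
  if (is.null(frameIndices)) frameIndices <- seq_len(nFrames(traj))
  if (length(labels) != length(frameIndices))
    stop("labels must have one entry per strided frame")
  cs <- .clusterSpace(traj, selection, frameIndices, massWeighted)
  .clusterMetricsOnSpace(cs$Y, labels, cs$scale)
}

.clusterMetricsOnSpace <- function(Y, labels, scale) {
  Fp <- nrow(Y)
  ks <- sort(unique(labels))
  if (any(tabulate(factor(labels, levels = ks)) == 0L))
    stop("empty cluster")
  K <- length(ks)
  gmean <- colMeans(Y)
  sst <- sum(sweep(Y, 2, gmean)^2)
  cmeans <- t(vapply(ks, function(k)
    colMeans(Y[labels == k, , drop = FALSE]), numeric(ncol(Y))))
  sse <- 0
  S <- numeric(K)
  for (i in seq_len(K)) {
    D <- sweep(Y[labels == ks[i], , drop = FALSE], 2, cmeans[i, ])
    sse <- sse + sum(D^2)
    S[i] <- mean(sqrt(rowSums(D^2))) / scale
  }
  ssr <- sst - sse
  ssrSst <- if (sst > 0) ssr / sst else 0
  psf <- if (K < 2L) NA_real_
         else if (sse <= 0) Inf
         else (ssr / (K - 1)) / (sse / (Fp - K))
  dbi <- NA_real_
  if (K >= 2L) {
    M <- as.matrix(stats::dist(cmeans)) / scale
    ratio <- outer(S, S, "+") / M
    diag(ratio) <- -Inf
    dbi <- mean(apply(ratio, 1, max))
  }
  list(dbi = dbi, psf = psf, ssr_sst = ssrSst, sst = sst / scale^2,
       sse = sse / scale^2, ssr = ssr / scale^2)
}

#' Select the optimal cluster count
#'
#' Applies the rule: the chosen K is a local Davies-Bouldin minimum whose
#' relative SSR/SST gain to K+1 falls below `plateauTol` (the curve has
#' plateaued); among several candidates the one with the largest pseudo-F
#' wins. If no K satisfies all conditions, the global DBI argmin is returned
#' with a warning.
#'
#' @param metrics data.frame with columns `k`, `dbi`, `psf`, `ssr_sst` over a
#'   contiguous K range of at least 3 values.
#' @param plateauTol relative SSR/SST gain threshold (default 0.05).
#' @return the chosen K (integer).
#' @export
selectClusterCount <- function(metrics, plateauTol = 0.05) {
  metrics <- metrics[order(metrics$k), ]
  n <- nrow(metrics)
  if (n < 3L) stop("need metrics for at least 3 cluster counts")
  dbi <- metrics$dbi; ssr <- metrics$ssr_sst
  localMin <- vapply(seq_len(n), function(i) {
    left <- i == 1L || dbi[i] <= dbi[i - 1L]
    right <- i == n || dbi[i] <= dbi[i + 1L]
    left && right
  }, TRUE)
  gain <- c((ssr[-1] - ssr[-n]) / pmax(ssr[-n], .Machine$double.eps), NA)
  plateau <- !is.na(gain) & gain < plateauTol
  cand <- which(localMin & plateau)
  if (length(cand) == 0L) {
    warning("no K satisfies the DBI-minimum + SSR/SST-plateau rule; ",
            "returning the DBI argmin")
    return(as.integer(metrics$k[which.min(dbi)]))
  }
  as.integer(metrics$k[cand[which.max(metrics$psf[cand])]])
}

#' Medoid centroids and cluster populations
#'
#' For each cluster, the member frame minimising the summed RMSD to all other
#' members (the structure with the smallest RMSD relative to the rest of its
#' cluster); populations are member counts over the strided frame total.
#'
#' @param dmat a [DistanceMatrix-class].
#' @param labels integer cluster labels for the strided frames.
#' @return list with `centroids` (index into the strided frames, per
#'   cluster), `centroidFrames` (original frame indices) and `populations`.
#' @export
extractCentroids <- function(dmat, labels) {
  M <- as.matrix(dmat@values)
  ks <- sort(unique(labels))
  cents <- vapply(ks, function(k) {
    members <- which(labels == k)
    if (length(members) == 0L) stop("empty cluster ", k)
    if (length(members) == 1L) return(members)
    members[which.min(rowSums(M[members, members, drop = FALSE]))]
  }, 0L)
  pops <- as.numeric(table(factor(labels, levels = ks))) / length(labels)
  list(centroids = setNames(as.integer(cents), ks),
       centroidFrames = setNames(dmat@frameIndices[cents], ks),
       populations = setNames(pops, ks))
}

#' Full RMSD-based clustering of a trajectory
#'
#' Convenience driver: pairwise RMSD matrix, agglomerative clustering over a
#' K range, quality metrics per K, cluster-count selection, medoid centroids
#' and populations.
#'
#' @param traj a [Trajectory-class].
#' @param selection a [Selection-class] (default: all atoms).
#' @param linkage linkage criterion (see [hierarchicalCluster()]).
#' @param kRange candidate cluster counts (default `2:8`).
#' @param stride frame stride (default: chosen so about 1200 strided frames
#'   remain).
#' @param plateauTol SSR/SST plateau threshold (default 0.05).
#' @param massWeighted logical.
#' @return a [ClusteringResult-class].
#' @export
clusterTrajectory <- function(traj, selection = NULL, linkage = "average",
                              kRange = 2:8, stride = NULL,
                              plateauTol = 0.05, massWeighted = TRUE) {
  if (is.null(stride)) stride <- max(1L, nFrames(traj) %/% 1200L)
  dmat <- rmsdMatrix(traj, selection, stride, massWeighted)
  labs <- hierarchicalCluster(dmat, linkage, kRange)
  cs <- .clusterSpace(traj, selection, dmat@frameIndices, massWeighted)
  met <- do.call(rbind, lapply(seq_along(kRange), function(j) {
    m <- .clusterMetricsOnSpace(cs$Y, labs[, j], cs$scale)
    data.frame(k = kRange[j], dbi = m$dbi, psf = m$psf, ssr_sst = m$ssr_sst)
  }))
  chosen <- selectClusterCount(met, plateauTol)
  cl <- extractCentroids(dmat, labs[, as.character(chosen)])
  new("ClusteringResult", labelsByK = labs, kRange = as.integer(kRange),
      metrics = met, chosenK = as.integer(chosen),
      centroids = cl$centroidFrames, populations = cl$populations,
      linkage = linkage, frameIndices = dmat@frameIndices)
}
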