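test_that("RMSD matrix matches frame-pairwise superposition", {
  s <- blobStructure(5, seed = 51)
  set.seed(2)
  frames <- lapply(1:6, function(t)
    coords(s) + matrix(rnorm(nAtoms(s) * 3, 0, 0.6), nAtoms(s), 3))
  traj <- Trajectory(frames, s)
  dm <- rmsdMatrix(traj)
  M <- as.matrix(dm@values)
  expect_true(isSymmetric(M))
  expect_equal(unname(diag(M)), rep(0, 6))
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(M[i, j],
                 superpose(frames[[j]], frames[[i]], masses(s))@rmsd,
                 tolerance = 1e-10)

  # duplicate-frame trajectory: all zeros
  dup <- Trajectory(list(frames[[1]], frames[[1]], frames[[1]]), s)
  expect_lt(max(rmsdMatrix(dup)@values), 1e-9)
})

test_that("separated groups are recovered exactly by all linkages", {
  s <- blobStructure(5, seed = 52)
  shift <- matrix(0, nAtoms(s), 3); shift[, 1] <- 5
  g1 <- coords(s); g2 <- coords(s) + shift * matrix(rnorm(nAtoms(s) * 3,
                                                          1, 0.2),
                                                    nAtoms(s), 3)
  frames <- list(g1, g1, g2, g1, g2, g2)
  truth <- c(1, 1, 2, 1, 2, 2)
  traj <- Trajectory(frames, s)
  dm <- rmsdMatrix(traj)
  for (link in c("average", "complete", "centroid")) {
    labs <- hierarchicalCluster(dm, link, kRange = c(2L, 6L))
    expect_equal(length(unique(paste(labs[, "2"], truth))), 2L)
    expect_equal(sort(unique(labs[, "6"])), 1:6)  # K = F': singletons
  }
  expect_error(hierarchicalCluster(dm, "average", kRange = 7L), "within")
})

test_that("average-linkage agglomeration matches exhaustive pair search", {
  s <- blobStructure(4, seed = 53)
  set.seed(4)
  frames <- lapply(1:6, function(t)
    coords(s) + matrix(rnorm(nAtoms(s) * 3, 0, 1.2), nAtoms(s), 3))
  traj <- Trajectory(frames, s)
  dm <- rmsdMatrix(traj)
  M <- as.matrix(dm@values)

  # brute force: repeatedly merge the pair of clusters with smallest mean
  # inter-cluster frame distance
  groups <- as.list(1:6)
  partitions <- list()
  while (length(groups) > 1L) {
    best <- c(Inf, NA, NA)
    for (a in seq_along(groups)) for (b in seq_along(groups)) {
      if (a >= b) next
      d <- mean(M[groups[[a]], groups[[b]]])
      if (d < best[1]) best <- c(d, a, b)
    }
    groups[[best[2]]] <- c(groups[[best[2]]], groups[[best[3]]])
    groups[[best[3]]] <- NULL
    partitions[[length(groups)]] <- groups
  }
  labs <- hierarchicalCluster(dm, "average", kRange = 2:5)
  for (k in 2:5) {
    want <- integer(6)
    for (i in seq_along(partitions[[k]])) want[partitions[[k]][[i]]] <- i
    got <- labs[, as.character(k)]
    # same partition up to label names
    expect_equal(length(unique(paste(want, got))), k)
  }
})

test_that("cluster metrics agree with a brute-force implementation", {
  s <- blobStructure(4, seed = 54, equalMass = TRUE)
  n <- nAtoms(s)
  for (seed in 1:4) {
    set.seed(seed)
    Fp <- sample(8:12, 1)
    frames <- lapply(seq_len(Fp), function(t)
      coords(s) + matrix(rnorm(n * 3, 0, 1), n, 3))
    traj <- Trajectory(frames, s)
    dm <- rmsdMatrix(traj, massWeighted = FALSE)
    labsAll <- hierarchicalCluster(dm, "average",
                                   kRange = 2:(Fp - 1))
    # align independently via the Horn oracle, equal weights
    al <- hornAlignToMean(frames, rep(1, n))
    Y <- t(vapply(al$frames, function(f) as.vector(t(f)), numeric(3 * n)))
    Ym <- sweep(Y, 2, as.vector(t(al$mean)))
    for (k in c(2, 3, Fp - 1)) {
      labels <- labsAll[, as.character(k)]
      got <- clusterMetrics(traj, labels, massWeighted = FALSE)
      want <- bruteMetrics(Ym, labels, sqrt(n))
      expect_equal(got$dbi, want$dbi, tolerance = 1e-6)
      expect_equal(got$psf, want$psf, tolerance = 1e-6)
      expect_equal(got$ssr_sst, want$ssr_sst, tolerance = 1e-6)
    }
    # SSR/SST non-decreasing in K for nested partitions
    curve <- vapply(2:(Fp - 1), function(k)
      clusterMetrics(traj, labsAll[, as.character(k)],
                     massWeighted = FALSE)$ssr_sst, 0)
    expect_true(all(diff(curve) >= -1e-12))
  }
})

test_that("degenerate metric cases behave as defined", {
  s <- blobStructure(4, seed = 55, equalMass = TRUE)
  # second state is an internal deformation (stretch), not a rigid motion
  stretched <- coords(s); stretched[, 1] <- stretched[, 1] * 1.3
  # two zero-scatter clusters with distinct means: DBI 0, SSR/SST 1
  frames <- list(coords(s), coords(s), stretched, stretched)
  traj <- Trajectory(frames, s)
  m <- clusterMetrics(traj, c(1, 1, 2, 2), massWeighted = FALSE)
  expect_equal(m$dbi, 0, tolerance = 1e-9)
  expect_equal(m$ssr_sst, 1, tolerance = 1e-9)
  expect_equal(m$psf, Inf)
  # single cluster: no explained variance
  set.seed(3)
  frames2 <- lapply(1:5, function(t)
    coords(s) + matrix(rnorm(nAtoms(s) * 3, 0, 0.5), nAtoms(s), 3))
  m1 <- clusterMetrics(Trajectory(frames2, s), rep(1, 5),
                       massWeighted = FALSE)
  expect_equal(m1$ssr_sst, 0, tolerance = 1e-9)
  expect_error(clusterMetrics(traj, c(1, 1, 3, 3), massWeighted = FALSE),
               NA)  # labels need not be contiguous
})

test_that("cluster-count selection applies the DBI/plateau/pSF rule", {
  # hand-built metric table: K = 4 is the only local DBI minimum on a
  # plateaued SSR/SST curve
  met <- data.frame(k = 2:7,
                    dbi = c(1.2, 0.9, 0.4, 0.8, 0.7, 0.9),
                    psf = c(50, 80, 300, 250, 200, 150),
                    ssr_sst = c(0.55, 0.8, 0.95, 0.96, 0.965, 0.97))
  expect_equal(selectClusterCount(met), 4L)
  # hand evaluation: make K = 6 a second local DBI minimum on the plateau;
  # both K = 4 and K = 6 qualify and the larger pSF (K = 4) wins
  met2 <- met; met2$dbi[5] <- 0.3
  expect_equal(selectClusterCount(met2), 4L)
  # no candidate: monotone falling dbi with rising ssr
  met3 <- data.frame(k = 2:5, dbi = c(1, .8, .6, .4),
                     psf = c(10, 20, 30, 40),
                     ssr_sst = c(0.2, 0.4, 0.6, 0.8))
  expect_warning(k3 <- selectClusterCount(met3), "DBI argmin")
  expect_equal(k3, 5L)
  expect_error(selectClusterCount(met3[1:2, ]), "at least 3")
})

test_that("medoid centroids match exhaustive search and populations sum to 1", {
  # 3-member cluster with hand distances: A is the medoid
  d <- matrix(0, 3, 3)
  d[1, 2] <- d[2, 1] <- 1; d[1, 3] <- d[3, 1] <- 1; d[2, 3] <- d[3, 2] <- 2
  dm <- new("DistanceMatrix", values = as.dist(d), frameIndices = 1:3,
            stride = 1L, selectionLabel = "all")
  got <- extractCentroids(dm, c(1, 1, 1))
  expect_equal(unname(got$centroids), 1L)

  # random instance vs exhaustive medoid search; singleton cluster maps to
  # its only member
  set.seed(6)
  n <- 10
  D <- as.matrix(dist(matrix(rnorm(2 * n), n, 2)))
  labels <- c(rep(1, 5), rep(2, 4), 3)
  dm2 <- new("DistanceMatrix", values = as.dist(D), frameIndices = 1:10,
             stride = 1L, selectionLabel = "all")
  got2 <- extractCentroids(dm2, labels)
  for (k in 1:2) {
    members <- which(labels == k)
    sums <- vapply(members, function(i) sum(D[i, setdiff(members, i)]), 0)
    expect_equal(unname(got2$centroids[k]), members[which.min(sums)])
  }
  expect_equal(unname(got2$centroids[3]), 10L)
  expect_equal(sum(got2$populations), 1, tolerance = 1e-12)
})

test_that("a planted four-state ensemble yields K = 4 with matching labels", {
  ref <- blobStructure(8, seed = 56)
  ms <- generateMultistateTrajectory(ref, nFrames = 300, seed = 77)
  cl <- clusterTrajectory(ms$trajectory, kRange = 2:8, stride = 1)
  expect_equal(cl@chosenK, 4L)
  labs <- cl@labelsByK[, "4"]
  expect_equal(length(unique(paste(labs, ms$labels))), 4L)
  expect_equal(sum(cl@populations), 1, tolerance = 1e-12)
  # centroid of each cluster is one of its members
  for (k in names(cl@centroids)) {
    members <- cl@frameIndices[labs == as.integer(k)]
    expect_true(cl@centroids[[k]] %in% members)
  }
})
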