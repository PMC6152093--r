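# All generators are seed-deterministic (set.seed on entry) and emit objects
# directly consumable by the analysis modules and the file writers.

# Project the rigid-body (translation + infinitesimal rotation) components
# out of a mass-weighted 3N displacement vector at the given reference, so
# the planted motion is purely internal (superposition cannot remove any of
# it). Generators operate in the sqrt(mass) basis throughout.
.removeRigidComponents <- function(vWeighted, reference) {
  x <- coords(reference)
  m <- masses(reference)
  sw <- sqrt(m)
  com <- colSums(x * m) / sum(m)
  xc <- sweep(x, 2, com)
  gen <- matrix(0, length(vWeighted), 6)
  for (ax in 1:3) {
    tr <- matrix(0, nrow(x), 3); tr[, ax] <- sw
    gen[, ax] <- .flatten(tr)
    e <- c(0, 0, 0); e[ax] <- 1
    rot <- t(vapply(seq_len(nrow(x)), function(i)
      sw[i] * c(e[2] * xc[i, 3] - e[3] * xc[i, 2],
                e[3] * xc[i, 1] - e[1] * xc[i, 3],
                e[1] * xc[i, 2] - e[2] * xc[i, 1]), numeric(3)))
    gen[, 3 + ax] <- .flatten(rot)
  }
  Q <- qr.Q(qr(gen))
  vWeighted - Q %*% crossprod(Q, vWeighted)
}

#' Trajectory with a planted collective mode
#'
#' Frames are `reference + a_t * mode + noise` with amplitudes
#' `a_t ~ N(0, amplitudeSd^2)` and isotropic Gaussian coordinate noise, so
#' PCA/FMA have an exactly known answer. The planted mode is a unit 3N
#' Cartesian vector; `modeWeighted` gives the same direction in the
#' mass-weighted basis (what a mass-weighted PCA recovers). The true
#' amplitude series is returned for use as a functional quantity.
#'
#' @param reference a [Structure-class].
#' @param amplitudeSd SD of the planted amplitude, Angstrom (default 1).
#' @param noiseSd isotropic noise SD per coordinate, Angstrom (default 0.1).
#' @param nFrames number of frames.
#' @param seed integer seed.
#' @param mode optional unit 3N Cartesian vector; default: a random direction
#'   supported on `modeSelection`.
#' @param modeSelection optional [Selection-class] the random mode is
#'   localised on (default: all atoms).
#' @return list with `trajectory` ([Trajectory-class]), `amplitudes`
#'   (numeric, Angstrom), `mode` (Cartesian unit 3N-vector) and
#'   `modeWeighted` (unit in the sqrt(mass) basis).
#' @export
generatePlantedModeTrajectory <- function(reference, amplitudeSd = 1,
                                          noiseSd = 0.1, nFrames = 1000L,
                                          seed = 1L, mode = NULL,
                                          modeSelection = NULL) {
  stopifnot(amplitudeSd >= 0, noiseSd >= 0, nFrames >= 1)
  set.seed(seed)
  n <- nAtoms(reference)
  if (is.null(mode)) {
    g <- numeric(3 * n)
    idx <- if (is.null(modeSelection)) seq_len(n) else modeSelection@indices
    slots <- as.vector(vapply(idx, function(i) 3L * (i - 1L) + 1:3,
                              integer(3)))
    g[slots] <- rnorm(length(slots))
    # plant an internal motion: remove rigid-body components (in the
    # weighted basis) so superposition cannot absorb the planted variance
    sw <- sqrt(rep(masses(reference), each = 3))
    gw <- .removeRigidComponents(g * sw, reference)
    g <- as.numeric(gw) / sw
    mode <- g / sqrt(sum(g^2))
  }
  if (abs(sqrt(sum(mode^2)) - 1) > 1e-8) stop("mode must be a unit vector")
  a <- rnorm(nFrames, 0, amplitudeSd)
  ref <- coords(reference)
  modeM <- .unflatten(mode)
  cube <- array(0, dim = c(n, 3, nFrames))
  for (t in seq_len(nFrames))
    cube[, , t] <- ref + a[t] * modeM +
      matrix(rnorm(3 * n, 0, noiseSd), n, 3)
  wc <- sqrt(rep(masses(reference), each = 3))
  mw <- mode * wc
  list(trajectory = Trajectory(cube, reference), amplitudes = a,
       mode = mode, modeWeighted = mw / sqrt(sum(mw^2)))
}

#' Multi-state conformational ensemble with known labels
#'
#' Each frame is drawn from one of several state structures (per the stated
#' occupancies) and jittered with isotropic Gaussian noise; the true state
#' labels are returned. States are either supplied or generated from a
#' reference by displacing it along random collective directions of RMSD
#' `separation`.
#'
#' @param reference a [Structure-class] (ignored when `states` given).
#' @param occupancies state fractions, summing to 1; default
#'   `c(0.55, 0.36, 0.06, 0.03)`, a four-state ensemble dominated by two
#'   conformations as typical equilibrated MD ensembles are.
#' @param withinStateSd within-state noise SD per coordinate, Angstrom
#'   (default 0.3).
#' @param nFrames number of frames (default 1200).
#' @param seed integer seed.
#' @param states optional list of [Structure-class] state structures
#'   (must share the topology).
#' @param separation RMSD of each generated state from the reference,
#'   Angstrom (default 8, i.e. separation/sigma about 27 with the default
#'   noise).
#' @return list with `trajectory`, `labels` (integer per frame) and `states`.
#' @export
generateMultistateTrajectory <- function(reference = NULL,
                                         occupancies = c(0.55, 0.36, 0.06,
                                                         0.03),
                                         withinStateSd = 0.3,
                                         nFrames = 1200L, seed = 1L,
                                         states = NULL, separation = 8) {
  stopifnot(abs(sum(occupancies) - 1) < 1e-8, all(occupancies >= 0),
            length(occupancies) >= 2L, withinStateSd >= 0)
  set.seed(seed)
  if (is.null(states)) {
    if (is.null(reference)) stop("supply a reference or explicit states")
    n <- nAtoms(reference)
    states <- lapply(seq_along(occupancies), function(k) {
      if (k == 1L) return(reference)
      g <- matrix(rnorm(3 * n), n, 3)
      g <- g - matrix(colMeans(g), n, 3, byrow = TRUE)   # no net translation
      g <- g / sqrt(mean(rowSums(g^2)))                  # unit RMSD shape
      s <- reference
      s@coords <- coords(reference) + separation * g
      s
    })
  } else {
    n0 <- nAtoms(states[[1]])
    if (any(vapply(states, nAtoms, 0L) != n0))
      stop("state structures have mismatched topologies")
    if (length(states) != length(occupancies))
      stop("one occupancy per state required")
  }
  labels <- sample.int(length(occupancies), nFrames, replace = TRUE,
                       prob = occupancies)
  n <- nAtoms(states[[1]])
  cube <- array(0, dim = c(n, 3, nFrames))
  for (t in seq_len(nFrames))
    cube[, , t] <- coords(states[[labels[t]]]) +
      matrix(rnorm(3 * n, 0, withinStateSd), n, 3)
  list(trajectory = Trajectory(cube, states[[1]]), labels = labels,
       states = states)
}

# Element-keyed LJ/GB parameter presets (Amber-flavoured heavy-atom values).
.paramPresets <- data.frame(
  element = c("C", "N", "O", "H", "S", "P"),
  rmin_half = c(1.908, 1.824, 1.661, 0.600, 2.000, 2.100),
  epsilon = c(0.1094, 0.1700, 0.2100, 0.0157, 0.2500, 0.2000),
  gb_radius = c(1.70, 1.55, 1.50, 1.20, 1.80, 1.85),
  gb_screen = c(0.72, 0.79, 0.85, 0.85, 0.96, 0.86))

.presetParams <- function(structure, charges) {
  up <- substr(toupper(gsub("[^A-Za-z]", "", atomNames(structure))), 1, 1)
  j <- match(up, .paramPresets$element)
  j[is.na(j)] <- 1L
  new("EnergyParameters", atomNames = atomNames(structure),
      charge = charges,
      ljRminHalf = .paramPresets$rmin_half[j],
      ljEpsilon = .paramPresets$epsilon[j],
      gbRadius = .paramPresets$gb_radius[j],
      gbScreen = .paramPresets$gb_screen[j])
}

#' Toy receptor-ligand complex with closed-form-checkable energetics
#'
#' Desk-scale complexes with named chains (receptor chain A, ligand chain B),
#' physically reasonable radii and charges, and a short jittered trajectory:
#'
#' * `"two-ion"`: one +1 ion and one -1 ion at `separation` Angstrom -- every
#'   energy term can be assembled by hand.
#' * `"helix-pair"`: two short backbone chains side by side with alternating
#'   partial charges (each chain net-neutral) -- exercises multi-residue
#'   decomposition and clean long-range separability.
#' * `"random-packed"`: atoms placed randomly with a minimum-distance
#'   constraint, random neutralised charges.
#'
#' @param geometry `"two-ion"`, `"helix-pair"` or `"random-packed"`.
#' @param receptorAtoms,ligandAtoms atom counts (residue counts for
#'   `"helix-pair"`, where each residue has 4 backbone atoms).
#' @param separation receptor-ligand distance, Angstrom.
#' @param nFrames frames in the jittered trajectory (default 5).
#' @param jitterSd per-coordinate jitter SD, Angstrom (default 0.05).
#' @param seed integer seed.
#' @return list with `structure` ([Structure-class]), `parameters`
#'   ([EnergyParameters-class]), `trajectory` ([Trajectory-class]),
#'   `receptor` and `ligand` ([Selection-class]).
#' @export
generateToyComplex <- function(geometry = c("two-ion", "helix-pair",
                                            "random-packed"),
                               receptorAtoms = 8L, ligandAtoms = 8L,
                               separation = 4, nFrames = 5L,
                               jitterSd = 0.05, seed = 1L) {
  geometry <- match.arg(geometry)
  set.seed(seed)
  if (geometry == "two-ion") {
    s <- Structure(c("C1", "C2"), c(1L, 2L), c("CAT", "ANI"), c("A", "B"),
                   rbind(c(0, 0, 0), c(separation, 0, 0)))
    params <- new("EnergyParameters", atomNames = atomNames(s),
                  charge = c(1, -1), ljRminHalf = c(1.7, 1.7),
                  ljEpsilon = c(0.1, 0.1), gbRadius = c(1.5, 1.5),
                  gbScreen = c(0.8, 0.8))
  } else if (geometry == "helix-pair") {
    a <- buildChain(max(2L, receptorAtoms), chainId = "A", startResid = 1L)
    b <- buildChain(max(2L, ligandAtoms), chainId = "B",
                    startResid = 100L, origin = c(0, separation + 2, 1))
    s <- combineStructures(a, b)
    q <- rep_len(c(0.3, -0.3), nAtoms(s))
    params <- .presetParams(s, q)
  } else {
    nR <- max(1L, receptorAtoms); nL <- max(1L, ligandAtoms)
    place <- function(n, center) {
      pts <- matrix(0, 0, 3)
      while (nrow(pts) < n) {
        p <- center + stats::runif(3, -3, 3)
        if (nrow(pts) == 0 ||
            min(sqrt(rowSums(sweep(pts, 2, p)^2))) > 2.2)
          pts <- rbind(pts, p)
      }
      pts
    }
    xyz <- rbind(place(nR, c(0, 0, 0)), place(nL, c(separation + 4, 0, 0)))
    s <- Structure(rep("C", nR + nL), seq_len(nR + nL),
                   chainIds = rep(c("A", "B"), c(nR, nL)), coords = xyz)
    q <- stats::runif(nR + nL, -0.5, 0.5)
    q[seq_len(nR)] <- q[seq_len(nR)] - mean(q[seq_len(nR)])
    q[-seq_len(nR)] <- q[-seq_len(nR)] - mean(q[-seq_len(nR)])
    params <- .presetParams(s, q)
  }
  n <- nAtoms(s)
  cube <- array(0, dim = c(n, 3, nFrames))
  for (t in seq_len(nFrames))
    cube[, , t] <- coords(s) + matrix(rnorm(3 * n, 0, jitterSd), n, 3)
  list(structure = s, parameters = params,
       trajectory = Trajectory(cube, s),
       receptor = makeSelection(s, "chain A"),
       ligand = makeSelection(s, "chain B"))
}
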