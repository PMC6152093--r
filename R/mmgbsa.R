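.allPairs <- function(n) {
  if (n < 2L) return(matrix(integer(0), 0, 2))
  cbind(rep(seq_len(n - 1L), times = (n - 1L):1L),
        unlist(lapply(2:n, function(j) seq(j, n))))
}

.pairDist <- function(coords, pairs) {
  d <- coords[pairs[, 1], , drop = FALSE] - coords[pairs[, 2], , drop = FALSE]
  sqrt(rowSums(d^2))
}

#' Coulomb energy over a pair set
#'
#' `sum(k * qi * qj / (eps_in * rij))` with `k = 332.0636` kcal*A/(mol*e^2).
#'
#' @param coords numeric N x 3 matrix, Angstrom.
#' @param charges numeric charges, e.
#' @param dielectricIn interior dielectric constant (default 1).
#' @param pairs 2-column integer matrix of atom index pairs (default: all
#'   unique pairs).
#' @return energy in kcal/mol.
#' @export
coulombEnergy <- function(coords, charges, dielectricIn = 1, pairs = NULL) {
  if (is.null(pairs)) pairs <- .allPairs(nrow(coords))
  if (nrow(pairs) == 0L) return(0)
  r <- .pairDist(coords, pairs)
  zero <- which(r == 0)
  if (length(zero))
    stop("coincident atoms in pair (", pairs[zero[1], 1], ", ",
         pairs[zero[1], 2], ")")
  sum(.kCoulomb * charges[pairs[, 1]] * charges[pairs[, 2]] /
        (dielectricIn * r))
}

#' Lennard-Jones 12-6 energy over a pair set
#'
#' `sum(eps_ij * ((rmin_ij/r)^12 - 2 (rmin_ij/r)^6))` with Lorentz-Berthelot
#' combination: `rmin_ij = rmin_i/2 + rmin_j/2`, `eps_ij = sqrt(eps_i eps_j)`.
#'
#' @param coords numeric N x 3 matrix, Angstrom.
#' @param rminHalf per-atom rmin/2, Angstrom.
#' @param epsilon per-atom well depth, kcal/mol.
#' @param pairs 2-column integer matrix (default: all unique pairs).
#' @return energy in kcal/mol.
#' @export
ljEnergy <- function(coords, rminHalf, epsilon, pairs = NULL) {
  if (is.null(pairs)) pairs <- .allPairs(nrow(coords))
  if (nrow(pairs) == 0L) return(0)
  r <- .pairDist(coords, pairs)
  zero <- which(r == 0)
  if (length(zero))
    stop("coincident atoms in pair (", pairs[zero[1], 1], ", ",
         pairs[zero[1], 2], ")")
  rmin <- rminHalf[pairs[, 1]] + rminHalf[pairs[, 2]]
  eps <- sqrt(epsilon[pairs[, 1]] * epsilon[pairs[, 2]])
  s6 <- (rmin / r)^6
  sum(eps * (s6^2 - 2 * s6))
}

#' Effective Born radii by HCT pairwise descreening
#'
#' Hawkins-Cramer-Truhlar effective radii under the Coulomb-field
#' approximation: `1/alpha_i = 1/rho_i - sum_j H(r_ij, rho_i, s_j rho_j)`
#' where H is the analytic descreening integral of a neighbour sphere of
#' scaled radius `s_j rho_j` (zero when the neighbour lies entirely inside
#' `rho_i`). An isolated atom's effective radius equals its intrinsic radius
#' exactly; the inverse radius is guarded against going non-positive for
#' deeply buried atoms.
#'
#' @param coords numeric N x 3 matrix, Angstrom.
#' @param gbRadius intrinsic radii `rho`, Angstrom, positive.
#' @param gbScreen dimensionless screening factors `s` in (0, 2].
#' @return numeric effective radii, Angstrom.
#' @export
bornRadii <- function(coords, gbRadius, gbScreen) {
  n <- nrow(coords)
  if (any(gbRadius <= 0)) stop("gbRadius must be > 0")
  if (n == 1L) return(gbRadius)
  invAlpha <- 1 / gbRadius
  for (i in seq_len(n)) {
    d <- sweep(coords[-i, , drop = FALSE], 2, coords[i, ])
    r <- sqrt(rowSums(d^2))
    sr <- gbScreen[-i] * gbRadius[-i]
    rho <- gbRadius[i]
    act <- which(r + sr > rho)
    if (length(act) == 0L) next
    r <- r[act]; sr <- sr[act]
    U <- r + sr
    L <- ifelse(r - sr <= rho, rho, r - sr)
    term <- (1 / L - 1 / U) + (r / 4) * (1 / U^2 - 1 / L^2) +
      (1 / (2 * r)) * log(L / U) + (sr^2 / (4 * r)) * (1 / L^2 - 1 / U^2)
    buried <- rho < sr - r
    term[buried] <- term[buried] + 2 * (1 / rho - 1 / L[buried])
    if (any(!is.finite(term))) stop("non-finite descreening term")
    invAlpha[i] <- invAlpha[i] - 0.5 * sum(term)
  }
  1 / pmax(invAlpha, 1e-3 / max(gbRadius))
}

# Full GB pair-energy matrix: entry (i,j) holds half the (i,j)+(j,i)
# double-sum contribution, so rowSums() gives per-atom energies and sum()
# the total. Diagonal entries are the Born self terms.
.gbPairMatrix <- function(coords, charges, radii, dielectricIn,
                          dielectricSolvent) {
  d2 <- as.matrix(stats::dist(coords))^2
  aa <- outer(radii, radii)
  fgb <- sqrt(d2 + aa * exp(-d2 / (4 * aa)))
  pref <- -(.kCoulomb / 2) * (1 / dielectricIn - 1 / dielectricSolvent)
  pref * outer(charges, charges) / fgb
}

#' Generalized Born polar solvation energy
#'
#' Still's pairwise form with self terms included:
#' `-(k/2) (1/eps_in - 1/eps_solv) sum_i sum_j qi qj / f_GB(r, ai, aj)` with
#' `f_GB = sqrt(r^2 + ai aj exp(-r^2 / (4 ai aj)))` (so `f_GB = alpha_i` for
#' i = j). A single ion reduces to the Born formula exactly.
#'
#' @param coords numeric N x 3 matrix, Angstrom.
#' @param charges numeric, e.
#' @param radii effective Born radii from [bornRadii()], Angstrom.
#' @param dielectricIn interior dielectric (default 1).
#' @param dielectricSolvent solvent dielectric (default 78.5).
#' @return energy in kcal/mol.
#' @export
gbEnergy <- function(coords, charges, radii, dielectricIn = 1,
                     dielectricSolvent = 78.5) {
  if (dielectricIn <= 0 || dielectricSolvent <= 0)
    stop("dielectric constants must be positive")
  sum(.gbPairMatrix(coords, charges, radii, dielectricIn, dielectricSolvent))
}

# Canonical molecule-fixed frame: centroid at the origin, first axis towards
# the atom farthest from the centroid, second axis towards the atom farthest
# from that line. Landmark-based (not principal axes) so it stays exactly
# rotation-equivariant even for molecules with a degenerate inertia tensor;
# it makes the numerical SASA invariant under global rigid motions.
.canonicalFrame <- function(coords) {
  xc <- sweep(coords, 2, colMeans(coords))
  if (nrow(xc) < 2L) return(xc)
  d <- sqrt(rowSums(xc^2))
  i1 <- which.max(d)
  if (d[i1] < 1e-12) return(xc)
  e1 <- xc[i1, ] / d[i1]
  perp <- xc - outer(as.numeric(xc %*% e1), e1)
  dp <- sqrt(rowSums(perp^2))
  i2 <- which.max(dp)
  if (dp[i2] < 1e-9) {
    # collinear molecule: any completion gives identical atom coordinates
    e2 <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e2 <- e2 - sum(e2 * e1) * e1
    e2 <- e2 / sqrt(sum(e2^2))
  } else e2 <- perp[i2, ] / dp[i2]
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  xc %*% cbind(e1, e2, e3)
}

# Deterministic near-uniform unit sphere points (golden-section spiral).
.spherePoints <- function(n) {
  i <- seq_len(n)
  z <- 1 - (2 * i - 1) / n
  phi <- i * pi * (3 - sqrt(5))
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Numerical SASA on probe-inflated spheres: each atom's sphere of radius
#' `radius + probe` is sampled with a deterministic spiral point set and the
#' accessible fraction (points outside every other inflated sphere) scales
#' its full area. The computation runs in a canonical molecule-fixed frame
#' (principal axes of the atom centres, deterministic signs), so the result
#' is invariant under global rotation and translation of the input.
#'
#' @param coords numeric N x 3 matrix, Angstrom.
#' @param radii per-atom radii, Angstrom, positive.
#' @param probe solvent probe radius, Angstrom (default 1.4).
#' @param nSpherePoints sample points per atom (default 960, minimum 100).
#' @param canonicalize canonicalize the frame first (default TRUE); set to
#'   FALSE when the caller already placed several species in one shared
#'   frame and their per-atom areas must be directly comparable.
#' @return numeric per-atom accessible areas, Angstrom^2 (sum for the total).
#' @export
sasa <- function(coords, radii, probe = 1.4, nSpherePoints = 960L,
                 canonicalize = TRUE) {
  if (any(radii <= 0)) stop("radii must be positive")
  if (nSpherePoints < 100L) stop("use at least 100 sphere points")
  if (canonicalize) coords <- .canonicalFrame(coords)
  n <- nrow(coords)
  R <- radii + probe
  pts <- .spherePoints(nSpherePoints)
  out <- numeric(n)
  d2all <- as.matrix(stats::dist(coords))^2
  for (i in seq_len(n)) {
    nb <- which(d2all[i, ] < (R[i] + R)^2 & seq_len(n) != i)
    if (length(nb) == 0L) { out[i] <- 4 * pi * R[i]^2; next }
    p <- sweep(pts * R[i], 2, coords[i, ], "+")
    acc <- rep(TRUE, nSpherePoints)
    for (j in nb) {
      d <- sweep(p, 2, coords[j, ])
      acc <- acc & rowSums(d^2) >= R[j]^2
      if (!any(acc)) break
    }
    out[i] <- 4 * pi * R[i]^2 * sum(acc) / nSpherePoints
  }
  out
}

#' Nonpolar solvation energy from total SASA
#'
#' `gamma * SASA + beta`.
#'
#' @param totalSasa total solvent-accessible area, Angstrom^2.
#' @param gamma surface tension coefficient, kcal/mol/Angstrom^2
#'   (default 0.005).
#' @param beta offset, kcal/mol (default 0).
#' @return energy in kcal/mol.
#' @export
nonpolarEnergy <- function(totalSasa, gamma = 0.005, beta = 0) {
  gamma * totalSasa + beta
}

# Shared single-frame engine. Returns the breakdown plus per-atom
# interaction terms over the scored (receptor + ligand) atoms.
.frameBE <- function(coords, idxR, idxL, params, opts) {
  if (length(intersect(idxR, idxL)))
    stop("receptor and ligand selections overlap")
  idxC <- sort(c(idxR, idxL))
  q <- params@charge; rh <- params@ljRminHalf; ep <- params@ljEpsilon
  rho <- params@gbRadius; scr <- params@gbScreen
  if (length(q) < max(idxC)) stop("missing parameters for selected atoms")
  # receptor-ligand cross terms (intramolecular MM terms cancel identically
  # in the single-trajectory approach)
  cross <- cbind(rep(idxR, times = length(idxL)),
                 rep(idxL, each = length(idxR)))
  r <- .pairDist(coords, cross)
  if (any(r == 0)) stop("coincident receptor/ligand atoms")
  ePair <- .kCoulomb * q[cross[, 1]] * q[cross[, 2]] / (opts$dielectricIn * r)
  rmin <- rh[cross[, 1]] + rh[cross[, 2]]
  s6 <- (rmin / r)^6
  vPair <- sqrt(ep[cross[, 1]] * ep[cross[, 2]]) * (s6^2 - 2 * s6)
  # GB: effective radii and pair matrix per species
  atomGb <- function(idx) {
    a <- bornRadii(coords[idx, , drop = FALSE], rho[idx], scr[idx])
    P <- .gbPairMatrix(coords[idx, , drop = FALSE], q[idx], a,
                       opts$dielectricIn, opts$dielectricSolvent)
    rowSums(P)
  }
  gbC <- atomGb(idxC); gbR <- atomGb(idxR); gbL <- atomGb(idxL)
  gbSpecies <- numeric(length(idxC))
  gbSpecies[match(idxR, idxC)] <- gbR
  gbSpecies[match(idxL, idxC)] <- gbL
  gbAtom <- gbC - gbSpecies
  # SASA per species, all in the complex's canonical frame so the species
  # areas are point-for-point comparable with the complex areas
  canon <- .canonicalFrame(coords[idxC, , drop = FALSE])
  canonOf <- function(idx) canon[match(idx, idxC), , drop = FALSE]
  saFor <- function(idx) sasa(canonOf(idx), rho[idx], opts$probe,
                              opts$nSpherePoints, canonicalize = FALSE)
  saC <- saFor(idxC)
  saSpecies <- numeric(length(idxC))
  saSpecies[match(idxR, idxC)] <- saFor(idxR)
  saSpecies[match(idxL, idxC)] <- saFor(idxL)
  saAtom <- opts$gamma * (saC - saSpecies)
  # per-atom ledger over idxC: half of each cross pair to each partner
  elecAtom <- vdwAtom <- numeric(length(idxC))
  pos1 <- match(cross[, 1], idxC); pos2 <- match(cross[, 2], idxC)
  add <- function(v, pos, x) { for (k in seq_along(x)) v[pos[k]] <- v[pos[k]] + x[k]; v }
  elecAtom <- add(add(elecAtom, pos1, ePair / 2), pos2, ePair / 2)
  vdwAtom <- add(add(vdwAtom, pos1, vPair / 2), pos2, vPair / 2)
  breakdown <- data.frame(
    e_elec = sum(ePair), e_vdw = sum(vPair), g_gb = sum(gbAtom),
    g_sa = sum(saAtom) - opts$beta, e_internal = 0)
  breakdown$total <- breakdown$e_elec + breakdown$e_vdw + breakdown$g_gb +
    breakdown$g_sa + breakdown$e_internal
  list(breakdown = breakdown,
       atoms = data.frame(index = idxC, elec = elecAtom, vdw = vdwAtom,
                          gb = gbAtom, sa = saAtom))
}

.beOpts <- function(dielectricIn = 1, dielectricSolvent = 78.5,
                    gamma = 0.005, beta = 0, probe = 1.4,
                    nSpherePoints = 960L) {
  list(dielectricIn = dielectricIn, dielectricSolvent = dielectricSolvent,
       gamma = gamma, beta = beta, probe = probe,
       nSpherePoints = as.integer(nSpherePoints))
}

#' Single-frame MM/GBSA binding energy
#'
#' Single-trajectory thermodynamic cycle: receptor and ligand coordinates
#' are extracted from the same complex frame, so internal (bond, angle,
#' dihedral) terms cancel identically and are reported as exactly zero; the
#' electrostatic and van der Waals interaction terms reduce to the
#' receptor-ligand cross interaction, while the GB and SASA terms capture
#' desolvation (effective radii and areas recomputed for complex, receptor
#' and ligand separately). The entropy term is treated as constant and never
#' reported.
#'
#' @param coords the complex frame: numeric N x 3 matrix (or a
#'   [Structure-class]).
#' @param receptor,ligand disjoint [Selection-class] objects partitioning
#'   the scored atoms.
#' @param params an [EnergyParameters-class] over the full topology.
#' @param dielectricIn,dielectricSolvent interior/solvent dielectrics
#'   (defaults 1 and 78.5).
#' @param gamma,beta SASA coefficients, kcal/mol/A^2 and kcal/mol
#'   (defaults 0.005 and 0).
#' @param probe probe radius, Angstrom (default 1.4).
#' @param nSpherePoints SASA sample points (default 960).
#' @return one-row data.frame: `e_elec`, `e_vdw`, `g_gb`, `g_sa`,
#'   `e_internal`, `total` (all Delta-Delta terms, kcal/mol).
#' @export
frameBindingEnergy <- function(coords, receptor, ligand, params,
                               dielectricIn = 1, dielectricSolvent = 78.5,
                               gamma = 0.005, beta = 0, probe = 1.4,
                               nSpherePoints = 960L) {
  if (is(coords, "Structure")) coords <- coords(coords)
  opts <- .beOpts(dielectricIn, dielectricSolvent, gamma, beta, probe,
                  nSpherePoints)
  .frameBE(coords, receptor@indices, ligand@indices, params, opts)$breakdown
}

#' Trajectory MM/GBSA binding energy
#'
#' Per-frame [frameBindingEnergy()] over an equilibrated, strided frame
#' window, with the mean and the population standard deviation of the
#' per-frame totals.
#'
#' @param traj a [Trajectory-class] of the complex.
#' @param receptor,ligand disjoint [Selection-class] objects.
#' @param params an [EnergyParameters-class].
#' @param startFrame first scored frame, e.g. from [detectEquilibration()]
#'   (default 1).
#' @param stride frame stride (default 1).
#' @param ... energy settings passed on to [frameBindingEnergy()].
#' @return a [BindingEnergyResult-class].
#' @export
trajectoryBindingEnergy <- function(traj, receptor, ligand, params,
                                    startFrame = 1L, stride = 1L, ...) {
  if (startFrame > nFrames(traj)) stop("empty frame window")
  frames <- seq(startFrame, nFrames(traj), by = stride)
  opts <- .beOpts(...)
  rows <- lapply(frames, function(t)
    .frameBE(frameCoords(traj, t), receptor@indices, ligand@indices,
             params, opts)$breakdown)
  perFrame <- cbind(frame = frames, do.call(rbind, rows))
  tot <- perFrame$total
  new("BindingEnergyResult", perFrame = perFrame, mean = mean(tot),
      sd = sqrt(mean((tot - mean(tot))^2)),
      receptorLabel = receptor@label, ligandLabel = ligand@label)
}

#' Per-residue MM/GBSA decomposition
#'
#' Splits every receptor-ligand pairwise interaction term half to each
#' partner atom's residue and attributes GB self/cross and SASA differences
#' to the owning atom's residue, so the per-residue contributions sum to the
#' total binding energy exactly (within numerical precision) in every frame.
#' Means and population SDs are taken over the scored frames.
#'
#' @inheritParams trajectoryBindingEnergy
#' @param threshold reporting threshold in kcal/mol for [residueTable()]
#'   (default 1).
#' @return a [ResidueDecomposition-class].
#' @export
perResidueDecomposition <- function(traj, receptor, ligand, params,
                                    startFrame = 1L, stride = 1L,
                                    threshold = 1, ...) {
  if (startFrame > nFrames(traj)) stop("empty frame window")
  frames <- seq(startFrame, nFrames(traj), by = stride)
  opts <- .beOpts(...)
  top <- topology(traj)
  idxC <- sort(c(receptor@indices, ligand@indices))
  key <- paste(top@chainIds[idxC], top@residueIds[idxC])
  ukey <- unique(key)
  grp <- match(key, ukey)
  acc <- matrix(0, length(ukey), 4,
                dimnames = list(ukey, c("elec", "vdw", "gb", "sa")))
  totsum <- totsq <- numeric(length(ukey))
  for (t in frames) {
    at <- .frameBE(frameCoords(traj, t), receptor@indices, ligand@indices,
                   params, opts)$atoms
    m <- vapply(c("elec", "vdw", "gb", "sa"), function(cn)
      as.numeric(rowsum(at[[cn]], grp, reorder = TRUE)), numeric(length(ukey)))
    acc <- acc + m
    rt <- rowSums(m)
    totsum <- totsum + rt
    totsq <- totsq + rt^2
  }
  nF <- length(frames)
  acc <- acc / nF
  mu <- totsum / nF
  sdres <- sqrt(pmax(0, totsq / nF - mu^2))
  first <- idxC[!duplicated(key)]
  tab <- data.frame(chain = top@chainIds[first],
                    residue_id = top@residueIds[first],
                    residue_name = top@residueNames[first],
                    elec = acc[, "elec"], vdw = acc[, "vdw"],
                    gb = acc[, "gb"], sa = acc[, "sa"],
                    total = mu, sd = sdres, row.names = NULL)
  new("ResidueDecomposition", table = tab, threshold = threshold,
      receptorLabel = receptor@label, ligandLabel = ligand@label)
}

#' Residue decomposition table
#'
#' @param x a [ResidueDecomposition-class].
#' @param all return every residue (default: only residues with
#'   `|total| > threshold`, mirroring the usual reporting filter).
#' @return a data.frame.
#' @export
residueTable <- function(x, all = FALSE) {
  if (all) x@table else x@table[abs(x@table$total) > x@threshold, ]
}
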