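kC <- 332.0636

test_that("Coulomb energy evaluates the screened point-charge formula", {
  x <- rbind(c(0, 0, 0), c(3.320636, 0, 0))
  expect_equal(coulombEnergy(x, c(1, -1)), -100, tolerance = 1e-10)
  # zero-charge partner contributes nothing
  expect_equal(coulombEnergy(x, c(1, 0)), 0)
  # 1/r scaling and interior dielectric
  x2 <- rbind(c(0, 0, 0), c(2 * 3.320636, 0, 0))
  expect_equal(coulombEnergy(x2, c(1, -1)), -50, tolerance = 1e-10)
  expect_equal(coulombEnergy(x, c(1, -1), dielectricIn = 4), -25,
               tolerance = 1e-10)
  expect_error(coulombEnergy(rbind(0, 0) %x% t(rep(0, 3)), c(1, 1)),
               "coincident")
})

test_that("Lennard-Jones energy has its minimum at rmin and decays to zero", {
  rh <- c(1.7, 1.9); ep <- c(0.12, 0.2)
  rmin <- sum(rh); eps <- sqrt(prod(ep))
  at <- function(r) ljEnergy(rbind(c(0, 0, 0), c(r, 0, 0)), rh, ep)
  expect_equal(at(rmin), -eps, tolerance = 1e-12)
  expect_lt(at(50), 0)
  expect_gt(at(50), -1e-6)
  # three-atom sum equals independent term-by-term evaluation
  x <- rbind(c(0, 0, 0), c(3.1, 0.4, 0), c(-1, 2.8, 1.2))
  rh3 <- c(1.7, 1.8, 1.6); ep3 <- c(0.1, 0.15, 0.2)
  pairTerm <- function(i, j) {
    r <- sqrt(sum((x[i, ] - x[j, ])^2))
    rm <- rh3[i] + rh3[j]; e <- sqrt(ep3[i] * ep3[j])
    e * ((rm / r)^12 - 2 * (rm / r)^6)
  }
  expect_equal(ljEnergy(x, rh3, ep3),
               pairTerm(1, 2) + pairTerm(1, 3) + pairTerm(2, 3),
               tolerance = 1e-12)
})

test_that("HCT Born radii match limits and the descreening quadrature", {
  # isolated atom: effective radius equals the intrinsic radius exactly
  expect_identical(bornRadii(matrix(0, 1, 3), 1.7, 0.8), 1.7)
  # distant neighbour: descreening vanishes
  far <- rbind(c(0, 0, 0), c(1e5, 0, 0))
  expect_equal(bornRadii(far, c(1.5, 1.5), c(0.8, 0.8)),
               c(1.5, 1.5), tolerance = 1e-9)

  # two atoms at 4 A: pairwise term equals the Coulomb-field descreening
  # integral over the scaled neighbour sphere, by 1D quadrature
  d <- 4; rho <- 1.5; sfac <- 0.8
  a <- sfac * rho
  integrand <- function(r) (1 / r^2) * (1 - (r^2 + d^2 - a^2) / (2 * r * d))
  I <- 0.5 * integrate(integrand, lower = max(rho, d - a), upper = d + a,
                       rel.tol = 1e-12)$value
  alpha <- bornRadii(rbind(c(0, 0, 0), c(d, 0, 0)), c(rho, rho),
                     c(sfac, sfac))
  expect_equal(1 / alpha[1], 1 / rho - I, tolerance = 1e-6)
  # overlapping-sphere branch (r - s*rho < rho): same quadrature, lower
  # limit clipped at rho
  d2 <- 1.8
  integrand2 <- function(r) (1 / r^2) * (1 - (r^2 + d2^2 - a^2) / (2 * r * d2))
  I2 <- 0.5 * integrate(integrand2, lower = rho, upper = d2 + a,
                        rel.tol = 1e-12)$value
  alpha2 <- bornRadii(rbind(c(0, 0, 0), c(d2, 0, 0)), c(rho, rho),
                      c(sfac, sfac))
  expect_equal(1 / alpha2[1], 1 / rho - I2, tolerance = 1e-6)
})

test_that("GB energy reproduces Born's formula and the pairwise sum", {
  # single ion: exact Born expression
  q <- 2; aR <- 1.8
  born <- -(kC / 2) * (1 - 1 / 78.5) * q^2 / aR
  got <- gbEnergy(matrix(0, 1, 3), q, aR)
  expect_equal(got, born, tolerance = 1e-10 * abs(born))
  # all charges zero
  expect_equal(gbEnergy(rbind(c(0, 0, 0), c(3, 0, 0)), c(0, 0), c(1.5, 1.5)),
               0)
  # two-ion system: term-by-term spreadsheet evaluation of the Still sum
  x <- rbind(c(0, 0, 0), c(4, 0, 0))
  qs <- c(1, -1); al <- c(1.62, 1.54)
  r2 <- 16
  f12 <- sqrt(r2 + al[1] * al[2] * exp(-r2 / (4 * al[1] * al[2])))
  pref <- -(kC / 2) * (1 - 1 / 78.5)
  want <- pref * (qs[1]^2 / al[1] + qs[2]^2 / al[2] +
                    2 * qs[1] * qs[2] / f12)
  expect_equal(gbEnergy(x, qs, al), want, tolerance = 1e-10)
  expect_error(gbEnergy(x, qs, al, dielectricIn = 0), "positive")
})

test_that("SASA matches sphere closed forms", {
  w <- 1.4
  # isolated sphere: 4 pi (r + w)^2 within 1% at 960 points
  r <- 1.9
  got <- sasa(matrix(0, 1, 3), r, probe = w)
  expect_equal(got, 4 * pi * (r + w)^2, tolerance = 0.01)
  # two far spheres: additivity
  far <- rbind(c(0, 0, 0), c(100, 0, 0))
  expect_equal(sum(sasa(far, c(1.9, 1.6), probe = w)),
               4 * pi * (1.9 + w)^2 + 4 * pi * (1.6 + w)^2,
               tolerance = 0.01)
  # two intersecting equal spheres: analytic cap formula within 2%
  r0 <- 1.6; R <- r0 + w; d <- 4
  x <- rbind(c(0, 0, 0), c(d, 0, 0))
  got2 <- sasa(x, c(r0, r0), probe = w)
  cosT <- (d^2 + R^2 - R^2) / (2 * d * R)
  hidden <- 2 * pi * R^2 * (1 - cosT)
  want <- 4 * pi * R^2 - hidden
  expect_equal(got2[1], want, tolerance = 0.02)
  expect_equal(got2[2], want, tolerance = 0.02)
  expect_error(sasa(x, c(1, 1), nSpherePoints = 10), "100")

  # nonpolar term is linear in area
  expect_equal(nonpolarEnergy(0, beta = 0.7), 0.7)
  expect_equal(nonpolarEnergy(1000, gamma = 0.005), 5)
  expect_equal(nonpolarEnergy(300, gamma = 0.01, beta = 1),
               2 * nonpolarEnergy(150, gamma = 0.01, beta = 0.5))
})

test_that("two-ion binding energy equals the hand-assembled thermodynamic cycle", {
  tc <- generateToyComplex("two-ion", separation = 4)
  x <- coords(tc$structure)
  p <- tc$parameters
  be <- frameBindingEnergy(x, tc$receptor, tc$ligand, p)
  expect_identical(be$e_internal, 0)
  expect_equal(be$total,
               be$e_elec + be$e_vdw + be$g_gb + be$g_sa + be$e_internal,
               tolerance = 1e-9)

  elec <- coulombEnergy(x, p@charge)
  vdw <- ljEnergy(x, p@ljRminHalf, p@ljEpsilon)
  aC <- bornRadii(x, p@gbRadius, p@gbScreen)
  gb <- gbEnergy(x, p@charge, aC) -
    gbEnergy(x[1, , drop = FALSE], p@charge[1], p@gbRadius[1]) -
    gbEnergy(x[2, , drop = FALSE], p@charge[2], p@gbRadius[2])
  sa <- 0.005 * (sum(sasa(x, p@gbRadius)) -
                   sum(sasa(x[1, , drop = FALSE], p@gbRadius[1])) -
                   sum(sasa(x[2, , drop = FALSE], p@gbRadius[2])))
  expect_equal(be$e_elec, elec, tolerance = 1e-10)
  expect_equal(be$e_vdw, vdw, tolerance = 1e-10)
  expect_equal(be$g_gb, gb, tolerance = 1e-10)
  expect_equal(be$g_sa, sa, tolerance = 1e-10)
  expect_error(frameBindingEnergy(x, tc$receptor, tc$receptor, p),
               "overlap")
})

test_that("all interaction terms vanish for a far-separated neutral pair", {
  tc <- generateToyComplex("helix-pair", receptorAtoms = 3, ligandAtoms = 3,
                           separation = 500, seed = 2)
  be <- frameBindingEnergy(coords(tc$structure), tc$receptor, tc$ligand,
                           tc$parameters)
  expect_lt(abs(be$total), 1e-6)
  expect_lt(abs(be$g_sa), 1e-9)
  expect_lt(abs(be$e_vdw), 1e-9)
})

test_that("binding energies are invariant under rigid motion and charge flips", {
  tc <- generateToyComplex("helix-pair", receptorAtoms = 2, ligandAtoms = 2,
                           separation = 5, seed = 3)
  x <- coords(tc$structure)
  p <- tc$parameters
  be <- frameBindingEnergy(x, tc$receptor, tc$ligand, p)
  moved <- rigidTransform(x, randomRotation(21), c(13, -6, 2))
  be2 <- frameBindingEnergy(moved, tc$receptor, tc$ligand, p)
  for (cn in names(be)) expect_equal(be2[[cn]], be[[cn]], tolerance = 1e-9)

  # quadratic forms: flipping every charge changes neither elec nor GB
  pf <- p; pf@charge <- -p@charge
  bef <- frameBindingEnergy(x, tc$receptor, tc$ligand, pf)
  expect_equal(bef$e_elec, be$e_elec, tolerance = 1e-12)
  expect_equal(bef$g_gb, be$g_gb, tolerance = 1e-12)
})

test_that("trajectory averaging uses the population SD", {
  tc <- generateToyComplex("two-ion", nFrames = 3, jitterSd = 0, seed = 5)
  be <- trajectoryBindingEnergy(tc$trajectory, tc$receptor, tc$ligand,
                                tc$parameters)
  expect_equal(be@sd, 0, tolerance = 1e-12)
  expect_equal(be@mean, be@perFrame$total[1], tolerance = 1e-12)

  tc2 <- generateToyComplex("two-ion", nFrames = 2, jitterSd = 0.3, seed = 6)
  be2 <- trajectoryBindingEnergy(tc2$trajectory, tc2$receptor, tc2$ligand,
                                 tc2$parameters)
  a <- be2@perFrame$total[1]; b <- be2@perFrame$total[2]
  expect_equal(be2@mean, (a + b) / 2, tolerance = 1e-12)
  expect_equal(be2@sd, abs(a - b) / 2, tolerance = 1e-12)
  expect_error(trajectoryBindingEnergy(tc2$trajectory, tc2$receptor,
                                       tc2$ligand, tc2$parameters,
                                       startFrame = 10), "empty")
})

test_that("per-residue decomposition conserves the total and partitions pairs", {
  tc <- generateToyComplex("helix-pair", receptorAtoms = 3, ligandAtoms = 3,
                           separation = 4, nFrames = 3, seed = 8)
  dec <- perResidueDecomposition(tc$trajectory, tc$receptor, tc$ligand,
                                 tc$parameters)
  be <- trajectoryBindingEnergy(tc$trajectory, tc$receptor, tc$ligand,
                                tc$parameters)
  expect_equal(sum(dec@table$total), be@mean, tolerance = 1e-6)
  for (cn in c("elec", "vdw", "gb", "sa"))
    expect_true(all(is.finite(dec@table[[cn]])))
  expect_equal(nrow(dec@table), 6L)

  # two-ion hand partition: each residue gets half the cross terms plus its
  # own desolvation
  ti <- generateToyComplex("two-ion", nFrames = 1, jitterSd = 0, seed = 9)
  x <- frameCoords(ti$trajectory, 1)
  p <- ti$parameters
  d1 <- perResidueDecomposition(ti$trajectory, ti$receptor, ti$ligand, p)
  elec <- coulombEnergy(x, p@charge)
  vdw <- ljEnergy(x, p@ljRminHalf, p@ljEpsilon)
  aC <- bornRadii(x, p@gbRadius, p@gbScreen)
  pref <- -(kC / 2) * (1 - 1 / 78.5)
  r <- sqrt(sum((x[1, ] - x[2, ])^2))
  f12 <- sqrt(r^2 + aC[1] * aC[2] * exp(-r^2 / (4 * aC[1] * aC[2])))
  gbSelf1 <- pref * p@charge[1]^2 / aC[1] - pref * p@charge[1]^2 / p@gbRadius[1]
  gbCross <- pref * p@charge[1] * p@charge[2] / f12
  expect_equal(d1@table$elec, rep(elec / 2, 2), tolerance = 1e-10)
  expect_equal(d1@table$vdw, rep(vdw / 2, 2), tolerance = 1e-10)
  expect_equal(d1@table$gb[1], gbSelf1 + gbCross, tolerance = 1e-10)

  # reporting filter keeps only residues beyond the threshold
  expect_true(all(abs(residueTable(d1)$total) > 1))
  expect_equal(nrow(residueTable(d1, all = TRUE)), 2L)
})

test_that("an uncharged, far ligand residue contributes nothing", {
  # ligand atom 500 A away with zero charge and epsilon: geometry of the
  # receptor is unchanged between species, so its contribution is ~0
  s <- Structure(c("C1", "C2", "C3"), c(1L, 1L, 2L),
                 chainIds = c("A", "A", "B"),
                 coords = rbind(c(0, 0, 0), c(2.5, 0, 0), c(500, 0, 0)))
  p <- new("EnergyParameters", atomNames = atomNames(s),
           charge = c(0.5, -0.5, 0), ljRminHalf = c(1.7, 1.7, 1.7),
           ljEpsilon = c(0.1, 0.1, 0), gbRadius = c(1.5, 1.5, 1.5),
           gbScreen = c(0.8, 0.8, 0.8))
  traj <- Trajectory(list(coords(s)), s)
  dec <- perResidueDecomposition(traj, makeSelection(s, "chain A"),
                                 makeSelection(s, "chain B"), p)
  expect_lt(abs(dec@table$total[dec@table$chain == "B"]), 1e-9)
})
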