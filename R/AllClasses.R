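setOldClass("dist")

#' Molecular structure with per-atom metadata
#'
#' A single conformation: atom names, 1-based residue ids (as in the source
#' file), residue names, chain ids, Cartesian coordinates in Angstrom and
#' atomic masses in amu.
#'
#' @slot atomNames character vector of atom names (e.g. \code{"CA"}).
#' @slot residueIds integer residue ids, 1-based, taken verbatim from input.
#' @slot residueNames character residue names.
#' @slot chainIds character chain identifiers.
#' @slot coords numeric N x 3 matrix, Angstrom.
#' @slot masses numeric atomic masses, amu, all positive.
#' @exportClass Structure
setClass("Structure",
  slots = c(atomNames = "character", residueIds = "integer",
            residueNames = "character", chainIds = "character",
            coords = "matrix", masses = "numeric"))

setValidity("Structure", function(object) {
  n <- length(object@atomNames)
  if (n < 1L) return("a Structure needs at least one atom")
  lens <- c(length(object@residueIds), length(object@residueNames),
            length(object@chainIds), nrow(object@coords), length(object@masses))
  if (any(lens != n)) return("all per-atom slots must share the atom count")
  if (ncol(object@coords) != 3L) return("coords must be an N x 3 matrix")
  if (!all(is.finite(object@coords))) return("coordinates must be finite")
  if (any(!is.finite(object@masses)) || any(object@masses <= 0))
    return("masses must be positive and finite")
  TRUE
})

#' Multi-frame trajectory
#'
#' Frames are stored as an N x 3 x F array (Angstrom); \code{times} holds the
#' frame times in ns, strictly increasing; \code{topology} carries the per-atom
#' metadata shared by every frame.
#'
#' @slot coords numeric N x 3 x F array, Angstrom.
#' @slot times numeric frame times, ns, strictly increasing, length F.
#' @slot topology a [Structure-class] with N atoms.
#' @exportClass Trajectory
setClass("Trajectory",
  slots = c(coords = "array", times = "numeric", topology = "Structure"))

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L) return("coords must be an N x 3 x F array")
  if (d[3] < 1L) return("a Trajectory needs at least one frame")
  if (d[1] != nAtoms(object@topology))
    return("frame atom count does not match the topology")
  if (length(object@times) != d[3]) return("times must have one entry per frame")
  if (any(diff(object@times) <= 0)) return("times must be strictly increasing")
  if (!all(is.finite(object@coords))) return("coordinates must be finite")
  TRUE
})

#' Atom selection
#'
#' A strictly increasing list of 1-based atom indices into a topology, plus
#' the expression it was built from.
#'
#' @slot indices integer, 1-based, strictly increasing, non-empty.
#' @slot label character, the selection expression.
#' @exportClass Selection
setClass("Selection", slots = c(indices = "integer", label = "character"))

setValidity("Selection", function(object) {
  if (length(object@indices) < 1L) return("empty selection")
  if (any(object@indices < 1L)) return("indices must be >= 1")
  if (any(diff(object@indices) <= 0L)) return("indices must be strictly increasing")
  TRUE
})

#' Per-atom energy parameters
#'
#' Point charges (e), Lennard-Jones rmin/2 (Angstrom) and well depth
#' (kcal/mol), intrinsic generalized-Born radii (Angstrom) and HCT screening
#' factors, one row per atom of the topology they are attached to.
#'
#' @slot atomNames character, for alignment diagnostics.
#' @slot charge numeric, elementary charges.
#' @slot ljRminHalf numeric, Angstrom.
#' @slot ljEpsilon numeric, kcal/mol, non-negative.
#' @slot gbRadius numeric, Angstrom, positive.
#' @slot gbScreen numeric, dimensionless, in (0, 2].
#' @exportClass EnergyParameters
setClass("EnergyParameters",
  slots = c(atomNames = "character", charge = "numeric", ljRminHalf = "numeric",
            ljEpsilon = "numeric", gbRadius = "numeric", gbScreen = "numeric"))

setValidity("EnergyParameters", function(object) {
  n <- length(object@charge)
  lens <- c(length(object@atomNames), length(object@ljRminHalf),
            length(object@ljEpsilon), length(object@gbRadius),
            length(object@gbScreen))
  if (any(lens != n)) return("all parameter slots must share the atom count")
  vals <- c(object@charge, object@ljRminHalf, object@ljEpsilon,
            object@gbRadius, object@gbScreen)
  if (any(!is.finite(vals))) return("parameters must be finite")
  if (any(object@ljEpsilon < 0)) return("ljEpsilon must be >= 0")
  if (any(object@gbRadius <= 0)) return("gbRadius must be > 0")
  if (any(object@gbScreen <= 0 | object@gbScreen > 2))
    return("gbScreen must lie in (0, 2]")
  TRUE
})

#' Result of an optimal superposition
#'
#' @slot rotation 3 x 3 proper orthogonal matrix (row-vector convention:
#'   aligned = centered mobile `%*%` rotation + translation offset).
#' @slot translation numeric 3-vector, Angstrom.
#' @slot rmsd numeric, the minimised mass-weighted RMSD, Angstrom.
#' @exportClass SuperpositionResult
setClass("SuperpositionResult",
  slots = c(rotation = "matrix", translation = "numeric", rmsd = "numeric"))

setValidity("SuperpositionResult", function(object) {
  if (abs(det(object@rotation) - 1) > 1e-9) return("rotation must be proper")
  if (object@rmsd < 0) return("rmsd must be non-negative")
  TRUE
})

#' Per-frame RMSD series
#' @slot values numeric RMSD per frame, Angstrom, non-negative.
#' @slot times numeric frame times, ns.
#' @slot referenceLabel,selectionLabel character provenance labels.
#' @exportClass RmsdSeries
setClass("RmsdSeries",
  slots = c(values = "numeric", times = "numeric",
            referenceLabel = "character", selectionLabel = "character"))

#' Per-residue RMSF profile
#' @slot residueIds integer residue ids.
#' @slot values numeric RMSF per residue, Angstrom, non-negative.
#' @slot label character provenance label.
#' @exportClass RmsfProfile
setClass("RmsfProfile",
  slots = c(residueIds = "integer", values = "numeric", label = "character"))

#' Principal component model of positional fluctuations
#'
#' @slot mean numeric n x 3 mean structure of the selected atoms (aligned
#'   frame of reference), Angstrom.
#' @slot vectors numeric 3n x m orthonormal eigenvector matrix, descending
#'   eigenvalue order; coordinate flattening is (x1,y1,z1,x2,...).
#' @slot values numeric eigenvalues (Angstrom^2 * amu when mass-weighted).
#' @slot weights numeric per-atom masses used for weighting.
#' @slot selection the [Selection-class] the model was fitted on.
#' @slot massWeighted logical.
#' @exportClass PCAModel
setClass("PCAModel",
  slots = c(mean = "matrix", vectors = "matrix", values = "numeric",
            weights = "numeric", selection = "Selection",
            massWeighted = "logical"))

#' Functional mode analysis result
#'
#' @slot betas numeric regression coefficients per retained mode.
#' @slot intercept numeric.
#' @slot mcm numeric unit 3n-vector, maximally correlated motion.
#' @slot ewmcm numeric unit 3n-vector, ensemble-weighted MCM.
#' @slot rTrain,rCv numeric Pearson correlations on the training and held-out
#'   splits.
#' @slot nComponents integer retained mode count.
#' @slot splitFraction numeric fraction of frames used for training.
#' @exportClass FMAResult
setClass("FMAResult",
  slots = c(betas = "numeric", intercept = "numeric", mcm = "numeric",
            ewmcm = "numeric", rTrain = "numeric", rCv = "numeric",
            nComponents = "integer", splitFraction = "numeric"))

setValidity("FMAResult", function(object) {
  if (abs(sqrt(sum(object@mcm^2)) - 1) > 1e-9) return("mcm must be unit length")
  if (abs(sqrt(sum(object@ewmcm^2)) - 1) > 1e-9) return("ewmcm must be unit length")
  r <- c(object@rTrain, object@rCv)
  if (any(abs(r) > 1 + 1e-9)) return("correlations must lie in [-1, 1]")
  TRUE
})

#' Pairwise frame-to-frame RMSD matrix
#'
#' Condensed (as \code{stats::dist}) superposition-minimised mass-weighted
#' RMSD between strided trajectory frames.
#'
#' @slot values a \code{dist} object, Angstrom.
#' @slot frameIndices integer original frame indices of the strided frames.
#' @slot stride integer stride used.
#' @slot selectionLabel character.
#' @exportClass DistanceMatrix
setClass("DistanceMatrix",
  slots = c(values = "dist", frameIndices = "integer", stride = "integer",
            selectionLabel = "character"))

#' Hierarchical clustering result
#'
#' @slot labelsByK integer matrix, one row per strided frame, one column per
#'   candidate cluster count K.
#' @slot kRange integer candidate counts.
#' @slot metrics data.frame with columns k, dbi, psf, ssr_sst.
#' @slot chosenK integer selected cluster count.
#' @slot centroids integer medoid frame index (into the strided frames) per
#'   cluster at the chosen K.
#' @slot populations numeric fraction of frames per cluster at the chosen K,
#'   summing to 1.
#' @slot linkage character linkage criterion used.
#' @slot frameIndices integer original frame indices of the strided frames.
#' @exportClass ClusteringResult
setClass("ClusteringResult",
  slots = c(labelsByK = "matrix", kRange = "integer", metrics = "data.frame",
            chosenK = "integer", centroids = "integer",
            populations = "numeric", linkage = "character",
            frameIndices = "integer"))

setValidity("ClusteringResult", function(object) {
  if (abs(sum(object@populations) - 1) > 1e-12)
    return("populations must sum to 1")
  TRUE
})

#' Trajectory binding-energy result
#'
#' Per-frame interaction (Delta-Delta) terms, complex minus receptor minus
#' ligand, kcal/mol, with mean and population SD of the totals.
#'
#' @slot perFrame data.frame with columns frame, e_elec, e_vdw, g_gb, g_sa,
#'   e_internal, total.
#' @slot mean,sd numeric kcal/mol.
#' @slot receptorLabel,ligandLabel character.
#' @exportClass BindingEnergyResult
setClass("BindingEnergyResult",
  slots = c(perFrame = "data.frame", mean = "numeric", sd = "numeric",
            receptorLabel = "character", ligandLabel = "character"))

#' Per-residue binding-energy decomposition
#'
#' @slot table data.frame with one row per residue: chain, residue_id,
#'   residue_name, elec, vdw, gb, sa, total (frame means, kcal/mol) and sd of
#'   the per-frame residue totals.
#' @slot threshold numeric reporting threshold, kcal/mol.
#' @slot receptorLabel,ligandLabel character.
#' @exportClass ResidueDecomposition
setClass("ResidueDecomposition",
  slots = c(table = "data.frame", threshold = "numeric",
            receptorLabel = "character", ligandLabel = "character"))
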