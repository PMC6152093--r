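# Standard atomic masses (amu) keyed by element symbol.
.elementMasses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    P = 30.974, S = 32.06, ZN = 65.38, MG = 24.305,
                    FE = 55.845, CL = 35.45, NA. = 22.99, K = 39.098,
                    BR = 79.904, F = 18.998)

#' Guess atomic masses from atom names
#'
#' Maps atom names to elements by PDB convention: names matching a known
#' two-letter element (ZN, MG, FE, CL, BR) are taken as that element,
#' otherwise the first alphabetic character decides (so `"CA"` is an alpha
#' carbon, not calcium).
#'
#' @param atomNames character vector of atom names.
#' @return numeric masses in amu.
#' @export
#' @examples
#' atomicMasses(c("N", "CA", "C", "O"))
atomicMasses <- function(atomNames) {
  up <- toupper(gsub("[^A-Za-z]", "", atomNames))
  twoLetter <- c("ZN", "MG", "FE", "CL", "BR")
  elem <- ifelse(up %in% twoLetter, up, substr(up, 1L, 1L))
  elem[elem == "NA"] <- "NA."
  m <- .elementMasses[elem]
  if (any(is.na(m)))
    stop("cannot assign a mass to atom name(s): ",
         paste(unique(atomNames[is.na(m)]), collapse = ", "))
  unname(m)
}

#' Construct a Structure
#'
#' @param atomNames character atom names.
#' @param residueIds integer residue ids (1-based, as in the source file).
#' @param residueNames character residue names (default `"ALA"`).
#' @param chainIds character chain ids (default `"A"`).
#' @param coords numeric N x 3 coordinate matrix, Angstrom.
#' @param masses numeric masses in amu; derived from `atomNames` via
#'   [atomicMasses()] when `NULL`.
#' @return a [Structure-class].
#' @export
#' @examples
#' Structure(c("N", "CA", "C"), c(1L, 1L, 1L),
#'           coords = matrix(rnorm(9), 3, 3))
Structure <- function(atomNames, residueIds, residueNames = NULL,
                      chainIds = NULL, coords, masses = NULL) {
  n <- length(atomNames)
  if (is.null(residueNames)) residueNames <- rep("ALA", n)
  if (is.null(chainIds)) chainIds <- rep("A", n)
  if (is.null(masses)) masses <- atomicMasses(atomNames)
  coords <- as.matrix(coords)
  dimnames(coords) <- NULL
  new("Structure", atomNames = as.character(atomNames),
      residueIds = as.integer(residueIds),
      residueNames = as.character(residueNames),
      chainIds = as.character(chainIds),
      coords = coords, masses = as.numeric(masses))
}

#' Construct a Trajectory
#'
#' @param coords an N x 3 x F array or a list of F coordinate matrices
#'   (N x 3), Angstrom.
#' @param topology a [Structure-class] with matching atom count.
#' @param times numeric frame times in ns, strictly increasing; defaults to
#'   `0, 1, 2, ...`.
#' @return a [Trajectory-class].
#' @export
Trajectory <- function(coords, topology, times = NULL) {
  if (is.list(coords)) {
    n <- nrow(coords[[1]])
    bad <- which(vapply(coords, nrow, 0L) != n)
    if (length(bad))
      stop("inconsistent atom count at frame ", bad[1])
    coords <- array(unlist(coords), dim = c(n, 3, length(coords)))
  }
  if (is.null(times)) times <- seq_len(dim(coords)[3]) - 1
  new("Trajectory", coords = coords, times = as.numeric(times),
      topology = topology)
}

#' Subset a Structure by atom indices
#'
#' @param x a [Structure-class].
#' @param idx integer atom indices (1-based) or a [Selection-class].
#' @return a [Structure-class] with the selected atoms.
#' @export
subsetStructure <- function(x, idx) {
  if (is(idx, "Selection")) idx <- idx@indices
  new("Structure", atomNames = x@atomNames[idx],
      residueIds = x@residueIds[idx], residueNames = x@residueNames[idx],
      chainIds = x@chainIds[idx], coords = x@coords[idx, , drop = FALSE],
      masses = x@masses[idx])
}

#' Build a procedural backbone chain
#'
#' Constructs a poly-alanine-like backbone (N, CA, C, O per residue) laid out
#' along a gently twisted extended curve, so `backbone` and residue-range
#' selections work naturally on synthetic data. Purely geometric; no
#' force-field realism is intended.
#'
#' @param nResidues number of residues.
#' @param chainId chain identifier.
#' @param startResid residue id of the first residue.
#' @param origin numeric 3-vector added to all coordinates.
#' @return a [Structure-class] with `4 * nResidues` atoms.
#' @export
#' @examples
#' buildChain(5)
buildChain <- function(nResidues, chainId = "A", startResid = 1L,
                       origin = c(0, 0, 0)) {
  stopifnot(nResidues >= 1)
  names <- character(0); rid <- integer(0)
  xyz <- matrix(0, 0, 3)
  for (i in seq_len(nResidues)) {
    ph <- 0.7 * i
    base <- c(3.6 * (i - 1), 1.8 * sin(ph), 1.8 * cos(ph))
    res <- rbind(base,
                 base + c(1.20, 0.85, 0.35),
                 base + c(2.45, 0.55, -0.40),
                 base + c(2.75, 1.55, -1.05))
    xyz <- rbind(xyz, res)
    names <- c(names, c("N", "CA", "C", "O"))
    rid <- c(rid, rep(startResid + i - 1L, 4L))
  }
  xyz <- sweep(xyz, 2, origin, "+")
  Structure(names, rid, rep("ALA", length(names)),
            rep(chainId, length(names)), xyz)
}

# Combine structures (e.g. receptor + ligand chains) into one.
#' Concatenate structures atom-wise
#' @param ... [Structure-class] objects.
#' @return a single [Structure-class].
#' @export
combineStructures <- function(...) {
  xs <- list(...)
  Structure(unlist(lapply(xs, atomNames)),
            unlist(lapply(xs, residueIds)),
            unlist(lapply(xs, residueNames)),
            unlist(lapply(xs, chainIds)),
            do.call(rbind, lapply(xs, coords)),
            unlist(lapply(xs, masses)))
}
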