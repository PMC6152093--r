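#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("coords", function(x, ...) standardGeneric("coords"))

#' @rdname accessors
#' @export
setGeneric("masses", function(x) standardGeneric("masses"))

#' @rdname accessors
#' @export
setGeneric("atomNames", function(x) standardGeneric("atomNames"))

#' @rdname accessors
#' @export
setGeneric("residueIds", function(x) standardGeneric("residueIds"))

#' @rdname accessors
#' @export
setGeneric("residueNames", function(x) standardGeneric("residueNames"))

#' @rdname accessors
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))

#' @rdname accessors
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' @rdname accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname accessors
#' @export
setGeneric("frameCoords", function(x, i) standardGeneric("frameCoords"))

#' @rdname accessors
#' @export
setGeneric("selectionIndices", function(x) standardGeneric("selectionIndices"))

#' Accessors for trajlens objects
#'
#' Slot access for the core data classes: atom and frame counts, coordinate
#' matrices, per-atom metadata, frame times and selection indices.
#'
#' @param x a [Structure-class], [Trajectory-class] or [Selection-class].
#' @param i frame index (1-based) for `frameCoords`.
#' @param ... unused.
#' @return the requested component; `coords` on a `Structure` returns an
#'   N x 3 matrix, on a `Trajectory` the N x 3 x F array.
#' @name accessors
#' @examples
#' s <- buildChain(3)
#' nAtoms(s)
#' head(coords(s))
NULL

#' @rdname accessors
setMethod("nAtoms", "Structure", function(x) length(x@atomNames))
#' @rdname accessors
setMethod("nAtoms", "Trajectory", function(x) dim(x@coords)[1])
#' @rdname accessors
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[3])
#' @rdname accessors
setMethod("coords", "Structure", function(x, ...) x@coords)
#' @rdname accessors
setMethod("coords", "Trajectory", function(x, ...) x@coords)
#' @rdname accessors
setMethod("masses", "Structure", function(x) x@masses)
#' @rdname accessors
setMethod("masses", "Trajectory", function(x) x@topology@masses)
#' @rdname accessors
setMethod("atomNames", "Structure", function(x) x@atomNames)
#' @rdname accessors
setMethod("residueIds", "Structure", function(x) x@residueIds)
#' @rdname accessors
setMethod("residueNames", "Structure", function(x) x@residueNames)
#' @rdname accessors
setMethod("chainIds", "Structure", function(x) x@chainIds)
#' @rdname accessors
setMethod("topology", "Trajectory", function(x) x@topology)
#' @rdname accessors
setMethod("frameTimes", "Trajectory", function(x) x@times)
#' @rdname accessors
setMethod("frameCoords", "Trajectory", function(x, i) {
  stopifnot(length(i) == 1L, i >= 1L, i <= nFrames(x))
  m <- x@coords[, , i, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
})
#' @rdname accessors
setMethod("selectionIndices", "Selection", function(x) x@indices)

setMethod("show", "Structure", function(object) {
  cat(sprintf("Structure: %d atoms, %d residues, chains %s\n",
              nAtoms(object),
              length(unique(paste(object@chainIds, object@residueIds))),
              paste(unique(object@chainIds), collapse = ",")))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d frames x %d atoms, t = %.4g..%.4g ns\n",
              nFrames(object), nAtoms(object),
              object@times[1], object@times[nFrames(object)]))
})

setMethod("show", "Selection", function(object) {
  cat(sprintf("Selection '%s': %d atoms\n", object@label,
              length(object@indices)))
})

setMethod("show", "SuperpositionResult", function(object) {
  cat(sprintf("SuperpositionResult: rmsd = %.6g A\n", object@rmsd))
})

setMethod("show", "RmsdSeries", function(object) {
  cat(sprintf("RmsdSeries (%s over %s): %d frames, mean %.3f A\n",
              object@referenceLabel, object@selectionLabel,
              length(object@values), mean(object@values)))
})

setMethod("show", "RmsfProfile", function(object) {
  cat(sprintf("RmsfProfile (%s): %d residues, range %.3f-%.3f A\n",
              object@label, length(object@values),
              min(object@values), max(object@values)))
})

setMethod("show", "PCAModel", function(object) {
  tot <- sum(object@values)
  top <- if (tot > 0) object@values[1] / tot else NA_real_
  cat(sprintf("PCAModel: %d modes on %d atoms (%s), top mode %.1f%% of variance\n",
              length(object@values), nrow(object@mean),
              if (object@massWeighted) "mass-weighted" else "unweighted",
              100 * top))
})

setMethod("show", "FMAResult", function(object) {
  cat(sprintf("FMAResult: %d components, r_train = %.4f, r_cv = %.4f\n",
              object@nComponents, object@rTrain, object@rCv))
})

setMethod("show", "DistanceMatrix", function(object) {
  cat(sprintf("DistanceMatrix: %d frames (stride %d), selection '%s'\n",
              attr(object@values, "Size"), object@stride,
              object@selectionLabel))
})

setMethod("show", "ClusteringResult", function(object) {
  cat(sprintf("ClusteringResult (%s linkage): chosen K = %d, populations %s\n",
              object@linkage, object@chosenK,
              paste(sprintf("%.1f%%", 100 * object@populations),
                    collapse = " ")))
})

setMethod("show", "BindingEnergyResult", function(object) {
  cat(sprintf("BindingEnergyResult %s | %s: %.2f +/- %.2f kcal/mol over %d frames\n",
              object@receptorLabel, object@ligandLabel, object@mean,
              object@sd, nrow(object@perFrame)))
})

setMethod("show", "ResidueDecomposition", function(object) {
  cat(sprintf("ResidueDecomposition: %d residues (reporting |mean| > %.2g kcal/mol: %d)\n",
              nrow(object@table), object@threshold,
              sum(abs(object@table$total) > object@threshold)))
})
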