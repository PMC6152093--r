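#' Build an atom selection from an expression
#'
#' Supported grammar: the clauses `backbone` (atoms named N, CA, C, O),
#' `resid A-B` (inclusive residue-id range; `resid A` selects one residue) and
#' `chain X`, combined with `and` (intersection). Selections are
#' deterministic: the same expression on the same topology always yields the
#' same strictly increasing index list.
#'
#' @param topology a [Structure-class].
#' @param expression selection text, e.g. `"backbone and resid 239-251"`.
#' @return a [Selection-class] (1-based atom indices).
#' @export
#' @examples
#' s <- buildChain(10)
#' makeSelection(s, "backbone and resid 3-5")
makeSelection <- function(topology, expression) {
  clauses <- strsplit(trimws(expression), "\\s+and\\s+")[[1]]
  if (length(clauses) == 0L || !nzchar(clauses[1]))
    stop("empty selection expression")
  keep <- rep(TRUE, nAtoms(topology))
  for (cl in clauses) {
    cl <- trimws(cl)
    if (cl == "backbone") {
      keep <- keep & topology@atomNames %in% c("N", "CA", "C", "O")
    } else if (grepl("^resid\\s+\\d+(-\\d+)?$", cl)) {
      rng <- strsplit(sub("^resid\\s+", "", cl), "-")[[1]]
      a <- as.integer(rng[1])
      b <- if (length(rng) > 1L) as.integer(rng[2]) else a
      keep <- keep & topology@residueIds >= a & topology@residueIds <= b
    } else if (grepl("^chain\\s+\\S+$", cl)) {
      ch <- sub("^chain\\s+", "", cl)
      keep <- keep & topology@chainIds == ch
    } else if (cl == "all") {
      # no-op
    } else {
      stop("unknown selection token: '", cl, "'")
    }
  }
  idx <- which(keep)
  if (length(idx) == 0L)
    stop("selection '", expression, "' matches no atoms")
  new("Selection", indices = as.integer(idx), label = expression)
}

#' Selection covering all atoms
#' @param topology a [Structure-class].
#' @return a [Selection-class].
#' @export
allAtoms <- function(topology) {
  new("Selection", indices = seq_len(nAtoms(topology)), label = "all")
}
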