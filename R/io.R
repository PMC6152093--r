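#' Read a trajectory from file
#'
#' Reads a multi-model PDB (`MODEL`/`ENDMDL` records; a file without `MODEL`
#' records is a single frame) or a concatenated XYZ trajectory
#' (count / comment / atom records per block). Coordinates are in Angstrom
#' and the atom order must be identical across frames.
#'
#' For PDB input the topology (atom names, residue ids and names, chains,
#' masses guessed from atom names) is taken from the first model. XYZ blocks
#' carry only atom names; residue/chain metadata comes from `topology` when
#' supplied, otherwise each atom becomes its own residue.
#'
#' @param path input file.
#' @param format `"pdb"` or `"xyz"`.
#' @param topology optional [Structure-class] providing per-atom metadata
#'   (required to be consistent in atom count).
#' @return a [Trajectory-class].
#' @seealso [writeTrajectory()]
#' @export
readTrajectory <- function(path, format = c("pdb", "xyz"), topology = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "pdb") .readPdb(path, topology) else .readXyz(path, topology)
}

.readPdb <- function(path, topology = NULL) {
  lines <- readLines(path)
  isAtom <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  modelStarts <- which(startsWith(lines, "MODEL"))
  frames <- list()
  if (length(modelStarts) == 0L) {
    groups <- list(which(isAtom))
  } else {
    ends <- which(startsWith(lines, "ENDMDL"))
    if (length(ends) != length(modelStarts))
      stop("unmatched MODEL/ENDMDL records in ", path)
    groups <- lapply(seq_along(modelStarts), function(k) {
      idx <- which(isAtom)
      idx[idx > modelStarts[k] & idx < ends[k]]
    })
  }
  if (length(groups[[1]]) == 0L) stop("no ATOM records found in ", path)
  parseBlock <- function(idx) {
    txt <- lines[idx]
    x <- suppressWarnings(as.numeric(substr(txt, 31, 38)))
    y <- suppressWarnings(as.numeric(substr(txt, 39, 46)))
    z <- suppressWarnings(as.numeric(substr(txt, 47, 54)))
    bad <- which(is.na(x) | is.na(y) | is.na(z))
    if (length(bad))
      stop("unparseable coordinate field at line ", idx[bad[1]], " of ", path)
    cbind(x, y, z, deparse.level = 0)
  }
  n0 <- length(groups[[1]])
  for (k in seq_along(groups)) {
    if (length(groups[[k]]) != n0)
      stop("inconsistent atom count at frame ", k, " (", length(groups[[k]]),
           " atoms, expected ", n0, ")")
    frames[[k]] <- parseBlock(groups[[k]])
  }
  if (is.null(topology)) {
    txt <- lines[groups[[1]]]
    nm <- trimws(substr(txt, 13, 16))
    resn <- trimws(substr(txt, 18, 20))
    ch <- trimws(substr(txt, 22, 22))
    rid <- suppressWarnings(as.integer(trimws(substr(txt, 23, 26))))
    if (any(is.na(rid)))
      stop("unparseable residue id at line ",
           groups[[1]][which(is.na(rid))[1]], " of ", path)
    ch[ch == ""] <- "A"
    topology <- Structure(nm, rid, resn, ch, frames[[1]])
  }
  Trajectory(frames, topology)
}

.readXyz <- function(path, topology = NULL) {
  lines <- readLines(path)
  frames <- list(); times <- numeric(0)
  i <- 1L; k <- 0L; n0 <- NA_integer_; nm0 <- NULL
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("unparseable atom count at line ", i, " of ", path)
    k <- k + 1L
    if (is.na(n0)) n0 <- n
    else if (n != n0) stop("inconsistent atom count at frame ", k)
    comment <- lines[i + 1L]
    tm <- regmatches(comment, regexpr("t=\\s*[-0-9.eE+]+", comment))
    times <- c(times, if (length(tm))
      as.numeric(sub("t=\\s*", "", tm)) else k - 1)
    rec <- lines[i + 1L + seq_len(n)]
    parts <- strsplit(trimws(rec), "\\s+")
    bad <- which(lengths(parts) < 4L)
    if (length(bad))
      stop("unparseable record at line ", i + 1L + bad[1], " of ", path)
    nm <- vapply(parts, `[`, "", 1L)
    xyz <- t(vapply(parts, function(p)
      suppressWarnings(as.numeric(p[2:4])), numeric(3)))
    if (any(is.na(xyz)))
      stop("unparseable coordinate at line ",
           i + 1L + which(rowSums(is.na(xyz)) > 0)[1], " of ", path)
    if (is.null(nm0)) nm0 <- nm
    frames[[k]] <- xyz
    i <- i + 2L + n
  }
  if (k == 0L) stop("no frames found in ", path)
  if (is.null(topology))
    topology <- Structure(nm0, seq_len(n0), chainIds = rep("A", n0),
                          coords = frames[[1]])
  Trajectory(frames, topology, times = times)
}

#' Write a trajectory to file
#'
#' Writes a multi-model PDB or an XYZ trajectory that round-trips through
#' [readTrajectory()] within format precision (coordinates are printed with
#' 3 decimals for PDB and 4 for XYZ). Residue ids are written verbatim.
#'
#' @param traj a [Trajectory-class].
#' @param path output file.
#' @param format `"pdb"` or `"xyz"`.
#' @return `path`, invisibly.
#' @export
writeTrajectory <- function(traj, path, format = c("pdb", "xyz")) {
  format <- match.arg(format)
  top <- topology(traj)
  F <- nFrames(traj)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "pdb") {
    for (t in seq_len(F)) {
      x <- frameCoords(traj, t)
      writeLines(sprintf("MODEL     %4d", t), con)
      nm <- ifelse(nchar(top@atomNames) < 4L,
                   sprintf(" %-3s", top@atomNames),
                   sprintf("%-4s", top@atomNames))
      writeLines(sprintf(
        "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
        seq_len(nrow(x)), nm, top@residueNames, top@chainIds,
        top@residueIds, x[, 1], x[, 2], x[, 3], 1, 0), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else {
    for (t in seq_len(F)) {
      x <- frameCoords(traj, t)
      writeLines(sprintf("%d", nrow(x)), con)
      writeLines(sprintf("frame %d t= %.6f", t, traj@times[t]), con)
      writeLines(sprintf("%-4s %12.4f %12.4f %12.4f",
                         top@atomNames, x[, 1], x[, 2], x[, 3]), con)
    }
  }
  invisible(path)
}

#' Read per-atom energy parameters
#'
#' Reads a plain CSV table with header
#' `name,charge,rmin_half,epsilon,gb_radius,gb_screen` (one row per atom, in
#' topology order). When a `topology` is supplied the row count must match its
#' atom count; rows are aligned by position and a warning is raised on atom
#' name mismatches.
#'
#' @param path CSV file.
#' @param topology optional [Structure-class] to validate against.
#' @return an [EnergyParameters-class].
#' @export
readParameters <- function(path, topology = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "charge", "rmin_half", "epsilon", "gb_radius", "gb_screen")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("parameter table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!is.null(topology)) {
    if (nrow(tab) < nAtoms(topology)) {
      absent <- topology@atomNames[(nrow(tab) + 1L):nAtoms(topology)]
      stop("missing parameter rows for atom(s): ",
           paste(unique(absent), collapse = ", "))
    }
    if (nrow(tab) > nAtoms(topology))
      stop("parameter table has ", nrow(tab), " rows but topology has ",
           nAtoms(topology), " atoms")
    if (any(tab$name != topology@atomNames))
      warning("parameter table atom names do not all match the topology; ",
              "rows aligned by position")
  }
  new("EnergyParameters", atomNames = as.character(tab$name),
      charge = as.numeric(tab$charge),
      ljRminHalf = as.numeric(tab$rmin_half),
      ljEpsilon = as.numeric(tab$epsilon),
      gbRadius = as.numeric(tab$gb_radius),
      gbScreen = as.numeric(tab$gb_screen))
}

#' Write per-atom energy parameters
#'
#' @param params an [EnergyParameters-class].
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
writeParameters <- function(params, path) {
  tab <- data.frame(name = params@atomNames, charge = params@charge,
                    rmin_half = params@ljRminHalf,
                    epsilon = params@ljEpsilon,
                    gb_radius = params@gbRadius,
                    gb_screen = params@gbScreen)
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
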