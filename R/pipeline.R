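.cfgGet <- function(cfg, path, default = NULL) {
  x <- cfg
  for (k in path) {
    if (is.null(x[[k]])) return(default)
    x <- x[[k]]
  }
  x
}

.writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
}

#' Run the full analysis pipeline from a declarative config
#'
#' Orchestrates equilibration detection, RMSD/RMSF profiling, functional
#' mode analysis, RMSD clustering and MM/GBSA binding energetics from a
#' single flat configuration (YAML file or named list), writing per-stage
#' CSV/JSON outputs plus a run log that echoes every setting. Stages are
#' run in order; a subset can be re-run via `stages`. The configuration is
#' validated up front: a missing file or unparsable selection aborts before
#' any output is written.
#'
#' Config keys (flat, with per-stage sections): `trajectory` (path),
#' `format` (`pdb`/`xyz`), `reference` (optional single-frame file),
#' `parameters` (optional CSV for the energy stage), `fit_selection`,
#' `report_selection`, `functional_selection` (enables the FMA stage),
#' `receptor`/`ligand` (enable the energy stage), `seed`, `output`, and
#' sections `equilibration` (`window`, `tolerance`), `rmsf` (`align`),
#' `fma` (`n_components`, `split`), `clustering` (`linkage`, `k_min`,
#' `k_max`, `stride`, `plateau_tol`), `energy` (`dielectric_in`,
#' `dielectric_solvent`, `gamma`, `beta`, `probe`, `sphere_points`,
#' `stride`, `start`).
#'
#' @param config path to a YAML file or a named list.
#' @param stages character subset of
#'   `c("equilibration", "rmsf", "fma", "clustering", "energy")`
#'   (default: all applicable).
#' @return (invisibly) a list with the per-stage results and the output
#'   directory.
#' @export
runPipeline <- function(config, stages = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  allStages <- c("equilibration", "rmsf", "fma", "clustering", "energy")
  if (is.null(stages)) stages <- allStages
  stages <- match.arg(stages, allStages, several.ok = TRUE)
  t0 <- Sys.time()

  # --- validate everything before writing anything
  trajPath <- .cfgGet(config, "trajectory")
  if (is.null(trajPath) || !file.exists(trajPath))
    stop("config error: trajectory file not found: ", trajPath)
  refPath <- .cfgGet(config, "reference")
  if (!is.null(refPath) && !file.exists(refPath))
    stop("config error: reference file not found: ", refPath)
  parPath <- .cfgGet(config, "parameters")
  if (!is.null(parPath) && !file.exists(parPath))
    stop("config error: parameter file not found: ", parPath)
  outDir <- .cfgGet(config, "output")
  if (is.null(outDir)) stop("config error: no output directory given")
  seed <- .cfgGet(config, "seed", 1L)

  format <- .cfgGet(config, "format", "pdb")
  traj <- readTrajectory(trajPath, format)
  top <- topology(traj)
  reference <- if (is.null(refPath)) {
    s <- top; s@coords <- frameCoords(traj, 1L); s
  } else topology(readTrajectory(refPath, format))
  sel <- function(key, default = NULL) {
    expr <- .cfgGet(config, key, default)
    if (is.null(expr)) NULL else makeSelection(top, expr)
  }
  fitSel <- sel("fit_selection", "all")
  repSel <- sel("report_selection")
  if (is.null(repSel)) repSel <- fitSel
  funSel <- sel("functional_selection")
  recSel <- sel("receptor")
  ligSel <- sel("ligand")
  params <- if (!is.null(parPath)) readParameters(parPath, top) else NULL
  if ("energy" %in% stages &&
      !is.null(recSel) && !is.null(ligSel) && is.null(params))
    stop("config error: energy stage needs a 'parameters' file")

  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  log <- c(sprintf("trajlens %s", as.character(utils::packageVersion("trajlens"))),
           sprintf("started %s", format(t0, "%Y-%m-%d %H:%M:%S")),
           sprintf("seed %d", seed),
           "config:",
           paste0("  ", utils::capture.output(utils::str(config))))
  results <- list(outputDir = outDir)
  timing <- function(stage, expr) {
    tic <- Sys.time()
    val <- tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
    log <<- c(log, sprintf("stage %-13s %8.2f s", stage,
                           as.numeric(difftime(Sys.time(), tic, units = "secs"))))
    val
  }

  eqStart <- 1L
  if ("equilibration" %in% stages) {
    results$equilibration <- timing("equilibration", {
      rs <- rmsdSeries(traj, reference, fitSel, repSel)
      write.csv(data.frame(frame = seq_along(rs@values),
                           time_ns = rs@times, rmsd_A = rs@values),
                file.path(outDir, "rmsd.csv"), row.names = FALSE)
      win <- .cfgGet(config, c("equilibration", "window"))
      tol <- .cfgGet(config, c("equilibration", "tolerance"), 0.3)
      t0f <- detectEquilibration(rs, window = win, tolerance = tol)
      .writeJson(list(start_frame = t0f, tolerance_A = tol),
                 file.path(outDir, "equilibration.json"))
      list(series = rs, startFrame = t0f)
    })
    eqStart <- results$equilibration$startFrame
  }

  if ("rmsf" %in% stages) {
    results$rmsf <- timing("rmsf", {
      align <- .cfgGet(config, c("rmsf", "align"), "mean-structure")
      prof <- rmsfPerResidue(traj, repSel, alignTo = align)
      write.csv(data.frame(resid = prof@residueIds, rmsf_A = prof@values),
                file.path(outDir, "rmsf.csv"), row.names = FALSE)
      prof
    })
  }

  if ("fma" %in% stages && !is.null(funSel)) {
    results$fma <- timing("fma", {
      model <- fitPCA(traj, fitSel)
      proj <- projectFrames(traj, model)
      f <- functionalRmsd(traj, funSel, reference, fitSelection = fitSel)
      nc <- .cfgGet(config, c("fma", "n_components"))
      split <- .cfgGet(config, c("fma", "split"), 0.5)
      fma <- fitFMA(model, proj, f, nComponents = nc, splitFraction = split)
      .writeJson(list(n_components = fma@nComponents,
                      r_train = fma@rTrain, r_cv = fma@rCv,
                      betas = fma@betas, intercept = fma@intercept),
                 file.path(outDir, "fma.json"))
      filt <- filterOnMode(traj, model, fma@ewmcm)
      writeTrajectory(filt, file.path(outDir, "fma_filtered.pdb"), "pdb")
      prof <- modeRmsf(filt)
      write.csv(data.frame(resid = prof@residueIds, rmsf_A = prof@values),
                file.path(outDir, "fma_mode_rmsf.csv"), row.names = FALSE)
      list(model = model, fma = fma, modeRmsf = prof)
    })
  }

  if ("clustering" %in% stages) {
    results$clustering <- timing("clustering", {
      kr <- seq(.cfgGet(config, c("clustering", "k_min"), 2L),
                .cfgGet(config, c("clustering", "k_max"), 8L))
      cl <- clusterTrajectory(
        traj, repSel,
        linkage = .cfgGet(config, c("clustering", "linkage"), "average"),
        kRange = kr,
        stride = .cfgGet(config, c("clustering", "stride")),
        plateauTol = .cfgGet(config, c("clustering", "plateau_tol"), 0.05))
      labs <- do.call(rbind, lapply(seq_along(cl@kRange), function(j)
        data.frame(frame = cl@frameIndices, k = cl@kRange[j],
                   cluster = cl@labelsByK[, j])))
      write.csv(labs, file.path(outDir, "cluster_labels.csv"),
                row.names = FALSE)
      write.csv(cl@metrics, file.path(outDir, "cluster_metrics.csv"),
                row.names = FALSE)
      .writeJson(list(chosen_k = cl@chosenK,
                      populations = as.list(cl@populations),
                      centroid_frames = as.list(cl@centroids)),
                 file.path(outDir, "populations.json"))
      cents <- Trajectory(lapply(cl@centroids, function(t)
        frameCoords(traj, t)), top)
      writeTrajectory(cents, file.path(outDir, "centroids.pdb"), "pdb")
      cl
    })
  }

  if ("energy" %in% stages && !is.null(recSel) && !is.null(ligSel)) {
    results$energy <- timing("energy", {
      en <- function(key, default) .cfgGet(config, c("energy", key), default)
      start <- en("start", eqStart)
      be <- trajectoryBindingEnergy(
        traj, recSel, ligSel, params, startFrame = start,
        stride = en("stride", 1L),
        dielectricIn = en("dielectric_in", 1),
        dielectricSolvent = en("dielectric_solvent", 78.5),
        gamma = en("gamma", 0.005), beta = en("beta", 0),
        probe = en("probe", 1.4), nSpherePoints = en("sphere_points", 960L))
      write.csv(be@perFrame, file.path(outDir, "be_totals.csv"),
                row.names = FALSE)
      .writeJson(list(mean_kcal_mol = be@mean, sd_kcal_mol = be@sd,
                      receptor = be@receptorLabel, ligand = be@ligandLabel),
                 file.path(outDir, "be_summary.json"))
      dec <- perResidueDecomposition(
        traj, recSel, ligSel, params, startFrame = start,
        stride = en("stride", 1L),
        dielectricIn = en("dielectric_in", 1),
        dielectricSolvent = en("dielectric_solvent", 78.5),
        gamma = en("gamma", 0.005), beta = en("beta", 0),
        probe = en("probe", 1.4), nSpherePoints = en("sphere_points", 960L))
      write.csv(residueTable(dec, all = TRUE),
                file.path(outDir, "be_residue.csv"), row.names = FALSE)
      list(binding = be, decomposition = dec)
    })
  }

  log <- c(log, sprintf("finished %8.2f s total",
                        as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  writeLines(log, file.path(outDir, "run_log.txt"))
  invisible(results)
}

#' Compare two pipeline runs
#'
#' Paired difference tables (run B minus run A) of per-residue RMSF,
#' per-residue binding-energy decomposition and cluster populations -- the
#' comparison surface for e.g. a wild-type versus mutant analysis. Residues
#' present in only one run are dropped to the intersection with a warning.
#'
#' @param dirA,dirB output directories of two completed [runPipeline()] runs.
#' @return list of data.frames: `rmsf` (resid, a, b, diff), `residues`
#'   (per-residue total BE diff), `populations`, and scalars
#'   `be_total_diff`.
#' @export
compareRuns <- function(dirA, dirB) {
  out <- list()
  fA <- file.path(dirA, "rmsf.csv"); fB <- file.path(dirB, "rmsf.csv")
  if (file.exists(fA) && file.exists(fB)) {
    a <- read.csv(fA); b <- read.csv(fB)
    m <- merge(a, b, by = "resid", suffixes = c("_a", "_b"))
    if (nrow(m) < max(nrow(a), nrow(b)))
      warning("rmsf residue ranges differ; aligned on intersection")
    out$rmsf <- data.frame(resid = m$resid, a = m$rmsf_A_a, b = m$rmsf_A_b,
                           diff = m$rmsf_A_b - m$rmsf_A_a)
  }
  fA <- file.path(dirA, "be_residue.csv"); fB <- file.path(dirB, "be_residue.csv")
  if (file.exists(fA) && file.exists(fB)) {
    a <- read.csv(fA); b <- read.csv(fB)
    m <- merge(a, b, by = c("chain", "residue_id"), suffixes = c("_a", "_b"))
    if (nrow(m) < max(nrow(a), nrow(b)))
      warning("decomposition residue ranges differ; aligned on intersection")
    out$residues <- data.frame(chain = m$chain, residue_id = m$residue_id,
                               a = m$total_a, b = m$total_b,
                               diff = m$total_b - m$total_a)
  }
  fA <- file.path(dirA, "be_summary.json"); fB <- file.path(dirB, "be_summary.json")
  if (file.exists(fA) && file.exists(fB)) {
    a <- jsonlite::read_json(fA); b <- jsonlite::read_json(fB)
    out$be_total_diff <- b$mean_kcal_mol - a$mean_kcal_mol
  }
  fA <- file.path(dirA, "populations.json"); fB <- file.path(dirB, "populations.json")
  if (file.exists(fA) && file.exists(fB)) {
    a <- jsonlite::read_json(fA); b <- jsonlite::read_json(fB)
    ks <- union(names(a$populations), names(b$populations))
    pa <- vapply(ks, function(k) {
      v <- a$populations[[k]]; if (is.null(v)) 0 else as.numeric(v)
    }, 0)
    pb <- vapply(ks, function(k) {
      v <- b$populations[[k]]; if (is.null(v)) 0 else as.numeric(v)
    }, 0)
    out$populations <- data.frame(cluster = ks, a = pa, b = pb,
                                  diff = pb - pa, row.names = NULL)
  }
  out
}
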