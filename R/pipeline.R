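# Unified run configuration and the end-to-end pipeline:
# simulate -> screen -> reconstruct (2D) -> post-process (3D) -> metrics,
# writing every intermediate artifact to an output directory.

#' Default run configuration
#'
#' Nested sections mirror the module configurations; every value can be
#' overridden through [resolveRunConfig()] or a YAML file via
#' [readRunConfig()].  The single global `seed` is fanned out to stage
#' sub-seeds as `seed + 1000003 * stage_index` (simulate is stage 1).
#'
#' @return nested list of defaults.
#' @export
defaultRunConfig <- function() {
  list(
    seed = 11L,
    phantom = list(outerRadius = 25, height = 5, insertCircleRadius = 15,
                   insertRadius = 2.5,
                   concentrations = seq(0.2, 1.2, by = 0.2)),
    geometry = list(standoff = 60, gap = 20, scatterSize = c(20, 20, 5),
                    absorberSize = c(50, 50, 5)),
    simulation = list(nEmissions = 5e5, sourceEnergy = 81,
                      fluorescenceEnergy = 68.8, blurScatter = 0.05,
                      blurAbsorber = 0.02, angleLaw = "klein_nishina"),
    filter = list(minDistance = 1.0, windowCenter = 68.8,
                  windowHalfwidth = 2.0, requireContainment = TRUE),
    grid = list(extent = c(50, 50, 5), spacing = 1),
    recon2d = list(nIter = 20, lambdaTV = 0.01, beta = 1.0,
                   tvMode = "as_written", sigmaConeDeg = 2),
    recon3d = list(lambdaTV3d = 0.01, epsilonDiff = 1e-6,
                   nDiffusionSteps = 10, stepSize = 0.1,
                   waveletFamily = "haar", levels = 2,
                   waveletThreshold = 0.01, isoThreshold = 0.001),
    metrics = list(exclusionMargin = 1, bestIteration = 10))
}

.mergeConfig <- function(base, user, path = "") {
  for (nm in names(user)) {
    if (!nm %in% names(base))
      stop("unknown configuration key: ", path, nm)
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- .mergeConfig(base[[nm]], user[[nm]],
                                 paste0(path, nm, "$"))
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Resolve a (partial) run configuration against the defaults
#'
#' Unknown keys are rejected; every defaulted value is present in the
#' result, which can be dumped and re-fed byte-identically.
#'
#' @param user partial nested list (or NULL for pure defaults).
#' @return complete configuration list.
#' @export
resolveRunConfig <- function(user = NULL) {
  cfg <- defaultRunConfig()
  if (!is.null(user)) cfg <- .mergeConfig(cfg, user)
  cfg
}

#' Read a YAML run configuration
#'
#' @param path YAML file with any subset of the [defaultRunConfig()]
#'   keys.
#' @return resolved configuration list.
#' @export
readRunConfig <- function(path) {
  resolveRunConfig(yaml::read_yaml(path))
}

#' Write a resolved configuration dump
#'
#' @param cfg configuration list.
#' @param path output YAML path.
#' @return invisibly, the path.
#' @export
writeRunConfig <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

.stageSeed <- function(seed, stage) as.integer(seed + 1000003 * stage)

# Build module objects from a resolved config.
.configObjects <- function(cfg) {
  phantom <- buildPhantom(outerRadius = cfg$phantom$outerRadius,
                          height = cfg$phantom$height,
                          insertCircleRadius = cfg$phantom$insertCircleRadius,
                          insertRadius = cfg$phantom$insertRadius,
                          concentrations = cfg$phantom$concentrations)
  geometry <- detectorGeometry(standoff = cfg$geometry$standoff,
                               gap = cfg$geometry$gap,
                               scatterSize = cfg$geometry$scatterSize,
                               absorberSize = cfg$geometry$absorberSize)
  sim <- simulationConfig(nEmissions = cfg$simulation$nEmissions,
                          sourceEnergy = cfg$simulation$sourceEnergy,
                          fluorescenceEnergy =
                            cfg$simulation$fluorescenceEnergy,
                          blurScatter = cfg$simulation$blurScatter,
                          blurAbsorber = cfg$simulation$blurAbsorber,
                          seed = .stageSeed(cfg$seed, 1L),
                          angleLaw = cfg$simulation$angleLaw)
  filt <- filterConfig(minDistance = cfg$filter$minDistance,
                       windowCenter = cfg$filter$windowCenter,
                       windowHalfwidth = cfg$filter$windowHalfwidth,
                       requireContainment = cfg$filter$requireContainment)
  grid <- makeGrid(cfg$grid$extent, cfg$grid$spacing)
  r2 <- recon2dConfig(nIter = cfg$recon2d$nIter,
                      lambdaTV = cfg$recon2d$lambdaTV,
                      beta = cfg$recon2d$beta,
                      tvMode = cfg$recon2d$tvMode)
  r3 <- recon3dConfig(lambdaTV3d = cfg$recon3d$lambdaTV3d,
                      epsilonDiff = cfg$recon3d$epsilonDiff,
                      nDiffusionSteps = cfg$recon3d$nDiffusionSteps,
                      stepSize = cfg$recon3d$stepSize,
                      waveletFamily = cfg$recon3d$waveletFamily,
                      levels = cfg$recon3d$levels,
                      waveletThreshold = cfg$recon3d$waveletThreshold,
                      isoThreshold = cfg$recon3d$isoThreshold)
  list(phantom = phantom, geometry = geometry, sim = sim, filt = filt,
       grid = grid, r2 = r2, r3 = r3,
       sigmaCone = cfg$recon2d$sigmaConeDeg * pi / 180)
}

#' Run the full pipeline
#'
#' simulate -> filter -> reconstruct2d -> reconstruct3d -> metrics,
#' writing events, kept events, the filter and efficiency reports,
#' per-iteration volumes, the mesh, metrics tables, the resolved config
#' and a stage log into `outDir`.  Identical config + seed reproduce all
#' artifacts byte-identically.
#'
#' @param config resolved configuration ([resolveRunConfig()]).
#' @param outDir output directory (created if missing).
#' @param verbose print stage progress.
#' @return invisibly, a list with the in-memory stage results and
#'   artifact paths.
#' @export
runPipeline <- function(config = resolveRunConfig(), outDir,
                        verbose = FALSE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logLines <- character()
  note <- function(stage, msg) {
    line <- sprintf("[%s] %s", stage, msg)
    logLines <<- c(logLines, line)
    if (verbose) message(line)
  }
  writeRunConfig(config, file.path(outDir, "resolved_config.yaml"))

  stage <- "simulate"
  res <- tryCatch({
    ob <- .configObjects(config)
    ev <- simulateDataset(ob$phantom, ob$geometry, ob$sim)
    note(stage, sprintf("%d events accepted (seed %d)", nEvents(ev),
                        ob$sim$seed))
    writeEvents(ev, file.path(outDir, "events.txt"))
    writeKeyValue(eventMetadata(ev)$efficiency,
                  file.path(outDir, "efficiency.txt"))

    stage <- "filter"
    fl <- filterEffective(ev, ob$filt, ob$geometry)
    note(stage, sprintf("%d of %d kept", fl$report[["kept"]],
                        fl$report[["input"]]))
    writeEvents(fl$events, file.path(outDir, "kept.txt"))
    writeKeyValue(as.list(fl$report), file.path(outDir,
                                                "filter_report.txt"))

    stage <- "recon2d"
    muVol <- muMap(ob$phantom, ob$grid, ob$sim$muTable)
    rec <- reconstruct2d(fl$events, ob$grid, muVol, ob$r2, ob$sigmaCone)
    note(stage, sprintf("%d iterations", ob$r2$nIter))
    volDir <- file.path(outDir, "volumes")
    dir.create(volDir, showWarnings = FALSE)
    for (it in seq_along(rec$volumes))
      writeVolume(rec$volumes[[it]],
                  file.path(volDir, sprintf("iter_%02d", it)))
    utils::write.csv(rec$log, file.path(outDir, "iteration_log.csv"),
                     row.names = FALSE)

    stage <- "recon3d"
    r3 <- reconstruct3d(rec, ob$r3)
    note(stage, sprintf("mesh: %d vertices", nrow(meshVertices(r3$mesh))))
    writeMeshPLY(r3$mesh, file.path(outDir, "isosurface.ply"))
    writeMeshOBJ(r3$mesh, file.path(outDir, "isosurface.obj"))
    writeVolume(r3$volume, file.path(outDir, "volume_post"))

    stage <- "metrics"
    best <- min(config$metrics$bestIteration, length(rec$volumes))
    arm <- armValues(fl$events)
    armTab <- if (sum(is.finite(arm)) >= 100)
      fwhmEstimate(arm) else list(fwhm = NA, fwhmGaussian = NA,
                                  binWidth = NA, multimodal = NA,
                                  peak = NA)
    rois <- phantomROIs(ob$phantom,
                        exclusionMargin = config$metrics$exclusionMargin)
    zmid <- ceiling(ob$grid@dims[3] / 2)
    slice <- intensities(rec$volumes[[best]])[, , zmid]
    cnrTab <- cnrSnr(slice, ob$grid, rois)
    utils::write.csv(cnrTab, file.path(outDir, "cnr_snr.csv"),
                     row.names = FALSE)
    writeKeyValue(list(armFWHMdeg = armTab$fwhm,
                       armFWHMGaussianDeg = armTab$fwhmGaussian,
                       armMultimodal = armTab$multimodal,
                       energyResolutionTotalPct =
                         energyResolution(eventData(fl$events)$Es +
                                          eventData(fl$events)$Ea)),
                  file.path(outDir, "metrics.txt"))
    note(stage, "done")
    list(events = ev, filtered = fl, recon = rec, recon3d = r3,
         cnr = cnrTab, arm = armTab)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "' (config: ",
         file.path(outDir, "resolved_config.yaml"), "): ",
         conditionMessage(e), call. = FALSE)
  })
  writeLines(logLines, file.path(outDir, "pipeline_log.txt"))
  invisible(c(res, list(outDir = outDir)))
}

#' Build a bundled test fixture
#'
#' `tiny`: a hand-checkable 3-voxel problem (identity-like system
#' matrix built from three synthetic events along one axis).  `demo`:
#' the seeded default phantom run at 2e4 emissions.
#'
#' @param scale `"tiny"` or `"demo"`.
#' @return list of fixture objects (events, grid and, for tiny, the
#'   expected matrix structure).
#' @export
makeFixture <- function(scale = c("tiny", "demo")) {
  scale <- match.arg(scale)
  if (scale == "tiny") {
    grid <- makeGrid(c(3, 1, 1), 1)
    en <- energiesFromAngle(68.8, pi / 2)
    mkEvent <- function(id, x0) {
      # source on the cone of a 90-degree event with apex above the voxel
      data.frame(event_id = id, side = "A", x0 = x0, y0 = 0, z0 = 0,
                 xs = x0, ys = 10, zs = 0, xa = x0 + 10, ya = 10, za = 0,
                 Es = en$E1, Ea = en$E2)
    }
    events <- comptonEvents(rbind(mkEvent(1, -1), mkEvent(2, 0),
                                  mkEvent(3, 1)))
    list(scale = scale, grid = grid, events = events)
  } else {
    cfg <- resolveRunConfig(list(seed = 11L))
    ob <- .configObjects(cfg)
    events <- simulateDataset(ob$phantom, ob$geometry, ob$sim)
    list(scale = scale, config = cfg, phantom = ob$phantom,
         geometry = ob$geometry, events = events, grid = ob$grid)
  }
}
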