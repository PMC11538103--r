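#' Pipeline configuration
#'
#' Bundles the per-stage configurations, the working resolution, the global
#' seed from which every stage derives its random substream, and the
#' checkpoint paths.
#'
#' @param seed Global integer seed.
#' @param workingResolution Isotropic working voxel size in mm, within
#'   (0, 1); 0.10 is the reference setting, up to 0.20 trades small-vessel
#'   detail for speed.
#' @param preprocess A [preprocessConfig()].
#' @param interval An [intensityInterval()].
#' @param spcnn An [spcnnConfig()].
#' @param patchSize CNN patch side in voxels.
#' @param probThreshold Segmentation probability cutoff.
#' @param tracking A [trackingConfig()].
#' @param forest A [stepForestConfig()].
#' @param screening A [screeningConfig()].
#' @param cnnCheckpoint,forestCheckpoint Optional paths to trained model
#'   checkpoints.
#' @return A `pipelineConfig` list.
#' @export
pipelineConfig <- function(seed = 1L, workingResolution = 0.10,
                           preprocess = preprocessConfig(workingResolution),
                           interval = intensityInterval(),
                           spcnn = spcnnConfig(),
                           patchSize = 25L, probThreshold = 0.5,
                           tracking = trackingConfig(),
                           forest = stepForestConfig(),
                           screening = screeningConfig(),
                           cnnCheckpoint = NULL, forestCheckpoint = NULL) {
  if (workingResolution <= 0 || workingResolution >= 1)
    stop("workingResolution must lie in (0, 1) mm")
  structure(as.list(environment()), class = "pipelineConfig")
}

#' Run the full phantom-to-morphometry pipeline
#'
#' Executes preprocess, segmentation, tracking, screening, modeling and
#' morphometry on one volume, writing every intermediate artifact plus a
#' machine-readable manifest (configuration, seed, checkpoint hashes, stage
#' wall times and voxel counts) to `outDir`. With fixed checkpoints, config
#' and seed, reruns are deterministic.
#'
#' @param volume Input [MRAVolume-class].
#' @param cnn A trained [SPCNN-class].
#' @param forest A trained `stepForest`.
#' @param config A [pipelineConfig()].
#' @param outDir Output directory (created).
#' @param largeMask Optional large-vessel override mask; by default the
#'   pre-screen's large-vessel mask is used.
#' @return List with `mask`, `branches`, `screened`, `model`, `morphometry`,
#'   `manifest`, invisibly written under `outDir`.
#' @export
runPipeline <- function(volume, cnn, forest, config = pipelineConfig(),
                        outDir = tempfile("lsarun"), largeMask = NULL) {
  if (!is(cnn, "SPCNN") || !cnn@trained)
    stop("pipeline stage 'segment' requires a trained SPCNN ",
         "(train one or pass cnnCheckpoint)")
  if (!inherits(forest, "stepForest"))
    stop("pipeline stage 'track' requires a trained step forest")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed,
                   workingResolution = config$workingResolution,
                   probThreshold = config$probThreshold,
                   stages = list())
  tick <- function(stage, expr) {
    t0 <- proc.time()[3]
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
    manifest$stages[[stage]] <<- list(seconds = round(proc.time()[3] - t0, 3))
    res
  }

  std <- tick("preprocess", preprocessVolume(volume, config$preprocess))
  manifest$stages$preprocess$voxels <- prod(dim(imgData(std)))
  writeVolume(std, file.path(outDir, "standardized.nii.gz"))

  pre <- prescreenCandidates(std, config$interval)
  mask <- tick("segment",
               segmentVolume(std, cnn, config$interval,
                             config$probThreshold, smallVesselsOnly = TRUE))
  manifest$stages$segment$vesselVoxels <- sum(imgData(mask))
  writeVolume(mask, file.path(outDir, "mask.nii.gz"))

  lm <- largeMask %||% cleanLargeVesselMask(pre$largeVesselMask)
  seeds <- detectSeeds(mask, lm, config$tracking)
  branchesRaw <- tick("track",
                      traceTree(seeds, mask, std, forest, config$tracking))
  writeBranchesJSON(branchesRaw, file.path(outDir, "branches_raw.json"))

  screened <- tick("screen",
                   screenBranches(branchesRaw, mask, lm, config$screening))
  writeBranchesJSON(screened, file.path(outDir, "branches.json"))

  result <- list(mask = mask, branches = branchesRaw, screened = screened,
                 model = NULL, morphometry = NULL)
  if (length(screened)) {
    model <- tick("model", buildVesselModel(screened, mask))
    tab <- tick("morphometry", morphometry(model))
    writeMorphometryCSV(tab, file.path(outDir, "morphometry.csv"))
    writeCenterlinesVTK(model, file.path(outDir, "centerlines.vtk"))
    result$model <- model
    result$morphometry <- tab
  }

  files <- list.files(outDir, full.names = TRUE)
  manifest$artifacts <- lapply(stats::setNames(files, basename(files)),
                               function(f) unname(tools::md5sum(f)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  result$manifest <- manifest
  invisible(result)
}
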