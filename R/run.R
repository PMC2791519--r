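#' Run a complete group model-selection map analysis
#'
#' End-to-end orchestration of one reproducible run: read the volumes named
#' in a manifest, optionally smooth them, apply the voxel-wise fixed- or
#' random-effects engine, threshold the resulting maps at `gamma`, and
#' write thresholded and unthresholded maps plus a JSON sidecar carrying
#' every parameter, the seed, input checksums, and convergence statistics —
#' enough to reproduce the run exactly.
#'
#' @param config a named list (or path to a JSON file) with fields:
#'   `manifest` (path or data.frame; see [readEvidenceVolumes()]),
#'   `out` (output directory), and optionally `method` ("rfx", default, or
#'   "ffx"), `mask` (path), `gamma` (default 0.75), `fwhmMm` (default 0, no
#'   smoothing), `alpha0`, `tol` (default 1e-4), `maxIter` (default 64),
#'   `epSamples` (default 1e6), `seed` (default 1).
#' @param quiet suppress progress messages (default `FALSE`).
#' @return Invisibly, the file manifest `data.frame` from [writeMaps()]
#'   (thresholded maps are written alongside under `thr_*`).
#' @seealso [bmsSimulate()] for generating a synthetic scenario to run on.
#' @export
bmsRun <- function(config, quiet = FALSE) {
  cfg <- normalizeRunConfig(config)
  say <- function(...) if (!quiet) message(...)

  say("reading volumes from manifest")
  set <- readEvidenceVolumes(cfg$manifest, maskPath = cfg$mask)
  say(sprintf("  %d subjects x %d models, %d in-mask voxels",
              nSubjects(set), nModels(set), sum(maskVolume(set))))

  if (any(cfg$fwhmMm > 0)) {
    say(sprintf("smoothing with FWHM = (%s) mm",
                paste(cfg$fwhmMm, collapse = ", ")))
    set <- smoothVolumes(set, cfg$fwhmMm)
  }

  t0 <- Sys.time()
  maps <- if (cfg$method == "rfx") {
    voxelwiseRfx(set, alpha0 = cfg$alpha0, tol = cfg$tol,
                 maxIter = cfg$maxIter, epSamples = cfg$epSamples,
                 seed = cfg$seed)
  } else {
    voxelwiseFfx(set)
  }
  maps@gamma <- cfg$gamma
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  say(sprintf("%s engine: %d voxels analysed in %.1f s",
              toupper(cfg$method), maps@metadata$nAnalysed, elapsed))

  maps@metadata$fwhmMm <- cfg$fwhmMm
  maps@metadata$wallTimeSec <- elapsed
  if (is.character(cfg$manifestPath)) {
    maps@metadata$inputChecksums <- inputChecksums(cfg$manifest, cfg$mask)
  }

  manifestOut <- writeMaps(maps, cfg$out)
  thrRows <- list()
  for (m in seq_along(modelNames(maps))) {
    safe <- gsub("[^A-Za-z0-9_.-]+", "_", modelNames(maps)[m])
    p <- file.path(cfg$out, sprintf("thr_ppm_%s.nii.gz", safe))
    writeVolume(thresholdMap(ppm(maps, m), cfg$gamma), affineMatrix(maps), p)
    thrRows[[length(thrRows) + 1L]] <- data.frame(
      type = "thr_ppm", model = modelNames(maps)[m], path = p,
      stringsAsFactors = FALSE
    )
    if (cfg$method == "rfx") {
      p <- file.path(cfg$out, sprintf("thr_epm_%s.nii.gz", safe))
      writeVolume(thresholdMap(epm(maps, m), cfg$gamma), affineMatrix(maps), p)
      thrRows[[length(thrRows) + 1L]] <- data.frame(
        type = "thr_epm", model = modelNames(maps)[m], path = p,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- rbind(manifestOut, do.call(rbind, thrRows))
  say("wrote ", nrow(out), " files to ", cfg$out)
  invisible(out)
}

# Validate and fill a run configuration. Errors name the offending field.
normalizeRunConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) {
    stop("'config' must be a named list or the path to a JSON file",
         call. = FALSE)
  }
  for (f in c("manifest", "out")) {
    if (is.null(config[[f]])) {
      stop("missing required config field: '", f, "'", call. = FALSE)
    }
  }
  cfg <- list(
    manifest = config$manifest,
    manifestPath = if (is.character(config$manifest)) config$manifest else NA,
    out = config$out,
    method = tolower(config$method %||% "rfx"),
    mask = config$mask,
    gamma = as.numeric(config$gamma %||% 0.75),
    fwhmMm = as.numeric(config$fwhmMm %||% 0),
    alpha0 = if (is.null(config$alpha0)) NULL else as.numeric(config$alpha0),
    tol = as.numeric(config$tol %||% 1e-4),
    maxIter = as.integer(config$maxIter %||% 64L),
    epSamples = as.numeric(config$epSamples %||% 1e6),
    seed = as.integer(config$seed %||% 1L)
  )
  if (!cfg$method %in% c("rfx", "ffx")) {
    stop("config field 'method' must be 'rfx' or 'ffx'", call. = FALSE)
  }
  if (is.na(cfg$gamma) || cfg$gamma < 0 || cfg$gamma > 1) {
    stop("config field 'gamma' must lie in [0, 1]", call. = FALSE)
  }
  if (length(cfg$fwhmMm) == 1L) cfg$fwhmMm <- rep(cfg$fwhmMm, 3L)
  if (any(is.na(cfg$fwhmMm)) || any(cfg$fwhmMm < 0)) {
    stop("config field 'fwhmMm' must be non-negative", call. = FALSE)
  }
  if (is.na(cfg$tol) || cfg$tol <= 0) {
    stop("config field 'tol' must be > 0", call. = FALSE)
  }
  if (is.na(cfg$maxIter) || cfg$maxIter < 1L) {
    stop("config field 'maxIter' must be >= 1", call. = FALSE)
  }
  if (is.na(cfg$epSamples) || cfg$epSamples < 1) {
    stop("config field 'epSamples' must be >= 1", call. = FALSE)
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

inputChecksums <- function(manifest, maskPath) {
  if (is.character(manifest)) {
    manifest <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  }
  paths <- c(as.character(manifest$path), maskPath)
  sums <- tools::md5sum(paths)
  as.list(stats::setNames(unname(sums), basename(paths)))
}

#' Generate and write a synthetic scenario
#'
#' Materialises a synthetic random-effects scenario on disk so it can be
#' analysed with [bmsRun()] or any external tool: either an outlier-group
#' log-evidence table (`type = "outlier"`) or a spatially structured volume
#' scenario (`type = "volumes"`, the default) written as one NIfTI volume
#' per subject and model plus a manifest, the ground-truth region volume,
#' and a JSON echo of all parameters and the seed.
#'
#' @param config a named list (or path to a JSON file) with fields `out`
#'   (output directory), optional `type` ("volumes" or "outlier"), optional
#'   `seed` (default 1), and the parameters of
#'   [simulateEvidenceVolumes()] / [makeOutlierScenario()] to override
#'   their defaults.
#' @return Invisibly, a list with the written file paths (for volume
#'   scenarios, `manifest` points at the subject x model table that
#'   [bmsRun()] consumes).
#' @export
bmsSimulate <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config) || is.null(config$out)) {
    stop("missing required config field: 'out'", call. = FALSE)
  }
  type <- config$type %||% "volumes"
  seed <- as.integer(config$seed %||% 1L)
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)

  if (type == "outlier") {
    lev <- makeOutlierScenario(
      nSubjects = config$nSubjects %||% 12L,
      majorityLogbf = config$majorityLogbf %||% -1,
      outlierLogbf = config$outlierLogbf %||% 30
    )
    levPath <- file.path(config$out, "logev.tsv")
    writeLogEvidence(lev, levPath)
    files <- list(logev = levPath)
  } else if (type == "volumes") {
    args <- config[intersect(names(config), names(formals(simulateEvidenceVolumes)))]
    args$seed <- seed
    sim <- do.call(simulateEvidenceVolumes, args)
    set <- sim$set
    rows <- list()
    for (s in seq_len(nSubjects(set))) {
      for (m in seq_len(nModels(set))) {
        p <- file.path(config$out, sprintf("logev_s%02d_m%d.nii.gz", s, m))
        writeVolume(volumeData(set)[, , , s, m], affineMatrix(set), p)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = subjectIds(set)[s], model = modelNames(set)[m], path = p,
          stringsAsFactors = FALSE
        )
      }
    }
    manifestPath <- file.path(config$out, "manifest.tsv")
    utils::write.table(do.call(rbind, rows), manifestPath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    truthPath <- file.path(config$out, "truth_region.nii.gz")
    writeVolume(array(as.numeric(sim$truthVolume), dim(sim$truthVolume)),
                affineMatrix(set), truthPath)
    files <- list(manifest = manifestPath, truth = truthPath)
  } else {
    stop("config field 'type' must be 'volumes' or 'outlier'", call. = FALSE)
  }

  echoPath <- file.path(config$out, "scenario.json")
  jsonlite::write_json(c(config, list(seedUsed = seed)), echoPath,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files$scenario <- echoPath
  invisible(files)
}
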