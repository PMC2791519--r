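#' Voxel-wise random-effects model-selection maps
#'
#' Applies the random-effects Dirichlet-multinomial fit ([rfxFit()])
#' independently at every in-mask voxel of a co-registered evidence-volume
#' set, producing a posterior probability map (PPM, the expected model
#' frequency `<r_k>`), an exceedance probability map (EPM, `phi_k`), and a
#' map of the fitted Dirichlet parameters for each model. Every voxel is
#' fitted from the same prior `alpha0`; no information is shared between
#' voxels. For K > 2 the Monte-Carlo exceedance step at each voxel uses a
#' seed derived deterministically from `(seed, voxel index)`, so results do
#' not depend on traversal order and are exactly reproducible.
#'
#' Voxels whose N x K matrix fails validation are recorded as unanalysed
#' (`NA` in all maps and counted in the metadata), not fatal.
#'
#' @param set an [EvidenceVolumeSet-class].
#' @param alpha0,tol,maxIter as in [rfxFit()].
#' @param epSamples Monte-Carlo samples per voxel for K > 2 exceedance
#'   probabilities (K = 2 is closed-form and deterministic).
#' @param seed base seed for per-voxel Monte-Carlo (K > 2 only).
#' @return A [BmsMaps-class] with `method = "rfx"`.
#' @export
voxelwiseRfx <- function(set, alpha0 = NULL, tol = 1e-4, maxIter = 64L,
                         epSamples = 1e6, seed = 1L) {
  stopifnot(is(set, "EvidenceVolumeSet"))
  d <- dim(set@data)
  grid <- d[1:3]
  n <- d[4L]
  k <- d[5L]
  if (is.null(alpha0)) alpha0 <- rep(1, k)

  nVox <- prod(grid)
  flat <- set@data
  dim(flat) <- c(nVox, n, k)
  voxIdx <- which(as.vector(set@mask))

  ppmFlat <- matrix(NA_real_, nVox, k)
  epmFlat <- matrix(NA_real_, nVox, k)
  alphaFlat <- matrix(NA_real_, nVox, k)
  iters <- integer(0)
  nFailed <- 0L
  nNotConverged <- 0L

  for (v in voxIdx) {
    mat <- matrix(flat[v, , ], n, k)
    fit <- tryCatch(
      rfxFit(mat, alpha0 = alpha0, tol = tol, maxIter = maxIter,
             epSamples = epSamples,
             seed = if (k > 2L) voxelSeed(seed, v) else NULL),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      nFailed <- nFailed + 1L
      next
    }
    ppmFlat[v, ] <- fit@expectedR
    epmFlat[v, ] <- fit@exceedance
    alphaFlat[v, ] <- fit@posterior@alpha
    iters <- c(iters, fit@iterations)
    if (!fit@converged) nNotConverged <- nNotConverged + 1L
  }

  meta <- list(
    alpha0 = alpha0, tol = tol, maxIter = as.integer(maxIter),
    epSamples = epSamples, seed = seed,
    nMaskVoxels = length(voxIdx),
    nAnalysed = length(voxIdx) - nFailed,
    nFailed = nFailed,
    nNotConverged = nNotConverged,
    iterationsMean = if (length(iters)) mean(iters) else NA_real_,
    iterationsMax = if (length(iters)) max(iters) else NA_integer_
  )
  new("BmsMaps",
      ppm = array(ppmFlat, c(grid, k)),
      epm = array(epmFlat, c(grid, k)),
      alphaMaps = array(alphaFlat, c(grid, k)),
      method = "rfx", gamma = NA_real_, affine = set@affine,
      modelNames = set@modelNames, metadata = meta)
}

#' Voxel-wise fixed-effects model-selection maps
#'
#' At every in-mask voxel, sums the log-evidence volumes over subjects for
#' each model, exponentiates the sums (after subtracting the per-voxel
#' maximum) and normalises to unity, yielding the fixed-effects posterior
#' model probability map. Exceedance probability maps are not defined for
#' fixed-effects analyses and are left absent. Fully deterministic.
#'
#' @param set an [EvidenceVolumeSet-class].
#' @return A [BmsMaps-class] with `method = "ffx"` and `epm = NULL`.
#' @export
voxelwiseFfx <- function(set) {
  stopifnot(is(set, "EvidenceVolumeSet"))
  d <- dim(set@data)
  grid <- d[1:3]
  k <- d[5L]
  nVox <- prod(grid)
  flat <- set@data
  dim(flat) <- c(nVox, d[4L], k)

  # summed log evidence per voxel and model
  lge <- apply(flat, c(1L, 3L), sum)
  mx <- apply(lge, 1L, max)
  z <- exp(lge - mx)
  post <- z / rowSums(z)
  post[!as.vector(set@mask), ] <- NA_real_

  meta <- list(
    nMaskVoxels = sum(set@mask),
    nAnalysed = sum(set@mask),
    nFailed = 0L
  )
  new("BmsMaps",
      ppm = array(post, c(grid, k)),
      epm = NULL, alphaMaps = NULL,
      method = "ffx", gamma = NA_real_, affine = set@affine,
      modelNames = set@modelNames, metadata = meta)
}

#' Threshold a probability map for display
#'
#' Keeps voxels whose value strictly exceeds the display threshold `gamma`
#' and sets all others to `NA`, so that sub-threshold voxels remain
#' distinguishable from voxels with probability near zero.
#'
#' @param volume numeric 3-D probability map (may contain `NA` for
#'   unanalysed voxels).
#' @param gamma threshold in `[0, 1]`.
#' @return The thresholded 3-D map.
#' @export
thresholdMap <- function(volume, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) ||
      gamma < 0 || gamma > 1) {
    stop("'gamma' must be a single value in [0, 1]", call. = FALSE)
  }
  out <- volume
  out[!(volume > gamma)] <- NA_real_
  out
}

#' Convert a probability map to the log-odds scale
#'
#' Maps each voxel probability p to its natural-log odds
#' `ln(p / (1 - p))`; probabilities of exactly 0 or 1 map to `-Inf` / `Inf`
#' and `NA` voxels are preserved. Log-odds spread the dynamic range of maps
#' whose values crowd against 1.
#'
#' @param volume numeric array of probabilities in `[0, 1]`.
#' @return Array of the same shape on the log-odds scale.
#' @export
toLogOdds <- function(volume) {
  ok <- !is.na(volume)
  if (any(volume[ok] < 0 | volume[ok] > 1)) {
    stop("'volume' must contain probabilities in [0, 1]", call. = FALSE)
  }
  log(volume / (1 - volume))
}

#' Write model-selection maps to NIfTI files
#'
#' Writes one volume per model for each available map type (`ppm_<model>`,
#' and for RFX also `epm_<model>` and `alpha_<model>`), carrying the input
#' affine unchanged, plus a JSON sidecar (`bms_run.json`) with the analysis
#' metadata: method, gamma, prior counts, tolerances, seed and iteration
#' statistics.
#'
#' @param maps a [BmsMaps-class].
#' @param outDir output directory (created if needed).
#' @return Invisibly, a `data.frame` manifest with columns `type`, `model`,
#'   `path`.
#' @export
writeMaps <- function(maps, outDir) {
  stopifnot(is(maps, "BmsMaps"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) {
    stop("cannot create output directory: ", outDir, call. = FALSE)
  }
  safe <- gsub("[^A-Za-z0-9_.-]+", "_", maps@modelNames)
  rows <- list()
  writeSet <- function(arr, type) {
    for (m in seq_along(maps@modelNames)) {
      p <- file.path(outDir, sprintf("%s_%s.nii.gz", type, safe[m]))
      writeVolume(arr[, , , m], maps@affine, p)
      rows[[length(rows) + 1L]] <<- data.frame(
        type = type, model = maps@modelNames[m], path = p,
        stringsAsFactors = FALSE
      )
    }
  }
  writeSet(maps@ppm, "ppm")
  if (!is.null(maps@epm)) writeSet(maps@epm, "epm")
  if (!is.null(maps@alphaMaps)) writeSet(maps@alphaMaps, "alpha")

  sidecar <- c(
    list(method = maps@method,
         gamma = if (is.na(maps@gamma)) NULL else maps@gamma,
         modelNames = maps@modelNames,
         affine = maps@affine),
    maps@metadata
  )
  sidecarPath <- file.path(outDir, "bms_run.json")
  jsonlite::write_json(sidecar, sidecarPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, matrix = "rowmajor")
  rows[[length(rows) + 1L]] <- data.frame(
    type = "sidecar", model = NA_character_, path = sidecarPath,
    stringsAsFactors = FALSE
  )
  invisible(do.call(rbind, rows))
}
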