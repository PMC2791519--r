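#' Simulate a random-effects group of log-evidence rows
#'
#' Draws a synthetic group under the random-effects generative model: each
#' subject's data-generating model is drawn from the population frequencies
#' `m_n ~ Multinomial(1, rTrue)`; the generating model's log evidence is
#' drawn from `Normal(effectMean, effectSd)` and every other model's from
#' `Normal(0, noiseSd)`, so evidence strength and between-subject
#' heterogeneity are controlled independently. The defaults
#' (`effectMean = 5`, `effectSd = 0`, `noiseSd = 0`) give every subject a
#' decisive 5-nat log Bayes factor in favour of its generating model.
#'
#' @param rTrue K-vector of true model frequencies (non-negative, sums to 1).
#' @param nSubjects number of subjects N (>= 1).
#' @param kModels number of models K (defaults to `length(rTrue)`).
#' @param effectMean mean log-evidence advantage of the generating model
#'   (nats).
#' @param effectSd standard deviation of that advantage (>= 0).
#' @param noiseSd standard deviation of the non-generating models' log
#'   evidences (>= 0).
#' @param seed optional seed; identical seeds give bitwise-identical output,
#'   and the caller's RNG state is restored.
#' @return A list with elements `logev` (a [LogEvidenceMatrix-class]) and
#'   `truth` (a [GroupSimTruth-class]).
#' @examples
#' sim <- simulateGroupLogev(c(0.7, 0.3), nSubjects = 20, seed = 1)
#' table(trueAssignments(sim$truth))
#' expectedR(rfxFit(sim$logev))
#' @export
simulateGroupLogev <- function(rTrue, nSubjects, kModels = length(rTrue),
                               effectMean = 5, effectSd = 0, noiseSd = 0,
                               seed = NULL) {
  assertSimplex(rTrue, "rTrue")
  nSubjects <- as.integer(nSubjects)
  if (nSubjects < 1L) stop("'nSubjects' must be >= 1", call. = FALSE)
  if (kModels != length(rTrue)) {
    stop("'kModels' must equal length(rTrue)", call. = FALSE)
  }
  if (effectSd < 0 || noiseSd < 0) {
    stop("'effectSd' and 'noiseSd' must be >= 0", call. = FALSE)
  }
  k <- length(rTrue)
  withSeed(seed, {
    assign <- sample.int(k, nSubjects, replace = TRUE, prob = rTrue)
    vals <- matrix(stats::rnorm(nSubjects * k, 0, noiseSd), nSubjects, k)
    eff <- stats::rnorm(nSubjects, effectMean, effectSd)
    vals[cbind(seq_len(nSubjects), assign)] <- eff
    truth <- new("GroupSimTruth", rTrue = as.numeric(rTrue),
                 assignments = as.integer(assign),
                 effectNats = eff,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
    list(logev = LogEvidenceMatrix(vals), truth = truth)
  })
}

#' Construct an outlier-group log-evidence matrix
#'
#' Builds the two-model group in which `nSubjects - 1` subjects carry a
#' log-evidence difference of `majorityLogbf` for model 1 over model 2
#' (negative values favour model 2) and one final subject carries
#' `outlierLogbf`. With the defaults (eleven subjects at -1, one at +30),
#' fixed-effects analysis is dominated by the single outlier and selects
#' model 1, while the random-effects analysis still favours model 2 — the
#' canonical demonstration of RFX robustness to outliers.
#'
#' @param nSubjects group size (>= 2).
#' @param majorityLogbf log Bayes factor (model 1 vs model 2, nats) carried
#'   by the first `nSubjects - 1` subjects.
#' @param outlierLogbf log Bayes factor carried by the last subject.
#' @return A [LogEvidenceMatrix-class] with `nSubjects` rows and 2 columns.
#' @examples
#' lev <- makeOutlierScenario(12)
#' posteriorProbs(ffxPosterior(lev))  # outlier drives model 1 near 1
#' expectedR(rfxFit(lev))             # model 2 still wins
#' @export
makeOutlierScenario <- function(nSubjects = 12L, majorityLogbf = -1,
                                outlierLogbf = 30) {
  nSubjects <- as.integer(nSubjects)
  if (nSubjects < 2L) stop("'nSubjects' must be >= 2", call. = FALSE)
  diffs <- c(rep(majorityLogbf, nSubjects - 1L), outlierLogbf)
  LogEvidenceMatrix(cbind(diffs, 0),
                    modelNames = c("model1", "model2"))
}

#' Simulate spatially structured log-evidence volumes
#'
#' Wraps [simulateGroupLogev()] into a volume scenario: inside a cuboid
#' active region the per-voxel subject rows are generated under
#' `rTrueInside`, elsewhere under `rTrueOutside`. By default a subject's
#' model assignment is a per-subject property shared across all voxels of a
#' compartment (one multinomial draw per subject inside the region and one
#' outside), which is the random-effects generative model applied to space;
#' `perVoxelAssignments = TRUE` instead redraws assignments independently at
#' every voxel and is intended only as a stress test, since it breaks the
#' within-subject spatial coherence real log-evidence maps have.
#'
#' @param gridShape integer 3-vector of grid dimensions.
#' @param voxelSizeMm numeric 3-vector of voxel sizes in millimetres.
#' @param activeRegion list with elements `min` and `max`, the inclusive
#'   voxel-index corners of the active cuboid.
#' @param rTrueInside,rTrueOutside model-frequency simplices inside/outside
#'   the region.
#' @param nSubjects group size.
#' @param effectMean log-evidence advantage (nats) of a subject's
#'   generating model at every voxel.
#' @param seed optional seed (restores the caller's RNG state).
#' @param perVoxelAssignments redraw assignments at every voxel
#'   (stress-test mode; default `FALSE`).
#' @return A list with `set` (an [EvidenceVolumeSet-class]), `truthVolume`
#'   (logical 3-D array marking the active region), and `truthInside`,
#'   `truthOutside` (the two [GroupSimTruth-class] objects; `NULL` in
#'   per-voxel mode).
#' @export
simulateEvidenceVolumes <- function(gridShape = c(8L, 8L, 8L),
                                    voxelSizeMm = c(3, 3, 3),
                                    activeRegion = list(min = c(3L, 3L, 3L),
                                                        max = c(5L, 5L, 5L)),
                                    rTrueInside = c(0.9, 0.1),
                                    rTrueOutside = c(0.5, 0.5),
                                    nSubjects = 12L,
                                    effectMean = 3,
                                    seed = NULL,
                                    perVoxelAssignments = FALSE) {
  gridShape <- as.integer(gridShape)
  stopifnot(length(gridShape) == 3L, all(gridShape >= 1L))
  assertSimplex(rTrueInside, "rTrueInside")
  assertSimplex(rTrueOutside, "rTrueOutside")
  if (length(rTrueInside) != length(rTrueOutside)) {
    stop("'rTrueInside' and 'rTrueOutside' must have the same length",
         call. = FALSE)
  }
  lo <- as.integer(activeRegion$min)
  hi <- as.integer(activeRegion$max)
  if (length(lo) != 3L || length(hi) != 3L || any(lo < 1L) ||
      any(hi > gridShape) || any(lo > hi)) {
    stop("'activeRegion' must be a cuboid inside the grid ",
         "(1 <= min <= max <= gridShape)", call. = FALSE)
  }
  n <- as.integer(nSubjects)
  k <- length(rTrueInside)

  truthVolume <- array(FALSE, gridShape)
  truthVolume[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  inside <- as.vector(truthVolume)
  nVox <- prod(gridShape)

  affine <- diag(c(voxelSizeMm, 1))

  withSeed(seed, {
    flat <- array(0, c(nVox, n, k))
    truthIn <- truthOut <- NULL
    if (perVoxelAssignments) {
      for (v in seq_len(nVox)) {
        r <- if (inside[v]) rTrueInside else rTrueOutside
        a <- sample.int(k, n, replace = TRUE, prob = r)
        flat[cbind(v, seq_len(n), a)] <- effectMean
      }
    } else {
      aIn <- sample.int(k, n, replace = TRUE, prob = rTrueInside)
      aOut <- sample.int(k, n, replace = TRUE, prob = rTrueOutside)
      for (s in seq_len(n)) {
        flat[inside, s, aIn[s]] <- effectMean
        flat[!inside, s, aOut[s]] <- effectMean
      }
      mkTruth <- function(r, a) {
        new("GroupSimTruth", rTrue = as.numeric(r),
            assignments = as.integer(a),
            effectNats = rep(as.numeric(effectMean), n),
            seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
      }
      truthIn <- mkTruth(rTrueInside, aIn)
      truthOut <- mkTruth(rTrueOutside, aOut)
    }
    set <- EvidenceVolumeSet(array(flat, c(gridShape, n, k)),
                             affine = affine)
    list(set = set, truthVolume = truthVolume,
         truthInside = truthIn, truthOutside = truthOut)
  })
}
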