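#' @import methods
NULL

setClassUnion("arrayOrNULL", c("array", "NULL"))

#' Per-subject, per-model log model evidences
#'
#' An N x K matrix of log model evidences (natural-log units, nats): one row
#' per subject, one column per candidate model. This is the elementary input
#' to both fixed-effects and random-effects group model selection; upstream
#' it is typically a variational free-energy approximation to
#' \eqn{\log p(y_n \mid m_k)} at a single voxel or for a region.
#'
#' @slot values numeric matrix, N subjects x K models, all entries finite.
#' @slot subjectIds character vector of length N.
#' @slot modelNames character vector of length K.
#'
#' @seealso [LogEvidenceMatrix()], [rfxFit()], [ffxPosterior()]
#' @export
setClass("LogEvidenceMatrix",
  slots = c(
    values = "matrix",
    subjectIds = "character",
    modelNames = "character"
  )
)

setValidity("LogEvidenceMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("'values' must be a numeric matrix")
  if (nrow(v) < 1L) return("at least one subject is required (N >= 1)")
  if (ncol(v) < 2L) {
    return("model selection requires at least two models (K >= 2)")
  }
  if (length(object@subjectIds) != nrow(v)) {
    return("length(subjectIds) must equal nrow(values)")
  }
  if (length(object@modelNames) != ncol(v)) {
    return("length(modelNames) must equal ncol(values)")
  }
  bad <- which(!is.finite(v), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    return(sprintf(
      "non-finite log evidence for subject '%s', model '%s'",
      object@subjectIds[bad[1L, 1L]], object@modelNames[bad[1L, 2L]]
    ))
  }
  TRUE
})

#' Dirichlet posterior over model frequencies
#'
#' The conjugate posterior \eqn{p(r \mid Y; \alpha)} over the population
#' model-frequency simplex, parameterised by counts \eqn{\alpha}. After a
#' completed random-effects fit, \eqn{\sum_k \alpha_k = \sum_k \alpha_{0k} + N}:
#' the prior counts plus one (fractionally allocated) count per subject.
#'
#' @slot alpha numeric K-vector of positive Dirichlet parameters.
#' @slot alpha0 numeric K-vector of positive prior counts.
#' @slot nSubjects integer, number of subjects the posterior conditions on.
#'
#' @seealso [DirichletPosterior()], [expectedModelProbs()], [exceedanceProbs()]
#' @export
setClass("DirichletPosterior",
  slots = c(
    alpha = "numeric",
    alpha0 = "numeric",
    nSubjects = "integer"
  )
)

setValidity("DirichletPosterior", function(object) {
  if (length(object@alpha) < 2L) return("alpha must have length K >= 2")
  if (any(!is.finite(object@alpha)) || any(object@alpha <= 0)) {
    return("all Dirichlet parameters alpha must be finite and > 0")
  }
  if (length(object@alpha0) != length(object@alpha)) {
    return("alpha0 must have the same length as alpha")
  }
  if (any(!is.finite(object@alpha0)) || any(object@alpha0 <= 0)) {
    return("all prior counts alpha0 must be finite and > 0")
  }
  TRUE
})

#' Posterior model-assignment beliefs
#'
#' The variational posterior over the latent per-subject model indicators:
#' `g[n, k]` is the normalised belief that model k generated subject n's
#' data, each row summing to one. `u` holds the corresponding unnormalised
#' beliefs as computed (each row is scaled by a per-subject constant for
#' numerical stability, which leaves `g` unchanged).
#'
#' @slot g numeric N x K matrix, rows on the simplex.
#' @slot u numeric N x K matrix of (row-rescaled) unnormalised beliefs.
#' @export
setClass("AssignmentPosterior",
  slots = c(g = "matrix", u = "matrix")
)

setValidity("AssignmentPosterior", function(object) {
  g <- object@g
  if (any(g < 0) || any(g > 1)) return("all g must lie in [0, 1]")
  if (any(abs(rowSums(g) - 1) > 1e-10)) {
    return("each row of g must sum to 1 (tolerance 1e-10)")
  }
  if (!all(dim(object@u) == dim(g))) return("u and g must share dimensions")
  TRUE
})

#' Result of a random-effects group model-selection fit
#'
#' Bundles the Dirichlet posterior over model frequencies with the derived
#' summaries: expected model probabilities \eqn{\langle r_k \rangle},
#' exceedance probabilities \eqn{\varphi_k} (the belief that model k is more
#' frequent than every other model), expected model counts \eqn{\beta_k},
#' the assignment beliefs, and convergence diagnostics.
#'
#' @slot posterior a [DirichletPosterior-class].
#' @slot expectedR numeric K-vector summing to 1.
#' @slot exceedance numeric K-vector of exceedance probabilities.
#' @slot assignment an [AssignmentPosterior-class].
#' @slot beta numeric K-vector of expected model counts, summing to N.
#' @slot iterations integer, variational iterations used.
#' @slot converged logical convergence flag.
#' @seealso [rfxFit()]
#' @export
setClass("RfxResult",
  slots = c(
    posterior = "DirichletPosterior",
    expectedR = "numeric",
    exceedance = "numeric",
    assignment = "AssignmentPosterior",
    beta = "numeric",
    iterations = "integer",
    converged = "logical"
  )
)

setValidity("RfxResult", function(object) {
  k <- length(object@posterior@alpha)
  if (length(object@expectedR) != k || length(object@beta) != k) {
    return("expectedR and beta must have length K")
  }
  if (abs(sum(object@expectedR) - 1) > 1e-10) {
    return("expectedR must sum to 1 (tolerance 1e-10)")
  }
  n <- object@posterior@nSubjects
  if (abs(sum(object@beta) - n) > 1e-8) {
    return("beta must sum to the number of subjects (tolerance 1e-8)")
  }
  TRUE
})

#' Result of a fixed-effects (group Bayes factor) analysis
#'
#' Holds the per-model summed log evidences, the resulting posterior model
#' probabilities under a uniform model prior, and the K x K matrix of
#' pairwise log group Bayes factors
#' \eqn{\log GBF_{ij} = \sum_n \log p(y_n|m_i) - \sum_n \log p(y_n|m_j)}.
#'
#' @slot logGroupEvidence numeric K-vector of summed log evidences.
#' @slot posterior numeric K-vector on the simplex.
#' @slot logGBF numeric antisymmetric K x K matrix with zero diagonal.
#' @slot modelNames character K-vector.
#' @seealso [ffxPosterior()]
#' @export
setClass("FfxResult",
  slots = c(
    logGroupEvidence = "numeric",
    posterior = "numeric",
    logGBF = "matrix",
    modelNames = "character"
  )
)

setValidity("FfxResult", function(object) {
  p <- object@posterior
  if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-10) {
    return("posterior must lie in [0,1] and sum to 1 (tolerance 1e-10)")
  }
  TRUE
})

#' Co-registered per-subject, per-model log-evidence volumes
#'
#' A set of N x K three-dimensional log-evidence volumes sharing one voxel
#' grid and one voxel-to-world affine, together with the binary analysis
#' mask. Stored internally as a 5-D array indexed
#' `[x, y, z, subject, model]`. Inputs must be pre-registered to a common
#' space; no resampling is performed.
#'
#' @slot data numeric 5-D array, dims `c(gridShape, N, K)` (nats).
#' @slot affine numeric 4 x 4 voxel-to-world transform.
#' @slot mask logical 3-D array; analysis is restricted to `TRUE` voxels.
#' @slot subjectIds character N-vector.
#' @slot modelNames character K-vector.
#' @seealso [readEvidenceVolumes()], [smoothVolumes()], [voxelwiseRfx()]
#' @export
setClass("EvidenceVolumeSet",
  slots = c(
    data = "array",
    affine = "matrix",
    mask = "array",
    subjectIds = "character",
    modelNames = "character"
  )
)

setValidity("EvidenceVolumeSet", function(object) {
  d <- dim(object@data)
  if (length(d) != 5L) return("data must be a 5-D array [x, y, z, N, K]")
  if (d[5L] < 2L) return("at least two models are required (K >= 2)")
  if (length(object@subjectIds) != d[4L]) {
    return("length(subjectIds) must equal dim(data)[4]")
  }
  if (length(object@modelNames) != d[5L]) {
    return("length(modelNames) must equal dim(data)[5]")
  }
  if (!all(dim(object@affine) == c(4L, 4L))) {
    return("affine must be a 4 x 4 matrix")
  }
  if (max(abs(object@affine[4L, ] - c(0, 0, 0, 1))) > 1e-6) {
    return("last affine row must be (0, 0, 0, 1)")
  }
  if (!is.logical(object@mask) || !all(dim(object@mask) == d[1:3])) {
    return("mask must be a logical array matching the voxel grid")
  }
  TRUE
})

#' Voxel-wise group model-selection maps
#'
#' Per-model posterior probability maps (PPM, the voxel-wise expected model
#' frequency for RFX or the FFX posterior model probability), exceedance
#' probability maps (EPM, RFX only), and Dirichlet alpha maps, all stored as
#' 4-D arrays `[x, y, z, model]`. Voxels outside the analysis mask carry
#' `NA`, which distinguishes "not analysed" from "probability near zero".
#'
#' @slot ppm numeric 4-D array `[x, y, z, K]`.
#' @slot epm 4-D array of exceedance probabilities, or `NULL` for FFX.
#' @slot alphaMaps 4-D array of Dirichlet parameters, or `NULL` for FFX.
#' @slot method `"rfx"` or `"ffx"`.
#' @slot gamma display threshold in `[0, 1]` (`NA` until thresholding).
#' @slot affine numeric 4 x 4 voxel-to-world transform, copied from input.
#' @slot modelNames character K-vector.
#' @slot metadata list of run parameters and diagnostics (smoothing FWHM,
#'   alpha0, tolerance, iteration statistics, seed, analysed-voxel count).
#' @seealso [voxelwiseRfx()], [voxelwiseFfx()], [writeMaps()]
#' @export
setClass("BmsMaps",
  slots = c(
    ppm = "array",
    epm = "arrayOrNULL",
    alphaMaps = "arrayOrNULL",
    method = "character",
    gamma = "numeric",
    affine = "matrix",
    modelNames = "character",
    metadata = "list"
  )
)

setValidity("BmsMaps", function(object) {
  d <- dim(object@ppm)
  if (length(d) != 4L) return("ppm must be a 4-D array [x, y, z, K]")
  if (!object@method %in% c("rfx", "ffx")) {
    return("method must be 'rfx' or 'ffx'")
  }
  if (length(object@modelNames) != d[4L]) {
    return("length(modelNames) must equal dim(ppm)[4]")
  }
  if (!is.na(object@gamma) && (object@gamma < 0 || object@gamma > 1)) {
    return("gamma must lie in [0, 1]")
  }
  ps <- apply(object@ppm, 4L, identity)
  TRUE
})

#' Ground truth of a simulated random-effects group
#'
#' Records the generating conditions of a synthetic group: the true model
#' frequencies on the simplex, the per-subject model assignments drawn from
#' them, the per-subject log-evidence advantage of the generating model, and
#' the seed, so every simulation is exactly reproducible.
#'
#' @slot rTrue numeric K-vector on the simplex.
#' @slot assignments integer N-vector in `1..K`.
#' @slot effectNats numeric N-vector, generating model's log-evidence
#'   advantage per subject (nats).
#' @slot seed integer seed used for the draw (`NA` if none given).
#' @seealso [simulateGroupLogev()]
#' @export
setClass("GroupSimTruth",
  slots = c(
    rTrue = "numeric",
    assignments = "integer",
    effectNats = "numeric",
    seed = "integer"
  )
)

setValidity("GroupSimTruth", function(object) {
  r <- object@rTrue
  if (any(r < 0) || abs(sum(r) - 1) > 1e-8) {
    return("rTrue must be non-negative and sum to 1")
  }
  k <- length(r)
  a <- object@assignments
  if (any(a < 1L) || any(a > k)) return("assignments must lie in 1..K")
  TRUE
})
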