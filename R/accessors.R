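#' Accessors for BMSmaps classes
#'
#' Small accessor functions exposing the slots of the package's S4 classes
#' without touching `@` directly.
#'
#' @param x the object.
#' @param model for [ppm()]/[epm()] on a [BmsMaps-class]: optional model
#'   name or index; if given, the single 3-D map for that model is returned,
#'   otherwise the full 4-D array.
#' @return The corresponding slot (see each class's documentation).
#' @name accessors
#' @aliases evidence subjectIds modelNames nSubjects nModels alphaPost
#'   alphaPrior dirichletPosterior expectedR exceedance assignments
#'   modelCounts iterations converged posteriorProbs logGroupEvidence
#'   logGBF volumeData maskVolume affineMatrix gridShape ppm epm alphaMaps
#'   mapMethod rTrue trueAssignments
NULL

#' @rdname accessors
setMethod("evidence", "LogEvidenceMatrix", function(x) {
  m <- x@values
  dimnames(m) <- list(x@subjectIds, x@modelNames)
  m
})

#' @rdname accessors
setMethod("subjectIds", "LogEvidenceMatrix", function(x) x@subjectIds)
#' @rdname accessors
setMethod("modelNames", "LogEvidenceMatrix", function(x) x@modelNames)
#' @rdname accessors
setMethod("nSubjects", "LogEvidenceMatrix", function(x) nrow(x@values))
#' @rdname accessors
setMethod("nModels", "LogEvidenceMatrix", function(x) ncol(x@values))

#' @rdname accessors
setMethod("subjectIds", "EvidenceVolumeSet", function(x) x@subjectIds)
#' @rdname accessors
setMethod("modelNames", "EvidenceVolumeSet", function(x) x@modelNames)
#' @rdname accessors
setMethod("nSubjects", "EvidenceVolumeSet", function(x) dim(x@data)[4L])
#' @rdname accessors
setMethod("nModels", "EvidenceVolumeSet", function(x) dim(x@data)[5L])
#' @rdname accessors
setMethod("volumeData", "EvidenceVolumeSet", function(x) x@data)
#' @rdname accessors
setMethod("maskVolume", "EvidenceVolumeSet", function(x) x@mask)
#' @rdname accessors
setMethod("affineMatrix", "EvidenceVolumeSet", function(x) x@affine)
#' @rdname accessors
setMethod("gridShape", "EvidenceVolumeSet", function(x) dim(x@data)[1:3])

#' @rdname accessors
setMethod("alphaPost", "DirichletPosterior", function(x) x@alpha)
#' @rdname accessors
setMethod("alphaPrior", "DirichletPosterior", function(x) x@alpha0)
#' @rdname accessors
setMethod("nSubjects", "DirichletPosterior", function(x) x@nSubjects)

#' @rdname accessors
setMethod("assignments", "AssignmentPosterior", function(x) x@g)

#' @rdname accessors
setMethod("dirichletPosterior", "RfxResult", function(x) x@posterior)
#' @rdname accessors
setMethod("alphaPost", "RfxResult", function(x) x@posterior@alpha)
#' @rdname accessors
setMethod("expectedR", "RfxResult", function(x) x@expectedR)
#' @rdname accessors
setMethod("exceedance", "RfxResult", function(x) x@exceedance)
#' @rdname accessors
setMethod("assignments", "RfxResult", function(x) x@assignment@g)
#' @rdname accessors
setMethod("modelCounts", "RfxResult", function(x) x@beta)
#' @rdname accessors
setMethod("iterations", "RfxResult", function(x) x@iterations)
#' @rdname accessors
setMethod("converged", "RfxResult", function(x) x@converged)

#' @rdname accessors
setMethod("posteriorProbs", "FfxResult", function(x) {
  stats::setNames(x@posterior, x@modelNames)
})
#' @rdname accessors
setMethod("logGroupEvidence", "FfxResult", function(x) {
  stats::setNames(x@logGroupEvidence, x@modelNames)
})
#' @rdname accessors
setMethod("logGBF", "FfxResult", function(x) x@logGBF)

.pickModelMap <- function(arr, names, model) {
  if (is.character(model)) model <- match(model, names)
  if (is.na(model) || model < 1L || model > length(names)) {
    stop("unknown model: ", model, call. = FALSE)
  }
  arr[, , , model, drop = TRUE]
}

#' @rdname accessors
setMethod("ppm", "BmsMaps", function(x, model) {
  if (missing(model)) x@ppm else .pickModelMap(x@ppm, x@modelNames, model)
})
#' @rdname accessors
setMethod("epm", "BmsMaps", function(x, model) {
  if (is.null(x@epm)) {
    stop("exceedance probability maps are only defined for RFX analyses",
         call. = FALSE)
  }
  if (missing(model)) x@epm else .pickModelMap(x@epm, x@modelNames, model)
})
#' @rdname accessors
setMethod("alphaMaps", "BmsMaps", function(x) x@alphaMaps)
#' @rdname accessors
setMethod("mapMethod", "BmsMaps", function(x) x@method)
#' @rdname accessors
setMethod("modelNames", "BmsMaps", function(x) x@modelNames)
#' @rdname accessors
setMethod("affineMatrix", "BmsMaps", function(x) x@affine)

#' @rdname accessors
setMethod("rTrue", "GroupSimTruth", function(x) x@rTrue)
#' @rdname accessors
setMethod("trueAssignments", "GroupSimTruth", function(x) x@assignments)

setMethod("show", "LogEvidenceMatrix", function(object) {
  cat(sprintf(
    "LogEvidenceMatrix: %d subjects x %d models (nats)\n",
    nrow(object@values), ncol(object@values)
  ))
  cat("models:", paste(object@modelNames, collapse = ", "), "\n")
})

setMethod("show", "DirichletPosterior", function(object) {
  cat(sprintf(
    "DirichletPosterior over %d models (N = %d)\n",
    length(object@alpha), object@nSubjects
  ))
  cat("alpha:   ", paste(signif(object@alpha, 4), collapse = " "), "\n")
  cat("<r>:     ", paste(signif(expectedModelProbs(object), 4),
                         collapse = " "), "\n")
})

setMethod("show", "RfxResult", function(object) {
  cat(sprintf(
    "RfxResult: %d models, N = %d, %d iteration(s), %sconverged\n",
    length(object@expectedR), object@posterior@nSubjects,
    object@iterations, if (object@converged) "" else "NOT "
  ))
  cat("alpha:      ", paste(signif(object@posterior@alpha, 4),
                            collapse = " "), "\n")
  cat("<r>:        ", paste(signif(object@expectedR, 4), collapse = " "), "\n")
  cat("exceedance: ", paste(signif(object@exceedance, 4),
                            collapse = " "), "\n")
})

setMethod("show", "FfxResult", function(object) {
  cat(sprintf("FfxResult (group Bayes factor): %d models\n",
              length(object@posterior)))
  cat("posterior:", paste(signif(object@posterior, 4), collapse = " "), "\n")
})

setMethod("show", "EvidenceVolumeSet", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "EvidenceVolumeSet: %d x %d x %d grid, %d subjects x %d models\n",
    d[1L], d[2L], d[3L], d[4L], d[5L]
  ))
  cat(sprintf("in-mask voxels: %d of %d\n",
              sum(object@mask), prod(d[1:3])))
})

setMethod("show", "BmsMaps", function(object) {
  d <- dim(object@ppm)
  cat(sprintf(
    "BmsMaps (%s): %d x %d x %d grid, %d models\n",
    toupper(object@method), d[1L], d[2L], d[3L], d[4L]
  ))
  if (!is.na(object@gamma)) cat("thresholded at gamma =", object@gamma, "\n")
})

setMethod("show", "GroupSimTruth", function(object) {
  cat(sprintf(
    "GroupSimTruth: N = %d, K = %d, r_true = (%s)\n",
    length(object@assignments), length(object@rTrue),
    paste(signif(object@rTrue, 4), collapse = ", ")
  ))
})
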