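#' @export
setGeneric("evidence", function(x) standardGeneric("evidence"))

#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @export
setGeneric("modelNames", function(x) standardGeneric("modelNames"))

#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' @export
setGeneric("nModels", function(x) standardGeneric("nModels"))

#' @export
setGeneric("alphaPost", function(x) standardGeneric("alphaPost"))

#' @export
setGeneric("alphaPrior", function(x) standardGeneric("alphaPrior"))

#' @export
setGeneric("dirichletPosterior", function(x) standardGeneric("dirichletPosterior"))

#' @export
setGeneric("expectedR", function(x) standardGeneric("expectedR"))

#' @export
setGeneric("exceedance", function(x) standardGeneric("exceedance"))

#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))

#' @export
setGeneric("modelCounts", function(x) standardGeneric("modelCounts"))

#' @export
setGeneric("iterations", function(x) standardGeneric("iterations"))

#' @export
setGeneric("converged", function(x) standardGeneric("converged"))

#' @export
setGeneric("posteriorProbs", function(x) standardGeneric("posteriorProbs"))

#' @export
setGeneric("logGroupEvidence", function(x) standardGeneric("logGroupEvidence"))

#' @export
setGeneric("logGBF", function(x) standardGeneric("logGBF"))

#' @export
setGeneric("volumeData", function(x) standardGeneric("volumeData"))

#' @export
setGeneric("maskVolume", function(x) standardGeneric("maskVolume"))

#' @export
setGeneric("affineMatrix", function(x) standardGeneric("affineMatrix"))

#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))

#' @export
setGeneric("ppm", function(x, model) standardGeneric("ppm"))

#' @export
setGeneric("epm", function(x, model) standardGeneric("epm"))

#' @export
setGeneric("alphaMaps", function(x) standardGeneric("alphaMaps"))

#' @export
setGeneric("mapMethod", function(x) standardGeneric("mapMethod"))

#' @export
setGeneric("rTrue", function(x) standardGeneric("rTrue"))

#' @export
setGeneric("trueAssignments", function(x) standardGeneric("trueAssignments"))
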