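#' Fixed-effects (group Bayes factor) model selection
#'
#' Aggregates evidence over subjects under the fixed-effects assumption that
#' a single model generated every subject's data: the per-model log
#' evidences are summed over subjects (equivalently, per-subject Bayes
#' factors are multiplied into the group Bayes factor), and posterior model
#' probabilities are obtained by exponentiating the sums and normalising to
#' unity under a uniform model prior. The maximum summed log evidence is
#' subtracted before exponentiation for numerical stability.
#'
#' Because evidence is pooled multiplicatively, a single subject with an
#' extreme evidence value can dominate the group result; see [rfxFit()] for
#' the random-effects alternative that is robust to such outliers.
#'
#' @param logev a [LogEvidenceMatrix-class] or numeric N x K matrix of log
#'   evidences (nats).
#' @return An [FfxResult-class] with the summed log evidences, the posterior
#'   model probabilities, and the K x K matrix of pairwise log group Bayes
#'   factors `logGBF[i, j] = sum_n log p(y_n|m_i) - sum_n log p(y_n|m_j)`.
#' @examples
#' lev <- rbind(c(log(3), 0), c(log(3), 0)) # two subjects, BF = 3 each
#' res <- ffxPosterior(lev)
#' exp(logGBF(res)[1, 2]) # group Bayes factor = 9
#' posteriorProbs(res)    # c(0.9, 0.1)
#' @export
ffxPosterior <- function(logev) {
  logev <- asLogEvidence(logev)
  lge <- colSums(logev@values)
  z <- exp(lge - max(lge))
  post <- z / sum(z)
  lgbf <- outer(lge, lge, "-")
  dimnames(lgbf) <- list(logev@modelNames, logev@modelNames)
  new("FfxResult", logGroupEvidence = lge, posterior = post,
      logGBF = lgbf, modelNames = logev@modelNames)
}

#' Two-model posterior probability from a Bayes factor
#'
#' Under a uniform prior over two models, a Bayes factor `bf` for model 1
#' over model 2 gives posterior model probability `bf / (1 + bf)`. A Bayes
#' factor above 20 corresponds to a posterior probability above 0.95 and is
#' conventionally labelled 'strong' evidence.
#'
#' @param bf positive Bayes factor.
#' @return Posterior probability of the favoured model, in (0, 1).
#' @examples
#' posteriorFromBayesFactor(20)     # 20/21 ~= 0.952
#' evidenceStrength(25)             # "strong"
#' @seealso [evidenceStrength()]
#' @export
posteriorFromBayesFactor <- function(bf) {
  if (!is.numeric(bf) || length(bf) != 1L || !is.finite(bf) || bf <= 0) {
    stop("'bf' must be a single positive finite number", call. = FALSE)
  }
  bf / (1 + bf)
}

#' Conventional evidence-strength label for a Bayes factor
#'
#' Stratifies a Bayes factor into the conventional qualitative bands:
#' `"weak"` (BF <= 3), `"positive"` (3 < BF <= 20) and `"strong"`
#' (BF > 20, i.e. posterior probability above 0.95 under uniform priors).
#'
#' @inheritParams posteriorFromBayesFactor
#' @return A character label.
#' @export
evidenceStrength <- function(bf) {
  if (!is.numeric(bf) || length(bf) != 1L || !is.finite(bf) || bf <= 0) {
    stop("'bf' must be a single positive finite number", call. = FALSE)
  }
  if (bf > 20) "strong" else if (bf > 3) "positive" else "weak"
}
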